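# End-to-end run drivers: configuration, enumeration, metrics and report
# emission (solutions TSV, metrics TSV, run-metadata JSON).

#' Run configuration
#'
#' Validates everything before any LP is solved; the configuration is echoed
#' verbatim into the run metadata.
#'
#' @param model a [metabolic_model()] or a model file path.
#' @param product_exchange_id target product exchange reaction id.
#' @param medium optional medium (named vector, data frame or file path; see
#'   [apply_medium()]).
#' @param format model file format for [load_model()] when `model` is a path.
#' @param co2_exchange_id optional CO2 exchange id for the metrics table.
#' @param exclude reaction ids (or a plain-text file) excluded from the
#'   candidate set.
#' @param out_dir output directory for report files.
#' @param mode qualification mode, see [traversal_config()] (named
#'   explicitly here so it can never be mistaken for the `model` argument).
#' @param ... further fields forwarded to [traversal_config()].
#' @return a validated `run_config` list.
#' @export
run_config <- function(model, product_exchange_id, medium = NULL,
                       format = "auto", co2_exchange_id = NULL,
                       exclude = character(0), out_dir = NULL,
                       mode = c("rate_max", "rate_grnt"), ...) {
  mode <- match.arg(mode)
  if (is.character(model)) model <- load_model(model, format = format)
  stopifnot(inherits(model, "metabolic_model"))
  if (!is.null(medium)) model <- apply_medium(model, medium)
  if (!product_exchange_id %in% model$reactions$id) {
    stop("configuration error: unknown product exchange '",
         product_exchange_id, "'", call. = FALSE)
  }
  if (!is.null(co2_exchange_id) &&
      !co2_exchange_id %in% model$reactions$id) {
    stop("configuration error: unknown CO2 exchange '", co2_exchange_id, "'",
         call. = FALSE)
  }
  structure(
    list(
      model = model,
      product_exchange_id = product_exchange_id,
      co2_exchange_id = co2_exchange_id,
      exclude = exclude,
      out_dir = out_dir,
      traversal = traversal_config(mode = mode, ...)
    ),
    class = "run_config"
  )
}

#' Run the full enumeration pipeline
#'
#' Preprocessing, threshold computation, pruned traversal, and (when
#' `config$out_dir` is set) report files: `solutions.tsv`,
#' `run_metadata.json`. A run that finds zero solutions is still a success.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return a list with `enumeration` (the [enumerate_knockouts()] result),
#'   `preprocess` (the [preprocess_model()] report) and `paths` (files
#'   written, if any).
#' @export
#' @examples
#' cfg <- run_config(make_toy1(), "EX_P", target_level = 1, mode = "rate_grnt")
#' res <- run_enumeration(cfg, quiet = TRUE)
#' solutions(res$enumeration)
run_enumeration <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  t0 <- Sys.time()
  say("preprocessing model '", config$model$id, "'")
  prep <- preprocess_model(
    config$model,
    cutoff_fraction = config$traversal$biomass_cutoff_fraction,
    exclude = config$exclude,
    gene_mode = config$traversal$gene_mode
  )
  say("removable candidates: ", length(prep$removable))
  thresholds <- compute_thresholds(
    config$model, config$product_exchange_id, config$traversal
  )
  say("thresholds: gr_wt = ", format(thresholds$gr_wt),
      ", production threshold = ", format(thresholds$th_chemical))
  if (!config$product_exchange_id %in% reactions(prep$reduced_model)$id) {
    # the product pathway is structurally dead under this medium: reduction
    # removed its exchange, so no knockout strategy can exist
    say("product exchange is blocked under this medium: no solutions possible")
    enum <- enumerate_knockouts(
      prep$reduced_model, character(0), prep$reduced_model$objective,
      config$traversal, thresholds = thresholds
    )
    enum$product_exchange_id <- config$product_exchange_id
  } else {
    enum <- enumerate_knockouts(
      prep$reduced_model, prep$removable, config$product_exchange_id,
      config$traversal, thresholds = thresholds
    )
  }
  sol <- solutions(enum)
  say("level-by-level: visited ", enum$node_count, " nodes, found ",
      nrow(sol), " minimal ", config$traversal$mode, " solution(s)")
  if (nrow(sol) == 0) say("no qualifying knockout strategy at k <= ",
                          config$traversal$target_level)

  paths <- list()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    sol_path <- file.path(config$out_dir, "solutions.tsv")
    readr::write_tsv(format_solution_table(sol), sol_path)
    meta_path <- file.path(config$out_dir, "run_metadata.json")
    meta <- list(
      model = config$model$id,
      product_exchange = config$product_exchange_id,
      config = unclass(config$traversal),
      thresholds = thresholds,
      preprocessing = list(
        n_blocked = length(prep$blocked),
        n_dead_end_metabolites = length(prep$dead_end_metabolites),
        n_essential = length(prep$essential),
        n_removable = length(prep$removable),
        removable = prep$removable
      ),
      node_count = enum$node_count,
      lp_count = enum$lp_count,
      fva_count = enum$fva_count,
      n_solutions = nrow(sol),
      wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )
    jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- list(solutions = sol_path, metadata = meta_path)
  }
  list(enumeration = enum, preprocess = prep, paths = paths)
}

# 6 significant digits in report files; tests compare numbers with
# tolerances, never strings
format_solution_table <- function(sol) {
  num <- vapply(sol, is.numeric, logical(1)) & names(sol) != "level"
  sol[num] <- lapply(sol[num], signif, digits = 6)
  sol
}

#' Compute the metrics table for enumerated solutions
#'
#' @param config a [run_config()].
#' @param sol a solutions tibble (from [solutions()]) or a solutions TSV
#'   path written by [run_enumeration()].
#' @param substrate_uptake substrate uptake magnitude for yields; defaults
#'   to the largest allowed uptake among the model's exchanges.
#' @return the metrics tibble (also written to `metrics.tsv` when
#'   `config$out_dir` is set).
#' @export
run_metrics <- function(config, sol, substrate_uptake = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(sol)) {
    sol <- readr::read_tsv(sol, col_types = readr::cols(), progress = FALSE)
  }
  if (is.null(substrate_uptake)) {
    ex <- config$model$reactions[config$model$reactions$is_exchange, ]
    substrate_uptake <- max(-ex$lb, 0)
    if (substrate_uptake <= 0) {
      stop("no open uptake to normalize yields by; pass substrate_uptake",
           call. = FALSE)
    }
  }
  if (nrow(sol) == 0) {
    met <- evaluate_strategies(config$model, list(), config$product_exchange_id,
                               substrate_uptake,
                               co2_exchange_id = config$co2_exchange_id)
  } else {
    met <- evaluate_strategies(
      config$model, sol, config$product_exchange_id, substrate_uptake,
      co2_exchange_id = config$co2_exchange_id
    )
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(format_solution_table(met),
                     file.path(config$out_dir, "metrics.tsv"))
  }
  met
}
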