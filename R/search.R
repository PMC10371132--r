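# The pruned depth-first enumeration of knockout strategies.
#
# Tree semantics: the root (level 0) is the unperturbed strain; a node at
# level L deletes L reactions. A node's children extend its deletion set by
# one reaction from the node's *target space*: the removable reactions that
# can still carry flux at the node's growth optimum. A node is pruned
# (subtree skipped) iff its LP is infeasible or its growth falls below the
# biomass floor; both conditions are monotone under added knockouts, so no
# qualifying superset is ever lost. Sibling deduplication: children are
# expanded in lexicographic order and each expanded reaction is barred from
# the subtrees of its later siblings, so every unordered set is constructed
# at most once.

#' Traversal configuration
#'
#' @param target_level maximum knockout cardinality k (>= 1).
#' @param biomass_cutoff_fraction growth floor as a fraction of wild-type
#'   growth (default 0.01).
#' @param product_threshold_fraction production threshold as a fraction of
#'   the maximum theoretical production rate (default 0.05).
#' @param mode qualification mode reported by default: `"rate_max"` (best
#'   case production at optimal growth above threshold) or `"rate_grnt"`
#'   (guaranteed, i.e. minimum, production above threshold). Both rates are
#'   always computed and recorded.
#' @param target_space_rule `"fva_support"` (default): a removable reaction
#'   enters the target space when it *can* carry nonzero flux at the node's
#'   growth optimum (FVA at fraction 1). `"fba_support"`: only reactions with
#'   nonzero flux in the node's single FBA vertex (cheaper, one LP per node,
#'   but a degenerate optimum can hide a true solution behind the solver's
#'   arbitrary vertex choice).
#' @param gene_mode translate each strategy to gene deletions and evaluate
#'   the *effective* reaction set (targets plus co-knocked reactions).
#' @param max_target_level guard on k (default 6).
#' @param pinned reactions knocked out in every node before the search starts
#'   (heuristic pre-fixing; they do not count toward `target_level`).
#' @return a list of class `traversal_config`.
#' @export
traversal_config <- function(target_level = 2L,
                             biomass_cutoff_fraction = 0.01,
                             product_threshold_fraction = 0.05,
                             mode = c("rate_max", "rate_grnt"),
                             target_space_rule = c("fva_support", "fba_support"),
                             gene_mode = FALSE,
                             max_target_level = 6L,
                             pinned = character(0)) {
  mode <- match.arg(mode)
  target_space_rule <- match.arg(target_space_rule)
  stopifnot(
    target_level >= 1,
    biomass_cutoff_fraction > 0, biomass_cutoff_fraction < 1,
    product_threshold_fraction > 0, product_threshold_fraction < 1
  )
  if (target_level > max_target_level) {
    stop("configuration error: target_level ", target_level,
         " exceeds max_target_level ", max_target_level, call. = FALSE)
  }
  structure(
    list(
      target_level = as.integer(target_level),
      biomass_cutoff_fraction = biomass_cutoff_fraction,
      product_threshold_fraction = product_threshold_fraction,
      mode = mode,
      target_space_rule = target_space_rule,
      gene_mode = isTRUE(gene_mode),
      max_target_level = as.integer(max_target_level),
      pinned = pinned
    ),
    class = "traversal_config"
  )
}

#' Growth and production thresholds of a run
#'
#' Wild-type growth `gr_wt` is the FBA optimum of the base model;
#' `v_chemical` is the maximum theoretical production rate (product exchange
#' as objective); the production threshold is
#' `product_threshold_fraction * v_chemical` and the biomass floor
#' `biomass_cutoff_fraction * gr_wt`.
#'
#' @param model the medium-constrained base model.
#' @param product_exchange_id target product exchange reaction.
#' @param config a [traversal_config()].
#' @return list with `gr_wt`, `v_chemical`, `th_chemical`, `biomass_floor`.
#' @export
#' @examples
#' compute_thresholds(make_toy1(), "EX_P", traversal_config(1))
compute_thresholds <- function(model, product_exchange_id,
                               config = traversal_config()) {
  wt <- solve_fba(model)
  if (wt$status != "optimal") stop("infeasible base model", call. = FALSE)
  prod <- solve_fba(model, objective_id = product_exchange_id)
  if (prod$status != "optimal") stop("infeasible base model", call. = FALSE)
  v_chem <- prod$objective_value
  if (v_chem <= ZERO_TOL) {
    warning("maximum theoretical production rate is 0; threshold degenerates ",
            "to 0 and every growth-viable knockout set qualifies")
  }
  list(
    gr_wt = wt$objective_value,
    v_chemical = v_chem,
    th_chemical = config$product_threshold_fraction * v_chem,
    biomass_floor = config$biomass_cutoff_fraction * wt$objective_value
  )
}

# Does a node with the given growth/product rates qualify? Shared verbatim
# between the traversal and the exhaustive oracle so that discrepancies
# isolate traversal bugs, not threshold drift.
qualify_node <- function(growth, product_min, product_max, thresholds) {
  ok_growth <- !is.na(growth) && growth >= thresholds$biomass_floor - ZERO_TOL
  list(
    viable = ok_growth,
    rate_max = ok_growth && product_max >= thresholds$th_chemical - ZERO_TOL,
    rate_grnt = ok_growth && product_min >= thresholds$th_chemical - ZERO_TOL
  )
}

#' Target space of a node
#'
#' Removable reactions, minus those already deleted and minus `excluded`,
#' that can support flux at the node's growth optimum under the configured
#' rule. Returns `NULL` (the prune signal) when the node model is infeasible
#' or its growth falls below the floor.
#'
#' @param model the node's model (base model with the node's knockouts
#'   applied).
#' @param removable candidate reaction ids from preprocessing.
#' @param deleted reactions already deleted at this node.
#' @param rule `"fva_support"` or `"fba_support"`.
#' @param biomass_floor minimum acceptable growth.
#' @param excluded reactions barred by sibling deduplication.
#' @return list with `target_space` (lexicographically sorted), `flux_dist`
#'   (the node's FBA solution) and `growth`; or `NULL` to prune.
#' @export
identify_target_space <- function(model, removable, deleted = character(0),
                                  rule = c("fva_support", "fba_support"),
                                  biomass_floor = 0, excluded = character(0)) {
  rule <- match.arg(rule)
  fba <- solve_fba(model)
  if (fba$status != "optimal" || fba$objective_value < biomass_floor - ZERO_TOL) {
    return(NULL)
  }
  candidates <- setdiff(setdiff(removable, deleted), excluded)
  ts <- if (rule == "fba_support") {
    active <- names(fba$fluxes)[abs(fba$fluxes) > ZERO_TOL]
    intersect(candidates, active)
  } else {
    if (length(candidates) == 0) {
      character(0)
    } else {
      rng <- run_fva(model, reaction_ids = candidates, objective_fraction = 1)
      rng$reaction[rng$max_flux > ZERO_TOL | rng$min_flux < -ZERO_TOL]
    }
  }
  list(target_space = lex_sort(ts), flux_dist = fba, growth = fba$objective_value)
}

#' Children of a node
#'
#' One child per reaction in the node's target space not yet expanded by an
#' earlier sibling, in lexicographic order.
#'
#' @param deleted the node's deleted reaction set.
#' @param target_space the node's target space.
#' @param checked reactions already expanded at this level within this
#'   parent's expansion.
#' @return list of character vectors (each a child's deletion set).
#' @export
construct_subtree <- function(deleted, target_space, checked = character(0)) {
  purrr::map(lex_sort(setdiff(target_space, checked)),
             function(r) c(deleted, r))
}

#' Enumerate knockout strategies
#'
#' Depth-first traversal to depth `config$target_level`. Every visited node
#' at level >= 1 is tested for qualification (both modes are always
#' recorded); a node is pruned when its LP is infeasible or its growth falls
#' below the biomass floor. After traversal, a minimality post-filter keeps,
#' per mode, only sets with no qualifying proper subset.
#'
#' @param model the medium-constrained base model (typically the reduced
#'   model from [preprocess_model()]).
#' @param removable candidate reaction ids.
#' @param product_exchange_id target product exchange reaction.
#' @param config a [traversal_config()].
#' @param thresholds optional precomputed [compute_thresholds()] result.
#' @return a `knockout_enumeration` object: use [solutions()], [tidy()],
#'   [glance()] and [autoplot()][ggplot2::autoplot] on it. Counts: `node_count`
#'   (every constructed node incl. the root), `lp_count` (one node-level FBA
#'   per node), `fva_count` (all FVA solves).
#' @export
#' @examples
#' toy <- make_toy1()
#' enum <- enumerate_knockouts(toy, c("R3", "R4"), "EX_P",
#'                             traversal_config(1, mode = "rate_grnt"))
#' solutions(enum)
enumerate_knockouts <- function(model, removable, product_exchange_id,
                                config = traversal_config(),
                                thresholds = NULL) {
  stopifnot(inherits(config, "traversal_config"))
  if (!product_exchange_id %in% model$reactions$id) {
    stop("unknown product exchange '", product_exchange_id, "'", call. = FALSE)
  }
  if (is.null(thresholds)) {
    thresholds <- compute_thresholds(model, product_exchange_id, config)
  }
  base_model <- if (length(config$pinned)) {
    apply_knockouts(model, config$pinned)
  } else {
    model
  }

  state <- new.env(parent = emptyenv())
  state$node_count <- 0L
  state$lp_count <- 0L
  state$fva_count <- 0L
  state$records <- list()

  node_model <- function(deleted) apply_knockouts(base_model, deleted)

  visit <- function(deleted, level, excluded) {
    state$node_count <- state$node_count + 1L
    fva0 <- lp_counts()[["fva"]]
    # leaves need no target space: bar every candidate so no FVA is spent
    eff_excluded <- if (level >= config$target_level) removable else excluded
    ts <- identify_target_space(
      node_model(deleted), removable, deleted,
      rule = config$target_space_rule,
      biomass_floor = thresholds$biomass_floor,
      excluded = eff_excluded
    )
    state$lp_count <- state$lp_count + 1L
    state$fva_count <- state$fva_count + (lp_counts()[["fva"]] - fva0)
    if (is.null(ts)) return(invisible(NULL))   # prune: infeasible or below floor

    if (level >= 1L) {
      m <- node_model(deleted)
      fva0 <- lp_counts()[["fva"]]
      eff <- deleted
      genes <- character(0)
      co <- character(0)
      if (config$gene_mode) {
        plan <- plan_gene_deletions(deleted, base_model)
        genes <- plan$deleted_genes
        co <- plan$co_knocked
        eff <- lex_sort(union(deleted, co))
        m <- apply_knockouts(base_model, eff)
      }
      rates <- product_rates_at_optimal_growth(m, product_exchange_id)
      state$fva_count <- state$fva_count + (lp_counts()[["fva"]] - fva0)
      if (rates$status == "optimal") {
        q <- qualify_node(rates$growth, rates$product_min, rates$product_max,
                          thresholds)
        if (q$viable && (q$rate_max || q$rate_grnt)) {
          key <- canonical_set(eff)
          if (is.null(state$records[[key]])) {
            state$records[[key]] <- tibble::tibble(
              level = level,
              reactions = canonical_set(deleted),
              effective_reactions = key,
              genes = paste(genes, collapse = ";"),
              co_knocked = paste(co, collapse = ";"),
              growth = rates$growth,
              product_min = rates$product_min,
              product_max = rates$product_max,
              qualifies_max = q$rate_max,
              qualifies_grnt = q$rate_grnt
            )
          }
        }
      }
    }

    if (level >= config$target_level) return(invisible(NULL))
    checked <- character(0)
    for (child in construct_subtree(deleted, ts$target_space, checked)) {
      visit(child, level + 1L, excluded = c(excluded, checked))
      checked <- c(checked, child[length(child)])
    }
    invisible(NULL)
  }

  visit(character(0), 0L, character(0))

  records <- dplyr::bind_rows(state$records)
  if (nrow(records) == 0) {
    records <- tibble::tibble(
      level = integer(0), reactions = character(0),
      effective_reactions = character(0), genes = character(0),
      co_knocked = character(0), growth = numeric(0),
      product_min = numeric(0), product_max = numeric(0),
      qualifies_max = logical(0), qualifies_grnt = logical(0)
    )
  }
  records <- dplyr::arrange(records, .data$level, .data$reactions)
  records$minimal_max <- minimality_flags(records, "qualifies_max")
  records$minimal_grnt <- minimality_flags(records, "qualifies_grnt")

  structure(
    list(
      records = records,
      thresholds = thresholds,
      config = config,
      product_exchange_id = product_exchange_id,
      removable = removable,
      node_count = state$node_count,
      lp_count = state$lp_count,
      fva_count = state$fva_count
    ),
    class = "knockout_enumeration"
  )
}

# A qualifying set is minimal in a mode iff no qualifying proper subset
# exists in the same mode. Records arrive sorted by level, so earlier kept
# sets can only be subsets of later ones.
minimality_flags <- function(records, flag_col) {
  kept <- list()
  out <- logical(nrow(records))
  if (nrow(records) == 0) return(out)
  sets <- strsplit(records$reactions, ";", fixed = TRUE)
  for (i in seq_len(nrow(records))) {
    if (!records[[flag_col]][i]) next
    has_subset <- any(vapply(kept, function(s) all(s %in% sets[[i]]), logical(1)))
    if (!has_subset) {
      out[i] <- TRUE
      kept <- c(kept, sets[i])
    }
  }
  out
}

#' Qualified solutions of an enumeration
#'
#' @param enum a `knockout_enumeration`.
#' @param mode `"rate_max"`, `"rate_grnt"` or `"both"`; defaults to the mode
#'   the run was configured with.
#' @param minimal_only keep only sets with no qualifying proper subset
#'   (default `TRUE`, matching how solution counts are reported).
#' @return tibble of solutions.
#' @export
solutions <- function(enum, mode = NULL, minimal_only = TRUE) {
  stopifnot(inherits(enum, "knockout_enumeration"))
  mode <- mode %||% enum$config$mode
  r <- enum$records
  keep <- switch(mode,
    rate_max = if (minimal_only) r$minimal_max else r$qualifies_max,
    rate_grnt = if (minimal_only) r$minimal_grnt else r$qualifies_grnt,
    both = if (minimal_only) r$minimal_max | r$minimal_grnt else
      r$qualifies_max | r$qualifies_grnt,
    stop("unknown mode '", mode, "'", call. = FALSE)
  )
  r[keep, ]
}

#' @export
print.knockout_enumeration <- function(x, ...) {
  cat("<knockout_enumeration> k = ", x$config$target_level,
      ", mode = ", x$config$mode, "\n", sep = "")
  cat("  thresholds: gr_wt = ", format(x$thresholds$gr_wt),
      ", production threshold = ", format(x$thresholds$th_chemical), "\n", sep = "")
  cat("  nodes: ", x$node_count, " | node LPs: ", x$lp_count,
      " | FVA LPs: ", x$fva_count, "\n", sep = "")
  sol <- solutions(x)
  cat("  minimal solutions (", x$config$mode, "): ", nrow(sol), "\n", sep = "")
  invisible(x)
}

#' Tidy / summarize an enumeration
#'
#' `tidy()` returns the minimal solutions under the configured mode (one row
#' per strategy); `glance()` a one-row run summary with thresholds, node/LP
#' counts and per-mode solution counts.
#'
#' @param x a `knockout_enumeration`.
#' @param ... unused.
#' @export
tidy.knockout_enumeration <- function(x, ...) solutions(x)

#' @rdname tidy.knockout_enumeration
#' @export
glance.knockout_enumeration <- function(x, ...) {
  tibble::tibble(
    target_level = x$config$target_level,
    mode = x$config$mode,
    gr_wt = x$thresholds$gr_wt,
    v_chemical = x$thresholds$v_chemical,
    th_chemical = x$thresholds$th_chemical,
    biomass_floor = x$thresholds$biomass_floor,
    node_count = x$node_count,
    lp_count = x$lp_count,
    fva_count = x$fva_count,
    n_solutions_max = sum(x$records$minimal_max),
    n_solutions_grnt = sum(x$records$minimal_grnt)
  )
}
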