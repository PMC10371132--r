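#' Construct a metabolic model
#'
#' The central container of the package: a stoichiometric network with flux
#' bounds, gene-protein-reaction (GPR) rules and a biomass objective. All
#' tabular pieces are tibbles so they compose with dplyr verbs; the model
#' itself is a classed list, the field convention of constraint-based
#' modelling tools.
#'
#' @param id model identifier.
#' @param metabolites tibble with columns `id`, `compartment` and optionally
#'   `is_boundary` (boundary metabolites are excluded from the steady-state
#'   constraint).
#' @param reactions tibble with columns `id`, `lb`, `ub` (flux bounds,
#'   mmol/gDW/h), and optionally `gpr` (rule string, `""` for none) and `name`.
#'   Reversibility is encoded purely via `lb < 0`; reactions are never split.
#' @param stoich long-format tibble with columns `reaction`, `metabolite`,
#'   `coef` (dimensionless stoichiometric coefficients; negative = consumed).
#' @param objective id of the biomass (objective) reaction.
#' @param genes character vector of gene ids; defaults to the genes appearing
#'   in the GPR rules.
#'
#' @return an object of class `metabolic_model`.
#' @export
#' @examples
#' m <- make_toy1()
#' m
#' reactions(m)
metabolic_model <- function(id, metabolites, reactions, stoich, objective,
                            genes = NULL) {
  metabolites <- tibble::as_tibble(metabolites)
  reactions <- tibble::as_tibble(reactions)
  stoich <- tibble::as_tibble(stoich)
  if (!"is_boundary" %in% names(metabolites)) metabolites$is_boundary <- FALSE
  if (!"gpr" %in% names(reactions)) reactions$gpr <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  if (anyDuplicated(metabolites$id)) stop("duplicate metabolite ids", call. = FALSE)
  if (anyDuplicated(reactions$id)) stop("duplicate reaction ids", call. = FALSE)
  if (any(reactions$lb > reactions$ub)) {
    bad <- reactions$id[reactions$lb > reactions$ub][1]
    stop("reaction '", bad, "' has lb > ub", call. = FALSE)
  }
  unknown_met <- setdiff(stoich$metabolite, metabolites$id)
  if (length(unknown_met)) {
    stop("stoichiometry references undeclared metabolite '", unknown_met[1], "'",
         call. = FALSE)
  }
  unknown_rxn <- setdiff(stoich$reaction, reactions$id)
  if (length(unknown_rxn)) {
    stop("stoichiometry references undeclared reaction '", unknown_rxn[1], "'",
         call. = FALSE)
  }
  if (!objective %in% reactions$id) {
    stop("objective reaction '", objective, "' not in model", call. = FALSE)
  }
  gpr_genes_all <- unique(unlist(lapply(reactions$gpr, function(g) {
    if (!nzchar(g)) character(0) else gpr_genes(parse_gpr(g))
  })))
  if (is.null(genes)) genes <- gpr_genes_all
  missing_genes <- setdiff(gpr_genes_all, genes)
  if (length(missing_genes)) {
    stop("GPR gene '", missing_genes[1], "' absent from gene set", call. = FALSE)
  }

  model <- structure(
    list(
      id = id,
      metabolites = metabolites,
      reactions = reactions,
      stoich = stoich,
      objective = objective,
      genes = sort(unique(genes))
    ),
    class = "metabolic_model"
  )
  model$reactions$is_exchange <- detect_exchanges(model)
  model
}

# A reaction is exchange-like (boundary) when it touches exactly one
# non-boundary metabolite: substrate/product exchanges, demand and sink
# reactions, and single-metabolite drains all fall in this class.
detect_exchanges <- function(model) {
  internal_mets <- model$metabolites$id[!model$metabolites$is_boundary]
  counts <- model$stoich |>
    dplyr::filter(.data$metabolite %in% internal_mets) |>
    dplyr::count(.data$reaction)
  n_touch <- stats::setNames(counts$n, counts$reaction)
  unname(n_touch[model$reactions$id] == 1L & !is.na(n_touch[model$reactions$id]))
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n", sep = "")
  cat("  metabolites: ", nrow(x$metabolites),
      " | reactions: ", nrow(x$reactions),
      " (", sum(x$reactions$is_exchange), " exchange)",
      " | genes: ", length(x$genes), "\n", sep = "")
  cat("  objective: ", x$objective, "\n", sep = "")
  invisible(x)
}

#' Reaction and metabolite tables of a model
#'
#' @param model a [metabolic_model()].
#' @return a tibble (one row per reaction / metabolite).
#' @export
reactions <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  model$reactions
}

#' @rdname reactions
#' @export
metabolites <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  model$metabolites
}

#' Dense stoichiometric matrix
#'
#' Rows are non-boundary metabolites, columns reactions, in model order.
#'
#' @param model a [metabolic_model()].
#' @return a numeric matrix with dimnames.
#' @export
stoich_matrix <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  mets <- model$metabolites$id[!model$metabolites$is_boundary]
  rxns <- model$reactions$id
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  keep <- model$stoich$metabolite %in% mets
  sub <- model$stoich[keep, ]
  S[cbind(match(sub$metabolite, mets), match(sub$reaction, rxns))] <- sub$coef
  S
}

#' Set flux bounds of one reaction
#'
#' @param model a [metabolic_model()].
#' @param reaction_id reaction id.
#' @param lb,ub new bounds; `NULL` leaves the bound unchanged.
#' @return the modified model (the input is untouched).
#' @export
set_bounds <- function(model, reaction_id, lb = NULL, ub = NULL) {
  i <- match(reaction_id, model$reactions$id)
  if (is.na(i)) stop("unknown reaction '", reaction_id, "'", call. = FALSE)
  if (!is.null(lb)) model$reactions$lb[i] <- lb
  if (!is.null(ub)) model$reactions$ub[i] <- ub
  model
}

# id ordering used everywhere a canonical order is needed (children expansion,
# reported reaction sets): plain C-locale lexicographic sort.
lex_sort <- function(x) sort(x, method = "radix")

canonical_set <- function(ids) paste(lex_sort(ids), collapse = ";")
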