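# Preprocessing: blocked reactions, dead-end metabolites, essential
# reactions, and the Removable candidate-knockout set that bounds the
# search space before any traversal starts.

#' Find blocked reactions
#'
#' A reaction is blocked under the applied medium when its flux range,
#' without any objective requirement (FVA at objective fraction 0), is
#' `[0, 0]` within tolerance: it can never carry flux.
#'
#' @param model a medium-constrained [metabolic_model()].
#' @return character vector of blocked reaction ids.
#' @export
find_blocked_reactions <- function(model) {
  feas <- solve_fba(model)
  if (feas$status != "optimal") stop("infeasible model", call. = FALSE)
  rng <- run_fva(model, objective_fraction = 0)
  rng$reaction[abs(rng$min_flux) <= ZERO_TOL & abs(rng$max_flux) <= ZERO_TOL]
}

# can the reaction produce (resp. consume) the metabolite, given its bounds?
met_roles <- function(model) {
  st <- dplyr::left_join(
    model$stoich,
    model$reactions[c("id", "lb", "ub")],
    by = c("reaction" = "id")
  )
  st$can_produce <- (st$coef > 0 & st$ub > 0) | (st$coef < 0 & st$lb < 0)
  st$can_consume <- (st$coef < 0 & st$ub > 0) | (st$coef > 0 & st$lb < 0)
  st
}

#' Find dead-end metabolites
#'
#' Structural test on the stoichiometry and reaction reversibilities: a
#' (non-boundary) metabolite is a dead end when no reaction can produce it or
#' no reaction can consume it. Removing the reactions attached to a dead end
#' can expose further dead ends, so the test iterates to a fixed point and
#' reports every metabolite discovered along the way.
#'
#' @param model a [metabolic_model()].
#' @return character vector of dead-end metabolite ids.
#' @export
find_dead_end_metabolites <- function(model) {
  st <- met_roles(model)
  st <- st[st$metabolite %in% model$metabolites$id[!model$metabolites$is_boundary], ]
  dead <- character(0)
  active_rxns <- unique(st$reaction)
  repeat {
    cur <- st[st$reaction %in% active_rxns, ]
    summary <- cur |>
      dplyr::group_by(.data$metabolite) |>
      dplyr::summarise(
        producible = any(.data$can_produce),
        consumable = any(.data$can_consume),
        .groups = "drop"
      )
    new_dead <- summary$metabolite[!(summary$producible & summary$consumable)]
    new_dead <- setdiff(new_dead, dead)
    if (length(new_dead) == 0) break
    dead <- c(dead, new_dead)
    touching <- unique(cur$reaction[cur$metabolite %in% dead])
    active_rxns <- setdiff(active_rxns, touching)
  }
  lex_sort(dead)
}

#' Preprocess a model: reduced model and removable knockout candidates
#'
#' Produces the reduced model (blocked and dead-end-attached reactions
#' structurally removed) and the `removable` set of knockout candidates:
#' all reactions minus blocked, dead-end-orphaned, exchange/drain, essential,
#' user-excluded and (in gene mode) non-gene-associated reactions. A reaction
#' is *essential* when its single knockout drives growth below
#' `cutoff_fraction` of the wild-type optimum; exchanges and the objective
#' are never knockout candidates (the medium is an experimental control, not
#' a genetic intervention).
#'
#' @param model a medium-constrained [metabolic_model()].
#' @param cutoff_fraction growth floor as a fraction of wild-type growth
#'   (default 0.01).
#' @param exclude character vector of reaction ids (or a plain-text file of
#'   ids, one per line) to exclude from the candidate set.
#' @param gene_mode if `TRUE`, reactions without a GPR are additionally
#'   excluded (they cannot be deleted by gene knockout).
#' @return a `preprocess_report`: list with `blocked`,
#'   `dead_end_metabolites`, `orphaned`, `essential`, `removable`,
#'   `reduced_model`, `gr_wt`.
#' @export
#' @examples
#' rep <- preprocess_model(make_toy1())
#' rep$removable  # R3, R4
preprocess_model <- function(model, cutoff_fraction = 0.01,
                             exclude = character(0), gene_mode = FALSE) {
  stopifnot(inherits(model, "metabolic_model"))
  if (is.character(exclude) && length(exclude) == 1 && file.exists(exclude)) {
    exclude <- readLines(exclude, warn = FALSE)
    exclude <- trimws(exclude[nzchar(trimws(exclude))])
  }
  wt <- solve_fba(model)
  if (wt$status != "optimal") stop("infeasible model", call. = FALSE)
  gr_wt <- wt$objective_value

  blocked <- find_blocked_reactions(model)
  dead <- find_dead_end_metabolites(model)
  orphaned <- unique(model$stoich$reaction[model$stoich$metabolite %in% dead])

  drop_rxns <- union(blocked, orphaned)
  drop_rxns <- setdiff(drop_rxns, model$objective)
  reduced <- remove_reactions(model, drop_rxns)

  floor_val <- cutoff_fraction * gr_wt
  candidates <- reduced$reactions$id
  candidates <- setdiff(candidates, reduced$reactions$id[reduced$reactions$is_exchange])
  candidates <- setdiff(candidates, reduced$objective)
  essential <- character(0)
  for (r in candidates) {
    ko <- solve_fba(apply_knockouts(reduced, r))
    g <- if (ko$status == "optimal") ko$objective_value else 0
    if (g < floor_val - ZERO_TOL) essential <- c(essential, r)
  }
  removable <- lex_sort(setdiff(candidates, c(essential, exclude)))
  if (gene_mode) {
    has_gpr <- nzchar(reduced$reactions$gpr)
    removable <- intersect(removable, reduced$reactions$id[has_gpr])
  }

  structure(
    list(
      blocked = lex_sort(blocked),
      dead_end_metabolites = dead,
      orphaned = lex_sort(setdiff(orphaned, blocked)),
      essential = lex_sort(essential),
      removable = removable,
      reduced_model = reduced,
      gr_wt = gr_wt
    ),
    class = "preprocess_report"
  )
}

# structural removal of reactions (and of metabolites left with no reaction)
remove_reactions <- function(model, reaction_ids) {
  if (length(reaction_ids) == 0) return(model)
  keep <- !model$reactions$id %in% reaction_ids
  model$reactions <- model$reactions[keep, ]
  model$stoich <- model$stoich[model$stoich$reaction %in% model$reactions$id, ]
  used <- unique(model$stoich$metabolite)
  model$metabolites <- model$metabolites[model$metabolites$id %in% used, ]
  model
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("<preprocess_report>\n")
  cat("  wild-type growth: ", format(x$gr_wt), "\n", sep = "")
  cat("  blocked: ", length(x$blocked),
      " | dead-end metabolites: ", length(x$dead_end_metabolites),
      " | essential: ", length(x$essential), "\n", sep = "")
  cat("  removable candidates: ", length(x$removable), "\n", sep = "")
  invisible(x)
}
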