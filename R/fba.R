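# Flux balance analysis (FBA), flux variability analysis (FVA), knockouts
# and product-rate queries at optimal growth: the LP layer every other
# module builds on.
#
# All solves go through the package's bounded-variable simplex (see
# simplex.R), which is deterministic for fixed input, so FBA vertex choice is
# reproducible run-to-run on one machine.

# LP accounting: one counter per solve class. The traversal reports the
# node-level FBA count (one LP per node of the tree) separately from FVA
# solves.
the_counters <- new.env(parent = emptyenv())
the_counters$fba <- 0L
the_counters$fva <- 0L

#' LP solve counters
#'
#' `solve_fba()` increments the `fba` counter once per call; every individual
#' min/max solve inside [run_fva()] (and the helpers built on it) increments
#' the `fva` counter.
#'
#' @return `lp_counts()`: named integer vector with elements `fba` and `fva`.
#' @export
lp_counts <- function() {
  c(fba = the_counters$fba, fva = the_counters$fva)
}

#' @rdname lp_counts
#' @export
reset_lp_counts <- function() {
  the_counters$fba <- 0L
  the_counters$fva <- 0L
  invisible(NULL)
}

# tolerance below which a flux is classified as zero
ZERO_TOL <- 1e-6
# growth "fixed at optimum" is implemented as growth >= (1 - OPT_SLACK) * opt
# to avoid empty feasible sets from floating-point ties
OPT_SLACK <- 1e-9

new_flux_result <- function(status, objective, fluxes) {
  structure(
    list(status = status, objective_value = objective, fluxes = fluxes),
    class = "flux_result"
  )
}

#' @export
print.flux_result <- function(x, ...) {
  cat("<flux_result> status: ", x$status, sep = "")
  if (x$status == "optimal") cat(" | objective: ", format(x$objective_value), sep = "")
  cat("\n")
  invisible(x)
}

#' Flux balance analysis
#'
#' Maximizes (or minimizes) the flux of one reaction subject to steady state
#' (`S v = 0`) and the model's flux bounds, returning an optimal vertex
#' solution or an infeasible status.
#'
#' @param model a [metabolic_model()].
#' @param objective_id reaction whose flux is optimized; defaults to the
#'   model's biomass objective.
#' @param sense `"max"` or `"min"`.
#' @return a `flux_result`: list with `status` (`"optimal"` or
#'   `"infeasible"`), `objective_value`, and `fluxes` (named numeric vector).
#'   A numerical solver failure raises an error, distinct from infeasibility.
#' @export
#' @examples
#' solve_fba(make_toy1())$objective_value  # 5
solve_fba <- function(model, objective_id = model$objective,
                      sense = c("max", "min")) {
  sense <- match.arg(sense)
  stopifnot(inherits(model, "metabolic_model"))
  j <- match(objective_id, model$reactions$id)
  if (is.na(j)) stop("unknown objective reaction '", objective_id, "'", call. = FALSE)
  S <- stoich_matrix(model)
  obj <- numeric(ncol(S))
  obj[j] <- 1
  the_counters$fba <- the_counters$fba + 1L
  res <- lp_solve(obj, S, rep(0, nrow(S)), model$reactions$lb,
                  model$reactions$ub, sense)
  if (res$status == "infeasible") {
    return(new_flux_result("infeasible", NA_real_, NULL))
  }
  if (res$status != "optimal") {
    stop("LP solver failure (", res$status, ") on model '", model$id, "'",
         call. = FALSE)
  }
  new_flux_result("optimal", res$objective,
                  stats::setNames(res$x, model$reactions$id))
}

#' Flux variability analysis
#'
#' For each requested reaction, the minimum and maximum attainable flux while
#' the model objective is held at at least `objective_fraction` of its FBA
#' optimum (two LPs per reaction). At fraction 1 the optimum is fixed up to a
#' relative slack of 1e-9.
#'
#' @param model a [metabolic_model()].
#' @param reaction_ids reactions to scan; defaults to all.
#' @param objective_fraction number in \[0, 1\].
#' @return tibble with columns `reaction`, `min_flux`, `max_flux`, or an
#'   object with `status = "infeasible"` attribute-free `NULL`-like tibble if
#'   the base model is infeasible (an error is raised in that case).
#' @export
run_fva <- function(model, reaction_ids = model$reactions$id,
                    objective_fraction = 1) {
  stopifnot(objective_fraction >= 0, objective_fraction <= 1)
  missing_ids <- setdiff(reaction_ids, model$reactions$id)
  if (length(missing_ids)) {
    stop("unknown reaction '", missing_ids[1], "'", call. = FALSE)
  }
  constrained <- model
  if (objective_fraction > 0) {
    base <- solve_fba(model)
    if (base$status != "optimal") {
      stop("infeasible base model: FVA undefined", call. = FALSE)
    }
    floor_val <- objective_fraction * base$objective_value
    if (floor_val > 0) floor_val <- floor_val * (1 - OPT_SLACK)
    if (floor_val < 0) floor_val <- floor_val * (1 + OPT_SLACK)
    i <- match(model$objective, model$reactions$id)
    constrained$reactions$lb[i] <- max(constrained$reactions$lb[i], floor_val)
  }
  S <- stoich_matrix(constrained)
  lb <- constrained$reactions$lb
  ub <- constrained$reactions$ub
  rhs <- rep(0, nrow(S))
  out <- purrr::map_dfr(reaction_ids, function(rid) {
    j <- match(rid, constrained$reactions$id)
    obj <- numeric(ncol(S))
    obj[j] <- 1
    the_counters$fva <- the_counters$fva + 2L
    lo <- lp_solve(obj, S, rhs, lb, ub, "min")
    hi <- lp_solve(obj, S, rhs, lb, ub, "max")
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("FVA solve failed for reaction '", rid, "'", call. = FALSE)
    }
    tibble::tibble(reaction = rid, min_flux = lo$objective, max_flux = hi$objective)
  })
  out
}

#' Knock out reactions
#'
#' Sets `lb = ub = 0` for every listed reaction; the input model is not
#' modified.
#'
#' @param model a [metabolic_model()].
#' @param reaction_ids character vector (possibly empty) of reaction ids.
#' @return the knockout model.
#' @export
apply_knockouts <- function(model, reaction_ids) {
  stopifnot(inherits(model, "metabolic_model"))
  if (length(reaction_ids) == 0) return(model)
  idx <- match(reaction_ids, model$reactions$id)
  if (anyNA(idx)) {
    stop("unknown reaction '", reaction_ids[which(is.na(idx))[1]], "'",
         call. = FALSE)
  }
  model$reactions$lb[idx] <- 0
  model$reactions$ub[idx] <- 0
  model
}

#' Growth and product flux range at optimal growth
#'
#' Computes the FBA growth optimum, then the min/max flux of the product
#' exchange with growth fixed at that optimum (within a 1e-9 relative
#' optimality slack). The minimum is the guaranteed production rate, the
#' maximum the best-case rate, of the strain.
#'
#' @param model a [metabolic_model()].
#' @param product_exchange_id exchange reaction id of the target product.
#' @return list with `status`, `growth`, `product_min`, `product_max`.
#' @export
#' @examples
#' toy <- make_toy1()
#' product_rates_at_optimal_growth(apply_knockouts(toy, "R4"), "EX_P")
product_rates_at_optimal_growth <- function(model, product_exchange_id) {
  if (!product_exchange_id %in% model$reactions$id) {
    stop("unknown product exchange '", product_exchange_id, "'", call. = FALSE)
  }
  base <- solve_fba(model)
  if (base$status != "optimal") {
    return(list(status = "infeasible", growth = NA_real_,
                product_min = NA_real_, product_max = NA_real_))
  }
  growth <- base$objective_value
  fixed <- model
  i <- match(model$objective, model$reactions$id)
  floor_val <- if (growth > 0) growth * (1 - OPT_SLACK) else growth * (1 + OPT_SLACK)
  fixed$reactions$lb[i] <- max(fixed$reactions$lb[i], floor_val)
  S <- stoich_matrix(fixed)
  j <- match(product_exchange_id, fixed$reactions$id)
  obj <- numeric(ncol(S))
  obj[j] <- 1
  the_counters$fva <- the_counters$fva + 2L
  lo <- lp_solve(obj, S, rep(0, nrow(S)), fixed$reactions$lb, fixed$reactions$ub, "min")
  hi <- lp_solve(obj, S, rep(0, nrow(S)), fixed$reactions$lb, fixed$reactions$ub, "max")
  if (lo$status != "optimal" || hi$status != "optimal") {
    stop("product FVA failed at fixed growth", call. = FALSE)
  }
  list(status = "optimal", growth = growth,
       product_min = lo$objective, product_max = hi$objective)
}

#' Tidy a flux result
#'
#' @param x a `flux_result`.
#' @param ... unused.
#' @return tibble with columns `reaction`, `flux`.
#' @export
tidy.flux_result <- function(x, ...) {
  if (x$status != "optimal") {
    return(tibble::tibble(reaction = character(0), flux = numeric(0)))
  }
  tibble::tibble(reaction = names(x$fluxes), flux = unname(x$fluxes))
}
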