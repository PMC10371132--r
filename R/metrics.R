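# Strain-ranking metrics: production envelopes, strength of growth coupling
# (SoGC), yield and substrate-specific productivity (SSP), CO2 exchange, and
# linear MOMA.

#' Production envelope
#'
#' Minimum and maximum product flux as a function of growth, on a uniform
#' grid from 0 to the growth optimum (inclusive); two LPs per grid point with
#' growth fixed at the grid value. Both edges are piecewise linear in growth.
#'
#' @param model a [metabolic_model()].
#' @param product_exchange_id product exchange reaction id.
#' @param n_points number of grid points (>= 2, default 40).
#' @return a tibble of class `production_envelope` with columns `growth`,
#'   `product_min`, `product_max`.
#' @export
#' @examples
#' env <- production_envelope(apply_knockouts(make_toy1(), "R4"), "EX_P", 5)
#' env
production_envelope <- function(model, product_exchange_id, n_points = 40) {
  stopifnot(n_points >= 2)
  if (!product_exchange_id %in% model$reactions$id) {
    stop("unknown product exchange '", product_exchange_id, "'", call. = FALSE)
  }
  base <- solve_fba(model)
  if (base$status != "optimal") stop("infeasible model", call. = FALSE)
  mu_max <- base$objective_value
  grid <- seq(0, mu_max, length.out = n_points)
  i <- match(model$objective, model$reactions$id)
  j <- match(product_exchange_id, model$reactions$id)
  S <- stoich_matrix(model)
  obj <- numeric(ncol(S))
  obj[j] <- 1
  rows <- purrr::map_dfr(grid, function(g) {
    m <- model
    m$reactions$lb[i] <- g
    m$reactions$ub[i] <- g
    lb <- m$reactions$lb
    ub <- m$reactions$ub
    the_counters$fva <- the_counters$fva + 2L
    lo <- lp_solve(obj, S, rep(0, nrow(S)), lb, ub, "min")
    hi <- lp_solve(obj, S, rep(0, nrow(S)), lb, ub, "max")
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("envelope LP failed at growth ", format(g), call. = FALSE)
    }
    tibble::tibble(growth = g, product_min = lo$objective, product_max = hi$objective)
  })
  structure(rows, class = c("production_envelope", class(rows)),
            mu_max = mu_max, product = product_exchange_id)
}

#' Strength of growth coupling (SoGC)
#'
#' The squared product yield per unit substrate divided by the slope of the
#' lower edge of the production envelope. The yield is taken at the growth
#' optimum on the lower (guaranteed) edge; the slope is that of the final
#' linear segment of the lower edge ending at the growth optimum, detected
#' from envelope breakpoints. When the lower edge is flat or decreasing
#' (uncoupled production) the SoGC is reported as 0 with a `coupled = FALSE`
#' flag.
#'
#' @param envelope a [production_envelope()].
#' @param substrate_uptake substrate uptake magnitude (mmol/gDW/h, > 0).
#' @param slope_method `"breakpoint"` (default): extend the final segment
#'   backwards from the growth optimum while the per-interval slope stays
#'   constant; `"endpoint"`: two-point finite difference at the growth
#'   optimum.
#' @return list with `sogc`, `yield`, `slope`, `coupled`.
#' @export
#' @examples
#' env <- production_envelope(apply_knockouts(make_toy1(), "R4"), "EX_P", 20)
#' compute_sogc(env, substrate_uptake = 10)$sogc  # 0.25
compute_sogc <- function(envelope, substrate_uptake,
                         slope_method = c("breakpoint", "endpoint")) {
  slope_method <- match.arg(slope_method)
  stopifnot(substrate_uptake > 0, nrow(envelope) >= 2)
  g <- envelope$growth
  lo <- envelope$product_min
  n <- length(g)
  if (g[n] <= ZERO_TOL) stop("degenerate envelope: zero growth optimum", call. = FALSE)
  yield <- lo[n] / substrate_uptake
  seg_slope <- (lo[n] - lo[n - 1]) / (g[n] - g[n - 1])
  if (slope_method == "breakpoint") {
    # walk back while consecutive interval slopes match the final one
    first <- n - 1
    slope_tol <- 1e-6 * max(1, abs(seg_slope))
    while (first > 1) {
      s <- (lo[first] - lo[first - 1]) / (g[first] - g[first - 1])
      if (abs(s - seg_slope) > slope_tol) break
      first <- first - 1
    }
    seg_slope <- (lo[n] - lo[first]) / (g[n] - g[first])
  }
  if (!is.finite(seg_slope) || seg_slope <= ZERO_TOL) {
    return(list(sogc = 0, yield = yield, slope = seg_slope, coupled = FALSE))
  }
  list(sogc = yield^2 / seg_slope, yield = yield, slope = seg_slope,
       coupled = TRUE)
}

#' Yield and substrate-specific productivity
#'
#' `yield = product_rate / substrate_uptake` (mmol product per mmol
#' substrate); `SSP = growth * product_rate`, the growth-weighted production
#' index as conventionally tabulated. `ssp_definition = "yield"` selects the
#' literature variant `growth * yield` instead.
#'
#' @param growth growth rate (1/h).
#' @param product_rate product flux (mmol/gDW/h).
#' @param substrate_uptake substrate uptake magnitude (> 0).
#' @param ssp_definition `"rate"` (default) or `"yield"`.
#' @return tibble with columns `yield`, `ssp`.
#' @export
#' @examples
#' compute_yield_ssp(0.12, 12.24, 10)
compute_yield_ssp <- function(growth, product_rate, substrate_uptake,
                              ssp_definition = c("rate", "yield")) {
  ssp_definition <- match.arg(ssp_definition)
  if (any(substrate_uptake <= 0)) stop("substrate uptake must be > 0", call. = FALSE)
  yield <- product_rate / substrate_uptake
  ssp <- if (ssp_definition == "rate") growth * product_rate else growth * yield
  tibble::tibble(yield = yield, ssp = ssp)
}

#' CO2 exchange flux of a production state
#'
#' Reports the FVA range (and midpoint) of the CO2 exchange flux with growth
#' fixed at its optimum and the product flux fixed at its maximum over that
#' optimum: the flux state the production-rate figures refer to. The range,
#' rather than an arbitrary vertex, is reported because the state is usually
#' degenerate. Negative values are uptake.
#'
#' @param model a [metabolic_model()].
#' @param product_exchange_id product exchange reaction id.
#' @param co2_exchange_id CO2 exchange reaction id.
#' @return list with `co2_min`, `co2_max`, `co2_mid`.
#' @export
co2_exchange_flux <- function(model, product_exchange_id, co2_exchange_id) {
  if (!co2_exchange_id %in% model$reactions$id) {
    stop("missing CO2 exchange reaction '", co2_exchange_id, "'", call. = FALSE)
  }
  rates <- product_rates_at_optimal_growth(model, product_exchange_id)
  if (rates$status != "optimal") stop("infeasible model", call. = FALSE)
  m <- model
  i <- match(model$objective, m$reactions$id)
  j <- match(product_exchange_id, m$reactions$id)
  g <- rates$growth
  m$reactions$lb[i] <- if (g > 0) g * (1 - OPT_SLACK) else g
  p <- rates$product_max
  m$reactions$lb[j] <- max(m$reactions$lb[j],
                           if (p > 0) p * (1 - OPT_SLACK) else p - ZERO_TOL)
  rng <- run_fva(m, reaction_ids = co2_exchange_id, objective_fraction = 0)
  list(co2_min = rng$min_flux, co2_max = rng$max_flux,
       co2_mid = (rng$min_flux + rng$max_flux) / 2)
}

#' Linear MOMA (minimization of metabolic adjustment)
#'
#' Finds the flux state of the knockout model minimizing the L1 distance to
#' a wild-type flux distribution, via the standard split-variable LP. By
#' default the distance penalizes internal (non-boundary) reactions only --
#' metabolic adjustment as an intracellular rerouting cost; `penalize =
#' "all"` includes exchange and drain fluxes in the distance as well.
#'
#' @param wild_flux a `flux_result` (optimal) on the pre-knockout model, or a
#'   named numeric flux vector.
#' @param ko_model the knockout model.
#' @param penalize `"internal"` (default) or `"all"`.
#' @return list with `status`, `distance`, `fluxes` (named vector),
#'   `growth` (flux of the objective reaction).
#' @export
#' @examples
#' toy <- make_toy1()
#' wt <- solve_fba(toy)
#' linear_moma(wt, apply_knockouts(toy, "R4"))
linear_moma <- function(wild_flux, ko_model, penalize = c("internal", "all")) {
  penalize <- match.arg(penalize)
  stopifnot(inherits(ko_model, "metabolic_model"))
  wild <- if (inherits(wild_flux, "flux_result")) {
    if (wild_flux$status != "optimal") {
      stop("wild-type flux distribution must be optimal", call. = FALSE)
    }
    wild_flux$fluxes
  } else {
    wild_flux
  }
  rxns <- ko_model$reactions$id
  if (!all(rxns %in% names(wild))) {
    stop("wild-type flux vector misses reactions of the knockout model",
         call. = FALSE)
  }
  wild <- wild[rxns]
  pen <- if (penalize == "all") rep(TRUE, length(rxns)) else
    !ko_model$reactions$is_exchange
  p <- sum(pen)

  S <- stoich_matrix(ko_model)
  m <- nrow(S)
  n <- ncol(S)
  # variables: v (n), d_plus (p), d_minus (p); rows: S v = 0 plus, for each
  # penalized reaction r, v_r - d_plus_r + d_minus_r = wild_r
  A <- matrix(0, m + p, n + 2 * p)
  A[seq_len(m), seq_len(n)] <- S
  pen_idx <- which(pen)
  for (k in seq_len(p)) {
    A[m + k, pen_idx[k]] <- 1
    A[m + k, n + k] <- -1
    A[m + k, n + p + k] <- 1
  }
  rhs <- c(rep(0, m), unname(wild[pen_idx]))
  obj <- c(rep(0, n), rep(1, 2 * p))
  lb <- c(ko_model$reactions$lb, rep(0, 2 * p))
  ub <- c(ko_model$reactions$ub, rep(Inf, 2 * p))
  res <- lp_solve(obj, A, rhs, lb, ub, "min")
  if (res$status == "infeasible") {
    return(list(status = "infeasible", distance = NA_real_, fluxes = NULL,
                growth = NA_real_))
  }
  if (res$status != "optimal") stop("MOMA LP failed (", res$status, ")", call. = FALSE)
  v <- stats::setNames(res$x[seq_len(n)], rxns)
  list(
    status = "optimal",
    distance = res$objective,
    fluxes = v,
    growth = unname(v[ko_model$objective])
  )
}

#' Evaluate knockout strategies with the full metrics panel
#'
#' One row per strategy: growth, product min/max at optimal growth, yield,
#' SSP, SoGC, optional CO2 exchange range, and linear-MOMA growth/product.
#' A strategy referencing unknown reactions yields a row of `NA`s with a
#' message, and the run continues.
#'
#' @param model the medium-constrained base model.
#' @param strategies list of character vectors (or a solutions tibble from
#'   [solutions()], whose `reactions` column is split on `";"`).
#' @param product_exchange_id product exchange reaction id.
#' @param substrate_uptake substrate uptake magnitude used for yields.
#' @param co2_exchange_id optional CO2 exchange id.
#' @param n_envelope_points grid size for the SoGC envelope (default 40).
#' @param moma_reference optional wild-type `flux_result`; defaults to the
#'   FBA vertex of `model`.
#' @return tibble of metrics, one row per strategy.
#' @export
evaluate_strategies <- function(model, strategies, product_exchange_id,
                                substrate_uptake,
                                co2_exchange_id = NULL,
                                n_envelope_points = 40,
                                moma_reference = NULL) {
  if (is.data.frame(strategies)) {
    strategies <- strsplit(strategies$reactions, ";", fixed = TRUE)
  }
  if (is.null(moma_reference)) moma_reference <- solve_fba(model)
  purrr::map_dfr(strategies, function(strat) {
    row <- tibble::tibble(
      reactions = canonical_set(strat), growth = NA_real_,
      product_min = NA_real_, product_max = NA_real_,
      yield = NA_real_, ssp = NA_real_, sogc = NA_real_,
      co2_min = NA_real_, co2_max = NA_real_,
      moma_growth = NA_real_, moma_product = NA_real_
    )
    out <- tryCatch({
      ko <- apply_knockouts(model, strat)
      rates <- product_rates_at_optimal_growth(ko, product_exchange_id)
      if (rates$status != "optimal") return(row)
      ys <- compute_yield_ssp(rates$growth, rates$product_max, substrate_uptake)
      env <- production_envelope(ko, product_exchange_id, n_envelope_points)
      sogc <- compute_sogc(env, substrate_uptake)
      moma <- linear_moma(moma_reference, ko)
      row$growth <- rates$growth
      row$product_min <- rates$product_min
      row$product_max <- rates$product_max
      row$yield <- ys$yield
      row$ssp <- ys$ssp
      row$sogc <- sogc$sogc
      if (!is.null(co2_exchange_id)) {
        co2 <- co2_exchange_flux(ko, product_exchange_id, co2_exchange_id)
        row$co2_min <- co2$co2_min
        row$co2_max <- co2$co2_max
      }
      if (moma$status == "optimal") {
        row$moma_growth <- moma$growth
        row$moma_product <- unname(moma$fluxes[product_exchange_id])
      }
      row
    }, error = function(e) {
      message("strategy '", canonical_set(strat), "' skipped: ",
              conditionMessage(e))
      row
    })
    out
  })
}
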