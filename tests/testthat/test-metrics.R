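toy <- make_toy1()

test_that("production envelopes have consistent, piecewise-linear edges", {
  # fully coupled strain: both edges collapse onto the product = growth line
  env <- production_envelope(apply_knockouts(toy, "R4"), "EX_P", 21)
  expect_equal(env$product_min, env$growth, tolerance = 1e-6)
  expect_equal(env$product_max, env$growth, tolerance = 1e-6)
  # wild type: lower edge identically zero (byproduct branch available)
  env_wt <- production_envelope(toy, "EX_P", 21)
  expect_equal(env_wt$product_min, rep(0, 21), tolerance = 1e-6)
  expect_true(all(env_wt$product_min <= env_wt$product_max + 1e-9))
  # envelope at the growth optimum reproduces the fixed-growth product range
  rates <- product_rates_at_optimal_growth(toy, "EX_P")
  expect_equal(env_wt$product_max[21], rates$product_max, tolerance = 1e-6)
  expect_equal(env_wt$product_min[21], rates$product_min, tolerance = 1e-6)
  expect_error(production_envelope(toy, "nope", 5), "unknown product")
  expect_s3_class(autoplot(env), "ggplot")
})

test_that("SoGC is the squared yield over the lower-edge slope, with closed form 0.25", {
  env <- production_envelope(apply_knockouts(toy, "R4"), "EX_P", 40)
  sg <- compute_sogc(env, substrate_uptake = 10)
  expect_true(sg$coupled)
  expect_equal(sg$yield, 0.5, tolerance = 1e-6)
  expect_equal(sg$slope, 1, tolerance = 1e-6)
  expect_equal(sg$sogc, 0.25, tolerance = 1e-6)
  # endpoint method agrees on a globally linear edge
  sg2 <- compute_sogc(env, 10, slope_method = "endpoint")
  expect_equal(sg2$sogc, sg$sogc, tolerance = 1e-6)
  # flat lower edge: uncoupled, SoGC 0 with flag
  env_wt <- production_envelope(toy, "EX_P", 40)
  sg_wt <- compute_sogc(env_wt, 10)
  expect_false(sg_wt$coupled)
  expect_identical(sg_wt$sogc, 0)
})

test_that("yield and SSP reproduce the tabulated arithmetic", {
  ys <- compute_yield_ssp(0.12, 12.24, 10)
  expect_equal(ys$yield, 1.224, tolerance = 1e-9)
  expect_equal(ys$ssp, 1.4688, tolerance = 1e-9)
  expect_equal(compute_yield_ssp(5, 5, 10)$yield, 0.5)
  expect_equal(compute_yield_ssp(5, 5, 10)$ssp, 25)
  expect_identical(compute_yield_ssp(0.5, 0, 10)$ssp, 0)
  # algebraic identity: yield * uptake = product rate
  for (p in c(0.3, 4.7, 9.2)) {
    expect_equal(compute_yield_ssp(1, p, 7.5)$yield * 7.5, p, tolerance = 1e-12)
  }
  # literature variant
  expect_equal(compute_yield_ssp(0.12, 12.24, 10, "yield")$ssp, 0.12 * 1.224)
  expect_error(compute_yield_ssp(1, 1, 0), "uptake")
})

test_that("CO2 reporting needs a CO2 exchange and returns its fixed-state range", {
  expect_error(co2_exchange_flux(toy, "EX_P", "EX_co2"), "missing CO2")
  # treat the byproduct exchange as a stand-in gas exchange: in the coupled
  # strain it is forced to zero
  ko <- apply_knockouts(toy, "R4")
  rng <- co2_exchange_flux(ko, "EX_P", "EX_D")
  expect_equal(rng$co2_min, 0, tolerance = 1e-6)
  expect_equal(rng$co2_max, 0, tolerance = 1e-6)
  expect_equal(rng$co2_mid, 0, tolerance = 1e-6)
})

test_that("linear MOMA reroutes flux at minimal L1 adjustment", {
  # wild vertex sending 5 through the byproduct branch
  wt <- solve_fba(toy)
  wt$fluxes[c("R3", "R4", "EX_P", "EX_D")] <- c(0, 5, 0, 5)
  res <- linear_moma(wt, apply_knockouts(toy, "R4"))
  expect_identical(res$status, "optimal")
  # rerouting 5 units from R4 to R3: internal adjustment distance 10
  expect_equal(res$distance, 10, tolerance = 1e-6)
  expect_equal(res$growth, 5, tolerance = 1e-6)
  expect_equal(unname(res$fluxes["R3"]), 5, tolerance = 1e-6)
  # penalizing exchanges too adds the EX_D -> EX_P shift
  res_all <- linear_moma(wt, apply_knockouts(toy, "R4"), penalize = "all")
  expect_equal(res_all$distance, 20, tolerance = 1e-6)
  # no knockout: wild flux is feasible, distance 0
  res0 <- linear_moma(solve_fba(toy), toy)
  expect_equal(res0$distance, 0, tolerance = 1e-6)
  # L1 optimum never exceeds the full wild norm over penalized reactions
  pen <- !reactions(toy)$is_exchange
  expect_lte(res$distance, sum(abs(wt$fluxes[reactions(toy)$id[pen]])) + 5 + 1e-6)
  # infeasible knockout model propagates status
  impossible <- set_bounds(toy, "BIOMASS", lb = 6)
  expect_identical(linear_moma(wt, impossible)$status, "infeasible")
})

test_that("the metrics panel evaluates strategies and survives bad rows", {
  sol <- tibble::tibble(reactions = c("R4", "R3;R4", "ghost"))
  met <- suppressMessages(
    evaluate_strategies(toy, sol, "EX_P", substrate_uptake = 10)
  )
  expect_identical(nrow(met), 3L)
  r4 <- met[met$reactions == "R4", ]
  expect_equal(r4$growth, 5, tolerance = 1e-6)
  expect_equal(r4$yield, 0.5, tolerance = 1e-6)
  expect_equal(r4$ssp, 25, tolerance = 1e-5)
  expect_equal(r4$sogc, 0.25, tolerance = 1e-6)
  # the lethal double knockout yields NA rows, not an error
  expect_true(is.na(met$yield[met$reactions == "R3;R4"]))
  expect_true(is.na(met$growth[met$reactions == "ghost"]))
})
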