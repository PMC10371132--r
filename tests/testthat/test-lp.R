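# the simplex kernel, cross-checked against an independent solver and
# against hand-derivable linear programs

test_that("kernel agrees with pracma::linprog on random feasible LPs", {
  skip_if_not_installed("pracma")
  set.seed(42)
  n_agree <- 0L
  for (i in 1:40) {
    m <- sample(3:6, 1)
    n <- m + sample(2:5, 1)
    A <- matrix(sample(-2:2, m * n, TRUE), m, n)
    lb <- runif(n, -5, 0)
    ub <- runif(n, 1, 10)
    x0 <- runif(n, lb, ub)           # interior point => feasibility guaranteed
    b <- drop(A %*% x0)
    obj <- runif(n, -1, 1)
    mine <- knockr:::lp_solve(obj, A, b, lb, ub, "max")
    expect_identical(mine$status, "optimal")
    ref <- tryCatch(
      pracma::linprog(obj, A = diag(n), b = ub - lb, Aeq = A,
                      beq = b - drop(A %*% lb), maximize = TRUE,
                      maxiter = 1000),
      error = function(e) NULL
    )
    if (!is.null(ref) && ref$errno == 1) {
      expect_equal(mine$objective, sum(obj * (ref$x + lb)),
                   tolerance = 1e-6, info = paste("case", i))
      n_agree <- n_agree + 1L
    }
  }
  expect_gte(n_agree, 30L)
})

test_that("FBA reproduces the hand-solved toy optimum and detects infeasibility", {
  toy <- make_toy1()
  res <- solve_fba(toy)
  expect_identical(res$status, "optimal")
  expect_equal(res$objective_value, 5, tolerance = 1e-9)
  # uptake closed -> zero growth
  closed <- set_bounds(toy, "EX_A", lb = 0)
  expect_equal(solve_fba(closed)$objective_value, 0, tolerance = 1e-9)
  # impossible growth demand -> infeasible status, not an error
  forced <- set_bounds(toy, "BIOMASS", lb = 6)
  expect_identical(solve_fba(forced)$status, "infeasible")
  expect_error(solve_fba(toy, objective_id = "nope"), "unknown objective")
})

test_that("optimal flux distributions satisfy steady state and bounds", {
  models <- c(list(make_toy1()),
              lapply(1:5, generate_toy_model, n_branches = 3))
  for (m in models) {
    res <- solve_fba(m)
    S <- stoich_matrix(m)
    expect_lt(max(abs(S %*% res$fluxes)), 1e-6)
    expect_true(all(res$fluxes >= reactions(m)$lb - 1e-6))
    expect_true(all(res$fluxes <= reactions(m)$ub + 1e-6))
  }
})

test_that("FVA brackets the FBA flux and resolves alternate optima", {
  toy <- make_toy1()
  rng <- run_fva(toy, c("R3", "R4"), objective_fraction = 1)
  expect_equal(rng$min_flux, c(0, 0), tolerance = 1e-6)
  expect_equal(rng$max_flux, c(5, 5), tolerance = 1e-6)
  # sandwich property across all reactions at matching fraction
  full <- run_fva(toy, objective_fraction = 1)
  fba <- solve_fba(toy)$fluxes[full$reaction]
  expect_true(all(full$min_flux <= fba + 1e-6))
  expect_true(all(full$max_flux >= fba - 1e-6))
  # after removing the byproduct branch the product branch is forced
  ko <- apply_knockouts(toy, "R4")
  forced <- run_fva(ko, "EX_P", objective_fraction = 1)
  expect_equal(forced$min_flux, 5, tolerance = 1e-6)
  expect_equal(forced$max_flux, 5, tolerance = 1e-6)
  # a bound-blocked reaction has range [0, 0] at fraction 0
  blocked <- set_bounds(toy, "R3", lb = 0, ub = 0)
  z <- run_fva(blocked, "R3", objective_fraction = 0)
  expect_equal(c(z$min_flux, z$max_flux), c(0, 0))
})

test_that("knockouts zero the bounds, keep the input intact, and are monotone", {
  toy <- make_toy1()
  expect_identical(apply_knockouts(toy, character(0)), toy)
  ko <- apply_knockouts(toy, "R1")
  expect_equal(solve_fba(ko)$objective_value, 0, tolerance = 1e-9)
  expect_equal(reactions(toy)$ub[match("R1", reactions(toy)$id)], 1000)
  expect_error(apply_knockouts(toy, "ghost"), "ghost")
  # growth is non-increasing in the knockout set (constraint monotonicity)
  for (seed in 1:5) {
    m <- generate_toy_model(seed, n_branches = 3)
    cand <- preprocess_model(m)$removable
    if (length(cand) < 2) next
    for (i in seq_along(cand)) {
      g1 <- solve_fba(apply_knockouts(m, cand[i]))$objective_value
      for (j in seq_along(cand)) {
        if (j == i) next
        r2 <- solve_fba(apply_knockouts(m, cand[c(i, j)]))
        g2 <- if (r2$status == "optimal") r2$objective_value else 0
        expect_lte(g2, g1 + 1e-6)
      }
    }
  }
})

test_that("product rates at optimal growth expose guaranteed vs best-case rates", {
  toy <- make_toy1()
  wild <- product_rates_at_optimal_growth(toy, "EX_P")
  expect_equal(wild$growth, 5, tolerance = 1e-9)
  expect_equal(wild$product_min, 0, tolerance = 1e-6)
  expect_equal(wild$product_max, 5, tolerance = 1e-6)
  coupled <- product_rates_at_optimal_growth(apply_knockouts(toy, "R4"), "EX_P")
  expect_equal(coupled$growth, 5, tolerance = 1e-6)
  expect_equal(coupled$product_min, 5, tolerance = 1e-6)
  expect_equal(coupled$product_max, 5, tolerance = 1e-6)
  dead <- product_rates_at_optimal_growth(
    set_bounds(toy, "BIOMASS", lb = 6), "EX_P"
  )
  expect_identical(dead$status, "infeasible")
})

test_that("LP counters track FBA and FVA solves separately", {
  toy <- make_toy1()
  reset_lp_counts()
  invisible(solve_fba(toy))
  expect_identical(lp_counts()[["fba"]], 1L)
  invisible(run_fva(toy, c("R3", "R4"), objective_fraction = 1))
  expect_identical(lp_counts()[["fva"]], 4L)
  reset_lp_counts()
  expect_identical(unname(lp_counts()), c(0L, 0L))
})
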