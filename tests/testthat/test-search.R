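toy <- make_toy1()
toy_th <- compute_thresholds(toy, "EX_P", traversal_config(1))

test_that("run thresholds derive from wild-type growth and theoretical yield", {
  expect_equal(toy_th$gr_wt, 5, tolerance = 1e-9)
  expect_equal(toy_th$v_chemical, 5, tolerance = 1e-9)
  expect_equal(toy_th$th_chemical, 0.25, tolerance = 1e-9)
  expect_equal(toy_th$biomass_floor, 0.05, tolerance = 1e-9)
  # a product that cannot be made at all degenerates the threshold with a warning
  nop <- set_bounds(toy, "EX_P", lb = 0, ub = 0)
  expect_warning(th0 <- compute_thresholds(nop, "EX_P", traversal_config(1)),
                 "threshold")
  expect_equal(th0$th_chemical, 0)
})

test_that("configuration guards reject out-of-range parameters", {
  expect_error(traversal_config(0), "target_level")
  expect_error(traversal_config(7), "max_target_level")
  expect_error(traversal_config(2, biomass_cutoff_fraction = 0))
  expect_error(traversal_config(2, product_threshold_fraction = 1.5))
})

test_that("the target space keeps only removable reactions able to carry flux", {
  removable <- c("R3", "R4")
  ts_fva <- identify_target_space(toy, removable, rule = "fva_support",
                                  biomass_floor = 0.05)
  expect_identical(ts_fva$target_space, c("R3", "R4"))
  # the single-vertex rule sees exactly one of the two interchangeable branches
  ts_fba <- identify_target_space(toy, removable, rule = "fba_support",
                                  biomass_floor = 0.05)
  expect_length(ts_fba$target_space, 1)
  expect_true(ts_fba$target_space %in% removable)
  # a lethal deletion set signals prune (NULL), never raises
  dead <- apply_knockouts(toy, "R2")
  expect_null(identify_target_space(dead, removable, deleted = "R2",
                                    rule = "fva_support", biomass_floor = 0.05))
  # sibling exclusion shrinks the space
  ts_ex <- identify_target_space(toy, removable, rule = "fva_support",
                                 biomass_floor = 0.05, excluded = "R3")
  expect_identical(ts_ex$target_space, "R4")
})

test_that("children extend the deleted set by unchecked target-space members", {
  expect_identical(
    construct_subtree(character(0), c("R4", "R3")),
    list("R3", "R4")
  )
  expect_identical(
    construct_subtree("R1", c("R3", "R4"), checked = "R3"),
    list(c("R1", "R4"))
  )
  expect_identical(construct_subtree("R1", character(0)), list())
})

test_that("TOY1 enumeration finds the unique guaranteed-rate single knockout", {
  enum <- enumerate_knockouts(toy, c("R3", "R4"), "EX_P",
                              traversal_config(1, mode = "rate_grnt"),
                              thresholds = toy_th)
  sol <- solutions(enum)
  expect_identical(sol$reactions, "R4")
  expect_equal(sol$growth, 5, tolerance = 1e-6)
  expect_equal(sol$product_min, 5, tolerance = 1e-6)
  # {R3} kills production entirely and must not appear in any mode
  expect_false("R3" %in% solutions(enum, mode = "both")$reactions)
  # empty candidate set: trivially no solutions
  empty <- enumerate_knockouts(toy, character(0), "EX_P",
                               traversal_config(1, mode = "rate_grnt"),
                               thresholds = toy_th)
  expect_identical(nrow(solutions(empty)), 0L)
})

test_that("enumeration equals the exhaustive oracle on toy models (completeness)", {
  for (seed in 1:6) {
    style <- c("one-to-one", "shared-gene", "isozyme")[(seed %% 3) + 1]
    m <- generate_toy_model(seed, n_branches = 2 + (seed %% 3),
                            gpr_style = style)
    prod <- attr(m, "product_exchange")
    prep <- preprocess_model(m)
    for (k in 1:3) {
      for (mode in c("rate_max", "rate_grnt")) {
        cfg <- traversal_config(k, mode = mode)
        th <- compute_thresholds(m, prod, cfg)
        enum <- enumerate_knockouts(prep$reduced_model, prep$removable, prod,
                                    cfg, thresholds = th)
        orc <- exhaustive_search(prep$reduced_model, prep$removable, prod,
                                 cfg, thresholds = th)
        expect_same_solution_sets(solutions(enum), orc$minimal_solutions)
        # never worse than exhaustive: node count bounded by subset count + root
        expect_lte(enum$node_count, orc$lp_count + 1L)
      }
    }
  }
})

test_that("pruned sets have no qualifying superset (pruning soundness)", {
  # TOY1 with a duplicated substrate-entry reaction: R1 stops being
  # essential, so the candidate set gains a lethal pair ({R1, R1b}) that has
  # true supersets -- the configuration the pruning rule must be sound on
  m <- make_toy1()
  m$reactions <- dplyr::bind_rows(
    m$reactions,
    tibble::tibble(id = "R1b", lb = 0, ub = 1000, gpr = "g1b",
                   is_exchange = FALSE)
  )
  m$stoich <- dplyr::bind_rows(
    m$stoich,
    tibble::tibble(reaction = "R1b", metabolite = c("A", "B"), coef = c(-1, 1))
  )
  m$genes <- c(m$genes, "g1b")
  prep <- preprocess_model(m)
  expect_setequal(prep$removable, c("R1", "R1b", "R3", "R4"))
  cfg <- traversal_config(3, mode = "rate_max")
  th <- compute_thresholds(m, "EX_P", cfg)
  cand <- prep$removable
  subsets <- unlist(lapply(1:2, function(j) utils::combn(cand, j, simplify = FALSE)),
                    recursive = FALSE)
  n_pruned_with_supersets <- 0L
  for (s in subsets) {
    r <- solve_fba(apply_knockouts(prep$reduced_model, s))
    g <- if (r$status == "optimal") r$objective_value else -Inf
    if (g < th$biomass_floor - 1e-6) {
      for (extra in setdiff(cand, s)) {
        n_pruned_with_supersets <- n_pruned_with_supersets + 1L
        r2 <- solve_fba(apply_knockouts(prep$reduced_model, c(s, extra)))
        g2 <- if (r2$status == "optimal") r2$objective_value else -Inf
        expect_lt(g2, th$biomass_floor)
      }
    }
  }
  # the property was actually exercised: at least the {R1, R1b} and
  # {R3, R4} pairs are below the floor and each has two extensions
  expect_gte(n_pruned_with_supersets, 4L)
})

test_that("guaranteed-rate solutions are a subset of best-case solutions at every level", {
  for (seed in c(3, 9, 21)) {
    m <- generate_toy_model(seed, n_branches = 3)
    prep <- preprocess_model(m)
    enum <- enumerate_knockouts(prep$reduced_model, prep$removable,
                                attr(m, "product_exchange"),
                                traversal_config(3, mode = "rate_grnt"))
    rec <- enum$records
    expect_true(all(!rec$qualifies_grnt | rec$qualifies_max))
    for (lv in unique(rec$level)) {
      sub <- rec[rec$level == lv, ]
      expect_lte(sum(sub$qualifies_grnt), sum(sub$qualifies_max))
    }
  }
})

test_that("reported states carry zero flux on knocked-out reactions and balance mass", {
  m <- generate_toy_model(5, n_branches = 3)
  prep <- preprocess_model(m)
  prod <- attr(m, "product_exchange")
  enum <- enumerate_knockouts(prep$reduced_model, prep$removable, prod,
                              traversal_config(2, mode = "rate_max"))
  sol <- solutions(enum, minimal_only = FALSE)
  S <- stoich_matrix(prep$reduced_model)
  for (i in seq_len(nrow(sol))) {
    kos <- strsplit(sol$reactions[i], ";")[[1]]
    state <- solve_fba(apply_knockouts(prep$reduced_model, kos))
    expect_true(all(abs(state$fluxes[kos]) <= 1e-9))
    expect_lt(max(abs(S %*% state$fluxes)), 1e-6)
  }
})

test_that("the traversal reports each unordered deletion set exactly once", {
  m <- generate_toy_model(13, n_branches = 4)
  prep <- preprocess_model(m)
  enum <- enumerate_knockouts(prep$reduced_model, prep$removable,
                              attr(m, "product_exchange"),
                              traversal_config(3, mode = "rate_max"))
  expect_false(anyDuplicated(enum$records$reactions) > 0)
  # node economy: never more nodes than all subsets plus the root
  n <- length(prep$removable)
  expect_lte(enum$node_count, 1 + sum(choose(n, 1:3)))
})

test_that("pinned reactions are excised before the search starts", {
  enum <- enumerate_knockouts(
    toy, c("R3", "R4"), "EX_P",
    traversal_config(1, mode = "rate_grnt", pinned = "R4"),
    thresholds = toy_th
  )
  # with R4 pre-fixed, the empty additional deletion already couples: the
  # remaining single candidates add nothing new that qualifies
  sol <- solutions(enum, minimal_only = FALSE)
  expect_false("R4" %in% sol$reactions)
})

test_that("tidy and glance summarize an enumeration", {
  enum <- enumerate_knockouts(toy, c("R3", "R4"), "EX_P",
                              traversal_config(2, mode = "rate_grnt"),
                              thresholds = toy_th)
  expect_identical(tidy(enum), solutions(enum))
  g <- glance(enum)
  expect_identical(nrow(g), 1L)
  expect_equal(g$gr_wt, 5, tolerance = 1e-9)
  expect_identical(g$node_count, enum$node_count)
  expect_s3_class(autoplot(enum), "ggplot")
})
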