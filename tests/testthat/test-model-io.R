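test_that("model construction enforces its invariants", {
  toy <- make_toy1()
  expect_s3_class(toy, "metabolic_model")
  expect_setequal(toy$genes, c("g1", "g2", "g3", "g4"))
  # exchange detection: single-metabolite boundary reactions
  expect_setequal(
    reactions(toy)$id[reactions(toy)$is_exchange],
    c("EX_A", "EX_P", "EX_D", "BIOMASS")
  )
  bad <- reactions(toy)
  bad$lb[2] <- bad$ub[2] + 1
  expect_error(
    metabolic_model("x", metabolites(toy), bad, toy$stoich, "BIOMASS"),
    "lb > ub"
  )
  expect_error(
    metabolic_model("x", metabolites(toy), reactions(toy), toy$stoich, "nope"),
    "objective"
  )
  st <- toy$stoich
  st$metabolite[1] <- "ghost"
  expect_error(
    metabolic_model("x", metabolites(toy), reactions(toy), st, "BIOMASS"),
    "undeclared metabolite"
  )
})

test_that("BiGG JSON serialization round-trips field by field", {
  toy <- make_toy1()
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(toy, path)
  back <- read_model_json(path)
  expect_identical(
    reactions(back)[c("id", "lb", "ub", "gpr", "is_exchange")],
    reactions(toy)[c("id", "lb", "ub", "gpr", "is_exchange")]
  )
  expect_identical(metabolites(back)$id, metabolites(toy)$id)
  expect_identical(back$objective, toy$objective)
  expect_identical(back$genes, toy$genes)
  expect_equal(
    dplyr::arrange(back$stoich, .data$reaction, .data$metabolite),
    dplyr::arrange(toy$stoich, .data$reaction, .data$metabolite),
    ignore_attr = TRUE
  )
  # also for a randomized generated model
  gen <- generate_toy_model(7, n_branches = 4, gpr_style = "isozyme")
  path2 <- withr::local_tempfile(fileext = ".json")
  write_model_json(gen, path2)
  back2 <- read_model_json(path2)
  expect_identical(
    reactions(back2)[c("id", "lb", "ub", "gpr")],
    reactions(gen)[c("id", "lb", "ub", "gpr")]
  )
  expect_equal(solve_fba(back2)$objective_value,
               solve_fba(gen)$objective_value, tolerance = 1e-9)
})

test_that("SBML L3+FBC files load with bounds, GPRs and objective intact", {
  path <- system.file("extdata", "toy1.xml", package = "knockr")
  m <- load_model(path, format = "sbml-fbc")
  toy <- make_toy1()
  expect_identical(
    reactions(m)[c("id", "lb", "ub", "gpr", "is_exchange")],
    reactions(toy)[c("id", "lb", "ub", "gpr", "is_exchange")]
  )
  expect_identical(m$objective, "BIOMASS")
  expect_equal(solve_fba(m)$objective_value, 5, tolerance = 1e-9)
  # format auto-detection by extension
  m2 <- load_model(path)
  expect_identical(reactions(m2)$id, reactions(m)$id)
})

test_that("unparsable or incomplete model files raise named errors", {
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(read_model_json(bad), "unparsable")
  noobj <- withr::local_tempfile(fileext = ".json")
  writeLines('{"id":"m","metabolites":[{"id":"A","compartment":"c"}],
    "reactions":[{"id":"R","lower_bound":0,"upper_bound":10,
    "metabolites":{"A":-1}}],"genes":[]}', noobj)
  expect_error(read_model_json(noobj), "objective")
  expect_error(load_model("does/not/exist.json"), "not found")
})

test_that("medium application follows the minimal-medium defaults and is idempotent", {
  toy <- make_toy1()
  m <- apply_medium(toy, c(EX_A = 10))
  expect_equal(reactions(m)$lb[match("EX_A", reactions(m)$id)], -10)
  # idempotent
  m2 <- apply_medium(m, c(EX_A = 10))
  expect_identical(reactions(m2), reactions(m))
  # empty medium: all uptakes closed, secretion still open
  closed <- apply_medium(toy, stats::setNames(numeric(0), character(0)))
  ex <- reactions(closed)[reactions(closed)$is_exchange, ]
  expect_true(all(ex$lb >= 0))
  expect_true(all(ex$ub > 0))
  expect_equal(solve_fba(closed)$objective_value, 0, tolerance = 1e-9)
  # unknown / non-exchange ids are configuration errors
  expect_error(apply_medium(toy, c(EX_missing = 5)), "unknown exchange")
  expect_error(apply_medium(toy, c(R1 = 5)), "not an exchange")
  # file-based specifications agree
  tsv <- apply_medium(toy, system.file("extdata", "toy_medium.tsv",
                                       package = "knockr"))
  yml <- apply_medium(toy, system.file("extdata", "toy_medium.yml",
                                       package = "knockr"))
  expect_identical(reactions(tsv), reactions(yml))
})
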