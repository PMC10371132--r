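# Built-in toy networks and the exhaustive-search oracle. The toys emulate
# the motif that makes knockout enumeration interesting: substrate uptake
# feeding branched internal pathways with a cofactor-coupling loop, so that
# deleting the byproduct branch(es) forces product secretion to run whenever
# biomass forms (growth-coupled production).

#' The canonical toy model
#'
#' Substrate A (uptake at most 10) is converted to B (`R1`); B plus the
#' reduced cofactor NH forms the biomass precursor C and the oxidized
#' cofactor N (`R2`); the cofactor is regenerated by two competing branches,
#' `R3` (B + N -> product P + NH) and `R4` (B + N -> byproduct D + NH). Each
#' reaction carries a one-to-one GPR (`g1`..`g4`). Hand-derivable facts:
#' wild-type growth 5, maximum product rate 5, and deleting `R4` is the
#' unique single knockout that growth-couples P (product range `[5, 5]`).
#'
#' @return a [metabolic_model()].
#' @export
#' @examples
#' toy <- make_toy1()
#' solve_fba(toy)$objective_value  # 5
make_toy1 <- function() {
  mets <- tibble::tibble(
    id = c("A", "B", "C", "N", "NH", "P", "D"),
    compartment = "c"
  )
  rxns <- tibble::tibble(
    id = c("EX_A", "R1", "R2", "R3", "R4", "EX_P", "EX_D", "BIOMASS"),
    lb = c(-10, 0, 0, 0, 0, 0, 0, 0),
    ub = 1000,
    gpr = c("", "g1", "g2", "g3", "g4", "", "", "")
  )
  stoich <- tibble::tribble(
    ~reaction, ~metabolite, ~coef,
    "EX_A", "A", -1,
    "R1", "A", -1, "R1", "B", 1,
    "R2", "B", -1, "R2", "NH", -1, "R2", "C", 1, "R2", "N", 1,
    "R3", "B", -1, "R3", "N", -1, "R3", "P", 1, "R3", "NH", 1,
    "R4", "B", -1, "R4", "N", -1, "R4", "D", 1, "R4", "NH", 1,
    "EX_P", "P", -1,
    "EX_D", "D", -1,
    "BIOMASS", "C", -1
  )
  metabolic_model("TOY1", mets, rxns, stoich, objective = "BIOMASS")
}

#' Generate a randomized toy model
#'
#' Seeded, reproducible variant of the [make_toy1()] motif with
#' `n_branches` cofactor-regenerating branches (branch 1 secretes the
#' product, the others byproducts) and configurable GPR wiring. With the
#' coupling motif on, the guaranteed-rate solution at cardinality
#' `n_branches - 1` is exactly the set of byproduct branches. Optionally a
#' structurally dead decoy reaction is added so preprocessing has something
#' to remove. The generated model is always feasible with positive growth
#' and positive maximum product rate.
#'
#' @param seed integer seed.
#' @param n_branches total number of branches (>= 2, default 3).
#' @param coupling_motif keep the cofactor loop that makes byproduct
#'   knockouts growth-couple the product (default `TRUE`; with `FALSE` the
#'   branches drain B directly and no knockout couples production).
#' @param gpr_style `"one-to-one"` (each reaction its own gene),
#'   `"shared-gene"` (two byproduct branches share a gene, so a co-knocked
#'   pair exists), or `"isozyme"` (the product branch needs either of two
#'   genes).
#' @return a [metabolic_model()].
#' @export
#' @examples
#' m <- generate_toy_model(1, n_branches = 3)
#' solve_fba(m)$status
generate_toy_model <- function(seed, n_branches = 3,
                               coupling_motif = TRUE,
                               gpr_style = c("one-to-one", "shared-gene",
                                             "isozyme")) {
  gpr_style <- match.arg(gpr_style)
  stopifnot(n_branches >= 2)
  for (attempt in seq_len(100)) {
    set.seed(seed + (attempt - 1L) * 100003L)
    uptake <- sample(8:12, 1)
    add_decoy <- stats::runif(1) < 0.5

    branch_ids <- sprintf("B%02d", seq_len(n_branches))
    branch_mets <- sprintf("X%02d", seq_len(n_branches))
    mets <- tibble::tibble(
      id = c("A", "B", "C", "N", "NH", branch_mets),
      compartment = "c"
    )
    gpr_of <- function(i) {
      switch(gpr_style,
        "one-to-one" = sprintf("gb%02d", i),
        "shared-gene" = if (i >= 2 && i <= 3) "gshared" else sprintf("gb%02d", i),
        "isozyme" = if (i == 1) "giso1 or giso2" else sprintf("gb%02d", i)
      )
    }
    rxns <- tibble::tibble(
      id = c("EX_A", "R1", "R2", branch_ids,
             paste0("EX_", branch_mets), "BIOMASS"),
      lb = c(-uptake, rep(0, 2 + 2 * n_branches + 1)),
      ub = 1000,
      gpr = c("", "g1", "g2", vapply(seq_len(n_branches), gpr_of, character(1)),
              rep("", n_branches), "")
    )
    core <- tibble::tribble(
      ~reaction, ~metabolite, ~coef,
      "EX_A", "A", -1,
      "R1", "A", -1, "R1", "B", 1,
      "R2", "B", -1, "R2", "NH", -1, "R2", "C", 1, "R2", "N", 1,
      "BIOMASS", "C", -1
    )
    branches <- purrr::map_dfr(seq_len(n_branches), function(i) {
      if (coupling_motif) {
        tibble::tibble(
          reaction = c(rep(branch_ids[i], 4), paste0("EX_", branch_mets[i])),
          metabolite = c("B", "N", branch_mets[i], "NH", branch_mets[i]),
          coef = c(-1, -1, 1, 1, -1)
        )
      } else {
        tibble::tibble(
          reaction = c(rep(branch_ids[i], 2), paste0("EX_", branch_mets[i])),
          metabolite = c("B", branch_mets[i], branch_mets[i]),
          coef = c(-1, 1, -1)
        )
      }
    })
    stoich <- dplyr::bind_rows(core, branches)
    if (add_decoy) {
      mets <- dplyr::bind_rows(mets,
                               tibble::tibble(id = c("Z1", "Z2"), compartment = "c"))
      rxns <- dplyr::bind_rows(
        rxns,
        tibble::tibble(id = "DEC1", lb = 0, ub = 1000, gpr = "gdec")
      )
      stoich <- dplyr::bind_rows(
        stoich,
        tibble::tibble(reaction = "DEC1", metabolite = c("Z1", "Z2"),
                       coef = c(-1, 1))
      )
    }
    model <- metabolic_model(sprintf("TOY_seed%d", seed), mets, rxns, stoich,
                             objective = "BIOMASS")
    growth <- solve_fba(model)
    prod <- solve_fba(model, objective_id = paste0("EX_", branch_mets[1]))
    if (growth$status == "optimal" && growth$objective_value > ZERO_TOL &&
        prod$status == "optimal" && prod$objective_value > ZERO_TOL) {
      attr(model, "product_exchange") <- paste0("EX_", branch_mets[1])
      attr(model, "substrate_uptake") <- uptake
      return(model)
    }
  }
  stop("failed to generate a feasible toy model after 100 attempts", call. = FALSE)
}

#' Exhaustive knockout search (oracle)
#'
#' Tests every subset of `removable` of size 1..k with exactly the same
#' qualification rule as the traversal, by brute force. Used to verify the
#' completeness of the pruned enumeration; infeasible beyond small models.
#'
#' @param model the medium-constrained base model.
#' @param removable candidate reaction ids.
#' @param product_exchange_id product exchange reaction id.
#' @param config a [traversal_config()].
#' @param thresholds optional precomputed thresholds.
#' @param subset_budget refuse to test more subsets than this (default
#'   100000).
#' @return list with `raw_solutions` (tibble: every qualifying subset),
#'   `minimal_solutions` (those with no qualifying proper subset, under the
#'   configured mode), and `lp_count` (number of subsets tested).
#' @export
#' @examples
#' toy <- make_toy1()
#' exhaustive_search(toy, c("R3", "R4"), "EX_P",
#'                   traversal_config(2, mode = "rate_grnt"))$minimal_solutions
exhaustive_search <- function(model, removable, product_exchange_id,
                              config = traversal_config(),
                              thresholds = NULL, subset_budget = 1e5) {
  stopifnot(inherits(config, "traversal_config"))
  if (is.null(thresholds)) {
    thresholds <- compute_thresholds(model, product_exchange_id, config)
  }
  k <- config$target_level
  removable <- lex_sort(removable)
  n_total <- sum(vapply(seq_len(min(k, length(removable))), function(j) {
    choose(length(removable), j)
  }, numeric(1)))
  if (n_total > subset_budget) {
    stop("exhaustive search over ", n_total, " subsets exceeds the budget; ",
         "reduce k or the candidate set", call. = FALSE)
  }
  rows <- list()
  tested <- 0L
  for (j in seq_len(min(k, length(removable)))) {
    combs <- utils::combn(removable, j, simplify = FALSE)
    for (sub in combs) {
      tested <- tested + 1L
      eff <- sub
      genes <- character(0)
      co <- character(0)
      if (config$gene_mode) {
        plan <- plan_gene_deletions(sub, model)
        genes <- plan$deleted_genes
        co <- plan$co_knocked
        eff <- lex_sort(union(sub, co))
      }
      rates <- product_rates_at_optimal_growth(
        apply_knockouts(model, eff), product_exchange_id
      )
      if (rates$status != "optimal") next
      q <- qualify_node(rates$growth, rates$product_min, rates$product_max,
                        thresholds)
      if (q$viable && (q$rate_max || q$rate_grnt)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          level = j,
          reactions = canonical_set(sub),
          effective_reactions = canonical_set(eff),
          growth = rates$growth,
          product_min = rates$product_min,
          product_max = rates$product_max,
          qualifies_max = q$rate_max,
          qualifies_grnt = q$rate_grnt
        )
      }
    }
  }
  raw <- dplyr::bind_rows(rows)
  if (nrow(raw) == 0) {
    raw <- tibble::tibble(
      level = integer(0), reactions = character(0),
      effective_reactions = character(0), growth = numeric(0),
      product_min = numeric(0), product_max = numeric(0),
      qualifies_max = logical(0), qualifies_grnt = logical(0)
    )
  }
  raw <- dplyr::arrange(raw, .data$level, .data$reactions)
  raw$minimal_max <- minimality_flags(raw, "qualifies_max")
  raw$minimal_grnt <- minimality_flags(raw, "qualifies_grnt")
  flag <- if (config$mode == "rate_max") raw$minimal_max else raw$minimal_grnt
  list(
    raw_solutions = raw,
    minimal_solutions = raw[flag, ],
    lp_count = tested
  )
}
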