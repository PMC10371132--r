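# shared helpers: tiny models built in code and set-comparison utilities

solution_sets <- function(tbl) sort(tbl$reactions)

expect_same_solution_sets <- function(a, b) {
  expect_identical(solution_sets(a), solution_sets(b))
}

# TOY1 extended with a structurally isolated reaction Z: M1 -> M2 where M1
# has no producer (a stoichiometric dead end)
toy1_with_orphan <- function() {
  toy <- make_toy1()
  toy$metabolites <- dplyr::bind_rows(
    toy$metabolites,
    tibble::tibble(id = c("M1", "M2"), compartment = "c", is_boundary = FALSE)
  )
  toy$reactions <- dplyr::bind_rows(
    toy$reactions,
    tibble::tibble(id = "Z", lb = 0, ub = 1000, gpr = "", is_exchange = FALSE)
  )
  toy$stoich <- dplyr::bind_rows(
    toy$stoich,
    tibble::tibble(reaction = "Z", metabolite = c("M1", "M2"), coef = c(-1, 1))
  )
  toy
}

# 2-reaction chain hanging off TOY1: B -> Q1 -> Q2 with Q2 a dead end, so
# removing the Q2 dead end exposes Q1 as a second-round dead end
toy1_with_cascade <- function() {
  toy <- make_toy1()
  toy$metabolites <- dplyr::bind_rows(
    toy$metabolites,
    tibble::tibble(id = c("Q1", "Q2"), compartment = "c", is_boundary = FALSE)
  )
  toy$reactions <- dplyr::bind_rows(
    toy$reactions,
    tibble::tibble(id = c("C1", "C2"), lb = 0, ub = 1000, gpr = "",
                   is_exchange = FALSE)
  )
  toy$stoich <- dplyr::bind_rows(
    toy$stoich,
    tibble::tibble(reaction = c("C1", "C1", "C2", "C2"),
                   metabolite = c("B", "Q1", "Q1", "Q2"),
                   coef = c(-1, 1, -1, 1))
  )
  toy
}

# location where the (optional, not shipped) iJR904 BiGG JSON would live for
# the genome-scale reproduction checks
ijr904_path <- function() test_path("models", "iJR904.json")
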