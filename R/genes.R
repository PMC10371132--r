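# Gene-level translation of reaction strategies: minimal disabling gene
# sets, deletion plans, and co-knocked-out reactions (reactions inactivated
# as a side effect of deleting the genes required for a targeted reaction).

#' Minimal gene sets disabling a reaction of a model
#'
#' @param model a [metabolic_model()].
#' @param reaction_id reaction id.
#' @return list of minimal disabling gene sets (possibly empty when the
#'   reaction has no GPR and is therefore non-deletable at the gene level).
#' @export
#' @examples
#' genes_disabling_reaction(make_toy1(), "R4")
genes_disabling_reaction <- function(model, reaction_id) {
  i <- match(reaction_id, model$reactions$id)
  if (is.na(i)) stop("unknown reaction '", reaction_id, "'", call. = FALSE)
  gene_cut_sets(model$reactions$gpr[i])
}

#' Plan gene deletions for a reaction-knockout strategy
#'
#' Chooses, per target reaction, a minimal disabling gene set; among the
#' candidate unions the one with the fewest genes wins, ties broken
#' lexicographically. `co_knocked` lists every *other* reaction whose GPR
#' evaluates inactive under the chosen gene deletions.
#'
#' @param strategy character vector of target reaction ids.
#' @param model a [metabolic_model()].
#' @return a `gene_deletion_plan`: list with `target_reactions`,
#'   `deleted_genes`, `co_knocked`.
#' @export
#' @examples
#' plan_gene_deletions("R4", make_toy1())
plan_gene_deletions <- function(strategy, model) {
  strategy <- lex_sort(unique(strategy))
  if (length(strategy) == 0) {
    return(structure(
      list(target_reactions = character(0), deleted_genes = character(0),
           co_knocked = character(0)),
      class = "gene_deletion_plan"
    ))
  }
  per_rxn <- lapply(strategy, function(r) genes_disabling_reaction(model, r))
  empty <- lengths(per_rxn) == 0
  if (any(empty)) {
    stop("reaction '", strategy[empty][1],
         "' has no GPR and cannot be deleted at the gene level", call. = FALSE)
  }
  # exact union minimization over the per-reaction choices, with a budget:
  # enumerate all combinations when the product of choice counts is small,
  # otherwise fall back to greedy smallest-set-first (GPRs in curated models
  # keep the product tiny in practice)
  n_comb <- prod(lengths(per_rxn))
  best <- NULL
  if (n_comb <= 4096) {
    grid <- expand.grid(lapply(per_rxn, seq_along))
    for (i in seq_len(nrow(grid))) {
      genes <- lex_sort(unique(unlist(
        purrr::map2(per_rxn, as.integer(grid[i, ]), function(sets, j) sets[[j]])
      )))
      if (is.null(best) ||
          length(genes) < length(best) ||
          (length(genes) == length(best) &&
             canonical_set(genes) < canonical_set(best))) {
        best <- genes
      }
    }
  } else {
    best <- lex_sort(unique(unlist(lapply(per_rxn, function(sets) sets[[1]]))))
  }
  co <- co_knocked_reactions(model, best, exclude = strategy)
  structure(
    list(target_reactions = strategy, deleted_genes = best, co_knocked = co),
    class = "gene_deletion_plan"
  )
}

# reactions whose GPR evaluates inactive under the deleted genes
co_knocked_reactions <- function(model, deleted_genes, exclude = character(0)) {
  has_gpr <- nzchar(model$reactions$gpr)
  ids <- model$reactions$id[has_gpr]
  rules <- model$reactions$gpr[has_gpr]
  inactive <- !vapply(rules, eval_gpr, logical(1), deleted_genes = deleted_genes)
  lex_sort(setdiff(ids[inactive], exclude))
}

#' Effective reaction set of a gene-level strategy
#'
#' The reactions actually forced to zero flux when the strategy is realized
#' genetically: the targets plus their co-knocked reactions.
#'
#' @param strategy character vector of target reaction ids.
#' @param model a [metabolic_model()].
#' @return character vector (sorted).
#' @export
expand_with_co_knockouts <- function(strategy, model) {
  plan <- plan_gene_deletions(strategy, model)
  lex_sort(union(plan$target_reactions, plan$co_knocked))
}

#' @export
print.gene_deletion_plan <- function(x, ...) {
  cat("<gene_deletion_plan>\n")
  cat("  targets: ", paste(x$target_reactions, collapse = ", "), "\n", sep = "")
  cat("  genes:   ", paste(x$deleted_genes, collapse = ", "), "\n", sep = "")
  cat("  co-knocked: ",
      if (length(x$co_knocked)) paste(x$co_knocked, collapse = ", ") else "(none)",
      "\n", sep = "")
  invisible(x)
}
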