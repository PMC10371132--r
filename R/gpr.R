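# Gene-protein-reaction (GPR) rules: parsing, boolean evaluation, and minimal
# disabling gene sets. Rules are boolean expressions over gene ids with
# and/or (case-insensitive) and parentheses; genes are opaque strings.

#' Parse a GPR rule string
#'
#' Grammar: `expr := term ('or' term)*`, `term := factor ('and' factor)*`,
#' `factor := '(' expr ')' | gene`. An empty string parses to an empty rule
#' that always evaluates active.
#'
#' @param rule a GPR string, e.g. `"(b0001 and b0002) or b0003"`.
#' @return an expression tree (nested list) of class `gpr`.
#' @export
#' @examples
#' g <- parse_gpr("(g1 and g2) or g3")
#' eval_gpr(g, deleted_genes = c("g1", "g3"))
parse_gpr <- function(rule) {
  if (is.null(rule) || is.na(rule) || !nzchar(trimws(rule))) {
    return(structure(list(op = "empty"), class = "gpr"))
  }
  tokens <- regmatches(rule, gregexpr("\\(|\\)|[^()\\s]+", rule, perl = TRUE))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  advance <- function() {
    tok <- peek()
    pos <<- pos + 1L
    tok
  }
  is_kw <- function(tok, kw) !is.na(tok) && tolower(tok) == kw

  parse_expr <- function() {
    args <- list(parse_term())
    while (is_kw(peek(), "or")) {
      advance()
      args <- c(args, list(parse_term()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (is_kw(peek(), "and")) {
      advance()
      args <- c(args, list(parse_factor()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    tok <- advance()
    if (is.na(tok)) stop("GPR parse error: unexpected end of rule in '", rule, "'",
                         call. = FALSE)
    if (tok == "(") {
      e <- parse_expr()
      if (!identical(advance(), ")")) {
        stop("GPR parse error: missing ')' in '", rule, "'", call. = FALSE)
      }
      return(e)
    }
    if (tok == ")" || is_kw(tok, "and") || is_kw(tok, "or")) {
      stop("GPR parse error: unexpected '", tok, "' in '", rule, "'", call. = FALSE)
    }
    list(op = "gene", id = tok)
  }

  out <- parse_expr()
  if (pos <= length(tokens)) {
    stop("GPR parse error: trailing '", peek(), "' in '", rule, "'", call. = FALSE)
  }
  structure(out, class = "gpr")
}

#' Evaluate a GPR rule under a set of deleted genes
#'
#' Standard boolean semantics with deleted genes false and all other genes
#' true; the empty rule evaluates active.
#'
#' @param gpr a parsed rule from [parse_gpr()] or a rule string.
#' @param deleted_genes character vector of deleted gene ids.
#' @return `TRUE` if the reaction remains active.
#' @export
eval_gpr <- function(gpr, deleted_genes = character(0)) {
  if (is.character(gpr)) gpr <- parse_gpr(gpr)
  rec <- function(node) {
    switch(node$op,
      empty = TRUE,
      gene = !(node$id %in% deleted_genes),
      and = all(vapply(node$args, rec, logical(1))),
      or = any(vapply(node$args, rec, logical(1))),
      stop("corrupt GPR node", call. = FALSE)
    )
  }
  rec(unclass(gpr))
}

#' Genes referenced by a GPR rule
#'
#' @param gpr parsed rule or rule string.
#' @return character vector of gene ids (sorted, unique).
#' @export
gpr_genes <- function(gpr) {
  if (is.character(gpr)) gpr <- parse_gpr(gpr)
  rec <- function(node) {
    switch(node$op,
      empty = character(0),
      gene = node$id,
      unlist(lapply(node$args, rec))
    )
  }
  lex_sort(unique(rec(unclass(gpr))))
}

# Drop supersets from a list of character sets.
minimal_sets <- function(sets) {
  sets <- unique(lapply(sets, lex_sort))
  if (length(sets) <= 1L) return(sets)
  ord <- order(lengths(sets))
  sets <- sets[ord]
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) {
    if (!keep[i]) next
    for (j in seq_along(sets)) {
      if (j <= i || !keep[j]) next
      if (all(sets[[i]] %in% sets[[j]])) keep[j] <- FALSE
    }
  }
  sets[keep]
}

#' Minimal gene sets disabling a reaction
#'
#' Computes all minimal sets of genes whose joint deletion makes the
#' reaction's GPR evaluate inactive (the minimal cut sets of the boolean
#' rule): a cut of an AND is a cut of any operand; a cut of an OR is a union
#' of cuts, one per operand. Reactions without a GPR cannot be disabled by
#' gene deletion and return an empty list.
#'
#' @param gpr parsed rule or rule string.
#' @return list of character vectors, each a minimal disabling gene set,
#'   ordered by size then lexicographically.
#' @export
#' @examples
#' gene_cut_sets("g1 and g2")   # either gene suffices
#' gene_cut_sets("g1 or g2")    # both genes needed
gene_cut_sets <- function(gpr) {
  if (is.character(gpr)) gpr <- parse_gpr(gpr)
  rec <- function(node) {
    switch(node$op,
      empty = list(),
      gene = list(node$id),
      and = minimal_sets(do.call(c, lapply(node$args, rec))),
      or = {
        parts <- lapply(node$args, rec)
        if (any(lengths(parts) == 0L)) return(list())
        combo <- Reduce(function(acc, nxt) {
          out <- list()
          for (a in acc) for (b in nxt) out <- c(out, list(unique(c(a, b))))
          minimal_sets(out)
        }, parts)
        combo
      }
    )
  }
  sets <- rec(unclass(gpr))
  key <- vapply(sets, canonical_set, character(1))
  sets[order(lengths(sets), key)]
}
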