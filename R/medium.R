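# Medium specification: per-exchange maximum uptake rates. Sign convention
# throughout the package: negative exchange flux = uptake, positive =
# secretion.

#' Read a medium specification
#'
#' Accepts a two-column TSV (`exchange_id`, `max_uptake`) or a YAML mapping of
#' exchange id to maximum uptake rate (mmol/gDW/h, non-negative magnitude).
#'
#' @param path file path (`.tsv`/`.txt` or `.yml`/`.yaml`).
#' @return named numeric vector of maximum uptake rates.
#' @export
read_medium <- function(path) {
  if (!file.exists(path)) stop("medium file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    lst <- yaml::read_yaml(path)
    out <- stats::setNames(as.numeric(unlist(lst)), names(lst))
  } else {
    tab <- readr::read_tsv(path, col_types = readr::cols(
      exchange_id = readr::col_character(),
      max_uptake = readr::col_double()
    ), progress = FALSE)
    out <- stats::setNames(tab$max_uptake, tab$exchange_id)
  }
  if (any(out < 0)) stop("uptake rates must be non-negative magnitudes", call. = FALSE)
  out
}

#' Apply a medium to a model
#'
#' Each listed exchange reaction gets `lb = -max_uptake` (uptake allowed up to
#' that rate); every *unlisted* exchange reaction is closed for uptake
#' (`lb = 0`) while secretion stays as permitted by its upper bound: the
#' minimal-medium convention. Non-exchange reactions are untouched. The
#' operation is idempotent for a fixed medium.
#'
#' @param model a [metabolic_model()].
#' @param medium named numeric vector (`exchange id -> max uptake`), a
#'   two-column data frame, or a file path accepted by [read_medium()].
#' @return the constrained model.
#' @export
#' @examples
#' m <- apply_medium(make_toy1(), c(EX_A = 10))
apply_medium <- function(model, medium) {
  stopifnot(inherits(model, "metabolic_model"))
  if (is.character(medium) && length(medium) == 1 && file.exists(medium)) {
    medium <- read_medium(medium)
  }
  if (is.data.frame(medium)) {
    medium <- stats::setNames(medium[[2]], medium[[1]])
  }
  exch <- model$reactions$id[model$reactions$is_exchange]
  unknown <- setdiff(names(medium), model$reactions$id)
  if (length(unknown)) {
    stop("configuration error: unknown exchange id '", unknown[1], "'",
         call. = FALSE)
  }
  not_exch <- setdiff(names(medium), exch)
  if (length(not_exch)) {
    stop("configuration error: '", not_exch[1], "' is not an exchange reaction",
         call. = FALSE)
  }
  if (any(medium < 0)) stop("uptake rates must be non-negative magnitudes", call. = FALSE)
  idx <- model$reactions$is_exchange
  # close all uptakes first (secretion direction untouched), then open listed
  model$reactions$lb[idx] <- pmax(model$reactions$lb[idx], 0)
  for (ex in names(medium)) {
    i <- match(ex, model$reactions$id)
    model$reactions$lb[i] <- -medium[[ex]]
  }
  model
}
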