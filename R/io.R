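# Standard-format model I/O: BiGG-style JSON (read + write) and SBML Level 3
# with the FBC extension (read). Reversibility is preserved purely through
# negative lower bounds.

#' Load a genome-scale metabolic model from disk
#'
#' @param path file path.
#' @param format `"bigg-json"` or `"sbml-fbc"`; `"auto"` guesses from the
#'   file extension.
#' @return a [metabolic_model()].
#' @export
load_model <- function(path, format = c("auto", "bigg-json", "sbml-fbc")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) {
      "sbml-fbc"
    } else {
      "bigg-json"
    }
  }
  switch(format,
    "bigg-json" = read_model_json(path),
    "sbml-fbc" = read_model_sbml(path)
  )
}

#' @rdname load_model
#' @export
read_model_json <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("unparsable BiGG JSON '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  for (field in c("metabolites", "reactions")) {
    if (is.null(doc[[field]])) {
      stop("format error in '", path, "': missing element '", field, "'",
           call. = FALSE)
    }
  }
  mets <- purrr::map_dfr(doc$metabolites, function(m) {
    tibble::tibble(
      id = m$id %||% stop("format error: metabolite without id", call. = FALSE),
      compartment = m$compartment %||% "",
      is_boundary = isTRUE(m$boundary_condition)
    )
  })
  rxn_rows <- purrr::map_dfr(doc$reactions, function(r) {
    tibble::tibble(
      id = r$id %||% stop("format error: reaction without id", call. = FALSE),
      lb = as.numeric(r$lower_bound %||% -1000),
      ub = as.numeric(r$upper_bound %||% 1000),
      gpr = as.character(r$gene_reaction_rule %||% ""),
      obj_coef = as.numeric(r$objective_coefficient %||% 0)
    )
  })
  stoich <- purrr::map_dfr(doc$reactions, function(r) {
    coefs <- r$metabolites
    if (length(coefs) == 0) return(NULL)
    tibble::tibble(
      reaction = r$id,
      metabolite = names(coefs),
      coef = as.numeric(unlist(coefs))
    )
  })
  obj <- rxn_rows$id[rxn_rows$obj_coef != 0]
  if (length(obj) == 0) {
    stop("configuration error: no objective reaction in '", path, "'",
         call. = FALSE)
  }
  genes <- purrr::map_chr(doc$genes %||% list(), function(g) g$id %||% "")
  metabolic_model(
    id = doc$id %||% basename(path),
    metabolites = mets,
    reactions = rxn_rows[c("id", "lb", "ub", "gpr")],
    stoich = stoich,
    objective = obj[1],
    genes = union(genes[nzchar(genes)], character(0))
  )
}

#' Serialize a model to BiGG-style JSON
#'
#' Round-trips with [read_model_json()]: bounds, stoichiometry, GPR rules and
#' the objective are all preserved.
#'
#' @param model a [metabolic_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "metabolic_model"))
  stoich_by_rxn <- split(model$stoich, model$stoich$reaction)
  rxns <- purrr::pmap(model$reactions, function(id, lb, ub, gpr, ...) {
    sub <- stoich_by_rxn[[id]]
    coefs <- if (is.null(sub)) {
      stats::setNames(list(), character(0))
    } else {
      as.list(stats::setNames(sub$coef, sub$metabolite))
    }
    list(
      id = id,
      metabolites = coefs,
      lower_bound = lb,
      upper_bound = ub,
      gene_reaction_rule = gpr,
      objective_coefficient = if (id == model$objective) 1 else 0
    )
  })
  mets <- purrr::pmap(model$metabolites, function(id, compartment, is_boundary, ...) {
    list(id = id, compartment = compartment, boundary_condition = is_boundary)
  })
  doc <- list(
    id = model$id,
    metabolites = mets,
    reactions = rxns,
    genes = lapply(model$genes, function(g) list(id = g))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname load_model
#' @export
read_model_sbml <- function(path) {
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) stop("unparsable SBML '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  ns <- c(
    s = "http://www.sbml.org/sbml/level3/version1/core",
    fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2"
  )
  model_node <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(model_node, "xml_missing")) {
    stop("format error in '", path, "': no <model> element", call. = FALSE)
  }

  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  param_val <- stats::setNames(
    as.numeric(xml2::xml_attr(params, "value")),
    xml2::xml_attr(params, "id")
  )

  species <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  mets <- tibble::tibble(
    id = xml2::xml_attr(species, "id"),
    compartment = xml2::xml_attr(species, "compartment") %||% "",
    is_boundary = xml2::xml_attr(species, "boundaryCondition") %in% "true"
  )

  parse_gpa <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      return(xml2::xml_attr(node, "geneProduct"))
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, parse_gpa, character(1))
    glue <- if (nm == "and") " and " else " or "
    paste0("(", paste(parts, collapse = glue), ")")
  }

  rxn_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (length(rxn_nodes) == 0) {
    stop("format error in '", path, "': no reactions", call. = FALSE)
  }
  rows <- list()
  stoich <- list()
  for (rn in rxn_nodes) {
    rid <- xml2::xml_attr(rn, "id")
    rev <- xml2::xml_attr(rn, "reversible") %in% "true"
    lb_ref <- xml2::xml_attr(rn, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(rn, "upperFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(param_val)) {
      param_val[[lb_ref]]
    } else if (rev) -1000 else 0
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(param_val)) {
      param_val[[ub_ref]]
    } else {
      1000
    }
    gpa <- xml2::xml_find_first(rn, ".//fbc:geneProductAssociation", ns)
    gpr <- ""
    if (!inherits(gpa, "xml_missing")) {
      gpr <- parse_gpa(xml2::xml_child(gpa))
    }
    rows[[rid]] <- tibble::tibble(id = rid, lb = lb, ub = ub, gpr = gpr)
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(rn, paste0("./s:", side, "/s:speciesReference"), ns)
      if (length(refs) == 0) next
      coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      coef[is.na(coef)] <- 1
      if (side == "listOfReactants") coef <- -coef
      stoich[[paste0(rid, side)]] <- tibble::tibble(
        reaction = rid,
        metabolite = xml2::xml_attr(refs, "species"),
        coef = coef
      )
    }
  }
  reactions <- dplyr::bind_rows(rows)
  stoich <- dplyr::bind_rows(stoich)
  # boundary species drop out of the steady-state constraint; remove rows
  stoich <- stoich[!stoich$metabolite %in% mets$id[mets$is_boundary], ]

  obj_node <- xml2::xml_find_first(
    doc, ".//fbc:listOfObjectives//fbc:fluxObjective", ns
  )
  if (inherits(obj_node, "xml_missing")) {
    stop("configuration error: no FBC objective in '", path, "'", call. = FALSE)
  }
  objective <- xml2::xml_attr(obj_node, "reaction")

  gene_nodes <- xml2::xml_find_all(doc, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  genes <- xml2::xml_attr(gene_nodes, "id")

  metabolic_model(
    id = xml2::xml_attr(model_node, "id") %||% basename(path),
    metabolites = mets[!mets$is_boundary | mets$id %in% stoich$metabolite, ],
    reactions = reactions,
    stoich = stoich,
    objective = objective,
    genes = genes
  )
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
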