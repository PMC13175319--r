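#' Read a BiGG-dialect JSON model
#'
#' Parses a constraint-based model from the JSON dialect used by the BiGG
#' database and by COBRA-style toolchains: top-level keys `metabolites`,
#' `reactions`, `genes`; each reaction carries a `metabolites` map of signed
#' stoichiometric coefficients, `lower_bound`, `upper_bound` and an optional
#' `gene_reaction_rule`. The objective is taken from the reaction with a
#' non-zero `objective_coefficient`. Real *E. coli* core-model files load
#' unmodified; [write_model_json()] inverts the mapping so that a
#' write-then-parse round trip is the identity on all semantic fields.
#'
#' @param path Path to a JSON file (or a JSON string).
#' @return A validated `constraint_model`.
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (key in c("metabolites", "reactions", "genes")) {
    if (is.null(doc[[key]])) {
      abort(paste0("model document is missing required key '", key, "'"))
    }
  }
  mets <- dplyr::bind_rows(lapply(doc$metabolites, function(m) {
    if (is.null(m$id)) abort("metabolite entry is missing required key 'id'")
    tibble::tibble(
      id = m$id,
      name = m$name %||% m$id,
      compartment = m$compartment %||% sub(".*_([a-z])$", "\\1", m$id),
      formula = m$formula %||% NA_character_,
      charge = as.integer(m$charge %||% NA_integer_)
    )
  }))
  objective <- NA_character_
  rxns <- dplyr::bind_rows(lapply(doc$reactions, function(r) {
    for (key in c("id", "metabolites", "lower_bound", "upper_bound")) {
      if (is.null(r[[key]])) {
        abort(paste0("reaction entry", if (!is.null(r$id)) paste0(" '", r$id, "'"),
                     " is missing required key '", key, "'"))
      }
    }
    if (!is.null(r$objective_coefficient) && r$objective_coefficient != 0) {
      objective <<- r$id
    }
    gpr <- r$gene_reaction_rule %||% ""
    rxn_row(
      id = r$id,
      stoichiometry = unlist(r$metabolites),
      lower_bound = as.numeric(r$lower_bound),
      upper_bound = as.numeric(r$upper_bound),
      gpr = if (nzchar(gpr)) gpr else NA_character_,
      name = r$name %||% r$id,
      subsystem = r$subsystem %||% NA_character_
    )
  }))
  genes <- vapply(doc$genes, function(g) {
    if (is.character(g)) g else g$id %||% abort("gene entry is missing 'id'")
  }, character(1))
  constraint_model(metabolites = mets, reactions = rxns, genes = genes,
                   objective = objective, id = doc$id %||% "model")
}

#' Write a model as BiGG-dialect JSON
#'
#' @param model A `constraint_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    out <- list(id = m$id, name = m$name, compartment = m$compartment)
    if (!is.na(m$formula)) out$formula <- m$formula
    if (!is.na(m$charge)) out$charge <- m$charge
    out
  })
  rxns <- lapply(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    st <- r$stoichiometry[[1]]
    out <- list(
      id = r$id, name = r$name,
      metabolites = as.list(st),
      lower_bound = r$lower_bound, upper_bound = r$upper_bound,
      gene_reaction_rule = if (is.na(r$gpr)) "" else r$gpr
    )
    if (!is.na(r$subsystem)) out$subsystem <- r$subsystem
    if (!is.na(model$objective) && r$id == model$objective) {
      out$objective_coefficient <- 1
    }
    out
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
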