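#' Construct a constraint-based metabolic model
#'
#' A `constraint_model` bundles the species, reactions, genes and objective of
#' a stoichiometric metabolic network: the ingredients of a flux-balance
#' problem (the stoichiometric matrix S, flux bounds, and the objective
#' vector). Metabolite identifiers carry a compartment suffix (`"_c"` cytosol,
#' `"_e"` extracellular); exchange reactions are boundary pseudo-reactions
#' touching a single extracellular metabolite, with negative flux denoting
#' uptake.
#'
#' @param metabolites A data frame with column `id` and optionally `name`,
#'   `compartment`, `formula`, `charge`. The compartment is derived from the
#'   id suffix when absent.
#' @param reactions A data frame with columns `id`, `stoichiometry` (a list
#'   column of named numeric vectors, negative = consumed), `lower_bound`,
#'   `upper_bound`, and optionally `name`, `gpr` (a boolean gene expression
#'   using AND/OR/parentheses), `subsystem`.
#' @param genes Character vector of gene identifiers.
#' @param objective Reaction id maximized by convention (may be `NA`).
#' @param id Model identifier.
#'
#' @return An object of class `constraint_model`.
#' @examples
#' m <- constraint_model(
#'   metabolites = tibble::tibble(id = c("a_e", "a_c")),
#'   reactions = tibble::tibble(
#'     id = c("EX_a", "At"),
#'     stoichiometry = list(c(a_e = -1), c(a_e = -1, a_c = 1)),
#'     lower_bound = c(-10, 0), upper_bound = c(0, 1000)
#'   ),
#'   objective = "At"
#' )
#' m
#' @export
constraint_model <- function(metabolites, reactions, genes = character(),
                             objective = NA_character_, id = "model") {
  mets <- tibble::as_tibble(metabolites)
  if (!"id" %in% names(mets)) abort("`metabolites` must have an `id` column.")
  if (!"name" %in% names(mets)) mets$name <- mets$id
  if (!"compartment" %in% names(mets)) {
    mets$compartment <- sub(".*_([a-z])$", "\\1", mets$id)
  }
  if (!"formula" %in% names(mets)) mets$formula <- NA_character_
  if (!"charge" %in% names(mets)) mets$charge <- NA_integer_
  mets <- mets[, c("id", "name", "compartment", "formula", "charge")]

  rxns <- tibble::as_tibble(reactions)
  needed <- c("id", "stoichiometry", "lower_bound", "upper_bound")
  missing <- setdiff(needed, names(rxns))
  if (length(missing) > 0) {
    abort(paste0("`reactions` is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!"name" %in% names(rxns)) rxns$name <- rxns$id
  if (!"gpr" %in% names(rxns)) rxns$gpr <- NA_character_
  if (!"subsystem" %in% names(rxns)) rxns$subsystem <- NA_character_
  rxns <- rxns[, c("id", "name", "stoichiometry", "lower_bound",
                   "upper_bound", "gpr", "subsystem")]

  model <- structure(
    list(id = id, metabolites = mets, reactions = rxns,
         genes = as.character(genes), objective = objective),
    class = "constraint_model"
  )
  issues <- validate_model(model)
  if (nrow(issues) > 0) {
    abort(paste0("Invalid model:\n",
                 paste0("- ", issues$message, collapse = "\n")))
  }
  model
}

#' Validate a constraint model
#'
#' Checks the structural invariants of a model and reports every violation:
#' unique metabolite/reaction ids, compartment suffixes consistent with the
#' compartment field, `lower_bound <= upper_bound`, non-empty stoichiometries
#' with no dangling metabolite references, GPR genes present in the gene list,
#' an existing objective reaction, and exchange reactions (single-metabolite
#' boundary reactions) touching only extracellular species.
#'
#' @param model A `constraint_model` (or a bare list with the same fields).
#' @return A tibble with columns `rule` and `message`, one row per violation
#'   (zero rows for a valid model).
#' @export
validate_model <- function(model) {
  issues <- list()
  note <- function(rule, message) {
    issues[[length(issues) + 1]] <<- tibble::tibble(rule = rule, message = message)
  }
  mets <- model$metabolites
  rxns <- model$reactions

  dup_m <- unique(mets$id[duplicated(mets$id)])
  if (length(dup_m) > 0) {
    note("unique_metabolite_ids",
         paste0("duplicate metabolite id(s): ", paste(dup_m, collapse = ", ")))
  }
  dup_r <- unique(rxns$id[duplicated(rxns$id)])
  if (length(dup_r) > 0) {
    note("unique_reaction_ids",
         paste0("duplicate reaction id(s): ", paste(dup_r, collapse = ", ")))
  }
  bad_comp <- mets$id[!is.na(mets$compartment) &
                        sub(".*_([a-z])$", "\\1", mets$id) != mets$compartment]
  for (m in bad_comp) {
    note("compartment_suffix",
         paste0("metabolite ", m, ": id suffix does not match compartment field"))
  }
  unknown_comp <- mets$id[!mets$compartment %in% c("c", "e")]
  for (m in unknown_comp) {
    note("compartment_known",
         paste0("metabolite ", m, ": compartment must be one of {c, e}"))
  }
  bad_b <- rxns$id[rxns$lower_bound > rxns$upper_bound]
  for (r in bad_b) {
    note("bounds_ordered", paste0("reaction ", r, ": lower_bound > upper_bound"))
  }
  for (i in seq_len(nrow(rxns))) {
    st <- rxns$stoichiometry[[i]]
    if (length(st) == 0) {
      note("stoichiometry_nonempty",
           paste0("reaction ", rxns$id[i], ": empty stoichiometry"))
      next
    }
    dangling <- setdiff(names(st), mets$id)
    if (length(dangling) > 0) {
      note("no_dangling_metabolites",
           paste0("reaction ", rxns$id[i], ": references unknown metabolite(s) ",
                  paste(dangling, collapse = ", ")))
    }
    # single-metabolite boundary reactions must sit on the extracellular side
    if (length(st) == 1 && all(names(st) %in% mets$id)) {
      comp <- mets$compartment[match(names(st), mets$id)]
      if (!identical(comp, "e")) {
        note("exchange_extracellular",
             paste0("reaction ", rxns$id[i],
                    ": exchange must touch exactly one metabolite in compartment e"))
      }
    }
  }
  for (i in seq_len(nrow(rxns))) {
    g <- rxns$gpr[i]
    if (is.na(g) || !nzchar(g)) next
    leaves <- tryCatch(gpr_genes(parse_gpr(g)), error = function(e) NULL)
    if (is.null(leaves)) {
      note("gpr_parse", paste0("reaction ", rxns$id[i], ": unparsable GPR '", g, "'"))
    } else {
      unknown <- setdiff(leaves, model$genes)
      if (length(unknown) > 0) {
        note("gpr_genes_known",
             paste0("reaction ", rxns$id[i], ": GPR gene(s) not in model: ",
                    paste(unknown, collapse = ", ")))
      }
    }
  }
  if (!is.na(model$objective) && !model$objective %in% rxns$id) {
    note("objective_exists",
         paste0("objective reaction '", model$objective, "' not in model"))
  }
  if (length(issues) == 0) {
    tibble::tibble(rule = character(), message = character())
  } else {
    dplyr::bind_rows(issues)
  }
}

#' @export
print.constraint_model <- function(x, ...) {
  cat("<constraint_model> ", x$id, "\n", sep = "")
  cat("  metabolites: ", nrow(x$metabolites),
      "  reactions: ", nrow(x$reactions),
      "  genes: ", length(x$genes), "\n", sep = "")
  cat("  objective: ", if (is.na(x$objective)) "<none>" else x$objective,
      "\n", sep = "")
  invisible(x)
}

#' Access the reaction or metabolite table of a model
#'
#' @param model A `constraint_model`.
#' @return A tibble (reactions carry a `stoichiometry` list column).
#' @export
reactions <- function(model) model$reactions

#' @rdname reactions
#' @export
metabolites <- function(model) model$metabolites

#' Identify exchange reactions
#'
#' Exchange (boundary) reactions touch exactly one metabolite, in the
#' extracellular compartment; by convention they are written as
#' `met_e ->` so that negative flux is uptake and positive flux secretion.
#'
#' @param model A `constraint_model`.
#' @return A named logical vector over reaction ids.
#' @export
is_exchange <- function(model) {
  comp <- setNames(model$metabolites$compartment, model$metabolites$id)
  out <- map_lgl(model$reactions$stoichiometry, function(st) {
    length(st) == 1 && identical(unname(comp[names(st)]), "e")
  })
  setNames(out, model$reactions$id)
}

#' Assemble the stoichiometric matrix
#'
#' Builds the dense stoichiometric matrix S of the model: entry (i, j) is the
#' signed coefficient of metabolite i in reaction j (negative = consumed).
#' Rows follow metabolite order, columns reaction order, so the steady-state
#' constraint of flux balance analysis reads `S %*% v == 0`.
#'
#' @param model A `constraint_model`.
#' @return A numeric matrix with metabolite ids as rownames and reaction ids
#'   as colnames.
#' @export
stoichiometric_matrix <- function(model) {
  mets <- model$metabolites$id
  rxns <- model$reactions$id
  S <- matrix(0, nrow = length(mets), ncol = length(rxns),
              dimnames = list(mets, rxns))
  for (j in seq_along(rxns)) {
    st <- model$reactions$stoichiometry[[j]]
    S[names(st), j] <- unname(st)
  }
  S
}

#' Override flux bounds on a model
#'
#' @param model A `constraint_model`.
#' @param reaction Reaction id.
#' @param lower,upper New bounds; `NULL` leaves a bound unchanged.
#' @return The modified model.
#' @export
set_bounds <- function(model, reaction, lower = NULL, upper = NULL) {
  i <- match(reaction, model$reactions$id)
  if (is.na(i)) abort(paste0("unknown reaction '", reaction, "'"))
  if (!is.null(lower)) model$reactions$lower_bound[i] <- lower
  if (!is.null(upper)) model$reactions$upper_bound[i] <- upper
  if (model$reactions$lower_bound[i] > model$reactions$upper_bound[i]) {
    abort(paste0("reaction ", reaction, ": lower_bound > upper_bound"))
  }
  model
}

# Apply a named list of c(lb, ub) overrides; names are reaction ids.
apply_bound_overrides <- function(model, overrides) {
  for (r in names(overrides)) {
    b <- overrides[[r]]
    model <- set_bounds(model, r, lower = b[[1]], upper = b[[2]])
  }
  model
}

# Internal: one reaction row as a tibble.
rxn_row <- function(id, stoichiometry, lower_bound, upper_bound,
                    gpr = NA_character_, name = id, subsystem = NA_character_) {
  tibble::tibble(id = id, name = name, stoichiometry = list(stoichiometry),
                 lower_bound = lower_bound, upper_bound = upper_bound,
                 gpr = gpr, subsystem = subsystem)
}

# Internal: metabolite rows from ids (+ optional formulas).
met_rows <- function(ids, formulas = NULL, names = ids) {
  tibble::tibble(
    id = ids, name = names,
    compartment = sub(".*_([a-z])$", "\\1", ids),
    formula = if (is.null(formulas)) NA_character_ else unname(formulas[ids]),
    charge = NA_integer_
  )
}
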