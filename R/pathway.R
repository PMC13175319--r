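#' Options for the l-fuculose pathway extension
#'
#' Toggles and bounds for the reactions grafted onto a host network to model
#' l-fuculose biosynthesis: the FucA aldolase condensing lactaldehyde (LAD)
#' and dihydroxyacetone phosphate (DHAP) into l-fuculose-1-phosphate, its
#' dephosphorylation by innate sugar phosphatases, and the competing routes
#' (FucI isomerase, FucK kinase, FucO 1,2-propanediol oxidoreductase, AldA
#' aldehyde dehydrogenase).
#'
#' @param include_isomerase Add the FucI isomerization (l-fuculose to
#'   l-fucose) with fucose export. Default `TRUE`.
#' @param include_kinase Add the FucK rephosphorylation of l-fuculose.
#'   Default `TRUE`.
#' @param include_aldA Add the AldA oxidation of LAD to lactate. Default
#'   `TRUE`.
#' @param lad_uptake_bound Maximum lactaldehyde uptake, mmol/gDW/h
#'   (default 5; the study medium supplies LAD at half the glucose charge in
#'   round numbers, and only the ratio matters for the scan campaigns).
#' @param fuculose_export Add l-fuculose transport and exchange (secretion
#'   only). Default `TRUE`.
#' @return A list of class `pathway_options`.
#' @export
pathway_options <- function(include_isomerase = TRUE, include_kinase = TRUE,
                            include_aldA = TRUE, lad_uptake_bound = 5,
                            fuculose_export = TRUE) {
  if (lad_uptake_bound < 0) abort("`lad_uptake_bound` must be >= 0")
  structure(
    list(include_isomerase = include_isomerase,
         include_kinase = include_kinase,
         include_aldA = include_aldA,
         lad_uptake_bound = lad_uptake_bound,
         fuculose_export = fuculose_export),
    class = "pathway_options"
  )
}

# Elemental formulas of the pathway species (neutral forms).
PATHWAY_FORMULAS <- c(
  lad = "C3H6O2", fc1p = "C6H13O8P", fcl = "C6H12O5", fuc = "C6H12O5",
  pdo = "C3H8O2", lac = "C3H6O3", h2o = "H2O", pi = "H3O4P",
  dhap = "C3H7O6P"
)

#' Extend a host model with the l-fuculose pathway
#'
#' Adds the l-fuculose biosynthesis reactions and their competing routes to a
#' host network, non-destructively (every host reaction and bound is
#' unchanged; removing the added reaction ids recovers the host exactly):
#'
#' * `EX_lad`, `LADt` — lactaldehyde exchange (uptake up to
#'   `lad_uptake_bound`) and transport;
#' * `FCPA` — FucA aldolase, `dhap_c + lad_c <-> fc1p_c` (reversible: with
#'   slow dephosphorylation the reverse reaction reconverts
#'   fuculose-1-phosphate to LAD and DHAP);
#' * `FCP` — dephosphorylation to l-fuculose by innate sugar phosphatases
#'   (no gene rule; water and orthophosphate are included when the host
#'   carries them and elided otherwise);
#' * `FCLK` — FucK kinase (rephosphorylation, ATP-dependent);
#' * `FUCI`, `FUCt`, `EX_fuc` — FucI isomerization to l-fucose with export;
#' * `FUCO` — FucO 1,2-PDO oxidoreductase, `lad_c + nadh_c <-> pdo_c +
#'   nad_c`;
#' * `ALDA` — AldA oxidation of LAD to lactate;
#' * `FCLt`, `EX_fcl` — l-fuculose secretion (the boundary reaction that
#'   lets FBA carry net fuculose production);
#' * `PDOt`, `EX_pdo` — 1,2-PDO secretion.
#'
#' Product exchanges are secretion-only: the medium supplies neither
#' 1,2-PDO, l-fucose nor l-fuculose, and a reversible product exchange would
#' let the LP manufacture lactaldehyde from imported 1,2-PDO.
#'
#' @param model Host `constraint_model`; must contain DHAP, NAD/NADH and
#'   ATP/ADP (ids configurable through `host_ids`).
#' @param options A [pathway_options()] object.
#' @param host_ids Named character vector mapping the roles `dhap`, `nad`,
#'   `nadh`, `atp`, `adp`, `lac`, `h2o`, `pi` to host metabolite ids.
#' @return The extended `constraint_model`.
#' @export
extend_with_fuculose_pathway <- function(model, options = pathway_options(),
                                         host_ids = c(
                                           dhap = "dhap_c", nad = "nad_c",
                                           nadh = "nadh_c", atp = "atp_c",
                                           adp = "adp_c", lac = "lac_c",
                                           h2o = "h2o_c", pi = "pi_c")) {
  stopifnot(inherits(options, "pathway_options"))
  host_mets <- model$metabolites$id
  required <- c("dhap", "nad", "nadh", "atp", "adp")
  for (role in required) {
    if (!role %in% names(host_ids) || !host_ids[[role]] %in% host_mets) {
      abort(paste0("host model lacks required metabolite for role '", role,
                   "' (looked for '",
                   if (role %in% names(host_ids)) host_ids[[role]] else "<unmapped>",
                   "')"))
    }
  }
  if (options$include_aldA &&
      (!"lac" %in% names(host_ids) || !host_ids[["lac"]] %in% host_mets)) {
    abort("host model lacks required metabolite for role 'lac' (needed by ALDA)")
  }
  has_h2o <- "h2o" %in% names(host_ids) && host_ids[["h2o"]] %in% host_mets
  has_pi <- "pi" %in% names(host_ids) && host_ids[["pi"]] %in% host_mets

  dhap <- host_ids[["dhap"]]; nad <- host_ids[["nad"]]
  nadh <- host_ids[["nadh"]]; atp <- host_ids[["atp"]]; adp <- host_ids[["adp"]]

  new_mets <- c("lad_e", "lad_c", "fc1p_c", "fcl_c")
  rows <- list(
    rxn_row("EX_lad", c(lad_e = -1), -options$lad_uptake_bound, 0,
            name = "lactaldehyde exchange"),
    rxn_row("LADt", c(lad_e = -1, lad_c = 1), 0, 1000,
            name = "lactaldehyde transport"),
    rxn_row(
      "FCPA",
      setNames(c(-1, -1, 1), c(dhap, "lad_c", "fc1p_c")), -1000, 1000,
      gpr = "fucA", name = "fuculose-1-phosphate aldolase (FucA)"),
    rxn_row(
      "FCP",
      if (has_h2o && has_pi) {
        setNames(c(-1, -1, 1, 1),
                 c("fc1p_c", host_ids[["h2o"]], "fcl_c", host_ids[["pi"]]))
      } else {
        c(fc1p_c = -1, fcl_c = 1)
      },
      0, 1000, name = "l-fuculose phosphatase (innate)"),
    rxn_row(
      "FUCO",
      setNames(c(-1, -1, 1, 1), c("lad_c", nadh, "pdo_c", nad)), -1000, 1000,
      gpr = "fucO", name = "1,2-PDO oxidoreductase (FucO)"),
    rxn_row("PDOt", c(pdo_c = -1, pdo_e = 1), 0, 1000,
            name = "1,2-PDO transport"),
    rxn_row("EX_pdo", c(pdo_e = -1), 0, 1000, name = "1,2-PDO exchange")
  )
  new_mets <- c(new_mets, "pdo_c", "pdo_e")
  if (options$include_kinase) {
    rows[[length(rows) + 1]] <- rxn_row(
      "FCLK", setNames(c(-1, -1, 1, 1), c("fcl_c", atp, "fc1p_c", adp)),
      0, 1000, gpr = "fucK", name = "l-fuculose kinase (FucK)")
  }
  if (options$include_isomerase) {
    rows[[length(rows) + 1]] <- rxn_row(
      "FUCI", c(fcl_c = -1, fuc_c = 1), -1000, 1000, gpr = "fucI",
      name = "l-fucose isomerase (FucI)")
    rows[[length(rows) + 1]] <- rxn_row(
      "FUCt", c(fuc_c = -1, fuc_e = 1), 0, 1000, name = "l-fucose transport")
    rows[[length(rows) + 1]] <- rxn_row(
      "EX_fuc", c(fuc_e = -1), 0, 1000, name = "l-fucose exchange")
    new_mets <- c(new_mets, "fuc_c", "fuc_e")
  }
  if (options$include_aldA) {
    rows[[length(rows) + 1]] <- rxn_row(
      "ALDA",
      if (has_h2o) {
        setNames(c(-1, -1, -1, 1, 1),
                 c("lad_c", nad, host_ids[["h2o"]], host_ids[["lac"]], nadh))
      } else {
        setNames(c(-1, -1, 1, 1), c("lad_c", nad, host_ids[["lac"]], nadh))
      },
      0, 1000, gpr = "aldA", name = "lactaldehyde dehydrogenase (AldA)")
  }
  if (options$fuculose_export) {
    rows[[length(rows) + 1]] <- rxn_row(
      "FCLt", c(fcl_c = -1, fcl_e = 1), 0, 1000, name = "l-fuculose transport")
    rows[[length(rows) + 1]] <- rxn_row(
      "EX_fcl", c(fcl_e = -1), 0, 1000, name = "l-fuculose exchange")
    new_mets <- c(new_mets, "fcl_e")
  }
  new_rxns <- dplyr::bind_rows(rows)

  collisions <- intersect(new_rxns$id, model$reactions$id)
  if (length(collisions) > 0) {
    abort(paste0("host model already contains reaction id(s): ",
                 paste(collisions, collapse = ", ")))
  }
  new_mets <- setdiff(new_mets, host_mets)
  formulas <- setNames(
    unname(PATHWAY_FORMULAS[sub("_[a-z]$", "", new_mets)]), new_mets)
  new_genes <- c("fucA", "fucO",
                 if (options$include_kinase) "fucK",
                 if (options$include_isomerase) "fucI",
                 if (options$include_aldA) "aldA")

  constraint_model(
    metabolites = dplyr::bind_rows(model$metabolites,
                                   met_rows(new_mets, formulas)),
    reactions = dplyr::bind_rows(model$reactions, new_rxns),
    genes = union(model$genes, new_genes),
    objective = model$objective,
    id = paste0(model$id, "+fuculose")
  )
}

#' Parse an elemental formula
#'
#' @param formula A formula string such as `"C6H13O8P"`.
#' @return Named numeric vector of element counts.
#' @export
parse_formula <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (length(parts) == 0 || paste(parts, collapse = "") != formula) {
    abort(paste0("cannot parse formula '", formula, "'"))
  }
  el <- sub("[0-9]*$", "", parts)
  ct <- as.numeric(sub("^[A-Z][a-z]?", "", parts))
  ct[is.na(ct)] <- 1
  tapply(ct, el, sum)[unique(el)]
}

# Default cofactor pairs: the reduced/phosphorylated partner is counted as
# the base partner plus a net transfer formula, so redox and phosphoryl
# reactions balance exactly without proton or charge bookkeeping.
default_cofactor_pairs <- function() {
  list(
    list(carrier = "nadh_c", base = "nad_c", net = "H2"),
    list(carrier = "atp_c", base = "adp_c", net = "HO3P")
  )
}

#' Check elemental mass balance of model reactions
#'
#' Report-only safeguard for the pathway stoichiometry. For every
#' non-exchange, non-biomass reaction, the per-element imbalance
#' (products minus substrates) is computed from metabolite formulas.
#' Cofactor pairs are declared balanced-by-pair with a net transfer formula
#' (NADH = NAD + H2 in reducing equivalents, ATP = ADP + HO3P); metabolites
#' without a formula that are not part of a cancelling pair make a reaction
#' unknown rather than unbalanced (lumped host reactions deliberately elide
#' CO2 and water and carry no formulas). When the host lacks free water /
#' orthophosphate species, an imbalance attributable purely to elided
#' H2O/H3PO4 is flagged as balanced-with-elision.
#'
#' @param model A `constraint_model`.
#' @param pairs List of cofactor pair declarations
#'   (`list(carrier=, base=, net=)`); defaults to NADH/NAD and ATP/ADP.
#' @return A tibble with one row per reaction: `reaction`, `checkable`,
#'   `balanced`, `imbalance` (e.g. `"H-2 O-1"`), `elision` (species charged
#'   with the imbalance, or `""`).
#' @export
check_mass_balance <- function(model, pairs = default_cofactor_pairs()) {
  formulas <- setNames(model$metabolites$formula, model$metabolites$id)
  exch <- is_exchange(model)
  allow <- list()
  if (!"h2o_c" %in% model$metabolites$id) allow$h2o <- parse_formula("H2O")
  if (!"pi_c" %in% model$metabolites$id) allow$pi <- parse_formula("H3O4P")

  rows <- lapply(seq_len(nrow(model$reactions)), function(i) {
    rid <- model$reactions$id[i]
    skip <- exch[[rid]] || grepl("biomass", rid, ignore.case = TRUE) ||
      (!is.na(model$objective) && rid == model$objective)
    if (skip) {
      return(tibble::tibble(reaction = rid, checkable = FALSE, balanced = NA,
                            imbalance = "", elision = ""))
    }
    st <- model$reactions$stoichiometry[[i]]
    elements <- c(); unknown <- c()
    bump <- function(vec, add) {
      for (nm in names(add)) {
        vec[nm] <- (if (nm %in% names(vec)) vec[[nm]] else 0) + add[[nm]]
      }
      vec
    }
    fml <- function(met) {
      f <- unname(formulas[met])
      if (length(f) == 0) NA_character_ else f
    }
    for (met in names(st)) {
      coef <- st[[met]]
      pair <- purrr::detect(pairs, ~ .x$carrier == met)
      if (!is.null(pair)) {
        elements <- bump(elements, coef * parse_formula(pair$net))
        base <- pair$base
        if (!is.na(fml(base))) {
          elements <- bump(elements, coef * parse_formula(fml(base)))
        } else {
          unknown <- bump(unknown, setNames(coef, base))
        }
      } else if (!is.na(fml(met))) {
        elements <- bump(elements, coef * parse_formula(fml(met)))
      } else {
        unknown <- bump(unknown, setNames(coef, met))
      }
    }
    if (length(unknown) > 0 && any(abs(unknown) > 1e-9)) {
      return(tibble::tibble(reaction = rid, checkable = FALSE, balanced = NA,
                            imbalance = "", elision = ""))
    }
    imb <- elements[abs(elements) > 1e-6]
    if (length(imb) == 0) {
      return(tibble::tibble(reaction = rid, checkable = TRUE, balanced = TRUE,
                            imbalance = "", elision = ""))
    }
    # attributable to elided water/phosphate?
    elision <- ""
    if (length(allow) > 0) {
      els <- unique(c(names(imb), unlist(lapply(allow, names))))
      M <- sapply(allow, function(f) {
        v <- setNames(numeric(length(els)), els); v[names(f)] <- f; v
      })
      M <- matrix(M, nrow = length(els),
                  dimnames = list(els, names(allow)))
      y <- setNames(numeric(length(els)), els); y[names(imb)] <- imb
      fit <- tryCatch(qr.solve(qr(M), y), error = function(e) NULL)
      if (!is.null(fit) && max(abs(M %*% fit - y)) <= 1e-6) {
        used <- names(allow)[abs(fit) > 1e-9]
        if (length(used) > 0) {
          elision <- paste(used, collapse = "+")
          return(tibble::tibble(reaction = rid, checkable = TRUE,
                                balanced = TRUE, imbalance = "",
                                elision = elision))
        }
      }
    }
    tibble::tibble(
      reaction = rid, checkable = TRUE, balanced = FALSE,
      imbalance = paste0(names(imb), ifelse(imb > 0, "+", ""), imb,
                         collapse = " "),
      elision = "")
  })
  dplyr::bind_rows(rows)
}
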