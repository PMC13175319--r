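#' Specification of the bundled mini-core network
#'
#' Parameters of the synthetic "mini-core" host model, a hand-specified
#' functional emulation of the *E. coli* core network: glucose uptake and
#' upper glycolysis with the DHAP/G3P split and triose-phosphate isomerase,
#' lower glycolysis, respiration with a fixed P/O ratio, fermentative
#' overflow (lactate, acetate), a lumped biomass reaction and non-growth ATP
#' maintenance. Hand-specifying the host keeps the package download-free and
#' makes every campaign property derivable from stated stoichiometry; a real
#' BiGG-dialect core-model file loads through [read_model_json()] just as
#' well.
#'
#' @param glc_uptake Glucose exchange lower bound, mmol/gDW/h (default -10).
#' @param lad_uptake Lactaldehyde uptake magnitude consumed by the pathway
#'   extension default, mmol/gDW/h (default 5; the study medium is 10 g/L
#'   glucose with 5 mM LAD, and only the ratio matters).
#' @param o2_uptake Oxygen exchange lower bound under aerobic conditions
#'   (default -20); anaerobic runs set it to 0.
#' @param atp_maintenance Non-growth ATP maintenance flux lower bound
#'   (default 1).
#' @param biomass_atp ATP consumed per unit biomass (default 10, alongside
#'   1 pyruvate).
#' @param po_ratio ATP formed per NADH oxidized by respiration (default 2).
#' @return A list of class `mini_core_spec`.
#' @export
mini_core_spec <- function(glc_uptake = -10, lad_uptake = 5, o2_uptake = -20,
                           atp_maintenance = 1, biomass_atp = 10,
                           po_ratio = 2) {
  if (atp_maintenance < 0) abort("`atp_maintenance` must be >= 0")
  structure(
    list(glc_uptake = glc_uptake, lad_uptake = lad_uptake,
         o2_uptake = o2_uptake, atp_maintenance = atp_maintenance,
         biomass_atp = biomass_atp, po_ratio = po_ratio),
    class = "mini_core_spec"
  )
}

#' Build the bundled mini-core host model
#'
#' Deterministically constructs the synthetic host network described in
#' [mini_core_spec()]. Internal reactions (lumped, deliberately not
#' elementally balanced — they elide CO2 and water and carry no formulas
#' except DHAP and lactate, which the fucose pathway checks against):
#'
#' * `GLYC_UP`: glc + 2 ATP -> DHAP + G3P + 2 ADP (upper glycolysis)
#' * `TPI`: DHAP <-> G3P (triose-phosphate isomerase, gene `tpiA`)
#' * `GLYC_LO`: G3P + 2 ADP + NAD -> pyruvate + 2 ATP + NADH
#' * `RESP`: NADH + 1/2 O2 + `po_ratio` ADP -> NAD + `po_ratio` ATP
#' * `LDH`: pyruvate + NADH -> lactate + NAD (fermentative overflow)
#' * `ACK`: pyruvate + ADP -> acetate + ATP (overflow with ATP gain)
#' * `BIOMASS`: pyruvate + `biomass_atp` ATP -> ADP + biomass (objective)
#' * `ATPM`: ATP -> ADP, lower bound = `atp_maintenance`
#'
#' plus transport/exchange for glucose, oxygen, acetate, lactate and
#' biomass.
#'
#' @param spec A [mini_core_spec()].
#' @return A `constraint_model` with objective `BIOMASS`.
#' @examples
#' model <- build_mini_core()
#' solve_fba(model)$objective_value
#' @export
build_mini_core <- function(spec = mini_core_spec()) {
  stopifnot(inherits(spec, "mini_core_spec"))
  mets <- met_rows(
    c("glc_e", "glc_c", "dhap_c", "g3p_c", "pyr_c", "nad_c", "nadh_c",
      "atp_c", "adp_c", "o2_e", "o2_c", "ac_c", "ac_e", "lac_c", "lac_e",
      "biomass_e"),
    formulas = c(dhap_c = "C3H7O6P", lac_c = "C3H6O3", lac_e = "C3H6O3")
  )
  p <- spec$po_ratio
  batp <- spec$biomass_atp
  rxns <- dplyr::bind_rows(
    rxn_row("EX_glc", c(glc_e = -1), spec$glc_uptake, 0,
            name = "glucose exchange"),
    rxn_row("GLCt", c(glc_e = -1, glc_c = 1), 0, 1000,
            name = "glucose transport"),
    rxn_row("GLYC_UP",
            c(glc_c = -1, atp_c = -2, dhap_c = 1, g3p_c = 1, adp_c = 2),
            0, 1000, name = "upper glycolysis (lumped)"),
    rxn_row("TPI", c(dhap_c = -1, g3p_c = 1), -1000, 1000, gpr = "tpiA",
            name = "triose-phosphate isomerase"),
    rxn_row("GLYC_LO",
            c(g3p_c = -1, adp_c = -2, nad_c = -1, pyr_c = 1, atp_c = 2,
              nadh_c = 1),
            0, 1000, name = "lower glycolysis (lumped)"),
    rxn_row("RESP",
            setNames(c(-1, -0.5, -p, 1, p),
                     c("nadh_c", "o2_c", "adp_c", "nad_c", "atp_c")),
            0, 1000, name = "respiration (lumped)"),
    rxn_row("LDH", c(pyr_c = -1, nadh_c = -1, lac_c = 1, nad_c = 1),
            0, 1000, name = "lactate dehydrogenase"),
    rxn_row("ACK", c(pyr_c = -1, adp_c = -1, ac_c = 1, atp_c = 1),
            0, 1000, name = "acetate overflow (lumped PTA-ACK)"),
    rxn_row("BIOMASS",
            setNames(c(-1, -batp, batp, 1),
                     c("pyr_c", "atp_c", "adp_c", "biomass_e")),
            0, 1000, name = "biomass (lumped)"),
    rxn_row("ATPM", c(atp_c = -1, adp_c = 1), spec$atp_maintenance, 1000,
            name = "ATP maintenance"),
    rxn_row("EX_o2", c(o2_e = -1), spec$o2_uptake, 0, name = "oxygen exchange"),
    rxn_row("O2t", c(o2_e = -1, o2_c = 1), 0, 1000, name = "oxygen transport"),
    rxn_row("ACt", c(ac_c = -1, ac_e = 1), 0, 1000, name = "acetate transport"),
    rxn_row("EX_ac", c(ac_e = -1), 0, 1000, name = "acetate exchange"),
    rxn_row("LACt", c(lac_c = -1, lac_e = 1), 0, 1000,
            name = "lactate transport"),
    rxn_row("EX_lac", c(lac_e = -1), 0, 1000, name = "lactate exchange"),
    rxn_row("EX_biomass", c(biomass_e = -1), 0, 1000, name = "biomass drain")
  )
  constraint_model(metabolites = mets, reactions = rxns, genes = "tpiA",
                   objective = "BIOMASS", id = "mini_core")
}

#' Build the production-ready mini-core model
#'
#' Convenience wrapper: [build_mini_core()] extended with the l-fuculose
#' pathway via [extend_with_fuculose_pathway()], using the LAD uptake bound
#' from the spec.
#'
#' @param spec A [mini_core_spec()].
#' @param options A [pathway_options()]; its `lad_uptake_bound` defaults to
#'   `spec$lad_uptake`.
#' @return An extended `constraint_model`.
#' @export
build_fuculose_model <- function(spec = mini_core_spec(),
                                 options = pathway_options(
                                   lad_uptake_bound = spec$lad_uptake)) {
  extend_with_fuculose_pathway(build_mini_core(spec), options)
}

#' Build a condensed 12-reaction production network
#'
#' A fully condensed variant of the extended mini-core, small enough for the
#' exhaustive [enumerate_vertices_oracle()]: lumped glycolysis with the
#' DHAP/G3P split, a lumped NADH-producing biomass branch, respiration,
#' the FucA condensation (lumped with dephosphorylation and export) and the
#' FucO route to 1,2-PDO. It reproduces, in miniature, the redox scenarios
#' of the full model: anaerobically every NADH forces a matching FucO flux,
#' so all lactaldehyde is diverted to 1,2-PDO and the fuculose range at
#' maximal growth is exactly (0, 0).
#'
#' @param glc,lad,o2 Exchange lower bounds (uptake, non-positive).
#' @return A `constraint_model` with 12 reactions, objective `EX_bio`.
#' @export
build_micro_core <- function(glc = -10, lad = -5, o2 = -20) {
  mets <- met_rows(c("glc_e", "dhap_c", "g3p_c", "nad_c", "nadh_c", "o2_e",
                     "lad_e", "bio_e", "fcl_e", "pdo_e"))
  rxns <- dplyr::bind_rows(
    rxn_row("EX_glc", c(glc_e = -1), glc, 0),
    rxn_row("GLYC_UP", c(glc_e = -1, dhap_c = 1, g3p_c = 1), 0, 1000),
    rxn_row("TPI", c(dhap_c = -1, g3p_c = 1), -1000, 1000, gpr = "tpiA"),
    rxn_row("GROW", c(g3p_c = -1, nad_c = -1, nadh_c = 1, bio_e = 1), 0, 1000),
    rxn_row("RESP", c(nadh_c = -1, o2_e = -0.5, nad_c = 1), 0, 1000),
    rxn_row("EX_o2", c(o2_e = -1), o2, 0),
    rxn_row("EX_bio", c(bio_e = -1), 0, 1000),
    rxn_row("EX_lad", c(lad_e = -1), lad, 0),
    rxn_row("FCPA", c(dhap_c = -1, lad_e = -1, fcl_e = 1), 0, 1000,
            gpr = "fucA"),
    rxn_row("FUCO", c(lad_e = -1, nadh_c = -1, pdo_e = 1, nad_c = 1),
            0, 1000, gpr = "fucO"),
    rxn_row("EX_fcl", c(fcl_e = -1), 0, 1000),
    rxn_row("EX_pdo", c(pdo_e = -1), 0, 1000)
  )
  constraint_model(metabolites = mets, reactions = rxns,
                   genes = c("tpiA", "fucA", "fucO"),
                   objective = "EX_bio", id = "micro_core")
}

#' Random toy chain network with a known optimum
#'
#' Generates a linear pathway `s0 -> s1 -> ... -> sn` with unit
#' stoichiometry and per-stage capacities drawn uniformly from 1..10. The
#' maximal flux through the chain equals the bottleneck (minimum stage
#' capacity), giving a closed-form optimum for cross-checking LP solvers.
#'
#' @param seed Integer seed (reproducible).
#' @param n_stages Number of internal stages (1..10).
#' @return List with `model` (a `constraint_model`, objective the terminal
#'   exchange) and `optimum` (the known maximal objective).
#' @export
random_toy_model <- function(seed, n_stages = 3) {
  if (n_stages < 1 || n_stages > 10) abort("`n_stages` must be in 1..10")
  caps <- with_seed(seed, sample(1:10, n_stages, replace = TRUE))
  mets <- met_rows(c("s0_e", if (n_stages > 1)
    paste0("s", seq_len(n_stages - 1), "_c"), paste0("s", n_stages, "_e")))
  stage_ids <- paste0("STAGE", seq_len(n_stages))
  met_chain <- mets$id
  rows <- list(rxn_row("EX_in", c(s0_e = -1), -1000, 0))
  for (k in seq_len(n_stages)) {
    st <- setNames(c(-1, 1), c(met_chain[k], met_chain[k + 1]))
    rows[[length(rows) + 1]] <- rxn_row(stage_ids[k], st, 0, caps[k])
  }
  rows[[length(rows) + 1]] <-
    rxn_row("EX_out", setNames(-1, met_chain[n_stages + 1]), 0, 1000)
  model <- constraint_model(
    metabolites = mets, reactions = dplyr::bind_rows(rows),
    objective = "EX_out", id = paste0("toy_chain_seed", seed)
  )
  list(model = model, optimum = min(caps))
}

#' Parameters for the synthetic fermentation simulator
#'
#' @param carrying_capacity Logistic OD600 plateau (default 6).
#' @param growth_rate Logistic growth rate, 1/h (default 0.3).
#' @param od0 Inoculum OD600 (default 0.05).
#' @param glucose0 Initial glucose, g/L (default 10).
#' @param lad0 Initial lactaldehyde, mM (default 5).
#' @param lad_depletion_time Hour at which LAD is fully consumed
#'   (default 48; linear depletion).
#' @param yield Molar yield parameter: fraction of consumed LAD converted to
#'   l-fuculose (default 0.068, the scale of the engineered strains).
#' @param pdo_fraction Fraction of consumed LAD diverted to 1,2-PDO
#'   (default 0.85: most LAD ends up as 1,2-PDO).
#' @param acetate_max Acetate plateau, g/L (default 3).
#' @param sigma Gaussian measurement noise on the fuculose series, mg/L
#'   (LAD receives the molar-equivalent noise); 0 disables noise.
#' @param seed Optional integer seed.
#' @param times Sampling times in hours.
#' @return A list of class `fermentation_params`.
#' @export
fermentation_params <- function(carrying_capacity = 6, growth_rate = 0.3,
                                od0 = 0.05, glucose0 = 10, lad0 = 5,
                                lad_depletion_time = 48, yield = 0.068,
                                pdo_fraction = 0.85, acetate_max = 3,
                                sigma = 0, seed = NULL,
                                times = c(0, 3, 6, 12, 24, 36, 48, 72, 96)) {
  if (carrying_capacity <= 0 || growth_rate <= 0) {
    abort("`carrying_capacity` and `growth_rate` must be positive")
  }
  if (sigma < 0) abort("`sigma` must be >= 0")
  structure(
    list(carrying_capacity = carrying_capacity, growth_rate = growth_rate,
         od0 = od0, glucose0 = glucose0, lad0 = lad0,
         lad_depletion_time = lad_depletion_time, yield = yield,
         pdo_fraction = pdo_fraction, acetate_max = acetate_max,
         sigma = sigma, seed = seed, times = times),
    class = "fermentation_params"
  )
}

#' Simulate a fermentation time course
#'
#' Emulates the structure of batch fermentations of the fuculose-producing
#' strains: logistic growth reaching stationary phase by about 24 h,
#' monotone glucose consumption, acetate accumulation that plateaus with
#' growth, linear lactaldehyde depletion, 1,2-PDO accumulation, and product
#' formation proportional to consumed LAD on a molar basis:
#' `fuculose (mg/L) = yield x consumed LAD (mM) x 164.16 (g/mol)`.
#' With `sigma = 0` the generator is exactly invertible by
#' [summarize_fermentation()]; with noise, Gaussian errors are added to the
#' fuculose (sd `sigma` mg/L) and LAD (molar-equivalent sd) series and
#' clipped at zero.
#'
#' @param params A [fermentation_params()].
#' @return A timecourse tibble (class `fuc_timecourse`) with columns `time`,
#'   `od600`, `glucose`, `acetate`, `lad`, `pdo`, `fuculose`.
#' @examples
#' tc <- simulate_timecourse(fermentation_params(yield = 1, sigma = 0))
#' max(tc$fuculose)  # complete molar conversion: 5 * 164.16 = 820.8 mg/L
#' @export
simulate_timecourse <- function(params = fermentation_params()) {
  stopifnot(inherits(params, "fermentation_params"))
  p <- params
  t <- p$times
  od <- p$carrying_capacity * p$od0 * exp(p$growth_rate * t) /
    (p$carrying_capacity + p$od0 * (exp(p$growth_rate * t) - 1))
  glucose <- p$glucose0 * (1 - od / p$carrying_capacity)
  acetate <- p$acetate_max * od / p$carrying_capacity
  lad <- p$lad0 * pmax(0, 1 - t / p$lad_depletion_time)
  consumed <- p$lad0 - lad
  pdo <- p$pdo_fraction * consumed
  fuculose <- p$yield * consumed * MW_FUCULOSE
  if (p$sigma > 0) {
    noise <- with_seed(p$seed, list(
      fcl = rnorm(length(t), 0, p$sigma),
      lad = rnorm(length(t), 0, p$sigma / MW_FUCULOSE)
    ))
    fuculose <- pmax(0, fuculose + noise$fcl)
    lad <- pmax(0, lad + noise$lad)
  }
  out <- tibble::tibble(time = t, od600 = od, glucose = glucose,
                        acetate = acetate, lad = lad, pdo = pdo,
                        fuculose = fuculose)
  class(out) <- c("fuc_timecourse", class(out))
  out
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`
# (NULL = use the current stream).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
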