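DEFAULT_DIAGNOSTICS <- c("EX_fcl", "EX_lad", "EX_pdo", "FUCO", "FCPA", "ALDA")

require_pathway <- function(model) {
  if (!"EX_fcl" %in% model$reactions$id) {
    abort(paste0("model '", model$id, "' lacks the l-fuculose exchange ",
                 "EX_fcl; extend it with extend_with_fuculose_pathway() first"))
  }
  invisible(model)
}

new_campaign <- function(x, control) {
  class(x) <- unique(c("fuc_campaign", class(x)))
  attr(x, "control") <- control
  x
}

#' Aerobic vs anaerobic flux scenarios
#'
#' Runs the two redox scenarios of the l-fuculose study on a
#' pathway-extended model: aerobic (oxygen uptake allowed up to
#' `aerobic_o2`) and anaerobic (oxygen exchange lower bound 0). For each
#' scenario the max-growth flux distribution is reported together with flux
#' variability ranges (at the growth optimum) for the diagnostic reactions.
#' Anaerobically every lactaldehyde taken up must serve as an electron sink
#' through FucO, so LAD uptake is matched by 1,2-PDO secretion and the
#' l-fuculose range collapses to (0, 0); aerobically respiration reoxidizes
#' NADH and fuculose production becomes feasible alongside growth.
#'
#' @param model A pathway-extended `constraint_model` whose objective is the
#'   biomass reaction.
#' @param aerobic_o2 Aerobic oxygen exchange lower bound (default -20).
#' @param diagnostics Reaction ids to range with flux variability.
#' @param o2_exchange Oxygen exchange reaction id.
#' @return A tibble: `scenario`, `reaction`, `flux` (max-growth vertex),
#'   `fva_min`, `fva_max` (diagnostics only), `growth`.
#' @export
run_redox_scenarios <- function(model, aerobic_o2 = -20,
                                diagnostics = DEFAULT_DIAGNOSTICS,
                                o2_exchange = "EX_o2") {
  require_pathway(model)
  diagnostics <- intersect(diagnostics, model$reactions$id)
  scenarios <- list(aerobic = aerobic_o2, anaerobic = 0)
  out <- purrr::imap(scenarios, function(o2_lb, name) {
    m <- set_bounds(model, o2_exchange, lower = o2_lb)
    sol <- solve_fba(m)
    if (sol$status != "optimal") {
      return(tibble::tibble(scenario = name, reaction = NA_character_,
                            flux = NA_real_, fva_min = NA_real_,
                            fva_max = NA_real_, growth = NA_real_,
                            status = sol$status))
    }
    fva <- flux_variability(m, fraction = 1, reactions = diagnostics)
    tibble::tibble(scenario = name, reaction = names(sol$fluxes),
                   flux = unname(sol$fluxes)) |>
      dplyr::left_join(fva, by = "reaction") |>
      dplyr::mutate(growth = sol$objective_value, status = "optimal")
  })
  new_campaign(dplyr::bind_rows(out), control = "scenario")
}

# Shared machinery for the gridded campaigns: per grid value, maximize
# growth, then maximize l-fuculose secretion subject to a growth demand.
# floor = "reference" fixes the demand at biomass_fraction x the best growth
# over the whole grid (the most permissive condition); "per-point" uses
# biomass_fraction x that grid point's own maximum.
campaign_grid <- function(model, exchange, grid, biomass_fraction, floor,
                          control, fixed = list()) {
  require_pathway(model)
  if (length(grid) == 0) abort("empty grid")
  if (any(grid > 0)) abort("grid values must be uptake bounds (<= 0)")
  grid <- grid[order(abs(grid))]
  for (r in names(fixed)) model <- set_bounds(model, r, lower = fixed[[r]])
  biomass <- model$objective
  growth <- purrr::map_dbl(grid, function(g) {
    sol <- solve_fba(set_bounds(model, exchange, lower = g))
    if (sol$status == "optimal") sol$objective_value else NA_real_
  })
  ref <- switch(floor, reference = max(growth, na.rm = TRUE), `per-point` = NA)
  rows <- purrr::map2(grid, growth, function(g, mu) {
    demand <- biomass_fraction * (if (floor == "reference") ref else mu)
    m <- set_bounds(model, exchange, lower = g)
    if (is.na(mu)) {
      return(tibble::tibble(!!control := g, max_growth = NA_real_,
                            biomass_floor = demand, max_fuculose = NA_real_,
                            status = "infeasible",
                            flux_FUCO = NA_real_, flux_FCPA = NA_real_,
                            flux_EX_pdo = NA_real_))
    }
    m <- set_bounds(m, biomass, lower = demand)
    sol <- solve_fba(m, objective = "EX_fcl")
    if (sol$status != "optimal") {
      # the growth demand cannot be met at this grid point: no feasible
      # operating point, hence no attainable fuculose production
      return(tibble::tibble(!!control := g, max_growth = mu,
                            biomass_floor = demand, max_fuculose = 0,
                            status = "growth_infeasible",
                            flux_FUCO = NA_real_, flux_FCPA = NA_real_,
                            flux_EX_pdo = NA_real_))
    }
    fx <- function(r) if (r %in% names(sol$fluxes)) unname(sol$fluxes[r]) else NA_real_
    tibble::tibble(!!control := g, max_growth = mu, biomass_floor = demand,
                   max_fuculose = sol$objective_value, status = "optimal",
                   flux_FUCO = fx("FUCO"), flux_FCPA = fx("FCPA"),
                   flux_EX_pdo = fx("EX_pdo"))
  })
  new_campaign(dplyr::bind_rows(rows), control = control)
}

#' Oxygen-uptake sweep
#'
#' Varies the oxygen exchange lower bound over a grid spanning anaerobic
#' (0) to fully aerobic conditions and reports, per grid value, the maximal
#' growth and the maximal l-fuculose secretion subject to a growth demand.
#' A single-objective FBA would show zero fuculose at every point (product
#' formation always costs biomass), so the campaign uses two optimizations
#' per point. The growth demand defaults to `biomass_fraction` times the
#' best growth over the grid, held fixed across conditions
#' (`floor = "reference"`): the question posed is how much product the cell
#' can make while still meeting one and the same growth requirement, which
#' is what makes oxygen limitation visible — anaerobically the demand
#' cannot be met at all and attainable fuculose production is zero.
#' `floor = "per-point"` instead rescales the demand to each grid point's
#' own maximum. Both reported columns are non-decreasing in oxygen
#' availability (relaxing an uptake bound only enlarges the feasible set).
#'
#' @param model A pathway-extended `constraint_model`, objective = biomass.
#' @param o2_grid Oxygen uptake bounds (non-positive), default 0 to -20 by
#'   -2.
#' @param biomass_fraction Growth demand as a fraction of the reference
#'   maximum (default 0.5).
#' @param floor `"reference"` (default) or `"per-point"`, see above.
#' @param o2_exchange Oxygen exchange reaction id.
#' @return A campaign tibble: `o2_bound`, `max_growth`, `biomass_floor`,
#'   `max_fuculose`, `status`, and diagnostic fluxes at the max-fuculose
#'   vertex (`flux_FUCO`, `flux_FCPA`, `flux_EX_pdo`).
#' @examples
#' sweep <- oxygen_sweep(build_fuculose_model())
#' sweep[, 1:4]
#' @export
oxygen_sweep <- function(model, o2_grid = seq(0, -20, by = -2),
                         biomass_fraction = 0.5,
                         floor = c("reference", "per-point"),
                         o2_exchange = "EX_o2") {
  floor <- match.arg(floor)
  campaign_grid(model, o2_exchange, o2_grid, biomass_fraction, floor,
                control = "o2_bound")
}

#' Glucose:lactaldehyde substrate-ratio scan
#'
#' Varies the glucose uptake bound at a fixed lactaldehyde uptake bound and
#' reports maximal growth and maximal l-fuculose secretion under the same
#' two-step protocol as [oxygen_sweep()]. Glucose is the sole source of
#' dihydroxyacetone phosphate, the co-substrate of the FucA condensation,
#' so no fuculose is possible without glucose; under the default fixed
#' growth demand the scan reproduces the prediction that glucose supplied
#' at or above the lactaldehyde charge is required to sustain fuculose
#' biosynthesis.
#'
#' @inheritParams oxygen_sweep
#' @param glc_grid Glucose uptake bounds (non-positive).
#' @param lad_bound Fixed lactaldehyde exchange lower bound (default -5).
#' @param glc_exchange,lad_exchange Exchange reaction ids.
#' @return A campaign tibble keyed by `glc_bound`.
#' @export
substrate_ratio_scan <- function(model,
                                 glc_grid = c(0, -1, -2.5, -5, -7.5, -10),
                                 lad_bound = -5, biomass_fraction = 0.5,
                                 floor = c("reference", "per-point"),
                                 glc_exchange = "EX_glc",
                                 lad_exchange = "EX_lad") {
  floor <- match.arg(floor)
  campaign_grid(model, glc_exchange, glc_grid, biomass_fraction, floor,
                control = "glc_bound",
                fixed = setNames(list(lad_bound), lad_exchange))
}

#' Default deletion-strain series
#'
#' The engineered strain series of the l-fuculose study (all with *fucA*
#' overexpression from a T7 promoter, represented in the model simply by
#' the FCPA reaction being present):
#' Fuc 1 = dfucI dfucK, Fuc 2 = + dtpiA, Fuc 3 = + dfucO,
#' Fuc 4 = + daldA; a wild-type row (no deletions) is included as baseline.
#'
#' @return A tibble with columns `strain` and `deletions` (list column).
#' @export
fuc_strains <- function() {
  tibble::tibble(
    strain = c("wild-type", "Fuc1", "Fuc2", "Fuc3", "Fuc4"),
    deletions = list(
      character(),
      c("fucI", "fucK"),
      c("fucI", "fucK", "tpiA"),
      c("fucI", "fucK", "tpiA", "fucO"),
      c("fucI", "fucK", "tpiA", "fucO", "aldA")
    )
  )
}

#' Gene-deletion strain series
#'
#' Applies each strain's deletion set via [apply_deletions()] and reports
#' maximal growth, maximal l-fuculose secretion at a growth demand of
#' `biomass_fraction` times that strain's own maximum, and flux-variability
#' ranges (at the growth demand) for the tracked reactions plus every
#' reaction silenced by the deletions. Deletions only remove capabilities,
#' so no engineered strain can out-grow the wild type in the model; the
#' experimental strain ranking involves effects outside FBA's scope (e.g.
#' DHAP toxicity) and is deliberately not predicted.
#'
#' @param model A pathway-extended `constraint_model`, objective = biomass.
#' @param strains A tibble like [fuc_strains()] (columns `strain`,
#'   `deletions`).
#' @param biomass_fraction Growth demand fraction (default 0.5).
#' @param track Reaction ids always included in the FVA report.
#' @return A tibble: `strain`, `deletions` (comma-collapsed), `max_growth`,
#'   `max_fuculose`, `status`, `fva` (list column of per-reaction ranges).
#' @export
strain_series <- function(model, strains = fuc_strains(),
                          biomass_fraction = 0.5,
                          track = c("FUCO", "ALDA")) {
  require_pathway(model)
  rows <- purrr::pmap(strains, function(strain, deletions) {
    m <- apply_deletions(model, deletions)
    silenced <- model$reactions$id[
      m$reactions$lower_bound == 0 & m$reactions$upper_bound == 0 &
        !(model$reactions$lower_bound == 0 & model$reactions$upper_bound == 0)]
    sol <- solve_fba(m)
    if (sol$status != "optimal") {
      return(tibble::tibble(strain = strain,
                            deletions = paste(deletions, collapse = ","),
                            max_growth = NA_real_, max_fuculose = NA_real_,
                            status = sol$status, fva = list(NULL)))
    }
    demand <- biomass_fraction * sol$objective_value
    m2 <- set_bounds(m, model$objective, lower = demand)
    prod <- solve_fba(m2, objective = "EX_fcl")
    targets <- intersect(unique(c(track, silenced)), m$reactions$id)
    fva <- flux_variability(m, fraction = biomass_fraction,
                            reactions = targets)
    tibble::tibble(strain = strain,
                   deletions = paste(deletions, collapse = ","),
                   max_growth = sol$objective_value,
                   max_fuculose = if (prod$status == "optimal")
                     prod$objective_value else 0,
                   status = "optimal",
                   fva = list(fva))
  })
  new_campaign(dplyr::bind_rows(rows), control = "strain")
}

#' Write a campaign table or flux result to CSV
#'
#' Campaigns are pure functions of (model, configuration, grid): rerunning
#' and rewriting yields byte-identical files.
#'
#' @param x A campaign tibble, FVA tibble, or `flux_solution`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flux_csv <- function(x, path) {
  if (inherits(x, "flux_solution")) x <- tidy(x)
  if ("fva" %in% names(x)) x <- dplyr::select(x, -"fva")
  readr::write_csv(x, path)
  invisible(path)
}
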