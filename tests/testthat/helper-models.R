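# Shared fixtures, all built in code.

# Linear chain: EX_A (uptake up to 10) -> A -> B -> EX_B, objective EX_B.
make_chain_model <- function(uptake = -10) {
  constraint_model(
    metabolites = tibble::tibble(id = c("a_e", "b_e")),
    reactions = tibble::tibble(
      id = c("EX_A", "R1", "EX_B"),
      stoichiometry = list(c(a_e = -1), c(a_e = -1, b_e = 1), c(b_e = -1)),
      lower_bound = c(uptake, 0, 0),
      upper_bound = c(0, 1000, 1000)
    ),
    objective = "EX_B", id = "chain"
  )
}

# Minimal host carrying water and orthophosphate, so the pathway extension
# uses the full (elision-free) FCP and ALDA forms. Not meant to grow.
make_watered_host <- function() {
  ids <- c("dhap_c", "nad_c", "nadh_c", "atp_c", "adp_c", "lac_c",
           "h2o_c", "pi_c", "h2o_e", "pi_e")
  mets <- tibble::tibble(
    id = ids, name = ids,
    compartment = sub(".*_([a-z])$", "\\1", ids),
    formula = c("C3H7O6P", NA, NA, NA, NA, "C3H6O3", "H2O", "H3O4P",
                "H2O", "H3O4P"),
    charge = NA_integer_
  )
  rxns <- tibble::tibble(
    id = c("DHAP_SRC", "H2Ot", "EX_h2o", "PIt", "EX_pi"),
    stoichiometry = list(
      c(atp_c = -1, dhap_c = 1, adp_c = 1, nadh_c = 1, nad_c = -1),
      c(h2o_e = -1, h2o_c = 1), c(h2o_e = -1),
      c(pi_c = -1, pi_e = 1), c(pi_e = -1)),
    lower_bound = c(0, -1000, -1000, 0, 0),
    upper_bound = c(1000, 1000, 1000, 1000, 1000)
  )
  constraint_model(metabolites = mets, reactions = rxns, id = "watered_host")
}

mini_core_json <- function(path = tempfile(fileext = ".json")) {
  write_model_json(build_mini_core(), path)
  path
}

write_tc_csv <- function(text, path = tempfile(fileext = ".csv")) {
  writeLines(text, path)
  path
}
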