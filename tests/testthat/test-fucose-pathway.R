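test_that("the default extension adds the full pathway inventory", {
  host <- build_mini_core()
  ext <- extend_with_fuculose_pathway(host)
  added <- setdiff(ext$reactions$id, host$reactions$id)
  expect_setequal(added, c("EX_lad", "LADt", "FCPA", "FCP", "FCLK",
                           "FUCI", "FUCt", "EX_fuc", "FUCO", "ALDA",
                           "FCLt", "EX_fcl", "PDOt", "EX_pdo"))
  new_mets <- setdiff(ext$metabolites$id, host$metabolites$id)
  expect_setequal(new_mets, c("lad_e", "lad_c", "fc1p_c", "fcl_c", "fcl_e",
                              "fuc_c", "fuc_e", "pdo_c", "pdo_e"))
  # LAD uptake bound lands on the exchange
  i <- match("EX_lad", ext$reactions$id)
  expect_equal(ext$reactions$lower_bound[i], -5)
  # product exchanges are secretion-only
  for (r in c("EX_fcl", "EX_pdo", "EX_fuc")) {
    expect_gte(ext$reactions$lower_bound[match(r, ext$reactions$id)], 0)
  }
})

test_that("pathway toggles prune reactions and metabolites together", {
  host <- build_mini_core()
  no_iso <- extend_with_fuculose_pathway(
    host, pathway_options(include_isomerase = FALSE))
  expect_false(any(c("FUCI", "FUCt", "EX_fuc") %in% no_iso$reactions$id))
  expect_false(any(c("fuc_c", "fuc_e") %in% no_iso$metabolites$id))

  no_k <- extend_with_fuculose_pathway(
    host, pathway_options(include_kinase = FALSE, include_aldA = FALSE))
  expect_false("FCLK" %in% no_k$reactions$id)
  expect_false("ALDA" %in% no_k$reactions$id)
  expect_false("fucK" %in% no_k$genes)

  bounded <- extend_with_fuculose_pathway(
    host, pathway_options(lad_uptake_bound = 2))
  expect_equal(
    bounded$reactions$lower_bound[match("EX_lad", bounded$reactions$id)], -2)
  expect_error(pathway_options(lad_uptake_bound = -1), ">= 0")
})

test_that("extension is non-destructive and removable", {
  host <- build_mini_core()
  ext <- extend_with_fuculose_pathway(host)
  # every host reaction row (bounds, stoichiometry, gpr) is bit-identical
  expect_identical(ext$reactions[match(host$reactions$id, ext$reactions$id), ],
                   host$reactions)
  expect_identical(
    ext$metabolites[match(host$metabolites$id, ext$metabolites$id), ],
    host$metabolites)
  # dropping the added ids recovers the host exactly
  added <- setdiff(ext$reactions$id, host$reactions$id)
  trimmed <- ext
  trimmed$reactions <- ext$reactions[!ext$reactions$id %in% added, ]
  trimmed$metabolites <-
    ext$metabolites[ext$metabolites$id %in% host$metabolites$id, ]
  expect_equal(trimmed$reactions, host$reactions)
  expect_equal(trimmed$metabolites, host$metabolites)
})

test_that("each pathway gene maps onto exactly one added reaction", {
  ext <- build_fuculose_model()
  added_gprs <- ext$reactions$gpr[!is.na(ext$reactions$gpr) &
                                    ext$reactions$id != "TPI"]
  expect_equal(sort(added_gprs), sort(c("fucA", "fucI", "fucK", "fucO", "aldA")))
})

test_that("extension errors name missing metabolites and id collisions", {
  host <- build_mini_core()
  crippled <- host
  crippled$metabolites <- host$metabolites[host$metabolites$id != "dhap_c", ]
  crippled$reactions <- host$reactions[
    !purrr::map_lgl(host$reactions$stoichiometry, ~ "dhap_c" %in% names(.x)), ]
  expect_error(extend_with_fuculose_pathway(crippled), "dhap")

  ext <- extend_with_fuculose_pathway(host)
  expect_error(extend_with_fuculose_pathway(ext), "EX_lad")
})

test_that("the added internal reactions are elementally balanced", {
  ext <- build_fuculose_model()
  rep <- check_mass_balance(ext)
  added_internal <- c("LADt", "FCPA", "FCP", "FCLK", "FUCI", "FUCt",
                      "FUCO", "ALDA", "FCLt", "PDOt")
  sub <- rep[rep$reaction %in% added_internal, ]
  expect_true(all(sub$checkable))
  expect_true(all(sub$balanced))
  # the mini-core has no free water/phosphate: the phosphatase and AldA
  # forms are balanced only up to the documented elision
  expect_equal(rep$elision[rep$reaction == "FCP"], "h2o+pi")
  expect_equal(rep$elision[rep$reaction == "ALDA"], "h2o")
  # isomerization is balanced as an isomer identity, no elision
  expect_equal(rep$elision[rep$reaction == "FUCI"], "")
  # lumped host reactions without formulas are not checkable, not failures
  expect_false(rep$checkable[rep$reaction == "GLYC_UP"])
})

test_that("a water-carrying host gets the full FCP/ALDA forms, and a corrupted FCP is flagged", {
  host <- make_watered_host()
  ext <- extend_with_fuculose_pathway(host)
  st_fcp <- ext$reactions$stoichiometry[[match("FCP", ext$reactions$id)]]
  expect_setequal(names(st_fcp), c("fc1p_c", "h2o_c", "fcl_c", "pi_c"))
  st_alda <- ext$reactions$stoichiometry[[match("ALDA", ext$reactions$id)]]
  expect_true("h2o_c" %in% names(st_alda))

  rep <- check_mass_balance(ext)
  sub <- rep[rep$reaction %in% c("FCP", "ALDA", "FCPA", "FCLK", "FUCO"), ]
  expect_true(all(sub$balanced))
  expect_true(all(sub$elision == ""))

  # drop the water reactant: hydrogen and oxygen no longer balance
  broken <- ext
  i <- match("FCP", broken$reactions$id)
  broken$reactions$stoichiometry[[i]] <-
    st_fcp[setdiff(names(st_fcp), "h2o_c")]
  rep2 <- check_mass_balance(broken)
  row <- rep2[rep2$reaction == "FCP", ]
  expect_false(row$balanced)
  expect_match(row$imbalance, "H")
  expect_match(row$imbalance, "O")
})

test_that("formula parsing counts elements", {
  expect_equal(parse_formula("C6H13O8P"),
               c(C = 6, H = 13, O = 8, P = 1), ignore_attr = TRUE)
  expect_equal(sum(parse_formula("H2O")), 3)
  expect_error(parse_formula("C6#"), "parse")
})
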