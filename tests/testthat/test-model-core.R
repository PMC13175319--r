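test_that("a minimal BiGG-dialect document parses to the smallest valid model", {
  doc <- '{
    "id": "tiny",
    "metabolites": [{"id": "a_e", "compartment": "e"}],
    "reactions": [{"id": "EX_a", "metabolites": {"a_e": -1},
                   "lower_bound": -10, "upper_bound": 0}],
    "genes": []
  }'
  m <- read_model_json(doc)
  expect_s3_class(m, "constraint_model")
  expect_equal(nrow(m$reactions), 1)
  expect_equal(m$reactions$stoichiometry[[1]], c(a_e = -1))
})

test_that("write-then-parse round-trips every semantic field", {
  model <- build_fuculose_model()
  f <- withr::local_tempfile(fileext = ".json")
  write_model_json(model, f)
  back <- read_model_json(f)
  expect_equal(back$metabolites, model$metabolites)
  expect_equal(back$reactions, model$reactions)
  expect_identical(back$genes, model$genes)
  expect_identical(back$objective, model$objective)
})

test_that("schema and reference violations are rejected with the offending key", {
  expect_error(read_model_json('{"metabolites": [], "genes": []}'),
               "reactions")
  dangling <- '{
    "metabolites": [{"id": "a_c"}],
    "reactions": [{"id": "R", "metabolites": {"xyz_c": -1, "a_c": 1},
                   "lower_bound": 0, "upper_bound": 1}],
    "genes": []
  }'
  expect_error(read_model_json(dangling), "xyz_c")
  expect_error(
    constraint_model(
      metabolites = tibble::tibble(id = c("a_e", "a_e")),
      reactions = tibble::tibble(id = "EX_a", stoichiometry = list(c(a_e = -1)),
                                 lower_bound = -1, upper_bound = 0),
      objective = "EX_a"),
    "duplicate")
  expect_error(
    constraint_model(
      metabolites = tibble::tibble(id = "a_e"),
      reactions = tibble::tibble(id = "EX_a", stoichiometry = list(c(a_e = -1)),
                                 lower_bound = 1, upper_bound = 0),
      objective = "EX_a"),
    "lower_bound")
})

test_that("the stoichiometric matrix is metabolites x reactions in model order", {
  m <- constraint_model(
    metabolites = tibble::tibble(id = c("a_c", "b_c", "a_e")),
    reactions = tibble::tibble(
      id = c("EX", "R"),
      stoichiometry = list(c(a_e = -1), c(a_c = -1, b_c = 1)),
      lower_bound = c(-10, 0), upper_bound = c(0, 10)),
    objective = "R")
  S <- stoichiometric_matrix(m)
  expect_equal(dim(S), c(3, 2))
  expect_equal(unname(S[, "R"]), c(-1, 1, 0))

  ext <- build_fuculose_model()
  Se <- stoichiometric_matrix(ext)
  expect_equal(dim(Se), c(nrow(ext$metabolites), nrow(ext$reactions)))
  # the FucA condensation consumes one DHAP and one LAD per fuculose-1-P
  expect_equal(Se["dhap_c", "FCPA"], -1)
  expect_equal(Se["lad_c", "FCPA"], -1)
  expect_equal(Se["fc1p_c", "FCPA"], 1)
  # every metabolite participates in at least one reaction
  expect_true(all(rowSums(abs(Se)) > 0))
})

test_that("adding a reaction appends exactly one column and preserves entries", {
  host <- build_mini_core()
  S0 <- stoichiometric_matrix(host)
  host2 <- host
  host2$reactions <- dplyr::bind_rows(
    host2$reactions,
    tibble::tibble(id = "DM_pyr", name = "DM_pyr",
                   stoichiometry = list(c(pyr_c = -1)),
                   lower_bound = 0, upper_bound = 1000,
                   gpr = NA_character_, subsystem = NA_character_))
  S1 <- stoichiometric_matrix(host2)
  expect_equal(ncol(S1), ncol(S0) + 1)
  expect_equal(S1[, colnames(S0)], S0)
})

test_that("GPR rules evaluate by boolean logic over deletions", {
  expect_false(evaluate_gpr("fucO", "fucO"))
  expect_true(evaluate_gpr("g1 or g2", "g1"))     # isozyme survives
  expect_false(evaluate_gpr("g1 and g2", "g2"))   # complex broken
  expect_true(evaluate_gpr("g1 and (g2 or g3)", "g2"))
  expect_false(evaluate_gpr("g1 and (g2 or g3)", c("g2", "g3")))
  expect_true(evaluate_gpr(NA_character_, "anything"))  # no rule: retained
  expect_error(parse_gpr("g1 and"), "unexpectedly")
  expect_error(parse_gpr("(g1 or g2"), "parenthes")
  expect_equal(sort(gpr_genes(parse_gpr("a and (b or a)"))), c("a", "b"))
})

test_that("apply_deletions zero-bounds exactly the unsupported reactions", {
  model <- build_fuculose_model()
  expect_identical(apply_deletions(model, character()), model)

  fuc1 <- apply_deletions(model, c("fucI", "fucK"))
  killed <- c("FUCI", "FCLK")
  for (r in killed) {
    i <- match(r, fuc1$reactions$id)
    expect_equal(fuc1$reactions$lower_bound[i], 0)
    expect_equal(fuc1$reactions$upper_bound[i], 0)
  }
  others <- setdiff(model$reactions$id, killed)
  keep <- match(others, model$reactions$id)
  expect_identical(fuc1$reactions[keep, ], model$reactions[keep, ])

  fuc4 <- apply_deletions(model, c("fucI", "fucK", "tpiA", "fucO", "aldA"))
  zeroed <- fuc4$reactions$id[fuc4$reactions$lower_bound == 0 &
                                fuc4$reactions$upper_bound == 0 &
                                !(model$reactions$lower_bound == 0 &
                                    model$reactions$upper_bound == 0)]
  expect_setequal(zeroed, c("FUCI", "FCLK", "TPI", "FUCO", "ALDA"))
})

test_that("deletions are idempotent, monotone, and ignore unknown genes", {
  model <- build_fuculose_model()
  once <- apply_deletions(model, c("fucI", "tpiA"))
  twice <- apply_deletions(once, c("fucI", "tpiA"))
  expect_identical(once, twice)

  zeroed <- function(m) m$reactions$id[m$reactions$lower_bound == 0 &
                                         m$reactions$upper_bound == 0]
  small <- apply_deletions(model, c("fucI"))
  big <- apply_deletions(model, c("fucI", "fucK", "fucO"))
  expect_true(all(zeroed(small) %in% zeroed(big)))

  expect_warning(out <- apply_deletions(model, "notagene"), "notagene")
  expect_identical(out, model)
})

test_that("validate_model reports exchange and compartment violations", {
  bad <- list(
    id = "bad",
    metabolites = tibble::tibble(id = "a_c", name = "a_c", compartment = "c",
                                 formula = NA_character_, charge = NA_integer_),
    reactions = tibble::tibble(id = "EX_a", name = "EX_a",
                               stoichiometry = list(c(a_c = -1)),
                               lower_bound = -1, upper_bound = 0,
                               gpr = NA_character_, subsystem = NA_character_),
    genes = character(), objective = NA_character_)
  class(bad) <- "constraint_model"
  issues <- validate_model(bad)
  expect_true("exchange_extracellular" %in% issues$rule)
})
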