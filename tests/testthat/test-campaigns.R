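ext <- build_fuculose_model()

test_that("anaerobically all LAD is diverted to 1,2-PDO with no fuculose flux", {
  rs <- run_redox_scenarios(ext)
  an <- rs[rs$scenario == "anaerobic", ]
  # FVA at the growth optimum: fuculose range pinned at (0, 0)
  fcl <- an[an$reaction == "EX_fcl", ]
  expect_lte(abs(fcl$fva_min), 1e-4)
  expect_lte(abs(fcl$fva_max), 1e-4)
  # LAD uptake sits at its bound and is matched by 1,2-PDO secretion
  lad <- an$flux[an$reaction == "EX_lad"]
  pdo <- an$flux[an$reaction == "EX_pdo"]
  expect_equal(lad, -5, tolerance = 1e-8)
  expect_lte(abs(abs(lad) - pdo), 1e-6)
})

test_that("aerobically fuculose production is feasible alongside growth", {
  rs <- run_redox_scenarios(ext)
  ae_growth <- unique(rs$growth[rs$scenario == "aerobic"])
  an_growth <- unique(rs$growth[rs$scenario == "anaerobic"])
  expect_gt(ae_growth, an_growth)
  # max fuculose at half the aerobic growth demand is strictly positive
  m <- set_bounds(ext, "BIOMASS", lower = 0.5 * ae_growth)
  expect_gt(solve_fba(m, objective = "EX_fcl")$objective_value, 0.1)
})

test_that("campaigns demand a pathway-extended model", {
  host <- build_mini_core()
  expect_error(run_redox_scenarios(host), "EX_fcl")
  expect_error(oxygen_sweep(host), "EX_fcl")
  expect_error(oxygen_sweep(ext, o2_grid = numeric()), "empty")
  expect_error(oxygen_sweep(ext, o2_grid = c(0, 5)), "<= 0")
})

test_that("oxygen availability monotonically enables growth and fuculose", {
  for (frac in c(0, 0.25, 0.5, 0.9)) {
    sw <- oxygen_sweep(ext, biomass_fraction = frac)
    expect_true(all(diff(sw$max_growth) >= -1e-8))
    expect_true(all(diff(sw$max_fuculose) >= -1e-8))
  }
  sw <- oxygen_sweep(ext)  # default fraction 0.5
  expect_equal(sw$max_fuculose[sw$o2_bound == 0], 0)
  expect_gt(max(sw$max_fuculose), 1)
  # with no growth demand, production plateaus at the LAD uptake bound
  sw0 <- oxygen_sweep(ext, biomass_fraction = 0)
  expect_equal(max(sw0$max_fuculose), 5, tolerance = 1e-8)
})

test_that("the substrate scan needs glucose at or above the LAD charge", {
  sc <- substrate_ratio_scan(ext)
  expect_equal(sc$max_fuculose[sc$glc_bound == 0], 0)
  expect_true(all(diff(sc$max_fuculose) >= -1e-8))
  # stoichiometric ceiling: at most 2 DHAP per glucose via the triose split
  expect_true(all(sc$max_fuculose <= 2 * abs(sc$glc_bound) + 1e-8))
  # fuculose appears only once glucose matches the LAD bound of 5
  expect_equal(sc$max_fuculose[abs(sc$glc_bound) < 5], c(0, 0, 0))
  expect_true(all(sc$max_fuculose[abs(sc$glc_bound) >= 5] > 0))
})

test_that("the strain series silences exactly the deleted-gene reactions", {
  ss <- strain_series(ext)
  expect_equal(ss$strain, c("wild-type", "Fuc1", "Fuc2", "Fuc3", "Fuc4"))

  fva1 <- ss$fva[[match("Fuc1", ss$strain)]]
  for (r in c("FUCI", "FCLK")) {
    row <- fva1[fva1$reaction == r, ]
    expect_equal(row$fva_min, 0, tolerance = 1e-9)
    expect_equal(row$fva_max, 0, tolerance = 1e-9)
  }
  fva3 <- ss$fva[[match("Fuc3", ss$strain)]]
  fuco <- fva3[fva3$reaction == "FUCO", ]
  expect_equal(fuco$fva_min, 0, tolerance = 1e-9)
  expect_equal(fuco$fva_max, 0, tolerance = 1e-9)

  # deletions only remove capability: wild type grows at least as fast
  wt <- ss$max_growth[ss$strain == "wild-type"]
  expect_true(all(ss$max_growth <= wt + 1e-9))
})

test_that("campaign outputs are pure functions of their inputs", {
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_flux_csv(oxygen_sweep(ext, o2_grid = c(0, -5, -10)), f1)
  write_flux_csv(oxygen_sweep(ext, o2_grid = c(0, -5, -10)), f2)
  expect_identical(readLines(f1), readLines(f2))
})
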