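test_that("a single uptake-limited chain is solved to its bound", {
  m <- make_chain_model()
  sol <- solve_fba(m)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 10)
  expect_lte(sol$residual, 1e-8)
  # every flux respects its bounds
  lb <- m$reactions$lower_bound; ub <- m$reactions$upper_bound
  expect_true(all(sol$fluxes >= lb - 1e-9 & sol$fluxes <= ub + 1e-9))
})

test_that("fuculose production requires a DHAP source and is LAD-limited", {
  ext <- build_fuculose_model()
  no_glc <- solve_fba(ext, objective = "EX_fcl",
                      bound_overrides = list(EX_glc = c(0, 0)))
  expect_equal(no_glc$objective_value, 0, tolerance = 1e-9)

  released <- solve_fba(ext, objective = "EX_fcl",
                        bound_overrides = list(ATPM = c(0, 1000)))
  expect_equal(released$objective_value, 5, tolerance = 1e-8)
})

test_that("flux variability collapses at a unique optimum and relaxes at fraction 0", {
  m <- make_chain_model()
  fva1 <- flux_variability(m, fraction = 1)
  expect_equal(fva1$fva_min, c(-10, 10, 10), tolerance = 1e-6)
  expect_equal(fva1$fva_max, c(-10, 10, 10), tolerance = 1e-6)

  fva0 <- flux_variability(m, fraction = 0)
  r1 <- fva0[fva0$reaction == "R1", ]
  expect_equal(r1$fva_min, 0, tolerance = 1e-9)
  expect_equal(r1$fva_max, 10, tolerance = 1e-6)
})

test_that("infeasible and unbounded problems are reported as such", {
  infeas <- build_mini_core(mini_core_spec(glc_uptake = -1,
                                           atp_maintenance = 50))
  sol <- solve_fba(infeas)
  expect_equal(sol$status, "infeasible")
  expect_true(is.na(sol$objective_value))

  mets <- tibble::tibble(id = "a_e")
  rx <- tibble::tibble(
    id = c("SRC", "EX_a"),
    stoichiometry = list(c(a_e = 1), c(a_e = -1)),
    lower_bound = c(-Inf, -Inf), upper_bound = c(Inf, Inf))
  unb <- constraint_model(mets, rx, objective = "EX_a")
  expect_equal(solve_fba(unb)$status, "unbounded")

  expect_error(flux_variability(infeas), class = "fucflux_infeasible")
})

test_that("optimal objectives scale with uptake bounds and respond concavely to glucose", {
  base <- build_mini_core(mini_core_spec(atp_maintenance = 0))
  k <- 2.5
  scaled <- build_mini_core(mini_core_spec(glc_uptake = -10 * k,
                                           o2_uptake = -20 * k,
                                           atp_maintenance = 0))
  expect_equal(solve_fba(scaled)$objective_value,
               k * solve_fba(base)$objective_value, tolerance = 1e-8)

  # with maintenance on, growth is nondecreasing in glucose availability
  mus <- purrr::map_dbl(c(-2, -4, -6, -8, -10), function(g) {
    solve_fba(build_mini_core(mini_core_spec(glc_uptake = g)))$objective_value
  })
  expect_true(all(diff(mus) >= -1e-9))
})

test_that("deletions never increase the optimal objective", {
  ext <- build_fuculose_model()
  base <- solve_fba(ext)$objective_value
  sets <- list("fucO", c("fucI", "fucK"), c("fucI", "fucK", "tpiA"),
               c("fucI", "fucK", "tpiA", "fucO", "aldA"))
  for (s in sets) {
    expect_lte(solve_fba(apply_deletions(ext, s))$objective_value,
               base + 1e-9)
  }
})

test_that("the simplex agrees with exhaustive vertex enumeration on toy networks", {
  for (seed in 1:25) {
    toy <- random_toy_model(seed, n_stages = 1 + (seed %% 8))
    sol <- solve_fba(toy$model)
    orc <- enumerate_vertices_oracle(toy$model)
    expect_equal(sol$objective_value, toy$optimum, tolerance = 1e-9)
    expect_equal(orc$objective_value, toy$optimum, tolerance = 1e-9)
    expect_lte(abs(sol$objective_value - orc$objective_value), 1e-6)
  }
})

test_that("simplex, oracle, and an external LP solver agree on a chain", {
  skip_if_not_installed("pracma")
  toy <- random_toy_model(3, 5)$model
  S <- stoichiometric_matrix(toy)
  lb <- toy$reactions$lower_bound; ub <- toy$reactions$upper_bound
  cc <- as.numeric(toy$reactions$id == "EX_out")
  res <- pracma::linprog(cc, A = diag(length(cc)), b = ub - lb,
                         Aeq = S, beq = -as.vector(S %*% lb),
                         maximize = TRUE, maxiter = 1000)
  expect_equal(sum(cc * (res$x + lb)), solve_fba(toy)$objective_value,
               tolerance = 1e-6)
})

test_that("oracle refuses oversized models and detects infeasibility", {
  ext <- build_fuculose_model()
  expect_error(enumerate_vertices_oracle(ext), "refused")

  m <- make_chain_model()
  m <- set_bounds(m, "EX_B", lower = 20)  # demand above uptake capacity
  expect_equal(solve_fba(m)$status, "infeasible")
  expect_equal(enumerate_vertices_oracle(m)$status, "infeasible")
})

test_that("micro-core scenarios match the oracle under both redox regimes", {
  mc <- build_micro_core()
  for (o2 in c(0, -5, -20)) {
    m <- set_bounds(mc, "EX_o2", lower = o2)
    expect_lte(abs(solve_fba(m)$objective_value -
                     enumerate_vertices_oracle(m)$objective_value), 1e-6)
    expect_lte(abs(solve_fba(m, objective = "EX_fcl")$objective_value -
                     enumerate_vertices_oracle(m, objective = "EX_fcl")$objective_value),
               1e-6)
  }
})
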