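test_that("truth instances are admissible anchored models", {
  for (seed in c(1, 2)) {
    inst <- generate_truth_instance(1, seed = seed)
    expect_s3_class(inst$params, "gma_parameters")
    r <- gma_rhs(inst$topology, inst$params, rep(100, 16))
    expect_lt(max(abs(r)), 1e-10)
    ss <- simulate_steady_state(inst$topology, inst$params)
    expect_equal(ss$status, "converged")
    expect_equal(unname(ss$state), rep(100, 16), tolerance = 1e-6)
  }
  # reproducible under the seed
  a <- generate_truth_instance(1, seed = 9)
  b <- generate_truth_instance(1, seed = 9)
  expect_identical(a$params$g, b$params$g)
  expect_identical(a$params$phi, b$params$phi)
})

test_that("zero-noise observations equal the instance's exact fold changes", {
  inst <- generate_truth_instance(1, seed = 4)
  obs <- generate_observations(inst, noise_sigma = 0, seed = 1)
  sc <- default_scenarios()
  for (i in seq_len(nrow(obs))) {
    rec <- simulate_scenario(inst$topology, inst$params,
                             sc[[obs$scenario[i]]])
    expect_equal(obs$H[i], rec$folds[["H"]], tolerance = 1e-9)
    expect_equal(obs$total[i], rec$folds[["total"]], tolerance = 1e-9)
    expect_equal(obs$SG_fold[i], rec$folds[["SG"]], tolerance = 1e-9)
    if (!is.na(obs$Z9[i]))
      expect_equal(obs$Z9[i], rec$met_fold[["Z9"]], tolerance = 1e-9)
  }
  expect_equal(obs$sg_direction,
               ifelse(obs$SG_fold > 1, "increase", "decrease"))
})

test_that("noisy observations stay positive and internally consistent", {
  inst <- generate_truth_instance(1, seed = 4)
  obs <- generate_observations(inst, noise_sigma = 0.05, seed = 11)
  expect_true(all(obs[c("H", "G", "S", "total", "SG_fold")] > 0))
  expect_equal(obs$sg_direction,
               ifelse(obs$SG_fold > 1, "increase", "decrease"))
  # deterministic under seed, different across seeds
  obs2 <- generate_observations(inst, noise_sigma = 0.05, seed = 11)
  expect_identical(obs, obs2)
  obs3 <- generate_observations(inst, noise_sigma = 0.05, seed = 12)
  expect_false(identical(obs$H, obs3$H))
})

test_that("a truth instance passes screening against its own noisy table", {
  inst <- generate_truth_instance(1, seed = 4)
  obs <- generate_observations(inst, noise_sigma = 0.05, seed = 2)
  crit <- criteria_from_observations(obs, rel_tol = 0.2)
  sc <- default_scenarios()
  recs <- lapply(stats::setNames(nm = obs$scenario), function(s)
    simulate_scenario(inst$topology, inst$params, sc[[s]]))
  ev <- evaluate_criteria(recs, crit)
  expect_true(ev$pass)
})

test_that("observation tables round-trip and convert to criteria", {
  inst <- generate_truth_instance(1, seed = 4)
  obs <- generate_observations(inst, noise_sigma = 0.02, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_observations(obs, path)
  back <- read_observations(path)
  expect_equal(back$H, obs$H, tolerance = 1e-9)
  expect_equal(back$sg_direction, obs$sg_direction)
  crit <- criteria_from_observations(back, rel_tol = 0.1)
  expect_s3_class(crit, "screening_criteria")
  expect_named(crit, obs$scenario)
  expect_equal(crit$`4CL`$H, obs$H[obs$scenario == "4CL"] * c(0.9, 1.1),
               tolerance = 1e-9)
  expect_null(crit$CAD$metabolites)
  expect_false(is.null(crit$COMT$metabolites))
  expect_error(criteria_from_observations(obs, rel_tol = -0.1))
})
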