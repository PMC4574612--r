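test_that("default scenarios encode the experimental knockdown levels", {
  sc <- default_scenarios()
  expect_named(sc, c("wildtype", "4CL", "CCR1", "COMT", "CAD"))
  expect_null(sc$wildtype$multipliers)
  expect_equal(unname(sc$`4CL`$multipliers), 0.6)
  expect_equal(unname(sc$CCR1$multipliers), 0.5)
  expect_equal(unname(sc$COMT$multipliers), 0.7)
  expect_equal(unname(sc$CAD$multipliers), 0.7)
  expect_true(sc$COMT$fourcl_inhibition)
  expect_false(sc$`4CL`$fourcl_inhibition)
  # activity vectors: 4CL scenario only touches Z20
  act <- enzyme_profile(TOP1, sc$`4CL`$multipliers)
  expect_equal(act[["Z20"]], 0.6)
  expect_equal(sum(act != 1), 1L)
})

test_that("the wild-type scenario is the identity", {
  p <- small_ensemble()$sets[[1]]
  rec <- simulate_scenario(TOP1, p, default_scenarios()$wildtype)
  expect_equal(rec$status, "converged")
  expect_equal(unname(rec$folds), rep(1, 5))
  expect_equal(unname(rec$met_fold), rep(1, 16))
})

test_that("criteria evaluation produces named reason codes", {
  crit <- default_criteria()
  mkrec <- function(folds, met = c(Z9 = 1.3, Z11 = 0.8)) {
    mf <- stats::setNames(rep(1, 16), names(pathway_metabolites()))
    mf[names(met)] <- met
    structure(list(scenario = "x", status = "converged",
                   folds = folds, met_fold = mf),
              class = "scenario_record")
  }
  good4 <- mkrec(c(H = 1.82, G = 0.53, S = 1.0, total = 0.78, SG = 1.3))
  goodC <- mkrec(c(H = 0.8, G = 0.75, S = 0.76, total = 0.75, SG = 1.01))
  goodM <- mkrec(c(H = 1.1, G = 0.85, S = 0.7, total = 0.9, SG = 0.8))
  goodD <- mkrec(c(H = 0.9, G = 0.75, S = 0.70, total = 0.80, SG = 0.93))
  recs <- list(`4CL` = good4, CCR1 = goodC, COMT = goodM, CAD = goodD)
  ev <- evaluate_criteria(recs, crit)
  expect_true(ev$pass)
  expect_length(ev$reasons, 0)

  # no H increase under the 4CL knockdown
  bad <- recs
  bad$`4CL` <- mkrec(c(H = 1.0, G = 0.53, S = 1.0, total = 0.78, SG = 1.3))
  ev2 <- evaluate_criteria(bad, crit)
  expect_false(ev2$pass)
  expect_true("4CL:H_fold" %in% ev2$reasons)

  # S/G moving the wrong way under the 4CL knockdown
  bad2 <- recs
  bad2$`4CL` <- mkrec(c(H = 1.82, G = 0.53, S = 1.0, total = 0.78,
                        SG = 0.9))
  expect_true("4CL:SG_direction" %in% evaluate_criteria(bad2, crit)$reasons)

  # COMT metabolite signature out of band
  bad3 <- recs
  bad3$COMT <- mkrec(c(H = 1.1, G = 0.85, S = 0.7, total = 0.9, SG = 0.8),
                     met = c(Z9 = 1.0, Z11 = 0.8))
  expect_true("COMT:Z9" %in% evaluate_criteria(bad3, crit)$reasons)

  # missing or inadmissible scenarios fail with a flagged reason
  ev4 <- evaluate_criteria(recs[-1], crit)
  expect_true(any(grepl("4CL:inadmissible", ev4$reasons)))
})

test_that("the strict table reading is more demanding than the default", {
  mkrec <- function(folds, met = c(Z9 = 1.3, Z11 = 0.8)) {
    mf <- stats::setNames(rep(1, 16), names(pathway_metabolites()))
    mf[names(met)] <- met
    structure(list(scenario = "x", status = "converged",
                   folds = folds, met_fold = mf),
              class = "scenario_record")
  }
  # a record set matching the match conditions but not the printed
  # CCR1/CAD fold values
  recs <- list(
    `4CL` = mkrec(c(H = 1.82, G = 0.75, S = 0.9, total = 0.85,
                    SG = 1.2)),
    CCR1 = mkrec(c(H = 0.9, G = 0.97, S = 0.99, total = 0.97,
                   SG = 1.02)),
    COMT = mkrec(c(H = 1.0, G = 0.9, S = 0.8, total = 0.9, SG = 0.89)),
    CAD = mkrec(c(H = 0.95, G = 0.98, S = 0.96, total = 0.98,
                  SG = 0.97)))
  expect_true(evaluate_criteria(recs, default_criteria())$pass)
  ev <- evaluate_criteria(recs, table_criteria())
  expect_false(ev$pass)
  expect_true(any(grepl("CCR1|CAD", ev$reasons)))
})

test_that("widening the tolerance never loses accepted records", {
  set.seed(5)
  # synthetic fold records around the targets
  recs_pool <- replicate(40, {
    mf <- stats::setNames(exp(stats::rnorm(16, 0, 0.2)),
                          names(pathway_metabolites()))
    mk <- function(v) structure(
      list(scenario = "x", status = "converged",
           folds = c(H = v[1], G = v[2], S = v[3], total = v[4],
                     SG = v[5]),
           met_fold = mf), class = "scenario_record")
    list(`4CL` = mk(c(1.82, 0.53, 1, 0.78, 1.2) *
                      exp(stats::rnorm(5, 0, 0.15))),
         CCR1 = mk(c(0.8, 0.75, 0.75, 0.75, 1.05) *
                     exp(stats::rnorm(5, 0, 0.15))),
         COMT = mk(c(1.1, 0.87, 0.7, 0.9, 0.9) *
                     exp(stats::rnorm(5, 0, 0.1))),
         CAD = mk(c(0.9, 0.75, 0.7, 0.82, 0.93) *
                    exp(stats::rnorm(5, 0, 0.05))))
  }, simplify = FALSE)
  narrow <- default_criteria(rel_tol = 0.05)
  wide <- default_criteria(rel_tol = 0.3)
  pass_narrow <- vapply(recs_pool, function(r)
    evaluate_criteria(r, narrow)$pass, TRUE)
  pass_wide <- vapply(recs_pool, function(r)
    evaluate_criteria(r, wide)$pass, TRUE)
  expect_true(all(pass_wide[pass_narrow]))
  expect_gte(sum(pass_wide), sum(pass_narrow))
})

test_that("screening a small ensemble is deterministic and consistent", {
  cfg <- sampler_config(n_sets = 12, seed = 31)
  r1 <- screen_ensemble(configs = 1, config = cfg)
  r2 <- screen_ensemble(configs = 1, config = cfg)
  expect_identical(r1$details, r2$details)
  expect_identical(r1$counts, r2$counts)
  expect_lte(r1$counts$accepted, r1$counts$admissible)
  expect_lte(r1$counts$admissible, r1$counts$sampled)
  expect_equal(r1$counts$sampled, 12)
  # reasons are first-failure codes or empty for passes
  expect_true(all(r1$details$reason[!r1$details$pass] != ""))
  expect_true(all(r1$details$reason[r1$details$pass] == ""))
  # lazy and eager evaluation accept exactly the same sets
  r3 <- screen_ensemble(configs = 1, config = cfg, lazy = FALSE)
  expect_identical(r3$details$pass, r1$details$pass)
})
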