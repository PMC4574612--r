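test_that("flux laws reproduce hand-evaluated power laws of the example set", {
  m <- example_model()
  v <- evaluate_fluxes(m$topology, m$params, rep(100, 16))
  # direct hand evaluation: alpha * 100^(sum of kinetic orders)
  expect_equal(v[["V5"]], 0.1832 * 100^(0.0710 - 0.0355 - 0.4505),
               tolerance = 1e-12)
  expect_equal(v[["V1"]], 0.5233 * 100^(0.2813 - 0.1406),
               tolerance = 1e-12)
  expect_equal(v[["V26"]], 0.0814 * 100^(0.7116 - 0.3558 - 0.0355),
               tolerance = 1e-12)
  expect_equal(v[["V5"]], 0.0271, tolerance = 1e-3)
})

test_that("steady-state flux identity V_j = alpha_j * 100^sum(g) holds", {
  ens <- small_ensemble()
  for (p in ens$sets[1:5]) {
    v <- evaluate_fluxes(TOP1, p, rep(100, 16))
    expect_equal(unname(v), unname(p$alpha * 100^colSums(p$g)),
                 tolerance = 1e-14)
  }
})

test_that("a zero enzyme activity zeroes exactly its fluxes", {
  m <- example_model()
  enz <- wildtype_enzymes()
  enz[["Z20"]] <- 0                       # 4CL
  v <- evaluate_fluxes(m$topology, m$params, rep(100, 16), enz)
  expect_equal(unname(v[c("V4", "V11", "V14")]), c(0, 0, 0))
  expect_true(all(v[setdiff(names(v), c("V4", "V11", "V14"))] > 0))
  # CAD = 0 kills V6, V16, V24 (and the complex under multiplicative
  # coupling)
  top_prod <- build_topology(1, channel_coupling = "product")
  enz2 <- enzyme_profile(top_prod, c(CAD = 0))
  v2 <- evaluate_fluxes(top_prod, m$params, rep(100, 16), enz2)
  expect_equal(unname(v2[c("V6", "V16", "V24", "V26")]), rep(0, 4))
})

test_that("non-positive states are rejected", {
  m <- example_model()
  expect_error(evaluate_fluxes(m$topology, m$params, c(rep(100, 15), 0)),
               "non-positive")
  expect_error(evaluate_fluxes(m$topology, m$params, rep(100, 15)),
               "16 entries")
})

test_that("rhs agrees with the brute-force oracle on random states", {
  set.seed(1234)
  ens <- small_ensemble()
  influx <- c(I1 = FD1$I1, I2 = FD1$I2)
  for (k in 1:100) {
    p <- ens$sets[[(k %% length(ens$sets)) + 1L]]
    state <- 100 * exp(stats::runif(16, -2, 2))
    enz <- wildtype_enzymes()
    enz[] <- stats::runif(18, 0.2, 1.5)
    got <- gma_rhs(TOP1, p, state, enz, influx)
    want <- oracle_rhs(TOP1, p, state, enz, influx)
    expect_equal(unname(got), want, tolerance = 1e-12)
  }
})

test_that("fluxes respond monotonically to enzymes, substrates, inhibitors", {
  set.seed(77)
  p <- small_ensemble()$sets[[3]]
  state <- 100 * exp(stats::runif(16, -1, 1))
  base <- evaluate_fluxes(TOP1, p, state)
  # enzyme activity up -> flux up, strictly
  enz <- wildtype_enzymes(); enz[["Z21"]] <- 1.3
  up <- evaluate_fluxes(TOP1, p, state, enz)
  ccr_fluxes <- TOP1$fluxes$flux[TOP1$fluxes$enzyme == 21]
  expect_true(all(up[ccr_fluxes] > base[ccr_fluxes]))
  expect_equal(up[setdiff(names(base), ccr_fluxes)],
               base[setdiff(names(base), ccr_fluxes)])
  # substrate up -> its fluxes up; inhibitor up -> inhibited fluxes down
  for (j in c("V5", "V15", "V12")) {
    sub <- TOP1$fluxes[j, "substrate"]
    inh <- TOP1$fluxes[j, "product"]
    s2 <- state; s2[sub] <- s2[sub] * 1.05
    expect_gt(evaluate_fluxes(TOP1, p, s2)[[j]], base[[j]])
    s3 <- state; s3[inh] <- s3[inh] * 1.05
    expect_lt(evaluate_fluxes(TOP1, p, s3)[[j]], base[[j]])
  }
})

test_that("enzyme profiles derive the channel activity by coupling rule", {
  expect_equal(enzyme_profile(TOP1, c(CCR1 = 0.5))[["Z34"]], 0.5)
  expect_equal(enzyme_profile(TOP1, c(CAD = 0.7))[["Z34"]], 1)  # ccr1 rule
  tp <- build_topology(1, channel_coupling = "product")
  expect_equal(enzyme_profile(tp, c(CCR1 = 0.5, CAD = 0.7))[["Z34"]], 0.35)
  tm <- build_topology(1, channel_coupling = "min")
  expect_equal(enzyme_profile(tm, c(CCR1 = 0.5, CAD = 0.7))[["Z34"]], 0.5)
  # explicit Z34 wins
  expect_equal(enzyme_profile(TOP1, c(CCR1 = 0.5, Z34 = 0.9))[["Z34"]], 0.9)
  expect_error(enzyme_profile(TOP1, c(XYZ = 0.5)), "unknown enzyme")
  expect_error(enzyme_profile(TOP1, c(CAD = -1)), ">= 0")
})
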