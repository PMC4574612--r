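test_that("the LP optimum satisfies all constraints of the bounds config", {
  b <- default_bounds()
  for (top in list(TOP1, TOP2, TOP3)) {
    fd <- solve_wildtype_fluxes(top, b)
    expect_lt(fd$residual, 1e-9)
    expect_equal(fd$I1, b$i1, tolerance = 1e-9)
    expect_true(fd$I2 >= b$i2_range[1] - 1e-9 &&
                  fd$I2 <= b$i2_range[2] + 1e-9)
    for (f in names(b$efflux_lb)) {
      expect_gte(fd$V[[f]], b$efflux_lb[[f]] - 1e-9)
      expect_lte(fd$V[[f]], b$efflux_cap * (fd$I1 + fd$I2) + 1e-9)
    }
    # composition: H share pinned, S/G in window
    expect_equal(fd$V[["V7"]] / fd$objective, b$h_share, tolerance = 1e-7)
    sg <- fd$V[["V25"]] / fd$V[["V17"]]
    expect_true(sg >= b$sg_range[1] - 1e-7 && sg <= b$sg_range[2] + 1e-7)
    expect_true(all(fd$V >= 0))
  }
})

test_that("config 3 forces the unsupplied coniferaldehyde branch to zero", {
  fd3 <- solve_wildtype_fluxes(TOP3)
  expect_equal(unname(fd3$V[c("V19", "V22", "V24")]), rep(0, 3))
  expect_gt(fd3$V[["V26"]], 0)
})

test_that("the flux anchor is invariant to metabolite row permutation", {
  set.seed(42)
  perm <- sample(16)
  topp <- TOP1
  topp$stoich <- topp$stoich[perm, ]
  topp$influx_targets <- c(I1 = match(1L, perm), I2 = match(3L, perm))
  fd <- solve_wildtype_fluxes(TOP1)
  fdp <- solve_wildtype_fluxes(topp)
  expect_equal(fdp$V, fd$V, tolerance = 1e-7)
})

test_that("scaling all absolute bounds by c scales the optimum by c", {
  b <- default_bounds()
  cc <- 2.5
  b2 <- default_bounds(i1 = b$i1 * cc, i2_range = b$i2_range * cc,
                       efflux_lb = b$efflux_lb * cc)
  fd <- solve_wildtype_fluxes(TOP1, b)
  fd2 <- solve_wildtype_fluxes(TOP1, b2)
  expect_equal(fd2$V, fd$V * cc, tolerance = 1e-6)
  expect_equal(fd2$I2, fd$I2 * cc, tolerance = 1e-6)
})

test_that("check_balance reports per-node residuals and flags imbalance", {
  fd <- solve_wildtype_fluxes(TOP1)
  rep <- check_balance(TOP1, fd)
  expect_true(all(rep$balanced))
  # zero fluxes with zero influx are balanced
  zero <- list(V = fd$V * 0, I1 = 0, I2 = 0)
  expect_true(all(check_balance(TOP1, zero)$balanced))
  # the example set's implied fluxes leave the cinnamic acid node
  # unbalanced by about -0.16, all other nodes near balance
  m <- example_model()
  fx <- list(V = m$fluxes, I1 = m$fluxes[["V1"]],
             I2 = m$fluxes[["V4"]] + m$fluxes[["V8"]] - m$fluxes[["V3"]])
  repm <- check_balance(TOP1, fx, tol = 0.02)
  expect_false(repm$balanced[repm$metabolite == "Z2"])
  expect_equal(repm$net[repm$metabolite == "Z2"], -0.155,
               tolerance = 0.01)
  expect_true(all(repm$balanced[!repm$metabolite %in% c("Z2")]))
})

test_that("infeasible bounds give a named diagnostic", {
  b <- default_bounds(efflux_lb = c(V2 = 10))   # more efflux than influx
  expect_error(solve_wildtype_fluxes(TOP1, b), "infeasible")
})

test_that("flux distributions round-trip through tabular text", {
  fd <- solve_wildtype_fluxes(TOP1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_flux_distribution(fd, path)
  back <- read_flux_distribution(path)
  expect_equal(back$V, fd$V, tolerance = 1e-12)
  expect_equal(back$I1, fd$I1)
  expect_equal(back$I2, fd$I2)
})
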