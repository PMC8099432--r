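test_that("all-zero state has all-zero derivative", {
  for (spec in list(model_spec("HYPIL6"), model_spec("IL27"),
                    model_spec("IL27", "CHIMERA"),
                    model_spec("IL27", hypothesis = "H2"))) {
    n <- nrow(build_registry(spec))
    expect_equal(rhs(spec, kinetic_rates(), numeric(n)), numeric(n))
  }
})

test_that("a single active binding term evaluates by hand", {
  spec <- model_spec("HYPIL6")
  reg <- build_registry(spec)
  y <- stats::setNames(numeric(22), reg$name)
  y["L6"] <- 10; y["R1"] <- 5
  r <- kinetic_rates(r1_6_on = 0.01, beta6 = 0)
  d <- stats::setNames(rhs(spec, r, y), reg$name)
  expect_equal(d[["C1"]], 0.5)   # 0.01 * 10 * 5
  expect_equal(d[["L6"]], -0.5)
  expect_equal(d[["R1"]], -0.5)
  expect_equal(sum(abs(d)), 1.5) # no other flux is active
})

test_that("rhs matches the hand-written HypIL-6 equations on random states", {
  spec <- model_spec("HYPIL6")
  set.seed(31)
  for (i in 1:20) {
    y <- stats::runif(22, 0, 10)
    r <- kinetic_rates(
      r1_6_on = stats::runif(1, 0, 0.01), r1_6_off = stats::runif(1, 0, 0.1),
      r2_6_on = stats::runif(1, 0, 1), r2_6_off = stats::runif(1, 0, 1),
      k1a_on = stats::runif(1, 0, 0.01), k1a_off = stats::runif(1, 0, 1),
      k3a_on = stats::runif(1, 0, 0.01), k3a_off = stats::runif(1, 0, 1),
      q = stats::runif(1, 0, 2), d1 = stats::runif(1, 0, 0.01),
      d3 = stats::runif(1, 0, 0.01), beta6 = stats::runif(1, 0, 0.01))
    expect_lt(max(abs(rhs(spec, r, y) - hyp6_rhs_manual(y, r))), 1e-10)
  }
})

test_that("compiled derivative equals the R implementation", {
  for (spec in list(model_spec("HYPIL6"), model_spec("IL27"),
                    model_spec("IL27", "CHIMERA"),
                    model_spec("HYPIL6", hypothesis = "H2"))) {
    reg <- build_registry(spec)
    set.seed(7)
    y <- stats::setNames(stats::runif(nrow(reg), 0, 5), reg$name)
    net <- build_network(spec, kinetic_rates())
    dC <- deSolve::DLLfunc(y = y, times = 0, func = "statkin_derivs",
                           initfunc = "statkin_initmod", dllname = "statkin",
                           parms = statkin:::encode_network_parms(net))$dy
    expect_lt(max(abs(rhs(spec, kinetic_rates(), y) - dC)), 1e-12)
  }
})

test_that("moiety-weighted derivative sums vanish without internalization", {
  set.seed(17)
  for (spec in list(model_spec("HYPIL6"), model_spec("IL27"))) {
    reg <- build_registry(spec)
    r <- kinetic_rates(beta6 = 0, beta27 = 0)
    y <- stats::runif(nrow(reg), 0, 8)
    d <- rhs(spec, r, y)
    for (m in list(reg$S1 + reg$pS1, reg$S3 + reg$pS3, reg$R1, reg$R2,
                   reg$L)) {
      expect_lt(abs(sum(m * d)), 1e-10)
    }
  }
})

test_that("H2 internalization removes receptor species at gamma x free pSTAT", {
  spec1 <- model_spec("IL27", hypothesis = "H1")
  spec2 <- model_spec("IL27", hypothesis = "H2")
  reg <- build_registry(spec2)
  set.seed(5)
  y <- stats::runif(33, 0, 4)
  gamma <- 0.02
  r0 <- kinetic_rates(beta27 = 0, gamma27 = gamma)
  pstat_free <- y[match("pS1", reg$name)] + y[match("pS3", reg$name)]
  extra <- rhs(spec2, r0, y) - rhs(spec1, r0, y)
  expected <- -gamma * pstat_free * y * reg$receptor
  expect_equal(extra, unname(expected), tolerance = 1e-12)
})

test_that("swapping STAT1 and STAT3 parameters swaps the pSTAT trajectories", {
  r <- kinetic_rates(k1a_on = 2e-4, k1b_on = 3e-3, k3a_on = 7e-4,
                     k3b_on = 5e-5, k1a_off = 0.2, k1b_off = 0.05,
                     k3a_off = 0.4, k3b_off = 0.15, d1 = 1e-3, d3 = 4e-3)
  rs <- kinetic_rates(k1a_on = 7e-4, k1b_on = 5e-5, k3a_on = 2e-4,
                      k3b_on = 3e-3, k1a_off = 0.4, k1b_off = 0.15,
                      k3a_off = 0.2, k3b_off = 0.05, d1 = 4e-3, d3 = 1e-3)
  spec <- model_spec("IL27")
  i1 <- initial_conditions(R1_0 = 25, R2_0 = 50, S1_0 = 300, S3_0 = 650,
                           L_0 = 2)
  i2 <- initial_conditions(R1_0 = 25, R2_0 = 50, S1_0 = 650, S3_0 = 300,
                           L_0 = 2)
  t1 <- integrate_model(spec, r, i1)
  t2 <- integrate_model(spec, rs, i2)
  expect_equal(total_pstat(t1, 1), total_pstat(t2, 3), tolerance = 1e-6)
  expect_equal(total_pstat(t1, 3), total_pstat(t2, 1), tolerance = 1e-6)
})

test_that("binding-only subsystem reaches the closed-form equilibrium", {
  # q = beta = 0, dimerization frozen, fixed dimer pool: detailed balance
  # fixes the bound/free ratios at k_on [free sites] / k_off
  spec <- model_spec("HYPIL6")
  reg <- build_registry(spec)
  r <- kinetic_rates(r1_6_on = 0, r1_6_off = 0, r2_6_on = 0, r2_6_off = 0,
                     k1a_on = 1e-3, k1a_off = 0.2,
                     k3a_on = 5e-4, k3a_off = 0.1,
                     q = 0, beta6 = 0)
  y0 <- stats::setNames(numeric(22), reg$name)
  y0["D6"] <- 2; y0["S1"] <- 100; y0["S3"] <- 50
  tr <- deSolve::ode(y = y0, times = c(0, 2e5),
                     parms = statkin:::encode_network_parms(
                       build_network(spec, r)),
                     func = "statkin_derivs", initfunc = "statkin_initmod",
                     dllname = "statkin", rtol = 1e-10, atol = 1e-12)
  yss <- tr[2, -1]
  # empty dimer has two free sites: [D6.S1]/([D6][S1]) = 2 k_on / k_off
  expect_equal(yss[["D6.S1"]] / (yss[["D6"]] * yss[["S1"]]),
               2 * 1e-3 / 0.2, tolerance = 0.01)
  # second site: [S1.D6.S1]/([D6.S1][S1]) = k_on / (2 k_off)
  expect_equal(yss[["S1.D6.S1"]] / (yss[["D6.S1"]] * yss[["S1"]]),
               1e-3 / (2 * 0.2), tolerance = 0.01)
  expect_equal(yss[["D6.S3"]] / (yss[["D6"]] * yss[["S3"]]),
               2 * 5e-4 / 0.1, tolerance = 0.01)
})
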