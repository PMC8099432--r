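test_that("no stimulus and no phosphorylation give zero pSTAT", {
  init0 <- initial_conditions(R1_0 = 25, R2_0 = 50, S1_0 = 500, S3_0 = 500,
                              L_0 = 0)
  for (cy in c("HYPIL6", "IL27")) {
    tr <- integrate_model(model_spec(cy), kinetic_rates(), init0)
    expect_equal(total_pstat(tr, 1), rep(0, 8), tolerance = 1e-9)
    expect_equal(total_pstat(tr, 3), rep(0, 8), tolerance = 1e-9)
  }
  initq <- initial_conditions(R1_0 = 25, R2_0 = 50, S1_0 = 500, S3_0 = 500,
                              L_0 = 2)
  trq <- integrate_model(model_spec("IL27"), kinetic_rates(q = 0), initq)
  expect_lt(max(total_pstat(trq, 1), total_pstat(trq, 3)), 1e-8)
})

test_that("trajectory starts at the mapped initial conditions", {
  init <- initial_conditions(R1_0 = 25, R2_0 = 50, S1_0 = 500, S3_0 = 500,
                             L_0 = 2)
  spec <- model_spec("IL27")
  tr <- integrate_model(spec, kinetic_rates(), init)
  expect_equal(unname(tr$state[1, ]), unname(initial_state(spec, init)))
})

test_that("moiety totals are conserved without internalization", {
  init <- initial_conditions(R1_0 = 25, R2_0 = 50, S1_0 = 500, S3_0 = 500,
                             L_0 = 2)
  spec <- model_spec("IL27")
  tr <- integrate_model(spec, kinetic_rates(beta27 = 0), init)
  for (i in seq_along(tr$time_min)) {
    tot <- conserved_totals(spec, tr$state[i, ])
    expect_equal(tot[["STAT1"]], 500, tolerance = 1e-6)
    expect_equal(tot[["STAT3"]], 500, tolerance = 1e-6)
    expect_equal(tot[["GP130"]], 25, tolerance = 1e-6)
    expect_equal(tot[["IL27Ra"]], 50, tolerance = 1e-6)
    expect_equal(tot[["ligand"]], 2, tolerance = 1e-6)
  }
})

test_that("halving solver tolerances changes observables by less than 0.1%", {
  init <- initial_conditions(R1_0 = 25, R2_0 = 50, S1_0 = 500, S3_0 = 500,
                             L_0 = 2)
  spec <- model_spec("IL27")
  t1 <- integrate_model(spec, kinetic_rates(), init)
  t2 <- integrate_model(spec, kinetic_rates(), init,
                        rtol = 5e-9, atol = 5e-11)
  rel <- abs(total_pstat(t1, 1)[-1] - total_pstat(t2, 1)[-1]) /
    total_pstat(t2, 1)[-1]
  expect_lt(max(rel), 1e-3)
})

test_that("H1 internalization vanishes continuously as beta goes to 0", {
  init <- initial_conditions(R1_0 = 25, R2_0 = 50, S1_0 = 500, S3_0 = 500,
                             L_0 = 2)
  spec <- model_spec("IL27")
  base <- total_pstat(integrate_model(spec, kinetic_rates(beta27 = 0), init), 1)
  eps <- total_pstat(integrate_model(spec, kinetic_rates(beta27 = 1e-8),
                                     init), 1)
  expect_equal(eps, base, tolerance = 1e-3)
})

test_that("H2 with matched effective rate stays close to H1 mid-course", {
  # gamma * (typical free pSTAT) ~ beta makes the two internalization
  # mechanisms comparable over the fitted window
  init <- initial_conditions(R1_0 = 25, R2_0 = 50, S1_0 = 500, S3_0 = 500,
                             L_0 = 2)
  beta <- 1e-4
  h1 <- integrate_model(model_spec("IL27", hypothesis = "H1"),
                        kinetic_rates(beta27 = beta), init)
  typ <- mean(total_pstat(h1, 1) + total_pstat(h1, 3))
  h2 <- integrate_model(model_spec("IL27", hypothesis = "H2"),
                        kinetic_rates(gamma27 = beta / typ), init)
  mid <- 3:6   # 15-90 min
  dev <- abs(total_pstat(h2, 1)[mid] - total_pstat(h1, 1)[mid]) /
    total_pstat(h1, 1)[mid]
  expect_lt(max(dev), 0.5)
})

test_that("model-output normalization fixes the IL-27 reference at 1", {
  init <- initial_conditions(R1_0 = 25, R2_0 = 50, S1_0 = 500, S3_0 = 500,
                             L_0 = 2)
  tr <- integrate_model(model_spec("IL27"), kinetic_rates(), init)
  s <- total_pstat(tr, 1)
  norm <- normalize_sim(s, s)
  expect_equal(norm[match(30, default_time_grid())], 1)
  expect_equal(normalize_sim(rep(2, 8), rep(2, 8)), rep(1, 8))
  expect_error(normalize_sim(s, rep(0, 8)), "non-positive")
})
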