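test_that("stochastic double-labeling correction evaluates by hand", {
  cc <- correct_homodimer_cotracking(100, 100, 10)
  expect_equal(cc$AB_star, 20)
  expect_equal(cc$rel_colocomotion, 0.2)
  # unequal labeling raises the correction factor
  cc2 <- correct_homodimer_cotracking(150, 50, 10)
  expect_equal(cc2$AB_star, 10 / (2 * 0.75 * 0.25))
  expect_equal(correct_homodimer_cotracking(80, 120, 0)$AB_star, 0)
  expect_error(correct_homodimer_cotracking(0, 100, 0), "must be > 0")
  expect_error(correct_homodimer_cotracking(10, 10, 11), "min")
})

test_that("heterodimer KD2D follows the mass-action equilibrium", {
  expect_equal(kd2d_hetero(2, 1, 0.5), 1.5)
  expect_equal(kd2d_hetero(1, 1, 1), 0)
  expect_error(kd2d_hetero(2, 1, 0), "alpha must be > 0")
  expect_error(kd2d_hetero(0.2, 1, 0.9), "invalid input")
})

test_that("homodimer KD2D follows the monomer-dimer equilibrium", {
  expect_equal(kd2d_homo(2, 0.5), 2)   # M = 1, D = 0.5
  expect_equal(kd2d_homo(2, 1), 0)
  expect_error(kd2d_homo(2, 0), "alpha must be > 0")
  expect_error(kd2d_homo(2, 1.2), "<= 1")
})

test_that("KD2D is strictly decreasing in the dimerized fraction", {
  a <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(vapply(a, kd2d_homo, numeric(1), gp130 = 3)) < 0))
  expect_true(all(diff(vapply(a, kd2d_hetero, numeric(1),
                              gp130 = 4, il27ra = 2)) < 0))
})

test_that("alpha solved from a KD2D round-trips through the estimators", {
  # uniroot on the raw balance equations is the independent oracle
  for (kd in c(0.21, 0.81, 2, 10)) {
    a_pkg <- alpha_homo(kd, gp130 = 3)
    a_ora <- stats::uniroot(function(a) kd2d_homo(3, a) - kd,
                            c(1e-9, 1 - 1e-9), tol = 1e-12)$root
    expect_equal(a_pkg, a_ora, tolerance = 1e-7)
    expect_equal(kd2d_homo(3, a_pkg), kd, tolerance = 1e-9)

    a_pkg2 <- alpha_hetero(kd, gp130 = 4, il27ra = 2)
    a_ora2 <- stats::uniroot(function(a) kd2d_hetero(4, 2, a) - kd,
                             c(1e-9, 1 - 1e-9), tol = 1e-12)$root
    expect_equal(a_pkg2, a_ora2, tolerance = 1e-7)
    expect_equal(kd2d_hetero(4, 2, a_pkg2), kd, tolerance = 1e-9)
  }
})

test_that("per-cell tables carry corrected fractions and estimates", {
  homo <- data.frame(cell_id = 1:2, A = c(100, 90), B = c(100, 110),
                     AB = c(10, 12), gp130_density = c(2, 3))
  th <- kd2d_homo_table(homo)
  expect_equal(th$AB_star[1], 20)
  expect_true(all(th$kd2d > 0))
  het <- data.frame(cell_id = 1, gp130_density = 2, il27ra_density = 1,
                    alpha = 0.5)
  expect_equal(kd2d_hetero_table(het)$kd2d, 1.5)
})
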