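test_that("the distance is a generalized Euclidean norm over the 32 cells", {
  summ <- rpe1_summary_fixture()
  sim <- summ[, c("stat", "time_min", "cytokine")]
  sim$value <- summ$mu
  expect_equal(distance_summary(sim, summ), 0)
  sim2 <- sim
  sim2$value[5] <- sim2$value[5] + 0.5
  expect_equal(distance_summary(sim2, summ), 0.5)
  set.seed(4)
  sim3 <- sim
  sim3$value <- sim3$value + stats::rnorm(nrow(sim3), 0, 0.3)
  expect_equal(distance_summary(sim3, summ), distance_brute(sim3, summ),
               tolerance = 1e-12)
  expect_error(distance_summary(sim[-1, ], summ), "every summary cell")
  sim4 <- sim
  sim4$value[1] <- NaN
  expect_equal(distance_summary(sim4, summ), Inf)
})

test_that("prior draws respect their supports and moments", {
  pr <- default_priors("H1")
  set.seed(12)
  draws <- sample_prior(pr, 1e4)
  r2on <- draws[, "r2_6_on"]
  expect_true(all(r2on >= 1e-2 & r2on <= 1e3))
  expect_true(all(draws[, "k1a_on"] >= 1e-7 & draws[, "k1a_on"] <= 10))
  expect_true(all(draws[, "q"] >= 1e-3 & draws[, "q"] <= 1e2))
  expect_true(all(draws[, "R1_0"] >= 0))
  s1 <- draws[, "S1_0"]
  expect_lt(abs(mean(s1) - 300), 3 * 100 / sqrt(length(s1)))
  # log10-normal location
  expect_lt(abs(mean(log10(draws[, "r1_6_on"])) + 3), 3 * 1.5 / sqrt(1e4))
})

test_that("prior density vanishes outside supports and integrates sense", {
  pr <- default_priors("H1")
  theta <- stats::setNames(drop(sample_prior(pr, 1)), pr$name)
  expect_gt(prior_density(pr, theta), 0)
  bad <- theta
  bad[["k1a_on"]] <- 1e2   # outside 10^U(-7, 1)
  expect_equal(prior_density(pr, bad), 0)
  neg <- theta
  neg[["R1_0"]] <- -1
  expect_equal(prior_density(pr, neg), 0)
  # transform round trip
  tt <- to_transformed(pr, theta)
  expect_equal(from_transformed(pr, tt), theta, tolerance = 1e-12)
})

test_that("H2 priors swap the internalization parameterization", {
  expect_true(all(c("gamma6", "gamma27") %in% default_priors("H2")$name))
  expect_false(any(c("beta6", "beta27") %in% default_priors("H2")$name))
  cs <- statkin:::.cell_specific_params("H1")
  expect_length(cs, 9)
  expect_setequal(cs, c("q", "d1", "d3", "beta6", "beta27",
                        "R1_0", "R2_0", "S1_0", "S3_0"))
})

test_that("rejection ABC with infinite threshold reproduces the prior", {
  m <- toy_gaussian_model(ybar_obs = 0, n = 10, sigma = 1,
                          mu0 = 2, tau0 = 2)
  set.seed(33)
  res <- abc_rejection(m, delta = Inf, N = 2000)
  expect_equal(res$acceptance_rate, 1)
  expect_lt(abs(mean(res$particles$mu) - 2), 3 * 2 / sqrt(2000))
  expect_error(abc_rejection(m, delta = 0, N = 10), "delta must be > 0")
})

test_that("rejection ABC approximates the conjugate Gaussian posterior", {
  set.seed(14)
  n <- 25; sigma <- 1
  y <- stats::rnorm(n, 1.3, sigma)
  m <- toy_gaussian_model(mean(y), n, sigma, mu0 = 0, tau0 = 2)
  res <- abc_rejection(m, delta = 0.05, N = 800,
                       max_attempts_per_accept = 5000)
  post <- conjugate_posterior(0, 2, sigma, n, mean(y))
  mc_se <- stats::sd(res$particles$mu) / sqrt(800)
  # delta > 0 inflates the ABC posterior slightly; allow for that bias
  expect_lt(abs(mean(res$particles$mu) - post$mean),
            3 * mc_se + 0.05)
})

test_that("a degenerate threshold aborts with an acceptance-rate message", {
  m <- toy_gaussian_model(0, 10, 1)
  set.seed(1)
  expect_error(abc_rejection(m, delta = 1e-9, N = 50,
                             max_attempts_per_accept = 20),
               "acceptance rate below floor")
})

test_that("shrinking the threshold never degrades accepted distances", {
  set.seed(44)
  m <- toy_gaussian_model(0, 10, 1)
  r1 <- abc_rejection(m, delta = 1, N = 400)
  r2 <- abc_rejection(m, delta = 0.3, N = 400)
  q1 <- stats::quantile(r1$particles$distance, c(0.25, 0.5, 0.9))
  q2 <- stats::quantile(r2$particles$distance, c(0.25, 0.5, 0.9))
  expect_true(all(q2 <= q1))
})

test_that("SMC model probabilities are normalized and single-model runs are 1", {
  set.seed(55)
  m <- toy_gaussian_model(0, 10, 1)
  res <- abc_smc(m, smc_config(N = 200, M = 3, delta_schedule = NULL,
                               seed = 56))
  expect_true(all(res$model_probabilities$probability == 1))
  expect_equal(unname(res$final_probability), 1)
  # two identical models split mass; probabilities sum to one per iteration
  m2 <- toy_gaussian_model(0, 10, 1, name = "toyB")
  res2 <- abc_smc(list(m, m2), smc_config(N = 200, M = 3,
                                          delta_schedule = NULL, seed = 57))
  sums <- tapply(res2$model_probabilities$probability,
                 res2$model_probabilities$iteration, sum)
  expect_equal(as.vector(sums), rep(1, 3))
  expect_gt(min(res2$final_probability), 0.2)
})

test_that("SMC agrees with rejection on the conjugate toy", {
  set.seed(66)
  n <- 25; sigma <- 1
  y <- stats::rnorm(n, 1.1, sigma)
  m <- toy_gaussian_model(mean(y), n, sigma, mu0 = 0, tau0 = 2)
  smc <- abc_smc(m, smc_config(N = 600, delta_schedule = c(2, 0.6, 0.2, 0.08),
                               seed = 67))
  rej <- abc_rejection(m, delta = 0.08, N = 600,
                       max_attempts_per_accept = 10000)
  w <- smc$particles$weight
  smc_mean <- sum(w * smc$particles$mu) / sum(w)
  mc_se <- stats::sd(rej$particles$mu) / sqrt(600)
  expect_lt(abs(smc_mean - mean(rej$particles$mu)), 3 * mc_se + 0.05)
})

test_that("the schedule must decrease and the reference schedule has 15 steps", {
  expect_error(smc_config(delta_schedule = c(1, 2)), "decreasing")
  expect_length(default_delta_schedule(), 15)
  expect_true(all(diff(default_delta_schedule()) < 0))
})

test_that("weighted posterior summaries match brute-force oracles", {
  expect_equal(weighted_quantile(c(1, 2, 3), probs = 0.5), 2)
  set.seed(9)
  x <- stats::rnorm(200)
  w <- stats::runif(200)
  for (p in c(0.025, 0.25, 0.5, 0.9, 0.975)) {
    expect_equal(weighted_quantile(x, w, p), weighted_quantile_brute(x, w, p))
  }
  post <- data.frame(a = x, b = 2 * x + stats::rnorm(200, 0, 0.1),
                     weight = w)
  s <- summarize_posterior(post)
  expect_true(all(s$summary$median >= s$summary$q2.5 &
                    s$summary$median <= s$summary$q97.5))
  expect_gt(s$correlation["a", "b"], 0.9)
  # degenerate sample: zero-width intervals, correlations flagged NA
  dg <- data.frame(a = rep(1, 5), b = rep(2, 5))
  sd <- summarize_posterior(dg)
  expect_equal(sd$summary$q2.5, sd$summary$q97.5)
  expect_true(all(is.na(sd$correlation)))
  expect_error(summarize_posterior(post[0, ]), "empty")
})
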