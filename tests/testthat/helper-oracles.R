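# Independent oracles used across the test files.  These are written
# directly from the biochemical reaction scheme / definitions, not from
# the package's network builder, so agreement is a genuine dual-route
# check.

# Hand-written right-hand side of the HypIL-6 model under H1, species
# order as enumerated in the registry.
hyp6_rhs_manual <- function(y, r) {
  L6 <- y[1]; R1 <- y[2]; C1 <- y[3]; D6 <- y[4]; S1 <- y[5]; S3 <- y[6]
  D6S1 <- y[7]; D6S3 <- y[8]; D6P1 <- y[9]; D6P3 <- y[10]
  S1D6S1 <- y[11]; P1D6S1 <- y[12]; P1D6P1 <- y[13]
  S3D6S3 <- y[14]; P3D6S3 <- y[15]; P3D6P3 <- y[16]
  S1D6S3 <- y[17]; P1D6S3 <- y[18]; S1D6P3 <- y[19]; P1D6P3 <- y[20]
  P1 <- y[21]; P3 <- y[22]

  k1a <- r[["k1a_on"]]; k1o <- r[["k1a_off"]]
  k3a <- r[["k3a_on"]]; k3o <- r[["k3a_off"]]
  q <- r[["q"]]; d1 <- r[["d1"]]; d3 <- r[["d3"]]; b <- r[["beta6"]]

  a1 <- r[["r1_6_on"]] * L6 * R1; a2 <- r[["r1_6_off"]] * C1
  a3 <- r[["r2_6_on"]] * C1^2;    a4 <- r[["r2_6_off"]] * D6

  f1 <- 2 * k1a * D6 * S1;  f2 <- 2 * k3a * D6 * S3
  f3 <- k1a * D6S1 * S1;    f4 <- k3a * D6S1 * S3
  f5 <- k1a * D6S3 * S1;    f6 <- k3a * D6S3 * S3
  f7 <- k1a * D6P1 * S1;    f8 <- k3a * D6P1 * S3
  f9 <- k1a * D6P3 * S1;    f10 <- k3a * D6P3 * S3

  g1 <- k1o * D6S1;  g2 <- k3o * D6S3;  g3 <- k1o * D6P1;  g4 <- k3o * D6P3
  g5 <- 2 * k1o * S1D6S1; g6 <- k1o * P1D6S1; g7 <- k1o * P1D6S1
  g8 <- 2 * k1o * P1D6P1
  g9 <- 2 * k3o * S3D6S3; g10 <- k3o * P3D6S3; g11 <- k3o * P3D6S3
  g12 <- 2 * k3o * P3D6P3
  g13 <- k1o * S1D6S3; g14 <- k3o * S1D6S3
  g15 <- k1o * P1D6S3; g16 <- k3o * P1D6S3
  g17 <- k1o * S1D6P3; g18 <- k3o * S1D6P3
  g19 <- k1o * P1D6P3; g20 <- k3o * P1D6P3

  p1 <- q * D6S1; p2 <- q * D6S3
  p3 <- 2 * q * S1D6S1; p4 <- q * P1D6S1
  p5 <- 2 * q * S3D6S3; p6 <- q * P3D6S3
  p7 <- q * S1D6S3; p8 <- q * S1D6S3
  p9 <- q * P1D6S3; p10 <- q * S1D6P3

  h1 <- d1 * P1; h2 <- d3 * P3

  c(
    -a1 + a2,                                        # L6
    -a1 + a2 - b * R1,                               # R1
    a1 - a2 - 2 * a3 + 2 * a4 - b * C1,              # C1
    a3 - a4 - f1 - f2 + g1 + g2 + g3 + g4 - b * D6,  # D6
    -f1 - f3 - f5 - f7 - f9 + g1 + g5 + g7 + g13 + g17 + h1,  # S1
    -f2 - f4 - f6 - f8 - f10 + g2 + g9 + g11 + g14 + g16 + h2, # S3
    f1 - g1 - p1 - f3 - f4 + g5 + g6 + g14 + g18 - b * D6S1,
    f2 - g2 - p2 - f5 - f6 + g9 + g10 + g13 + g15 - b * D6S3,
    p1 - g3 - f7 - f8 + g7 + g8 + g16 + g20 - b * D6P1,
    p2 - g4 - f9 - f10 + g11 + g12 + g17 + g19 - b * D6P3,
    f3 - g5 - p3 - b * S1D6S1,
    f7 + p3 - g6 - g7 - p4 - b * P1D6S1,
    p4 - g8 - b * P1D6P1,
    f6 - g9 - p5 - b * S3D6S3,
    f10 + p5 - g10 - g11 - p6 - b * P3D6S3,
    p6 - g12 - b * P3D6P3,
    f4 + f5 - g13 - g14 - p7 - p8 - b * S1D6S3,
    f8 + p7 - g15 - g16 - p9 - b * P1D6S3,
    f9 + p8 - g17 - g18 - p10 - b * S1D6P3,
    p9 + p10 - g19 - g20 - b * P1D6P3,
    g3 + g6 + g8 + g15 + g19 - h1,                   # pS1
    g4 + g10 + g12 + g18 + g20 - h2                  # pS3
  )
}

# Brute-force generalized Euclidean distance over explicit loops.
distance_brute <- function(sim, data_summary) {
  tot <- 0
  for (i in seq_len(nrow(data_summary))) {
    row <- data_summary[i, ]
    v <- sim$value[sim$stat == row$stat & sim$time_min == row$time_min &
                     sim$cytokine == row$cytokine]
    tot <- tot + (v - row$mu)^2
  }
  sqrt(tot)
}

# Brute-force weighted quantile: walk the sorted sample accumulating
# normalized weight.
weighted_quantile_brute <- function(x, w, p) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  acc <- 0
  for (i in seq_along(x)) {
    acc <- acc + w[i]
    if (acc >= p - 1e-12) return(x[i])
  }
  x[length(x)]
}

# Conjugate-normal posterior for a known-variance Gaussian mean with a
# Normal(mu0, tau0^2) prior and n observations of mean ybar.
conjugate_posterior <- function(mu0, tau0, sigma, n, ybar) {
  prec <- 1 / tau0^2 + n / sigma^2
  list(mean = (mu0 / tau0^2 + n * ybar / sigma^2) / prec,
       sd = sqrt(1 / prec))
}

# One-parameter Gaussian-mean toy ABC model: the data summary is the
# sample mean, the distance its absolute deviation.
toy_gaussian_model <- function(ybar_obs, n, sigma, mu0 = 2, tau0 = 2,
                               name = "toy") {
  priors <- data.frame(name = "mu", family = "normal",
                       p1 = mu0, p2 = tau0)
  class(priors) <- c("statkin_priors", "data.frame")
  abc_model(name, priors, function(params) {
    ybar_sim <- mean(stats::rnorm(n, params[["mu"]], sigma))
    abs(ybar_sim - ybar_obs)
  })
}

# Small data-summary fixture for the RPE1 design, generated once per
# session from a fixed seed (noise-free variants built inline in tests).
rpe1_summary_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_dataset(seed = 11)
      cache <<- preprocess(ds)$summary
    }
    cache[cache$cell_type == "RPE1", ]
  }
})
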