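#' Prior specification for the model parameters
#'
#' Builds the default prior table for one internalization hypothesis.
#' Families:
#' \describe{
#'   \item{log10_normal}{\code{10^r} with \code{r ~ Normal(p1, p2)} (p2 a
#'     standard deviation)}
#'   \item{log10_uniform}{\code{10^r} with \code{r ~ Uniform(p1, p2)}}
#'   \item{normal_trunc0}{\code{Normal(p1, p2)} truncated below at 0}
#' }
#' Defaults: ligand-receptor rates are log10-normal centred on
#' surface-quantification estimates (\code{r1_6_on ~ 10^N(-3, 1.5)},
#' \code{r1_6_off ~ 10^N(-3.9, 1.96)}, \code{r1_27_on ~ 10^N(-2.34, 1.17)},
#' \code{r1_27_off ~ 10^N(-2.82, 1.41)}); dimerization rates
#' \code{10^U(-2, 3)} (on) and \code{10^U(-3, 1)} (off); STAT on rates
#' \code{10^U(-7, 1)}; STAT off rates \code{10^U(-2, 1)};
#' \code{q ~ 10^U(-3, 2)}; \code{d1, d3 ~ 10^U(-5, -2)}; internalization
#' \code{10^U(-5, -1)}; initial concentrations truncated normals
#' \code{R1_0 ~ N(12.7, 6.35)}, \code{R2_0 ~ N(33.8, 16.9)},
#' \code{S1_0 ~ N(300, 100)}, \code{S3_0 ~ N(400, 100)}.
#'
#' @param hypothesis "H1" (beta internalization rates) or "H2" (gamma).
#' @param params Optional character vector restricting the table to a
#'   subset of parameters (e.g. the cell-specific set of the second
#'   inference stage).
#' @return A \code{statkin_priors} data frame: \code{name}, \code{family},
#'   \code{p1}, \code{p2}.
#' @export
default_priors <- function(hypothesis = c("H1", "H2"), params = NULL) {
  hypothesis <- match.arg(hypothesis)
  ln <- function(name, p1, p2) data.frame(name = name, family = "log10_normal",
                                          p1 = p1, p2 = p2)
  lu <- function(name, p1, p2) data.frame(name = name, family = "log10_uniform",
                                          p1 = p1, p2 = p2)
  tn <- function(name, p1, p2) data.frame(name = name, family = "normal_trunc0",
                                          p1 = p1, p2 = p2)
  int_names <- if (hypothesis == "H1") c("beta6", "beta27") else
    c("gamma6", "gamma27")
  pr <- rbind(
    ln("r1_6_on", -3, 1.5), ln("r1_6_off", -3.9, 1.96),
    ln("r1_27_on", -2.34, 1.17), ln("r1_27_off", -2.82, 1.41),
    lu("r2_6_on", -2, 3), lu("r2_6_off", -3, 1),
    lu("r2_27_on", -2, 3), lu("r2_27_off", -3, 1),
    lu("k1a_on", -7, 1), lu("k1a_off", -2, 1),
    lu("k1b_on", -7, 1), lu("k1b_off", -2, 1),
    lu("k3a_on", -7, 1), lu("k3a_off", -2, 1),
    lu("k3b_on", -7, 1), lu("k3b_off", -2, 1),
    lu("q", -3, 2), lu("d1", -5, -2), lu("d3", -5, -2),
    lu(int_names[1], -5, -1), lu(int_names[2], -5, -1),
    tn("R1_0", 12.7, 6.35), tn("R2_0", 33.8, 16.9),
    tn("S1_0", 300, 100), tn("S3_0", 400, 100)
  )
  if (!is.null(params)) {
    miss <- setdiff(params, pr$name)
    if (length(miss)) stop("no prior defined for: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    pr <- pr[match(params, pr$name), ]
  }
  rownames(pr) <- NULL
  class(pr) <- c("statkin_priors", "data.frame")
  pr
}

## Parameters handled on the log10 scale (sampling, perturbation kernel,
## and importance weights all operate in this transformed space).
.is_log_family <- function(family) family %in% c("log10_normal",
                                                 "log10_uniform")

#' Sample parameter vectors from a prior specification
#'
#' @param priors A \code{statkin_priors} table.
#' @param n Number of draws.
#' @return Numeric matrix (n x parameters) on the natural scale, columns
#'   named by parameter.
#' @export
sample_prior <- function(priors, n = 1) {
  draws <- vapply(seq_len(nrow(priors)), function(i) {
    p <- priors[i, ]
    switch(p$family,
      log10_normal  = 10^stats::rnorm(n, p$p1, p$p2),
      log10_uniform = 10^stats::runif(n, p$p1, p$p2),
      normal        = stats::rnorm(n, p$p1, p$p2),
      normal_trunc0 = {
        x <- stats::rnorm(n, p$p1, p$p2)
        while (any(bad <- x < 0)) x[bad] <- stats::rnorm(sum(bad), p$p1, p$p2)
        x
      },
      stop("unknown prior family: ", p$family))
  }, numeric(n))
  if (n == 1) draws <- matrix(draws, nrow = 1)
  colnames(draws) <- priors$name
  draws
}

#' Prior density of a parameter vector
#'
#' Evaluated in the internal (transformed) parameterization: log10 scale
#' for the log-family parameters, natural scale for truncated-normal
#' concentrations.  This is the measure in which the ABC-SMC importance
#' weights and perturbation kernel operate.
#'
#' @param priors A \code{statkin_priors} table.
#' @param theta Named vector on the natural scale (or transformed scale
#'   with \code{transformed = TRUE}).
#' @param log Return the log density?
#' @param transformed Is \code{theta} already in the transformed space?
#' @return Scalar density (0 outside any support).
#' @export
prior_density <- function(priors, theta, log = FALSE, transformed = FALSE) {
  t_ <- if (transformed) theta[priors$name] else
    to_transformed(priors, theta[priors$name])
  ld <- .prior_logdens_fast(priors)(unname(unlist(t_)))
  if (log) ld else exp(ld)
}

## Vectorized log-density evaluator over the transformed parameterization;
## built once per prior table, cheap enough for the ABC proposal loop.
.prior_logdens_fast <- function(priors) {
  fam <- priors$family
  p1 <- priors$p1
  p2 <- priors$p2
  i_norm <- fam %in% c("log10_normal", "normal")
  i_unif <- fam == "log10_uniform"
  i_tn <- fam == "normal_trunc0"
  tn_corr <- sum(stats::pnorm(0, p1[i_tn], p2[i_tn], lower.tail = FALSE,
                              log.p = TRUE))
  function(x) {
    if (any(x[i_unif] < p1[i_unif] | x[i_unif] > p2[i_unif])) return(-Inf)
    if (any(x[i_tn] < 0)) return(-Inf)
    sum(stats::dnorm(x[i_norm], p1[i_norm], p2[i_norm], log = TRUE)) -
      sum(base::log(p2[i_unif] - p1[i_unif])) +
      sum(stats::dnorm(x[i_tn], p1[i_tn], p2[i_tn], log = TRUE)) - tn_corr
  }
}

#' @rdname prior_density
#' @export
to_transformed <- function(priors, theta) {
  out <- theta
  lg <- .is_log_family(priors$family)
  out[lg] <- log10(pmax(theta[lg], .Machine$double.xmin))
  out
}

#' @rdname prior_density
#' @export
from_transformed <- function(priors, theta_t) {
  out <- theta_t
  lg <- .is_log_family(priors$family)
  out[lg] <- 10^theta_t[lg]
  out
}
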