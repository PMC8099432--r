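#' Weighted quantiles of a sample
#'
#' Inverse of the left-continuous weighted empirical distribution
#' function: the smallest sample value whose cumulative normalized weight
#' reaches the probability.
#'
#' @param x Numeric sample.
#' @param w Non-negative weights (recycled if length 1).
#' @param probs Probabilities in \code{[0, 1]}.
#' @return Numeric vector of quantiles.
#' @export
weighted_quantile <- function(x, w = rep(1, length(x)), probs = 0.5) {
  if (length(w) == 1) w <- rep(w, length(x))
  stopifnot(length(x) == length(w), all(w >= 0))
  tot <- sum(w)
  if (tot <= 0) stop("zero total weight", call. = FALSE)
  o <- order(x)
  cw <- cumsum(w[o]) / tot
  vapply(probs, function(p) x[o][which(cw >= p - 1e-12)[1]], numeric(1))
}

.weighted_mean <- function(x, w) sum(x * w) / sum(w)

.weighted_cor <- function(X, w) {
  w <- w / sum(w)
  mu <- colSums(X * w)
  Xc <- sweep(X, 2, mu)
  cov <- crossprod(Xc * sqrt(w), Xc * sqrt(w))
  sd <- sqrt(diag(cov))
  out <- cov / tcrossprod(sd)
  out[!is.finite(out)] <- NA_real_
  out
}

#' Summarize a weighted posterior sample
#'
#' Weighted mean, median, and 2.5/97.5 percent quantiles per parameter,
#' plus the weighted pairwise correlation matrix.  Degenerate parameters
#' (zero weighted variance) yield zero-width intervals and \code{NA}
#' correlations.
#'
#' @param particles Data frame with one column per parameter and
#'   optionally a \code{weight} column (equal weights assumed otherwise);
#'   non-parameter bookkeeping columns (\code{model}, \code{distance},
#'   \code{particle_id}) are ignored.
#' @param params Optional character vector restricting which columns to
#'   summarize.
#' @return List with \code{summary} (data frame: parameter, mean, median,
#'   q2.5, q97.5) and \code{correlation} (matrix).
#' @export
summarize_posterior <- function(particles, params = NULL) {
  particles <- as.data.frame(particles)
  if (nrow(particles) == 0) stop("empty posterior sample", call. = FALSE)
  w <- if ("weight" %in% names(particles)) particles$weight else
    rep(1, nrow(particles))
  if (sum(w) <= 0) stop("zero total weight", call. = FALSE)
  drop_cols <- c("weight", "model", "distance", "particle_id", "iteration")
  if (is.null(params)) {
    params <- setdiff(names(particles)[vapply(particles, is.numeric,
                                              logical(1))], drop_cols)
  }
  X <- as.matrix(particles[params])
  summ <- do.call(rbind, lapply(params, function(nm) {
    qs <- weighted_quantile(X[, nm], w, c(0.025, 0.5, 0.975))
    data.frame(parameter = nm, mean = .weighted_mean(X[, nm], w),
               median = qs[2], q2.5 = qs[1], q97.5 = qs[3])
  }))
  rownames(summ) <- NULL
  list(summary = summ, correlation = .weighted_cor(X, w))
}
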