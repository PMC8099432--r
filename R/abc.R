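#' Build an ABC model object
#'
#' Bundles a prior specification with a simulator-distance function, the
#' unit the ABC engines operate on.  For hypothesis selection, supply one
#' model per hypothesis.
#'
#' @param name Model label (e.g. "H1").
#' @param priors A \code{statkin_priors} table for the parameters sampled
#'   by this model.
#' @param simulate_distance Function taking a named parameter vector on
#'   the natural scale and returning a non-negative distance
#'   (\code{Inf} marks a failed simulation).
#' @param shared Optional list with a \code{draw()} function returning a
#'   named vector of additional parameters resampled from an earlier
#'   posterior (used by the second inference stage); these are appended to
#'   every proposal but are not perturbed or weighted.
#' @return List of class \code{statkin_abc_model}.
#' @export
abc_model <- function(name, priors, simulate_distance, shared = NULL) {
  stopifnot(is.function(simulate_distance))
  structure(list(name = name, priors = priors,
                 simulate_distance = simulate_distance, shared = shared),
            class = "statkin_abc_model")
}

#' ABC-SMC configuration
#'
#' @param N Posterior sample size per iteration (across models).
#' @param delta_schedule Strictly decreasing acceptance thresholds; its
#'   length sets the number of iterations.  The reference schedule of the
#'   full-scale analysis is [default_delta_schedule()].  If \code{NULL},
#'   an adaptive schedule is used: iteration 1 keeps every finite-distance
#'   prior draw and each later threshold is the \code{quantile} of the
#'   previous iteration's accepted distances, for \code{M} iterations.
#' @param M Number of iterations when the schedule is adaptive.
#' @param quantile Quantile used by the adaptive schedule.
#' @param kernel_width_factor Uniform perturbation-kernel half-width
#'   multiplier (transformed scale): times the weighted standard
#'   deviation of the previous accepted population for
#'   \code{kernel_type = "sd"}, times the per-component range for
#'   \code{kernel_type = "range"}.
#' @param kernel_type "sd" (default; half-width
#'   \code{kernel_width_factor * sqrt(6)/2 * sd}, matching a kernel
#'   variance of twice the population variance at the default factor) or
#'   "range" (half-width \code{kernel_width_factor * (max - min)}).  The
#'   range rule mirrors the plain uniform-kernel prescription but in
#'   high-dimensional broad-prior settings it degenerates to prior-wide
#'   proposals; the sd rule tracks the concentrating population.
#' @param max_attempts_per_accept Attempt budget per accepted particle
#'   before the run aborts with an acceptance-rate diagnostic.
#' @param seed Integer seed.
#' @param verbose Emit a progress message per iteration?
#' @return List of class \code{statkin_smc_config}.
#' @export
smc_config <- function(N = 1e4, delta_schedule = default_delta_schedule(),
                       M = NULL, quantile = 0.5,
                       kernel_width_factor = NULL,
                       kernel_type = c("sd", "range"),
                       max_attempts_per_accept = 2000,
                       seed = 1L, verbose = FALSE) {
  kernel_type <- match.arg(kernel_type)
  if (is.null(kernel_width_factor)) {
    kernel_width_factor <- if (kernel_type == "sd") 1 else 0.5
  }
  if (!is.null(delta_schedule)) {
    if (any(diff(delta_schedule) >= 0)) {
      stop("delta schedule must be strictly decreasing", call. = FALSE)
    }
    M <- length(delta_schedule)
  } else if (is.null(M)) {
    stop("either delta_schedule or M must be given", call. = FALSE)
  }
  structure(list(N = N, delta_schedule = delta_schedule, M = M,
                 quantile = quantile,
                 kernel_width_factor = kernel_width_factor,
                 kernel_type = kernel_type,
                 max_attempts_per_accept = max_attempts_per_accept,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "statkin_smc_config")
}

#' Reference threshold schedule of the full-scale analysis
#'
#' @return The 15-element decreasing delta sequence
#'   \code{c(100, 10, 5, 3, 2.5, 2.25, 2, 1.75, 1.5, 1.25, 1.1, 1, 0.9,
#'   0.8, 0.7)}.
#' @export
default_delta_schedule <- function() {
  c(100, 10, 5, 3, 2.5, 2.25, 2, 1.75, 1.5, 1.25, 1.1, 1, 0.9, 0.8, 0.7)
}

.as_model_list <- function(models) {
  if (inherits(models, "statkin_abc_model")) models <- list(models)
  stopifnot(all(vapply(models, inherits, logical(1), "statkin_abc_model")))
  stats::setNames(models, vapply(models, `[[`, character(1), "name"))
}

.draw_full_params <- function(model, theta_t) {
  th <- from_transformed(model$priors, theta_t)
  names(th) <- model$priors$name
  shared <- if (!is.null(model$shared)) model$shared$draw() else NULL
  list(params = c(th, shared), shared = shared)
}

#' ABC rejection sampling
#'
#' Draws parameters from the prior of a model sampled uniformly among
#' \code{models}, simulates, and accepts particles whose distance falls
#' below \code{delta} until \code{N} are collected.
#'
#' @param models One [abc_model()] or a list of them.
#' @param delta Acceptance threshold (> 0; may be \code{Inf}, in which
#'   case the posterior is a prior sample excluding failed simulations).
#' @param N Number of accepted particles.
#' @param max_attempts_per_accept Attempt budget per accepted particle.
#' @return List with \code{particles} (data frame: \code{model},
#'   \code{weight}, \code{distance}, one column per parameter on the
#'   natural scale) and \code{acceptance_rate}.
#' @export
abc_rejection <- function(models, delta, N,
                          max_attempts_per_accept = 2000) {
  models <- .as_model_list(models)
  if (!(delta > 0)) stop("delta must be > 0", call. = FALSE)
  max_attempts <- max_attempts_per_accept * N
  accepted <- list()
  attempts <- 0L
  while (length(accepted) < N) {
    if (attempts >= max_attempts) {
      stop(sprintf(
        "acceptance rate below floor (%d accepted in %d attempts at delta = %g)",
        length(accepted), attempts, delta), call. = FALSE)
    }
    attempts <- attempts + 1L
    m <- models[[sample.int(length(models), 1)]]
    theta_t <- to_transformed(m$priors, drop(sample_prior(m$priors, 1)))
    full <- .draw_full_params(m, theta_t)
    d <- m$simulate_distance(full$params)
    if (is.finite(d) && d < delta) {
      accepted[[length(accepted) + 1L]] <- c(
        list(model = m$name, weight = 1, distance = d),
        as.list(full$params))
    }
  }
  particles <- do.call(rbind, lapply(accepted, function(x)
    as.data.frame(x, stringsAsFactors = FALSE)))
  list(particles = particles, acceptance_rate = N / attempts)
}

#' ABC sequential Monte Carlo with joint model selection
#'
#' Iteration 1 is rejection sampling at the first threshold with models
#' given equal weight.  At each later iteration, a model is sampled from
#' the previous iteration's model probabilities, a particle from that
#' model's weighted population, and its parameters are perturbed with a
#' component-wise uniform kernel (half-width a fixed fraction of the
#' previous population's per-component range, on the log10 scale for
#' log-scale parameters).  Accepted particles receive importance weights
#' prior / (sum of previous weights times kernel density); cross-model
#' moves are not made.  The per-iteration model probability is the
#' fraction of the N accepted particles carrying that model; a model with
#' no accepted particles is dropped from subsequent iterations.
#'
#' @param models One [abc_model()] or a list (e.g. H1 and H2).
#' @param config An [smc_config()].
#' @return List with \code{particles} (final weighted population),
#'   \code{model_probabilities} (data frame: iteration, model,
#'   probability), \code{history} (iteration, delta, acceptance_rate), and
#'   \code{final_probability} (named vector).
#' @export
abc_smc <- function(models, config) {
  stopifnot(inherits(config, "statkin_smc_config"))
  models <- .as_model_list(models)
  set.seed(config$seed)
  N <- config$N
  adaptive <- is.null(config$delta_schedule)
  M <- config$M

  pop <- NULL          # per-model list: theta_t matrix, w, d
  pdens <- lapply(models, function(m) .prior_logdens_fast(m$priors))
  probs <- stats::setNames(rep(1 / length(models), length(models)),
                           names(models))
  prob_rows <- list(); hist_rows <- list(); shared_store <- list()

  for (iter in seq_len(M)) {
    delta <- if (adaptive) {
      if (iter == 1) Inf else {
        prev_d <- unlist(lapply(pop, function(p) p$d))
        max(stats::quantile(prev_d, config$quantile, names = FALSE),
            .Machine$double.eps)
      }
    } else config$delta_schedule[iter]

    kernel <- NULL
    if (iter > 1) {
      kernel <- lapply(pop, function(p) {
        if (is.null(p)) return(NULL)
        hw <- if (config$kernel_type == "range") {
          config$kernel_width_factor *
            apply(p$theta_t, 2, function(col) diff(range(col)))
        } else {
          wn <- p$w / sum(p$w)
          mu <- colSums(p$theta_t * wn)
          sd <- sqrt(colSums(sweep(p$theta_t, 2, mu)^2 * wn))
          config$kernel_width_factor * sqrt(6) / 2 * sd
        }
        hw[hw <= 0 | !is.finite(hw)] <- 1e-8
        hw
      })
    }

    new_pop <- lapply(models, function(m) list(
      theta_t = NULL, w = numeric(), d = numeric(), shared = list()))
    n_acc <- 0L; attempts <- 0L; n_sims <- 0L
    max_attempts <- config$max_attempts_per_accept * N
    alive <- names(models)[probs[names(models)] > 0]

    while (n_acc < N) {
      if (attempts >= max_attempts) {
        stop(sprintf(
          "acceptance rate below floor at iteration %d (delta = %g, %d/%d)",
          iter, delta, n_acc, attempts), call. = FALSE)
      }
      attempts <- attempts + 1L
      mk <- if (length(alive) == 1) alive else
        sample(alive, 1, prob = probs[alive])
      m <- models[[mk]]
      if (iter == 1) {
        theta_t <- to_transformed(m$priors, drop(sample_prior(m$priors, 1)))
        w_raw <- 1
      } else {
        p <- pop[[mk]]
        j <- sample.int(length(p$w), 1, prob = p$w)
        hw <- kernel[[mk]]
        theta_t <- p$theta_t[j, ] + stats::runif(length(hw), -hw, hw)
        names(theta_t) <- m$priors$name
        ld <- pdens[[mk]](unname(theta_t))
        if (!is.finite(ld)) next
        inbox <- rowSums(abs(sweep(p$theta_t, 2, theta_t)) >
                           rep(hw, each = nrow(p$theta_t))) == 0
        sw <- sum(p$w[inbox])
        if (sw <= 0) next
        ## kernel density is constant 1/prod(2 hw) inside the box; work in
        ## logs to dodge under/overflow in high dimension
        w_raw <- exp(ld - base::log(sw) + sum(base::log(2 * hw)))
      }
      full <- .draw_full_params(m, theta_t)
      n_sims <- n_sims + 1L
      d <- m$simulate_distance(full$params)
      if (is.finite(d) && d < delta) {
        np <- new_pop[[mk]]
        np$theta_t <- rbind(np$theta_t, theta_t)
        np$w <- c(np$w, w_raw)
        np$d <- c(np$d, d)
        np$shared <- c(np$shared, list(full$shared))
        new_pop[[mk]] <- np
        n_acc <- n_acc + 1L
      }
    }

    counts <- vapply(new_pop, function(p) length(p$w), integer(1))
    probs <- counts / N
    for (mk in names(new_pop)) {
      if (counts[mk] > 0) {
        new_pop[[mk]]$w <- new_pop[[mk]]$w / sum(new_pop[[mk]]$w)
        colnames(new_pop[[mk]]$theta_t) <- models[[mk]]$priors$name
      } else {
        new_pop[mk] <- list(NULL)
        if (counts[mk] == 0 && probs[mk] == 0) {
          message("model ", mk, " dropped at iteration ", iter,
                  " (no accepted particles)")
        }
      }
    }
    pop <- new_pop
    if (config$verbose) {
      message(sprintf(
        "iteration %d: delta = %.4g, accepted %d in %d attempts, %d sims (%s)",
        iter, delta, N, attempts, n_sims,
        paste(names(counts), counts, sep = "=", collapse = ", ")))
    }
    prob_rows[[iter]] <- data.frame(iteration = iter,
                                    model = names(counts),
                                    probability = unname(counts) / N)
    hist_rows[[iter]] <- data.frame(iteration = iter, delta = delta,
                                    acceptance_rate = N / attempts)
  }

  particles <- .rbind_fill(lapply(names(pop), function(mk) {
    p <- pop[[mk]]
    if (is.null(p)) return(NULL)
    df <- as.data.frame(from_transformed_matrix(models[[mk]]$priors,
                                                p$theta_t))
    if (length(p$shared) && !is.null(p$shared[[1]])) {
      df <- cbind(df, do.call(rbind, lapply(p$shared, function(s)
        as.data.frame(as.list(s)))))
    }
    cbind(data.frame(model = mk, weight = p$w / probs_weight_scale(pop, mk),
                     distance = p$d), df)
  }))
  rownames(particles) <- NULL
  list(particles = particles,
       model_probabilities = do.call(rbind, prob_rows),
       history = do.call(rbind, hist_rows),
       final_probability = probs)
}

## weights are normalized within each model; keep helper explicit
probs_weight_scale <- function(pop, mk) 1

## rbind data frames with non-identical columns (missing filled with NA),
## e.g. H1 (beta) and H2 (gamma) particle tables
.rbind_fill <- function(dfs) {
  dfs <- Filter(Negate(is.null), dfs)
  if (!length(dfs)) return(NULL)
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (nm in setdiff(cols, names(d))) d[[nm]] <- NA_real_
    d[cols]
  }))
}

from_transformed_matrix <- function(priors, theta_t) {
  out <- theta_t
  lg <- .is_log_family(priors$family)
  out[, lg] <- 10^theta_t[, lg, drop = FALSE]
  out
}
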