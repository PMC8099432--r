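#' Simulate a receptor variant
#'
#' Runs the chimera (IL-27-style assembly with two GP130-type STAT sites)
#' or Y613F (wild-type IL-27 topology with the STAT1/IL-27Ralpha rates
#' fixed at \code{k1b_on = 1e-5} nM^-1 s^-1, \code{k1b_off = 10} s^-1)
#' model and returns the total pSTAT observables.
#'
#' @param variant "CHIMERA" or "Y613F".
#' @param rates A [kinetic_rates()] vector.
#' @param init An [initial_conditions()] object (IL-27 dose in \code{L_0}).
#' @param grid Time grid in minutes.
#' @param hypothesis "H1" or "H2".
#' @return Data frame from [observable_series()].
#' @export
simulate_variant <- function(variant = c("CHIMERA", "Y613F"), rates, init,
                             grid = default_time_grid(), hypothesis = "H1") {
  variant <- match.arg(variant)
  spec <- model_spec("IL27", variant, hypothesis)
  observable_series(integrate_model(spec, rates, init, grid))
}

#' Dose-response of a model at a fixed readout time
#'
#' Simulates one model across a dose grid for each supplied parameter set
#' and reads the total pSTAT observables at the readout time.  The default
#' grid is 18 log-spaced doses spanning 1e-4 to 1e2 nM; the default
#' readout time is 15 minutes, matching the experimental dose-response
#' protocol.
#'
#' @param spec A [model_spec()].
#' @param particles Data frame of parameter sets, one row per particle,
#'   with rate columns plus \code{R1_0}, \code{R2_0}, \code{S1_0},
#'   \code{S3_0}; a single [kinetic_rates()] vector is also accepted when
#'   accompanied by \code{init}.
#' @param doses Positive dose grid (nM).
#' @param readout_time Readout time in minutes (must lie on the grid used).
#' @param init Baseline initial concentrations used when \code{particles}
#'   has no concentration columns.
#' @return Tidy data frame: \code{particle_id}, \code{dose}, \code{stat},
#'   \code{value} (total pSTAT in nM at the readout time).
#' @export
dose_response <- function(spec, particles,
                          doses = default_dose_grid(),
                          readout_time = 15,
                          init = baseline_init()) {
  if (any(doses <= 0)) stop("doses must be > 0", call. = FALSE)
  pt <- .as_particle_table(particles, init)
  if (nrow(pt) == 0) stop("empty particle set", call. = FALSE)
  grid <- sort(unique(c(default_time_grid(), readout_time)))
  out <- list()
  for (p in seq_len(nrow(pt))) {
    pars <- .particle_row(pt, p)
    for (d in doses) {
      tr <- .try_integrate(spec, pars$rates,
                           .particle_init(pars, d, spec), grid)
      if (is.null(tr)) next
      i <- match(readout_time, grid)
      out[[length(out) + 1L]] <- data.frame(
        particle_id = p, dose = d, stat = c(1, 3),
        value = c(total_pstat(tr, 1)[i], total_pstat(tr, 3)[i]))
    }
  }
  do.call(rbind, out)
}

#' Default dose grid for dose-response simulations
#'
#' @return 18 log-spaced doses between 1e-4 and 1e2 nM.
#' @export
default_dose_grid <- function() 10^seq(-4, 2, length.out = 18)

#' Receptor/STAT abundance scan across posterior particles
#'
#' Simulates both cytokine models for every parameter set with the
#' baseline initial abundances (GP130 25 nM, IL-27Ralpha 50 nM,
#' STAT1 = STAT3 = 500 nM) after applying the requested overrides, and
#' summarizes the pSTAT time courses as pointwise weighted medians with
#' 95 percent credible bands.
#'
#' @param particles Data frame of parameter sets (optionally with a
#'   \code{weight} column).
#' @param overrides Named list overriding any of \code{R1_0}, \code{R2_0},
#'   \code{S1_0}, \code{S3_0} (nM, non-negative).
#' @param doses Named vector \code{c(IL27 = , HYPIL6 = )} in nM.
#' @param base Baseline abundances, a named vector
#'   \code{(R1_0, R2_0, S1_0, S3_0)}.
#' @param hypothesis "H1" or "H2".
#' @param grid Time grid in minutes.
#' @return Tidy data frame: \code{cytokine}, \code{stat}, \code{time_min},
#'   \code{lo} (2.5 percent), \code{median}, \code{hi} (97.5 percent) of
#'   total pSTAT (nM) across particles.
#' @export
concentration_scan <- function(particles, overrides = list(),
                               doses = default_doses()$RPE1,
                               base = c(R1_0 = 25, R2_0 = 50,
                                        S1_0 = 500, S3_0 = 500),
                               hypothesis = "H1",
                               grid = default_time_grid()) {
  bad <- setdiff(names(overrides), names(base))
  if (length(bad)) stop("unknown override(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  for (nm in names(overrides)) {
    if (overrides[[nm]] < 0) stop("negative override for ", nm, call. = FALSE)
    base[[nm]] <- overrides[[nm]]
  }
  pt <- .as_particle_table(particles, NULL)
  w <- if ("weight" %in% names(pt)) pt$weight else rep(1, nrow(pt))
  specs <- list(HYPIL6 = model_spec("HYPIL6", hypothesis = hypothesis),
                IL27 = model_spec("IL27", hypothesis = hypothesis))
  out <- list()
  for (cy in names(specs)) {
    vals1 <- matrix(NA_real_, nrow(pt), length(grid))
    vals3 <- matrix(NA_real_, nrow(pt), length(grid))
    for (p in seq_len(nrow(pt))) {
      pars <- .particle_row(pt, p)
      ini <- initial_conditions(R1_0 = base[["R1_0"]], R2_0 = base[["R2_0"]],
                                S1_0 = base[["S1_0"]], S3_0 = base[["S3_0"]],
                                L_0 = doses[[cy]])
      tr <- .try_integrate(specs[[cy]], pars$rates, ini, grid)
      if (is.null(tr)) next
      vals1[p, ] <- total_pstat(tr, 1)
      vals3[p, ] <- total_pstat(tr, 3)
    }
    for (stat in c(1, 3)) {
      vals <- if (stat == 1) vals1 else vals3
      ok <- stats::complete.cases(vals)
      qs <- apply(vals[ok, , drop = FALSE], 2, function(col)
        weighted_quantile(col, w[ok], c(0.025, 0.5, 0.975)))
      out[[length(out) + 1L]] <- data.frame(
        cytokine = cy, stat = stat, time_min = grid,
        lo = qs[1, ], median = qs[2, ], hi = qs[3, ])
    }
  }
  do.call(rbind, out)
}

## ---- particle-table helpers ------------------------------------------

.as_particle_table <- function(particles, init) {
  if (inherits(particles, "statkin_rates") ||
      (is.numeric(particles) && !is.null(names(particles)))) {
    pt <- as.data.frame(as.list(unlist(particles)))
    if (!is.null(init)) {
      for (nm in c("R1_0", "R2_0", "S1_0", "S3_0")) {
        if (is.null(pt[[nm]])) pt[[nm]] <- init[[nm]]
      }
    }
    return(pt)
  }
  as.data.frame(particles)
}

.particle_row <- function(pt, p) {
  row <- as.list(pt[p, , drop = FALSE])
  have <- intersect(.rate_names, names(row))
  base <- default_true_rates()
  base[have] <- unlist(row[have])
  list(rates = kinetic_rates(base = base), row = row)
}

.particle_init <- function(pars, dose, spec) {
  row <- pars$row
  g <- function(nm, def) if (!is.null(row[[nm]])) row[[nm]] else def
  initial_conditions(R1_0 = g("R1_0", 25), R2_0 = g("R2_0", 50),
                     S1_0 = g("S1_0", 500), S3_0 = g("S3_0", 500),
                     L_0 = dose)
}
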