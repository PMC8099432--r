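#' Default experimental time grid
#'
#' The sampling times of the phospho-flow time courses, in minutes.
#'
#' @return Numeric vector \code{c(0, 5, 15, 30, 60, 90, 120, 180)}.
#' @export
default_time_grid <- function() c(0, 5, 15, 30, 60, 90, 120, 180)

.check_grid <- function(grid) {
  if (length(grid) < 2 || grid[1] != 0 || any(diff(grid) <= 0)) {
    stop("time grid must start at 0 and be strictly increasing (minutes)",
         call. = FALSE)
  }
  grid
}

#' Integrate a receptor-STAT model
#'
#' Solves the mass-action ODE system from the given initial conditions over
#' a time grid in minutes (internally the models run in seconds, matching
#' the s^-1 rate units) with a stiff-capable solver.
#'
#' @param spec A [model_spec()].
#' @param rates A [kinetic_rates()] vector; receptor-variant overrides are
#'   applied automatically.
#' @param init An [initial_conditions()] object.
#' @param grid Time grid in minutes (strictly increasing, starting at 0).
#' @param rtol,atol Relative and absolute solver tolerances (nM).
#' @return A \code{statkin_traj}: list with \code{time_min}, the state
#'   matrix \code{state} (time points x species, columns named by the
#'   registry), and the \code{spec}.
#' @examples
#' tr <- integrate_model(model_spec("HYPIL6"), kinetic_rates(),
#'                       initial_conditions(R1_0 = 25, S1_0 = 500,
#'                                          S3_0 = 500, L_0 = 10))
#' total_pstat(tr, 1)
#' @export
integrate_model <- function(spec, rates, init, grid = default_time_grid(),
                            rtol = 1e-8, atol = 1e-10, maxsteps = 50000) {
  .check_grid(grid)
  rates <- apply_variant_rates(spec, rates)
  net <- build_network(spec, rates)
  y0 <- initial_state(spec, init)
  times <- grid * 60
  out <- deSolve::ode(
    y = y0, times = times, parms = encode_network_parms(net),
    func = "statkin_derivs", initfunc = "statkin_initmod",
    dllname = "statkin", method = "lsoda",
    rtol = rtol, atol = atol, maxsteps = maxsteps
  )
  if (!is.matrix(out) || nrow(out) < length(times) || anyNA(out)) {
    stop("simulation failure: integrator did not complete", call. = FALSE)
  }
  state <- out[, -1, drop = FALSE]
  if (min(state) < -1e-6) {
    stop("simulation failure: negative concentrations beyond tolerance",
         call. = FALSE)
  }
  structure(list(time_min = grid, state = state, spec = spec),
            class = "statkin_traj")
}

## Inference-facing wrapper: any integration failure becomes NULL, which
## the ABC distance maps to +Inf.  Fails fast on pathological (extremely
## stiff) parameter draws and swallows the solver's console diagnostics.
.try_integrate <- function(..., maxsteps = 5000) {
  out <- NULL
  utils::capture.output({
    out <- tryCatch(suppressWarnings(integrate_model(..., maxsteps = maxsteps)),
                    error = function(e) NULL)
  })
  out
}

#' Total phosphorylated STAT along a trajectory
#'
#' The multiplicity-weighted sum of every species containing pSTATi (free
#' or receptor bound): a dimer with two bound pSTAT1 contributes twice its
#' concentration.  This is the model output compared against the
#' phospho-flow measurements.
#'
#' @param traj A trajectory from [integrate_model()].
#' @param stat 1 or 3.
#' @return Numeric series (nM), one value per grid time.
#' @export
total_pstat <- function(traj, stat) {
  stopifnot(inherits(traj, "statkin_traj"), stat %in% c(1, 3))
  reg <- build_registry(traj$spec)
  w <- if (stat == 1) reg$pS1 else reg$pS3
  as.vector(traj$state %*% w)
}

#' Observable time series of a trajectory
#'
#' @param traj A trajectory from [integrate_model()].
#' @return Data frame with \code{time_min}, \code{pSTAT1}, \code{pSTAT3}
#'   (total concentrations, nM).
#' @export
observable_series <- function(traj) {
  data.frame(time_min = traj$time_min,
             pSTAT1 = total_pstat(traj, 1),
             pSTAT3 = total_pstat(traj, 3))
}

#' Normalize a model output series by its IL-27 reference
#'
#' Model outputs are made dimensionless by dividing through the IL-27
#' simulation's value at the reference time point (default 30 min), the
#' same normalization applied to the fluorescence data.  The IL-27 series
#' normalized by itself therefore passes through 1 at the reference time;
#' a HypIL-6 series is divided by the matching IL-27 reference
#' (cross-model, same STAT and parameter set).
#'
#' @param series Numeric series aligned to \code{grid}, or a trajectory
#'   observable column.
#' @param reference The IL-27 series for the same STAT and parameter set.
#' @param grid Time grid in minutes for both series.
#' @param ref_time Reference time point (minutes, default 30).
#' @return Dimensionless numeric series.
#' @export
normalize_sim <- function(series, reference = series,
                          grid = default_time_grid(), ref_time = 30) {
  i <- match(ref_time, grid)
  if (is.na(i)) stop("ref_time not on the time grid", call. = FALSE)
  refval <- reference[i]
  if (!is.finite(refval) || refval <= 0) {
    stop("normalization error: non-positive IL-27 reference value",
         call. = FALSE)
  }
  series / refval
}
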