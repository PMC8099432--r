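#' Distance between normalized model output and the data summary
#'
#' A generalized Euclidean distance: the square root of the sum of squared
#' differences between the normalized simulated values and the
#' replicate-mean data values over every (STAT, time point, cytokine) cell
#' of one cell type — 2 STATs x 8 time points x 2 cytokines = 32 cells on
#' the default design.
#'
#' @param sim Data frame with columns \code{stat}, \code{time_min},
#'   \code{cytokine}, \code{value} (normalized model output).
#' @param data_summary Summary table with columns \code{stat},
#'   \code{time_min}, \code{cytokine}, \code{mu} (from [preprocess()],
#'   already restricted to one cell type).
#' @return Non-negative scalar; \code{Inf} if any simulated value is
#'   non-finite (the simulation-failure sentinel).
#' @export
distance_summary <- function(sim, data_summary) {
  m <- merge(data_summary, sim, by = c("stat", "time_min", "cytokine"))
  if (nrow(m) != nrow(data_summary)) {
    stop("simulation output does not cover every summary cell",
         call. = FALSE)
  }
  if (any(!is.finite(m$value))) return(Inf)
  sqrt(sum((m$value - m$mu)^2))
}
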