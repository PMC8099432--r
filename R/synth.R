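#' Fluorescence noise model for the synthetic-data generator
#'
#' Synthetic mean-fluorescence intensities are built as
#' \code{intensity = (a + c * t) + kappa * pSTAT_total(t) * (1 + eps)}
#' with \code{eps ~ Normal(0, sigma^2)}, truncated at zero.  The linear
#' term emulates the slowly drifting background fluorescence of the
#' phospho-antibodies in unstimulated cells; the multiplicative noise
#' emulates the intensity-proportional variability of flow-cytometry MFI.
#'
#' @param kappa Signal gain (a.u. per nM), > 0.
#' @param a Background intercept (a.u.).
#' @param c Background slope (a.u. per minute).
#' @param sigma Multiplicative noise standard deviation, >= 0.
#' @return Named list of class \code{statkin_noise}.
#' @export
noise_model <- function(kappa = 100, a = 200, c = 0.5, sigma = 0.05) {
  if (!is.finite(kappa) || kappa <= 0) stop("kappa must be > 0", call. = FALSE)
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  structure(list(kappa = kappa, a = a, c = c, sigma = sigma),
            class = "statkin_noise")
}

#' Generate a replicate-level synthetic fluorescence dataset
#'
#' Emulates the study design: for each cell type, 4 replicates x
#' 2 STAT antibodies x 8 time points x 3 treatments (HypIL-6, IL-27,
#' unstimulated) = 192 records.  Stimulated intensities follow the noise
#' model applied to the model's total pSTAT time course under the shared
#' true rates and cell-specific initial concentrations; unstimulated
#' series carry the linear background only.
#'
#' @param true_rates A [kinetic_rates()] vector (the generator truth).
#' @param init_by_celltype Named list of \code{(R1_0, R2_0, S1_0, S3_0)}
#'   vectors per cell type, as [default_celltype_init()].
#' @param doses Named list of per-cell-type dose vectors, as
#'   [default_doses()].
#' @param noise A [noise_model()].
#' @param hypothesis Internalization hypothesis generating the data.
#' @param replicates Replicate identifiers.
#' @param grid Time grid in minutes.
#' @param seed Integer seed; fixed seed gives identical datasets.
#' @return A \code{statkin_dataset}: data frame with columns
#'   \code{cell_type}, \code{cytokine} (incl. \code{"UNSTIM"}),
#'   \code{stat}, \code{replicate}, \code{time_min}, \code{intensity},
#'   with the generating parameters and seed in attributes.
#' @export
generate_dataset <- function(true_rates = kinetic_rates(),
                             init_by_celltype = default_celltype_init(),
                             doses = default_doses(),
                             noise = noise_model(),
                             hypothesis = "H1",
                             replicates = 1:4,
                             grid = default_time_grid(),
                             seed = 1L) {
  stopifnot(inherits(noise, "statkin_noise"))
  set.seed(as.integer(seed))
  recs <- list()
  for (ct in names(init_by_celltype)) {
    ini <- init_by_celltype[[ct]]
    totals <- list()
    for (cy in c("HYPIL6", "IL27")) {
      spec <- model_spec(cy, hypothesis = hypothesis)
      init <- initial_conditions(R1_0 = ini[["R1_0"]], R2_0 = ini[["R2_0"]],
                                 S1_0 = ini[["S1_0"]], S3_0 = ini[["S3_0"]],
                                 L_0 = doses[[ct]][[cy]])
      tr <- integrate_model(spec, true_rates, init, grid)
      totals[[cy]] <- list(`1` = total_pstat(tr, 1), `3` = total_pstat(tr, 3))
    }
    bg <- noise$a + noise$c * grid
    for (r in replicates) {
      for (stat in c(1, 3)) {
        for (cy in c("HYPIL6", "IL27", "UNSTIM")) {
          signal <- if (cy == "UNSTIM") numeric(length(grid)) else
            totals[[cy]][[as.character(stat)]]
          eps <- stats::rnorm(length(grid), 0, noise$sigma)
          intensity <- pmax(bg + noise$kappa * signal * (1 + eps), 0)
          recs[[length(recs) + 1L]] <- data.frame(
            cell_type = ct, cytokine = cy, stat = stat, replicate = r,
            time_min = grid, intensity = intensity)
        }
      }
    }
  }
  ds <- do.call(rbind, recs)
  rownames(ds) <- NULL
  attr(ds, "true_rates") <- true_rates
  attr(ds, "init_by_celltype") <- init_by_celltype
  attr(ds, "doses") <- doses
  attr(ds, "noise") <- noise
  attr(ds, "hypothesis") <- hypothesis
  attr(ds, "seed") <- as.integer(seed)
  class(ds) <- c("statkin_dataset", "data.frame")
  ds
}

#' Fit the linear background-fluorescence model
#'
#' Ordinary least squares of unstimulated intensity against time, fit per
#' (STAT antibody, cell type) with replicates pooled.
#'
#' @param unstim Data frame of unstimulated records with \code{time_min}
#'   and \code{intensity}.
#' @return Named vector \code{c(intercept, slope)}.
#' @export
fit_background <- function(unstim) {
  if (length(unique(unstim$time_min)) < 2) {
    stop("background fit needs >= 2 distinct time points", call. = FALSE)
  }
  co <- stats::coef(stats::lm(intensity ~ time_min, data = unstim))
  c(intercept = unname(co[1]), slope = unname(co[2]))
}

#' Preprocess a fluorescence dataset
#'
#' Applies the study's preprocessing: (1) fit the linear background model
#' on unstimulated cells per (STAT, cell type) and subtract its value at
#' each time point from the stimulated intensities; (2) divide every
#' background-subtracted record by the same replicate/STAT/cell-type's
#' IL-27 value at the reference time point (default 30 min), making the
#' data dimensionless with the IL-27 reference at 1; (3) average the
#' replicates into the summary table used by the inference distance.
#' Replicates whose IL-27 reference is non-positive after background
#' subtraction are excluded with a warning.
#'
#' @param raw A \code{statkin_dataset} (or compatible data frame).
#' @param ref_time Reference time point in minutes (default 30; 15 is the
#'   robustness-check alternative).
#' @return List with \code{normalized} (record-level data frame adding
#'   \code{background} and \code{normalized}) and \code{summary} (the
#'   replicate-mean table: \code{cell_type}, \code{cytokine}, \code{stat},
#'   \code{time_min}, \code{mu}).
#' @export
preprocess <- function(raw, ref_time = 30) {
  raw <- as.data.frame(raw)
  need <- c("cell_type", "cytokine", "stat", "replicate", "time_min",
            "intensity")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  stim <- raw[raw$cytokine != "UNSTIM", ]
  out <- list()
  for (ct in unique(stim$cell_type)) {
    for (stat in unique(stim$stat)) {
      un <- raw[raw$cytokine == "UNSTIM" & raw$cell_type == ct &
                  raw$stat == stat, ]
      if (nrow(un) == 0) stop("no unstimulated records for cell_type ", ct,
                              ", stat ", stat, call. = FALSE)
      bg <- fit_background(un)
      sub <- stim[stim$cell_type == ct & stim$stat == stat, ]
      sub$background <- bg["intercept"] + bg["slope"] * sub$time_min
      sub$corrected <- sub$intensity - sub$background
      sub$normalized <- NA_real_
      for (r in unique(sub$replicate)) {
        sel <- sub$replicate == r
        refval <- sub$corrected[sel & sub$cytokine == "IL27" &
                                  sub$time_min == ref_time]
        if (length(refval) != 1) {
          stop("preprocessing requires exactly one IL-27 record at the ",
               "reference time per replicate/stat/cell type", call. = FALSE)
        }
        if (!is.finite(refval) || refval <= 0) {
          warning("excluding replicate ", r, " (", ct, ", STAT", stat,
                  "): non-positive IL-27 reference after background ",
                  "subtraction", call. = FALSE)
          sub <- sub[!sel, ]
          next
        }
        sub$normalized[sel] <- sub$corrected[sel] / refval
      }
      if (nrow(sub)) out[[length(out) + 1L]] <- sub
    }
  }
  if (!length(out)) {
    stop("no replicates remain after reference-value exclusions",
         call. = FALSE)
  }
  normalized <- do.call(rbind, out)
  normalized$corrected <- NULL
  rownames(normalized) <- NULL
  agg <- stats::aggregate(normalized ~ cell_type + cytokine + stat + time_min,
                          data = normalized, FUN = replicate_mean)
  names(agg)[names(agg) == "normalized"] <- "mu"
  agg <- agg[order(agg$cell_type, agg$cytokine, agg$stat, agg$time_min), ]
  rownames(agg) <- NULL
  list(normalized = normalized, summary = agg)
}

#' Replicate mean
#'
#' Arithmetic mean of the per-replicate normalized values entering the
#' summary table.
#'
#' @param values Non-empty numeric vector.
#' @return Scalar mean.
#' @export
replicate_mean <- function(values) {
  if (length(values) == 0) stop("empty replicate set", call. = FALSE)
  sum(values) / length(values)
}
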