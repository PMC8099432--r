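## Wiring between the receptor-STAT simulators and the generic ABC engine.

#' Normalized model output for one parameter set and cell type
#'
#' Simulates both cytokine models with a shared parameter vector and the
#' given doses, and returns the four normalized time courses (2 STATs x
#' 2 cytokines) in the layout of the preprocessing summary table.  Both
#' cytokines' outputs for a STAT are divided by the IL-27 simulation's
#' value at the reference time, mirroring the data normalization.
#'
#' @param params Named parameter vector on the natural scale (rates plus
#'   \code{R1_0}, \code{R2_0}, \code{S1_0}, \code{S3_0}).
#' @param doses Named vector \code{c(IL27 = , HYPIL6 = )} (nM).
#' @param hypothesis "H1" or "H2".
#' @param grid Time grid (minutes).
#' @param ref_time Normalization reference time (minutes).
#' @return Data frame \code{stat}, \code{time_min}, \code{cytokine},
#'   \code{value}; \code{NULL} if either simulation fails or the IL-27
#'   reference is non-positive.
#' @export
simulate_normalized <- function(params, doses, hypothesis = "H1",
                                grid = default_time_grid(), ref_time = 30) {
  base <- default_true_rates()
  have <- intersect(.rate_names, names(params))
  base[have] <- params[have]
  rates <- kinetic_rates(base = base)
  out <- list()
  il27 <- list()
  for (cy in c("IL27", "HYPIL6")) {
    spec <- model_spec(cy, hypothesis = hypothesis)
    init <- initial_conditions(R1_0 = params[["R1_0"]],
                               R2_0 = if (cy == "IL27") params[["R2_0"]] else 0,
                               S1_0 = params[["S1_0"]],
                               S3_0 = params[["S3_0"]],
                               L_0 = doses[[cy]])
    tr <- .try_integrate(spec, rates, init, grid)
    if (is.null(tr)) return(NULL)
    for (stat in c(1, 3)) {
      tot <- total_pstat(tr, stat)
      key <- paste(cy, stat)
      out[[key]] <- data.frame(stat = stat, time_min = grid, cytokine = cy,
                               value = tot)
      if (cy == "IL27") il27[[as.character(stat)]] <- tot
    }
  }
  iref <- match(ref_time, grid)
  for (key in names(out)) {
    refval <- il27[[as.character(out[[key]]$stat[1])]][iref]
    if (!is.finite(refval) || refval <= 0) return(NULL)
    out[[key]]$value <- out[[key]]$value / refval
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build the ABC model for one internalization hypothesis
#'
#' @param hypothesis "H1" or "H2".
#' @param data_summary Summary table for one cell type (columns
#'   \code{stat}, \code{time_min}, \code{cytokine}, \code{mu}).
#' @param doses Named dose vector \code{c(IL27 = , HYPIL6 = )}.
#' @param ref_time Normalization reference time (minutes).
#' @param priors Prior table; defaults to the full Table of priors for the
#'   hypothesis.
#' @param shared Optional shared-parameter sampler (see [abc_model()]).
#' @param rtol,atol Solver tolerances used inside the inference loop.  The
#'   defaults are looser than [integrate_model()]'s because the distance
#'   resolution is limited by the measurement noise, not the integrator.
#' @return An [abc_model()].
#' @export
cytokine_abc_model <- function(hypothesis, data_summary,
                               doses = default_doses()$RPE1,
                               ref_time = 30,
                               priors = default_priors(hypothesis),
                               shared = NULL, rtol = 1e-6, atol = 1e-8) {
  grid <- sort(unique(data_summary$time_min))
  data_summary <- data_summary[order(data_summary$cytokine,
                                     data_summary$stat,
                                     data_summary$time_min), ]
  ## fixed cell order: (cytokine, stat, time); precompute everything the
  ## per-particle simulation needs so the hot loop stays lean
  mu <- data_summary$mu
  key <- paste(data_summary$cytokine, data_summary$stat)
  iref <- match(ref_time, grid)
  specs <- list(HYPIL6 = model_spec("HYPIL6", hypothesis = hypothesis),
                IL27 = model_spec("IL27", hypothesis = hypothesis))
  w_pstat <- lapply(specs, function(s) {
    reg <- build_registry(s)
    list(`1` = reg$pS1, `3` = reg$pS3)
  })
  base_rates <- default_true_rates()
  simfun <- function(params) {
    rates <- base_rates
    have <- intersect(.rate_names, names(params))
    rates[have] <- params[have]
    sim <- numeric(length(mu))
    refs <- list()
    for (cy in c("IL27", "HYPIL6")) {
      init <- c(R1_0 = params[["R1_0"]],
                R2_0 = if (cy == "IL27") params[["R2_0"]] else 0,
                S1_0 = params[["S1_0"]], S3_0 = params[["S3_0"]],
                L_0 = doses[[cy]])
      tr <- .try_integrate(specs[[cy]], rates, init, grid,
                           rtol = rtol, atol = atol)
      if (is.null(tr)) return(Inf)
      for (stat in c("1", "3")) {
        tot <- as.vector(tr$state %*% w_pstat[[cy]][[stat]])
        if (cy == "IL27") {
          refs[[stat]] <- tot[iref]
          if (!is.finite(tot[iref]) || tot[iref] <= 0) return(Inf)
        }
        sim[key == paste(cy, stat)] <- tot / refs[[stat]]
      }
    }
    if (any(!is.finite(sim))) return(Inf)
    sqrt(sum((sim - mu)^2))
  }
  abc_model(hypothesis, priors, simfun, shared = shared)
}

#' Joint hypothesis selection and parameter inference for one cell type
#'
#' Runs ABC-SMC with one model per hypothesis against the preprocessed
#' summary of one cell type.
#'
#' @param data_summary Summary table restricted to one cell type.
#' @param doses Named dose vector for that cell type.
#' @param hypotheses Hypotheses to compare.
#' @param config An [smc_config()].
#' @param ref_time Normalization reference time (minutes).
#' @return The [abc_smc()] result.
#' @export
fit_celltype <- function(data_summary, doses = default_doses()$RPE1,
                         hypotheses = c("H1", "H2"),
                         config = smc_config(), ref_time = 30) {
  models <- lapply(hypotheses, cytokine_abc_model,
                   data_summary = data_summary, doses = doses,
                   ref_time = ref_time)
  abc_smc(models, config)
}

## Parameters expected to differ between cell types (one hypothesis):
## initial concentrations, phosphorylation, dephosphorylation and
## internalization rates.
.cell_specific_params <- function(hypothesis = "H1") {
  int <- if (hypothesis == "H1") c("beta6", "beta27") else
    c("gamma6", "gamma27")
  c("q", "d1", "d3", int, "R1_0", "R2_0", "S1_0", "S3_0")
}

#' Two-stage inference across cell types
#'
#' Stage 1 fits all parameters of one hypothesis to the first cell type's
#' data.  Stage 2 fits only the cell-specific parameters (initial
#' concentrations, q, d1, d3, and the internalization rates — nine
#' parameters) to the second cell type, while the shared STAT/receptor
#' binding and assembly rates are resampled jointly (particle-wise, to
#' preserve their correlations) from the stage-1 weighted posterior.
#'
#' @param data_stage1,data_stage2 Summary tables (one cell type each).
#' @param doses_stage1,doses_stage2 Dose vectors for the two cell types.
#' @param hypothesis Hypothesis carried through both stages.
#' @param config An [smc_config()] used for both stages.
#' @param ref_time Normalization reference time (minutes).
#' @return List with \code{stage1} and \code{stage2} [abc_smc()] results
#'   and \code{shared_params} (the names resampled from stage 1).
#' @export
staged_inference <- function(data_stage1, data_stage2,
                             doses_stage1 = default_doses()$RPE1,
                             doses_stage2 = default_doses()$TH1,
                             hypothesis = "H1",
                             config = smc_config(), ref_time = 30) {
  m1 <- cytokine_abc_model(hypothesis, data_stage1, doses_stage1, ref_time)
  stage1 <- abc_smc(list(m1), config)
  p1 <- stage1$particles
  if (is.null(p1) || nrow(p1) == 0) stop("empty stage-1 posterior",
                                         call. = FALSE)
  cs <- .cell_specific_params(hypothesis)
  shared_names <- setdiff(default_priors(hypothesis)$name, cs)
  shared_draw <- function() {
    j <- sample.int(nrow(p1), 1, prob = p1$weight)
    unlist(p1[j, shared_names])
  }
  m2 <- cytokine_abc_model(
    hypothesis, data_stage2, doses_stage2, ref_time,
    priors = default_priors(hypothesis, params = cs),
    shared = list(draw = shared_draw))
  stage2 <- abc_smc(list(m2), config)
  list(stage1 = stage1, stage2 = stage2, shared_params = shared_names)
}
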