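.timecourse_cols <- c("cell_type", "cytokine", "stat", "replicate",
                      "time_min", "intensity")

#' Read and write replicate-level fluorescence time courses
#'
#' Tidy long-format CSV with columns \code{cell_type}, \code{cytokine},
#' \code{stat}, \code{replicate}, \code{time_min}, \code{intensity}.
#' Numeric values are written as decimal text with 12 significant digits,
#' so a write/read cycle is the identity at that precision and repeated
#' writes are byte-identical.
#'
#' @param path CSV file path.
#' @return \code{read_timecourse_csv}: the dataset as a data frame.
#' @export
read_timecourse_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.timecourse_cols, names(df))
  if (length(miss)) {
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(df$intensity) || anyNA(df$intensity)) {
    stop("non-numeric intensity values in ", path, call. = FALSE)
  }
  if (!is.numeric(df$time_min)) stop("non-numeric time_min in ", path,
                                     call. = FALSE)
  key <- df[, c("replicate", "stat", "time_min", "cytokine", "cell_type")]
  if (anyDuplicated(key)) {
    stop("duplicate (replicate, stat, time, cytokine, cell_type) keys in ",
         path, call. = FALSE)
  }
  df[.timecourse_cols]
}

#' @param dataset Data frame with the time-course columns.
#' @rdname read_timecourse_csv
#' @export
write_timecourse_csv <- function(dataset, path) {
  df <- as.data.frame(dataset)[.timecourse_cols]
  df$time_min <- formatC(df$time_min, format = "g", digits = 12)
  df$intensity <- formatC(df$intensity, format = "g", digits = 12)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write and read posterior particle tables
#'
#' CSV persistence for [abc_smc()] particle populations: columns
#' \code{particle_id}, \code{model}, \code{weight}, \code{distance}, then
#' one column per parameter.
#'
#' @param particles Particle data frame.
#' @param path CSV file path.
#' @export
write_posterior_csv <- function(particles, path) {
  df <- as.data.frame(particles)
  df <- cbind(particle_id = seq_len(nrow(df)), df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, format = "g", digits = 12))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_posterior_csv
#' @export
read_posterior_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Serialize rates or priors to a structured config file
#'
#' YAML config keyed by the published parameter symbols (for example
#' \code{"k1a+"} for \code{k1a_on}, \code{"r2,27-"} for \code{r2_27_off}),
#' keeping the mapping between code and model notation auditable.
#'
#' @param rates A [kinetic_rates()] vector (optionally with initial
#'   concentrations appended).
#' @param path Output file.
#' @export
write_rates_config <- function(rates, path) {
  v <- unlist(rates)
  keys <- .rate_symbols[names(v)]
  yaml::write_yaml(stats::setNames(as.list(unname(v)), keys), path,
                   precision = 12)
  invisible(path)
}

#' @rdname write_rates_config
#' @export
read_rates_config <- function(path) {
  lst <- yaml::read_yaml(path)
  inv <- stats::setNames(names(.rate_symbols), .rate_symbols)
  nm <- inv[names(lst)]
  if (anyNA(nm)) stop("unknown parameter symbol(s) in ", path, ": ",
                      paste(names(lst)[is.na(nm)], collapse = ", "),
                      call. = FALSE)
  stats::setNames(unlist(lst), nm)
}

#' Run the full synthetic-study pipeline
#'
#' Orchestrates generate -> preprocess -> hypothesis selection/fit ->
#' posterior summary -> predictions with a single seed, writing every
#' product (dataset, normalized data, posterior, model probabilities,
#' scan predictions, manifest) as CSV/JSON-free text under \code{out_dir}.
#' All randomness derives from \code{seed}; rerunning with the same
#' config is reproducible.
#'
#' @param config List with optional elements \code{seed}, \code{out_dir},
#'   \code{N}, \code{M}, \code{hypotheses}, \code{cell_type},
#'   \code{noise}, \code{true_rates}, \code{ref_time},
#'   \code{delta_schedule} (NULL for adaptive), \code{scan_overrides}.
#' @return The run manifest (list), invisibly written as
#'   \code{manifest.yaml}.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- utils::modifyList(list(
    seed = 1L, out_dir = "statkin_run", N = 200, M = 4,
    hypotheses = c("H1", "H2"), cell_type = "RPE1",
    true_rates = kinetic_rates(), noise = noise_model(),
    ref_time = 30, delta_schedule = NULL,
    scan_overrides = list(R1_0 = 2.5)), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  stage_times <- c()

  tick <- function(name, expr) {
    s <- Sys.time()
    val <- force(expr)
    stage_times[[name]] <<- as.numeric(difftime(Sys.time(), s, units = "secs"))
    val
  }

  ds <- tick("synth", generate_dataset(true_rates = cfg$true_rates,
                                       noise = cfg$noise, seed = cfg$seed))
  write_timecourse_csv(ds, file.path(cfg$out_dir, "dataset.csv"))

  prep <- tick("preprocess", preprocess(ds, ref_time = cfg$ref_time))
  utils::write.csv(prep$summary, file.path(cfg$out_dir, "summary.csv"),
                   row.names = FALSE)

  summ <- prep$summary[prep$summary$cell_type == cfg$cell_type, ]
  sc <- smc_config(N = cfg$N, M = cfg$M, delta_schedule = cfg$delta_schedule,
                   seed = cfg$seed + 1L)
  fit <- tick("fit", fit_celltype(summ, doses = default_doses()[[cfg$cell_type]],
                                  hypotheses = cfg$hypotheses, config = sc,
                                  ref_time = cfg$ref_time))
  write_posterior_csv(fit$particles,
                      file.path(cfg$out_dir, "posterior.csv"))
  utils::write.csv(fit$model_probabilities,
                   file.path(cfg$out_dir, "model_probabilities.csv"),
                   row.names = FALSE)

  best <- names(which.max(fit$final_probability))
  post <- fit$particles[fit$particles$model == best, ]
  summary_tab <- tick("summarize", summarize_posterior(post))
  utils::write.csv(summary_tab$summary,
                   file.path(cfg$out_dir, "posterior_summary.csv"),
                   row.names = FALSE)

  scan <- tick("predict", {
    set.seed(cfg$seed + 2L)
    idx <- sample.int(nrow(post), min(nrow(post), 50), prob = post$weight,
                      replace = TRUE)
    rbind(cbind(scenario = "baseline",
                concentration_scan(post[idx, ], list(),
                                   hypothesis = best)),
          cbind(scenario = "override",
                concentration_scan(post[idx, ], cfg$scan_overrides,
                                   hypothesis = best)))
  })
  utils::write.csv(scan, file.path(cfg$out_dir, "predictions.csv"),
                   row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("statkin")),
    seed = cfg$seed,
    n_particles = cfg$N, n_iterations = sc$M,
    selected_model = best,
    final_probability = as.list(fit$final_probability),
    acceptance_rates = fit$history$acceptance_rate,
    stage_runtime_sec = as.list(round(unlist(stage_times), 3)),
    total_runtime_sec = round(as.numeric(difftime(Sys.time(), t0,
                                                  units = "secs")), 3))
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))
  invisible(manifest)
}
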