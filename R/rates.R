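## Internal parameter names, their published symbols, and units.  The
## symbol map is used when serializing rates/priors to config files so the
## keys match the notation of the model description tables.
.rate_symbols <- c(
  r1_6_on  = "r1,6+",  r1_6_off  = "r1,6-",
  r1_27_on = "r1,27+", r1_27_off = "r1,27-",
  r2_6_on  = "r2,6+",  r2_6_off  = "r2,6-",
  r2_27_on = "r2,27+", r2_27_off = "r2,27-",
  k1a_on = "k1a+", k1a_off = "k1a-",
  k1b_on = "k1b+", k1b_off = "k1b-",
  k3a_on = "k3a+", k3a_off = "k3a-",
  k3b_on = "k3b+", k3b_off = "k3b-",
  q = "q", d1 = "d1", d3 = "d3",
  beta6 = "beta6", beta27 = "beta27",
  gamma6 = "gamma6", gamma27 = "gamma27",
  R1_0 = "R1(0)", R2_0 = "R2(0)", S1_0 = "S1(0)", S3_0 = "S3(0)"
)

.rate_names <- setdiff(names(.rate_symbols),
                       c("R1_0", "R2_0", "S1_0", "S3_0"))
.init_names <- c("R1_0", "R2_0", "S1_0", "S3_0")

#' Kinetic rate constants for the receptor-STAT models
#'
#' Constructs and validates the full named set of mass-action rate
#' constants shared by the HypIL-6 and IL-27 models:
#' \describe{
#'   \item{r1_6_on, r1_27_on}{ligand-receptor binding (nM^-1 s^-1); HypIL-6
#'     binds GP130, IL-27 binds IL-27Ralpha}
#'   \item{r1_6_off, r1_27_off}{ligand-receptor dissociation (s^-1)}
#'   \item{r2_6_on, r2_27_on}{dimer formation (nM^-1 s^-1): C1 + C1 for
#'     HypIL-6, C2 + R1 for IL-27}
#'   \item{r2_6_off, r2_27_off}{dimer dissociation (s^-1)}
#'   \item{k1a_on, k1a_off, k3a_on, k3a_off}{STAT1/STAT3 binding to and
#'     dissociation from a GP130 chain in a dimer (nM^-1 s^-1, s^-1)}
#'   \item{k1b_on, k1b_off, k3b_on, k3b_off}{STAT1/STAT3 binding to and
#'     dissociation from the IL-27Ralpha chain (nM^-1 s^-1, s^-1)}
#'   \item{q}{phosphorylation of any dimer-bound STAT (s^-1); independent of
#'     STAT type and receptor chain}
#'   \item{d1, d3}{dephosphorylation of free cytoplasmic pSTAT1/pSTAT3
#'     (s^-1)}
#'   \item{beta6, beta27}{hypothesis-1 internalization of receptor species
#'     (s^-1)}
#'   \item{gamma6, gamma27}{hypothesis-2 internalization (nM^-1 s^-1),
#'     multiplied by free pSTAT1 + pSTAT3}
#' }
#' Phosphorylated and unphosphorylated STATs dissociate with the same off
#' rate (no allostery), and only unphosphorylated STATs bind.
#'
#' @param ... Named rate values overriding the supplied \code{base}.
#' @param base Named numeric vector/list of all 24 rates to start from.
#' @return Named numeric vector of class \code{statkin_rates}.
#' @seealso [default_true_rates()] for the reference parameterization used
#'   by the synthetic-data generator.
#' @export
kinetic_rates <- function(..., base = default_true_rates()) {
  r <- unlist(base)[.rate_names]
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), .rate_names)
    if (length(bad)) stop("unknown rate name(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    r[names(dots)] <- unlist(dots)
  }
  if (anyNA(r)) stop("missing rate value(s): ",
                     paste(.rate_names[is.na(r)], collapse = ", "), call. = FALSE)
  if (any(r < 0)) stop("all kinetic rates must be >= 0", call. = FALSE)
  structure(r, class = "statkin_rates")
}

#' Reference kinetic rates of the synthetic study
#'
#' The fixed "ground truth" parameterization used by
#' [generate_dataset()].  Values sit inside the prior supports and
#' reproduce the qualitative kinetics the models were built to explain:
#' STAT1 binds the IL-27Ralpha chain ten-fold faster than GP130
#' (\code{k1b_on/k1a_on = 10}) while STAT3 prefers GP130 ten-fold
#' (\code{k3a_on/k3b_on = 10}), giving sustained IL-27 pSTAT1 and transient
#' HypIL-6 pSTAT1; HypIL-6 receptor complexes internalize faster than
#' IL-27's.
#'
#' @return Named numeric vector of all 24 rate constants.
#' @export
default_true_rates <- function() {
  c(r1_6_on  = 1e-3,    r1_6_off  = 10^-3.9,
    r1_27_on = 10^-2.34, r1_27_off = 10^-2.82,
    r2_6_on  = 1,       r2_6_off  = 0.1,
    r2_27_on = 1,       r2_27_off = 0.1,
    k1a_on = 1e-4, k1a_off = 0.1,
    k1b_on = 1e-3, k1b_off = 0.1,
    k3a_on = 1e-3, k3a_off = 0.1,
    k3b_on = 1e-4, k3b_off = 0.1,
    q = 1, d1 = 1e-3, d3 = 1e-3,
    beta6 = 5e-4, beta27 = 1e-4,
    gamma6 = 1e-5, gamma27 = 1e-5)
}

#' Initial molecular concentrations
#'
#' @param R1_0 GP130 (nM).
#' @param R2_0 IL-27Ralpha (nM); unused (may be 0) for HypIL-6.
#' @param S1_0,S3_0 STAT1 and STAT3 (nM).
#' @param L_0 Ligand dose (nM).
#' @return Named numeric vector of class \code{statkin_init}.
#' @export
initial_conditions <- function(R1_0, R2_0 = 0, S1_0, S3_0, L_0) {
  v <- c(R1_0 = R1_0, R2_0 = R2_0, S1_0 = S1_0, S3_0 = S3_0, L_0 = L_0)
  if (anyNA(v) || any(v < 0)) {
    stop("initial concentrations must be non-negative numbers", call. = FALSE)
  }
  structure(v, class = "statkin_init")
}

#' Baseline initial concentrations for model predictions
#'
#' The baseline receptor/STAT abundances used for prediction experiments
#' (approximately the posterior medians of the calibrated models):
#' GP130 25 nM, IL-27Ralpha 50 nM, STAT1 = STAT3 = 500 nM.
#'
#' @param L_0 Ligand dose (nM).
#' @return A [initial_conditions()] object.
#' @export
baseline_init <- function(L_0 = 2) {
  initial_conditions(R1_0 = 25, R2_0 = 50, S1_0 = 500, S3_0 = 500, L_0 = L_0)
}

#' Default saturating cytokine doses per cell type
#'
#' Fitting doses of the study design: RPE1 cells were stimulated with 2 nM
#' IL-27 and 10 nM HypIL-6, Th-1 cells with 2 nM IL-27 and 20 nM HypIL-6.
#'
#' @return Named list with elements \code{RPE1} and \code{TH1}, each a
#'   named vector \code{c(IL27 = , HYPIL6 = )} in nM.
#' @export
default_doses <- function() {
  list(RPE1 = c(IL27 = 2, HYPIL6 = 10),
       TH1  = c(IL27 = 2, HYPIL6 = 20))
}

#' Cell-type initial concentrations used by the synthetic-data generator
#'
#' RPE1 uses the baseline abundances; Th-1 emulates a T cell with low
#' GP130, abundant IL-27Ralpha and somewhat higher STAT levels.
#'
#' @return Named list of named vectors \code{(R1_0, R2_0, S1_0, S3_0)} in nM.
#' @export
default_celltype_init <- function() {
  list(RPE1 = c(R1_0 = 25, R2_0 = 50, S1_0 = 500, S3_0 = 500),
       TH1  = c(R1_0 = 5,  R2_0 = 80, S1_0 = 700, S3_0 = 600))
}

#' Apply receptor-variant rate overrides
#'
#' For the Y613F mutant of IL-27Ralpha the STAT1 association/dissociation
#' rates at the mutated chain are fixed to \code{k1b_on = 1e-5} nM^-1 s^-1
#' and \code{k1b_off = 10} s^-1 (a strong reduction of the STAT1 on-rate at
#' a dissociation rate near the posterior median); other variants pass
#' through unchanged.
#'
#' @param spec A [model_spec()].
#' @param rates A [kinetic_rates()] vector.
#' @return Possibly modified rates vector.
#' @export
apply_variant_rates <- function(spec, rates) {
  if (spec$receptor_variant == "Y613F") {
    rates[["k1b_on"]] <- 1e-5
    rates[["k1b_off"]] <- 10
  }
  rates
}
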