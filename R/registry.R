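#' Define a receptor signalling model variant
#'
#' A model specification selects one of the receptor-ligand systems
#' (HypIL-6 homodimerizing GP130, or IL-27 heterodimerizing IL-27Ralpha
#' and GP130), a receptor variant, and an internalization hypothesis.
#'
#' Under hypothesis \code{"H1"} every receptor-containing species is
#' internalized/degraded at a first-order rate (\code{beta6} or
#' \code{beta27}).  Under hypothesis \code{"H2"} the internalization rate is
#' additionally proportional to the sum of free cytoplasmic pSTAT1 and
#' pSTAT3 (\code{gamma6}/\code{gamma27}), an implicit negative feedback.
#'
#' The \code{"CHIMERA"} variant models a receptor with the IL-27Ralpha
#' ectodomain and the GP130 cytoplasmic domain: the dimer assembles like
#' IL-27's (ligand binds IL-27Ralpha, then recruits GP130) but carries two
#' equivalent GP130-type STAT docking sites.  The \code{"Y613F"} variant
#' keeps the wild-type IL-27 topology; it is realised purely by overriding
#' the STAT1/IL-27Ralpha binding rates (see [apply_variant_rates()]).
#'
#' @param cytokine "HYPIL6" or "IL27".
#' @param receptor_variant "WT", "CHIMERA" or "Y613F" (the latter two are
#'   only valid for IL-27).
#' @param hypothesis "H1" or "H2".
#' @return An object of class \code{statkin_spec}.
#' @examples
#' model_spec("HYPIL6")
#' model_spec("IL27", "CHIMERA")
#' @export
model_spec <- function(cytokine = c("HYPIL6", "IL27"),
                       receptor_variant = c("WT", "CHIMERA", "Y613F"),
                       hypothesis = c("H1", "H2")) {
  cytokine <- match.arg(cytokine)
  receptor_variant <- match.arg(receptor_variant)
  hypothesis <- match.arg(hypothesis)
  if (cytokine == "HYPIL6" && receptor_variant != "WT") {
    stop("receptor variant '", receptor_variant,
         "' is only defined for cytokine = 'IL27'", call. = FALSE)
  }
  structure(
    list(cytokine = cytokine,
         receptor_variant = receptor_variant,
         hypothesis = hypothesis),
    class = "statkin_spec"
  )
}

#' @export
print.statkin_spec <- function(x, ...) {
  cat("<statkin model spec> cytokine:", x$cytokine,
      " variant:", x$receptor_variant,
      " hypothesis:", x$hypothesis, "\n")
  invisible(x)
}

## Occupant codes for dimer STAT sites: "E" empty, "S1"/"S3" unphosphorylated,
## "P1"/"P3" phosphorylated STAT1/STAT3.
.occ_label <- c(E = "", S1 = "S1", S3 = "S3", P1 = "pS1", P3 = "pS3")

## Canonical unordered pair ordering used in the species enumeration of the
## homodimer-style models: STAT1 forms before STAT3 forms, and within a type
## the phosphorylated form first (pS1.D6.S1, not S1.D6.pS1).
.pair_rank <- c(P1 = 1, S1 = 2, P3 = 3, S3 = 4)

.canon_pair <- function(a, b) {
  if (.pair_rank[[a]] <= .pair_rank[[b]]) c(a, b) else c(b, a)
}

## Display order of unordered pairs follows the published species list.
.homodimer_pairs <- list(
  c("E", "S1"), c("E", "S3"), c("E", "P1"), c("E", "P3"),
  c("S1", "S1"), c("P1", "S1"), c("P1", "P1"),
  c("S3", "S3"), c("P3", "S3"), c("P3", "P3"),
  c("S1", "S3"), c("P1", "S3"), c("S1", "P3"), c("P1", "P3")
)

## Ordered (R1 site, R2 site) occupants of the IL-27 heterodimer, following
## the published species list: four single occupancies via R1, four via R2,
## then doubles.
.heterodimer_pairs <- list(
  c("S1", "E"), c("S3", "E"), c("P1", "E"), c("P3", "E"),
  c("E", "S1"), c("E", "S3"), c("E", "P1"), c("E", "P3"),
  c("S1", "S1"), c("P1", "S1"), c("S1", "P1"), c("P1", "P1"),
  c("S3", "S3"), c("P3", "S3"), c("S3", "P3"), c("P3", "P3"),
  c("S1", "S3"), c("S3", "S1"), c("P1", "S3"), c("S3", "P1"),
  c("S1", "P3"), c("P3", "S1"), c("P1", "P3"), c("P3", "P1")
)

.dimer_species_name <- function(core, left, right) {
  l <- .occ_label[[left]]
  r <- .occ_label[[right]]
  if (l == "" && r == "") return(core)
  if (l == "") return(paste0(core, ".", r))
  if (r == "") return(paste0(l, ".", core))
  paste0(l, ".", core, ".", r)
}

## Homodimer naming collapses (E, X) to "D6.X" and orders pairs canonically.
.homodimer_species_name <- function(core, a, b) {
  if (a == "E" && b == "E") return(core)
  if (a == "E") return(paste0(core, ".", .occ_label[[b]]))
  if (b == "E") return(paste0(core, ".", .occ_label[[a]]))
  p <- .canon_pair(a, b)
  paste0(.occ_label[[p[1]]], ".", core, ".", .occ_label[[p[2]]])
}

.occ_moieties <- function(occ) {
  m <- c(S1 = 0, S3 = 0, pS1 = 0, pS3 = 0)
  switch(occ,
         E = NULL,
         S1 = { m["S1"] <- 1 },
         S3 = { m["S3"] <- 1 },
         P1 = { m["pS1"] <- 1 },
         P3 = { m["pS3"] <- 1 })
  m
}

.species_row <- function(name, R1 = 0, R2 = 0, L = 0,
                         S1 = 0, S3 = 0, pS1 = 0, pS3 = 0,
                         receptor = FALSE) {
  data.frame(name = name, R1 = R1, R2 = R2, L = L,
             S1 = S1, S3 = S3, pS1 = pS1, pS3 = pS3,
             receptor = receptor, stringsAsFactors = FALSE)
}

.dimer_row <- function(name, core_moieties, a, b) {
  ma <- .occ_moieties(a)
  mb <- .occ_moieties(b)
  .species_row(name,
               R1 = core_moieties["R1"], R2 = core_moieties["R2"],
               L = core_moieties["L"],
               S1 = ma["S1"] + mb["S1"], S3 = ma["S3"] + mb["S3"],
               pS1 = ma["pS1"] + mb["pS1"], pS3 = ma["pS3"] + mb["pS3"],
               receptor = TRUE)
}

#' Build the ordered species registry for a model variant
#'
#' Every model variant maps to a fixed, ordered list of molecular species
#' with per-species moiety multiplicities: the number of GP130 chains (R1),
#' IL-27Ralpha chains (R2), ligand copies, and unphosphorylated/
#' phosphorylated STAT1 and STAT3 copies it contains, plus a flag marking
#' receptor-containing species (the ones subject to internalization).
#'
#' Registry sizes: 22 species for HypIL-6, 33 for wild-type IL-27 (and
#' Y613F, which shares the topology), 23 for the chimera.
#'
#' @param spec A [model_spec()].
#' @return A \code{statkin_registry}: a data frame with columns
#'   \code{name}, moiety multiplicities \code{R1, R2, L, S1, S3, pS1, pS3},
#'   and logical \code{receptor}.
#' @examples
#' nrow(build_registry(model_spec("HYPIL6")))  # 22
#' nrow(build_registry(model_spec("IL27")))    # 33
#' @export
build_registry <- function(spec) {
  stopifnot(inherits(spec, "statkin_spec"))
  key <- paste(spec$cytokine, spec$receptor_variant, sep = "_")
  cached <- .statkin_cache[[key]]
  if (!is.null(cached)) return(cached)

  rows <- list()
  if (spec$cytokine == "HYPIL6") {
    core <- c(R1 = 2, R2 = 0, L = 2)
    rows <- c(rows, list(
      .species_row("L6", L = 1),
      .species_row("R1", R1 = 1, receptor = TRUE),
      .species_row("C1", R1 = 1, L = 1, receptor = TRUE),
      .species_row("D6", R1 = 2, L = 2, receptor = TRUE),
      .species_row("S1", S1 = 1),
      .species_row("S3", S3 = 1)
    ))
    for (p in .homodimer_pairs) {
      nm <- .homodimer_species_name("D6", p[1], p[2])
      rows <- c(rows, list(.dimer_row(nm, core, p[1], p[2])))
    }
    rows <- c(rows, list(.species_row("pS1", pS1 = 1),
                         .species_row("pS3", pS3 = 1)))
  } else if (spec$receptor_variant == "CHIMERA") {
    ## IL-27-style assembly, HypIL-6-style (two equivalent GP130-type
    ## sites) STAT handling on the heterodimer.
    core <- c(R1 = 1, R2 = 1, L = 1)
    rows <- c(rows, list(
      .species_row("L27", L = 1),
      .species_row("R1", R1 = 1, receptor = TRUE),
      .species_row("R2", R2 = 1, receptor = TRUE),
      .species_row("C2", R2 = 1, L = 1, receptor = TRUE),
      .species_row("D27", R1 = 1, R2 = 1, L = 1, receptor = TRUE),
      .species_row("S1", S1 = 1),
      .species_row("S3", S3 = 1)
    ))
    for (p in .homodimer_pairs) {
      nm <- .homodimer_species_name("D27", p[1], p[2])
      rows <- c(rows, list(.dimer_row(nm, core, p[1], p[2])))
    }
    rows <- c(rows, list(.species_row("pS1", pS1 = 1),
                         .species_row("pS3", pS3 = 1)))
  } else {
    ## Wild-type IL-27 (and Y613F, same topology): the two dimer sites are
    ## distinct (left occupant via GP130, right occupant via IL-27Ralpha).
    core <- c(R1 = 1, R2 = 1, L = 1)
    rows <- c(rows, list(
      .species_row("L27", L = 1),
      .species_row("R1", R1 = 1, receptor = TRUE),
      .species_row("R2", R2 = 1, receptor = TRUE),
      .species_row("C2", R2 = 1, L = 1, receptor = TRUE),
      .species_row("D27", R1 = 1, R2 = 1, L = 1, receptor = TRUE),
      .species_row("S1", S1 = 1),
      .species_row("S3", S3 = 1)
    ))
    for (p in .heterodimer_pairs) {
      nm <- .dimer_species_name("D27", p[1], p[2])
      rows <- c(rows, list(.dimer_row(nm, core, p[1], p[2])))
    }
    rows <- c(rows, list(.species_row("pS1", pS1 = 1),
                         .species_row("pS3", pS3 = 1)))
  }

  reg <- do.call(rbind, rows)
  rownames(reg) <- NULL
  class(reg) <- c("statkin_registry", "data.frame")
  .statkin_cache[[key]] <- reg
  reg
}

## per-session cache of registries and reaction templates
.statkin_cache <- new.env(parent = emptyenv())

#' Moiety totals of a state vector
#'
#' Multiplicity-weighted totals of the five conserved moieties.  Each total
#' counts every copy of the moiety in every species: the HypIL-6 dimer D6
#' contributes twice its concentration to both the GP130 and ligand totals,
#' a doubly-STAT1-loaded dimer contributes twice to the STAT1 total, and
#' STAT totals count phosphorylated and unphosphorylated copies alike.
#' With internalization switched off every total is constant along a
#' trajectory.
#'
#' @param spec A [model_spec()].
#' @param state Numeric state vector aligned to the registry order (nM).
#' @return Named numeric vector with elements \code{STAT1}, \code{STAT3},
#'   \code{GP130}, \code{IL27Ra}, \code{ligand} (nM).
#' @export
conserved_totals <- function(spec, state) {
  reg <- build_registry(spec)
  if (length(state) != nrow(reg)) {
    stop("state length ", length(state), " does not match registry size ",
         nrow(reg), call. = FALSE)
  }
  c(STAT1  = sum((reg$S1 + reg$pS1) * state),
    STAT3  = sum((reg$S3 + reg$pS3) * state),
    GP130  = sum(reg$R1 * state),
    IL27Ra = sum(reg$R2 * state),
    ligand = sum(reg$L * state))
}

#' Map initial conditions into a registry-aligned state vector
#'
#' @param spec A [model_spec()].
#' @param init An [initial_conditions()] object (or named list/vector with
#'   \code{L_0}, \code{R1_0}, \code{R2_0}, \code{S1_0}, \code{S3_0}).
#' @return Numeric state vector (nM) aligned to the registry, with free
#'   ligand, receptors, and STATs at their initial values and all complexes
#'   at zero.
#' @export
initial_state <- function(spec, init) {
  reg <- build_registry(spec)
  y <- stats::setNames(numeric(nrow(reg)), reg$name)
  lig <- if (spec$cytokine == "HYPIL6") "L6" else "L27"
  y[lig] <- init[["L_0"]]
  y["R1"] <- init[["R1_0"]]
  if ("R2" %in% reg$name) y["R2"] <- init[["R2_0"]]
  y["S1"] <- init[["S1_0"]]
  y["S3"] <- init[["S3_0"]]
  y
}
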