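# statkin

Mechanistic models and likelihood-free inference of STAT1/STAT3
signalling kinetics at IL-6 and IL-27 receptors.

IL-6 (modelled through the IL-6Rα-independent agonist HypIL-6) and IL-27
both signal through GP130 and activate STAT1 and STAT3, yet IL-27 drives
sustained STAT1 phosphorylation while IL-6's is transient. `statkin` is
for systems biologists who want to work with explicit mass-action models
of these first signalling steps: ligand capture, receptor dimerization
(GP130 homodimers for HypIL-6; IL-27Rα/GP130 heterodimers for IL-27),
competitive STAT docking, phosphorylation, receptor internalization and
pSTAT dephosphorylation — 22 coupled ODEs for HypIL-6 and 33 for IL-27,
plus chimeric and Y613F receptor variants.

At its core are:

* **Model selection between internalization mechanisms.** H1: receptor
  species are internalized at a first-order rate β_j. H2: the rate is
  γ_j·([pS1] + [pS3]), an implicit negative feedback. Selection and
  calibration run jointly by ABC-SMC (sequential Monte Carlo around
  rejection-ABC), with the per-iteration model probability
  P_ik = (accepted particles from model k)/N.
* **The study's data pipeline on synthetic data.** A generator emulates
  the phospho-flow design (4 replicates × 2 STATs × 8 time points ×
  2 cytokines + unstimulated × 2 cell types) with linear background
  fluorescence and multiplicative noise; preprocessing fits and
  subtracts the background, normalizes each replicate by its IL-27
  value at 30 min, and averages replicates. The fit minimises the
  Euclidean distance over the 32 normalized (STAT, time, cytokine)
  cells, δ² = Σ_i Σ_tp Σ_j [sim − μ_data]².
* **Predictions.** Dose–response over 18 log-spaced doses (1e-4–1e2 nM),
  receptor/STAT abundance scans from the baseline GP130 25 nM,
  IL-27Rα 50 nM, STAT1 = STAT3 = 500 nM, and receptor-variant
  simulations, all with pointwise credible bands across posterior
  particles.
* **Membrane dimerization constants.** Corrected single-molecule
  co-tracking fractions (AB\* = AB / (2·p_A·p_B)) and two-dimensional
  dissociation constants KD2D for hetero- and homodimers from surface
  densities and dimerized fractions.

## Worked example

Simulate both wild-type models at the baseline abundances, then estimate
a heterodimer KD2D:

```r
library(statkin)

rates <- kinetic_rates()                       # reference parameterization
init27 <- initial_conditions(R1_0 = 25, R2_0 = 50,
                             S1_0 = 500, S3_0 = 500, L_0 = 2)
tr <- integrate_model(model_spec("IL27"), rates, init27)
round(observable_series(tr), 2)
#>   time_min pSTAT1 pSTAT3
#> 1        0   0.00   0.00
#> 2        5  39.66  39.66
#> 3       15  85.98  85.98
#> 4       30 111.85 111.85
#> 5       60 110.83 110.83
#> 6       90  95.89  95.89
#> 7      120  81.08  81.08
#> 8      180  57.25  57.25

kd2d_hetero(gp130 = 2, il27ra = 1, alpha = 0.5)
#> [1] 1.5
```

The pSTAT columns are total (free + receptor-bound) phosphorylated STAT
in nM; with the symmetric baseline (equal STAT pools, mirrored binding
preferences) the two IL-27 outputs coincide, while HypIL-6 breaks the
symmetry. The KD2D is in molecules/μm²: the density at which half the
limiting receptor would be dimerized.

A full synthetic study — generate, preprocess, select H1 vs H2, fit,
summarize, predict — runs from one call:

```r
run_pipeline(list(seed = 1, out_dir = "run", N = 500, M = 6))
```

which writes `dataset.csv`, `summary.csv`, `posterior.csv`,
`model_probabilities.csv`, `posterior_summary.csv`, `predictions.csv`
and a `manifest.yaml` with seeds, acceptance rates and runtimes.

## Package layout

* `R/registry.R`, `R/network.R`, `src/massaction.c` — species
  registries, reaction networks, compiled mass-action RHS
* `R/integrate.R`, `R/predict.R` — ODE integration, observables,
  normalization, variants, dose–response and abundance scans
* `R/synth.R` — synthetic dataset generator and preprocessing
* `R/priors.R`, `R/abc.R`, `R/fit.R`, `R/summarize.R` — priors, ABC
  rejection/SMC with model selection, two-stage inference, posterior
  summaries
* `R/kd2d.R` — co-tracking correction and KD2D estimators
* `R/io.R` — CSV/YAML persistence and the pipeline orchestrator
* `vignettes/stat-competition-kinetics.Rmd` — the methods vignette
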