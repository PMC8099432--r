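---
title: "Modelling STAT1/STAT3 competition at IL-6 and IL-27 receptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling STAT1/STAT3 competition at IL-6 and IL-27 receptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statkin)
```

## The biological question

IL-6 and IL-27 both signal through the shared receptor chain GP130 and
activate the transcription factors STAT1 and STAT3, yet they produce very
different phospho-STAT kinetics: IL-27 drives sustained STAT1
phosphorylation while IL-6 (modelled here through the engineered,
IL-6Rα-independent agonist HypIL-6) drives a transient one.  `statkin`
implements mechanistic mass-action models of the first steps of both
systems — ligand capture, receptor dimerization, STAT docking,
phosphorylation, receptor internalization, and dephosphorylation — and the
likelihood-free Bayesian machinery needed to calibrate them against
phospho-flow time courses and to ask which internalization mechanism the
data support.

## The models

Both models track every molecular species explicitly.  For HypIL-6 the
ligand binds GP130 (`R1`) to form a monomeric complex `C1`; two such
complexes dimerize into the signalling homodimer `D6`, which carries two
equivalent GP130 docking sites for STATs.  For IL-27 the ligand binds
IL-27Rα (`R2`), and the resulting `C2` recruits free GP130 into the
heterodimer `D27`, whose two docking sites are distinct: the GP130 site
binds STATi with rates `kia+/kia-`, the IL-27Rα site with `kib+/kib-`.
Enumerating all occupancy and phosphorylation states gives 22 species for
HypIL-6 and 33 for IL-27.

Assumptions worth stating explicitly:

* **Mass action everywhere.**  Every reaction is an elementary step; no
  Michaelis–Menten lumping.
* **JAKs are implicit.**  Dimerization is equated with receptor
  phosphorylation/activation; no kinase species appear.
* **Phosphorylation is site-blind.**  A dimer-bound unphosphorylated STAT
  is phosphorylated at rate `q` regardless of STAT type and receptor
  chain.  Free pSTATi dephosphorylates at `di`.
* **No allostery.**  Phosphorylated and unphosphorylated STATs leave a
  docking site with the same off-rate; only unphosphorylated STATs bind.
* **Statistical site counting.**  On dimers with two equivalent
  GP130-type sites (the HypIL-6 homodimer and the chimera), an empty
  dimer binds a STAT at `2*k_on`, a doubly occupied one loses either
  copy at a total rate `2*k_off`, and a dimer carrying two
  unphosphorylated STATs phosphorylates one of them at `2*q`.  The
  distinct sites of the IL-27 heterodimer carry no such factors.
* **Internalization hypotheses.**  Under H1 every receptor-containing
  species (free receptors included) is removed at a first-order rate
  `beta_j`; under H2 the removal rate is `gamma_j` times the free
  cytoplasmic pSTAT1 + pSTAT3 concentration — an implicit negative
  feedback standing in for induced inhibitors such as SOCS3, chosen over
  explicit feedback species to keep the state space small.
* **Ligand is depletable** and enters as an initial concentration (dose,
  nM); there is no receptor synthesis or recycling.

The measured observables are the multiplicity-weighted totals of all
pSTAT1- and pSTAT3-containing species.  We define them canonically as
moiety sums over the registry (a doubly loaded dimer counts twice); for
the HypIL-6 model this reduces exactly to the published component-wise
sums, and it gives the unambiguous generalization for the larger IL-27
state space.

Receptor variants reuse this machinery: the IL-27Rα/GP130 **chimera**
assembles like IL-27's receptor but carries two GP130-type docking sites
(23 species); the **Y613F** mutant keeps the wild-type topology with the
STAT1/IL-27Rα rates pinned at `k1b+ = 1e-5 nM^-1 s^-1`, `k1b- = 10 s^-1`.
These published override values are implemented verbatim; we note that
their ratio corresponds to a 1 mM-scale affinity rather than the
10^2 μM quoted alongside them, and we do not attempt to reconcile the
two.

## Numerics

Time is integrated in seconds (all rates are per second) with `lsoda`
(stiff-capable), relative tolerance `1e-8` and absolute tolerance
`1e-10` nM, sampled on the experimental grid {0, 5, 15, 30, 60, 90, 120,
180} minutes.  The right-hand side is a generic compiled mass-action
kernel driven by a per-model reaction table; an equivalent pure-R
implementation (`rhs()`) exists for inspection and is tested against
hand-written equations.  Inside inference, integrations that exceed a
reduced step budget are treated as failed simulations and score an
infinite distance — this both guards against pathological prior draws
and keeps runtimes bounded.  Halving the tolerances moves the observables
by well under 0.1%.

## The synthetic study

No raw numeric time courses are published, so the package generates its
own data with the study's design: 2 cell types x 4 replicates x 2 STAT
antibodies x 8 time points x (2 cytokines + unstimulated).  Intensities
are built as `(a + c*t) + kappa * pSTAT_total(t) * (1 + eps)` with
`eps ~ N(0, sigma^2)`: a linear background drift (the unstimulated
series contain only this term) plus a signal proportional to the model
output with multiplicative Gaussian noise, reflecting how flow-cytometry
MFI variability scales with intensity.  Defaults: `sigma = 0.05`,
`kappa = 100` a.u./nM, background `200 + 0.5*t` a.u.  The generator's
kinetic truth (`default_true_rates()`) was fixed once to sit inside the
prior supports and reproduce the qualitative phenotypes the models were
built around — STAT1 prefers IL-27Rα ten-fold (`k1b+/k1a+ = 10`), STAT3
prefers GP130 ten-fold (`k3a+/k3b+ = 10`), HypIL-6 receptor complexes
internalize faster than IL-27's — and is not adjusted thereafter.
What the generator does *not* emulate: barcoded multi-well cytometry,
compensation/gating artefacts, cell-to-cell heterogeneity, or
non-linear detector effects.  Passing recovery tests therefore show the
inference machinery is sound under the stated noise model, not that the
real data would identify the same parameters.

Preprocessing mirrors the study: a linear background model is fitted to
the unstimulated series — pooled across replicates, per (antibody, cell
type), since a single line per antibody is all the design warrants — and
subtracted; each record is then divided by the same replicate's IL-27
value at the 30-minute reference point (the empirical maximum), and
replicates are averaged.  The 15-minute reference is available as a
robustness switch.  Replicates with a non-positive reference after
subtraction are excluded with a warning.

## Inference

The distance between a simulated parameter set and the data is the
Euclidean norm over the 32 normalized (STAT, time, cytokine) cells of
one cell type; model outputs are normalized exactly like the data, by
the same particle's IL-27 value at the reference time.  Both cytokine
models are simulated per particle with shared STAT/receptor rates, so
the distance couples them.

ABC-SMC follows the standard sequential scheme with joint model
selection: iteration 1 is rejection sampling with hypotheses weighted
equally; later iterations resample a hypothesis from the previous
iteration's acceptance fractions, resample a particle from that
hypothesis' weighted population, and perturb it with a component-wise
uniform kernel.  Design choices the published description leaves open,
resolved here as:

* **Kernel widths**: component-wise uniform, on the log10 scale for
  log-scale parameters and the natural scale for concentrations.  The
  default half-width is `sqrt(6)/2` times the weighted standard
  deviation of the previous accepted population (kernel variance twice
  the population variance, the usual near-optimal choice for SMC
  perturbation kernels); a half-range rule is available as
  `kernel_type = "range"`.  With 20+ parameters under broad uniform
  priors the range rule never concentrates — accepted ranges stay
  prior-wide, so proposals degenerate to fresh prior draws — which is
  why the sd rule is the default.
* **Weights**: standard importance weights, prior density over the
  kernel-smoothed previous population, computed entirely in the
  transformed (log10/linear) space; weights normalize within a
  hypothesis.
* **No cross-model moves**: H1 and H2 differ only in their
  internalization parameter (`beta` vs `gamma`); the hypothesis index is
  resampled, parameters never jump between models.  A hypothesis with no
  accepted particles is dropped from subsequent iterations.
* **Schedules**: the reference configuration is N = 10^4 particles and
  the fixed 15-step threshold sequence 100, 10, 5, 3, 2.5, 2.25, 2,
  1.75, 1.5, 1.25, 1.1, 1, 0.9, 0.8, 0.7.  For desk-scale work the
  package also offers an adaptive schedule: each threshold is a
  configurable quantile of the previous iteration's accepted distances,
  tracking the attainable distance floor without hand-tuning.  With few
  iterations the quantile must be aggressive enough that the final
  threshold approaches the noise floor — hypothesis selection is only
  informative there, since at coarse thresholds both internalization
  mechanisms fit equally well; the shipped six-iteration recovery run
  uses the 0.25 quantile.
* **Two-stage design**: shared STAT/receptor rates are estimated on the
  first cell type; the second stage infers only the nine cell-specific
  parameters (initial concentrations, `q`, `d1`, `d3`, internalization)
  while drawing the shared block jointly — particle-wise, preserving
  correlations — from the stage-1 posterior.  The shared draws are
  refreshed at every proposal and excluded from kernel and weights,
  which marginalizes them out by Monte Carlo.

Priors follow the published table: informative log10-normals for the
ligand-receptor rates, broad log10-uniforms for assembly, STAT docking,
phosphorylation, dephosphorylation and internalization, and truncated
normals for the initial concentrations, whose second parameter we read
as a standard deviation (the table consistently uses half the mean).

The test suite exercises this machinery at reduced scale: the shipped
recovery run uses N = 500 particles and M = 6 adaptive iterations
against data generated under H1 with 5% noise, checking that the final
hypothesis probability favours H1 and that the posterior medians
preserve both ten-fold binding-preference orderings.  A one-parameter
conjugate-Gaussian toy verifies the sampler against the analytic
posterior at N = 2000.  These sizes are the package's compromise between
statistical resolution and a test suite that runs in minutes; the
full-scale configuration is a config change, not a code change.

## Predictions

Dose–response curves use 18 log-spaced doses over 1e-4 to 1e2 nM with a
15-minute readout (the experimental dose–response protocol; both are
configurable).  Abundance scans start from the baseline concentrations
GP130 25 nM, IL-27Rα 50 nM, STAT1 = STAT3 = 500 nM (approximately the
posterior medians of the calibrated models) with RPE1 fitting doses of
2 nM IL-27 and 10 nM HypIL-6 (Th-1: 2 and 20 nM), and report pointwise
weighted medians with 2.5/97.5% credible bands across particles.  The
direction checks shipped in the tests — a ten-fold GP130 reduction
collapses HypIL-6 pSTAT1 but barely moves IL-27's; a ten-fold STAT1
increase raises pSTAT1 for both cytokines and depresses IL-27 pSTAT3;
the chimera trades IL-27's sustained pSTAT1 for a transient one while
leaving pSTAT3 kinetics within 20% of wild type — are evaluated at the
recovered posterior-median parameter set.

## Dimerization constants

The single-molecule module is deliberately small: it starts from
trajectory counts and surface densities, not images.  For homodimers,
stochastic double labeling hides same-dye dimers, so observed
co-trajectories are corrected by the dual-color probability
`2 p_A p_B` with `p` the channel fractions; `2 AB*/(A+B)` is then the
fraction of receptors in dimers.  Two-dimensional dissociation constants
follow from the monomer–dimer mass-action balance, heterodimer
`KD2D = (G - aR)(R - aR)/(aR)` and homodimer `KD2D = 2 G (1-a)^2 / a`,
with closed-form inverses provided for round-trip checks.  Whether the
heterodimer fraction is referenced to all IL-27Rα trajectories or only
ligand-bound ones is the caller's choice; the estimator takes the
fraction as given.

## Known limitations

* H2's feedback is implicit; it cannot represent delayed inhibitor
  synthesis kinetics.
* Desk-scale ABC posteriors are broad; only robust orderings and
  hypothesis probabilities should be interpreted at N = 500.
* The component-wise uniform kernel ignores parameter correlations; a
  covariance-adapted (multivariate) kernel would mix faster in the
  correlated directions but is deliberately not used, to stay close to
  the published algorithm's component-wise uniform perturbation.
* The synthetic noise model is multiplicative-Gaussian only; heavier
  tailed MFI noise would loosen the recovery guarantees demonstrated by
  the tests.
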