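---
title: "A tumor-immune dynamics model of prostate cancer treatment combinations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A tumor-immune dynamics model of prostate cancer treatment combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prostimm)
library(dplyr)
```

## The biological problem

Androgen-deprivation therapy (ADT, modelled as surgical castration, CX) is
the standard hormonal treatment for advanced prostate cancer, but tumors
eventually escape it by switching from castration-sensitive (CSPC) to
castration-resistant (CRPC) growth. Castration also perturbs the immune
system: dying tumor cells shed antigen, dendritic cells prime cytotoxic T
lymphocytes (CTLs), the activated CTLs secrete IL-2, and IL-2 expands
regulatory T cells (Tregs) which then shut the CTL response back down. Two
immunological interventions target this inhibitory brake — Treg depletion
(AR, an anti-Treg antibody) and IL-2 neutralization (AI) — and a tumor-cell
vaccine (V) stimulates the priming arm directly. `prostimm` implements a
mechanistic model of these interactions to ask which combinations of
\{CX, V, AI, AR\} control the tumor best, and whether the combinations act
synergistically in the Bliss-independence sense.

## The model

The system tracks 15 state variables in two tissue compartments (prostate
and lymphoid): four treatment inputs (androgen `A`, vaccine stimulus `V`,
anti-IL-2 antibody `B_I`, anti-Treg antibody `B_R`), the two tumor
populations (`S` = CSPC, `R` = CRPC), the shed-antigen pool `Ag`, two
dendritic-cell types in lymphoid (functional `D_L`, regulatory `Dr_L`),
and CTL, Treg and IL-2 in both compartments (`C_L`, `G_L`, `I_L`;
`C_P`, `G_P`, `I_P`). All biological states start at 1 — the data are
relative measurements — and the treatment variables start at 1 exactly when
the corresponding treatment is given. Castration acts through an indicator
on the androgen decay; the other three treatments act through their
decaying initial pulses.

The right-hand side (see `tumor_immune_rhs()` for the exact expressions)
encodes: androgen-gated logistic CSPC growth through a saturating gate
`h(A) = A / (theta_A + A)`; deprivation-driven CSPC-to-CRPC transition at
rate `lambda (1 - h(A))`; CTL killing of both tumor populations; antigen
shedding proportional to tumor cell death (apoptotic and CTL-mediated);
antigen- and vaccine-driven activation of functional DCs; induction of
regulatory DCs; DC-mediated CTL priming boosted by IL-2; Treg suppression
of CTLs; IL-2 secretion by CTLs; IL-2-driven Treg expansion; lymphoid-to-
prostate trafficking of CTLs and Tregs; and antibody-mediated removal of
IL-2 (`kappa_AI B_I I`) and Tregs (`kappa_AR B_R G`).

Twenty-five rate constants are estimated from data. The remaining
constants are fixed by convention: `delta_A = 2` per week (androgen falls
to ~1% within 2.5 weeks of castration), unit decay rates for the three
treatment pulses and IL-2, carrying capacity `kappa = 20` (relative
units — the tumor can grow an order of magnitude before saturating on the
5-week horizon), and unit antibody efficiencies. These choices pin the
treatment pulses to the 0–5-week timescale on which the outcomes are read.

Simulation uses a stiff-capable solver (`deSolve::lsoda`, relative
tolerance 1e-6, absolute 1e-8) with a compiled right-hand side; an R
reference implementation of the same equations is kept alongside and the
two are verified against each other in the test suite. Every loss term in
the equations is proportional to its own state, so exact solutions are
non-negative; solver-level negative excursions are floored at zero after
each solve rather than reflected.

## Treatment outcomes

Two scalar outcomes summarize a trajectory: the **type I** outcome is the
instantaneous relative tumor size `(S + R) / (S(0) + R(0))` at 5 weeks
post-treatment, and the **type II** outcome is its average over weeks 0–5
(composite trapezoid on the solution grid; the default 0.05-week grid puts
the quadrature error far below every tolerance used here). Treatment
effect is the percent inhibition of either outcome relative to the
untreated control SX.

```{r outcomes}
oc <- predict_all_regimens(default_truth())
oc |> arrange(desc(inhibition_I)) |> head(5)
```

## The packaged ground truth

The original animal measurements behind this model are not publicly
redistributable, so the package carries a fixed, versioned ground-truth
parameter set (`default_truth()`) from which synthetic datasets are
generated. Its values were chosen once, by direct search against the
qualitative biology the model is meant to express, and then frozen:

* castration alone inhibits the tumor; CRPC regrowth limits the benefit;
* lymphoid CTLs rise transiently after castration and then fall as
  IL-2-driven Treg expansion takes hold; lymphoid Tregs rise;
* efficacy orderings CX + AR > CX + AI > CX > SX and
  CX + V + AR > CX + V > SX + V > SX, with CX + V + AR the best of the
  seven experimental conditions;
* mean component efficacy over all 16 regimens ordered
  AR > V > CX > AI;
* type I and type II inhibition strongly correlated (r > 0.99 here).

These are structural properties of the parameter point, not of any random
draw, and the acceptance suite re-derives all of them from the frozen
values. No claim is made that the values equal the original study's
estimates — only that they generate data with the same qualitative
signatures.

## Synthetic data

`generate_dataset()` emulates the design of the mouse experiments: 7
treatment conditions (SX, CX, CX + AI, CX + AR, SX + V, CX + V,
CX + V + AR), up to 5 observables per condition (relative tumor size and
CTL/Treg in prostate and lymphoid), 2 post-treatment time points (2.5 and
5 weeks), and replicate animals per cell. Noise is multiplicative
lognormal with median 1 (`sdlog = sigma`, default 0.15) — positivity-
preserving, and the noise-free model value is the *median* rather than the
mean of the replicate distribution (the test suite checks replicate
medians converge to the model value). Default replicate count is 5, a
typical mouse group size. Initial (t = 0) values are never emitted as
data. By default the lymphoid observables are missing for the CX + AI and
CX + AR arms, mimicking the limited lymphoid sampling of the original
design; this leaves 62 of the 70 possible data boxes. A data box — all
replicates of one (condition, observable, time) cell — is the unit of
bootstrap resampling and of the box-wise cross-validation holdout.

What the generator does *not* emulate: between-animal heterogeneity beyond
i.i.d. multiplicative noise, litter or cage effects, measurement-method
differences between tumor weights and flow-cytometry counts, and censoring
or dropout. Passing tests on synthetic data therefore demonstrate the
correctness and internal calibration of the machinery, not performance on
real animal data.

## Calibration: GA with hyperparameter selection

The 25 parameters are estimated by minimizing the sum of squared errors
between model observables and every replicate measurement. The optimizer
is a real-coded genetic algorithm (binary tournament selection,
simulated-binary crossover, polynomial mutation, one-elite preservation)
preceded by a selection step over its own settings: a grid of candidate
GA configurations (default 3 levels for each of generation count,
population size, crossover probability and the two distribution indices,
with the per-gene mutation probability fixed at 1/25 — 243 candidates) is
run once per candidate, and each setting's level is then chosen
one-at-a-time by the smallest *median* fitting error across the runs at
that level (the median resists the occasional diverged GA run; ties go to
the first-listed level). Under the selected configuration the fit is
repeated with fresh seeds and the best result returned.

Design choices worth recording:

* **Log-scale search.** The GA operates on log10-transformed parameters.
  Rates span orders of magnitude (default bounds 1e-3 to 1e2), and both
  SBX and polynomial mutation take steps of a size relative to the bound
  box — meaningful on the log scale, badly scale-dependent on the raw one.
  Initialization is therefore log-uniform within bounds.
* **Local polish.** Each replicate GA fit can be refined by bounded
  Levenberg–Marquardt on the residual vector (`minpack.lm::nls.lm`),
  and replicates are compared *after* refinement: different GA runs land
  in different basins, and basin depth — not the raw GA value — is what
  should rank them. Large-scale studies substitute hundreds of replicate
  fits on a cluster for this step; at desk scale the polish is what makes
  noise-free recovery to SSE below 1e-4 attainable. It defaults to on for
  point estimation and off for cross-validation (below).
* **Objective evaluation.** All conditions in the dataset are stacked
  into one compiled ODE system (independent 15-state copies), so each
  objective evaluation is a single solver call; a failed or exploding
  integration scores `+Inf`.

## Identifiability

Two complementary tools assess which parameters the data actually pin
down. `bootstrap_identifiability()` resamples replicates within each data
box, refits each resample, and computes each parameter's coefficient of
variation CV = sd/mean (sample standard deviation) over the bootstrap
estimates, flagging CV > 1 as non-identifiable.
`identifiability_screen()` is the fast deterministic counterpart: the
Gauss–Newton covariance from the residual Jacobian at a reference point,
propagated to a predicted CV under nominal 5% measurement noise, with the
same threshold. On the default design the screen flags the antigen-scale
parameters (`sigma_Ag`, `delta_Ag`, and the DC-activation chain) as
sloppy — unsurprising, since the antigen pool itself is never measured and
only products of these rates reach the observables — while the tumor and
T-cell kinetic rates are well constrained. The recovery experiments in
the acceptance suite assert 10% recovery exactly on the screen-identified
subset.

## Cross-validation

Two schemes mirror the original study: leave-one-condition-out (7 folds)
and leave-one-data-box-out (one fold per box). In each fold the model is
refit `replicates` times with fresh GA seeds on the training portion, the
held-out regimen is simulated under every replicate fit, and each held-out
box gets a mean prediction with a 95% normal band (mean ± 1.96 sd of the
replicate predictions — the spread of replicate *fits*, not a standard
error). The polish step is off by default here: the bands are meant to
express training stochasticity, which a fully converged local refinement
would collapse to zero width. Coverage is summarized against the
noise-free truth with `band_coverage()`; at the default noise level the
nominal 95% bands cover the truth in well over 85% of boxes.

## Synergy analysis

Percent-inhibition effects feed the Bliss combination index. For two
*disjoint* treatment groups A and B with inhibition fractions `e_A`,
`e_B` and combined effect `e_AB`,

&nbsp;&nbsp;&nbsp;&nbsp;CI = (e_A + e_B − e_A·e_B) / e_AB,

the Bliss-independence expectation over the observed combined effect:
CI < 1 synergy, CI = 1 additivity, CI > 1 antagonism. Effects are clipped
to [0, 0.999] (negative inhibition counts as zero effect, with a
warning), and a non-positive combined effect leaves the index undefined.
The index is pairwise only — `(A + B) + C` is analyzable as the pair
((A + B), C), the three-way split A + B + C is not — so the CI matrix runs
over all 15 non-empty treatment groups with blanks on overlapping pairs.
Component summaries average inhibition over the 8 regimens containing a
component and average CI over the component's matrix rows, restricted to
synergistic (CI < 1) entries.

```{r synergy}
cim <- ci_matrix(oc, "I")
tidy(cim) |> arrange(ci) |> head(3)
component_summary(oc, cim)
```

Under the packaged truth, adding Treg depletion to castration-plus-
vaccination is the stronger synergy — CI((CX + V), AR) < CI(CX, V) — and
the component synergy ordering matches the efficacy ordering.

## Sensitivity

`local_sensitivity()` perturbs each estimated parameter upward by 5% and
reports the percent response of both outcomes under each of the 7
experimental conditions. Under the packaged truth the largest responses
concentrate on the CRPC growth axis (its proliferation rate above all),
consistent with castration-resistant regrowth dominating the late tumor
burden; the forward-difference ratio is stable between 5% and 1%
perturbations.

## Problem sizes and numerical conventions

The defaults in the package are desk-scale: hyperparameter grids of a few
candidates in tests (the full 243-candidate grid is the documented
default of `hyper_grid()` and is exercised by enumeration), 8–20
replicate fits, 12 bootstrap resamples in the acceptance script (the
full-scale analysis would use 100, and 500 replicate fits). The recovery
experiments use informative bounds — a factor of 2–3 around the reference
values — standing in for the empirical ranges a modeller would impose;
with the uninformative default box (1e-3 to 1e2) the sloppy directions
are unrecoverable by construction, which the identifiability analysis
makes explicit rather than hiding. Solver tolerances are rtol 1e-6 /
atol 1e-8 everywhere; outcome quadrature is trapezoidal on the output
grid; all stochastic stages derive their seeds from a single master seed
and are bit-reproducible given it.

## Known limitations

* The right-hand side is a faithful reconstruction of the documented
  interaction structure, not a transcription of unpublished equations;
  it is pluggable (`simulate_model(compiled = FALSE)` accepts the R
  reference, and the C and R implementations are interchangeable).
* Whether IL-2 belongs in one or both compartments is not settled by the
  interaction diagram alone; both compartments carry it here, with
  trafficking only of cells.
* No helper-T-cell (Th17/CD4) biology, no blood-vessel compartment, no
  spatial structure, no dose axis (hence Bliss rather than dose-response
  synergy models).
* Identifiability at the 2-time-point design is intrinsically limited;
  conclusions about individual sloppy parameters should go through the
  identifiability tools, not point estimates.
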