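---
title: "Modeling Treg adoptive transfer in transplant rejection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling Treg adoptive transfer in transplant rejection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tregsim)
```

## The model

`tregsim` simulates the alloimmune response to a murine heterotopic
heart transplant as 14 coupled ordinary differential equations across
two well-mixed compartments: a representative draining lymph node, where
antigen presentation and T cell activation occur, and the graft, where
effector cells destroy the transplanted tissue. The tracked populations
are CD4 helper and CD8 cytotoxic T cells (in both compartments),
activated Tregs (both compartments), naive Tregs (lymph node), immature
dendritic cells (donor-derived, graft-associated), mature dendritic
cells (both compartments), inflammatory macrophages, one
pro-inflammatory and one anti-inflammatory cytokine pool (normalized
units), and the surviving graft cells. Time is measured in days after
transplantation (POD); all cell populations are absolute counts.

The causal skeleton is a feed-forward inflammation cascade with Treg
brakes at every stage. Surgery leaves a pool of immature donor dendritic
cells and a small pro-inflammatory cytokine signal. Dendritic cells
mature only in the presence of pro-inflammatory cytokine or
graft-infiltrating CD4 T cells — when both signals are zero the
maturation rate is exactly zero — and immature dendritic cells decay at
a rate proportional to the remaining graft mass, so a graft that is
destroyed early stops feeding the antigen-presenting pool. Mature
dendritic cells traffic to the lymph node (the package assumes
directed graft-to-lymph-node trafficking; whether mature DC populations
exchange between compartments was genuinely open, and one-way transport
is the conventional immunological picture), where they activate and
expand CD4 and CD8 T cells through saturating (Michaelis-type) terms.
Effectors traffic to the graft and kill graft cells by mass action;
pro-inflammatory cytokine produced by the activated populations recruits
inflammatory macrophages, a second destruction channel. Graft cells have
no regrowth term: their derivative is a sum of two non-positive
destruction channels, which is also what makes the per-channel
attribution (`graft_destruction_terms()`) exact rather than
approximate.

Tregs suppress the cascade at four points: dendritic-cell maturation
(graft Tregs), T cell activation and proliferation (lymph-node Tregs),
macrophage recruitment (via anti-inflammatory cytokine), and the
effector kill rates themselves (graft Tregs and anti-inflammatory
cytokine jointly). All suppression takes the form `k / (k + x)` with an
inhibition constant `k` in cells or cytokine units. Adoptive transfer
enters exclusively through the three Treg equations, partitioned by the
fractions `f_G`, `f_LN`, `f_N`.

### Dosing input

Each injection contributes an exponentially decaying input
`D0 * exp(-beta (t - t_i))` from its injection day `t_i`; `beta`
defaults to 2/day, representing fast absorption of an injected bolus,
and the delivered total is `C = n D0 / beta`. `C` is defined as cells
reaching the modeled compartments: the roughly 50% of injected cells
lost systemically are outside the model by convention rather than
represented by an extra loss parameter, so a user quoting an
experimental injection size should halve it before setting `C`.
`equal_split_schedule()` constructs the equal-split daily regimens used
throughout the dosing experiments. The input is right-continuous at each
`t_i` (`d_i(t_i) = 1`); since the integrator restarts at every dose day,
the one-sided convention has no numerical consequence.

## Numerical choices

Integration uses `deSolve::lsoda` (stiff-capable, adaptive) with
relative tolerance `1e-8` and per-state absolute tolerance `1e-10`
scaled by `max(initial value, 1)`. These are deliberately tight:
rejection times are read at 0.1-day resolution up to POD 150, and the
test suite checks that halving the tolerances moves no reported
rejection time by more than 0.05 day. The integration is restarted at
every dose day so the kink in `D(t)` never falls inside a solver step.
States are clipped to zero after integration; an excursion below
`-1e-9` relative to the state's scale aborts the run as a genuine
failure rather than roundoff. Saturation denominators are evaluated on
states clamped at zero, and every saturating ratio uses the convention
`num/den = 0` when `den = 0`, which makes the right-hand side total on
the closed nonnegative orthant including degenerate parameter sets with
zero half-saturation constants.

Rejection — a 75% reduction of the initial graft cells — is located by
sign-change bracketing on the output grid followed by root refinement on
a monotone cubic interpolant of `G(t)` (Hyman-filtered spline; linear
fallback where `G` is locally non-monotone or flat), giving crossing
times well below the `1e-3`-day documentation tolerance. A trajectory
that never crosses within the horizon reports `NA` and is treated as
censored by the sweep experiments; censored entries are excluded from
argmax readouts unless every entry is censored. Argmax ties break toward
the earlier day or smaller dose number — the conservative clinical
reading.

The right-hand side is implemented twice: a documented reference
implementation in R (`rhs_full()`, which the three printed Treg
equations delegate to term by term) and a compiled C version used by the
solver, because the sweep experiments and the evolutionary calibrator
run tens of thousands of integrations. The test suite asserts the two
agree along dosed trajectories to `1e-6`.

### Default grids and problem sizes

Sweeps default to: administration day 0-10 in 0.1-day steps; dose
magnitude on 150-200 log-spaced points spanning `1e3`-`1e7` cells; dose
number 1-30; graft fraction 0-1 in steps of 0.01. These resolve every
threshold the package reports at least one grid step finer than it is
quoted. The acceptance tests run each sweep once at these sizes (a few
hundred 150-170-day integrations, a few minutes in total); the
parameter-recovery experiment uses ten runs of population 50 over 100
generations against 15 sample days, the sizes at which the recovery
claim is stated.

## The reference calibration

The values returned by `default_parameters()` are a synthetic reference
calibration produced with this package, not a transcription of
experimentally fitted constants. Structural constants were fixed at
immunologically conventional scales (naive Treg pool `1e5` cells, graft
of `1e9` cells, a `1e5`-cell donor dendritic-cell pool, per-day death
rates between 0.04 and 1.7), and the remaining constants were then
calibrated by a stochastic search so that the untreated model rejects
near POD 11 and single-dose adoptive transfer of `C = 5e5` cells on
POD 0 produces the published contrast between graft-homing (POD ~74)
and lymph-node-homing (POD ~25) delivery. The calibration was frozen
before the acceptance checks were written and is not adjusted by any
test.

Under this calibration the model reproduces the headline site-of-
accumulation readouts within a day and exhibits the right qualitative
phenomenology elsewhere: the single-dose timing curve is strongly
non-monotonic (delaying a `5e5`-cell dose from POD 0 to POD 1-3 extends
survival by ~30 days, with the optimum near POD 2.5), splitting the dose
into daily injections is substantially better than a single bolus once a
small fraction of cells reaches the graft, and there are intervals where
the 14-dose regimen shows *more* graft CD8 T cells yet *less* CD8-
mediated destruction — the signature of effector-function regulation
rather than effector exclusion. Readouts that depend on fine quantitative
detail of the original calibration (the exact POD 1.5 optimum, the
`2.9e4`-cell crossover below which lymph-node delivery wins, the
14-dose optimum at POD 115) are not all matched; the acceptance test
records each such claim and its measured value explicitly. Users with an
externally calibrated parameter table can load it through
`read_model_config()` without touching code — every non-printed constant
lives in the named `supplementary_rates` registry.

## Calibration machinery

`calibrate()` wraps a from-scratch NSGA-II: fast non-dominated sorting,
crowding distance with infinite sentinels at front extremes, binary
tournament on (rank, crowding), simulated binary crossover
(distribution index 15), polynomial mutation (index 20, rate `1/n`),
and elitist (mu + lambda) environmental selection. The sorting core is
verified in the test suite against a brute-force dominance oracle on a
thousand random instances. Genomes live in log10 parameter space with
ten-fold default bounds around nominal values, which makes the search
scale-free across rate constants spanning five orders of magnitude. A
genome whose simulation fails is assigned a huge sentinel objective
vector — it is dominated by every finite solution and washed out — and
a generation in which every evaluation fails aborts with a diagnostic.

The reference objective construction (`model_objectives()`) emits one
discrepancy per observed population: the sum over sample days of
squared standardized log-residuals, with the log-scale residual
standard deviation implied by the observation noise CV. Log residuals
match the multiplicative noise model and weigh each population on its
own scale.

### Synthetic observations

`generate_observations()` samples the named states at the requested
days (exactly, via the solver's dense output) and applies independent
multiplicative lognormal noise parameterized by a coefficient of
variation, mean-corrected so the expected observation equals the
noise-free value. Cell counts are positive and span orders of
magnitude, which is what a multiplicative model captures. The generator
does not emulate flow-cytometry gating, detection limits, or sampling
(sacrifice) designs — passing recovery tests therefore demonstrates
that the calibrator works on well-behaved direct state readouts, not
that real experimental data of this richness could be collected. The
default design (15 days evenly spaced over POD 0.5-11, all 14 states,
10% CV) covers the untreated rejection window.

### A known limitation: many objectives

With all 14 populations observed, the objective space has 14
dimensions, and the dominance relation loses discriminating power: most
of the population becomes mutually non-dominated within a few
generations, and selection is driven by crowding distance, which favors
the spread of the front over convergence to its knee. In the package's
parameter-recovery experiment (three free parameters, ten seeded runs)
the Pareto front contains a genome within 20% of the truth on every
free parameter in roughly seven of ten runs rather than nine; the
acceptance test records the observed rate. This is the documented
many-objective weakness of crowding-based NSGA-II selection, not an
implementation defect — the sorting core is oracle-verified — and the
practical remedies (aggregating objectives into fewer groups, or
reference-point selection as in NSGA-III) are outside the scope of the
canonical algorithm implemented here.

## What the tests do and do not show

The property tier of the suite is independent of any calibration: dose
conservation (quadrature of `D(t)` against `n D0 / beta` on random
schedules), zero-dose equivalence, exactness of the destruction
decomposition and its trapezoidal integral against the realized graft
loss, closed-form rejection of a linear decay, finite-difference
consistency of trajectories with the right-hand side, nonnegativity of
boundary derivatives, and the NSGA-II core against brute force. These
validate the machinery. The calibration-dependent tier compares the
reference calibration's dosing-strategy readouts with the published
values and reports every miss alongside every match; it validates the
phenomenology of one particular parameter set, and transfers to real
transplant systems only as far as that calibration does.
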