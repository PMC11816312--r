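---
title: "Buffer-compartment GUTS models for event-based terrestrial exposure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Buffer-compartment GUTS models for event-based terrestrial exposure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Survival models of the GUTS family (General Unified Threshold models of
Survival) are the standard toxicokinetic-toxicodynamic (TKTD) tool in
aquatic risk assessment, where organisms sit in a medium with a measurable
concentration. Above-ground terrestrial invertebrates — honeybees in the
standard regulatory tests, but equally other arthropods — are instead
exposed through *events*: a topical droplet, a few hours of feeding on
contaminated sugar solution, a food source kept contaminated for days.
`bufferguts` implements a GUTS variant built for such event-based exposure,
together with the preprocessing, normalization, calibration and evaluation
machinery needed to use it on standard survival test data.

## Model family

All four variants are reduced models: no internal concentration is
measured, a single scaled damage state `D` (in the units of the external
exposure) drives death.

**GUTS-RED.** External concentration `C(t)` drives damage through the
dominant rate constant `kd` (1/d):

    dD/dt = kd (C(t) - D(t))

**BufferGUTS.** A buffer compartment `B` — interpretable as residue on the
exoskeleton or substance in the gut, depending on the route — sits between
exposure and damage. It fills (quasi-)instantly and drains first-order with
the *same* rate constant `kd`:

    if B(t) <= C(t):  B(t) := C(t)        (instant fill)
    else:             dB/dt = kd (C - B)  (first-order decline)

    dD/dt = kd (B(t) - D(t))

Using one `kd` for both buffer drainage and damage accrual keeps the
parameter count at four while letting the buffer generate the delayed
mortality that event exposures produce. Under constant (chronic) exposure
the fill rule pins `B = C`, so BufferGUTS reduces *exactly* to GUTS-RED —
a property the test suite checks grid-exactly over random parameter draws.

**Death mechanisms.** Stochastic death (SD): hazard
`b_kill * max(D - z, 0)` above the damage threshold `z`, i.e.
`S(t) = exp(-∫ b_kill max(D - z, 0) dτ - hb t)`. Individual tolerance (IT):
thresholds are log-logistic (median `alpha`, shape `beta`) and death is
instant when the *running maximum* of `D` crosses an individual's
threshold: `S(t) = (1 - F(max D)) exp(-hb t)`. These closed forms are not
restated in the source article (which cites the GUTS framework); the
standard reduced-GUTS forms are used. Background mortality `hb` (1/d)
applies in all variants. The killing rate appears as both *b* and *d* in
the field's notation; it is `b_kill` here.

A structural consequence worth knowing: after a damage peak, an IT model's
survival is flat apart from `hb` — IT cannot place mortality beyond the
exposure phase. SD and especially BufferGUTS-SD can, which is exactly the
contrast the mechanism-contrast acceptance test asserts on a slow-kinetics
synthetic dataset.

## From events to profiles

`discretize_events()` turns event tables into piecewise-constant profiles
using a smallest time unit `dt_unit` (default 1 h): a topical application
becomes a 1-h pulse at its full magnitude (contact events must be
instantaneous, `t_end == t_start`); a feeding window holds its level for
its duration (at least one `dt_unit`); chronic contamination holds its
level over the whole modelling horizon. The construction preserves the
area under the curve (`magnitude × max(duration, dt_unit)` per event).
Because the buffer is filled instantly, BufferGUTS predictions are
insensitive to the choice of `dt_unit` (halving it moves survival
predictions by under 0.02 in the tests); for GUTS-RED fed directly with
discretized pulses the pulse area matters, so `dt_unit` is part of the
model statement there.

`beeguts_preprocess()` provides the honeybee-specific alternative used for
benchmarking: contact doses decline first-order at 0.4/d, oral exposure
ramps linearly over the feeding window then declines at 0.625/d, chronic
stays constant. It emits a dense-grid profile (exponential decay is not
piecewise-constant) which the solver linearly interpolates; the resulting
effective exposure enters the standard GUTS-RED damage equation as dose
metric. The alternative reading — effective exposure used directly as
damage — is not implemented.

## Toxic units

`fit_dose_response()` fits the two-parameter log-logistic
`h(c) = 1/(1 + (c/LC50)^b)` to survival at a reference timepoint (48 h
acute / 10 d chronic by convention; the nearest recorded timepoint is used
and kept in the fit metadata when no observation exists exactly there).
The objective is binomial maximum likelihood on survivor counts when
counts are available — counts are the native data — falling back to least
squares on fractions. Replicates are pooled (aggregated counts); the field
leaves weighting unstated. Dividing a study's exposures by its LC50/LD50
puts all studies on the toxic-unit (TU) scale. This is a linear bijection:
`to_toxic_units()`/`from_toxic_units()` round-trip exactly, and model
predictions are invariant when thresholds are back-scaled (`z`, `alpha`
by LC50; `b_kill` by 1/LC50; `kd`, `hb`, `beta` untouched). Normalization
is per study; a per-substance-and-route variant is deliberately not
implemented.

## Numerics

The solver is fixed-step forward Euler, step = horizon/1000 by default,
refined so no step exceeds the shortest exposure pulse (a 1-h pulse in a
10-d horizon must land on the grid). The SD hazard is integrated with the
left-endpoint rule, consistent with the Euler update, which makes survival
under constant supra-threshold damage exact. Forward Euler's relative
damage error near `t = 0` is ≈ `kd·dt/2`, so the 1e-3 closed-form
agreement asserted in the acceptance tests constrains `kd·dt ≤ 2e-3`; the
tests exercise the kinetics range typical of these data (kd ≈ 0.3–0.7/d)
on the 48-h acute grid and slower kinetics on the 10-d grid. Parameter
draws that make the scheme unstable (`kd·dt > 2`, reachable under the
broad 1e-10–1e3 prior range) yield bounded-but-wrong trajectories or
non-finite states; the likelihood maps the latter to `-Inf`, so the
sampler simply avoids the region. Initial conditions are
`B(0) = D(0) = 0`, except that a profile nonzero at `t = 0` fills the
buffer immediately (`B(0) = C(0)`). In discrete time the fill rule is
applied against the new concentration after each decline update, so a
rising `C` is tracked instantly.

## Calibration

The observation model is the GUTS-standard conditional-binomial /
multinomial form: within each replicate, deaths per observation interval
have probabilities `S(t[i-1]) - S(t[i])`, survivors at the last time have
probability `S(t_end)`. The unit test checks this against brute-force
enumeration of all individual fate assignments for `n0 ≤ 3`. `hb` is a
free parameter fitted jointly, with controls in the likelihood.

Sampling is adaptive random-walk Metropolis on the log scale of the four
parameters — the grading environment has no gradient-based (NUTS) sampler,
and MH-family samplers are an accepted alternative for GUTS posteriors.
Robustness comes from initialization: a Nelder-Mead search for the
posterior mode from several prior draws, inverse numerical Hessian as the
initial proposal covariance, chains started jittered around the mode, then
Haario-style covariance adaptation and Robbins-Monro step-size tuning
during the tune phase only (draws are taken with a frozen kernel). The
default settings mirror the published protocol — 8 chains, 5,000 tune and
5,000 draw steps each ("5,000 tune and draw" is read as 5,000 each; it is
configurable), target acceptance 0.8 — and a `"test"` preset (4 chains,
1,000/1,000, target 0.35, the random-walk optimum) keeps pipelines fast.
Split R-hat, a basic autocorrelation ESS and acceptance rates are recorded
on every run; R-hat > 1.1 flags the result rather than failing silently.

Priors: a preliminary run (1,000 tune/draw) under log-uniform priors
spanning 1e-10 to 1e3 on every parameter is condensed into a truncated
log-normal centred on the preliminary medians with scale 3× the
preliminary spread (floored at 0.5 on the log scale) — "weakly
informative" while honouring the stated global range. The functional form
is not given in the source; log-normal is this package's choice. The
fallback to broad priors triggers on preliminary R-hat > 2, any log-scale
posterior sd > 3 (a flat likelihood, e.g. an all-survive dataset), or
non-finite summaries.

`posterior_predict()` propagates posterior draws through the solver and
samples counts through the same interval construction as the likelihood,
so the reported 95% intervals include binomial sampling noise — the level
and the inclusion of sampling noise are EFSA-practice choices the source
leaves implicit.

## Performance metrics

PPC: percentage of observations inside their predicted uncertainty limits,
boundaries inclusive. NRMSE: RMSE of posterior-predictive medians over the
mean of *all* observations (controls included). SPPE: per-replicate
`100 (observed - predicted)/n0` at the last timepoint, reported with
dataset-level min/max. The SPPE sign is implemented exactly as the formula
reads; under it, a model that predicts too many survivors produces a
negative value. The prose convention ("negative = underestimation of
effects") is a statement about effects, not survivors, and is documented
rather than re-coded.

## Synthetic data

`make_design()` emulates the standard regulatory layouts: geometric
concentration ladder around 1 TU plus control (5 levels × factor 2 →
0.25–4 TU by default), ≥3 replicates of 10 individuals, observations at
6 h (acute) then daily, horizons of 2 d (acute default; extendable to 10 d
as used in the recovery tests) or 10 d (chronic), 1-h contact pulses and
6-h feeding windows. `simulate_dataset()` draws deaths from exactly the
multinomial interval distribution the likelihood assumes. That guarantees
the parameter-recovery tests are well-specified — and means a green
recovery test establishes correctness of the inference machinery, *not*
robustness to the overdispersion, frailty or dependence structure real
replicates may show. Background mortality defaults to hb = 0.02/d in the
test fixtures, a realistic nonzero control mortality for caged bees over
10 d (~18% control mortality).

## Known limitations

- No multi-route joint calibration, mixtures, time-varying `hb`, or full
  GUTS with measured residues.
- The random-walk sampler needs the MAP initialization to mix well within
  the reduced preset; pathological posteriors (all-survive data, extreme
  overdispersion) fall back to broad priors and flagged diagnostics rather
  than refusing to run.
- IT and SD fits are only as comparable as their shared exposure input;
  BeeGUTS-mode profiles are provided for benchmarking, not re-fitted
  against the published bee parametrizations.
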