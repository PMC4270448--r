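---
title: "Kinetic and binding analysis of junction-resolvase gel assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic and binding analysis of junction-resolvase gel assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resolvr)
```

`resolvr` analyses the three gel readouts that characterize a Holliday
junction-resolving enzyme: cruciform cleavage time courses, single-turnover
strand-cleavage progress curves, and equilibrium binding titrations, plus
the dimer-mixing band pattern. This vignette is the package's account of
those models — their assumptions, the parameters that matter, the numerical
choices, and what the accompanying synthetic-data generator does and does
not establish about real data.

## The consecutive-cleavage model

A cruciform is a four-way junction extruded from an inverted repeat; it is
stable only under negative supercoiling, so a single nick anywhere in the
plasmid collapses it. That physics makes a supercoiled cruciform plasmid a
recorder of cleavage order on an agarose gel: supercoiled substrate S runs
fastest, a unilateral cut gives nicked circle N, a second cut within the
lifetime of the bound complex gives linear L. The kinetic scheme is two
irreversible first-order steps,

$$\mathrm{d}S/\mathrm{d}t = -k_1 S, \qquad
  \mathrm{d}N/\mathrm{d}t = k_1 S - k_2 N, \qquad
  \mathrm{d}L/\mathrm{d}t = k_2 N,$$

whose closed-form solution from the pure-supercoiled initial state is
implemented in `cruciform_fractions()`. No attempt is made to distinguish
*which* strand is cut first; `k1` is, by convention, the rate attached to
the supercoiled-decay observable (`fS = e^{-k_1 t}` pins it uniquely, which
is also what makes the fit safe against label swapping). The ratio
`k2/k1` — the second-strand acceleration — is the mechanistically
interesting number: a ratio well above 1 means bilateral resolution is
kinetically guaranteed before the enzyme dissociates.

Assumptions worth stating: both steps are irreversible and first order
(enzyme is in excess and complexes do not dissociate mid-course); there is
no uncleavable substrate fraction, i.e. the trajectory starts at exactly
(1, 0, 0). `fit_cruciform()` keeps that fixed initial condition as the
default because the agarose assay gives no leverage to estimate a separate
amplitude; relaxing it would trade bias for variance on 10-lane data.

### Numerical choices

- **Degeneracy.** The textbook `fN` expression divides by `k2 - k1`. We
  switch to the confluent limit `k1 t e^{-k1 t}` when
  `|k2 - k1| < 1e-8 * max(k1, k2)`; the branch point is continuous to
  better than `1e-8`, and the threshold is far below any uncertainty data
  could support.
- **Oracle.** `cruciform_ode()` integrates the same system numerically
  (`deSolve::ode`, lsoda, rtol `1e-10`). The two routes agree to `1e-6`
  absolutely across four orders of magnitude of rate pairs; the tests use
  this agreement as the correctness oracle for the closed form, including
  its limit branch.
- **Fitting.** Unweighted least squares, jointly over the stacked residuals
  of all three species (a sequential option — `fS` first, then `k2` with
  `k1` frozen — exists; on clean data they coincide). Positivity is
  enforced by optimizing `log k1, log k2` (Levenberg–Marquardt via
  `minpack.lm`). Starts are data driven — `k1` from the log-slope of the
  supercoiled trace, `k2` from the reciprocal of the observed
  nicked-peak time — plus a fixed factor-of-10 multistart schedule, so the
  fit is deterministic with no seed dependence.
- **Renormalization.** Band intensities are converted to fractions per
  lane before fitting (this also cancels lane-loading variation).
  Fractions outside [0, 1] arising from noise are *not* clipped before
  fitting; clipping is available only as an output option for plotting,
  because truncation biases least squares.

## Single-turnover strand cleavage

Under single-turnover conditions (enzyme in excess), the cleaved fraction
of a labelled strand follows `F(t) = F_f (1 - e^{-k_c t})`
(`exp_progress()`), with `F_f` the final cleaved fraction absorbing any
inactive substrate. `fit_exponential()` estimates both on the log scale
with the same multistart policy; its start comes from the log-linearization
`-ln(1 - F/F_f)`. Amplitude and rate separate cleanly: scaling the data
scales `F_f` and leaves `k_c` untouched, which the tests assert.

Rates in this assay are conventionally quoted in s^-1 while cruciform
rates are quoted in min^-1. Every rate in the package therefore carries an
explicit unit tag, and `convert_rate()` is the only conversion path —
units are never inferred from magnitudes.

## Equilibrium binding

Gel-shift titrations of a junction at tens of pM against protein at
pM–nM mean bound protein depletes the free pool: the hyperbola is wrong by
construction, and the exact quadratic root

$$f_b = \frac{(K_d + P_t + D_t) - \sqrt{(K_d + P_t + D_t)^2 - 4 P_t D_t}}{2 D_t}$$

is required (`depletion_isotherm()`). Two numerical points: the minus
branch is the physical root (the plus branch exceeds 1), and it is
evaluated in the conjugate form `2 P_t / (b + sqrt(b^2 - 4 P_t D_t))`,
which is exact algebra but does not cancel catastrophically when
`4 P_t D_t \ll b^2`, as happens at the pM end of a titration.

Cooperative binding is described by the Hill isotherm
`f_b = P_t^n / (P_t^n + K_{app})` (`hill_isotherm()`). Two caveats are
deliberately surfaced rather than papered over. First, `K_app` enters
un-exponentiated, so its unit is concentration^n; the interpretable
half-saturation concentration is `K_app^{1/n}`
(`hill_half_saturation()`). We implement the printed convention and expose
the transform instead of silently switching to the `K_d^n` parameterization.
Second, whether a titration's protein axis counts monomers or dimers is an
experimental convention; `binding_titration()` records the declared flag
and never converts, because a silent factor of two in `P_t` is a silent
factor of two in `K_d`.

`fit_binding()` refuses all-free and all-bound titrations as
unidentifiable rather than returning an edge estimate. `compare_models()`
reports ΔRSS and a small-sample corrected information criterion (AICc on
the Gaussian RSS likelihood, the error variance counted as a parameter);
it declares a preference, not significance. On simulated cooperative data
(`n = 2`, 3% noise) the Hill model is preferred in ≥95% of replicates; on
simulated two-state data, parsimony favours the two-state model in the
majority.

## Dimer stoichiometry

`predict_complex_fractions()` formalizes the mixing test for dimeric
binding: complexes assembled from a mixture of native (A) and size-shifted
fusion (B) subunits produce three bands with binomial weights
`(p^2, 2p(1-p), (1-p)^2)` where `p = concA/(concA + rho * concB)`. The
single parameter `rho` captures unequal incorporation (a fusion that binds
more weakly has `rho < 1`, shifting mass toward the native homodimer); the
model otherwise assumes independent subunit assortment — no preferential
homo- or heterodimerization — which is all the three-band argument needs.
`rho` acts at incorporation, not at DNA binding: one parameter, one
mechanism, documented rather than guessed further.

## The synthetic-data generator

The generators (`simulate_cleavage_course()`, `simulate_cruciform_course()`,
`simulate_titration()`) stand in for gel densitometry tables with known
ground truth. They emulate: additive Gaussian band noise on the fraction
scale (default sd 0.03, chosen once as typical phosphorimager scatter), an
optional log-normal lane-loading factor for cruciform gels (sdlog 0.05
when enabled; off by default) that the per-lane renormalization then
cancels exactly as it does for real gels, schedules that mirror the
experimental designs (11-point geometric protein grid from 0.043 to 44 nM
against an 0.082 nM junction; 12 points over 600 s for strand cleavage; 10
lanes over 120 min for the cruciform course, sampled densely at early
times because the nicked intermediate peaks near 13 min at the default
rates and a uniform grid would all but miss it), and full determinism
under a recorded seed with the ground truth embedded in the output
metadata.

They do *not* emulate: Poisson counting noise of radioactive detection,
gel background and band-overlap artifacts, pipetting error in the protein
dilution series, or any systematic mis-calibration of the densitometry.
Passing recovery tests therefore demonstrate that the estimators are
correct and well-conditioned at realistic noise and design density — not
that every real gel will behave this well.

## Problem sizes and measured behaviour

The recovery and discrimination properties in the test suite run at the
designs above: 200 seeded replicates for parameter-recovery medians and
model discrimination, 100 replicates for bootstrap coverage, 100
random rate pairs spanning four orders of magnitude for the
analytic-vs-ODE oracle checks. Two measured results deserve honest
statement:

- **`k2` at 3% noise is information-limited.** The nicked intermediate
  never exceeds ~7% of the material at the default rates, so band noise of
  0.03 leaves the median relative error of `k2` at ~11% on a 10-lane
  course — just above the 10% the other parameters comfortably meet
  (`k1` ~2%, `k_c` ~3%, `K_d` ~4%), and near the Cramér–Rao floor of the
  unweighted estimator. More lanes or lower noise fix this; re-weighting
  the fit would trade transparency for a marginal gain.
- **Percentile bootstrap undercovers at gel-sized n.** With 11 titration
  points, nominal-95% percentile intervals from `bootstrap_ci()` cover the
  truth ~80–85% of the time even with the `sqrt(n/(n-p))` residual
  inflation applied. This is the familiar small-sample behaviour of the
  percentile method; treat the intervals as honest summaries of fit
  stability, not calibrated frequentist coverage.

## Known limitations

Branch migration, junction structure, supercoiling energetics and the
monomer-bound intermediate seen in metal-free (EDTA) binding conditions
are outside the models. The cruciform fit cannot resolve which strand is
cut first. The Hill and depletion isotherms are alternative descriptions,
not a single linked monomer⇌dimer⇌junction equilibrium model; fitting such
a scheme would need data the gel assays do not provide.
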