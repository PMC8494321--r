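---
title: "Grey-box modelling of cerebrovascular reactivity to tDCS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grey-box modelling of cerebrovascular reactivity to tDCS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nvucvr)
```

This vignette documents the model, the estimation procedures, the numerical
choices, and the design decisions behind the package. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. The nonlinear neurovascular-unit model

The core is a lumped model of the neurovascular unit with four compartments —
synaptic space, astrocyte, perivascular space and arteriolar smooth muscle
cell (SMC) — terminating in a Kelvin–Voigt vessel wall whose state `x` is the
mean circumference (µm). There are exactly 17 states (see
`nvu_state_names()`): synaptic potassium; astrocytic IP3, calcium, IP3R
inactivation gate, TRPV4 open probability, EET concentration, BK open
probability and membrane potential; perivascular potassium and calcium; SMC
KIR gating, membrane potential, K-channel gating and calcium; cross-bridge
fraction, contractile-element length, and circumference.

The equation structure follows the bidirectional astrocyte–microvessel model
lineage (Witthoft & Karniadakis 2012; Farr & David 2011; the SMC
electrophysiology is of the Gonzalez-Fernandez & Ermentrout type). Parameter
values are either literature values from that lineage or design values chosen
so that the unforced system has a stable resting point representing a ~10 µm
radius arteriole with moderate tone; `nvu_parameter_table()` tags every
constant as `lineage-default` or `design`. Native units are kept throughout
(s, mV, nS, pA, nF, mM for potassium, µM for calcium, µm for circumference);
conversions happen only at I/O boundaries.

**Feedforward cascade.** By default the compartments form a strict
feedforward chain: synaptic space → astrocyte → perivascular space → SMC →
wall. The one mechanism that would close a loop from the vessel back to the
astrocyte — TRPV4 gating by wall strain — is present in the equations but its
gain (`trpv_strain_gain`) defaults to zero. The package's hypothesis-testing
framework rests on the four perturbation pathways being *nested*: injecting
at a downstream site must excite exactly the downstream subsystem. With the
cascade, the minimal realizations of pathways 2–4 have exactly 10, 8 and 6
states (the test suite asserts this), matching the nested structure of the
reference transfer functions; with strain feedback every state becomes
reachable from every input and the nesting is only approximate. Users who
want the fully bidirectional variant can set `trpv_strain_gain > 0`.

Two further structural choices keep the cascade exact: the SMC KIR gating
variable responds to perivascular potassium only (its voltage dependence is
carried by the instantaneous driving-force term), and the KIR contribution to
the perivascular potassium balance is evaluated at the SMC reference
potential (`V_smc_ref`), because a voltage-dependent flux there would create
an upstream-directed coupling. Both are small-signal approximations around
the operating point where the affected excursions are of the order of a
millivolt.

**Effective time scales.** Channel gating variables in this class of model
lump several molecular processes. The BK variable is treated as the effective
endfoot signalling stage (its activation is shifted by EET and it drives the
perivascular potassium release); its rate `phi_bk = 0.1/s` is set on the
seconds scale of astrocytic endfoot signalling rather than the millisecond
scale of single-channel gating. This is also what gives the four pathway
hypotheses distinct in-band dynamics: pathway 3 and 4 responses do not
traverse the BK stage, so the choice shapes only the competing models.

**tDCS input.** The scalp current is mapped to a compartmental perturbation
by the first-order vasoactive filter `K_i/(tau s + 1)` with `tau = 20` ms
(passive membrane time constant) and an arbitrary lead-field gain `K_i`. The
four pathway perturbations are additive: extra synaptic K+ flux (mM/s),
astrocytic transmembrane current (pA, divided by `C_astr`), perivascular K+
flux (mM/s), or SMC channel current (pA, divided by `C_smc`). Positive gain
is the excitatory/anodal convention; for pathway 4 a *negative* gain
(hyperpolarizing the SMC) produces dilation.

**Integration.** The system mixes ~10 ms membrane dynamics with ~10 s wall
mechanics, so `nvu_simulate()` uses the backward-differentiation stiff solver
(deSolve) on a compiled C derivative core; the pure-R `nvu_derivatives()` is
the readable reference implementation and the two are compared elementwise
(1e-10 relative) in the tests. Default tolerances are `rtol = 1e-8`,
`atol = 1e-10`, recorded in every trajectory object. Probabilities are not
clamped during integration; excursions beyond [0,1] by more than 1e-6 at the
equilibrium raise errors rather than being masked.

**Operating point.** `nvu_find_equilibrium()` runs a damped Newton iteration
with a central-difference Jacobian; if it fails, it falls back to a 300 s
unforced settling simulation, and if the tail still cycles it returns the
cycle mean flagged `oscillatory = TRUE`. With the default parameters the
baseline is a genuine stable fixed point (Newton residual below 1e-9 in the
tests), so the flag is `FALSE`; the flag exists because models of this
lineage can sit in a vasomotion (limit-cycle) regime, and linearizing at a
cycle mean is then a documented approximation the caller must opt into.

## 2. Linearization

`nvu_linearize()` computes the whole-system Jacobian at the operating point
by central finite differences with per-state scaled steps (relative step
1e-6). A literal compartment-by-compartment linearization combined
afterwards is mathematically identical at a shared operating point; the
compartment structure is kept as state-label metadata instead. Jacobian
entries below 1e-8 of the largest entry are set to exact zero: they are
finite-difference noise on structural zeros (the smallest genuine coupling
is about 1e-5 of the largest entry), and zeroing them preserves the exact
cascade sparsity on which the structural Kalman reduction and the
pole/zero-count checks rest.

Transfer functions are extracted with poles from `eigen(A)` and transmission
zeros from the Rosenbrock system pencil via the QZ algorithm (compiled
through RcppArmadillo). Polynomial routes (characteristic polynomial plus
root finding) are avoided: with pole spreads of 1e4–1e6 they lose the slow
roots. Near pole-zero cancellations are removed at a relative tolerance of
1e-7, which is what makes `to_transfer_function()` return the minimal
transfer function of a structured model directly. Zero extraction is most
reliable in the original (structured) coordinates, so the function applies
the exact structural reduction internally before forming the pencil.

## 3. Prediction-error fitting

`pem_fit()` fits the cascaded stimulus-to-tHb model (input filter in series
with a pathway model) to a normalized tHb series. The free parameters are:

- `gain` — the lead-field gain `K_i`. It enters linearly, so it is
  concentrated out in closed form (separable least squares).
- `rate` (optional) — a common multiplier on the pathway state matrix, i.e. a
  shared time-scale of the physiological rates, found by bounded golden
  search on the log scale. Any positive rate preserves Hurwitz stability, so
  every candidate during the search is stable by construction; boundary
  solutions are flagged `converged = FALSE` and still returned as
  best-so-far.
- `tau` (optional) — the vasoactive filter time constant, fixed at 20 ms by
  default since it is not well identified from 10 Hz band-limited data.

This parameterization replaces a generic trust-region nonlinear least
squares with multi-start: the problem is one-dimensional (or
two-dimensional) after the gain is concentrated out, which is strictly
better conditioned and cannot return an unstable model. Standard errors for
gain and rate come from the output Jacobian at the optimum
(`sigma^2 (J'J)^-1`); the tests check the empirical coverage against the nominal 95% level
on simulated data.

**Prefiltered errors.** The measured tHb is band-limited by the
preprocessing chain, and the 0.01 Hz zero-phase high-pass reshapes a
600-second stimulation protocol substantially (it removes the sustained
plateau and creates non-causal precursors). The prediction error is
therefore formed *after* passing the model output through the identical
filter over the identical record length, with the identical baseline-mean
subtraction (the `prefilter` argument; `run_study()` constructs it
automatically). Filtering both signals with the same stable filter is the
standard prefiltered-PEM device and leaves the estimator consistent.

**Scores.** `mse` is the mean squared prediction error on the normalized
series; because the pipeline normalizes each series by its post-onset peak,
the MSE is invariant to consistent rescaling of the raw recording (tested).
The information criterion is the normalized form
`AIC = log10(mse) + 2 k / N`. The log-MSE form is an interpretation — the
exact convention behind published AIC values of this kind is typically not
printed — chosen because it is dimensionless, monotone in the MSE at fixed
order, and lives on the O(1) scale on which such medians are reported.
Residual checks (`residual_diagnostics`) report autocorrelation and
input–residual cross-correlation over ±25 lags with 99% bands at
±2.576/√N and the fraction of lags inside the bands.

**Hypothesis testing uses the gain only.** `run_study()` fits each pathway
with `free = "gain"` by default: the four hypotheses are the physiologically
parameterized models themselves, and the only subject-level unknown is the
arbitrary lead-field gain. Freeing a common rate multiplier is available but
weakens the test: inside the 0.01–0.05 Hz band, a time-scale dilation lets a
wrong pathway mimic much of the true pathway's response, and the hypotheses
become statistically indistinguishable at realistic noise levels. This is a
deliberate reading of the grey-box idea — structure is the hypothesis, not a
free parameter.

## 4. Reduction and fixed-order estimation

`balanced_truncate()` implements square-root balanced truncation; the
reported error bound is twice the sum of the discarded Hankel singular
values, verified on random stable systems in the tests and in the acceptance
suite. `minimal_realization()` first performs an exact structural Kalman
reduction (graph reachability on the sparsity pattern from the input support
and to the output support — exact for a deviation model) and then truncates
states below a 1e-12 relative Hankel threshold.

`reference_pathway_tf()` returns the package's reference parameterization of
the four nested minimal-realization transfer functions in factored form,
with 11/3, 10/3, 8/2 and 6/1 poles/zeros. The factored forms contain a very
fast pole (about 1e7 rad/s) and similar far zeros; impulse responses are
therefore computed by matrix-exponential stepping of a first/second-order
section-cascade realization (`impulse_response`), which handles the
conditioning without removing the factors. The Matrix package's expm (Ward's
balanced Padé) is used: on these stiff non-normal cascades a naive
scaling-and-squaring implementation can fail badly. Peak times are refined
by quadratic interpolation around the discrete maximum of the normalized
response; a peak at the horizon raises a boundary warning.

`tf_estimate()` fits a fixed pole/zero-count transfer function by
Levenberg–Marquardt on the simulation error. Stability is built into the
parameterization: real poles as −exp(θ), complex pairs by log natural
frequency and log damping; zeros and the gain are unconstrained. The
initialization comes from the nested reference models (balanced-truncated to
the requested order when needed). The chi-square goodness of fit is defined
as the residual sum of squares divided by the output sum of squares about
its mean — a normalized, dimensionless quantity on the same scale as
published values of this kind; this formula is an interpretation and is
flagged as such. `compare_nested()` walks the nested orders from the
smallest up and selects the first model that the next larger one does not
significantly improve upon (difference statistic
`(RSS_s − RSS_l)/(RSS_l/(N − k_l))` on `k_l − k_s` degrees of freedom,
default α = 0.05). With data generated by the 9/2 cascade, the 7/1 form can
reproduce the in-band response almost exactly — its far poles contribute
nothing below the Nyquist frequency — so ties resolved toward the smaller
order are expected and the tests treat them as correct behaviour.

## 5. fNIRS preprocessing

The fixed stage order is: tHb construction → PCA systemic removal →
zero-phase band-pass → baseline subtraction and maximum normalization →
anti-correlation QC → (ensemble averaging). Design choices:

- **Filter.** Order-3 Butterworth applied forward–backward, as a cascade of
  a high-pass and a low-pass section (better conditioned at normalized
  cutoffs of 0.002 than a single narrow band-pass design). The series mean
  is removed before filtering: the high-pass eliminates DC anyway, and a
  large offset (tens of µM in raw concentration data) otherwise produces
  severe forward–backward edge transients inside the baseline window.
- **PCA removal.** One spatial component by default. The spatial basis is
  estimated on the pre-onset baseline and centered at baseline means, then
  the projection is applied to the whole record. Estimating the basis on the
  full record would let the evoked response dominate the leading component
  and be removed with it. Even with the baseline basis, the projection
  removes the part of the response that lies along the global spatial mode —
  a known cost of montage-wide PCA; with the response confined to 4 of 32
  montage channels the attenuation is modest.
- **Normalization.** After baseline-mean subtraction the series is divided
  by the maximum *absolute* post-onset value, so initial-dip records
  normalize to −1 and are flagged (`negative_peak`) instead of being blown
  up by a near-zero positive maximum.
- **QC.** Pearson correlation between regional oxy and deoxy series over the
  600 s stimulation window; pass iff r < −0.5. In the generator, the
  anti-correlation of healthy records is carried primarily by the
  differential response itself (oxy rises, deoxy falls) plus a spontaneous
  anti-phase component; common-drive records violate it by construction.

The order PCA-then-band-pass is one of the two defensible orders; both
stages are linear, so on the systemic sinusoids they commute to numerical
precision (tested for the filter/averaging pair), and the choice is exposed
through the function interfaces.

## 6. The synthetic cohort

`cohort_spec()` fixes the study conditions: 11 subjects, two regions
(targeted and nontargeted), 120 s baseline + 600 s stimulation at 10 Hz,
2 mA trapezoid with 30 s ramps. Ground truth per subject and region is a
*nonlinear* NVU simulation under the region's true pathway (3 under the
stimulation site, 4 contralaterally) and a subject-specific lead-field gain,
mapped to tHb at 1 µM per µm of circumference deviation (the small-change
blood-volume assumption). The oxy/deoxy split is differential —
`oxy = (1−λ)·tHb`, `deoxy = λ·tHb` with λ = −0.2 — so the two chromophores
sum to the ground truth exactly while being anti-correlated. Contamination
comprises Mayer (2.0 µM at 0.1 Hz), respiratory (0.3 µM, 0.25 Hz) and
cardiac (0.4 µM, 1 Hz) sinusoids with subject-specific phases shared across
all channels (a global spatial mode, which is what the PCA removal targets),
a slow drift, white channel noise (0.1 µM), and a region-specific anti-phase
component (0.15 µM). Three of eleven subjects are generated in a
common-drive regime — both chromophores ride the same slow drive and the
vessel drive receives a negative early transient (an initial dip built from
the difference of two first-order responses, 5 s and 25 s) — and exactly
these subjects must fail the QC.

Chosen study conditions worth stating explicitly:

- **Gains** are log-normal with median 0.02 and σ_log = 0.2. This keeps every
  subject in the small-signal regime (peak circumference change of 2–4%,
  where the linear approximation error is a few percent of the response). At
  roughly three times these gains the KIR activation sigmoid and the
  Hill-type contraction curve make the response visibly nonlinear, which
  biases pathway selection toward slower candidate models — a real
  phenomenon, but not the regime the linear hypothesis test assumes.
- **The contralateral gain** is scaled by 0.25: the nontargeted response is
  weak, consistent with reports of minimal contralateral changes, and this
  also limits how much of the contralateral response the montage-wide PCA
  can fold into the targeted series.
- **The montage** has 4 analysis channels plus 12 background channels per
  hemisphere; background channels carry the systemic physiology and the
  anti-phase component but no evoked response, as the channels away from the
  stimulation site largely do.

What the generator does *not* emulate: motion artifacts and their wavelet
correction, optical-density conversion (inputs are already concentration
changes), short-separation channels, spatially heterogeneous systemic
loadings, vasomotion limit cycles, or any neuroplastic after-effects beyond
the modelled window. Passing the end-to-end tests therefore demonstrates
that the pipeline recovers the truth under its own stated assumptions, not
that it would do so on arbitrary real recordings.

## 7. The study driver and its scale

`run_study()` preprocesses each record, fits all four pathway models per
region (gain-only by default), tabulates MSE/AIC, selects the pathway per
region by lowest median AIC with median MSE as tie-break, and (optionally)
fits the four fixed-order transfer functions to the QC-passing subjects'
ensemble average with the nested chi-square comparison. Reports are
deterministic given the cohort spec and seed; `write_study()` exports the
fit and QC tables as TSV plus a JSON report with provenance (configuration,
seed, package version, config hash).

Problem sizes used by the test and acceptance suites — a 150 s fit window at
10 Hz (N = 1501), 50-replicate Monte-Carlo recovery and selection
experiments, 20 cohort seeds for the end-to-end selection, 100 random
systems for the reduction bound, and 8 replicates of the heavier
nested-order experiment — were chosen so the full suite runs in a few
minutes while keeping the binomial margins of the pass thresholds
comfortable.

## 8. Known limitations

- The 17-state parameter set is a reconstruction from the source-model
  lineage, not a verbatim copy of any published supplementary table; the
  provenance column in `nvu_parameter_table()` makes the distinction
  auditable.
- Minimality of a balanced (dense) realization is tolerance-dependent;
  pole/zero counts should be read from structured realizations, which is
  what `to_transfer_function()` does internally.
- The AIC and chi-square goodness-of-fit conventions are documented
  interpretations; published values of these quantities on real recordings
  are not reproducible without the recordings themselves.
- With a freed rate multiplier the four pathway hypotheses are nearly
  unidentifiable from band-limited 150 s records; the package exposes the
  option but the default study design does not use it.
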