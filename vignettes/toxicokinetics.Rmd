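---
title: "Compartment-model toxicokinetics for waterborne exposure of zebrafish larvae"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartment-model toxicokinetics for waterborne exposure of zebrafish larvae}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvatk)
```

## The problem

Zebrafish (*Danio rerio*) larvae are exposed to drugs through the water, not
by injection or feeding, so the externally applied concentration says little
about the dose the animal actually experiences. Interpreting toxicity or
behavioural responses therefore requires toxicokinetics: how fast a chemical
is taken up, where it distributes, and how fast it leaves. For basic
(cationic) psychoactive drugs such as meta-chlorophenylpiperazine (mCPP),
two features dominate the picture in larvae: uptake is far faster than
passive lipid partitioning predicts (pointing to active transport), and a
large share of the body burden sits in the melanin-rich eye, which releases
the drug only slowly. `larvatk` packages the models and analyses needed to
quantify both.

## Models

### One-compartment model

The whole larva is a single well-mixed compartment exchanging with the
water:

$$\frac{d}{dt} C_\mathrm{int}(t) = k_\mathrm{in}\, C_w(t) - k_\mathrm{out}\, C_\mathrm{int}(t)$$

with $C_\mathrm{int}$ in mg/kg wet weight, $C_w$ in mg/L, $k_\mathrm{in}$
in L kg⁻¹ h⁻¹ and $k_\mathrm{out}$ in h⁻¹. The exposure regime is encoded
by `exposure_scenario()`: $C_w$ constant at `c_w` for `t_uptake` hours,
then exactly zero. Treating the bath as constant is justified because test
solutions are renewed and the bath volume vastly exceeds larval mass, so
larval uptake does not deplete it. Under this forcing the model has a
closed form — saturating exponential rise during uptake, single-exponential
decay during depuration — which `simulate_one_compartment()` evaluates
directly; `method = "ode"` integrates the differential equation with
`deSolve::lsoda` (rtol 1e-10, atol 1e-30) as an independent numerical path.
The steady-state ratio $k_\mathrm{in}/k_\mathrm{out}$ is the kinetic
bioconcentration factor (BCF, L/kg), computed by `compute_bcf()`.

### Eye / rest-of-body model

Because the eye accumulates basic drugs through melanin binding, a single
compartment cannot describe both the whole-body curve and the tissue data.
The multi-compartment model gives the eyes and the rest of the body their
own rate constants, each compartment exchanging only with the water — there
is no eye-to-body flux term, mirroring how the governing equations are
defined. The whole-body concentration is the weight-weighted mean

$$C_\mathrm{larvae} = \frac{C_\mathrm{eyes} W_\mathrm{eyes} + C_\mathrm{rest} W_\mathrm{rest}}{W_\mathrm{eyes} + W_\mathrm{rest}},$$

which conserves chemical mass exactly (`combine_whole_body()`). A slow eye
compartment combined with a fast rest compartment makes the whole-body
depuration curve biphasic — fast early decay dominated by the body, slow
late decay dominated by the eye reservoir.

### Passive-partitioning baseline

`predict_passive_rates()` computes what the rates *would* be if uptake and
elimination were pure passive partitioning, using the classic fish
gill-uptake kinetic formulation: gill uptake efficiency
$E_W = 1/(1.85 + 155/K_\mathrm{ow})$, ventilation scaling with body
weight$^{0.65}$ and dissolved oxygen, and elimination by the reverse route
so that the implied steady-state BCF is exactly
$L_B \times K_\mathrm{ow}$ (lipid fraction times the partition
coefficient). All coefficients live in a versioned JSON config
(`inst/extdata/passive_coefficients.json`), not in code. The point of this
baseline is not point accuracy — allometric coefficients calibrated on
juvenile/adult fish are being extrapolated to a 360 µg larva — but the
order-of-magnitude gap: at the defaults the passive BCF for mCPP is
5.7 L/kg against a measured kinetic BCF of ~450 L/kg, and the predicted
8-h whole-body level is tens of fold below what the fitted model
reproduces. That gap is robust to any plausible coefficient choice and is
the quantitative argument for active transport and melanin binding.

## Estimation

Both fitters minimise unweighted least squares on the concentration scale
with the Levenberg–Marquardt algorithm (`minpack.lm`), jointly over uptake
and depuration. Nothing in the source data indicates a variance model
beyond roughly constant CV; the raw scale keeps the fit anchored to the
high-information uptake plateau, and a log-scale objective is available via
`log_scale = TRUE` for users who prefer equal relative weighting.
Replicates are pooled to per-time means before fitting, matching a design
in which each observation is already a pooled homogenate. Starting values
are data-driven — $k_\mathrm{out}$ from the terminal log-linear depuration
slope, $k_\mathrm{in}$ from the earliest uptake point — so no hand-tuned
starts are needed. The multi-compartment fit stacks eye residuals and
combined whole-body residuals with equal weight (configurable) and
optimises on the log-parameter scale to keep rates positive; standard
errors come from the Jacobian at the optimum, delta-transformed back.
The one-compartment whole-body fit and the multi-compartment fit are kept
strictly independent: the whole-body $k_\mathrm{in}$ is *not* constrained
to equal the weight-combined eye/rest value, because the two models are
alternative descriptions of the same data, not a hierarchy.

## Biphasic half-life estimation

The depuration data themselves, model-free, show two exponential phases.
`biphasic_half_lives()` fits two log-linear segments to ln(concentration)
versus time since transfer to clean water, scanning every interior observed
time point as the candidate breakpoint and keeping the split with minimal
total SSE — an exhaustive scan, so no optimiser can miss the global
optimum. The breakpoint observation belongs to both segments; SSE ties
break toward the earlier breakpoint (a conservative, shorter initial
phase). Each phase's half-life is $\ln 2 / |\mathrm{slope}|$. Two
numerical guards: non-positive concentrations cannot enter a log
regression and are dropped with a warning rather than imputed, and when the
two slopes differ by less than 5% (relative) the series is flagged
degenerate — genuinely single-exponential data produce two equal
half-lives, and the flag says so rather than inventing a second phase.
Pooled per-time means are the default unit of analysis, with a
per-replicate option, since the source depuration curves are means of
pooled larvae.

A note on reported half-lives: for the eye/rest model the package reports
$\ln 2 / k_\mathrm{out}$ exactly (13.9 h for $k_\mathrm{out}$ = 0.05 h⁻¹,
52 min for 0.8 h⁻¹). Published roundings of such values (13 h, 48 min)
differ slightly; the package does not force agreement and documents the
definitional value.

## Dose–response and internal dose

`fit_4pl()` fits the standard four-parameter logistic (variable-slope)
curve to response proportions by least squares, the convention of the
dose–response software this field uses, with a binomial-likelihood option.
Data that are all-0% or all-100% carry no location information and are
rejected as non-estimable rather than silently extrapolated; EC50
confidence limits use a normal approximation on log₁₀(EC50), and an
interval spanning more than two decades triggers an explicit warning.

`internal_dose_metric()` converts an external effect concentration to an
internal molar body burden as mmol/L × BCF (L/kg) → mmol/kg. This is a
documented approximation: published internal-dose metrics (ILC50, IEC50,
INTC) vary in their exact convention, so outputs carry an `approximate`
attribute and analyses should rely on ratios between compounds, which are
insensitive to the convention.

## Key parameters and defaults

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `molecular_weight`, `log_p`, `p_ka` (mCPP) | 196.68, 2.06, 8.87 | g/mol, –, – | the study compound's descriptors |
| `c_w` | 0.98 | mg/L | 5 µM exposure converted by MW |
| `t_uptake`, `t_depuration` | 8, 48 | h | the study's exposure schedule |
| `larva_weight_ug` | 360 | µg | measured mean 5–7 dpf wet weight |
| `eye_mass_fraction` | 0.10 | – | dissected eye weights are not published; 0.10 places the combined whole-body level (≈368 mg/kg at 8 h from eye 2100 / rest 175) consistent with the measured ~308 mg/kg, and is overridable everywhere |
| `lipid_fraction` | 0.05 | kg/kg | typical larval zebrafish lipid content |
| `water_temperature_c` | 28 | °C | standard husbandry temperature |
| noise `cv` | 0.06 | – | matches the ~5–6% relative SD of pooled measurements (e.g. 308 ± 18 mg/kg) |
| `ph` (for logD) | none | – | deliberately has **no default**: the medium pH behind a published logD is often unstated (0.91 back-solves to pH ≈ 7.75; physiological 7.4 gives 0.58), so the user must say which pH they mean |

## What the synthetic data do and do not emulate

`gen_timecourse()`, `gen_tissue_panel()` and `gen_zfet_outcomes()` generate
data with the statistical structure the analyses assume: the model curve
(or group means, or 4PL response probabilities) plus mean-preserving
multiplicative lognormal noise at 6% CV, on the study's sampling grids
(uptake 0.25–10 h, depuration 1–48 h, 16 replicates; pools of 16 larvae;
10 embryos per concentration). Every generator is a pure function of
(parameters, seed): the caller's RNG stream is saved and restored.

They deliberately do **not** emulate: biotransformation (1–2% of parent
over the uptake window — small enough to ignore for the parent compound's
kinetics), bath depletion or renewal transients, inter-batch variability
beyond the single CV, measurement censoring near the quantification limit,
or growth over the experiment. Passing round-trip tests on these data
therefore demonstrates that the estimators are correct and well-calibrated
for the assumed data-generating process; they do not prove the
one-compartment or two-compartment structure is the right biology — that
case is made by the measured-vs-passive gap and the tissue data.

## Numerical choices

* Closed forms are the default solution path; the `lsoda` path exists to
  cross-check them (agreement well under 1e-6 relative where the solution
  is above numerical extinction) and the integrator stops at the forcing
  discontinuity rather than stepping across it.
* All internal maths is at full precision; rounding to printed precision
  happens only in display/report layers.
* Rates are constrained positive (box constraints in the one-compartment
  fit, log-parameterisation in the joint fit).
* Validation errors are a distinct condition class
  (`larvatk_validation_error`) and name the offending argument or row.

## Problem sizes

The test suite and the reproduction script use the study's own scales: 13
sampling times × 16 replicates for one-compartment recovery (100 stochastic
replicates for the bias study), 4 replicates for the joint eye/whole fit,
3–4 pools per panel group, and 9-concentration embryo tests at 10–50
embryos per concentration. The full suite runs in a few seconds.

## Limitations

* The eye mass fraction default (0.10) is an assumption, not a
  measurement; all eye-compartment concentrations in combined whole-body
  terms scale with it.
* The passive baseline extrapolates gill-based allometry to a pre-gill
  life stage (skin-dominated exchange); only its order of magnitude is
  meaningful, which is the use the package puts it to.
* Internal-dose metrics use the documented BCF approximation; absolute
  values should not be compared against metrics computed under a different
  convention.
* Exposure forcing is constant-then-zero only; arbitrary $C_w(t)$ profiles
  are out of scope.
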