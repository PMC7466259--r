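---
title: "Methods: response-surface optimization of a gradient HPLC separation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: response-surface optimization of a gradient HPLC separation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromrsm)
```

## The problem

Developing a multi-analyte HPLC method means choosing gradient and
mobile-phase settings under which every adjacent pair of peaks is
resolved while the run stays short. `chromrsm` implements the standard
statistical route: a three-level Box–Behnken design (BBD) over the
factors, second-order polynomial models for every response, and
importance-weighted desirability optimization to reconcile the competing
responses. The package is built around the published optimization of a
separation of seven food additives and caffeine, whose printed tables it
ships as fixtures and reproduces computationally.

## Design and coding

For three factors the BBD consists of the 12 midpoints of the cube's
edges — every pair of factors at (±1, ±1) with the third at 0 — plus
center replicates; with 3 centers, 15 runs. Factors are coded so that
−1/0/+1 map to the low/mid/high natural levels; all fits are on the
coded scale, so coefficient magnitudes are comparable across factors.
`build_bbd()` emits a canonical order (the (x1,x2), (x1,x3), (x2,x3)
blocks, each in (−,−), (−,+), (+,−), (+,+) order, centers last);
randomized run order is available through a seed but the analysis is
order-invariant.

## Responses

From a peak list, `response_row()` computes the resolution of each
adjacent pair, Rs = (t₂ − t₁)/(½(w₁ + w₂)), with w the *baseline*
(tangent) width — 4σ for a Gaussian peak — and the analysis time as the
last peak's retention time. Rs ≥ 1.5 is complete separation, 1.0–1.5
acceptable, below 1.0 poor (`classify_separation()`).

Two situations produce a fully-overlapped-peaks (`FOP`) marker instead
of a number: the two analytes sit inside one merged peak, or the
computed Rs falls below `fop_threshold` (default 0.2 — the data carry
no numeric rule for the label, so a small positive guard value is used
for "maxima indistinguishable"). For modelling, FOP cells are encoded
as 0 (`fop_encode()`). The packaged response table supports this
choice internally: the published constant for the TAR–CAF resolution is
0.000, and the full-quadratic intercept on a BBD provably equals the
center-replicate mean, whose three cells for that column are all FOP —
only a zero encoding is consistent with the printed value.

## Model fitting

`fit_full_quadratic()` fits the 10-term second-order polynomial by
ordinary least squares. OLS was chosen deliberately: a 10-parameter
polynomial on 15 runs is the universal response-surface practice, and
it carries an exact, testable identity — the center-replicate indicator
1 − (x1² + x2² + x3²)/2 lies in the model's column span for any 3-factor
BBD, so the fitted intercept equals the mean of the center responses
regardless of how the edge runs are labelled. The package's tests
assert this identity to 1e-9 on randomly generated data, and it is what
makes the printed model constants reproducible without knowing the run
order. One printed value, the analysis-time constant of 23.085, is
inconsistent with this identity (the center-replicate mean of the
packaged table is 17.833); no least-squares fit of the stated model can
produce it, and the package does not attempt to.

Per-term p-values are two-sided t tests on the residual degrees of
freedom (5 for the full model on 15 runs); for single-degree terms these
agree with the partial-F ANOVA. An interpolating (zero-residual) fit is
flagged degenerate and reports p = 0 for nonzero coefficients.
`reduce_model()` refits with only the terms significant at α,
intentionally *not* enforcing hierarchy (a quadratic term may survive
without its linear parent), which matches how such reduced predictive
equations are commonly reported. Goodness of fit is summarized by R²,
adjusted R², residual SE and MAE, all on the training data.

## Recovering the run assignment

The packaged response table lists responses per run but not the factor
settings per run (those were only shown graphically in the source).
`infer_run_assignment()` treats this as a linear assignment problem:
center replicates are detected as the mutually closest triple of rows
(after scaling each response to unit range), and the cost of assigning
edge run r to edge combination c is the squared prediction error of the
published models summed over responses. The minimum-cost bijection is
found exactly by dynamic programming over subsets (4096 states for 12
runs) — no approximate matching — with ties resolved toward the lowest
run taking the lexicographically smallest combination. The refit under
the recovered assignment reproduces the published per-response R²
values to the printed precision, which is strong evidence the recovered
assignment is the experimental one.

## Desirability optimization

Each response y is mapped to d(y) ∈ [0, 1] by a linear ramp
(`shape = 1`): resolutions are maximized, analysis time minimized. The
composite is the impact-weighted geometric mean
D = (Π dᵢ^wᵢ)^(1/Σwᵢ), with the conventional impacts 3 for every
resolution and 1 for time; any d = 0 annihilates D.

Anchor choice is the one genuinely open design decision, because the
original software's settings are not recorded. Two conventions are
implemented:

* `"separation"` (default): d ramps from 0 at Rs = 0 to 1 at Rs = 1.5.
  This encodes the chemistry — a fully overlapped pair is worthless, a
  baseline-separated pair is fully satisfactory, and resolution beyond
  1.5 buys nothing analytically. Under this convention the optimum of
  the packaged study is an interior point of the factor cube, close to
  the published optimal method.
* `"observed"`: each response anchored at its observed min/max over the
  design, the default of generic response-surface software. Under this
  convention the packaged study's composite pushes the initial-%B
  factor to its boundary — extra resolution far beyond 1.5 keeps
  earning desirability — which contradicts the published interior
  optimum; the convention remains available because it is the right
  choice when responses do not saturate in value (it is used, for
  instance, in the simulator recovery check below, where resolutions
  span far past 1.5 everywhere and a saturating ramp would be flat).

Time is always anchored at its observed range. `optimize_desirability()`
scans a deterministic lattice (default 201 points per axis, ~8.1M
evaluations) in lexicographic order and polishes the best cell with
Nelder–Mead (penalty-clamped to the cube, relative tolerance 1e-12).
Exact ties — constant surfaces — resolve to the lexicographically
smallest coded point; improvements below 1e-12 are treated as ties so
floating-point fuzz cannot override that rule. An everywhere-zero
desirability surface is returned flagged rather than as an error. The
full (10-term) models feed the optimizer by default; α-reduced models
are an option (`use_reduced = TRUE`), but a reduced model that dropped
all terms in one factor is flat along that axis and cannot place an
interior optimum there.

## The synthetic instrument

`simulate_run()` stands in for the chromatograph. Retention follows the
linear-solvent-strength law log₁₀k(φ) = log₁₀kw,eff − S·φ, with kw,eff
the Henderson–Hasselbalch-weighted mix of the neutral and ionized forms'
aqueous retention (for an acid, fraction ionized 1/(1 + 10^(pKa − pH));
pKa = NA means pH-insensitive). Gradient retention times solve the
general elution equation ∫₀^(tR−t0) dt/(t0·k(φ(t))) = 1 with φ(t) linear
over the ramp, then held. The integral is accumulated by a trapezoidal
rule on a fixed time grid (dt = 0.002 min by default) with linear
interpolation of the unit crossing: the cumulative form is vectorizable
across thousands of lattice runs, is exact in the isocratic limit
(where tR = t0(1 + k) is asserted to 1e-6 relative), and has O(dt²)
error well under 1e-6 relative at the default step for gradient runs.
Peak base widths follow w = 4tR/√N from the plate count; optional
Gaussian retention jitter uses a fixed seed; peaks closer than
0.15·(w₁ + w₂)/2 merge into one labelled co-eluting peak, which the
response extraction reports as FOP.

The default eight-analyte set (ACE … ASP) is phenomenological, not a
calibration to any instrument: aqueous log kw 1.30–2.72, slopes S
3.2–3.5, a −0.6 log₁₀ retention shift on ionization, acid pKa values
5.0–6.5 (upper half of the pH 3–7 window, so ionization grows across
the box without saturating), caffeine pH-insensitive, plate counts near
10⁴, dead time 1.5 min, 30-min ramp. These values were chosen once to
emulate the statistical structure the pipeline must handle — smooth,
strongly pH-dependent surfaces on the realistic resolution scale, a
pH-driven order crossing (SOR/SAC) with peak-merge events in part of
the cube, analysis times in the tens of minutes — and the tests verify
the consequences: quadratic fits to a noise-free 15-run study achieve
R² > 0.9, and the optimum found from those 15 fitted runs falls within
0.25 coded units of a 13³ dense-search optimum of the simulator itself.

What the simulator does *not* emulate: detector response and spectra,
baseline drift and integration error, buffer-capacity and temperature
effects, column ageing, and injection-to-injection carryover. Passing
the recovery test therefore shows the statistical pipeline is sound,
not that any real separation will behave this smoothly.

## Validation metrics

`calibrate()` fits signal on concentration by simple least squares and
derives LOD = 3.3σ/slope, LOQ = 10σ/slope with σ the residual standard
error of the line (the ICH convention; whether the original work used a
blank-based SD instead is not decidable from printed data, and the
packaged LOD/LOQ values are fixtures, not assertions). LOQ/LOD =
10/3.3 identically. `precision()` uses the sample (n−1) SD; CV < 2%
passes system suitability, CV ≤ 10% passes the AOAC gate (boundary
inclusive). `recovery()` is the baseline-corrected spike percentage
with the 80–110% acceptance window. `check_compliance()` compares
concentrations against the built-in NADFC limits with an inclusive
boundary.

## Problem sizes and runtime choices

The shipped tests run the 15-run fixture pipeline at the default
201-point lattice; property suites use 100 random BBD datasets for the
intercept identity, 25 for the normal-equations cross-check, a 101-point
lattice for the synthetic recovery run, and a 13³ lattice (dt = 0.01
min) for the simulator's dense-search oracle — sizes at which the whole
suite completes in well under a minute on a single core while leaving
the assertions at full precision (1e-9 for the least-squares
identities, 1e-6 relative for the isocratic closed form).

## Known limitations

* Only the 3-factor BBD is generated; no central-composite or optimal
  designs, no blocking.
* No lack-of-fit test against pure error, and no stepwise selection
  beyond the single-pass α filter.
* The desirability optimizer is deterministic local-in-a-lattice; it is
  adequate for smooth quadratic composites on a cube but is not a
  global optimizer for arbitrary surfaces.
* The run-assignment recovery assumes the published models are close to
  the models that generated the responses; with grossly wrong models the
  minimum-cost bijection is still returned but means little.
* Real chromatographic data with drifting baselines or asymmetric peaks
  must be reduced to peak lists (retention time, base width) upstream of
  this package.
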