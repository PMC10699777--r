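---
title: "Partitioning pulsed soil N2O emissions with isotopocules, tracers, and gene abundances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning pulsed soil N2O emissions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(n2osip)
```

## Scope and model

Rewetting a dry soil triggers a pulse of N2O within minutes. `n2osip`
implements the chain of measurements and models that identifies the
responsible process: chamber fluxes, N2O isotopocule arithmetic, Keeling
source signatures, 15N tracer mass balance, endmember mixing with
Rayleigh reduction trajectories, and qPCR gene quantification. Every
stage consumes either real delimited tables or the output of the
package's seeded generators, which emulate the instruments.

This vignette records the scientific and numerical decisions behind each
stage: what is assumed, which parameters matter, and what the synthetic
tests do and do not demonstrate about real data.

## Chamber fluxes

A closure is 2 min of recirculation through a fixed system volume. The
estimator is ordinary least squares of N2O (ppb) on time over the window
remaining after a 30 s deadband — i.e. the last 90 s — because the first
seconds after closure mix chamber and loop air. Both the deadband and
the gating level are configuration, not constants.

The slope converts to an areal flux by the ideal gas law:

$$F = s \cdot \frac{P V}{R T} \cdot \frac{M_{N}}{A},$$

with $s$ in ppb s$^{-1}$ (i.e. $10^{-9}$ mol fraction s$^{-1}$), $P V /
(R T)$ the moles of air in the system, $M_N = 28.014$ g N per mol N2O
(two N atoms), and $A$ the collar area. The conversion is exactly linear
in the slope, so the generator inverts it to place a known flux into a
synthetic closure; with zero noise the estimator recovers the generating
flux to floating-point precision, which is the closure test the suite
runs.

*Gating.* A flux whose slope is not significant (two-sided t test of the
OLS slope, p > 0.05 by default) is reported as zero with the fit
diagnostics retained. For simple regression the slope t test and the
Pearson correlation test coincide, so the ambiguity in "linear
correlation was not statistically significant" is immaterial. On
pure-noise closures the empirical gating rate must equal the nominal
level; the suite verifies this over 10^4 simulated closures.

*What is not modeled.* Dilution of the loop by ambient make-up air is
deliberately absent from the estimator: over 2 min it is small relative
to a ~6–10 L system and leaves the concentration rise linear. The
generator can emulate only the linear regime, so the tests say nothing
about strongly curved chamber traces — users with long closures should
inspect R².

*Pulse summaries.* The peak flux over a window (default 24 h) treats
gated estimates as zero and breaks ties by earliest time. The cumulative
emission is a trapezoid over the actual sampling times, reported with the
largest gap and its fraction of the span rather than silently
interpolated, because instrument dropouts are the norm in multiplexed
deployments. On the generator's pulse family (30-min closure spacing)
the trapezoid tracks dense quadrature within 2%, and peak and cumulative
emissions are strongly rank-correlated, which is what justifies using
the peak as the response variable when gaps prevent integration.

*Pulse shape.* The generator's flux trajectory is a linear rise to the
peak (default 45 min) followed by exponential decay (default time
constant 60 min): peaks within the first hour, near-baseline within ~4 h.
The shape is a named function (`pulse_flux`) and is swappable; nothing
downstream assumes it. Default scenario amplitudes (414 ng N m^-2 s^-1
peak over ~1 ng baseline, 0.3 ppb 1-s noise at 330 ppb ambient) describe
the strong-pulse regime the package targets; independence of noise
across closures is assumed because no within-pulse autocorrelation
information is available.

## Isotopocule arithmetic and calibration

Delta notation is anchored to the AIR 15N/14N ratio (0.0036765) and the
VSMOW 18O/16O ratio (0.0020052) — conventional constants carried in the
configuration. Site preference and bulk delta15N are *derived* from the
site deltas (`SP = δα − δβ`, `bulk = (δα + δβ)/2`) inside the reading
constructor, never stored independently, so the defining identities hold
by construction before and after calibration. The arithmetic-mean bulk
is exact to first order and agrees with the certified USGS values at
printed precision (USGS 51: (0.48 + 2.15)/2 = 1.315 ≈ 1.32; the USGS 52
certified SP differs from its printed site-delta difference by 0.01 —
certified values are taken as authoritative).

*Calibration.* Laser N2O isotope analyzers drift with concentration and
CO2. The model is linear per channel:
`measured = b0 + b1·true + b2/[N2O] + b3·[CO2]`, fitted by least squares
to reference-standard runs across a concentration/CO2 grid and inverted
exactly when applied. The form is explicit and swappable; it was chosen
because the dependencies are empirically near-linear in 1/[N2O] over the
calibrated range (0.6–8 ppm by default; readings outside are corrected
but flagged). The fit/apply closure on synthetic standards reproduces
certified deltas to 1e-6 permil — this demonstrates the algebra, not the
adequacy of the linear form for any particular instrument.

*Keeling plots.* Accumulation of a constant source over background makes
δ exactly linear in 1/C, with the source signature as intercept. OLS
(model I) is the default; geometric-mean regression (model II) is
available by flag since the choice is not dictated by the underlying
model and matters only under comparable x-error. With exactly two
points, the fit is exact and the intercept SE is reported missing rather
than zero.

*Tracer mass balance.* At 2 at% enrichment the delta scale is far from
linear, so two-pool mixing is computed on atom fractions
(`x = R/(1+R)`), with exact delta conversions both ways. The generator's
Keeling series defaults to linear-in-delta mixing — its error is below
0.1 permil for |δ| < 3000 at these mixing ratios, and it keeps the
noiseless intercept recovery exact — with exact atom-fraction mixing
available via `mixing = "atom"`, recommended for enriched-tracer
sources. The switch is an explicit argument rather than an automatic
threshold so that a scenario's mixing model is always visible in the
call.

## Endmember mixing and Rayleigh reduction

Each candidate process occupies a box in (SP, δ15N_bulk, δ18O) space.
Literature boxes are substrate-relative; `build_endmembers()` translates
the δ15N axis by the measured NO3-/NO2- (or NH4+) signature and the δ18O
axis by the water signature (defaults: +7.2 and −9 permil). SP is
substrate-independent and never shifted; correction is a pure
translation, so box widths are conserved exactly — a property the suite
asserts.

The SP ranges for bacterial denitrification (−7.5 to 3.7 permil), fungal
denitrification (27.2 to 39.9) and chemodenitrification (20.1 to 25.7)
are well-established; the remaining ranges, and all δ15N/δ18O ranges,
are literature-informed defaults that ship as *configuration with
documentation*, not as claims — real applications should confirm or
override them, and the same holds for the net isotope effects of
N2O→N2 reduction (defaults ε_SP = −6, ε15 = −7, ε18 = −15 permil), for
which published estimates vary substantially.

*Rayleigh model.* Closed system: δ = δ0 + ε·ln f. Open (steady-state)
system: δ = δ0 − ε·(1 − f), bounded by −ε. Both use the same sign
convention (negative ε enriches the residual pool as f falls), so one ε
set serves both modes; which mode describes a given incubation is a user
decision and both are provided. Shift and inversion are exact inverses,
tested to 1e-12 across f ∈ [0.001, 1] in both modes.

*Classification.* `classify_point()` is a deterministic grid search:
start points are each box's 8 corners plus centroid; f runs over 200
log-spaced points on [0.01, 1]; the residual is unweighted Euclidean
distance in permil over the available axes (axis weights are available
to encode unequal measurement precision). Log spacing matches the
geometry — equal steps in ln f are equal shifts in delta. A continuous
optimizer could refine the grid argmin but must agree with it within
grid resolution; determinism and testability won over polish here.

*Identifiability.* With literature-width boxes, a reduction trajectory's
starting point is uncertain along the trajectory's own direction, and
that uncertainty maps directly onto f: the classifier's point estimate
of f_rem is then only loosely determined even when the process
attribution is solid. `partition_uncertainty()` makes this honest by
Monte-Carlo over uniform box draws (and optional ε ranges), returning
f_rem quantiles and process weights. The parameter-recovery test in the
suite therefore runs with the generating endmember point supplied as a
zero-width box: it measures estimator error (recovering f within 0.1
under 2-permil noise on six-sample means), not box ambiguity, which the
coverage test quantifies separately.

## qPCR quantification

Standards follow `Cq = Cq_ref − log10(copies/ref)/log10(1+E)`; the curve
fit is OLS of Cq on log10(copies), and `E = 10^(−1/slope) − 1` (E = 1 is
perfect doubling, slope −3.3219; E = 0.65 gives slope −4.598). A
nonnegative slope is treated as a failed/inhibited run and raised as an
error, not returned. Replicates are averaged on the Cq scale before
inversion (triplicates by convention). Copies per gram of soil require
the extraction metadata (soil mass, elution and template volumes,
dilution); there are no silent defaults because these factors vary per
protocol and scale the result linearly. Efficiencies are reported, not
judged: acceptance thresholds belong to the user's QA, since assays are
run and interpreted at efficiencies well below the textbook 90% in
difficult soils. Detection is a replicate-majority rule below a cycle
limit (default 40), both configurable.

## Problem sizes and numerical choices

The test suite generates all data at run time: 10^4 closures for the
gating-size check, 200 replicates for f-recovery, 60 for interval
coverage, grids of 100–400 points for inverse identities; the full suite
runs in well under a minute. Tolerances are tiered by what the
arithmetic supports: exact identities at 1e-12, least-squares closures
at 1e-9 to 1e-6, Monte-Carlo properties at their binomial/sampling
error. Degenerate inputs (flat designs, equal concentrations, zero time
variance, f = 0, indistinguishable tracer pools) raise classed errors
rather than NaNs; out-of-range but physically possible values
(f slightly above 1, readings outside the calibrated span) are clipped
or corrected *and flagged*, because they are data, not bugs.

## Limitations

The generators emulate the statistical structure of the measurements
(linear closures, two-source mixing, box endmembers with a single
reduction overprint, log-linear plates with Gaussian cycle noise), not
the biogeochemistry: no diffusion, no microbial dynamics, no spatial
heterogeneity, no within-pulse autocorrelation, no 17O corrections, no
spectral interference physics beyond the empirical calibration. Passing
tests therefore demonstrate that the inference chain is internally
correct and invertible under its stated assumptions — on real data the
binding questions are whether the endmember boxes and ε values apply,
which only the user can decide.
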