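---
title: "Models, measurements and design choices in synplastkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, measurements and design choices in synplastkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

synplastkit packages the analysis chain of a class of cellular
neurophysiology experiments: whole-cell recordings from neocortical basket
cells (BCs) combined with two-photon Ca²⁺ imaging of their dendrites and
with mapping and plasticity induction at pyramidal-cell (PC) → BC synapses.
This vignette explains the models the code implements, the tunable
parameters and their defaults, what the synthetic-data generator does and
does not emulate, and the design choices made where the procedures were
genuinely open. It states no empirical result beyond what the package's
tests and acceptance script themselves compute.

## dG/R quantification

Two-channel scans carry a Ca²⁺-sensitive green signal (e.g. Fluo-5F) and a
Ca²⁺-insensitive red structural signal (e.g. Alexa 594). Scattering and
depth attenuate both channels by the same factor, so the ratio

dG/R(t) = (G_roi(t) − Ḡ_roi,baseline) / R̄_roi,baseline

is depth-robust. `compute_dgr()` computes this quantity on the ROI mask,
subtracts the identical quantity computed on a background mask, and
baseline-zeroes it; the baseline-window mean is exactly zero by
construction, which the suite asserts for arbitrary inputs.

Two points were open and are settled here as package policy:

- **Denominator.** A "change in red" denominator would be degenerate — the
  red channel is Ca²⁺-insensitive, so its change is noise. The denominator
  is the baseline-mean red signal, the standard dG/R convention.
- **Background masks.** How background regions are chosen is an
  acquisition-side decision; both masks are explicit arguments (movies may
  carry defaults).

`integrate_transient()` reports the time-averaged dG/R over a protocol
window, ×100 (units %). The window is a protocol parameter: 0–1000 ms for
synaptic-pairing frame scans, 0–275 ms for the bAP line-scan variant.
Baseline windows default to the 100 ms (line scans) or 200 ms (frame scans)
preceding the stimulus.

bAP transients are multiplied by the local dendritic diameter before
distance fitting, compensating surface-to-volume scaling of indicator
fluorescence in thin dendrites. The diameter estimator was unstated in the
source procedures; here it is the full width at half maximum of the
time-averaged red line profile above its background level (profile median),
because the red channel is purely morphological. Planted-profile tests
bound its error at < 10% across realistic widths.

The **boost** of a bAP transient by somatic depolarization is the
difference (depolarized − rest) of diameter-corrected integrals at matched
locations; a ratio option exists. The difference was preferred because it
remains defined when the rest response approaches zero distally — exactly
where boosting matters.

## bAP attenuation model

The generator plants an exponential decrement with distance d from the
soma: amplitude ∝ A₀ · exp(−d/λ) · (1 + β·d) when depolarized (β = 0 at
rest). Defaults: A₀ = 0.5 dG/R units, λ = 100 µm, β = 0.005/µm — i.e. a
75 % boost at 150 µm, vanishing at the soma, which makes the boost–distance
correlation strictly positive in expectation. `bap_distance_profile()`
fits A·exp(−d/λ) per state by nonlinear least squares (log-linear start)
and reports the Pearson correlation of boost versus distance. Note the
depolarized-state curve is *not* a pure exponential (the (1 + βd) factor
flattens it), so only the rest-state λ estimates the planted decay length;
the suite's recovery criterion uses the rest state.

One train-frequency discrepancy in the source protocol (5 pulses at 50 Hz
in the methods text versus a 30-Hz description elsewhere) is resolved by
making the frequency a generator parameter; it does not enter the analysis
path, which only needs the stimulus onset.

## EPSP/AP/Both linearity

Three interleaved conditions — presynaptic stimulation alone (EPSPs),
postsynaptic spikes alone (APs), and both — are compared per dendritic
segment: supralinearity = 100 × Both / (EPSPs + APs), computed on dG/R
integrals averaged across repeats. The group statistic is the **mean of
per-segment ratios**, not the ratio of group means; with heterogeneous
segments the two differ (the suite pins the arithmetic: printed-style group
means of 7.8 % and 5.6 % divide to 139.3 %, while a mean-of-ratios near
143 % is what the per-segment aggregation produces). Segments with
non-positive Sum are excluded with a logged message rather than silently
dropped.

The generator's interaction term γ makes the expected Both response
(1 + γ)(EPSPs + APs). Defaults: γ = 0.43 for synchronous timing and −0.10
for asynchronous, chosen so the noise-free supralinearities are 143 % and
90 % — the regime the analysis is meant to distinguish. γ = 0 is the exact
linearity null, asserted pixel-wise on noise-free output.

## Binomial release model and CV analysis

EPSPs are drawn from a binomial model: N release sites, release probability
p, quantal size q with quantal CV, so E[EPSP₁] = Npq and 1/CV² = Np/(1−p)
when quantal and recording noise vanish — the quantal law the acceptance
suite checks at 10⁴ sweeps against a 3-SE band. Defaults N = 5, p = 0.5,
q = 0.3 mV, quantal CV 0.3 are generic cortical unitary-synapse values; the
paired-pulse second release draws from sites thinned by a per-site
depletion fraction (default 0.15) after pulse 1.

Two noise terms are this package's own additions, documented rather than
sourced: a per-sample recording noise (default 0.05 mV) and a common
multiplicative trial factor (CV 0.3, applied to both pulses of a sweep) that
models drive fluctuation; the null-calibration cohorts prescribe exactly
this trial noise. Both are set to zero for quantal-law assertions.

`cv_analysis()` normalizes the mean and 1/CV² of the post epoch by the
baseline epoch. A presynaptic change (Δp) moves 1/CV² *more* than the mean
(below the diagonal); a postsynaptic change (Δq) leaves 1/CV² untouched (on
the diagonal at the new mean). Amplitudes at or below zero are included as
measured — clipping would destroy the binomial variance structure the
diagnostic relies on. Epochs under 10 sweeps trigger a warning and a
bootstrap CI, because the CV of a CV estimate is large at such n.

## EPSP measurement and PPR

Amplitude is the mean of a 1-ms window centred on the post-onset peak minus
the mean of the 8 ms before onset; the peak is searched up to 30 ms after
onset (bounded away from the second pulse of a 30-Hz pair). The peak is
*located* on a ~0.5-ms smoothed copy of the trace and *measured* on the raw
trace: picking the argmax of raw noise would bias amplitudes upward, and
the smoothed peak-pick removes that bias without filtering the measurement
itself. Latency is the 20%-of-amplitude rise point (also on the smoothed
copy); extracellularly evoked responses are expected at 1–2 ms and flagged
otherwise. Spikes inside the search window mark the sweep contaminated and
the amplitude is withheld.

EPSP₂ of a pair rides on the decay of EPSP₁. Before measuring EPSP₂, a
single exponential fitted to the 10 ms preceding the second stimulus is
subtracted from the fit window onward (so the EPSP₂ baseline is corrected
too — correcting only beyond the onset re-introduces the overlap error).
With α-function kinetics (τ ≈ 5 ms default; the correction stays within 5 %
up to τ ≈ 10 ms), the naive uncorrected estimate is several-fold worse,
which the suite quantifies. Sweeps whose EPSP₁ is at or below a noise floor
(default 0.05 mV, i.e. binomial failures) leave PPR undefined and are
excluded from per-sweep PPR averages.

PPR per epoch defaults to the mean of per-sweep EPSP₂/EPSP₁ ratios
(undefined sweeps excluded); a ratio-of-epoch-means mode exists. The
per-sweep convention matches the calibration cohorts' definition, at the
cost of a heavier-tailed estimate under low-N binomial release.

## Plasticity magnitude

`plasticity_magnitude()` applies QC first (reference = mean of the first 5
sweeps; input resistance ±30 %, resting potential ±8 mV, temperature
32–34 °C; the record is truncated at the first failure, with a discard-only
mode available), measures every passing sweep, and compares the baseline
epoch to the post epoch starting 10 min after induction. The per-connection
after/before ratio carries a small (≈ +1 point) finite-sample inflation
from the noisy epoch mean in the denominator; it is a property of the
estimator, not a bug, and the acceptance tests size their cohorts so the
tolerance resolves it.

## Optogenetic mapping logic

Spirals are Archimedean, r(θ) = spacing·θ/2π, sampled at constant angular
progress by default (the galvo parameterization was not specified; a
constant-linear-speed option exists), 15 µm diameter, ~1 µm revolution
spacing, 7 ms. Stimulation plans give each candidate cell a 2-spiral 30-Hz
burst, 500 ms apart across cells, repeated over 20 sweeps. Connection
detection — delegated to prior work in the source and therefore a package
policy here — calls a cell connected when its mean EPSP amplitude exceeds
k·(baseline noise SD/√sweeps) (k = 3 default) with a physiological median
latency; the noise SD comes from applying the *same* measurement statistic
at stimulus-free onsets. Null-scene simulations in the suite bound the
false-positive rate.

Induction timing is specified relative to EPSP onset and compensated for
the measured latency ℓ: synchronous pulses start at spiral onset + ℓ + Δt
(Δt = +10 ms); asynchronous trains lead so the first EPSP onset lands 10 ms
after the last pulse (Δt = −90 ms with 5 pulses at 50 Hz). Baseline pairs
run at 30 Hz, induction pairing at 50 Hz; the two constants are never
conflated.

## Mixed models and tests

`fit_lmm_reml()` wraps a standard REML engine (lme4) for random-intercept
models with optional nesting (cell within animal), but all inference is
implemented in-package: containment denominator degrees of freedom (a fixed
effect is assigned to the outermost grouping level within whose groups it
is constant; denominator df at level l is m_l − m_{l−1} − p_l), marginal
Wald F tests, and Tukey-adjusted pairwise contrasts on estimated marginal
means (model-matrix rows averaged with the factor forced to each level,
studentized-range adjustment at the factor's containment df). With two
levels the Tukey-adjusted p equals the unadjusted test exactly; the suite
asserts this identity, the balanced-case equality of REML variance
components with the ANOVA closed form, null-uniform F p-values, and
familywise error control.

The Wilcoxon signed-rank test versus zero uses the exact null distribution
(generating-function convolution over doubled average ranks, valid under
ties) up to n = 25 non-zero differences, with Pratt handling of zeros
(zeros rank, then drop), and a tie-corrected continuity-corrected normal
approximation beyond. Reporting REML-based AIC comparisons across different
fixed-effect structures is statistically questionable and deliberately not
packaged.

## Synthetic morphologies and contacts

BC arbors grow as seeded random walks: `n_stems` primary dendrites, 10-µm
steps with direction jitter, branching probability 0.08 per step, growth
clipped to a 150-µm soma-centred envelope (so 100 % of dendritic length is
inside it) and to |z| ≤ 10 µm — arbors are near-planar, as in
slice-projection reconstructions. Connected PC → BC pairs route the PC axon
in a z = 30 µm clearance plane, descending from a soma placed above the BC
(upper-layer origin), with vertical dips that approach exactly
`n_contacts` chosen dendritic loci to within 1.2 µm. Loci are sampled below
the BC soma with probability `axon_descent_bias` (default 0.8), and must be
> 4 µm from unrelated dendrite edges (bounded rejection), so the planted
contact count is recovered exactly by the detector. This stages the
below-soma contact asymmetry as controllable ground truth; it does not
emulate axonal tortuosity, boutons, or true 3-D arborization.

Contact detection computes minimum distances between 3-D line segments
(reconstructions are piecewise linear; node-to-node distances would miss
mid-segment approaches), thresholds at 2 µm, and merges candidates within
3 µm so one apposition spanning several nodes counts once. Distance to soma
is radial Euclidean — consistent with Sholl radii — with path distance also
reported, since the convention was unstated. Sholl counts are
edge-straddle counts (an edge crossing k radii counts once at each), the
cumulative curve is normalized and r75 interpolated linearly; averaging
across cells is done without normalization.

## What a green test does and does not establish

The generator reproduces the *statistical structure* the analyses assume —
exponential bAP decrement with multiplicative boost, a scalable interaction
term for pairing supralinearity, binomial release with depletion and
pre/post expression loci, planted contact geometry, shot-noise-like
channel noise (Gaussian with SD ∝ √signal), depth attenuation. It does not
model optics (PSF, bleaching, motion), cable biophysics, channel kinetics,
dye buffering, or waveform realism beyond α-kinetics; noise magnitudes for
the imaging channels are stand-ins chosen here (no source values exist) and
are flagged as such in the parameter documentation. A passing recovery test
therefore establishes that the *analysis operations* are correct and
calibrated on data with the assumed structure — not that the assumed
structure exhausts real recordings.

## Numerical choices

- Exponential fits: log-linear start then `nls`; on failure the log-linear
  fit stands. Degenerate zero-variance boosts yield NA correlations rather
  than errors.
- Jarvis march: counter-clockwise, deterministic start at the
  lowest-then-leftmost point, collinear edge-interior points excluded by
  preferring the farther point on ties; degenerate inputs (< 3 points or
  all collinear) return flagged extreme points.
- Segment-segment distance uses the clamped closest-point algorithm,
  vectorized over all axon × dendrite edge pairs.
- dG/R division guards error on non-positive baseline red signal; empty
  masks error.
- Seeds are explicit everywhere; generators save and restore the caller's
  RNG state, and derived child seeds stay below 2³¹.
- QC truncation (not discard) is the default, matching the invariant that
  the pass mask is false from the first failure onward.

## Known limitations

- The depolarized-state λ is a descriptive fit, biased long by the boost
  factor (by design; see above).
- Per-sweep PPR under low-N binomial release is heavy-tailed; cohort-level
  ΔPPR needs tens of connections for tight bands.
- The containment-df rule covers nested random intercepts (the only
  designs in scope), not crossed random effects.
- Connection detection assumes sub-threshold, non-saturating responses;
  spiking sweeps are excluded, opsin kinetics are out of scope.
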