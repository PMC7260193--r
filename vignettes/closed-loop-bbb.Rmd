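---
title: "Closed-loop cavitation control and quantification for FUS BBB opening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop cavitation control and quantification for FUS BBB opening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusbbb)
```

## The problem

Microbubble-mediated blood-brain barrier (BBB) opening exposes circulating
ultrasound contrast agent to a focused acoustic field, driving stable
cavitation that transiently loosens tight junctions. Too little acoustic
pressure produces no opening; too much drives inertial cavitation and
vascular damage. On a clinical low-frequency (230 kHz) transcranial
phased-array system treating a rat brain, the therapeutic window is narrow
and varies between animals, sessions and even targets a millimetre apart,
so the acoustic power must be servoed in real time on the microbubbles'
own acoustic emissions.

`fusbbb` implements that servo loop and the downstream quantification:

1. **Spectral features** — per-burst harmonic, subharmonic and wideband
   emission levels in dB relative to noise floors, with detection flags.
2. **Controller** — a per-target proportional power controller with a
   goal band for harmonic emission, hard power limits, and a 40 %
   reduce-and-lock safety trigger on subharmonic/wideband detection.
3. **Planning** — the 36-target, four-sonication volumetric grid, 2.5 mm
   analysis ROIs with mirrored contralateral controls, and the summed
   focal-intensity energy-density map.
4. **MRI quantification** — voxelwise R1 from a variable-TR
   saturation-recovery series, hemispheric ΔR1, gadolinium concentration
   via the relaxivity, percent enhancement with maximum-intensity
   projection, and the predicted spin-echo enhancement curve.
5. **PK statistics** — geometric means with geometric %CV, paired
   two-tailed t-tests on log concentrations, hemisphere ratios, and
   below-LLOQ censoring bookkeeping.
6. **Synthetic data** — seeded generators for burst spectra, phantoms and
   concentration tables, so the full pipeline is testable without any raw
   recordings.

## Emission features

Each 5 ms burst yields a magnitude spectrum (4.1 ms at 2 MS/s, ~244 Hz
bins). Analysis bands sit at the second and third harmonics
(460 and 690 ± 10 kHz), the subharmonic (115 ± 10 kHz) and a wideband
window (660 ± 40 kHz) monitored by a broadband hydrophone.

Levels are `20·log10` ratios of the in-band **mean** magnitude to a noise
floor's mean level. Two conventions deserve comment:

* **Amplitude (20 log) convention.** The controller design assumes the
  harmonic enhancement in dB is proportional to pressure *amplitude*, so
  spectra are treated as amplitude-like throughout. Had 10·log10 been
  intended, only the effective gain changes; the loop structure is
  unaffected.
* **Mean over bins, not max.** The in-band mean is robust to grid
  resolution and is what the scale-equivariance property tests assert.

Two floors are used, mirroring practice: a *pre-sonication* floor (3.5 s
of bursts before the sonication) is the dB reference for all reported
levels, and an *early fixed-power* floor (bursts of the first 8 s of the
microbubble sonication, before bubbles reach the brain) sets the
detection thresholds — subharmonic at 3.3 and wideband at 4 standard
deviations (computed in the dB domain, sample SD across bursts) above
that floor.

**Wideband window vs third harmonic.** The wideband window
[620, 700] kHz fully contains the third-harmonic band [680, 700] kHz. A
naive in-band mean would therefore rise ~2 dB whenever the controller
drives the harmonics to their 6–7.5 dB goal — locking essentially every
target through the safety trigger. The wideband *statistic* therefore
excludes bins inside the harmonic bands (`band_indices()`): it measures
elevation of the spectral floor *between* lines, which is the signature
of inertial cavitation, while the band definition itself is unchanged.

## The control law

Per target, with `H` the dB-domain mean of the two harmonic levels:

```
P_new = ( sqrt(P_current) − P_gain · (H − H_goal) )²,   P_gain = 0.0167
```

clamped to [0.01, 0.39] W. If `H` lies in the goal band [6, 7.5] dB the
power is held and recorded as a *goal hit*. Design choices where the
published description leaves room:

* **`H_goal` is the nearest band edge** (7.5 when overshooting, 6 when
  undershooting): the minimal correction, giving a continuous control law
  whose fixed points are exactly the in-band states.
* **A lower power bound (0.01 W)** is added; only the start (0.16 W) and
  maximum (0.39 W) are prescribed, and repeated safety triggers would
  otherwise drive the power to zero.
* **Trigger precedence.** Within a burst, a subharmonic/wideband
  detection wins over the proportional update: power drops 40 % and locks.
* **Timeline.** Bursts before 8 s hold the start power (the early floor
  is still being measured, so flags are undefined there); 8–25 s is the
  control window; at the first burst past 25 s the power is committed to
  the mean of the goal-hit powers (held unchanged if there were none —
  the description is silent on that case); after 25 s the power may only
  fall, never rise, and trigger checks remain armed.
* **Independence.** Each of the nine interleaved targets (101.6 ms burst
  interval, per-target PRF 1/(9 × 0.1016 s) ≈ 1.1 Hz) carries its own
  controller state; there is no cross-target coupling.

Power maps to peak negative pressure linearly in √power through the two
calibration points (0.16 W, 68 kPa) and (0.39 W, 165 kPa) — neither a
pure p ∝ √W law nor linearity in W passes through both.

`run_session()` orchestrates the session protocol: per volumetric group a
30 s fixed-power pass without microbubbles, then a controlled 55 s pass
with microbubbles, each preceded by baseline bursts for the floor.
`summarize_session()` aggregates goal achievement, detection rates and
max-power burst fractions per pass and group.

## The synthetic emission model

The generator emulates what the controller needs to see, not bubble
physics (no Rayleigh–Plesset dynamics, no skull reflections or standing
waves, no hydrophone frequency response):

* **Noise floor**: per-bin log-normal magnitudes (2 dB per-bin spread).
  The resulting burst-to-burst spread of in-band means (~0.1–0.3 dB)
  yields detection thresholds and spurious-flag rates of the same order
  as reported session statistics.
* **Harmonic enhancement**: `H_true = gain_h · p(kPa) · c(t)` dB applied
  multiplicatively over both harmonic bands, plus one shared Gaussian
  jitter draw per burst (0.5 dB SD). The default `gain_h` = 0.05 dB/kPa
  places the goal band inside the calibrated pressure range at peak
  bubble concentration.
* **Bubble kinetics** `c(t)`: zero before arrival (6 s), a
  gamma-variate-shaped rise peaking at `t_arrival + α·τ` (defaults
  α = 2, τ = 2 s), then exponential clearance with a 40 s half-life.
  Folding the clearance rate into the gamma-variate exponent would make
  the rise scale (2 s) dominate the decay, collapsing the concentration
  within seconds of the peak and making the goal band unreachable over
  most of the control window; the piecewise form keeps the decay governed
  by the stated half-life. Only arrival timing and monotone clearance are
  observationally constrained — the shape parameters are exposed
  configuration, not values fitted to any measurement.
* **Subharmonic / wideband events**: rare stochastic events with logistic
  probability in the pressure-concentration product (defaults chosen so
  event rates sit below ~0.1 % of bursts near goal conditions) that
  multiply their band by a configurable 3 dB.

Under these defaults the closed loop reaches the goal band in ≥95 % of
targets before 25 s (measured at ~99 % over 100 seeded runs), and the
committed power decreases monotonically as the harmonic gain doubles —
the two behaviours the controller exists to produce. Passing these tests
says the *loop* is correct; it says nothing about how a real skull
cavity, real bubble size distributions, or real hydrophones behave.

## Planning geometry

Planning is 2D in the axial target plane, in millimetres, voxel-center
convention. `build_target_grid()` scans a 1 mm lattice anterior→posterior
and medial→lateral inside one hemisphere of the brain mask (a stylized
ellipse stands in for the anatomical template, which is not available),
skips an optional ventricle-exclusion mask, takes the first 36 points and
partitions them into four contiguous groups of nine ordered
anterior→posterior — the published grouping is not printed, so blocks in
scan order are used. Analysis ROIs are 2.5 mm-diameter disks rasterized
by voxel-center inclusion, mirrored exactly across the midline (an
involution on midline-symmetric grids); targets keep a 1.3 mm midline
margin so sonicated and mirrored disks never meet.

The energy-density map sums one Gaussian focal kernel per target. The
axial FWHM default (3.5 mm) is anchored to the measured length of the
disruption along the beam; the lateral FWHM (3.0 mm) is not printed and
is exposed configuration. In the axial planning plane both in-plane
directions use the lateral width (the beam axis is through-plane); the
axial width matters only for 3D use.

## R1 relaxometry and enhancement

The variable-TR fast-spin-echo series is modeled as saturation recovery,

```
S(TR) = M0 · (1 − exp(−TR · R1)),
```

with echo-train and TE effects absorbed into `M0` (single-TE
acquisitions). The originally cited fitting method is not reproducible
from its description, so the package states its own: per-voxel nonlinear
least squares (Levenberg–Marquardt via `minpack.lm`), initialized from
the two extreme TRs (`M0 ≈ S(TR_max)`, closed-form `R1` from the shortest
TR), voxels below 3× the noise SD at the longest TR or failing to
converge marked invalid. Correctness is established by recovery: exact
(≤10⁻⁶ relative) on noiseless data at the 7-TR protocol
(6000…100 ms), and ΔR1 bias <2 % at 1 % image noise for offsets
0.05–0.10 s⁻¹. A single noisy realization carries ~2 % random scatter in
ΔR1, so bias is always measured as a mean over 10 seeded replicates.
`r1_two_point()` provides the exact two-measurement solution as an
algebraic cross-check.

ΔR1 is the ROI-mean difference between each sonicated disk and its
mirrored control; hemispheric comparisons use a one-way ANOVA on the
target-level ROI means (for two groups, F = t²). Concentration follows
`C = ΔR1 / 4.44 mM⁻¹s⁻¹` (gadobutrol relaxivity), exactly linear;
negative ΔR1 passes through flagged, not clipped.

Percent enhancement takes a voxelwise maximum-intensity projection over
the repeated post-injection acquisitions inside the brain mask before
computing `100·(MIP − pre)/pre`; zero-signal pre voxels are excluded and
counted. The predicted spin-echo enhancement,

```
S(C) ∝ (1 − exp(−TR·(R1₀ + r1·C))) · exp(−TE·(R2₀ + r2·C)),
```

uses tissue defaults R1₀ = 0.7 s⁻¹, R2₀ = 12.5 s⁻¹ (typical low-field
brain values, not measured ones) and `r2 = 0` by default — only the
tissue R2 enters the published prediction; with a positive `r2` the curve
quenches non-monotonically at high concentration, which is asserted, not
hidden.

## Pharmacokinetic statistics

Concentrations are summarized as geometric mean with geometric %CV
(`100·√(exp(s²) − 1)` on log values). Below-LLOQ samples are excluded and
reported as detected/total counts — never imputed, matching how
non-detects are tabulated. Sonicated/control comparisons use the
classical paired two-tailed t-test on log differences; for fully paired
data the ratio of GMs equals the GM of per-pair ratios exactly, and both
are reported to surface incomplete pairing. Pairing is by animal (and
sampling site when a `site` column is present).

The simulator draws correlated log-normal triples (plasma, sonicated
tissue, control tissue) per animal; the default within-animal log
correlation 0.8 gives a paired log-difference SD near 0.35 at ~60 % GCV.
The tissue LLOQ defaults to 15× the plasma LLOQ (homogenate dilution).
The default cohort parameters follow the high-dose arm, whose tissue
concentrations sit far above that LLOQ; `pk_cohort_10mg()` provides the
low-dose preset (whose SN-38 analog falls below quantitation, as
observed).

## Numerical choices and problem sizes

* Synthesis grid: 8200 samples at 2 MS/s (~244 Hz bins) by default;
  property suites and the acceptance script use 2048 samples (~977 Hz
  bins), which keeps every band resolvable (≥20 bins) while a full
  session simulates in well under a second.
* Phantoms: 64 × 72 voxels at 0.5 mm for recovery studies; fits are
  restricted to the ROI voxels actually analysed.
* Ties and degenerate inputs: non-finite `H` skips the burst; an
  all-censored cohort returns undefined GM with a zero detection count; a
  zero-variance paired test is flagged degenerate rather than returning
  an infinite t.
* All generators are bit-reproducible given a seed; sessions derive
  nothing from global state beyond the RNG.

## Known limitations

* The emission model is phenomenological; it cannot probe skull-cavity
  standing waves, bubble-size effects, or hydrophone directivity, and its
  event thresholds are placeholders, not fitted rates.
* Planning is 2D; no acoustic propagation or steering-range modeling.
* The R1 method is a stated surrogate for the study's unavailable fitting
  procedure; absolute agreement with that implementation cannot be
  checked, only recovery of known truth.
* Session statistics from the simulator (goal rates, trigger rates)
  resemble the published magnitudes but are properties of the synthetic
  model, not reproductions of in-vivo recordings.
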