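---
title: "Mapping gastric slow waves with gastroMap: methods and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping gastric slow waves with gastroMap: methods and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gastroMap)
```

Gastric slow waves are rhythmic extracellular depolarisations, a few
hundred microvolts in amplitude, that recur every 15–30 s in most species
and propagate across the stomach wall at millimetres per second. A
high-resolution mapping experiment records them on a rectangular serosal
electrode array; the analysis problem is to go from raw multichannel
signal to per-wavefront spatial descriptions. This vignette describes the
models and procedures `gastroMap` uses at each stage, why the defaults
are what they are, and what the validation suite does and does not
establish.

## Signal model and pre-processing

A serosal channel is modelled as a sparse train of biphasic or triphasic
deflections — approximately derivatives of a Gaussian, reflecting the
second spatial derivative of the transmembrane potential seen by an
extracellular electrode — superimposed on baseline wander (movement,
respiration, electrode drift) and broadband noise. The activation time of
a wavefront at an electrode is, by convention, the steepest negative
slope of its deflection.

Pre-processing therefore has two jobs: remove the wander without touching
the deflection's falling edge, and attenuate noise above the deflection
band. The default chain is

1. moving-median baseline subtraction with a 20 s window. A median over
   several slow-wave periods rides over the sparse deflections (they
   occupy ~10 % of each window) while tracking drift; windows should span
   at least five periods, and `removeBaseline()` warns when told the
   dominant period and given less.
2. Savitzky–Golay smoothing, 1 s window, order 2. A quadratic fit over
   ~1 s preserves the slope of a 2 s deflection far better than a moving
   average of equal bandwidth, which matters because detection and mark
   placement both read the derivative.

Zero-phase Butterworth (forward–backward, odd-reflection padding) and a
periodised Daubechies wavelet decomposition (db2/db4, keep-band
reconstruction) are available as alternatives. All four filters are
zero-phase in effect; the unit tests assert that the steepest-descent
sample of a clean deflection moves by less than one sample under each.
Edge handling is replicate-padding for the two local smoothers and
odd-reflection for the IIR filter, chosen so that recording edges do not
manufacture falling edges for the detector. Window parameters are given
in seconds and converted to odd sample counts (rounding up), so parameter
files transfer across sampling rates.

## Event detection (FEVT)

The falling-edge variable-threshold detector computes, per channel,

\[ D(t) = \mathrm{MA}_{0.25\,\mathrm{s}}\!\left[\max(0, -s'(t))\right]^{2},
\qquad \theta(t) = \max\!\big(\varepsilon,\ \eta\cdot
\mathrm{med}_{15\,\mathrm{s}} D\big) \]

with `s'` the centred first difference in µV/s. Rectification makes
rising edges invisible; squaring emphasises the high-energy falling edge;
the short moving average integrates over one deflection's descent. The
moving median tracks each channel's noise floor — because events are
sparse, the median is immune to them (the tests assert zero threshold
inflation for duty cycles below half the window) — and `η` sets the
operating point. The floor `ε` is scale-aware (`1e-12 · max D`) so silent
channels stay silent, and the whole construction is equivariant to
channel rescaling: gain differences between electrodes do not move marks.

Supra-threshold runs closer than the refractory period `T_r = 2 s` are
merged; each surviving run yields one mark at the steepest negative slope
within it. Runs containing several descent maxima separated by more than
0.5 s (fractionated potentials) are marked at the first deflection whose
`D` reaches 50 % of the run's peak — the first-major-deflection
convention used in manual marking.

**Calibration of `η`.** `η` is a multiplier on the *detection signal*,
which is the square of the rectified slope. A threshold conceived as
"five times the background slope" therefore corresponds to `η = 5² = 25`
on the `D` scale, and 25 is the default. On the package's reference
conditions (below) this operating point gives ~99 % sensitivity at ~3 %
false positives; `η` applied un-squared (5 on the `D` scale) floods the
output with noise triggers. Sensitivity is monotone non-increasing in
`η`, which the property tests assert, so users trade the two error rates
along a single axis.

## Cycle clustering (REGROUPS)

Marks are grouped into wavefronts by region growing over the 8-connected
electrode graph, stabilised by a quadratic activation-time surface:

- **Seed**: the earliest unassigned mark on the channel whose 8-neighbours
  hold the most unassigned marks within 10 s (ties to the smallest
  channel). Requiring at least one supporting neighbour means an isolated
  spurious mark cannot found a wavefront once real ones exist; it ends as
  an orphan. On degenerate inputs where nothing has support (e.g. a
  single mark in total) the earliest mark seeds anyway, so tiny inputs
  still produce a cycle rather than nothing.
- **Grow**: each frontier channel contributes its unassigned mark nearest
  the predicted arrival time, accepted when within `τ = 3 s`. While the
  group has fewer than six members the prediction is the mean of assigned
  neighbour times; from six on it is the least-squares quadratic surface
  `T(x, y)`, which captures curved and radial wavefronts that a plane
  would mispredict.
- **Stabilise**: after every 5 acceptances the surface is refit and any
  member whose residual exceeds `max(2·RMS, τ)` is ejected back to the
  pool (the residual-scaled bound tightens as the fit improves but never
  below `τ`, so exact fits do not eject on numerical noise). Ejected
  marks may be adopted by a later cycle; never-adopted ones become
  orphans.

Cycles are closed when the frontier empties, dissolved if smaller than
`min_cycle_size` (default 1), and finally renumbered 1-based by mean
member time. Termination is guaranteed: every pass permanently assigns at
least one mark, and a mark enters a given cycle attempt at most once.
The constants (10 s seed window, `τ = 3 s`, batch 5) are scaled to
gastric periods (~20 s) and typical array spans; all are exposed in the
parameter set. On noisy recordings, correlated false positives can form
small spurious cycles; they are easily removed by raising
`min_cycle_size`, which was nevertheless left at 1 so that genuinely
small patches of activity are not silently discarded.

Re-entrant activity that revisits an electrode within one cycle is out of
scope; such recordings are best handled with manual regrouping
(`editCluster()`) and the propagation animation.

## Spatial products

**Activation maps** place one cycle's marks on the grid. The two-stage
SIV scheme fills a missing site from the median of its measured
8-neighbours when at least `K₁ = 5` are present, then repeats once with
threshold `K₂ = 3` counting stage-1 values too, to close borders. Exactly
two stages run — the scheme is deliberately not recursive — and measured
values are never altered. Interpolated sites may feed rendering and
velocity display but are excluded from amplitude, interval and text
statistical exports.

**Velocity** uses smoothed finite differences: the gradient of the
activation-time grid (central differences, one-sided at borders and next
to missing sites), each component smoothed by a truncated Gaussian
(σ = 1 electrode, 3σ support) with missing-aware kernel normalisation,
then \(v = \nabla T / |\nabla T|^2\) scaled by the electrode spacing.
Smoothing the *gradient* rather than the time map preserves an exact
identity on planar waves — a constant gradient convolved with a
normalised kernel is itself — so the acceptance test can demand the
closed-form speed `spacing/delay` to 1 × 10⁻⁹ at every defined site.
Gradients below `1e-3 s/mm` (speeds above 1000 mm/s, i.e. effectively
simultaneous activation) are flagged undefined rather than clipped.

**Amplitude** is estimated in a 1.5 s window centred on the mark: the
first derivative is Savitzky–Golay smoothed (0.25 s, order 2), its zero
crossings classified by sign change into local maxima and minima, and the
amplitude is the highest maximum minus the lowest minimum. Against a
noisy raw max-minus-min this halves the typical bias (the raw estimator
rides on noise extremes); with fewer than one maximum or one minimum, or
a window truncated by a recording edge, the raw value is returned flagged
low-confidence. The estimate is invariant to constant offsets.

**Intervals** are computed per consecutive cycle pair at channels holding
measured marks in both cycles; the equivalent frequency `60/I` cycles/min
is classified against configurable bradygastric/tachygastric bounds,
default (2, 4) cycles/min — appropriate for human recordings and
deliberately configurable because porcine work runs far faster.

## Synthetic data: what it emulates, what it does not

`slowWaveScenario()` defines the study conditions used throughout the
tests: an 8×8 array at 4 mm spacing, 32 Hz sampling, 10 minutes, planar
antegrade propagation at 6 mm/s, 20 s period (3 cycles/min), biphasic
400 µV deflections of 2 s width, white noise at 5 dB SNR plus sinusoidal
wander (0.005 Hz, 200 µV) with a small random-walk component. SNR is
defined as peak-to-trough amplitude over twice the noise RMS, in dB —
the definition the generator also reports, and which the tests verify
against empirical RMS. Mains interference defaults to off because the
32 Hz sampling used in mapping sits below the mains band; a line term is
available for higher-rate scenarios. Radial (ectopic pacemaker),
retrograde, conduction-block and tachygastric-patch patterns have exact
closed-form arrival times, and every waveform is placed so its steepest
descent lands on the ground-truth sample.

What the generator does **not** emulate: fractionated multi-deflection
potentials, spatially correlated noise, electrode-contact dropouts that
come and go, re-entry, and amplitude/velocity gradients across the field.
Passing the synthetic suite therefore demonstrates correctness of the
algorithms under their stated model, not performance on every species or
pathology; detector and clustering error rates on real recordings depend
on signal quality and should be spot-checked with the manual review
tools.

## Validation strategy and reference figures

The test suite validates each stage against independent oracles: format
arithmetic and hand-computed medians for I/O and filters, a cross-library
EDF/BDF reader for the writer, brute-force derivative searches for mark
placement, `lm()` and closed-form least-squares theory for the surface
fit, time-gap bisection for clustering, and closed forms from the
generator for maps. End to end, noise-free planar, radial and retrograde
recordings must be recovered exactly: every mark within one sample,
membership exact, zero orphans, intervals equal to the period.

The headline benchmark (`scripts/acceptance.R`) runs detection on five
seeded 10-minute recordings at 5 dB SNR and reports mean sensitivity and
false-positive rate at a ±0.5 s matching window; the suite requires
≥ 90 % and ≤ 10 % respectively, and the defaults achieve ≈ 99 % / ≈ 3 %.
Ten-minute, 64-channel problems were chosen for these checks because
they exercise ~2000 events per run while keeping the full suite fast;
all algorithms are linear or near-linear in recording length.

## Numerical and design notes

- All internal times are seconds from sample 1, amplitudes µV, distances
  mm; grid indices are 0-based row-major with row 0 at the top.
  `orientation_deg` rotates rendering only and never enters computation.
- The BDF dialect is fixed to BioSemi (0xFF + "BIOSEMI", 24-bit
  little-endian two's complement); other EDF variants are rejected rather
  than guessed. Calibration is fixed at digital ±2²³ over physical
  ±262144 µV (~0.03 µV/LSB), and the writer uses 1 s records when the
  sample count divides by the rate, otherwise a single record — never
  zero-padding, so read(write(x)) stays within one LSB everywhere.
- Layout, parameter and session files are schema-versioned JSON with
  full-precision doubles (17 significant digits), making every round trip
  an identity for computation-relevant fields; session version mismatches
  are hard errors, never partial loads.
- Map rendering composes RGB rasters directly and writes them with
  `png::writePNG`, so identical products give byte-identical files —
  convenient for regression testing and caching. The refractory-tail fade
  in animations is linear over `tail_s` (a fade law must be fixed; linear
  is the simplest monotone choice).
- Isochronal contouring will happily interpolate across a conduction
  block, visually crowding isochrones at the block line; inspect the
  patch plot or the per-site export when block physiology is suspected.
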