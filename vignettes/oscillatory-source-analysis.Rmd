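---
title: "Methods: source-space oscillatory power analysis on synthetic MEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: source-space oscillatory power analysis on synthetic MEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(oscmeg)
```

## Overview

`oscmeg` studies how auditory feature attention (phonetic "what" versus
spatial "where") modulates oscillatory power in visual cortical areas, using
cortically constrained MEG source estimates. Because no raw recordings of
this kind are shipped, the package simulates the whole study — geometry,
forward model, paradigm, and signals — with known planted effects, and the
analysis chain is judged by whether it recovers them. This vignette explains
the model, the defaults and why they were chosen, what the generator does
and does not emulate, and the numerical decisions a maintainer would want
written down.

## Geometry and forward model

The toy cortex is two disjoint deformed spherical-cap patches (one per
hemisphere, default 64 vertices each; the full-resolution regime of roughly
a thousand vertices per hemisphere is supported and tested). A structured
row-major grid is triangulated directly — no Delaunay dependency — giving
exact vertex counts and deterministic meshes for a fixed seed. Sixteen
anatomical-style ROIs (pericalcarine, cuneus, lingual, fusiform, …) are
grown from farthest-point-sampled seeds by FIFO region growing, which
guarantees every parcel is connected under triangle-edge adjacency; parcel
sizes follow a largest-remainder apportionment of the requested fractions.

The lead field replaces a boundary-element forward solution with a smooth
parametric kernel: sensor $i$ with gain jitter $s_i$ responds to a dipole
$\mathbf{e}$ at $\mathbf{q}$ as
$s_i\,(\mathbf{p}_i-\mathbf{q})\cdot\mathbf{e}\,/\,(r^2+h^2)^{(k+1)/2}$
with falloff exponent $k = 2$ and smoothing length $h = 10$ mm. This keeps
the two properties the analyses actually depend on — distance-decaying,
spatially correlated sensitivity and a full-rank but ill-conditioned inverse
problem — while making every entry reproducible from first principles.
Columns are rescaled to mean norm 1, which fixes the unit convention for
everything downstream.

## The synthetic study

Defaults mirror the paradigm: two cycles of (Attend Phoneme 60 s, Passive
30 s, Attend Location 60 s, Passive 30 s) — 360 s per subject — with sound
pairs (two 300 ms sounds, 250 ms gap) every 3.4 s, the first pair 1 s after
block onset and pairs truncated so a full 1.75 s post-onset window fits in
the block. That yields 17 pairs per attend block (34 trials per active
condition, 36 passive); real sessions collect an order of magnitude more
trials, and the 9-subject group compensates for the reduced per-subject
averaging. Sampling rate is 300 Hz, Nyquist-safe for the 80 Hz analysis
ceiling. Nine subjects differ by multiplicative lead-field jitter (sd 0.05)
and lognormal effect-size jitter (sd 0.1), which is what gives the paired
t statistics realistic between-subject variance.

Source activity per vertex is unit-variance 1/f background (exponent 1,
spectrally shaped noise with the scale fixed analytically, not by realized
sample variance). The planted effect is narrowband 7–13 Hz Gaussian noise
(band-passed white noise, so its envelope fluctuates realistically) shared
by the vertices of each planted parcel. Its variance is calibrated so that
the **total** in-band source variance ratio between conditions equals the
configured `power_ratio` exactly in expectation — the boosted-condition
variance absorbs the background's in-band power — so a measured
$10\log_{10}$ ratio of 3.01 dB at `power_ratio = 2` is the designed
behaviour, not an approximation. The Passive condition sits at the geometric
mean of the two active conditions, giving symmetric polarity against
Passive. The base oscillation strength is four times the background's
in-band variance (`alpha_snr = 4`), a strong-posterior-alpha regime.
Stimulus-locked damped-sinusoid transients (10 Hz carrier, 80 ms decay,
amplitude 2) are added in superior temporal parcels at both sound onsets of
every pair, identical across trials, so evoked subtraction has a measurable
target. Sensor noise is Gaussian with an AR(1) spatial covariance
($\sigma = 1$, $\rho = 0.3$), about half the per-sensor brain-signal
variance. Blinks are 400 ms raised-cosine pulses on the EOG channel (170 µV
peak, against 5 µV Gaussian EOG noise, so contaminated epochs exceed 100 µV
peak-to-peak and clean ones stay under 50 µV) with a fixed frontal-pattern
projection onto the sensors; by default 8% of pairs are contaminated.

What the generator does **not** emulate: realistic head geometry or sensor
arrays, auditory stimulus acoustics, behavioural responses, heartbeat and
muscle artifacts, non-stationary background spectra, or head movement.
Passing tests therefore certify the analysis chain's correctness and
calibration, not its performance on any particular real dataset.

## Inverse modeling

The inverse operator is
$\mathbf{W} = \mathbf{R}\mathbf{A}^{\mathsf T}(\mathbf{A}\mathbf{R}\mathbf{A}^{\mathsf T} + \lambda^2\mathbf{C})^{-1}$,
solved through a Cholesky factorization of the sensor-space matrix, never an
unfactorized explicit inverse. $\lambda^2 = 1/\mathrm{snr}^2$ with default
snr 3, the conventional minimum-norm operating point; `snr = Inf` reproduces
the unregularized textbook form in which the noise covariance enters with
unit weight. The source covariance is diagonal in per-vertex surface
coordinates: depth weight proportional to the gain-column norm to the power
$-2\times0.8$ (compensating the superficial bias of minimum-norm solutions;
the exponent is configurable in $[0,1]$), tangential components scaled by a
loose orientation factor of 0.6, and the global scale normalized to mean
diagonal 1. The noise covariance is estimated from Passive-block samples
excluding −0.1 to 1.0 s around every sound onset, with 5% diagonal loading —
an "estimated from the raw data" convention; one operator serves both the
sustained and time-frequency analyses (re-estimating per condition would
risk condition-dependent spatial filters).

Whole-mesh power maps use the loose-orientation estimate with power summed
over the three components of each vertex (how the three components are
collapsed is our decision; summing is the rotation-invariant choice). ROI
analyses use the surface-normal component averaged with sign alignment: each
vertex's waveform is multiplied by the sign of its normal's dot product with
the parcel's dominant orientation direction. That direction is the principal
eigenvector of the orientation tensor $\sum_v \mathbf{n}_v\mathbf{n}_v^{\mathsf T}$
with a canonical sign, rather than the plain mean normal: the tensor is
invariant under per-vertex sign flips of the normals, which makes the ROI
time course exactly robust to normal-orientation conventions (a plain mean
normal is not — flipping one normal moves the mean and can silently flip
other vertices' alignment). For oriented patches the two coincide. Zero dot
products resolve to +1.

## Spectral estimation

Sustained power: each 1.75 s epoch ([−2.0, −0.25] s relative to pair onset)
is demeaned, Hanning-tapered over its full length, Fourier transformed with
no zero padding, and converted to one-sided power spectral density with
taper-power correction, so that the summed spectrum times the bin width
equals the tapered signal's mean square exactly (the Parseval identity is a
unit test). Power is computed per trial then averaged — the convention also
used for the time–frequency estimates — and averaged over band bins whose
center satisfies low ≤ f ≤ high. The scaling convention cancels in every
normalized comparison. Note one consequence of the natural 4/7 Hz bin grid:
a 10 Hz tone falls exactly between two bins and its energy is shared by
them, which is why the tests assert main-lobe concentration and closed-form
Hanning leakage rather than single-bin dominance.

Time–frequency power: at each frequency the window is 3 cycles long
(`round` to samples, ties up), Hanning-tapered, and evaluated at a single
frequency on a common 50 ms center grid across the [−0.75, 1.75] s epoch;
cells whose window does not fit inside the epoch are undefined (NA). The
defined-center span at frequency $f$ is the epoch shrunk by $3/(2f)$ at each
end — at 4 Hz, −0.375 to 1.375 s. The 50 ms stride (our choice; the window
placement grid is not dictated by the design) is fine enough to resolve
effects a few hundred milliseconds wide. The trial-averaged evoked response
is subtracted per condition before windowing, restricting the estimate to
induced activity; epochs are demeaned at the epoch level to avoid DC leakage
through the taper. Evoked subtraction is not applied to the sustained
window, which precedes the stimuli by design.

Normalizations are $10\log_{10}(\mathrm{power}/\mathrm{reference})$:
per-frequency pre-stimulus baseline (defined cells with center < −0.1 s)
for time–frequency estimates, and the Passive-condition power of the same
element and band for sustained ROI power.

## Cluster inference

Paired t statistics (df = n−1; df = 8 for the default 9 subjects) are
thresholded at the two-tail 5% critical value (|t| > 2.306 at df 8);
supra-threshold elements are clustered by adjacency separately for positive
and negative signs, cross-hemisphere adjacency is forbidden (each hemisphere
is a separate sheet), and time–frequency bins use 4-neighborhood lattice
adjacency without diagonals. The cluster statistic is the sum of member
t values; the reference distribution is the maximum |sum-t| over clusters of
either sign under per-subject condition-label exchange (equivalently,
sign-flipping each subject's difference) — the conservative two-sided
reading. Sampled nulls use the add-one estimator
$(\#\{\text{null} \ge \text{obs}\}+1)/(n+1)$ so p is never 0; when
$2^n \le n_{\text{rand}}$ all sign patterns are enumerated exactly
(including identity), so for 9 subjects the nominal 1,500 randomizations
become the exact 512-pattern null and p values are deterministic. Because
the maximum cluster statistic is invariant under the global sign flip, the
smallest attainable exact p is $2/2^n$. Zero-variance elements are flagged
and excluded from clustering. A-priori ROI comparisons are plain paired or
one-sample t tests per ROI/hemisphere/band with raw p values flagged at 0.05
and 0.01 — no multiplicity correction beyond the cluster procedure,
matching the a-priori design. The default 1,500 randomizations are used for
both the cortical-map and the time–frequency tests (the count is explicit
only for the latter in the source design; we apply it to both,
configurable).

## Recovery scoring and calibration

A planted ROI counts as recovered iff at least one of its vertices lies in a
cluster with p ≤ α of the planted sign; ROIs touched by significant clusters
outside the planted set are reported as false positives. With a 32-sensor,
128-vertex configuration, minimum-norm point spread leaks the planted alpha
contrast broadly (the planted parcels carry about a 3 dB contrast, their
surroundings 1–2 dB), so significant clusters typically extend well beyond
the planted parcels; the report states this rather than masking it, and the
band-specificity flag verifies that no other band produces significant
clusters. Test validity is checked empirically: over 150 null datasets
(9 Gaussian subject maps on a 64-vertex cortex, exact sign-flip null) the
any-cluster rejection rate at nominal 0.05 must fall inside the 95% binomial
interval — the sign-flip null is exact under the symmetric-null assumption,
so this is a calibration check of the whole clustering path, not of the
Gaussianity of real data.

## Problem sizes and determinism

The shipped configuration — 9 subjects, 64 vertices per hemisphere, 32
sensors, 360 s sessions, 1,500 requested randomizations — runs the full
pipeline in about two minutes on one CPU and was chosen so the complete
suite (including the end-to-end recovery run and the null calibration)
completes comfortably in an ordinary development loop; all statistical
conclusions are reproduced identically at larger mesh and session sizes,
only more slowly. Every random draw derives from one master seed through a
counter-based fan-out (mesh, lead field, per-subject session, each test),
so any stage can be re-run in isolation bit-identically; the RNG state of
the caller is always restored.

## Known limitations

- The forward model is generic; no claims about anatomical localization
  accuracy on real heads follow from these simulations.
- Noise covariance is estimated from Passive raw data and therefore contains
  brain signal; this mirrors the stated convention but differs from
  empty-room estimation.
- The time–frequency stage plants no transient effect, so its cluster tests
  are expected to be null here (baseline normalization removes the sustained
  contrast by construction); the machinery is exercised and calibrated, but
  transient-effect recovery is not demonstrated.
- Dipoles are simulated along surface normals only; tangential source
  components exist in the inverse model but carry no simulated signal.
- Sessions are stationary within blocks: no drowsiness drift, adaptation,
  or artifact non-stationarity.
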