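---
title: "From raw inertial signals to gait parameters and cohort classification: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw inertial signals to gait parameters and cohort classification: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aclgait)
```

`aclgait` analyses lower-limb inertial recordings of a run-and-sidestep
task to (i) extract temporal gait parameters and compare them between
post-ACL-reconstruction and healthy athletes, and (ii) discriminate the
two cohorts with subject-independent machine-learning models. This
vignette explains the models and procedures, the tunable parameters and
their defaults, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design was open.

## The measurement model

Four sensors (left/right shank and thigh) each record tri-axial
acceleration (±16 g range, in g) and angular rate (±2000 deg/s range, in
deg/s) at a nominal 100 Hz. After preprocessing, axes follow a fixed
anatomical convention: x mediolateral, y anteroposterior, z vertical, so
the y–z plane is the sagittal plane. Each repetition starts with a deep
squat performed to give all sensors a common, recognisable
low-frequency event; the athlete then runs ~5 m, sidesteps at 45°
(left or right), runs ~3 m and stops.

## Preprocessing

**Resampling.** Consumer IMU clocks drift and jitter, so raw timestamps
are non-uniform. Every channel is linearly interpolated onto an
arithmetic grid at the target rate (default 100 Hz). Linear
interpolation is adequate here because the informative content sits well
below 20 Hz at a 100 Hz rate; a spline alternative would only matter
near the Nyquist frequency.

**Squat synchronization.** The squat appears as a deep valley of the
vertical acceleration. Each recording is low-passed at 1 Hz (zero-phase
Butterworth), the minimum within the leading 5 s window is located, and
the feature time is refined as the deficit-weighted centroid of the
valley below 40% of its depth — the centroid is used instead of the raw
minimum because low-frequency noise is strongly correlated over the wide
valley and shifts a pointwise minimum by tens of milliseconds. Offsets
are reported relative to the first sensor (left shank, an arbitrary but
fixed reference). A valley shallower than 0.2 g raises an explicit
sync-failure error. With ideal clocks the offsets are recovered to a few
milliseconds; a relative sampling-rate error between sensors (the
generator draws ±1%) leaves a residual misalignment that grows with
distance from the squat, which is why the sub-sample recovery claims are
tested in the zero-rate-error configuration.

**Shank frame alignment.** The knee is treated as a hinge: shank and
thigh angular rates may differ only about the flexion axis, so the
magnitudes of their components perpendicular to the axis agree. With the
thigh sensor mounted mediolaterally, the shank axis $j$ minimises
$\sum_t (\lVert\omega_s(t)\times j\rVert - \lVert\omega_{t,\perp
x}(t)\rVert)^2$ over the unit sphere. The minimisation is a damped
Gauss–Newton iteration multi-started from the six coordinate axes
(iteration cap 200, relative tolerance 1e-10 on the cost decrease, with
the gradient projected onto the sphere's tangent plane); the best
converged start wins. The shank is then rotated about the vertical so
the axis' horizontal component becomes +x, and the sign is fixed so the
dominant mid-swing angular-rate lobes are positive. Whether the original
procedure rotated only about the vertical is ambiguous; restricting the
correction to yaw is this package's recorded choice, consistent with
sensors worn upright on the segment. Confidence is judged by
identifiability: the ratio of the optimal cost to the cost of orthogonal
candidate axes is near 0 for genuine hinge motion and near 1 for
axis-free data (e.g. pure noise), and ratios above 0.25 — or an axis
leaving the horizontal plane by more than 30° — are flagged (an error
under `strict = TRUE`).

## Gait events and temporal parameters

Detection operates on the mediolateral shank angular rate, low-passed at
15 Hz: mid-swing is a positive peak above 0.6 × the 95th percentile of
the positive part, with a 0.3 s refractory period; terminal contact is
the last negative peak before each mid-swing and initial contact the
first negative peak after it (negative peaks shallower than 0.5 × the
95th percentile of the negative part are ignored as noise). Event times
get parabolic sub-sample refinement. Per complete initial-contact cycle:
GCT, STP, SWP = GCT − STP, rSTP/rSWP as percentages of GCT, and cadence
= 1/GCT. A validity filter discards strides with GCT outside [0.2, 1.2] s
or rSTP outside [20, 80]% — these arise at the run's start/stop and
around the sidestep transient; the bounds are configurable and steps
during the sidestep are kept whenever they pass the filter. On
noise-free synthetic strides every event is recovered within one sample
period, which is the accuracy ceiling of a 100 Hz recording, and the
thresholds above are documented defaults for the unpublished reference
detector, not claims about it.

## The feature registry

Per sensor, 13 derived series feed 10 time statistics each (mean, SD,
skewness, excess kurtosis, RMS, min, max, peak-to-peak, CV, IQR): the 3
gyro axes, 3 jerk axes (central-difference derivative of acceleration,
one-sided at the endpoints), 3 body- and 3 gravity-frame acceleration
axes, and the acceleration magnitude. The gravity frame is a zero-phase
4th-order Butterworth low-pass at 0.3 Hz (configurable) with
odd-reflection end padding and mean re-insertion so a constant input is
reproduced exactly; body = acceleration − gravity by construction. Triad
statistics (3 pairwise correlations, per-axis energy, signal magnitude
area) are computed for the four tri-axial signals; spectral features
(dominant frequency, power-weighted centroid, 95% spectral edge,
harmonic ratio = even/odd harmonic power over the first 10 harmonics of
the dominant frequency, and index of harmonicity = dominant power over
the first 6 harmonics) for the gyro, raw-acceleration and jerk axes plus
the magnitude, on a Hann-windowed periodogram of the detrended series
with nearest-bin harmonic lookup. Smoothness measures: dimensionless
jerk per acceleration axis, and sample entropy and SPARC per gyro and
acceleration axis. The total is 223 named scalars per sensor and 892 per
repetition over four sensors; a single-sensor registry is a supported
configuration because the published per-repetition count (250) cannot be
decomposed unambiguously into these families, so the package asserts its
own documented composition instead.

Three conventions deserve note. **Dimensionless jerk** treats the axis
as the acceleration record of a movement: the speed proxy is the
cumulative trapezoidal integral of the mean-removed acceleration, jerk
is its derivative, and the measure is $-(T^3/v_\text{peak}^2)\int j^2\,dt$
— the only reading of the duration-cubed normalisation that is actually
dimensionless for accelerometer input — with the negative-log variant
returned by default. **Sample entropy** is $-\ln(A/B)$ with template
length m = 2 and tolerance r = 0.2 SD under the Chebyshev distance,
self-matches excluded; the O(N²) count runs in compiled code. A constant
series returns 0 and an unmatched series is flagged `NA`. **SPARC**
follows the canonical definition: zero-padding level 4, 10 Hz spectral
cutoff, adaptive 0.05 amplitude threshold on the max-normalised
magnitude spectrum; the value is invariant to amplitude scaling.
Undefined values anywhere in the registry are explicit `NA` flags —
never silent `NaN`s — and `drop_undefined_features()` removes flagged
columns before modelling.

## Statistics

Levene's test is a one-way ANOVA on absolute deviations from the group
mean (median optional, giving Brown–Forsythe). The condition × limb
ANOVA uses Type III sums of squares with sum-to-zero contrasts, the
convention standard statistics packages apply to unbalanced factorial
data. Cohen's d uses the equal-weight pooled SD
$\sqrt{(s_1^2+s_2^2)/2}$ — this pooling reproduces the published
left-leg effect-size cells from the descriptive table to the printed
precision, while sample-size-weighted pooling is available as an option
— with the conventional bands at 0.2/0.5/0.8/1.3. Power calculations use
the exact noncentral-t distribution (noncentrality $d\sqrt{n/2}$, df
$2n-2$), not the normal approximation, and the sample-size search
returns the smallest integer n per group reaching the target power.

A power consideration worth recording: at the study's own size (~210
steps per cell) the interaction contrast implied by the descriptive
table (≈0.030 s against an ≈0.095 s stride SD) gives an expected t of
only ≈2.0–2.3, i.e. roughly coin-flip detection at α = 0.05. The test
suite therefore asserts the detection property at ~840 steps per cell,
where it is reliable, rather than pretending the smaller design is
stable.

## Evaluation protocol

Subjects (not repetitions) are the unit of partitioning: 6 training, 2
validation, 4 test, stratified so each partition is cohort-balanced. For
every grid point — a model family, its hyper-parameters, and K ∈ 1..10
features kept by one-way F score — a leave-one-subject-out pass fits
z-scoring, selection and the model on the remaining subjects only and
scores the held-out player's repetitions; the grid point with the best
mean per-subject accuracy wins, ties resolving to the smallest K and
then the first combination in lexicographic grid order. The optimum is
confirmed on the validation pair, training and validation merge into 8
subjects, the grid search reruns, and the final model scores the 4 test
subjects. The whole procedure repeats over random subject assignments
(10 by default), pooling per-player accuracies and confusion counts.
Mean accuracy is the average over player scores with SE =
SD/√(number of scores); pooled-matrix accuracy is reported alongside and
differs slightly by construction. The leakage guard is structural — the
fitting path only ever receives training rows — and is asserted in the
suite by deleting unseen subjects and requiring a byte-identical model.
Because all repetitions of a player classify dependently, chance bands
for accuracy are binomial over subjects, not over repetitions. The MLP
engine is single-hidden-layer, so its grid spans layer sizes {8, 16, 32}
and L2 decay {1e-4, 1e-3}; stacking fits fixed configurations of the
five base families and combines their out-of-fold LOSO probabilities
with a logistic-regression meta-learner.

## The synthetic generator

The generator exists so every stage is testable without human data; it
emulates the study conditions, not the biomechanics. Per limb it draws a
stride train around the cohort/limb mean gait cycle times (defaults:
healthy 0.490/0.509 s left/right, post-ACL 0.514/0.503 s
affected/unaffected, stride-to-stride SD 0.091 s, between-subject SD
0.025 s, stance fraction 44.6% ± 3) and renders the mediolateral shank
angular rate as one dominant positive mid-swing lobe with smaller
negative lobes at the contacts (Gaussian lobes, ±300/−120 deg/s × a
subject amplitude factor, 20 ms width); the thigh sees a 0.45-scaled
copy plus the same y/z "wobble" so the hinge-joint constraint holds.
Vertical acceleration carries a 1 g baseline, a 1.5 s half-cosine squat
dip (0.5 g), and a decaying 12 Hz impact transient at each initial
contact; the sidestep adds a signed 2.5 g mediolateral pulse. The
post-ACL asymmetry is a gait-cycle-time shift plus a roughness
multiplier (default 1.5) on the affected limb's band-limited (>6 Hz)
acceleration content — the latter is this package's operationalisation
of the jerk-related differences the application domain reports, and its
default is a choice, not a measured value, because no amplitude
statistics were published. Sensors sample the continuous signals on
imperfect clocks: offset uniform in ±0.5 s, rate error uniform in ±1%,
timestamp jitter ±2 ms, plus white measurement noise (0.05 g, 5 deg/s)
and range clipping. A null variant equalises every cohort parameter so
the label is independent of the signal by construction; a drop-out
option removes six repetitions (four post-ACL, two healthy) to mirror
recordings lost to hardware issues.

What it does **not** emulate: musculoskeletal dynamics, magnetometer or
environmental channels, soft-tissue artifact, fatigue drift, or real
between-athlete morphological variation. Passing tests therefore show
that the pipeline recovers what the generator programs under realistic
noise and clock imperfections — not that the classifier would reach any
particular accuracy on real athletes.

## Problem sizes and determinism

The test suite and acceptance checks run the full pipeline at the study
size (6+6 subjects × 10 repetitions, ~9 s of 100 Hz data per sensor)
with a compact kNN grid and 3 assignment permutations; generator
determinism is bit-exact under a fixed master seed, from which all
subject, repetition and permutation seeds derive. Degenerate inputs have
defined behaviour throughout: empty series error, zero-variance series
flag their scale-dependent features, all-zero spectra flag every
spectral feature, and an unmatched sample-entropy template pair returns
a flagged `NA` rather than ±∞.

## Known limitations

Rate-error estimation is out of scope, so paired-sensor alignment
degrades late in long recordings at the generator's ±1% clock model;
the hinge-axis estimate absorbs most of this but a few degrees of yaw
error remain at full noise. The published per-repetition feature count
cannot be reproduced exactly (composition unpublished), and published
headline accuracies cannot be reproduced at all without the human
recordings; the package substitutes property-based claims on synthetic
cohorts for the latter. The event detector's thresholds are documented
defaults, not the cited method's (unpublished) values.
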