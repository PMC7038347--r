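---
title: "Methods: stride segmentation, gait events, and ZUPT-aided dead reckoning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stride segmentation, gait events, and ZUPT-aided dead reckoning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipdr)
```

## The estimation problem

A foot-mounted IMU measures specific force $\mathbf{f}(t)$ (m/s$^2$) and
angular rate $\boldsymbol\omega(t)$ (deg/s) in the sensor frame at 200 Hz.
Strapdown navigation propagates the sensor-to-navigation rotation $C_k$
from the gyroscope, rotates the specific force, removes gravity and
integrates twice:

$$
C_k = C_{k-1}\,\mathrm{Exp}(\boldsymbol\omega_{k-1}\,\Delta t),\qquad
\mathbf{v}_k = \mathbf{v}_{k-1} + (C_{k-1}\mathbf{f}_{k-1} + \mathbf{g})\,\Delta t,\qquad
\mathbf{p}_k = \mathbf{p}_{k-1} + \mathbf{v}_k\,\Delta t .
$$

Sensor noise and residual bias make the double integral drift without
bound; on a one-minute recording pure strapdown is typically hundreds of
metres off (the package's acceptance run measures a median of roughly
400–600% of the travelled distance). The structure of gait rescues the
estimate: once per stride the foot rests on the ground with exactly zero
velocity. Each detected zero-velocity sample becomes a pseudo-measurement
$\mathbf{v}_k = \mathbf{0}$ fed to an error-state Kalman filter. Finding
those samples requires knowing where strides are (segmentation), where
mid-stance lies inside each stride (event detection), and how fast the
person moved (activity classification, because the stance signature of
running differs from walking). That ordering is the pipeline.

Assumptions: the sensor is rigidly attached to the foot; accelerometer
data are pre-calibrated (units and scale correct); the gyroscope has an
approximately constant bias over a recording, estimable from a standing
interval; heading is unobservable, so reconstructed shapes are reported up
to a global rotation (initial yaw is set to 0, roll/pitch are levelled
from gravity).

## Tunable parameters

| parameter | unit | default | role |
|---|---|---|---|
| feature window / overlap | samples | 200 / 100 | 1 s of data per classification window at 200 Hz |
| msDTW threshold | scale-free cost | 35 | segmentation acceptance; see below |
| segment length window | template lengths | [1/4, 2] | guards degenerate warps |
| TO-TO span rule | s | > 2 keep 1.5 | standing/sitting between strides |
| mid-stance window / overlap | samples | 20 / 10 | 100 ms energy window |
| walking ZV threshold | deg/s | 0.6 | rate-of-turn magnitude rule |
| walking ZV min run | samples | 3 | suppresses single-sample chatter (a package choice) |
| jog/run ZV window | samples | MS ± 5 | 50 ms each side of mid-stance |
| $\sigma_a,\ \sigma_w$ | m/s$^2$, rad/s | 0.01, 0.01 | filter process noise |
| $\sigma_v$ | m/s | 0.01 fixed, or swept 0.001–0.05 step 0.001 | ZUPT measurement noise; swept per closed-loop trajectory when the endpoint is known |
| event tolerance | stride fraction | 0.15 | TP window for F-scores |

**The msDTW threshold.** The historical fixed threshold of 65 for this
segmentation family presupposes a template normalization that is not
fixed by the method's description, so it does not transfer across
implementations. The package instead divides both signal and template by
the template's peak absolute value, making the accumulated Manhattan cost
scale-free, and calibrates the default on synthetic data with
`sweep_threshold()` over the grid 0–100 in steps of 5. On jittered, noisy
synthetic bouts of all three activities the F-score is 1.0 on a wide
plateau (roughly 5–100); the default 35 sits mid-plateau. Real data with
atypical strides will narrow that plateau, which is why the sweep is
exported.

## The synthetic gait generator

`plan_trajectory()` builds a per-stride C$^1$ foot path: during swing a
raised-cosine forward displacement (and a raised-cosine vertical lift)
along the stride heading; during stance the position is constant. The
sagittal foot pitch runs through a plantar-flexion dip, a dominant
dorsiflexion rise and a descent back to flat (piecewise raised-cosines,
total excursion 60° by default), so its rate — which a lateral mounting
maps onto gyroscope z — shows the canonical stride morphology: small
negative valley, large positive swing peak, negative peak before
foot-flat. Early and late stance carry small (2°) pitch adjustments with a
perfectly quiet middle, so the minimum-energy window sits at the stance
centre, where ground-truth mid-stance is defined; toe-off truth is the
zero-crossing before the swing peak, heel-strike the first stance sample.

`synthesize_imu()` is an exact inverse of the strapdown integrator:
angular rates are $\mathrm{Log}(C_k^{\top}C_{k+1})/\Delta t$, specific
force is $C_k^{\top}((\mathbf{v}_{k+1}-\mathbf{v}_k)/\Delta t -
\mathbf{g})$ with velocities taken as position differences. Integrating a
noise-free synthetic signal from the true initial state therefore
reproduces the ground-truth positions to machine precision — the
round-trip property the tests rely on. White sensor noise and a constant
gyroscope bias are then added (single integer seed).

Defaults describe typical adult gait, chosen once: stride length / time
1.4 m / 1.1 s walking, 2.0 m / 0.8 s jogging, 2.6 m / 0.7 s running;
stance occupies the last 60% of a walking stride and the last 40% of
jogging/running strides.

What the generator does **not** emulate: soft-tissue and impact
transients at heel strike, slow bias drift and temperature effects,
scale-factor and axis-misalignment errors, surface slope, and
between-subject morphology differences. Green tests therefore demonstrate
algorithmic correctness and internal consistency — the filter, DTW,
detectors and metrics do exactly what they claim on signals with the
stated structure — not field accuracy on arbitrary hardware. Published
accuracies measured on real labelled datasets (e.g. classification
accuracies in the 90s, sub-percent RPE for walking) are dataset-bound and
are not reproduction targets for the synthetic conditions.

## Numerical and design choices

* **Indexing.** All sample intervals are 1-based and inclusive
  `[start, end]`, the natural R convention.
* **Units.** m/s$^2$ and deg/s everywhere; radians appear only inside the
  strapdown/filter code, because every gait threshold in the literature is
  stated in deg/s.
* **msDTW.** Local cost is the absolute difference on gyroscope z (summed
  over dimensions for multi-channel input); steps (1,1), (1,0), (0,1),
  unweighted. Per end column the DP yields the minimal-cost window ending
  there (free start, with the start column propagated through the
  recurrence); candidates under the threshold are accepted greedily in
  ascending cost order, ties to the leftmost, discarding overlaps. This
  all-ends greedy is equivalent in effect to scanning the last row for
  local minima — neighbours of an accepted minimum overlap it and are
  discarded — and has the advantage that a brute-force all-windows oracle
  can be compared *exactly*. With a Manhattan cost, distinct start columns
  can tie algebraically (two signal samples straddling consecutive
  template samples contribute identical totals); tied predecessors resolve
  to the smallest start column.
* **Toe-off.** Crossing definition: index $i$ with
  $x_{i-1} \le 0 < x_i$; "nearest" = largest such $i$ at or before the
  global maximum. The global (not first local) maximum anchors the search;
  this is precisely what makes the detector robust to early spurious peaks
  in jogging/running strides. An all-nonpositive stride raises an event
  error; a stride with no crossing before the peak returns its first index
  flagged low-confidence.
* **Mid-stance.** Heel strike is the global minimum of the
  [swing-peak, 160] portion of the 200-sample stride (the natural reading
  of "minimum peak"); energy-window ties break toward the earlier window
  (deterministic, and earlier is biomechanically closer to foot-flat);
  200-grid indices map back to the nearest original sample (< 1 sample
  effect). The listing's restriction to sample 160 (80% of the stride) is
  followed as written.
* **Filter.** Error state $[\delta\boldsymbol\theta, \delta\mathbf{v},
  \delta\mathbf{p}]$ with $C_{\text{true}} \approx (I -
  [\delta\boldsymbol\theta]_\times)\,C_{\text{est}}$; the only
  off-diagonal propagation term couples attitude into velocity error
  through $-\Delta t\,[C\mathbf{f}]_\times$. Measurement $H = [0\; I\;
  0]$, $R = \sigma_v^2 I$, Joseph-form covariance update, correction fed
  back and error reset each update. First-order (rectangular) integration
  at the sampling rate; rotation matrices re-orthonormalized every step by
  one symmetric Newton iteration (keeps $\|C^\top C - I\|$ at machine
  level). ZUPT measurements are applied at every zero-velocity sample, not
  once per stride. Gravity magnitude comes from calibration, not a
  constant.
* **Initial state.** Roll/pitch by gravity levelling over the first
  second, yaw 0, velocity 0, position at the origin.
* **Restitching.** The last toe-off opens a final stride running to the
  signal end (subject to the same 2 s/1.5 s truncation); without it, a
  closed loop's final stride — and with it loop closure — would be lost.
* **Classification.** Features are z-scored inside the SVM; the
  polynomial kernel uses `coef0 = 1` (the homogeneous variant separates
  z-scored features poorly). Near-static windows (summed gyroscope energy
  below $10^4$ (deg/s)$^2$, three orders below gait) carry no gait
  information and are excluded from the majority vote; ties break toward
  the slower activity. "Velocity" features integrate the raw
  accelerometer without gravity removal — they are relative features, and
  no gravity-handling step is defined for this stage.
* **Metrics.** Event matching is greedy nearest-first one-to-one (the
  TP/FP/FN definitions do not fix a matching discipline; greedy is
  deterministic and symmetric in the reported F-score). Stride-out
  testing uses the mid-stance point against the zone polygons
  (boundary-inclusive); headings are `atan2` of the planar increment.

## Problem sizes in the tests

The suite exercises: 100 m+ noise-free closed loops per activity
(round-trip below 0.1% RPE, measured at ~1e-14%); a 151 m walking loop at
0.05 m/s$^2$ / 0.2 deg/s noise and 0.5 deg/s bias over 20 seeds (median
ZUPT RPE ≈ 0.1%, three orders below pure strapdown); 100 random
signal/template pairs against the brute-force DTW oracle; 500 strides per
activity for event F-scores (1.0 noise-free and at 2 deg/s); and a
10-fold cross-validation of the classifier on ~350 synthetic windows
(≥ 95%). These sizes make the full suite run in about a minute while
keeping every statistical margin wide.

## Limitations

Heading is unobservable without a magnetometer or map: long straight
segments accumulate yaw uncertainty that closed-loop metrics partially
hide. Jogging and running rely on 11-sample ZUPT windows per stride, so
their drift between updates is larger than walking's (a few percent RPE
under the synthetic noise conditions, versus ~0.1% for walking). The
shipped templates and classifier are trained on the generator's synthetic
morphology; for real recordings, build templates from labelled strides
(`build_template()`) and retrain (`train_activity_model()`). Stops longer
than 2 s are truncated rather than modelled; sitting/standing phases are
handled only through that rule.
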