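---
title: "Camera-based virtual timing gates: model, calibration and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Camera-based virtual timing gates: model, calibration and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virtualgate)
```

## The measurement problem

Sprint coaches time short runs between two gates on a track. Beam-based
photocells are the reference technology; a camera can emulate one by
watching a narrow vertical band of pixels placed on the measurement line.
When an athlete crosses the line, consecutive frames differ strongly inside
the band; when nothing moves, they differ only by sensor noise. The gate is
therefore a change detector with a threshold, and everything else — noise
calibration, clock synchronization, run assembly — exists to turn its
binary firings into accurate elapsed times.

`virtualgate` implements this chain and, because the interesting question
is *how accurate such a gate can be*, pairs it with a synthetic scene
generator with known ground truth and with Bland–Altman agreement
statistics, the standard method-comparison tool in sports and clinical
measurement.

## Detection model

For consecutive frames $I_t, I_{t+1}$ and a band $\Omega$ of $n$ pixels:

$$\mathrm{MSE}(I_t, I_{t+1}) = \frac{1}{n}\sum_{y\in\Omega}
  (\Delta r_y)^2 + (\Delta g_y)^2 + (\Delta b_y)^2,$$

with a single channel term in grayscale mode. The trigger decision is
$B = 1$ iff $\mathrm{MSE} > \theta + \tau$ — a *strict* inequality, so the
boundary value does not fire. Normalizing by the pixel count (not pixel ×
channels) makes the metric invariant to the band's size: tiling a band's
content $p$ times into a $p$-fold larger band leaves the MSE unchanged, so
a single sensitivity threshold $\theta$ serves bands of any geometry.

Key parameters:

* **$\theta$ (default 400, squared gray levels).** The user's sensitivity
  threshold. Sensor noise on small low-cost sensors produces a static-scene
  MSE of roughly 20-30, so 400 sits an order of magnitude above the noise
  while remaining far below the MSE of a genuine high-contrast crossing
  (a 50-gray-level edge over a quarter of the band already yields
  $50^2 \times 3 \times 0.25 \approx 1875$).
* **$\tau$ (default 0, i.e. uncalibrated).** The noise floor, estimated by
  `estimate_noise()` as the *maximum* consecutive-pair MSE over a static
  recording. The maximum, rather than the mean, also absorbs recurring
  background perturbation (foliage, flicker) present during calibration.
  $\tau$ is estimated per region; regions of a multi-barrier share
  $\theta$.
* **Color mode (default RGB).** Color is advised: an athlete's shirt may
  match the background in brightness but rarely in hue, and a grayscale
  gate is blind to equal-luminance contrast.
* **Refractory period (default 1000 ms).** A single athlete presents
  limbs, torso and trailing limbs to the band over several hundred
  milliseconds; the dead time collapses these into one event. The value is
  a design choice — long enough for one passage, far shorter than any
  plausible inter-athlete gap.
* **Timestamp convention (default `later_frame`).** A trigger is a
  property of a frame *pair*; we stamp it with the later frame, the first
  image in which motion is visible. `earlier_frame` and `midpoint` are
  offered; the choice shifts all events by at most one frame interval and
  cancels in elapsed times when both gates use the same convention.
* **Multi-barrier simultaneity.** All regions must fire on the *same*
  frame pair. This is the strictest reading of the dual-beam AND; a
  tolerance-window variant would admit slightly tilted crossings at the
  cost of re-admitting some limb artifacts, and is left as future work.

The MSE is computed in floating point on 8-bit values. Streams captured in
RGB565 (the 16-bit format of the emulated camera module) can be emulated
with `quantize_rgb565()`, which reduces channels to 5/6/5 bits and expands
back by bit replication — replication rather than zero-padding so that
full-scale white maps to 255 and MSE magnitudes remain comparable between
quantized and native streams; detection on the quantized stream is the
firmware-faithful mode.

## Clock synchronization

Each gate keeps its own millisecond clock; transport latency between the
controller and a gate is volatile (tens to hundreds of ms). A ping carries
the controller's send time, the gate stamps its own clock on arrival, and
the controller records the receive time. The midpoint (Cristian-style)
estimator $o_i = t_{dev} - (t_{send}+t_{recv})/2$ is exact whenever forward
and backward latencies are equal; its per-ping error is half the latency
asymmetry and is bounded by half the round-trip time. A synchronization
burst uses 20 pings; pings with RTT above 1.5× the median are discarded
(heavy-tailed delays would otherwise bias the mean), and the surviving
estimates are averaged. Clock drift within a session is not modeled: the
offset is re-estimated at every connection, and consumer oscillators drift
microseconds over the minutes a session lasts — far below the frame
interval.

## What the synthetic generator emulates — and what it does not

`scene_spec()` defaults emulate the target hardware: a 160×240 (portrait
HQVGA) stream at 25 fps. Sensor noise is iid Gaussian per channel, rounded
and clamped to the 8-bit range; for noise SD $\sigma$ the expected
static-scene MSE is $3 \times 2\sigma^2 = 6\sigma^2$, so
`calibrate_noise_sd(24)` = 2 gray levels puts the generator in the middle
of the 20–30 band measured on real sensors (integer rounding adds
$\approx 2 \times 1/12$ per channel, i.e. ~0.5 on top of 24). The athlete
is a solid rectangle of configurable contrast translating at constant
speed; the ground-truth crossing time is the *continuous-time* instant its
leading edge reaches the crossing column — a property of the motion,
independent of frame rate, so only the detector's report is quantized.
Lighting steps ("lights switched on": a global shift of $\delta$ per
channel, producing a single-pair MSE of $3\delta^2$ unclamped) and a
periodic flicker patch reproduce the documented false-positive modes.

Deliberately not modeled: rolling-shutter skew, shadows, photorealistic
texture, articulated limbs, camera shake trajectories, JPEG artifacts.
Passing tests on these scenes therefore demonstrate the *logic* of the
chain — thresholding, calibration, synchronization, quantization — under
controlled conditions; they do not certify performance against real
athletes, where limb-vs-torso triggering and background clutter dominate
the error budget.

## Numerical and design choices

* Grayscale conversion is the unweighted channel mean (the MSE treats
  channels symmetrically, so perceptual weights would be arbitrary here).
  The mean of three integers in thirds never lands on .5, so rounding is
  unambiguous.
* Timestamps are integer milliseconds; synthetic capture times follow
  `round(i * 1000 / fps)`.
* Pixel coordinates are 0-based, row-major, with half-open ranges, and are
  converted to R's 1-based indexing only at the array boundary.
* Bland–Altman limits use the sample SD ($n-1$) and 1.96; boundary points
  count as within (the common convention; on continuous data the event has
  probability zero).
* `pair_runs()` matches greedily in chronological order under plausibility
  bounds (default 1–30 s for a 25 m flying sprint), which discards stray
  triggers that survive the refractory logic.
* All generators and simulators take explicit seeds and are bit-exact
  reproducible; seeded code restores the caller's RNG state.

## Validation harness and problem sizes

`simulate_experiment()` replicates a field comparison: true times uniform
over a realistic range, the reference system reports truth, the camera
system adds a Normal(bias, sd) error and snaps to its frame grid. With the
two observed error regimes (94 ± 62 ms over 84 runs; −52 ± 91 ms over 45
runs) the simulated within-limits percentage averages ≈ 95%, bracketing
the single observed realizations (94.05% and 93.33%).

`end_to_end_accuracy()` exercises the whole chain: per-gate clock offsets
drawn from ±10⁵ ms, a random frame phase per gate, ping-based correction,
session-time noise calibration, per-run crossing scenes with the crossing
phase randomized relative to the frame grid, detection, conversion to
controller time and pairing. With high-contrast silhouettes the elapsed
error stays within two frame intervals (80 ms at 25 fps): one interval of
quantization per gate plus a few ms of synchronization error.

The test suite runs these simulations on frames whose *width* is trimmed
to 24–120 columns while the detection band, its full 160-pixel height (960
band pixels) and the noise calibration stay at the sensor's conditions;
the banded MSE depends only on band pixels, so the statistics are
unchanged while the suite stays fast. Static calibration scenes use 150
frames (6 s), matching a realistic calibration duration.

## Known limitations

* The detector is purely differential: anything that changes the band —
  lighting steps, gusts moving the camera, a second athlete — fires it.
  The negative-control tests demonstrate the lighting failure mode rather
  than defend against it; illumination normalization is out of scope.
* A crossing is localized to one frame interval; sub-frame interpolation
  from the MSE profile is not attempted.
* Single-athlete operation is assumed; `pair_runs()` has no identity
  model and will happily pair two athletes' crossings that fall within the
  plausibility bounds.
* The latency model for synchronization is iid lognormal per direction;
  real transports show bursts and asymmetry drift that the outlier
  rejection only partially addresses.
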