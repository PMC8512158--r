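---
title: "Methods: from belt capacitance to muscle state"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from belt capacitance to muscle state}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beltgait)
```

## The measurement problem

Muscle co-contraction — simultaneous activation of antagonists such as the
quadriceps and hamstrings — stiffens a joint without producing motion, so
it is invisible to motion capture and hard to monitor outside the lab with
surface EMG. A capacitive stretch belt worn around the thigh offers a
cross-modal route: an active muscle belly thickens, the thigh circumference
grows, the belt's elastic segment lengthens, and its capacitance rises.
`beltgait` implements the full analysis chain for such recordings:
calibration of the belt, preprocessing of EMG/GRF/circumference, gait-cycle
statistics, and a quadratic model linking the five recorded thigh muscles
(VL, RF, VM, BFL, BFS) to circumference.

## Calibration

A static stretch sweep of the belt gives (capacitance $C$ in nF, elastic
length $L$ in mm) pairs, fitted by ordinary least squares to

$$L = a_2 C^2 + a_1 C + a_0 .$$

`default_calibration()` carries the reference coefficients
$(a_2, a_1, a_0) = (0.00223, -1.72592, 416.9272)$ with a validity range of
465–606 nF (natural length 95 mm up to the fully stretched 200 mm).
Only the increasing branch of the parabola is physical; the fitted validity
range therefore never extends below the vertex (about 387 nF for the
reference coefficients), and `length_to_capacitance()` always takes the
larger quadratic root. Goodness of fit is reported as $100 R^2$, the
"percent agreement" convention for calibration curves. The hysteresis
index interpolates a stretch sweep and a release sweep onto their common
length grid and reports the largest capacitance gap; a hysteresis-free
sensor gives values at the interpolation-error level.

Walking data can transiently leave the static calibration range, so
`capacitance_to_length()` extrapolates with a warning rather than failing.
Note that evaluating the reference quadratic at the sweep endpoints gives
96.56 mm and 189.96 mm, not exactly 95 and 200 mm — the printed endpoint
lengths are measurements, not points on the fitted curve, and the package
treats them as such.

## Signal preprocessing

All filters are second-order Butterworth, designed with `signal::butter`.

* **EMG envelope**: high-pass at 20 Hz (zero-lag), full-wave
  rectification, low-pass at 10 Hz. The final low-pass is causal by
  default with a `lowpass_zero_lag` switch, because the processing
  description leaves the phase behaviour of that stage open; both variants
  are supported and neither is asserted as the original intent. Envelope
  samples driven slightly negative by the low-pass are clipped to zero.
* **Circumference**: capacitance to length through the calibration curve,
  low-pass at 10 Hz (same causal default and switch), then differentiation
  by central differences (one-sided at the ends) for the rate of change.
* **Vertical GRF**: low-pass at 50 Hz zero-lag upstream of event detection
  (the synthetic generator produces band-limited GRF, so the tests apply
  the detector directly).

Zero-lag mode applies the designed filter forward and backward. That
cancels the phase and squares the magnitude, so the gain at the cutoff is
$1/2$ rather than $1/\sqrt{2}$ — the cutoff-gain tests use 0.5 in that
mode. Edges are padded by odd reflection over $3\times$ the filter order,
and both passes reference their initial state to the first sample value
(scaled by the filter's DC gain), which makes a constant signal an exact
fixed point of both modes and suppresses startup ringing on signals with a
large DC component such as circumference in mm.

MVC normalization divides each muscle's envelope by the maximum envelope
value across the maximal voluntary co-contraction trials (standing and
sitting). Values above 1 are allowed: dynamic activity can exceed a
static maximum.

## Gait segmentation and cycle statistics

Heel contact is the first frame with vertical GRF above 20 N. The bare
first-frame rule is fragile around the threshold, so the detector requires
a rising edge preceded by at least 50 ms continuously at or below the
threshold and discards events within 300 ms of the previous one; both
guards are configurable and the defaults are far shorter than any
physiological swing or stride time (walking stride about 1.1 s at 4 km/h,
running 0.7 s at 12 km/h). Cycles span $[{\rm contact}_k, {\rm
contact}_{k+1})$; each is linearly interpolated onto a 101-point 0–100%
grid (the biomechanics convention), and ensemble means and sample
standard deviations (divisor $n-1$; the divisor is a package choice, as is
SD $= 0$ for a single cycle) are computed per grid point.

Between-cycle stability is summarized per condition by the average
amplitude in a cycle (mean over the cycle of the offset from a reference
length, averaged over cycles), the average deviation between cycles (mean
over the grid of the across-cycle SD), and their ratio, the coefficient
of variation in percent. The reference length is a required explicit
argument: tabulated amplitudes of about 130 mm cannot be reconciled with
the 95–200 mm elastic range without knowing the original reference, so
the package refuses to hard-code one. Because a "cycle amplitude" can
also be read as the within-cycle excursion, the mean peak-to-peak range
is reported alongside (`range_mm`). For muscle activity, the averaged
row reports the CV under both conventions — ratio of averages and mean of
per-muscle CVs — explicitly labelled, since the two differ whenever
muscles have unequal amplitudes and the original convention is not
recoverable from the published numbers.

## The cross-modal model

The core estimator is the quadratic map from the five activities
$A_{it}$ (fractions of MVC) to circumference:

$$\hat L_t = \sum_{i=1}^{5}\left(w_{i1} A_{it} + w_{i2} A_{it}^2\right) + b,
\qquad E = \sum_{t=1}^{T}\left(L_t - \hat L_t\right)^2 .$$

`crossmodal_fit()` minimizes $E$ by an SVD least-squares solve. Sustained
co-contraction drives all five activities up and down together, which can
make the design rank-deficient; the fit then returns the minimum-norm
solution with a warning instead of failing. Muscle order is fixed to
(VL, RF, VM, BFL, BFS) in every matrix and serialization.

Agreement between measured and estimated circumference is evaluated by
RMSE, the OLS regression of measured on estimated, and ICC(2,1) — the
Shrout–Fleiss two-way random-effects, absolute-agreement, single-measure
intraclass correlation with the paired frames as targets and the two
signals as raters ($k = 2$):

$$\mathrm{ICC}(2,1) =
\frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)} .$$

Evaluation pairs are resampled to 10 Hz by decimation (configurable via
`eval_rate`): the paired-scatter evaluation is defined at 10 Hz, while
fitting uses the full 1 kHz frames by default; whether the original fit
used 1 kHz or 10 Hz frames is not recoverable, so both are supported.

`evaluate_session()` exposes `activities_source` and
`circumference_source` switches (`"envelope"`/`"capacitance"` for the
measured path, `"truth"` for generator ground truth). The truth path
exists because the envelope is an estimate of activation, not the
activation itself: even on noiseless data the envelope-based refit cannot
reproduce the circumference to machine precision, so exactness checks
(ICC $=1$, RMSE $<10^{-8}$ mm) run on truth sources while the envelope
path is validated by its own bound (envelope–activation correlation
$> 0.8$).

## The synthetic session generator

No recordings are distributed with the package, so `generate_session()`
produces complete, seed-reproducible sessions with known ground truth.
One global seed drives independent per-channel substreams; adding a
channel never perturbs the others, and a fixed configuration and seed are
byte-identical.

* **Activations** are sums of Gaussian bumps on the cycle phase
  (wrap-around continuous): quadriceps around heel contact and late
  swing, hamstrings around mid-cycle and just before contact, with
  running at about 2.2-fold walking peaks and squats as one broad
  knee-extensor bump. Per-cycle, per-muscle amplitudes are jittered by a
  uniform ±30% factor, which yields between-cycle activity CVs in the
  10–30% range typical of treadmill gait. Co-contraction presets use a
  maximal raised-cosine plateau (defining MVC = 1), the passive preset is
  silent. Gait styles add a tonic offset (conscious co-contraction,
  default 0.2) or scale swing activity by 0.5 (conscious relaxation).
* **EMG** is the standard surrogate: a zero-mean band-limited Gaussian
  carrier (20–450 Hz, unit RMS, 0.5 V gain) multiplied by the activation.
  It reproduces envelope behaviour, not motor-unit physiology.
* **GRF**: walking stance is two Gaussian humps (1.1 and 1.0 body
  weight), running one higher hump (2.3 BW), tapered to zero at the
  stance edges; swing is exactly 0 N. Body weight defaults to 700 N
  (one healthy adult male). The ground-truth contact of each cycle is
  defined by the same first-frame-above-20 N rule the detector uses, so
  generator and detector are comparable sample by sample.
* **Circumference** is the truth model applied to the activations, plus
  an optional swing-phase negative half-sine (passive deformation: the
  belt sees the relaxed muscle flatten while EMG is silent; amplitude
  2 mm in the passive preset), plus Gaussian measurement noise with SD
  1.8 mm by default — the magnitude of the reported model error, taken
  as the realistic per-sample uncertainty of the belt-to-model
  comparison. **Capacitance** is the calibration inverse of the noisy
  circumference.
* The truth model defaults to $w_1 = (5,4,6,3,2)$ mm,
  $w_2 = (-2,3,-1,2,1)$ mm and $b = 96.6$ mm: circumference excursions of
  a few mm during gait and up to ~23 mm under maximal co-contraction,
  anchored at the elastic part's natural length.

What the generator does *not* emulate: electrode noise and motion
artefact, EMG crosstalk between muscles, soft-tissue wobble, belt
slippage, temperature or pressure cross-sensitivity of the sensor, and
stride-time variability (cycles have fixed duration; only amplitudes
vary). Passing tests therefore demonstrate the correctness of the
analysis chain under its stated model, not field performance of the
hardware.

## Validation conditions and problem sizes

The test suite and `scripts/acceptance.R` use:

* **Worked examples**: the tabulated (deviation, amplitude) pairs
  reproduce their CVs by straight ratio; elongation 95→200 mm ≈ 110%;
  flocking areal density 18 mg / (15 × 150 mm²) = 8.0 × 10⁻³ mg/mm².
* **Evaluation protocol sessions**: five 4 s sitting maximal
  co-contractions followed by ten 4 s squats — 60 s (60 000 frames) at
  1 kHz, noise SD 1.8 mm, 20 seeds. This mirrors the original evaluation
  movements (with and without explicit co-contraction); the squat count
  is raised from the original five so the session reaches the stated
  60 000 frames.
* **Coefficient recovery**: 29 walking strides plus 7 squats
  (≈ 60 000 frames), fitting on the unfiltered noisy circumference; the
  recovered coefficient vector $(w_1, w_2, b)$ has median relative error
  well under 5% across 20 seeds. The *split* between a muscle's linear
  and quadratic coefficient is only weakly identified from gait-range
  activities ($A$ and $A^2$ are nearly collinear on $[0, 0.8]$), so
  per-coefficient errors are larger than the vector error while
  predictions remain accurate — a property of the design, not of the
  solver.
* Small analytic fixtures (tones at and above filter cutoffs, 3-point
  ICC cases, 3-frame interpolation fits) verify the numerics against
  closed forms and independent oracles (normal equations, `stats::aov`
  mean squares).

## Worked example

```{r example, eval = FALSE}
ses <- generate_session("walk", n_cycles = 10, seed = 42)
ev <- detect_heel_contacts(ses$channels$vgrf_N)          # 10 contacts
circ <- process_circumference(ses$channels$capacitance_nF,
                              default_calibration())
gcs <- gait_cycles(circ$length, ev)
circumference_cycle_stats(gcs, reference_length = 96.6)
res <- evaluate_session(ses, activities_source = "truth")
res                                                       # RMSE, ICC(2,1)
```

## Known limitations

The belt integrates all muscles under it: the model estimates the joint
effect, never an individual muscle's tension, and passive deformation
(circumference change without EMG activity) is visible to the belt but
unexplainable by the model — it surfaces as locally inflated residuals,
which is itself diagnostic. CVs computed from rounded tabulated pairs
inherit the table's rounding. The causal/zero-lag ambiguity of two
low-pass stages is exposed as a switch rather than resolved.
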