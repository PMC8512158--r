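# beltgait

Analysis of muscle state from a capacitive stretch-sensor belt worn on the
thigh, recorded together with surface EMG of five thigh muscles (vastus
lateralis, rectus femoris, vastus medialis, biceps femoris long and short
head) and vertical ground reaction force.

Muscle co-contraction stiffens a joint without moving it, so it escapes
motion capture; but an active muscle belly thickens, and a stretch belt
around the thigh sees the circumference change. `beltgait` implements the
analysis chain for such multimodal recordings, for biomechanists and
wearable-sensing researchers:

* **Calibration** — the belt's elastic-part length is a quadratic in its
  capacitance, `L = a₂C² + a₁C + a₀`, fitted by OLS to a static stretch
  sweep and inverted on its monotone branch
  (`fit_calibration()`, `capacitance_to_length()`,
  `length_to_capacitance()`). The reference curve is
  `L = 0.00223C² − 1.72592C + 416.9272` over 465–606 nF.
* **Preprocessing** — EMG envelopes (20 Hz high-pass, zero-lag → full-wave
  rectification → 10 Hz low-pass), MVC normalization against maximal
  co-contraction trials, circumference conversion and filtering
  (`emg_envelope()`, `compute_mvc()`, `process_circumference()`).
* **Gait** — heel contacts from the vertical-GRF > 20 N rule with debounce
  guards, segmentation into cycles, time-normalization onto a 101-point
  0–100 % grid, ensemble mean/SD, and between-cycle statistics (average
  amplitude, average deviation, coefficient of variation)
  (`detect_heel_contacts()`, `gait_cycles()`,
  `circumference_cycle_stats()`).
* **Cross-modal model** — the core estimator: circumference as a quadratic
  form of the five muscle activities `A_i` (fractions of MVC),

  ```
  L̂(t) = Σᵢ [ wᵢ₁ Aᵢ(t) + wᵢ₂ Aᵢ²(t) ] + b,   E = Σₜ (Lₜ − L̂ₜ)²
  ```

  fitted by least squares (`crossmodal_fit()`, an S3 model object with
  `coef`/`predict`/`summary`/`plot`/`simulate`/`residuals` methods) and
  evaluated by RMSE, the measured-vs-estimated regression line, and the
  Shrout–Fleiss ICC(2,1) on 10 Hz-resampled pairs (`evaluate_session()`).
* **Synthetic sessions** — a seed-reproducible generator for walking,
  running, squatting, maximal co-contraction and passive-flexion sessions
  with known ground truth (`generate_session()`), used throughout the
  tests in place of the original recordings, which are not public.

## Worked example

```r
library(beltgait)

ses <- generate_session("walk", n_cycles = 10, seed = 42)
ev  <- detect_heel_contacts(ses$channels$vgrf_N)
circ <- process_circumference(ses$channels$capacitance_nF,
                              default_calibration())
gcs <- gait_cycles(circ$length, ev)
circumference_cycle_stats(gcs, reference_length = 96.6)
#> Cycle statistics
#>   average amplitude in a cycle : 1.488
#>   average deviation between cycles: 0.312
#>   coefficient of variation     : 21 %
#>   mean within-cycle range      : 6.343
#>   cycles: 9

evaluate_session(ses, activities_source = "truth")
#> Cross-modal session evaluation
#>   fit frames: 11500; evaluation pairs: 115
#>   RMSE      : 0.622 mm
#>   regression: y = 0.9734 x +2.583
#>   ICC(2,1)  : 0.9463
```

Ten simulated strides are segmented into 9 full cycles; the circumference
rides about 1.5 mm above the 96.6 mm natural length on average, with a
0.31 mm between-cycle deviation (CV 21 % — dominated here by the
generator's deliberate ±30 % stride-to-stride amplitude jitter and the
1.8 mm default measurement noise). The quadratic model fitted to this
single short noisy session already agrees with the measured circumference
at ICC(2,1) ≈ 0.95 with sub-millimetre RMSE; longer sessions with larger
movements (co-contraction + squats) reach ICC > 0.99.

The full pipeline — calibration, preprocessing, segmentation, statistics,
fit, JSON report — is chained by `run_pipeline()`, and sessions round-trip
through CSV (`write_session_csv()` / `read_session_csv()`) with a
`write_truth_json()` sidecar for synthetic ground truth.

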