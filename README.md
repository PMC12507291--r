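# streakvision

Rapid eye movements (saccades) sweep the visual scene across the retina at
several hundred degrees of visual angle per second. An object that is
itself displaced *during* a saccade leaves an oriented smear — a motion
streak — on the retina, and such streaks are known to speed up corrective
(secondary) saccades to the displaced object. `streakvision` implements a
physiologically grounded early-vision model and a predictive "switch"
model that together explain how these streaks can be represented and used
for gaze correction, driven entirely by a synthetic trial generator that
emulates the corresponding psychophysical experiment.

## The model

The pipeline maps a retinotopic input movie `I(t, y, x)` to a population
response `R_N(θ, ω, t, y, x)` resolved over spatial frequency θ and
orientation ω:

1. **Log-Gabor filter bank.** Seven SFs (0.25–4 cpd) × eight orientations
   (22.5° steps) × two quadrature phases. SF bandwidth is constant at
   1.5 octaves above 2 cpd and widens by 0.26 octaves per octave below;
   orientation bandwidth follows the Gabor relationship
   `w_ω = 2 atan( sqrt(2 ln 2) / (2π σ_RF θ) )`, giving ≈41° FWHM above
   1 cpd and ≈100° at 0.1 cpd.
2. **Temporal response functions.** Per-SF impulse responses
   `H(t) = A (t/τ)^n e^(−t/τ) (1/n! − B (t/τ)^k/(n+k)!)` are fitted so
   that, after temporal probability summation
   `S(f) = [∫ |I(t,f) ∗ H(t)|^β dt]^{1/β}`, they reproduce a
   spatiotemporal contrast-sensitivity surface (Kelly's stabilized
   surface, converted from motion to flicker thresholds). A penalized
   tensor-spline surface over (time, log SF) interpolates the fitted
   kernels so a TRF can be extracted for any SF.
3. **Energy and delayed normalization.** Quadrature responses are squared
   and summed (`R_E = R_even² + R_odd²`) and divisively normalized by a
   temporally lowpassed, spatially blurred, channel-pooled copy of
   themselves: `R_N = R_E^n / (σ^n + R_LP^n)` with σ = 0.07, n = 1.4 —
   producing transient-then-sustained dynamics.
4. **Switch model.** A sensorimotor contingency `x̄` (mean static-trial
   response, collapsed over channels) predicts the visual change a
   saccade should cause. The prediction error
   `y_k = Δz_k⁺ − Δx̄_k⁺` compares each trial's measured positive change
   against the windowed prediction; the first sample with `y_k > λ` is
   the switch (prediction-error) time at which gaze correction can be
   triggered.

The synthetic generator reproduces the study conditions: a bandpass noise
target (−3 dB cutoffs 0.33/1.02 cpd, Gaussian aperture SD 0.56 dva, 100%
Michelson contrast) displaced 6.6 dva in 25 ms strictly during a
horizontal saccade (mean amplitude 17.6 dva, duration 53.6 ms, peak
velocity ≈528 dva/s), in five direction conditions × streak
present/absent.

## Worked example

```r
library(streakvision)

## orientation bandwidth anchors of the filter bank
orientation_bandwidth(c(2, 0.25, 0.1))
#> [1]  41.09011  73.70770  99.68691

## fit temporal response functions and the time-by-SF surface (~1 min)
fits <- fit_trf_set()
surface <- fit_trf_surface(fits)
surface
#> <trf_surface> 31 training SFs in [0.05, 10] cpd, window 0.35 s, max rel RMSE 0.035
surface_reconstruction_mse(surface)$mse
#> [1] 0.00331909

## a single trial through the full model
patch <- make_noise_patch(seed = 7)
trial <- simulate_trial("upward", "present", patch, scale = battery_scale(),
                        seed = 1)
trial
#> <retinal_movie> 141 x 251 px (pitch 0.1220 dva), 45 frames @ 240 Hz
```

`fit_trf_set()` fits one temporal kernel per spatial frequency; the
reported reconstruction error (mean squared error in log10 sensitivity
between the target surface and the surface re-predicted from spline
kernels) summarizes how faithfully the kernel family compresses the
sensitivity data. `run_battery()` simulates a full trial battery, builds
the sensorimotor contingency from its static trials, and returns
per-trial switch times and channel engagement summaries.

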