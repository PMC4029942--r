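# akfvitals

Adaptive Kalman filtering of multichannel cardiorespiratory recordings
from non-contact sensors (e.g. magnetic induction coils): separates three
raw channels into per-channel baseline offsets, one shared respiratory
signal and one shared cardiac signal, while continuously estimating
respiration and heart rates and feeding them back into the filter model.
Intended for researchers in biomedical signal processing who need a
real-time-capable alternative to frequency filtering when respiratory
harmonics overlap the cardiac band.

## The model

A seven-state time-varying Kalman filter with state vector

```
x = (X_f, V_f, X_s, V_s, C1, C2, C3)'
```

— cardiac position/velocity, respiratory position/velocity, and one
random-walk offset per sensor. The transition matrix A_k holds two
discretized harmonic-oscillator blocks `[[1, dt], [-w^2 dt, 1]]` at the
(fed-back) angular rates `w_f = 2*pi*f_f` and `w_s = 2*pi*f_s`, plus an
identity block for the offsets. Adaptation re-estimates, at every 10th
sample (9.5 Hz effective rate at the 95 Hz processing rate):

* `R_k = diag(sigma_noise^2)` from the std of the first-differenced last
  0.5 s of each channel (divided by sqrt(2));
* `Q_k = diag(1, w_f^2, 1, w_s^2, sigma_trend^2)` with
  `sigma_trend = 0.1 * sigma_resp` and `sigma_resp` the std of the last
  20 s;
* the fusion gains of the measurement matrix,
  `h_f = (sigma_heart / sigma_noise)^2 * scal_f` and
  `h_s = sigma_resp^2 * scal_s`;
* both rates, by peak detection on the filtered states X_s and X_f over
  20 s / 10 s buffers, clamped and lowpass-smoothed (0.05 / 0.1 Hz).

All estimates are smoothed by first-order Butterworth IIR lowpass filters;
the first 22.5 s (warm-up) see no rate feedback and are excluded from all
metrics. Setting `adaptive = FALSE` freezes every matrix at its
initialization — the non-adaptive baseline filter.

## Worked example

The package ships a synthetic-session generator (no recordings of this
sensor type are publicly deposited). The `worst_case` preset places the
heart rate (42 bpm) exactly on the second respiratory harmonic
(respiration 21 min^-1) — the configuration where band-pass separation is
impossible — and the `BS` configuration preset initializes the filter with
deliberately wrong variances:

```r
library(akfvitals)
sess <- generate_session(session_preset("worst_case", duration = 150, seed = 1))
fit <- akf(sess, akf_config("BS"))
summary(fit)
#> Adaptive Kalman filter, preset BS, 14250 samples (warm-up 22.5 s excluded from metrics)
#>   heart-rate error vs truth:       mean   0.59 bpm   (sd 2.42)
#>   respiration-rate error vs truth: mean  -0.37 /min  (sd 1.63)
#>   offset residuals (raw - offset), per sensor:
#>     s1: mean       37.7   sd     1117.9
#>     s2: mean     8621.5   sd    11022.8
#>     s3: mean     6833.2   sd     8761.3

summary(akf(sess, akf_config("BS", adaptive = FALSE)))
#> Non-adaptive Kalman filter, preset BS, 14250 samples (warm-up 22.5 s excluded from metrics)
#>   heart-rate error vs truth:       mean  18.85 bpm   (sd 2.40)
#>   respiration-rate error vs truth: mean  -0.37 /min  (sd 1.64)
#>   ...
```

Despite the misconfigured start, the adaptive filter recovers the heart
rate to within ~0.6 bpm (the residual spread is dominated by the
sample-resolution quantization of peak intervals, 0.0175 % per bpm at
95 Hz), while the baseline filter is pulled ~19 bpm off by the respiratory
harmonic. Respiration, being the dominant oscillation, is estimated well
by both. `plot(fit)` draws the raw channels with estimated offsets, the
separated cardiac and respiratory states, and both rate tracks against
the ground truth.

A command-line front end wraps the same functions:

```sh
inst/cli/akfvitals simulate --preset worst_case --seed 1 --out sess.csv
inst/cli/akfvitals run --input sess.csv --preset BS --out results.csv --metrics metrics.json
inst/cli/akfvitals compare --input sess.csv --preset BS --out report.json
```

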