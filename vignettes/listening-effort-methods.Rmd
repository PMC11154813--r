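---
title: "Measuring listening effort: EEG alpha power and pupillometry methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring listening effort: EEG alpha power and pupillometry methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effortlab)
```

# Overview

`effortlab` analyzes listening-effort experiments in which participants
repeat noise-vocoded sentences in babble while EEG and pupil diameter
are recorded simultaneously. This vignette documents the methods each
module implements and the conventions behind them.

# Stimuli: noise vocoding and trial assembly

A noise vocoder degrades speech to a controlled number of spectral
channels while preserving temporal envelopes. `design_filterbank()`
splits 80–8000 Hz into `n_channels` contiguous bands with log-spaced
(geometric) edges: edge $i$ is $f_{lo} (f_{hi}/f_{lo})^{i/n}$, so every
band spans the same ratio.

```{r}
bank <- design_filterbank(n_channels = 6, f_lo = 80, f_hi = 8000)
round(bank$edges_hz, 1)
```

`vocode_signal()` band-passes the input with zero-phase 4th-order
Butterworth responses, extracts each band's Hilbert envelope, uses it to
modulate a band-limited white-noise carrier, and sums the bands
(dividing each envelope by the channel count to keep the sum bounded).
Fine structure is destroyed; only the envelopes survive:

```{r}
fs <- 32000
t <- seq(0, 1 - 1/fs, by = 1/fs)
tone <- sin(2 * pi * 1000 * t)
voc <- vocode_signal(tone, bank, fs, seed = 1)
# no correlation with the original carrier remains
round(cor(tone[6400:25600], voc[6400:25600]), 3)
```

`assemble_trial()` builds the 6-second trial: babble alone for 1 s, the
vocoded sentence mixed in from 1–4.5 s (shorter sentences are padded
symmetrically), babble alone again until 6 s. Speech and babble are
RMS-equalized first, then the speech is scaled by $10^{\mathrm{SNR}/20}$,
so the nominal SNR is exact by construction. `write_trial_batch()`
renders batches to 32-bit float WAV with a CSV manifest.

# Speech reception thresholds: the adaptive staircase

Thresholds are estimated with a 20-sentence staircase over 5-word
sentences. After sentence $i$ with $c_i$ words correct, the SNR moves by

$$ \mathrm{SNR}_{i+1} = \mathrm{SNR}_i - s_i \frac{c_i/5 - p_t}{0.5},
   \qquad s_i = \max(4 \cdot 0.8^i,\ 1)\ \mathrm{dB}, $$

where $p_t$ is the target intelligibility (0.5 or 0.8). The SRT is the
SNR presented at the 20th sentence. `virtual_listener()` supplies a
logistic psychometric function for simulation:

```{r}
listener <- virtual_listener(srt50_db = 1.7, slope_per_db = 0.15)
sim <- simulate_srt_experiment(listener, target = 0.5,
                               n_runs = 200, seed = 11)
round(median(sim$srt_db), 2)  # converges near the true 1.7 dB
```

# EEG alpha power

`alpha_envelope()` runs each channel through a 50 Hz notch (Q = 30), an
8–12 Hz band-pass, and the Hilbert transform, yielding the instantaneous
alpha amplitude. Filtering is zero-phase: the squared analog Butterworth
magnitude is applied in the FFT domain, which has exactly the magnitude
response of a forward–backward pass, unity at the band center, and no
stability issues at narrow relative bandwidths.

`trial_alpha_change()` averages the parietal channels (P3, P4, Pz),
takes window means — baseline 0.3–0.8 s and sentence encoding
3.3–4.3 s after trial onset, both inside settled portions of the trial —
and reports

$$ \Delta\alpha = \frac{\bar a_{\mathrm{enc}} - \bar a_{\mathrm{base}}}
   {\bar a_{\mathrm{base}}} \times 100\%. $$

Positive values mean alpha rises during encoding. The measure is
invariant to overall amplitude scale. `qc_recording()` flags channels
whose fraction of samples at or above 80 µV exceeds 5%.

```{r}
rec <- synth_eeg_trial(180, alpha_amp_uv = 12.5, noise_sd_uv = 0.1,
                       trial_jitter_pct = 0, seed = 21)
res <- trial_alpha_change(alpha_envelope(rec), trial_onset = 1)
round(res$percent_change, 1)  # true injected change: 180%
```

# Pupillometry

Traces are 1000 Hz pupil diameters in pixels, starting 500 ms before
stimulus onset. The pipeline:

1. `detect_blinks()` finds runs of invalid samples;
   `deblink_and_interpolate()` widens each by 100 ms on both sides and
   bridges the gap linearly. A gap touching a trace edge has no anchor,
   so the trial is flagged excluded rather than extrapolated.
2. `preprocess_trace()` subtracts the mean of the 500 ms pre-stimulus
   span (for averaged-curve outputs) and downsamples to 50 Hz by
   20-sample bin means. Because the mean is linear, downsampling and
   baseline subtraction commute exactly.
3. `trial_mpd_percent()` computes the maximum pupil dilation: the peak of
   the *raw* downsampled trace over 2–6 s, as percent change over the
   0–1 s noise-phase mean. Using the raw trace makes the ratio
   scale-invariant.
4. `pupil_condition_summary()` drops the first five trials of each
   condition (pupil responses habituate early in a block) and any
   excluded trials before averaging.

```{r}
trace <- synth_pupil_trial(10.7, seed = 31)
pp <- preprocess_trace(deblink_and_interpolate(trace))
round(trial_mpd_percent(pp)$percent_change, 1)  # true MPD: 10.7%
```

# Group statistics

`thi_score()` totals the 25-item tinnitus handicap questionnaire
(yes/sometimes/no scored 4/2/0). `compare_groups()` first runs a
mean-centered Levene test; with Levene $p \ge .05$ it uses the
pooled-variance Student t test, otherwise Welch's, and reports the
two-sided p-value and pooled-SD Cohen's d.

```{r}
a <- effortlab:::with_seed(41, rnorm(21, 9.1, 0.3))
b <- effortlab:::with_seed(42, rnorm(26, 10.7, 0.3))
compare_groups(a, b)
```

`t_test_power()` uses the noncentral t distribution
($\mathrm{df} = 2n-2$, $\mathrm{ncp} = d\sqrt{n/2}$);
`required_sample_size()` inverts it. Note that the tails matter: at
$d = 1.16$, $\alpha = .05$, power $.95$, the one-tailed answer is 17 per
group and the two-tailed answer is 21.

```{r}
required_sample_size(1.16, alpha = 0.05, power = 0.95, tails = "one")
required_sample_size(1.16, alpha = 0.05, power = 0.95, tails = "two")
```

# Synthetic cohorts and end-to-end reproduction

`default_cohort_spec()` holds the reference cohort parameters: group
sizes (21 + 26), per-condition group means and SDs of the alpha change
and the MPD, SRT distributions, a reference THI score set, and the
physiological generator settings. `draw_cohort_truth()` draws each
subject's latent true values; `synth_eeg_block()` and
`synth_pupil_trial()` generate raw data embedding those truths (pink
noise plus modulated 10 Hz parietal alpha; drifting ~1000 px pupil with
a gamma-shaped dilation, blinks, and sensor noise).

`analyze_cohort()` closes the loop — generate, then analyze with the
exact same pipelines used for real data — so recovery of the injected
parameters is a testable property. `reproduce_tables()` wraps
everything (staircases included) and writes provenance-stamped summary
tables:

```{r, eval = FALSE}
cfg <- run_config(seed = 1, out_dir = "effortlab-out")
rep <- reproduce_tables(cfg)   # ~6 min for the full default cohort
rep$mpd[, c("condition", "tinnitus_mean", "control_mean", "p_value")]
```

All randomness descends from one master seed through a stable string
hash (`derive_seed()`), so identical seeds give identical datasets and
reports on any platform.

# Reproducibility notes

* Every writer embeds units in column names (ms, µV, px); readers
  validate columns and report parse errors with row numbers.
* `run_config()` merges YAML and programmatic overrides over built-in
  defaults and attaches a content hash that is stamped into every output
  table.
* The acceptance script (`scripts/acceptance.R`) recomputes the key
  worked examples against the installed package and writes them as JSON.
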