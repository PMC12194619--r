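---
title: "Methods: neuromuscular crossover analysis and its synthetic test bed"
author: "primetrial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neuromuscular crossover analysis and its synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primetrial)
```

# The analysis problem

A randomized crossover, sham-controlled priming experiment asks whether a
~25 min exercise protocol performed with tonic spinal cord transcutaneous
stimulation (scTS) changes subsequent lower-limb motor output differently
than the same protocol with sham stimulation. Each of 12 subjects is
measured before (Pre) and after (Post) both priming conditions, on three
voluntary tasks and one stimulation assessment:

* **MVC** — maximal isometric knee extension: maximum torque, peak rate of
  torque development (RTD), and EMG amplitude/median power frequency (MDF)
  of vastus lateralis (VL) and rectus femoris (RF).
* **Torque steadiness** — a 20%-MVC hold: lowest coefficient of variation
  (CV) of torque over a sliding window, with EMG metrics in that window.
* **Explosive extension** — maximal pushes on an inclined sled ergometer:
  peak force, rate of force development (RFD), velocity and power, with
  push-phase EMG.
* **Recruitment curves** — evoked-potential amplitude vs stimulation
  intensity in supine rest: activation threshold and maximal peak-to-peak
  amplitude (scTS condition only).

The statistical layer is a 2x2 within-subject design per outcome variable:
Time (Pre/Post) x Treatment (scTS/sham) repeated-measures ANOVA, Bonferroni
post hoc tests on the simple effects when the interaction is significant,
and a paired comparison of the within-session percent changes
(Post-Pre-delta%) between conditions with Cohen's dz.

Because the underlying human recordings are not deposited, the package
carries a synthetic-data generator that emulates the signals and the effect
structure, so every stage of the chain is testable end to end.

# Signal processing

All channels are sampled at 1000 Hz. Three filters are applied before any
metric is computed, mirroring standard practice for these signals:

| signal | filter | default |
|---|---|---|
| EMG | band-pass | 10–499 Hz |
| isometric torque | low-pass | 10 Hz |
| sled force & velocity | low-pass | 25 Hz |

The acquisition software's filter family and phase handling are not
published, so the package makes them explicit configuration: a 4th-order
Butterworth applied forward and backward (`zero_phase = TRUE`), giving an
effective 8th-order magnitude response and zero group delay. Zero phase
matters here because the timing of RTD/RFD peaks is itself an outcome.
Since no filter-design package is available in the target environment, the
Butterworth bilinear-transform design and the forward-backward pass are
implemented in the package and were verified against an independent
reference implementation during development (coefficients agree to full
double precision).

Edge handling: the forward-backward pass runs over an odd-symmetric edge
extension whose length covers 3 filter lengths and up to ~7 decay constants
of the slowest pole (capped at 1024 samples). Residual edge transients are
kept out of the metrics by excluding the first and last 100 ms of each
trial from the sliding-window searches at the trial level (the low-level
window functions accept an `edge_trim_s` argument, default 0).

Window conventions: all window arguments are in seconds, converted to
samples by rounding half up; windows are half-open `[start, start + dur)`.

**Spectral estimation.** MDF uses a Welch estimate (Hamming window, 256 ms
segments, 50% overlap, per-segment mean removal) with linear interpolation
of the half-power crossing between spectral bins, restricted to the
10–499 Hz band. On 10 s windows the estimator's standard deviation is
~1 Hz; on 1 s MVC windows it is ~4 Hz, which is why tests of 1 s window MDF
use a 3-sigma (~15 Hz) band while whole-trace and 10 s window checks use
the generator's 5 Hz contract.

# Task analyses and their open definitions

Several operational definitions are not stated in the source protocol; the
package fixes them as follows (each is an explicit argument where
sensitivity analysis is plausible):

* **MVC window**: the 1 s sliding window maximizing the windowed *mean*
  torque (1-sample step, earliest window on ties). Maximizing the windowed
  mean rather than the instantaneous maximum makes the EMG window and the
  torque outcome refer to the same epoch.
* **RTD rising phase**: from contraction onset — the last sample before the
  global maximum at which torque is below baseline + 5% of (max −
  baseline), baseline being the first 200 ms — to the global maximum.
  Slope by central difference of the 10 Hz-filtered trace; the filter
  itself suppresses derivative noise.
* **Steadiness**: CV = sample SD / mean over a 10 s sliding window,
  1-sample step, lowest CV wins, earliest on ties. Attempts of any length
  >= the window are scanned in full.
* **Push phase**: onset when the 25 Hz-filtered force exceeds baseline mean
  + 3 baseline SD; the threshold is floored at 1% of the peak excursion
  because a pure k·SD rule fires on zero-phase filter pre-ringing when
  baseline noise is near zero. The end is the earlier of force returning to
  the baseline band and the backward velocity starting to fall (negative
  derivative sustained 50 ms) — the latter is the physical signature of the
  force dropping below the gravity component along the rail.
* **Evoked-potential windows**: response 5–55 ms and baseline −55 to −5 ms
  around each stimulus, clear of the 1 ms artifact and covering
  posterior-root-reflex latencies for thigh and calf muscles.
* **"Reproducible" evoked responses**: the activation threshold is the
  lowest intensity at which >= 4 of 5 per-stimulus peak-to-peak amplitudes
  exceed the noise floor criterion (baseline mean + 3 SD of the pooled
  baseline-window peak-to-peak values) *and* the next available intensity
  does too; the final grid intensity, having no confirmation step,
  qualifies on its own responses. Thresholds are reported on the 5 mA grid
  (no interpolation).
* **Pre/Post curve normalization**: both curves are scaled by the joint
  Pre/Post maximum (exactly one curve attains 100%); a per-phase option
  exists (`scope = "per_phase"`) because the published wording is ambiguous.
* **Best attempts**: highest max torque (MVC), lowest CV (steadiness),
  highest peak power (explosive); ties go to the earliest attempt. In the
  pipeline the selection cell is subject x session x condition x time x
  limb.

# Statistics

The 2x2 within-subject ANOVA is computed from the classical sum-of-squares
decomposition with each effect tested against its own effect-by-subject
stratum, F(1, n−1). With two-level factors sphericity holds by
construction. The implementation is checked in the test suite against a
first-principles projection-matrix oracle (agreement to 1e-8 relative) and
against base R's `aov` error-strata route.

The delta% comparison gates on Shapiro–Wilk normality of the paired
differences at alpha = 0.05 (the gate alpha is not published; 0.05 is the
package's choice): paired t when not rejected, otherwise Wilcoxon
signed-rank with Pratt handling of zero differences and the exact
distribution when n <= 25 without ties. The effect size is Cohen's dz
(mean of paired differences / their SD), consistent with the matched-pairs
a-priori power computation that the study's n = 12 is based on; d_av is
available as an alternative. ES bins: negligible < 0.20 <= small < 0.50 <=
medium < 0.80 <= large.

Power for the matched-pairs design is exact noncentral-t:
`matched_pairs_power(0.9, 12)` = `r round(matched_pairs_power(0.9, 12), 3)`
(> 0.80), and `required_n(0.9)` = `r required_n(0.9)`, reproducing the
published a-priori design point.

The post hoc family is the 4 simple effects (Pre vs Post within each
condition, condition contrast within each time), Bonferroni-multiplied and
capped at 1; the family size is configurable since it is not published.
Missing design cells are hard errors, never imputed: the study is
complete-case by design.

# The synthetic world

The generators state one concrete world; their defaults are the protocol's
stated parameters wherever those exist, and otherwise a value a
practitioner would call typical, fixed once:

* **Anthropometrics**: body mass ~ N(77.5, 10.1) kg, stature ~ N(178, 7.2)
  cm (the published cohort moments), rejection-sampled into the BMI
  18.5–29.9 inclusion window. MVC torque ~ N(230, 35) N·m; MVC EMG RMS
  300–400 µV by muscle; MDF ~ N(80, 8) Hz — typical young-male knee
  extensor values.
* **MVC trials**: logistic torque rise (k = 12 s^-1, so peak RTD = A·k/4)
  to a 4–5 s plateau; EMG scaled proportionally to the torque plateau.
* **Steadiness**: 2 s ramp to 20% MVC, ~18 s hold; the plateau fluctuation
  is <= 6 Hz noise standardized so the plateau CV equals the programmed
  value (default 1.5%, a typical young-adult value) — the 6 Hz cap keeps it
  essentially untouched by the 10 Hz torque filter.
* **Explosive pushes**: raised-cosine force pulse of 300 ms (the
  "~300 ms push") with peak force 7 N per N·m of MVC torque (~1600 N
  typical); velocity from point-mass dynamics M·dv/dt = F − M·g·sin(20°)
  with M = body + 31.6 kg sled mass, RK4 at 1000 Hz, velocity clipped at
  zero (the mechanical blocks prevent countermovement; rail friction is
  not modelled because it is uncharacterized). At the cohort mean mass the
  static load is 48% of body weight, matching the published figure. The
  ledger records both the programmed pulse duration and the *detectable*
  push duration implied by the waveform and the detection rules (closed
  form), because deceleration begins while force is still falling.
* **Recruitment sweeps**: 5→100 mA in 5 mA steps, 5 stimuli per intensity,
  4 s apart; per-stimulus amplitude is a hard-threshold logistic of
  intensity (zero below the subject's threshold), with a biphasic 10 ms
  template at 15 ms latency and Gaussian baseline noise (2 µV SD). Subject
  thresholds ~ N(51.6, 11.1) mA — the published mean with the SE scaled to
  a between-subject SD. Post-priming shifts the threshold by −6 mA and
  scales the maximum by 1.13, the published Pre→Post changes.
* **Effect structure**: per-subject percent changes are drawn per condition
  and applied to the latent metric *before* attempt noise (default CV 3%),
  so best-attempt selection interacts realistically with variability.
  Default means are the published headline values (max torque +4.7/−4.3%,
  peak force +0.2/−3.3%, RFD +6.0/−15.1%); the delta-SD defaults are derived
  from the published between-condition effect sizes (for max torque,
  dz = 1.19 with a 9.0-point mean difference implies SD(diff) ≈ 7.56, i.e.
  ≈ 5.35 per condition). The published ±0.07 on the +4.67% change is
  inconsistent with that effect size if read as an SE and is treated as a
  misprint.

**EMG synthesis.** EMG is Gaussian noise shaped by a band-pass around a
calibrated centre frequency — no motor-unit simulation, since the analysis
consumes only RMS, MDF and peak-to-peak amplitude. Two non-obvious choices:

1. The shaping band is calibrated so that the *estimated* MDF — after the
   shaping filter, the analysis band-pass, and the Welch estimator's
   binning and spectral smoothing — equals the target. Calibrating against
   the estimator (rather than the continuous spectrum) removes a ~2 Hz
   bias that the coarse Welch grid otherwise introduces.
2. The amplitude is flattened by a 100 ms running-RMS normalization and
   then scaled exactly, so sub-window RMS tracks the target. Even so, the
   RMS over a window of duration T of noise with bandwidth B fluctuates
   with SD ≈ (2BT)^(-1/2): ~1% for 1 s MVC windows but ~4% for ~0.25 s push
   windows. Test tolerances follow this bound (2% for MVC %MVC, 12% ≈
   3 sigma for push-phase %MVC); they are properties of window statistics,
   not implementation slack.

What a green suite does **not** establish: real EMG is non-Gaussian and
non-stationary, real torque drift and baseline instability are richer than
the generator's noise, and the generator's effect model imposes exactly the
crossover structure the statistics assume. The synthetic world validates
the *computations*, not the physiology.

# Numerical and degenerate-input choices

* Sliding-window statistics run in O(n) via cumulative sums over the
  mean-centred trace; results equal naive exhaustive search to 1e-10.
* A monotone-decreasing torque trace has no rising phase: peak RTD is 0
  with a warning rather than an error.
* Zero error variance in an ANOVA stratum flags the result as degenerate
  (F = NA) instead of dividing by zero; all-equal cells give SS = 0.
* Zero-variance post hoc contrasts give p = 1 when the mean difference is
  0 and p = 0 otherwise.
* A constant evoked-potential baseline has peak-to-peak 0, so the noise
  floor is (0, 0) and any positive response is supra-threshold.
* `matched_pairs_power(0, n)` equals alpha exactly (the null case).
* Stimulation epochs whose windows leave the recording are skipped with a
  warning, not errors, matching how a sweep with clipped ends is handled in
  practice.

# Pipeline and reproducibility

`run_pipeline()` chains generation (or reading a TSV trial tree), trial
analysis, best-attempt selection, limb averaging and the per-variable
statistics, and writes a Markdown report plus tidy TSVs. All randomness
flows from the single config seed; the same config and seed give
byte-identical trial files and reports. Configurations serialize to JSON
(`write_config()`/`read_config()`); JSON rather than YAML is used so the
package depends only on `jsonlite`. The `validate` entry point reports
unparseable files and missing design cells without modifying anything.

The recruitment assessment is analysed as a paired Pre/Post comparison
(scTS only): the protocol has no sham arm for session 6, so no 2x2 ANOVA
is possible there — a deliberate reflection of the design, not a gap.

# Known limitations

* Early-phase RFD (fixed 0–50 ms windows from onset) is deliberately out of
  scope: the protocol's own baselines were too unstable for reliable onset
  detection, and the package follows that judgement.
* The Wilcoxon normal approximation (used when zeros/ties are present) is
  asymptotic; for the study's n = 12 the exact path is the common one.
* The sled model neglects rail friction and wire-tachometer dynamics.
* The generator's fatigue model is a condition-specific multiplicative
  drift; it does not model its physiological origin.
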