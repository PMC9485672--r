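---
title: "Quantifying dyadic nonverbal synchrony: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dyadic nonverbal synchrony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadsync)
```

## The measurement problem

When a patient and a therapist talk, their body movements coordinate:
one member's gestures are echoed, anticipated, or answered by the
other's. `dyadsync` quantifies this *nonverbal synchrony* from video,
through a pipeline of four stages:

1. **Motion energy.** Each person is assigned fixed regions of interest
   (head, upper body, lower body) in the frame. For every consecutive
   frame pair, the number of pixels in a region whose intensity changes
   by more than a noise threshold is counted. This yields a
   non-negative movement time series per region at the frame rate,
   with no information about *what* moved — only *how much*.
2. **Windowed lagged cross-correlation.** The per-person series
   (regions summed) are split into short windows; within each window
   the two members are Pearson-correlated at every integer lag up to a
   maximum. Correlations are Fisher-Z transformed and their absolute
   values averaged: over everything (the grand average `|zCCF|`), at
   lag zero only, and separately over the negative-lag and
   positive-lag halves, which attribute temporal precedence
   (therapist-leading vs patient-leading).
3. **Pseudosynchrony.** Absolute correlation averages are positive
   even for strangers who never met, so observed synchrony is only
   meaningful relative to chance. The chance level is estimated by
   recombining one recording's patient series with a *different*
   recording's therapist series, for every ordered pair of recordings
   and both role crossings — `m(m-1)*2` surrogate dyads from `m`
   recordings — and running the identical synchrony computation on
   each.
4. **Session statistics.** Descriptives with Shapiro-Wilk diagnostics,
   paired pre/post contrasts (Wilcoxon signed-rank with matched-pairs
   rank-biserial correlation, paired t), and simple regressions of
   synchrony on self-reported therapy readiness (a 10 cm visual
   analogue scale scored so that the left anchor, absolute readiness,
   is 100%).

The package is organized as an analysis workflow: the numbered scripts
under `analysis/` walk through a complete simulated study, and every
computational step they use is an exported, tested function.

## Windowing, lags, and the correlation model

Movement during conversation is non-stationary — gesturing alternates
with stillness — so a single whole-segment correlation would be
dominated by slow covariation. The default configuration analyses
2-minute segments with:

* `window_s = 10` — non-overlapping 10 s windows (12 windows per
  segment at 30 fps; 300 samples each). Window length obeys two rules
  of thumb: at least 50 samples per window, and a window at least 4-5
  times the maximum lag. `window_size_sweep()` recomputes the
  real-vs-chance effect size at 10/20/30 s for sensitivity analysis.
* `max_lag_s = 2` — lags up to ±2 s in 1-sample steps (±60 at 30 fps,
  grid endpoints inclusive). Longer lags capture slower echoing but
  weaken the surrogate test.
* `smoothing_s = 0.5` — a centred 0.5 s moving average applied to each
  series before correlation (edge windows shrink). Motion-energy
  pipelines conventionally smooth at about this scale to suppress
  camera sensor flicker; it is configurable and `0` disables it.
* `fisher_clip_epsilon = 1e-6` — correlations are clipped to
  `±(1 - 1e-6)` before `atanh`, which diverges at `|r| = 1`; exactly
  identical windows do occur in synthetic data.

**Lag anchoring.** For lag `l`, the later-starting member's window is
shifted by `|l|` samples into the samples adjacent to the window, so
every correlation uses two full-length vectors, and the
earlier-starting window sits on the window grid. This makes the matrix
exactly symmetric under member swap (`z[w, l] -> z[w, -l]`), which in
turn guarantees that swapping the input roles exactly exchanges the
two leading components — a property the test suite pins. Cells whose
shifted window would run past the end of the recording (the last
window at nonzero lags) are `NA` and excluded from averages.

**Lag sign convention.** At lag `l > 0` the therapist's samples are
paired with *earlier* patient samples: the patient precedes, so
positive lags accumulate into `patient_lead` and negative lags into
`therapist_lead`. Lag zero belongs to neither component. Any fixed
convention works if applied consistently; this one is stored in the
result object and enforced by the swap-symmetry and
generator-recovery tests rather than left implicit.

**Degenerate windows.** A window in which either member is motionless
has zero variance and no defined correlation. Stillness carries no
correlation evidence, so such cells score `z = 0` and are flagged;
the flags propagate to the summaries (`n_degenerate`). They are not
errors: long stillness is a real feature of clinical interaction that
frame differencing simply cannot see.

Numerically, the windowed correlations are computed by a compiled
routine over prefix sums, after globally centring each series to avoid
cancellation; windows are flagged degenerate when their variance falls
below `1e-13` of their mean square. The test suite verifies elementwise
agreement with a naive triple-loop reference within `1e-10`.

## The surrogate test: calibration matters

Surrogate pools follow the standard three-way layout: both phases
pooled (`m = 22` recordings, 924 surrogates for 11 dyads), pretalk
only, and posttalk only (220 each). Pretalk synchrony is tested
against the first two, posttalk against the first and third.
Exclusion is at recording level: the pooled-phase enumeration does
pair one dyad's pretalk with the same dyad's posttalk, which is what
gives `22 x 21 x 2 = 924`.

A natural significance test — a two-sample test of the `m` genuine
values against the `m(m-1)*2` surrogate values — is **miscalibrated**
here, because the surrogate values are not independent: all of them
reuse the same `2m` series, and they are positively correlated with
the genuine values. In null simulations (uncoupled members) a Welch
t-test at nominal 5% rejected in under 2% of replicates. The package
therefore reports significance from an exactly calibrated
**permutation test**: arrange all patient-by-therapist pairings of the
pool in an `m x m` value matrix, whose diagonal holds the genuine
dyads. With no genuine coupling the member series are mutually
independent, so the diagonal mean is exchangeable with the mean over
any random transversal (one cell per row, columns permuted); the
one-sided p-value is the Monte Carlo rank of the genuine-pairing mean
among `n_perm = 2000` random pairings. This costs nothing extra —
every cell is already part of the surrogate enumeration. Cohen's d
(pooled SD, `n-1` denominators) against the full surrogate
distribution and the Welch statistic are still reported as effect-size
descriptives, since that is how such comparisons are conventionally
summarized.

## Session statistics

* **Wilcoxon signed-rank:** differences are `pre - post`; zeros are
  dropped, tied absolute differences mid-ranked. `W` is the smaller of
  the two rank sums, so `W = 0` means a perfectly ordered contrast.
  The two-sided p is exact (`2 * P(V <= W)`, identical to exhaustive
  sign-flip enumeration, verified up to `n = 12`) for `n <= 25`
  without ties, otherwise a tie-corrected normal approximation. The
  matched-pairs rank-biserial correlation `(T+ - T-) / (T+ + T-)` is
  negative when post exceeds pre — the direction convention used
  throughout.
* **Shapiro-Wilk** is reported as a diagnostic next to every
  descriptive column; it never switches tests automatically.
* **No multiple-testing correction** is applied across the contrast
  and regression tables; with ten regressions at `n = 10`, readers
  should treat isolated p-values near 0.05 accordingly.
* **VAS scoring:** `readiness% = 100 * (1 - mark/scale)`. The
  direction is fixed by the anchors (left end = absolute readiness);
  the linear mapping from mark position to percent is an assumption,
  isolated in `score_vas()`.

## What the synthetic-data generator emulates

No movement data are bundled; every stage is exercised on simulated
input from `gen_dyad()` / `gen_study()`. The generator produces:

* **Burst morphology.** Motion energy is non-negative and
  intermittent. Each member's envelope is a sum of Poisson-timed
  boxcar bursts (default `burst_rate = 8`/min — a gesture or posture
  shift every 7-8 s of conversation — and `burst_dur_s = 2`), with
  lognormal amplitudes, light 0.2 s smoothing of burst edges, and
  truncated Gaussian sensor noise (`noise_sd = 0.2` in amplitude
  units). A Gaussian autoregressive process would be smoother and
  sign-symmetric — unlike real movement series.
* **Coupling on the envelope.** The follower's envelope is
  `alpha * (leader envelope delayed by delta) + (1 - alpha) *
  independent bursts`. Coupling the envelope rather than the noise
  gives `alpha` a clean monotone relation to measured `|zCCF|`
  (verified over `alpha` in 0-0.8). The sign of `delta_s` encodes who
  leads (positive = patient), matching the analysis lag convention by
  construction and asserted by a cross-module test.
* **Study conditions.** `study_spec()` defaults to 11 dyads, pretalk
  coupling `alpha = 0.2` with the therapist leading by 0.5 s, and
  posttalk coupling `alpha = 0.5` with the patient leading by 0.5 s —
  a study in which the intervention strengthens coupling and hands the
  lead to the patient. The VAS distribution is normal with mean 94.2
  and SD 6.23, truncated at the 100% ceiling, with one missing
  response: a strong ceiling effect, as questionnaires of highly
  motivated in-patients show. The burst rate was chosen so that
  replicate-to-replicate `|zCCF|` variability matches the cross-dyad
  spread reported for real dyads (~0.04); the pre/post coupling gap
  was set to give a clearly detectable contrast (paired d ≈ 1.3) at
  `n = 11` rather than to reproduce any particular printed mean.
* **Rendered frames.** `gen_frames()` draws moving blobs with exact
  changed-pixel ground truth, and `trajectory_from_series()` converts
  a movement series into blob displacements so the video front end can
  be validated end to end (recovered energy rank-correlates > 0.9 with
  the driving series).

What the generator does **not** emulate: visual appearance (lighting,
occlusion, camera shake), shared periodic structure from a single
therapist appearing in every recording (which inflates real
pseudosynchrony), slow within-session drifts of movement level, or any
relation between VAS readiness and coupling (the default study carries
no such association, so its regressions estimate a true zero). Passing
tests therefore demonstrate the *statistical machinery* — calibration,
monotonicity, power at study scale — not performance on real video.

## Validation at study scale

The acceptance-style tests run the whole pipeline at the default study
conditions (2-minute segments, 30 fps, 11 dyads where applicable):

* surrogate enumeration sizes (220 / 924) against the closed form;
* windowed correlations against a naive triple-loop oracle (`1e-10`);
* motion energy against an exhaustive per-pixel count;
* type-I error of the permutation test on uncoupled dyads: 400 null
  replicates, binomial 95% CI required to cover the nominal 5%;
* monotone `|zCCF|` in coupling strength (5 levels x 100 replicates,
  consecutive rank-sum tests) and >= 90% lead-direction recovery at
  `alpha = 0.6`, `|delta| = 1` s;
* >= 80% power for the paired pre/post Wilcoxon contrast at `n = 11`
  over 100 simulated studies;
* exact Wilcoxon p against sign-flip enumeration.

These replicate counts keep the full suite at a few minutes on one
core while leaving the binomial/Monte-Carlo margins comfortable.

## Known limitations

* Motion energy is appearance-based: it cannot distinguish a smile
  from an eye-roll, confuses camera noise with micro-movement near the
  threshold, and sees nothing during stillness.
* The permutation test assumes member series are exchangeable across
  recordings under the null; a single therapist with idiosyncratic
  periodic movement violates this mildly in real data and makes the
  chance level conservative rather than liberal.
* The exact Wilcoxon p requires tie-free data; motion-energy summaries
  are continuous, so ties arise only from degenerate inputs.
* With `n = 11` dyads and 10 VAS values, the regression layer has
  power only for very large associations; it is reported for
  completeness, not as a screening tool.
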