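---
title: "Modelling memory for auditory regularities: observers, synthetic EEG, and the sustained-response analysis chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling memory for auditory regularities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regmem)
```

## The problem

Passive listeners track the statistical structure of rapidly unfolding tone
sequences, and slow ("sustained") M/EEG activity covaries with the inferred
predictability of the input. A central open question is which span of past
input — the current pattern, the current trial, or many preceding trials —
the brain uses as the context against which predictability is evaluated.
`regmem` packages the three ingredients needed to study this question with
full control over ground truth:

1. **Stimuli** — regularly cycling tone-pip sequences, pattern transitions
   (REGx to REGy), and brief random interruptions of a resumed pattern
   (INT0/1/3/5).
2. **Ideal observers** — a variable-order Markov model with
   prediction-by-partial-matching (PPM) smoothing, wrapped in observer
   variants that differ only in their memory span, including a memory-reset
   variant.
3. **Synthetic EEG plus the analysis chain** — multichannel epochs with
   planted sustained, onset (N1), and deviance (MMN) components, and the
   group-level pipeline: zero-phase Butterworth filtering, detrending,
   baseline correction, denoising source separation (DSS), auditory channel
   selection, RMS summaries, bootstrap sign tests, split-half
   cluster-duration null distributions, and recovery-latency estimation.

Everything is validated by parameter recovery: components are planted with
known parameters and the pipeline must find them.

## Stimuli

All sequences use 50 ms tone pips (5 ms raised-cosine ramps), 70 pips per
3.5 s trial, with frequencies drawn from a pool of 20 log-spaced values
between 222 and 2000 Hz. A regular (REG) pattern cycles 10 frequencies
sampled without replacement. In the transition design, a second pattern
built from the 10 remaining frequencies takes over after 2 s. In the
interruption design, 1, 3, or 5 novel tones are inserted at 2 s (after four
full cycles) and the original pattern then *re-starts from cycle position
1*, keeping total length at 70 tones; the resumed portion therefore lasts
1500, 1450, 1350, or 1250 ms for 0/1/3/5 interrupting tones.

```{r stimuli}
pool <- make_frequency_pool()
trial <- generate_int_trial(pool, n_int = 3, seed = 1)
trial
```

Tone indexing is 1-based; the interruption occupies tones `41..40+n_int`.
Restarting at cycle position 1 puts post-resumption cycle onsets at tones
`41 + n_int + 10k`: tones 52/62, 54/64, and 56/66 for 1-, 3-, and 5-tone
interruptions — the positions where a perfect-memory observer expects the
interruption to recur (the "phantom" positions). Interruption frequencies
are drawn per trial from the pool frequencies unused by that trial's REG
set; no cross-trial constraint is imposed, since every trial's frequency
assignment is independent.

## The PPM observer

`new_ppm()` implements an online variable-order Markov model. At each
position the model blends continuation counts across context lengths, from
the longest matched context (at most `order_bound`, default 10) down to a
uniform base:

* With escape method C (the default), a context with `n` continuation
  tokens over `t` distinct symbols contributes weight `count(s) / (n + t)`
  to symbol `s` and passes mass `t / (n + t)` down to the next-shorter
  context.
* **Exclusion** (default on) removes symbols already counted at a longer
  context from the counts of shorter ones.
* **Shortest deterministic** (default on) starts the chain at the shortest
  matched context with a single distinct continuation, when one exists.
* **Update exclusion** (default off) stops count updates below the longest
  context that already predicted the observed symbol.

The order “−1” base is uniform, `1/alphabet_size`, over the *full*
alphabet; exclusion applies to the count levels only. This choice matters:
if excluded symbols were also removed from the base, a once-seen symbol
(weight `1/(n + t)`) could become *less* probable than a novel symbol
(escape mass spread over few remaining symbols), creating a spurious
surprisal peak at the first re-encounter of any symbol after a memory
reset — at exactly the position where recurrence-expectation peaks are
sought. With the uniform base, novelty is always at least as surprising as
recurrence. In regular cases the blended distribution sums to one exactly;
a final renormalisation guards the degenerate corner in which every symbol
has been excluded before the base is reached. Probabilities are carried on
the linear scale: with at most `order_bound + 1` escape levels the smallest
reachable probability is far above double-precision underflow, so no
log-domain bookkeeping is needed.

Information content (IC, surprisal) is `-log2 p` of the observed symbol
under the model's prediction *before* observing it (predict-then-update):

```{r ppm}
m <- new_ppm(alphabet_size = 20)
trace <- process_trial(m, trial$tones)
round(trace$ic_bits[c(1, 11, 41, 44, 54)], 2)
```

Counts persist across trials, but `begin_sequence()` clears the context so
that n-grams never span the silent gap between separately presented trials.

## Observer variants

`observer_spec()` encodes five memory policies that differ only in the span
of accessible past input:

| label | accessible memory when predicting tone *i* |
|-------|--------------------------------------------|
| m1.1  | tones 21..*i*−1 of the current trial (anchored two cycles before the transition) |
| m1.2  | tones 1..*i*−1 of the current trial |
| m1.3  | the 3 preceding session trials, plus the current trial |
| m1.4  | the 240 preceding session trials (all available at desk scale), plus the current trial |
| m2    | like m1.2, but memory is cleared at the deviant |

The preceding-trial policies use the session's actual randomized trial
order, mixing conditions, as in a real experiment.

The reset observer's trigger deserves care. "The first novel symbol"
cannot be taken literally: early in any trial *every* tone is novel, and a
literal trigger would fire at tone 2 and then at every new tone, leaving a
one-tone memory. The implemented trigger is a novel (zero-count) symbol
arriving while the accessible memory already contains an *established
repetition* (some symbol count ≥ 2, i.e. the pattern has cycled). On these
stimuli that fires exactly once — at the transition or interruption onset —
and reproduces the intended context (after a transition at tone 41, the
memory at tone 50 is tones 41–49). The deviant itself is scored against the
full pre-reset memory (its IC is the full escape-chain value) and then
becomes the first symbol of the new memory.

```{r observers}
session <- build_session(c(INT1 = 100), seed = 42)
res <- run_observer(observer_spec("m1.3"), session)
detect_phantom_peaks(res, search_start = 45)
```

A context-incorporating observer shows strict local IC maxima at the
phantom positions (52 and 62 above); their location depends only on the
interruption length, never on the seed. The reset observer shows none, and
it re-learns the resumed pattern more slowly
(`time_to_criterion()`), because the pre-interruption memory is gone.

Window summaries (`summarize_window()`, default tones 61–70, the last
cycle) are offered raw (bits) and log-transformed; quantitative comparisons
use raw IC. One behaviour of this model family is worth documenting
explicitly: the late-window IC difference between a transition condition
and its uninterrupted control *grows slightly* as the pre-training window
lengthens. Two mechanisms drive this. First, an observer anchored within
the trial assigns the control condition fewer pattern repetitions, raising
its control-window IC and shrinking the difference relative to a
whole-trial observer. Second, with exclusion enabled, cross-trial counts
break the short deterministic contexts on which a twice-repeated new
pattern relies much more than a five-times-repeated control, so memory
saturation penalises the new pattern more. Claims that the difference
shrinks with longer memory are not reproduced by this implementation under
any of its escape/exclusion configurations; the corresponding check in the
test suite is expected to fail and is retained as an open discrepancy.

## Synthetic EEG

`simulate_subject()` builds `trials x channels x samples` epochs (−1 to
+5 s around onset, 256 Hz by default — the post-downsampling analysis rate;
a 2048 Hz mode exercises `resample_recording()`). Each planted component is
a fixed random dipolar topography (unit norm, both polarities, so that
5-positive/5-negative channel selection is well posed) times a source time
course:

* **Sustained response** (`sustained_params()`): zero before onset,
  exponential-saturating rise (τ = 400 ms) to a plateau, a linear drop
  (latency 200 ms, duration 150 ms) to a trough after the pattern
  violation, linear recovery (400 ms) to plateau + `post_offset`
  (`post_offset = 0` models full recovery; negative values model the
  persistent post-interruption deficit). Amplitudes are arbitrary units —
  only latencies and signs are recovery targets.
* **N1**: negative Gaussian transient at 100 ms post-onset on every trial.
* **MMN**: negative Gaussian transient 175 ms after the interruption onset,
  on interruption/transition trials only.
* **Noise**: per-channel pink noise (spectrally shaped `1/f^alpha`, random
  phases), per-epoch random linear drift, and white sensor noise.

The generator emulates what the analysis chain needs to be validated —
trial-reproducible components in noise with realistic low-frequency
content — and deliberately not more: no biophysical head model, no eye or
muscle artifacts, no electrode bridges, no non-stationarity across a
session. Passing recovery tests therefore demonstrates that the analysis
chain is correct and calibrated, not that it is robust to every failure
mode of real recordings.

## The analysis chain

`preprocess_subject()` runs, in order: zero-phase Butterworth lowpass
(30 Hz, 5th order, two-pass), optional 2 Hz two-pass 4th-order highpass
(for deviance-response analyses), optional per-epoch linear detrend,
baseline correction (−0.5–0 s), DSS over 0–4 s with the first three
components projected back to sensor space, re-referencing to the channel
average, and channel selection on the grand average.

Numerical and interpretation choices:

* "Two-pass, 5th order" is implemented as a 5th-order design applied
  forward and backward; the effective magnitude response is the square of
  the single-pass response. Filters are designed with `signal::butter()`
  and applied by a column-vectorised forward–backward routine that matches
  `signal::filtfilt` to ~1e-14 (verified in the suite) while filtering all
  epochs and channels in one pass.
* Downsampling uses a zero-phase 8th-order Butterworth at 80% of the target
  Nyquist followed by decimation; in-band amplitude error is < 1%.
* **Detrending caveat**: in a continuous acquisition, the 1st-order
  detrend runs before epoching and removes slow drift. Applied per epoch
  instead, it regresses out the linear component of the *response*, and —
  more insidiously — when epochs contain condition-specific slow structure
  (a deficit in one condition), the fitted lines differ between conditions
  and inject a spurious, subject-consistent linear difference across the
  whole epoch. The parameter-recovery fixtures therefore run with
  `detrend = FALSE`; the switch is exposed and the pitfall is worth knowing
  about when working with epoch-level data.
* **DSS**: total covariance from demeaned single trials in the analysis
  window, bias covariance from their average; whitening by rank-truncated
  eigendecomposition (eigenvalues below 1e-9 of the largest are dropped),
  rotation by the eigendecomposition of the whitened bias covariance;
  components ordered by evoked-to-total power ratio; sensor reconstruction
  via the pseudo-inverse of the unmixing matrix. Covariances are computed
  after baseline correction.
* **Channel selection**: the N1 rule finds the onset-response peak (sample
  of maximal spatial spread in 0.05–0.2 s) and takes the 5 most positive
  plus 5 most negative channels at that sample; the MMN rule takes the 10
  most negative mean amplitudes in 150–200 ms post-interruption. Ties break
  towards the lower channel index.
* **RMS** across selected channels summarises instantaneous response power
  regardless of polarity; condition comparisons re-baseline the RMS series
  (pre-transition 1.5–2 s, or post-recovery 2.8–3.3 s for recovery-latency
  analyses). Outlier screening (peak-to-peak beyond median + 6 MAD) stands
  in for manual inspection and is off by default on synthetic data.

## Group statistics

`bootstrap_sign_test()` resamples subjects with replacement and marks a
timepoint significant when at least `1 - alpha` of resampled group means
fall on one side of zero (two-sided; exact zeros count for neither side).
Note that this criterion corresponds to a pointwise two-sided rate near
`2 * alpha` for symmetric null noise — the calibration test measures
exactly this.

Cluster-level control uses `null_cluster_distribution()`: the control
condition is repeatedly split in half per subject, the half-difference
series are run through the same bootstrap at the cluster-forming level
(0.05, deliberately more liberal than the 0.01 main mask, making the
resulting threshold conservative for the main analysis — the mismatch
follows the original procedure and is configurable), and the 95th
percentile of per-split *maximum* cluster durations is the threshold. The
maximum (rather than all clusters) is the conservative standard choice for
a single-threshold use. A cluster-weight variant (weight = Σ(1 − p)) is
available through `cluster_stat = "weight"`.

`recovery_latency()` estimates when a condition deficit ends. Each
bootstrap iteration resamples subjects and records the end of the
deficit-sign run of the resampled group mean anchored at the interval
start. Three details make the estimator calibrated, each fixing a measured
failure mode:

1. A nested design (an inner bootstrap significance test inside each outer
   resample) is badly anticonservative — duplicated subjects understate
   variance — and overshot planted recovery points by 45–64 samples; it was
   discarded.
2. A strict zero-crossing criterion has an irreducible late tail: past the
   true recovery point the group mean is pure noise and stays on the
   deficit side with probability 1/2 per noise correlation length. The run
   is therefore ended once the mean recovers to within 5% of its own value
   at the interval start (`threshold_frac`).
3. The threshold crossing is deterministically early by
   `threshold_frac x ramp width`; a local-slope extrapolation from the
   crossing to the zero crossing removes this offset.

A minimum anchored-run duration (0.1 s) makes null cohorts yield empty
iterations rather than noise latencies. On planted ramps (deficit-to-noise
ratio 10:1, 16 subjects) the median recovered latency is within ±1 sample
of ground truth across seeds, and planted 50 ms (13-sample) latency
differences between conditions yield non-overlapping interquartile ranges
through the full pipeline.

## Problem sizes and SNR used in the validation suite

The suite favours many small, fully controlled experiments over few large
ones. Choices, all stated here as the package's own desk-scale designs:

* Observer checks: sessions of 40–120 trials per condition; phantom-peak
  checks use 100–120 trials, matching the scale at which trial-averaged IC
  traces are smooth.
* Null calibration: 200 independent cohorts (8 subjects, 10 trials per
  condition, 10 channels, 3 s epochs), each analysed end-to-end against its
  own 50-split cluster threshold; the supra-threshold rate must stay within
  the nominal 5% plus Monte-Carlo slack.
* Power anchor: 100 cohorts with a planted persistent deficit
  (`post_offset = -0.4`, pink/drift/white noise 0.5/0.3/0.3, 16 trials per
  condition, 8 subjects) must be detected in at least 80% of runs. The SNR
  is a documented regression anchor, not an empirical claim.
* DSS recovery: one planted reproducible source, 100 trials, white noise
  0.6, 16 channels; first-component correlation with the planted source
  must exceed 0.95 (the correlation is noise-limited at roughly
  `1/sqrt(1 + k/n_trials)`, so the fixture is sized to leave margin).
* Latency recovery: difference-series cohorts of 16 subjects at 10:1 SNR.

## Known limitations

* The observer family varies only the pre-training window; no decay,
  attention, or capacity constraints, and no change-point inference beyond
  the hard reset variant.
* Synthetic EEG omits artifacts and non-stationarity (above), so automatic
  outlier rejection is exercised only on constructed outliers.
* The split-half null and the main comparison differ in per-average trial
  counts, an intentional conservatism inherited from the procedure it
  follows.
* WAV audio export is a minimal 16-bit PCM writer; it is a convenience for
  listening checks, not a calibrated stimulus-delivery path.
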