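# End-to-end analysis chain: filter -> detrend -> baseline -> DSS ->
# re-reference -> average -> channel selection -> RMS -> group statistics.

#' Preprocess one subject's recording
#'
#' Runs the sustained-response signal chain on an epoched recording:
#' zero-phase Butterworth lowpass, linear detrend, baseline correction,
#' DSS with the leading components projected back to sensor space, and
#' re-referencing to the channel average. Channels are then selected from
#' the grand average over all conditions.
#'
#' @param rec A `subject_recording`.
#' @param lowpass [filter_spec()] for the lowpass stage (default 30 Hz,
#'   5th order, two-pass); `NULL` skips it.
#' @param highpass Optional [filter_spec()] applied after the lowpass (used
#'   by the deviance-response chain: 2 Hz, 4th order, two-pass).
#' @param baseline_window Epoch baseline window in seconds (default the
#'   pre-onset interval).
#' @param detrend Remove a per-epoch linear trend. In a continuous
#'   acquisition the detrend runs before epoching and removes slow drift;
#'   on epoch-level synthetic data the equivalent is removing the planted
#'   per-epoch drift, at the cost of also regressing out the linear part of
#'   the response, so it is exposed as a switch.
#' @param dss_window,dss_keep DSS analysis window and number of retained
#'   components; `dss_keep = 0` skips DSS.
#' @param select_rule,select_window Channel-selection rule and window (see
#'   [select_channels()]).
#' @return A `prepped_subject`: list with `recording` (processed) and
#'   `selection`.
#' @export
preprocess_subject <- function(rec,
                               lowpass = filter_spec("lowpass", 30, 5),
                               highpass = NULL,
                               baseline_window = c(-0.5, 0),
                               detrend = TRUE,
                               dss_window = c(0, 4), dss_keep = 3,
                               select_rule = "n1",
                               select_window = c(0.05, 0.2)) {
  if (!is.null(lowpass)) rec <- filter_epochs(rec, lowpass)
  if (!is.null(highpass)) rec <- filter_epochs(rec, highpass)
  if (detrend) rec <- detrend_linear(rec)
  rec <- baseline_correct(rec, baseline_window)
  if (dss_keep > 0) rec <- dss(rec, dss_window, dss_keep)$recording
  rec <- rereference_average(rec)
  sel <- select_channels(epoch_average(rec), rec$times, select_rule,
                         select_window)
  structure(list(recording = rec, selection = sel),
            class = "prepped_subject")
}

#' Condition RMS series of a preprocessed subject
#'
#' RMS over the subject's selected channels of the condition-average
#' response, optionally baseline-corrected on the RMS output (the sustained
#' -response comparisons baseline the RMS to the pre-transition window
#' 1.5-2 s or the post-recovery window 2.8-3.3 s).
#'
#' @param prep A `prepped_subject`.
#' @param condition Condition label.
#' @param rms_baseline Optional window in seconds for baselining the RMS
#'   series.
#' @return Numeric vector over samples.
#' @export
subject_rms <- function(prep, condition, rms_baseline = NULL) {
  avg <- epoch_average(prep$recording, condition)
  r <- rms_over_channels(avg, prep$selection)
  if (!is.null(rms_baseline)) {
    idx <- window_samples(prep$recording$times, rms_baseline)
    r <- r - mean(r[idx])
  }
  r
}

#' Per-subject condition-difference series for a cohort
#'
#' @param preps List of `prepped_subject`s.
#' @param cond_a,cond_b Condition labels; the series is `a - b`.
#' @param rms_baseline Optional RMS baseline window (seconds).
#' @return `subjects x timepoints` matrix (a difference series for
#'   [bootstrap_sign_test()] and friends).
#' @export
cohort_difference <- function(preps, cond_a, cond_b, rms_baseline = NULL) {
  t(vapply(preps, function(p)
    subject_rms(p, cond_a, rms_baseline) -
      subject_rms(p, cond_b, rms_baseline),
    numeric(length(preps[[1]]$recording$times))))
}

#' Per-trial selected-channel epochs of one condition
#'
#' Extracts a subject's single-trial epochs restricted to the selected
#' channels, the input expected per subject by
#' [null_cluster_distribution()] and
#' [half_split_resampling_comparison()] together with [rms_statistic()].
#'
#' @param prep A `prepped_subject`.
#' @param condition Condition label.
#' @return `trials x channels x samples` array.
#' @export
subject_trial_epochs <- function(prep, condition) {
  sel <- which(prep$recording$conditions %in% condition)
  prep$recording$epochs[sel, prep$selection, , drop = FALSE]
}

#' Trial-subset RMS summary
#'
#' Statistic for the split-half machinery: averages a subset of trials and
#' takes the RMS over channels, matching the main analysis pipeline.
#'
#' @param trials `trials x channels x samples` array.
#' @param subset Trial indices.
#' @return Numeric series over samples.
#' @export
rms_statistic <- function(trials, subset) {
  avg <- colMeans(trials[subset, , , drop = FALSE], dims = 1)
  sqrt(colMeans(avg^2))
}
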