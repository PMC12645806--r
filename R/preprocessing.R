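# Epochs are stored as trials x channels x samples arrays inside a
# subject_recording; time-domain operations are vectorised by reshaping to a
# samples x (trials*channels) matrix and running C-level filters columnwise.

flatten_epochs <- function(epochs) {
  d <- dim(epochs)
  m <- aperm(epochs, c(3, 1, 2))
  dim(m) <- c(d[3], d[1] * d[2])
  m
}

unflatten_epochs <- function(m, d) {
  dim(m) <- c(nrow(m), d[1], d[2])
  aperm(m, c(2, 3, 1))
}

with_epochs <- function(rec, f) {
  d <- dim(rec$epochs)
  m <- f(flatten_epochs(rec$epochs))
  rec$epochs <- unflatten_epochs(m, d[1:2])
  rec
}

#' Butterworth filter specification
#'
#' @param kind `"lowpass"` or `"highpass"`.
#' @param cutoff_hz Corner frequency in Hz.
#' @param order Per-pass filter order (>= 1).
#' @param two_pass Apply forward and backward (zero-phase; squares the
#'   magnitude response). The default analysis chain uses a 30 Hz two-pass
#'   5th-order lowpass, and a 2 Hz two-pass 4th-order highpass for
#'   deviance-response analyses.
#' @return A `filter_spec`.
#' @export
filter_spec <- function(kind = c("lowpass", "highpass"), cutoff_hz,
                        order = 5, two_pass = TRUE) {
  kind <- match.arg(kind)
  if (order < 1) stop("order must be >= 1")
  if (cutoff_hz <= 0) stop("cutoff must be positive")
  structure(list(kind = kind, cutoff_hz = cutoff_hz, order = order,
                 two_pass = two_pass), class = "filter_spec")
}

# columnwise IIR y = filter(b, a, x); matches signal::filter per column
iir_filter_matrix <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  z <- stats::filter(x, b, method = "convolution", sides = 1)
  nb <- length(b)
  if (nb > 1) {
    for (n in seq_len(min(nb - 1, nrow(x)))) {
      k <- seq_len(n)
      z[n, ] <- colSums(x[n - k + 1, , drop = FALSE] * b[k])
    }
  }
  if (length(a) > 1) z <- stats::filter(z, -a[-1], method = "recursive")
  matrix(as.numeric(z), nrow(x), ncol(x))
}

# columnwise zero-phase filtering; matches signal::filtfilt per column
zero_phase_matrix <- function(b, a, x) {
  n <- nrow(x)
  pad <- matrix(0, 2 * max(length(a), length(b)), ncol(x))
  y <- iir_filter_matrix(b, a, rbind(x, pad))
  y <- iir_filter_matrix(b, a, y[nrow(y):1, , drop = FALSE])
  y[nrow(y):1, , drop = FALSE][seq_len(n), , drop = FALSE]
}

#' Filter every epoch and channel
#'
#' Applies a Butterworth filter (designed with [signal::butter()])
#' independently to each channel of each epoch; two-pass specifications are
#' applied forward and backward for zero phase shift.
#'
#' @param rec A `subject_recording`.
#' @param spec A [filter_spec()].
#' @return The filtered recording.
#' @export
filter_epochs <- function(rec, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$cutoff_hz >= rec$fs / 2) stop("cutoff at or above Nyquist")
  bf <- signal::butter(spec$order, spec$cutoff_hz / (rec$fs / 2),
                       type = switch(spec$kind, lowpass = "low",
                                     highpass = "high"))
  with_epochs(rec, function(m)
    if (spec$two_pass) zero_phase_matrix(bf$b, bf$a, m)
    else iir_filter_matrix(bf$b, bf$a, m))
}

#' Remove a per-channel linear trend from every epoch
#'
#' Subtracts the least-squares first-order polynomial fit over the whole
#' epoch, per channel and per epoch.
#'
#' @param rec A `subject_recording`.
#' @return The detrended recording.
#' @export
detrend_linear <- function(rec) {
  with_epochs(rec, function(m) {
    if (nrow(m) < 2) stop("need at least 2 samples")
    x <- cbind(1, seq_len(nrow(m)))
    m - x %*% solve(crossprod(x), crossprod(x, m))
  })
}

#' Downsample a recording
#'
#' Anti-aliased integer-factor downsampling, e.g. from a 2048 Hz
#' acquisition rate to the 256 Hz analysis rate: a zero-phase 8th-order
#' Butterworth lowpass at 80% of the target Nyquist frequency, then
#' decimation.
#'
#' @param rec A `subject_recording`.
#' @param to Target sampling rate in Hz; `rec$fs / to` must be an integer.
#' @return The resampled recording (with updated `fs` and `times`).
#' @export
resample_recording <- function(rec, to) {
  from <- rec$fs
  if (to == from) return(rec)
  q <- from / to
  if (abs(q - round(q)) > 1e-9 || q < 1)
    stop("unsupported ratio: only integer downsampling factors")
  q <- as.integer(round(q))
  bf <- signal::butter(8, 0.8 / q, "low")
  d <- dim(rec$epochs)
  m <- zero_phase_matrix(bf$b, bf$a, flatten_epochs(rec$epochs))
  pick <- seq(1, nrow(m), by = q)
  rec$epochs <- unflatten_epochs(m[pick, , drop = FALSE], d[1:2])
  rec$fs <- to
  rec$times <- rec$times[pick]
  rec
}

window_samples <- function(times, window) {
  idx <- which(times >= window[1] & times <= window[2])
  if (length(idx) == 0) stop("window outside epoch")
  idx
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean amplitude over a reference
#' window. Typical windows: the pre-onset interval (-0.5 to 0 s), the
#' pre-transition interval (1.5 to 2 s), or the post-recovery interval
#' (2.8 to 3.3 s).
#'
#' @param rec A `subject_recording`.
#' @param window Length-2 numeric, window in seconds on the epoch time axis.
#' @return The baseline-corrected recording.
#' @export
baseline_correct <- function(rec, window = c(-0.5, 0)) {
  idx <- window_samples(rec$times, window)
  with_epochs(rec, function(m)
    sweep(m, 2, colMeans(m[idx, , drop = FALSE])))
}

#' Reject outlier epochs by a peak-to-peak MAD rule
#'
#' Automatic stand-in for manual outlier screening: an epoch is rejected
#' when its maximum peak-to-peak amplitude across channels exceeds the
#' median plus `k` times the MAD of that statistic over epochs. Off by
#' default in the synthetic pipeline.
#'
#' @param rec A `subject_recording`.
#' @param k MAD multiplier (default 6).
#' @return The recording with outlier epochs dropped.
#' @export
reject_outlier_epochs <- function(rec, k = 6) {
  ptp <- apply(rec$epochs, 1, function(e) max(apply(e, 1, function(ch)
    diff(range(ch)))))
  keep <- ptp <= stats::median(ptp) + k * stats::mad(ptp)
  rec$epochs <- rec$epochs[keep, , , drop = FALSE]
  rec$conditions <- rec$conditions[keep]
  rec
}

#' Average epochs over trials
#'
#' @param rec A `subject_recording`.
#' @param condition Optional condition filter.
#' @return `channels x samples` matrix.
#' @export
epoch_average <- function(rec, condition = NULL) {
  sel <- if (is.null(condition)) seq_along(rec$conditions)
         else which(rec$conditions %in% condition)
  if (length(sel) == 0) stop("no epochs in condition")
  colMeans(rec$epochs[sel, , , drop = FALSE], dims = 1)
}

#' Re-reference to the average of all channels
#'
#' @param rec A `subject_recording`.
#' @return The re-referenced recording.
#' @export
rereference_average <- function(rec) {
  d <- dim(rec$epochs)
  ref <- colMeans(aperm(rec$epochs, c(2, 1, 3)), dims = 1)  # trials x samples
  rec$epochs <- rec$epochs - aperm(array(ref, c(d[1], d[3], d[2])),
                                   c(1, 3, 2))
  rec
}

#' Denoising source separation (DSS)
#'
#' Linear decomposition that ranks components by trial-to-trial
#' reproducibility: the total covariance is computed from single trials
#' within the analysis window and the bias covariance from the trial
#' average; whitening by the (rank-truncated) eigendecomposition of the
#' total covariance followed by a rotation diagonalising the whitened bias
#' covariance yields components ordered by the ratio of evoked to total
#' power. The first `n_keep` components are projected back into sensor
#' space.
#'
#' @param rec A `subject_recording`.
#' @param window Analysis window in seconds (default 0-4 s).
#' @param n_keep Number of components to retain (default 3).
#' @param rank_tol Relative eigenvalue threshold for rank truncation of the
#'   total covariance (default 1e-9).
#' @return A `dss_result`: list with `unmixing`, `mixing`, `scores`,
#'   `n_keep`, and `recording` (the sensor-space reconstruction).
#' @export
dss <- function(rec, window = c(0, 4), n_keep = 3, rank_tol = 1e-9) {
  d <- dim(rec$epochs)
  if (d[1] < 2) stop("DSS needs at least 2 trials")
  idx <- window_samples(rec$times, window)
  n_ch <- d[2]
  c_total <- matrix(0, n_ch, n_ch)
  avg <- matrix(0, n_ch, length(idx))
  for (i in seq_len(d[1])) {
    e <- rec$epochs[i, , idx]
    e <- e - rowMeans(e)
    c_total <- c_total + tcrossprod(e)
    avg <- avg + e
  }
  avg <- avg / d[1]
  c_total <- c_total / (d[1] * length(idx))
  c_bias <- tcrossprod(avg) / length(idx)
  et <- eigen(c_total, symmetric = TRUE)
  keep_ev <- et$values > rank_tol * et$values[1]
  w <- et$vectors[, keep_ev, drop = FALSE] %*%
    diag(1 / sqrt(et$values[keep_ev]), sum(keep_ev))
  eb <- eigen(crossprod(w, c_bias %*% w), symmetric = TRUE)
  unmix <- w %*% eb$vectors                       # channels x components
  scores <- eb$values                             # bias variance, whitened
  n_keep <- min(n_keep, ncol(unmix))
  mixing <- t(unmix %*% solve(crossprod(unmix)))  # components x channels
  # sensor-space projection keeping the first n_keep components:
  # comps = t(unmix) x ; x_hat = t(mixing)[, 1:k] comps[1:k]
  proj <- t(mixing[seq_len(n_keep), , drop = FALSE]) %*%
    t(unmix[, seq_len(n_keep), drop = FALSE])     # channels x channels
  out <- rec
  for (i in seq_len(d[1])) out$epochs[i, , ] <- proj %*% rec$epochs[i, , ]
  structure(list(unmixing = unmix, mixing = mixing, scores = scores,
                 n_keep = n_keep, window = window, recording = out),
            class = "dss_result")
}

#' Component time courses of a DSS decomposition
#'
#' @param result A `dss_result`.
#' @param rec The recording the decomposition was computed from.
#' @param component Component index.
#' @return `trials x samples` matrix of component activations.
#' @export
dss_component <- function(result, rec, component = 1) {
  u <- result$unmixing[, component]
  t(apply(rec$epochs, 1, function(e) as.numeric(crossprod(e, u))))
}

#' @export
print.dss_result <- function(x, ...) {
  cat(sprintf("<dss_result> %d components, %d kept; top scores: %s\n",
              length(x$scores), x$n_keep,
              paste(sprintf("%.3f", utils::head(x$scores, 5)),
                    collapse = ", ")))
  invisible(x)
}

#' Select the most auditory-responsive channels
#'
#' Two selection rules on a grand-average (`channels x samples`) matrix:
#' `"n1"` locates the onset-response peak (the sample of maximal spatial
#' spread within the search window) and returns the 5 most positive plus 5
#' most negative channels at that sample; `"mmn"` returns the 10 channels
#' with the most negative mean amplitude over the window. Ties are broken
#' towards the lower channel index.
#'
#' @param grand_average `channels x samples` matrix.
#' @param times Time axis (seconds) matching the columns.
#' @param rule `"n1"` or `"mmn"`.
#' @param window Search window in seconds.
#' @param n_each Channels per polarity for the N1 rule (default 5).
#' @return A `channel_selection`: integer channel indices, with the rule
#'   and peak time as attributes.
#' @export
select_channels <- function(grand_average, times,
                            rule = c("n1", "mmn"), window, n_each = 5) {
  rule <- match.arg(rule)
  if (nrow(grand_average) < 2 * n_each) stop("fewer channels than required")
  idx <- window_samples(times, window)
  if (rule == "n1") {
    spread <- apply(grand_average[, idx, drop = FALSE], 2, stats::sd)
    peak <- idx[which.max(spread)]
    v <- grand_average[, peak]
    pos <- order(-v, seq_along(v))[seq_len(n_each)]
    neg <- order(v, seq_along(v))[seq_len(n_each)]
    sel <- c(sort(pos), sort(neg))
    peak_t <- times[peak]
  } else {
    v <- rowMeans(grand_average[, idx, drop = FALSE])
    sel <- sort(order(v, seq_along(v))[seq_len(2 * n_each)])
    peak_t <- NA_real_
  }
  structure(unique(sel), rule = rule, peak_time = peak_t,
            class = "channel_selection")
}

#' RMS across selected channels
#'
#' Instantaneous, polarity-free response power: per timepoint, the square
#' root of the mean squared amplitude over the selected channels.
#'
#' @param epoch_average `channels x samples` matrix.
#' @param selection Channel indices (e.g. from [select_channels()]).
#' @return Numeric vector, one value per sample.
#' @export
rms_over_channels <- function(epoch_average, selection) {
  if (length(selection) == 0) stop("empty channel selection")
  sqrt(colMeans(epoch_average[selection, , drop = FALSE]^2))
}

#' Mini-epochs around model-inferred phantom peak times
#'
#' Cuts 600 ms segments (400 ms before to 200 ms after each model-based
#' peak time) from a channel-averaged series, baseline-corrects each
#' segment on its initial 200 ms, and averages across peaks.
#'
#' @param epoch_average `channels x samples` matrix (one condition).
#' @param times Time axis in seconds.
#' @param peak_times_s Model-inferred peak times (seconds re stimulus
#'   onset), e.g. the onsets of tones 52 and 62 for a 1-tone interruption.
#' @param selection Channel indices to average over.
#' @param pre_s,post_s Segment extent around each peak.
#' @param baseline_s Initial baseline span of each segment.
#' @return List with `epochs` (peaks x samples matrix), `mean`, and
#'   `times` (segment time axis re peak).
#' @export
phantom_epoching <- function(epoch_average, times, peak_times_s, selection,
                             pre_s = 0.4, post_s = 0.2, baseline_s = 0.2) {
  fs <- 1 / diff(times[1:2])
  series <- colMeans(epoch_average[selection, , drop = FALSE])
  n_pre <- round(pre_s * fs)
  n_post <- round(post_s * fs)
  n_base <- round(baseline_s * fs)
  segs <- vapply(peak_times_s, function(pt) {
    i0 <- which.min(abs(times - pt))
    if (i0 - n_pre < 1 || i0 + n_post - 1 > length(series))
      stop("peak time out of range")
    seg <- series[(i0 - n_pre):(i0 + n_post - 1)]
    seg - mean(seg[seq_len(n_base)])
  }, numeric(n_pre + n_post))
  segs <- t(segs)
  list(epochs = segs, mean = colMeans(segs),
       times = (seq_len(n_pre + n_post) - 1 - n_pre) / fs)
}

#' Onset times of tones within a trial
#'
#' @param tone_index Tone position(s), 1-based.
#' @param tone_duration_ms Pip duration (default 50 ms).
#' @return Onset time(s) in seconds relative to stimulus onset.
#' @export
tone_onset_s <- function(tone_index, tone_duration_ms = 50) {
  (tone_index - 1) * tone_duration_ms / 1000
}
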