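#' Random dipolar sensor topography
#'
#' Draws a unit-norm channel weight vector with both positive and negative
#' weights, emulating the dipolar scalp patterns that motivate selecting the
#' five most positive plus five most negative channels at the N1 peak.
#'
#' @param n_channels Number of channels.
#' @return Numeric vector of unit Euclidean norm with both polarities.
#' @export
make_topography <- function(n_channels = 64) {
  repeat {
    w <- stats::rnorm(n_channels)
    if (any(w > 0) && any(w < 0)) break
  }
  w / sqrt(sum(w^2))
}

#' Sustained-response source parameters
#'
#' The sustained response rises from stimulus onset to a plateau as the
#' regular pattern is discovered, drops rapidly after the pattern is
#' violated, and recovers towards the plateau plus a condition-specific
#' offset (zero for full recovery; negative for the persistent
#' post-interruption deficit).
#'
#' @param onset_latency_ms Response onset relative to stimulus onset.
#' @param rise_tau_ms Exponential-saturation time constant of the rise.
#' @param plateau Plateau amplitude (arbitrary units).
#' @param drop_latency_ms Delay between the pattern violation and the start
#'   of the amplitude drop.
#' @param drop_duration_ms Duration of the linear fall to the trough.
#' @param trough Trough level (<= plateau).
#' @param recovery_duration_ms Duration of the linear recovery.
#' @param post_offset Amplitude offset relative to plateau after recovery.
#' @return A list of class `sustained_params`.
#' @export
sustained_params <- function(onset_latency_ms = 50, rise_tau_ms = 400,
                             plateau = 1, drop_latency_ms = 200,
                             drop_duration_ms = 150, trough = 0.2,
                             recovery_duration_ms = 400, post_offset = 0) {
  if (trough > plateau) stop("trough must not exceed plateau")
  if (any(c(onset_latency_ms, rise_tau_ms, drop_latency_ms,
            drop_duration_ms, recovery_duration_ms) < 0))
    stop("durations must be non-negative")
  structure(list(onset_latency_ms = onset_latency_ms,
                 rise_tau_ms = rise_tau_ms, plateau = plateau,
                 drop_latency_ms = drop_latency_ms,
                 drop_duration_ms = drop_duration_ms, trough = trough,
                 recovery_duration_ms = recovery_duration_ms,
                 post_offset = post_offset),
            class = "sustained_params")
}

#' Sustained-response source time course for one epoch
#'
#' Piecewise trajectory: zero before onset, exponential-saturating rise to
#' the plateau, linear fall to the trough starting `drop_latency_ms` after
#' the pattern transition, then linear recovery to `plateau + post_offset`.
#' With `transition_s = NA` (no violation in the trial) the envelope stays
#' at plateau.
#'
#' @param params A [sustained_params()].
#' @param transition_s Time of the pattern violation in seconds relative to
#'   stimulus onset, or `NA` for none.
#' @param fs Sampling rate (Hz).
#' @param epoch_start_s,epoch_end_s Epoch limits relative to stimulus onset.
#' @return Numeric vector of `fs * (epoch_end_s - epoch_start_s)` samples.
#' @export
make_envelope <- function(params, transition_s = NA, fs = 256,
                          epoch_start_s = -1, epoch_end_s = 5) {
  t <- epoch_time(fs, epoch_start_s, epoch_end_s)
  on <- params$onset_latency_ms / 1000
  env <- ifelse(t < on, 0,
                params$plateau * (1 - exp(-(t - on) /
                                            (params$rise_tau_ms / 1000))))
  if (!is.na(transition_s)) {
    t_drop <- transition_s + params$drop_latency_ms / 1000
    t_trough <- t_drop + params$drop_duration_ms / 1000
    t_rec <- t_trough + params$recovery_duration_ms / 1000
    lvl_drop <- env[which.min(abs(t - t_drop))]
    final <- params$plateau + params$post_offset
    seg <- t >= t_drop & t < t_trough
    env[seg] <- lvl_drop + (params$trough - lvl_drop) *
      (t[seg] - t_drop) / (params$drop_duration_ms / 1000)
    seg <- t >= t_trough & t < t_rec
    env[seg] <- params$trough + (final - params$trough) *
      (t[seg] - t_trough) / (params$recovery_duration_ms / 1000)
    env[t >= t_rec] <- final
  }
  env
}

epoch_time <- function(fs, epoch_start_s = -1, epoch_end_s = 5) {
  n <- round(fs * (epoch_end_s - epoch_start_s))
  epoch_start_s + (seq_len(n) - 1) / fs
}

#' Gaussian transient source time course
#'
#' Models brief evoked deflections: the onset N1 (negative peak near 100 ms
#' post-onset) and the MMN-like deviance response (negative peak 150-200 ms
#' after an interruption).
#'
#' @param latency_s Peak time in seconds relative to stimulus onset.
#' @param width_ms Gaussian full width at half maximum.
#' @param amplitude Peak amplitude (negative for N1/MMN conventions).
#' @inheritParams make_envelope
#' @return Numeric vector over the epoch.
#' @export
make_transient <- function(latency_s, width_ms = 60, amplitude = -1,
                           fs = 256, epoch_start_s = -1, epoch_end_s = 5) {
  t <- epoch_time(fs, epoch_start_s, epoch_end_s)
  sigma <- width_ms / 1000 / (2 * sqrt(2 * log(2)))
  amplitude * exp(-(t - latency_s)^2 / (2 * sigma^2))
}

#' Pink (1/f^alpha) noise via spectral shaping
#'
#' @param n Samples per series.
#' @param n_series Number of independent series (columns).
#' @param alpha Spectral exponent (1 = pink).
#' @param amplitude Standard deviation scaling.
#' @return `n x n_series` matrix.
#' @export
pink_noise <- function(n, n_series = 1, alpha = 1, amplitude = 1) {
  nfft <- n
  freqs <- seq_len(nfft %/% 2)
  shape <- freqs^(-alpha / 2)
  # random phases, Hermitian spectrum -> real series
  ph <- matrix(stats::runif(length(freqs) * n_series, 0, 2 * pi),
               ncol = n_series)
  amp <- matrix(stats::rnorm(length(freqs) * n_series, sd = shape),
                ncol = n_series) * exp(1i * ph)
  spec <- matrix(0i, nfft, n_series)
  spec[freqs + 1, ] <- amp
  spec[nfft - freqs + 1, ] <- Conj(amp[seq_along(freqs), , drop = FALSE])
  x <- Re(stats::mvfft(spec, inverse = TRUE)) / nfft
  x <- scale(x, center = TRUE, scale = apply(x, 2, stats::sd))
  matrix(x * amplitude, nfft, n_series)
}

#' Noise specification for synthetic EEG
#'
#' @param pink_amplitude Per-channel pink-noise SD.
#' @param pink_alpha Spectral exponent.
#' @param drift_amplitude SD of the per-epoch, per-channel linear drift
#'   (amplitude reached at epoch end).
#' @param white_sd Per-sample white-noise SD.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(pink_amplitude = 1, pink_alpha = 1,
                       drift_amplitude = 0.5, white_sd = 0.5) {
  if (any(c(pink_amplitude, drift_amplitude, white_sd) < 0))
    stop("noise amplitudes must be non-negative")
  structure(list(pink_amplitude = pink_amplitude, pink_alpha = pink_alpha,
                 drift_amplitude = drift_amplitude, white_sd = white_sd),
            class = "noise_spec")
}

condition_transition_s <- function(condition) {
  # time of the first pattern-violating tone (50 ms pips, violation at 2 s)
  if (condition %in% c("REG", "INT0")) NA_real_ else 2.0
}

condition_n_int <- function(condition) {
  if (grepl("^INT", condition)) as.integer(sub("^INT", "", condition))
  else NA_integer_
}

#' Simulate one subject's epoched EEG
#'
#' Builds `trials x channels x samples` epochs as a sum of planted
#' components, each a fixed topography times a source time course:
#' a condition-specific sustained response, an onset N1 on every trial, an
#' MMN-like deviance response on interruption/transition trials, plus pink
#' noise, per-epoch linear drift, and white sensor noise. All ground-truth
#' parameters are stored with the recording.
#'
#' @param conditions Character vector, one condition label per trial
#'   (`REG`, `REGxREGy`, `INT0`, `INT1`, `INT3`, `INT5`).
#' @param sustained Named list mapping each condition to a
#'   [sustained_params()].
#' @param noise A [noise_spec()].
#' @param n_channels Number of channels.
#' @param fs Sampling rate (Hz; epochs span -1 to +5 s around onset).
#' @param n1_amplitude,mmn_amplitude Transient peak amplitudes (negative).
#' @param mmn_latency_s MMN peak delay after the interruption onset.
#' @param seed Integer seed.
#' @param epoch_start_s,epoch_end_s Epoch limits (seconds re stimulus onset).
#' @return A `subject_recording`: list with `epochs` (trials x channels x
#'   samples array), `fs`, `times`, `conditions`, and `ground_truth`.
#' @export
simulate_subject <- function(conditions, sustained, noise = noise_spec(),
                             n_channels = 64, fs = 256,
                             n1_amplitude = -2, mmn_amplitude = -1.5,
                             mmn_latency_s = 0.175, seed = 1,
                             epoch_start_s = -1, epoch_end_s = 5) {
  set.seed(seed)
  miss <- setdiff(unique(conditions), names(sustained))
  if (length(miss))
    stop("no sustained parameters for condition(s): ",
         paste(miss, collapse = ", "))
  t <- epoch_time(fs, epoch_start_s, epoch_end_s)
  n_samp <- length(t)
  n_trials <- length(conditions)
  topo <- list(sustained = make_topography(n_channels),
               n1 = make_topography(n_channels),
               mmn = make_topography(n_channels))
  n1 <- make_transient(0.1, 60, n1_amplitude, fs, epoch_start_s, epoch_end_s)
  env <- lapply(unique(conditions), function(cc)
    make_envelope(sustained[[cc]], condition_transition_s(cc), fs,
                  epoch_start_s, epoch_end_s))
  names(env) <- unique(conditions)
  # planted signal, computed once per condition (channels x samples)
  sig <- lapply(unique(conditions), function(cc) {
    src <- outer(topo$sustained, env[[cc]]) + outer(topo$n1, n1)
    tr_s <- condition_transition_s(cc)
    if (!is.na(tr_s))
      src <- src + outer(topo$mmn,
                         make_transient(tr_s + mmn_latency_s, 80,
                                        mmn_amplitude, fs,
                                        epoch_start_s, epoch_end_s))
    src
  })
  names(sig) <- unique(conditions)
  epochs <- array(0, dim = c(n_trials, n_channels, n_samp))
  for (cc in unique(conditions)) {
    rows <- which(conditions == cc)
    epochs[rows, , ] <- rep(sig[[cc]], each = length(rows))
  }
  if (noise$pink_amplitude > 0) {
    pn <- pink_noise(n_samp, n_trials * n_channels, noise$pink_alpha,
                     noise$pink_amplitude)
    epochs <- epochs + aperm(array(pn, c(n_samp, n_trials, n_channels)),
                             c(2, 3, 1))
  }
  if (noise$drift_amplitude > 0) {
    slopes <- matrix(stats::rnorm(n_trials * n_channels,
                                  sd = noise$drift_amplitude),
                     n_trials, n_channels)
    ramp <- (t - t[1]) / (t[n_samp] - t[1])
    epochs <- epochs + outer(slopes, ramp)
  }
  if (noise$white_sd > 0)
    epochs <- epochs + array(stats::rnorm(length(epochs),
                                          sd = noise$white_sd), dim(epochs))
  structure(list(epochs = epochs, fs = fs, times = t,
                 conditions = conditions,
                 ground_truth = list(sustained = sustained,
                                     topographies = topo, noise = noise,
                                     n1_amplitude = n1_amplitude,
                                     mmn_amplitude = mmn_amplitude,
                                     mmn_latency_s = mmn_latency_s,
                                     envelopes = env, seed = seed)),
            class = "subject_recording")
}

#' @export
print.subject_recording <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<subject_recording> %d trials x %d channels x %d samples @ %g Hz (%.1f to %.1f s)\n",
              d[1], d[2], d[3], x$fs, x$times[1], x$times[length(x$times)]))
  print(table(x$conditions))
  invisible(x)
}

#' Simulate a cohort of subjects
#'
#' Each subject gets an independent head model (topographies), independent
#' noise, and sustained parameters jittered around the cohort means
#' (multiplicative log-normal jitter on amplitudes, additive Gaussian jitter
#' on latencies/durations).
#'
#' @inheritParams simulate_subject
#' @param n_subjects Number of subjects.
#' @param amp_jitter SD of the multiplicative amplitude jitter (0 = none).
#' @param lat_jitter_ms SD of the additive latency jitter in ms (0 = none).
#' @param seed Master seed; per-subject seeds derive from it.
#' @param ... Passed on to [simulate_subject()].
#' @return List of `subject_recording`s.
#' @export
simulate_cohort <- function(n_subjects, conditions, sustained,
                            noise = noise_spec(), amp_jitter = 0.1,
                            lat_jitter_ms = 20, seed = 1, ...) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  lapply(seq_len(n_subjects), function(s) {
    set.seed(seeds[s])
    subj_sust <- lapply(sustained, function(p) {
      q <- p
      if (amp_jitter > 0) {
        g <- exp(stats::rnorm(1, sd = amp_jitter))
        q$plateau <- p$plateau * g
        q$trough <- p$trough * g
        q$post_offset <- p$post_offset * g
      }
      if (lat_jitter_ms > 0)
        q$drop_latency_ms <- max(0, p$drop_latency_ms +
                                   stats::rnorm(1, sd = lat_jitter_ms))
      q
    })
    simulate_subject(conditions, subj_sust, noise, seed = seeds[s], ...)
  })
}
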