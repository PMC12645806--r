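#' Logarithmically spaced tone-frequency pool
#'
#' Builds the fixed pool of pure-tone frequencies from which all sequences
#' draw. Frequencies are log-spaced so that adjacent tones are a constant
#' ratio apart; the default pool is 20 values from 222 to 2000 Hz.
#'
#' @param n Number of frequencies (>= 2).
#' @param f_min,f_max Lowest and highest frequency in Hz (0 < f_min < f_max).
#' @return Numeric vector of length `n`, strictly ascending, with
#'   `x[1] == f_min` and `x[n] == f_max`.
#' @examples
#' pool <- make_frequency_pool()
#' range(pool)
#' @export
make_frequency_pool <- function(n = 20, f_min = 222, f_max = 2000) {
  if (length(n) != 1 || n < 2 || n != round(n))
    stop("'n' must be a single integer >= 2")
  if (!(f_min > 0 && f_max > f_min))
    stop("require 0 < f_min < f_max")
  exp(seq(log(f_min), log(f_max), length.out = n))
}

new_trial_seq <- function(tones, condition, pool, cycle_length,
                          interruption_span = integer(0),
                          tone_duration_ms = 50, trial_id = NA_integer_,
                          seed = NA_integer_) {
  structure(
    list(tones = as.integer(tones), condition = condition, pool = pool,
         cycle_length = as.integer(cycle_length),
         interruption_span = as.integer(interruption_span),
         tone_duration_ms = tone_duration_ms,
         trial_id = trial_id, seed = seed),
    class = "trial_seq")
}

#' @export
print.trial_seq <- function(x, ...) {
  cat(sprintf("<trial_seq> %s: %d tones x %g ms (%g ms total)\n",
              x$condition, length(x$tones), x$tone_duration_ms,
              length(x$tones) * x$tone_duration_ms))
  if (length(x$interruption_span))
    cat(sprintf("  interruption: tones %d-%d\n",
                min(x$interruption_span), max(x$interruption_span)))
  cat("  tones:", paste(utils::head(x$tones, 25), collapse = " "),
      if (length(x$tones) > 25) "...", "\n")
  invisible(x)
}

#' Frequencies (Hz) of a trial's tones
#' @param trial A `trial_seq`.
#' @return Numeric vector of tone frequencies in Hz.
#' @export
trial_frequencies <- function(trial) trial$pool[trial$tones]

#' Generate a regularly cycling (REG) trial
#'
#' Samples `cycle_length` distinct pool indices without replacement and
#' cycles them to fill the trial, producing a regularly repeating pattern
#' with period `cycle_length`.
#'
#' @param pool Frequency pool from [make_frequency_pool()].
#' @param cycle_length Number of distinct tones per cycle (default 10).
#' @param n_tones Total trial length in tones (default 70, i.e. 3.5 s of
#'   50 ms pips).
#' @param seed Optional integer seed for the per-trial draw.
#' @return A `trial_seq` object.
#' @export
generate_reg_trial <- function(pool, cycle_length = 10, n_tones = 70,
                               seed = NULL) {
  if (cycle_length > length(pool))
    stop("cycle_length exceeds pool size")
  if (!is.null(seed)) set.seed(seed)
  cyc <- sample.int(length(pool), cycle_length)
  new_trial_seq(rep_len(cyc, n_tones), "REG", pool, cycle_length,
                seed = if (is.null(seed)) NA_integer_ else seed)
}

#' Generate a pattern-transition (REGxREGy) trial
#'
#' Tones 1-40 (2 s) cycle a first 10-tone regular pattern (REGx); tones
#' 41-70 (1.5 s) cycle a second pattern (REGy) built from the 10 pool
#' frequencies not used by REGx, so the two sets are disjoint and the first
#' REGy tone is always novel within the trial.
#'
#' @inheritParams generate_reg_trial
#' @return A `trial_seq` with condition `"REGxREGy"`.
#' @export
generate_regxregy_trial <- function(pool, cycle_length = 10, n_tones = 70,
                                    seed = NULL) {
  if (length(pool) != 2 * cycle_length)
    stop("pool size must equal 2 * cycle_length")
  if (!is.null(seed)) set.seed(seed)
  x <- sample.int(length(pool), cycle_length)
  y <- sample(setdiff(seq_along(pool), x))
  n_x <- 4 * cycle_length
  tones <- c(rep_len(x, n_x), rep_len(y, n_tones - n_x))
  new_trial_seq(tones, "REGxREGy", pool, cycle_length,
                seed = if (is.null(seed)) NA_integer_ else seed)
}

#' Generate an interrupted-regularity (INT) trial
#'
#' Four full REG cycles (tones 1-40, 2 s), then `n_int` interruption tones
#' drawn without replacement from the pool frequencies not used by the REG
#' pattern, after which the same REG pattern is re-started from cycle
#' position 1 and runs to tone 70. `n_int = 0` reduces to an uninterrupted
#' REG trial (condition INT0).
#'
#' @inheritParams generate_reg_trial
#' @param n_int Number of interruption tones; one of 0, 1, 3, 5 unless
#'   `strict = FALSE`.
#' @param strict Enforce the canonical set of interruption lengths.
#' @return A `trial_seq` with condition `"INT<n_int>"`; the interruption
#'   occupies tones `41 .. 40 + n_int`.
#' @export
generate_int_trial <- function(pool, n_int, cycle_length = 10, n_tones = 70,
                               seed = NULL, strict = TRUE) {
  if (strict && !n_int %in% c(0L, 1L, 3L, 5L))
    stop("n_int must be one of 0, 1, 3, 5")
  if (n_int + cycle_length > length(pool))
    stop("pool too small for REG cycle plus interruption")
  if (!is.null(seed)) set.seed(seed)
  cyc <- sample.int(length(pool), cycle_length)
  pre <- 4 * cycle_length
  int_tones <- if (n_int > 0)
    sample(setdiff(seq_along(pool), cyc))[seq_len(n_int)] else integer(0)
  tones <- c(rep_len(cyc, pre), int_tones,
             rep_len(cyc, n_tones - pre - n_int))
  span <- if (n_int > 0) (pre + 1L):(pre + n_int) else integer(0)
  new_trial_seq(tones, paste0("INT", n_int), pool, cycle_length,
                interruption_span = span,
                seed = if (is.null(seed)) NA_integer_ else seed)
}

#' Assemble a randomized stimulus session
#'
#' Generates one independently drawn trial per requested condition instance,
#' shuffles trial order, assigns a uniformly jittered inter-stimulus
#' interval, and splits trials into blocks. All randomness derives from a
#' single master seed; the same seed reproduces the session exactly.
#'
#' @param conditions Named integer vector of trial counts per condition.
#'   Names from `REG`, `REGxREGy`, `INT0`, `INT1`, `INT3`, `INT5`.
#'   Use [exp1_config()] / [exp2_config()] for the canonical designs.
#' @param pool Frequency pool (default the canonical 20-tone pool).
#' @param isi_range Inter-stimulus-interval jitter range in ms.
#' @param n_blocks Number of presentation blocks.
#' @param seed Master seed (integer).
#' @return A `stimulus_set`: list with `trials` (list of `trial_seq`),
#'   `isi_ms`, `block`, `conditions`, `seed`.
#' @examples
#' ses <- build_session(exp1_config(n_per_condition = 4), seed = 1)
#' table(session_conditions(ses))
#' @export
build_session <- function(conditions, pool = make_frequency_pool(),
                          isi_range = c(2500, 3000), n_blocks = 1,
                          seed = 1) {
  if (is.null(names(conditions)) || any(conditions < 1))
    stop("'conditions' must be a named vector of counts >= 1")
  set.seed(seed)
  labels <- rep(names(conditions), conditions)
  labels <- sample(labels)                      # randomized presentation order
  trial_seeds <- sample.int(.Machine$integer.max - 1L, length(labels))
  trials <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    trials[[i]] <- switch(
      labels[i],
      REG      = generate_reg_trial(pool, seed = trial_seeds[i]),
      REGxREGy = generate_regxregy_trial(pool, seed = trial_seeds[i]),
      {
        n_int <- as.integer(sub("^INT", "", labels[i]))
        generate_int_trial(pool, n_int, seed = trial_seeds[i])
      })
    trials[[i]]$trial_id <- i
  }
  set.seed(seed + 1L)
  isi <- stats::runif(length(labels), isi_range[1], isi_range[2])
  block <- sort(rep(seq_len(n_blocks), length.out = length(labels)))
  structure(list(trials = trials, isi_ms = isi,
                 block = block, conditions = conditions,
                 pool = pool, seed = seed),
            class = "stimulus_set")
}

#' Canonical session configurations
#'
#' `exp1_config()` describes the two-condition design (REG vs REGxREGy, 120
#' trials each in 4 blocks); `exp2_config()` the four-condition interrupted
#' design (INT0/1/3/5, 150 trials each in 5 blocks). `n_per_condition`
#' scales the design down for simulation work.
#'
#' @param n_per_condition Trials per condition.
#' @return Named integer vector of condition counts.
#' @export
exp1_config <- function(n_per_condition = 120) {
  c(REG = n_per_condition, REGxREGy = n_per_condition)
}

#' @rdname exp1_config
#' @export
exp2_config <- function(n_per_condition = 150) {
  c(INT0 = n_per_condition, INT1 = n_per_condition,
    INT3 = n_per_condition, INT5 = n_per_condition)
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("<stimulus_set> %d trials, seed %s\n", length(x$trials),
              format(x$seed)))
  print(table(session_conditions(x)))
  invisible(x)
}

#' Condition label of every trial in a session
#' @param session A `stimulus_set`.
#' @return Character vector of per-trial condition labels.
#' @export
session_conditions <- function(session) {
  vapply(session$trials, function(t) t$condition, character(1))
}

#' Synthesize the audio waveform of one trial
#'
#' Concatenates gap-free 50 ms pure-tone pips with raised-cosine on/off
#' ramps. Mostly useful for listening checks; the observer models consume
#' the symbolic sequences directly.
#'
#' @param trial A `trial_seq`.
#' @param sample_rate Audio sampling rate in Hz (must exceed twice the
#'   highest pool frequency).
#' @param ramp_ms Raised-cosine ramp duration (<= half the pip duration).
#' @param amplitude Linear peak amplitude.
#' @return Numeric vector of samples,
#'   `length(trial$tones) * tone_duration * sample_rate` long.
#' @export
synthesize_waveform <- function(trial, sample_rate = 44100, ramp_ms = 5,
                                amplitude = 0.8) {
  if (sample_rate < 2 * max(trial$pool))
    stop("sample_rate below Nyquist rate of the frequency pool")
  dur_s <- trial$tone_duration_ms / 1000
  if (ramp_ms > trial$tone_duration_ms / 2)
    stop("ramp longer than half the pip")
  n_pip <- round(dur_s * sample_rate)
  t <- (seq_len(n_pip) - 1) / sample_rate
  n_ramp <- round(ramp_ms / 1000 * sample_rate)
  env <- rep(1, n_pip)
  ramp <- 0.5 * (1 - cos(pi * (seq_len(n_ramp) - 1) / n_ramp))
  env[seq_len(n_ramp)] <- ramp
  env[n_pip + 1 - seq_len(n_ramp)] <- ramp
  freqs <- trial_frequencies(trial)
  as.numeric(vapply(freqs,
                    function(f) amplitude * env * sin(2 * pi * f * t),
                    numeric(n_pip)))
}

#' Write a waveform as a 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE writer (mono, 16-bit little-endian).
#'
#' @param wave Numeric vector in \[-1, 1\].
#' @param path Output file path.
#' @param sample_rate Sampling rate in Hz.
#' @return `path`, invisibly.
#' @export
write_trial_wav <- function(wave, path, sample_rate = 44100) {
  pcm <- as.integer(round(pmax(-1, pmin(1, wave)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + n_bytes, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")       # PCM
  writeBin(1L, con, size = 2, endian = "little")       # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")       # block align
  writeBin(16L, con, size = 2, endian = "little")      # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Export a session's symbolic sequences
#'
#' Writes one long-format CSV (trial_id, condition, tone_index, pool_index,
#' frequency_hz, onset_ms) plus a JSON metadata sidecar (pool, seed, ISI
#' list, block map).
#'
#' @param session A `stimulus_set`.
#' @param dir Output directory (created if missing).
#' @param stem File name stem.
#' @return Invisibly, the paths written.
#' @export
write_session <- function(session, dir, stem = "session") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- do.call(rbind, lapply(session$trials, function(tr) {
    n <- length(tr$tones)
    data.frame(trial_id = tr$trial_id, condition = tr$condition,
               tone_index = seq_len(n), pool_index = tr$tones,
               frequency_hz = trial_frequencies(tr),
               onset_ms = (seq_len(n) - 1) * tr$tone_duration_ms)
  }))
  csv <- file.path(dir, paste0(stem, ".csv"))
  utils::write.csv(rows, csv, row.names = FALSE)
  meta <- list(pool_hz = session$pool, seed = session$seed,
               isi_ms = session$isi_ms, block = session$block,
               conditions = as.list(session$conditions))
  js <- file.path(dir, paste0(stem, ".json"))
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = js))
}
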