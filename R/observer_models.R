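#' Observer-model specification
#'
#' The five observer variants differ only in the span of past input (the
#' "pre-training window") accessible when predicting each tone:
#'
#' * `m1.1` — memory starts within the current trial, two cycles before the
#'   transition tone (tone 21 by default for 10-tone cycles).
#' * `m1.2` — memory starts at the current trial's onset.
#' * `m1.3` — the 3 preceding session trials plus the current trial.
#' * `m1.4` — the 240 preceding session trials plus the current trial
#'   (effectively the whole session at desk scale).
#' * `m2`   — like `m1.2`, but all memory is cleared upon detecting a
#'   deviant: the first novel (zero-count) symbol that arrives while the
#'   accessible memory already contains an established repetition (some
#'   symbol count >= 2). The deviant itself is scored against the full
#'   pre-reset memory, then becomes the first symbol of the new memory.
#'
#' @param label One of `"m1.1"`, `"m1.2"`, `"m1.3"`, `"m1.4"`, `"m2"`.
#' @param anchor Within-trial memory onset (tones) for the anchored
#'   observer.
#' @param n_preceding Number of preceding session trials kept in memory for
#'   the trial-window observers.
#' @param ... PPM configuration overrides passed to [new_ppm()]
#'   (`order_bound`, `escape`, `exclusion`, ...).
#' @return An `observer_spec`.
#' @export
observer_spec <- function(label = c("m1.1", "m1.2", "m1.3", "m1.4", "m2"),
                          anchor = 21, n_preceding = NULL, ...) {
  label <- match.arg(label)
  policy <- switch(label,
                   "m1.1" = "anchor",
                   "m1.2" = "trial",
                   "m1.3" = ,
                   "m1.4" = "preceding_trials",
                   "m2"   = "reset")
  if (is.null(n_preceding))
    n_preceding <- switch(label, "m1.3" = 3L, "m1.4" = 240L, 0L)
  structure(list(label = label, policy = policy, anchor = as.integer(anchor),
                 n_preceding = as.integer(n_preceding),
                 ppm_config = list(...)),
            class = "observer_spec")
}

#' @export
print.observer_spec <- function(x, ...) {
  cat(sprintf("<observer_spec> %s (policy: %s%s)\n", x$label, x$policy,
              switch(x$policy,
                     anchor = sprintf(", anchor tone %d", x$anchor),
                     preceding_trials = sprintf(", %d preceding trials",
                                                x$n_preceding),
                     "")))
  invisible(x)
}

make_observer_model <- function(spec, alphabet_size) {
  do.call(new_ppm, c(list(alphabet_size = alphabet_size), spec$ppm_config))
}

score_trial_reset <- function(model, tones) {
  n <- length(tones)
  p <- numeric(n)
  for (i in seq_len(n)) {
    d <- predictive_distribution(model)
    p[i] <- d[tones[i]]
    cnt0 <- symbol_counts(model)
    deviant <- cnt0[tones[i]] == 0L && max(cnt0) >= 2L
    if (deviant) clear_ppm(model)
    observe_symbol(model, tones[i])
  }
  p
}

#' Run an observer model over a stimulus session
#'
#' Processes every trial of the session in presentation order under the
#' observer's memory policy, scoring each tone by predict-then-update
#' online learning, and collects per-tone information content.
#'
#' @param spec An [observer_spec()].
#' @param session A [build_session()] stimulus set.
#' @param conditions Optional character vector: keep only these conditions
#'   in the result (trial-window observers still use the full session order
#'   as context).
#' @return A `simulation_result`: list with `ic` (trials x tones matrix of
#'   information content in bits), `probability` (same shape), `condition`
#'   (per-trial labels), `observer`, `seed`.
#' @export
run_observer <- function(spec, session, conditions = NULL) {
  stopifnot(inherits(spec, "observer_spec"), inherits(session, "stimulus_set"))
  trials <- session$trials
  if (length(trials) == 0) stop("empty session")
  a_size <- length(session$pool)
  n_tones <- length(trials[[1]]$tones)
  n_trials <- length(trials)
  prob <- matrix(NA_real_, n_trials, n_tones)

  if (spec$policy %in% c("trial", "anchor", "reset")) {
    for (i in seq_len(n_trials)) {
      tones <- trials[[i]]$tones
      model <- make_observer_model(spec, a_size)
      if (spec$policy == "anchor" && spec$anchor > 1) {
        # memory opens at the anchor; earlier tones are predicted from an
        # empty model (uniform) and never enter memory
        pre <- seq_len(min(spec$anchor - 1L, n_tones))
        prob[i, pre] <- 1 / a_size
        if (spec$anchor <= n_tones)
          prob[i, spec$anchor:n_tones] <-
            process_trial(model, tones[spec$anchor:n_tones])$probability
      } else if (spec$policy == "reset") {
        prob[i, ] <- score_trial_reset(model, tones)
      } else {
        prob[i, ] <- process_trial(model, tones)$probability
      }
    }
  } else {                                   # preceding_trials
    if (spec$n_preceding >= n_trials - 1L) {
      # window covers every preceding trial: one persistent model
      model <- make_observer_model(spec, a_size)
      for (i in seq_len(n_trials)) {
        begin_sequence(model)
        prob[i, ] <- process_trial(model, trials[[i]]$tones)$probability
      }
    } else {
      for (i in seq_len(n_trials)) {
        model <- make_observer_model(spec, a_size)
        first <- max(1L, i - spec$n_preceding)
        for (j in seq(first, length.out = i - first)) {
          begin_sequence(model)
          for (s in trials[[j]]$tones) observe_symbol(model, s)
        }
        begin_sequence(model)
        prob[i, ] <- process_trial(model, trials[[i]]$tones)$probability
      }
    }
  }

  cond <- session_conditions(session)
  keep <- if (is.null(conditions)) seq_len(n_trials) else
    which(cond %in% conditions)
  structure(list(ic = -log2(prob[keep, , drop = FALSE]),
                 probability = prob[keep, , drop = FALSE],
                 condition = cond[keep], observer = spec$label,
                 seed = session$seed),
            class = "simulation_result")
}

result_rows <- function(result, condition) {
  if (is.null(condition)) seq_len(nrow(result$ic))
  else which(result$condition %in% condition)
}

#' Per-position mean information content
#'
#' @param result A `simulation_result`.
#' @param condition Optional condition filter.
#' @param scale `"raw"` (bits) or `"log"` (natural log of IC, the scale
#'   used for display in sequence-tracking work).
#' @return Numeric vector, one value per tone position.
#' @export
mean_ic_trace <- function(result, condition = NULL, scale = c("raw", "log")) {
  scale <- match.arg(scale)
  x <- result$ic[result_rows(result, condition), , drop = FALSE]
  if (scale == "log") x <- log(x)
  colMeans(x)
}

#' Mean information content over a window of tone positions
#'
#' Averages per-trial window means, optionally on the log scale (the
#' transform is applied per tone before averaging).
#'
#' @param result A `simulation_result`.
#' @param window Integer vector of tone positions (default the last cycle,
#'   tones 61-70).
#' @param scale `"raw"` or `"log"`.
#' @param condition Optional condition filter.
#' @return Scalar mean.
#' @export
summarize_window <- function(result, window = 61:70,
                             scale = c("raw", "log"), condition = NULL) {
  scale <- match.arg(scale)
  if (length(window) == 0) stop("empty window")
  if (min(window) < 1 || max(window) > ncol(result$ic))
    stop("window outside trial")
  x <- result$ic[result_rows(result, condition), window, drop = FALSE]
  if (scale == "log") x <- log(x)
  mean(rowMeans(x))
}

#' Difference of window means between two conditions
#'
#' @param result_a,result_b `simulation_result`s from the same observer.
#'   `result_b` may be omitted to compare two conditions within `result_a`.
#' @param window Tone positions to average (default 61-70).
#' @param scale `"raw"` or `"log"`.
#' @param condition_a,condition_b Condition filters.
#' @return `summarize_window(a) - summarize_window(b)`.
#' @export
condition_difference <- function(result_a, result_b = result_a,
                                 window = 61:70, scale = "raw",
                                 condition_a = NULL, condition_b = NULL) {
  if (!identical(result_a$observer, result_b$observer))
    stop("results come from different observers")
  summarize_window(result_a, window, scale, condition_a) -
    summarize_window(result_b, window, scale, condition_b)
}

peak_prominence <- function(x, i) {
  # nearest strictly higher point on each side bounds the peak's base
  left <- if (i > 1) {
    j <- which(x[seq_len(i - 1)] > x[i])
    lo <- if (length(j)) max(j) + 1L else 1L
    min(x[lo:(i - 1)])
  } else x[i]
  right <- if (i < length(x)) {
    j <- which(x[(i + 1):length(x)] > x[i])
    hi <- if (length(j)) i + min(j) - 1L else length(x)
    min(x[(i + 1):hi])
  } else x[i]
  x[i] - max(left, right)
}

#' Detect phantom interruption peaks
#'
#' Finds strict local maxima of the trial-averaged information-content
#' trace after the interruption. A context-incorporating observer expects
#' the interruption to recur at each post-resumption cycle onset, producing
#' "phantom" IC spikes there; a reset observer does not.
#'
#' @param result A `simulation_result`.
#' @param search_start First tone position of the search window (must lie
#'   after the interruption).
#' @param min_prominence Minimum peak prominence in bits (default 0.5).
#' @param condition Optional condition filter.
#' @param scale `"raw"` or `"log"`.
#' @return A `peak_report`: list with `peaks` (ascending tone indices) and
#'   `prominence`.
#' @export
detect_phantom_peaks <- function(result, search_start, min_prominence = 0.5,
                                 condition = NULL, scale = "raw") {
  trace <- mean_ic_trace(result, condition, scale)
  n <- length(trace)
  if (search_start >= n) stop("search_start beyond trial end")
  idx <- seq(max(2L, search_start), n - 1L)
  is_max <- trace[idx] > trace[idx - 1L] & trace[idx] > trace[idx + 1L]
  cand <- idx[is_max]
  win <- trace[search_start:n]
  prom <- vapply(cand, function(i) peak_prominence(win, i - search_start + 1L),
                 numeric(1))
  keep <- prom >= min_prominence
  structure(list(peaks = cand[keep], prominence = prom[keep],
                 search_start = search_start, trace = trace),
            class = "peak_report")
}

#' @export
print.peak_report <- function(x, ...) {
  if (length(x$peaks) == 0) {
    cat("<peak_report> no peaks\n")
  } else {
    cat("<peak_report> peaks at tones:",
        paste(x$peaks, collapse = ", "), "\n")
    cat("  prominence (bits):",
        paste(sprintf("%.2f", x$prominence), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tones until the mean IC falls below a criterion
#'
#' Measures how quickly an observer re-discovers the regular pattern: the
#' smallest offset `k >= 0` such that the trial-averaged IC at tone
#' `from + k` is below `criterion`.
#'
#' @param result A `simulation_result`.
#' @param criterion IC level in bits (> 0).
#' @param from Tone position from which to start.
#' @param condition Optional condition filter.
#' @return Integer offset, or `NA` if the criterion is never met.
#' @export
time_to_criterion <- function(result, criterion, from, condition = NULL) {
  if (criterion <= 0) stop("criterion must be positive")
  trace <- mean_ic_trace(result, condition)
  below <- which(trace[from:length(trace)] < criterion)
  if (length(below) == 0) NA_integer_ else below[1] - 1L
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> observer %s: %d trials x %d tones\n",
              x$observer, nrow(x$ic), ncol(x$ic)))
  print(table(x$condition))
  invisible(x)
}

#' @export
summary.simulation_result <- function(object, window = 61:70, ...) {
  conds <- unique(object$condition)
  data.frame(condition = conds,
             n_trials = vapply(conds, function(cc)
               sum(object$condition == cc), numeric(1)),
             window_mean_ic = vapply(conds, function(cc)
               summarize_window(object, window, condition = cc), numeric(1)),
             row.names = NULL)
}

#' @export
plot.simulation_result <- function(x, conditions = unique(x$condition),
                                   scale = "raw", ...) {
  traces <- sapply(conditions, function(cc) mean_ic_trace(x, cc, scale))
  graphics::matplot(traces, type = "l", lty = 1, xlab = "tone position",
                    ylab = sprintf("mean IC (%s)", scale),
                    main = sprintf("observer %s", x$observer), ...)
  graphics::legend("topright", legend = conditions, lty = 1,
                   col = seq_along(conditions), bty = "n")
  invisible(x)
}
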