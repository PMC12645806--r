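#' Variable-order Markov model with PPM smoothing
#'
#' Creates an empty prediction-by-partial-matching (PPM) model over a finite
#' symbol alphabet `1..alphabet_size`. The model learns online: counts of
#' n-grams up to `order_bound + 1` symbols are accumulated as symbols are
#' observed, and predictive distributions blend match counts across context
#' lengths via escape probabilities, falling through to a uniform order
#' "-1" base so no symbol ever has zero probability.
#'
#' The returned object has reference semantics (it is an environment, like
#' other online-learning model objects): [observe_symbol()] and
#' [process_trial()] update it in place.
#'
#' @param alphabet_size Number of symbols (>= 2).
#' @param order_bound Maximum context length (>= 0; default 10).
#' @param escape Escape method, one of `"c"` (default), `"a"`, `"b"`,
#'   `"d"`, `"ax"`. Method C assigns a context of `n` continuation tokens
#'   over `t` distinct symbols escape mass `t / (n + t)` and symbol weight
#'   `count / (n + t)`.
#' @param exclusion Apply exclusion: symbols already matched at a longer
#'   context are removed from the counts of shorter contexts (default TRUE).
#' @param update_exclusion Stop propagating count updates below the longest
#'   context that already predicted the observed symbol (default FALSE).
#' @param shortest_deterministic Start the escape chain at the shortest
#'   matched context with a single distinct continuation, when one exists
#'   (default TRUE).
#' @return An object of class `ppm`.
#' @examples
#' m <- new_ppm(alphabet_size = 2, order_bound = 2)
#' process_trial(m, c(1, 2, 1, 2, 1, 2))
#' @export
new_ppm <- function(alphabet_size, order_bound = 10, escape = "c",
                    exclusion = TRUE, update_exclusion = FALSE,
                    shortest_deterministic = TRUE) {
  if (length(alphabet_size) != 1 || alphabet_size < 2)
    stop("alphabet_size must be >= 2")
  if (length(order_bound) != 1 || order_bound < 0)
    stop("order_bound must be >= 0")
  escape <- match.arg(tolower(escape), c("c", "a", "b", "d", "ax"))
  m <- new.env(parent = emptyenv())
  m$alphabet_size <- as.integer(alphabet_size)
  m$order_bound <- as.integer(order_bound)
  m$escape <- escape
  m$exclusion <- isTRUE(exclusion)
  m$update_exclusion <- isTRUE(update_exclusion)
  m$shortest_deterministic <- isTRUE(shortest_deterministic)
  m$counts <- new.env(hash = TRUE, parent = emptyenv())
  m$hist_buf <- integer(256)
  m$hist_len <- 0L
  class(m) <- "ppm"
  m
}

#' Accessible symbol history of a model
#' @param model A [new_ppm()] model.
#' @return Integer vector of observed symbols, oldest first.
#' @export
ppm_history <- function(model) {
  model$hist_buf[seq_len(model$hist_len)]
}

#' @export
print.ppm <- function(x, ...) {
  cat(sprintf(
    "<ppm> alphabet %d, order bound %d, escape %s%s%s%s; history %d symbols\n",
    x$alphabet_size, x$order_bound, toupper(x$escape),
    if (x$exclusion) ", exclusion" else "",
    if (x$update_exclusion) ", update-exclusion" else "",
    if (x$shortest_deterministic) ", shortest-deterministic" else "",
    x$hist_len))
  invisible(x)
}

context_key <- function(ctx) {
  if (length(ctx) == 0) "k" else paste0("k", paste(ctx, collapse = "."))
}

#' Observe one symbol
#'
#' Extends the model's history by `symbol` and increments the count of
#' `symbol` under every context suffix of the history up to the order
#' bound. Modifies the model in place.
#'
#' @param model A [new_ppm()] model.
#' @param symbol Integer symbol in `1..alphabet_size`.
#' @return The model, invisibly.
#' @export
observe_symbol <- function(model, symbol) {
  symbol <- as.integer(symbol)
  if (is.na(symbol) || symbol < 1 || symbol > model$alphabet_size)
    stop("symbol outside alphabet")
  n <- model$hist_len
  h <- model$hist_buf
  kmax <- min(model$order_bound, n)
  keys <- character(kmax + 1)
  key <- "k"
  keys[1] <- key
  for (k in seq_len(kmax)) {             # suffix of length k ends at h[n]
    key <- context_key(h[(n - k + 1):n])
    keys[k + 1] <- key
  }
  cnts <- model$counts
  if (model$update_exclusion) {
    # propagate from the longest context down; stop once a context already
    # predicted the symbol (increment it, then halt)
    for (k in rev(seq_along(keys))) {
      key <- keys[k]
      v <- if (is.null(cnts[[key]])) integer(model$alphabet_size) else cnts[[key]]
      seen <- v[symbol] > 0
      v[symbol] <- v[symbol] + 1L
      cnts[[key]] <- v
      if (seen) break
    }
  } else {
    for (key in keys) {
      v <- cnts[[key]]
      if (is.null(v)) v <- integer(model$alphabet_size)
      v[symbol] <- v[symbol] + 1L
      cnts[[key]] <- v
    }
  }
  if (n + 1L > length(model$hist_buf))
    model$hist_buf <- c(model$hist_buf, integer(length(model$hist_buf)))
  model$hist_buf[n + 1L] <- symbol
  model$hist_len <- n + 1L
  invisible(model)
}

escape_weights <- function(cnt, method) {
  # returns list(alpha = per-symbol weight, gamma = escape mass)
  n <- sum(cnt)
  if (n == 0) return(list(alpha = NULL, gamma = 1))
  t <- sum(cnt > 0)
  switch(method,
    c  = list(alpha = cnt / (n + t), gamma = t / (n + t)),
    a  = list(alpha = cnt / (n + 1), gamma = 1 / (n + 1)),
    b  = list(alpha = pmax(cnt - 1L, 0L) / n, gamma = t / n),
    d  = list(alpha = pmax(cnt - 0.5, 0) / n, gamma = (t / 2) / n),
    ax = {
      t1 <- sum(cnt == 1L)
      list(alpha = cnt / (n + t1 + 1), gamma = (t1 + 1) / (n + t1 + 1))
    })
}

ppm_distribution <- function(model, context) {
  a_size <- model$alphabet_size
  kmax <- min(model$order_bound, length(context))
  ctx <- if (kmax > 0) context[(length(context) - kmax + 1):length(context)]
         else integer(0)
  cnts <- model$counts
  # gather count vectors for suffixes of length kmax .. 0
  cnt_list <- vector("list", kmax + 1)
  for (k in kmax:0) {
    key <- if (k == 0) "k" else context_key(ctx[(kmax - k + 1):kmax])
    v <- cnts[[key]]
    cnt_list[[k + 1]] <- if (is.null(v)) integer(a_size) else v
  }
  # starting order: longest matched context, or the shortest deterministic
  # matched context if that option is enabled
  ns <- vapply(cnt_list, sum, numeric(1))
  matched <- which(ns > 0)                 # index = order + 1
  start <- if (length(matched) == 0) 0 else max(matched)
  if (model$shortest_deterministic && length(matched)) {
    ts <- vapply(cnt_list[matched], function(v) sum(v > 0), numeric(1))
    det <- matched[ts == 1]
    if (length(det)) start <- min(det)
  }
  p <- numeric(a_size)
  excluded <- logical(a_size)
  w <- 1
  if (start > 0) {
    for (idx in start:1) {
      cnt <- cnt_list[[idx]]
      if (model$exclusion) cnt[excluded] <- 0L
      ew <- escape_weights(cnt, model$escape)
      if (!is.null(ew$alpha)) p <- p + w * ew$alpha
      if (model$exclusion) excluded <- excluded | cnt > 0L
      w <- w * ew$gamma
      if (w == 0) break
    }
  }
  # order -1 base: uniform 1/alphabet_size over all symbols (exclusion acts
  # on the count levels only); the chain then sums to 1 exactly
  p <- p + w / a_size
  p / sum(p)
}

#' Predictive distribution over the alphabet
#'
#' Computes the PPM-smoothed conditional distribution of the next symbol
#' given a context, by blending continuation counts from the longest
#' matched context down through shorter contexts to the uniform base.
#'
#' @param model A [new_ppm()] model.
#' @param context Integer vector of preceding symbols (defaults to the
#'   model's full history). Only the final `order_bound` symbols are used.
#' @return Numeric vector of length `alphabet_size`; strictly positive,
#'   sums to 1.
#' @export
predictive_distribution <- function(model, context = ppm_history(model)) {
  if (length(context) && (any(context < 1) || any(context > model$alphabet_size)))
    stop("context symbols outside alphabet")
  ppm_distribution(model, as.integer(context))
}

#' @export
predict.ppm <- function(object, context = ppm_history(object), ...) {
  predictive_distribution(object, context)
}

#' Information content (surprisal) of a symbol
#'
#' @param dist Predictive distribution from [predictive_distribution()].
#' @param symbol Integer symbol.
#' @return Surprisal in bits, `-log2(dist[symbol])`.
#' @export
information_content <- function(dist, symbol) {
  -log2(dist[symbol])
}

#' Score a symbol sequence online (predict, then update)
#'
#' For each position the model first computes the predictive distribution
#' given everything seen so far, records the probability and information
#' content of the observed symbol, and then learns it. The model is
#' updated in place.
#'
#' @param model A [new_ppm()] model.
#' @param symbols Integer vector of symbols.
#' @return A data frame (class `ic_trace`) with columns `position`,
#'   `symbol`, `probability`, `ic_bits`.
#' @export
process_trial <- function(model, symbols) {
  symbols <- as.integer(symbols)
  if (any(symbols < 1) || any(symbols > model$alphabet_size))
    stop("symbols outside alphabet")
  n <- length(symbols)
  p <- numeric(n)
  for (i in seq_len(n)) {
    d <- ppm_distribution(model, model$hist_buf[seq_len(model$hist_len)])
    p[i] <- d[symbols[i]]
    observe_symbol(model, symbols[i])
  }
  structure(data.frame(position = seq_len(n), symbol = symbols,
                       probability = p, ic_bits = -log2(p)),
            class = c("ic_trace", "data.frame"))
}

#' Reset a model to its empty state
#'
#' Clears all counts and history (in place), as when an observer discards
#' its memory upon detecting a deviant.
#'
#' @param model A [new_ppm()] model.
#' @return The model, invisibly.
#' @export
clear_ppm <- function(model) {
  model$counts <- new.env(hash = TRUE, parent = emptyenv())
  model$hist_len <- 0L
  invisible(model)
}

#' Start a new sequence without forgetting
#'
#' Clears the model's current context (history) while keeping all learned
#' n-gram counts, so that contexts never span the boundary between two
#' separately presented sequences. Modifies the model in place.
#'
#' @param model A [new_ppm()] model.
#' @return The model, invisibly.
#' @export
begin_sequence <- function(model) {
  model$hist_len <- 0L
  invisible(model)
}

#' Order-0 symbol counts of a model
#'
#' How often each alphabet symbol occurs in the model's accessible memory.
#' Used, e.g., to detect novel (zero-count) symbols.
#'
#' @param model A [new_ppm()] model.
#' @return Integer vector of length `alphabet_size`.
#' @export
symbol_counts <- function(model) {
  v <- model$counts[["k"]]
  if (is.null(v)) integer(model$alphabet_size) else v
}

#' Export an information-content trace as CSV
#'
#' @param trace An `ic_trace` from [process_trial()], or a list of them.
#' @param path Output CSV path.
#' @param trial_id Trial identifier(s) recycled over traces.
#' @return `path`, invisibly.
#' @export
write_ic_trace <- function(trace, path, trial_id = 1) {
  if (inherits(trace, "ic_trace")) trace <- list(trace)
  rows <- do.call(rbind, Map(function(tr, id)
    cbind(trial_id = id, as.data.frame(tr)), trace,
    rep_len(trial_id, length(trace))))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
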