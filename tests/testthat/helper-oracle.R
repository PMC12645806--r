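# Independent brute-force evaluator of the PPM escape recursion.
#
# Works directly on the raw symbol history by scanning for context
# occurrences (no count store, no incremental update), so it shares no code
# path with the package implementation. Intended for small problems
# (alphabet <= 3, history <= 8, order <= 2).

oracle_continuations <- function(history, ctx, alphabet_size) {
  k <- length(ctx)
  cnt <- integer(alphabet_size)
  if (length(history) < k + 1) return(cnt)
  for (i in seq(k + 1, length(history))) {
    if (k == 0 || identical(history[(i - k):(i - 1)], ctx))
      cnt[history[i]] <- cnt[history[i]] + 1L
  }
  cnt
}

oracle_escape <- function(cnt, method) {
  n <- sum(cnt)
  t <- sum(cnt > 0)
  if (n == 0) return(list(alpha = cnt * 0, gamma = 1))
  switch(method,
         c = list(alpha = cnt / (n + t), gamma = t / (n + t)),
         a = list(alpha = cnt / (n + 1), gamma = 1 / (n + 1)),
         stop("oracle supports escape methods a and c"))
}

# full predictive distribution by explicit recursion over context lengths
oracle_ppm_distribution <- function(history, context, alphabet_size,
                                    order_bound, escape = "c",
                                    exclusion = TRUE,
                                    shortest_deterministic = TRUE) {
  history <- as.integer(history)
  context <- as.integer(context)
  kmax <- min(order_bound, length(context))
  suffix <- function(k) if (k == 0) integer(0) else
    context[(length(context) - k + 1):length(context)]
  counts <- lapply(0:kmax, function(k)
    oracle_continuations(history, suffix(k), alphabet_size))
  ns <- vapply(counts, sum, numeric(1))
  matched <- which(ns > 0) - 1L                     # orders with any counts
  start <- if (length(matched) == 0) -1L else max(matched)
  if (shortest_deterministic && length(matched) > 0) {
    det <- matched[vapply(matched, function(k)
      sum(counts[[k + 1]] > 0) == 1, logical(1))]
    if (length(det) > 0) start <- min(det)
  }
  rec <- function(order, excluded) {
    if (order < 0) return(rep(1 / alphabet_size, alphabet_size))
    cnt <- counts[[order + 1]]
    if (exclusion) cnt[excluded] <- 0L
    ew <- oracle_escape(cnt, escape)
    lower <- rec(order - 1, if (exclusion) excluded | cnt > 0 else excluded)
    ew$alpha + ew$gamma * lower
  }
  p <- rec(start, rep(FALSE, alphabet_size))
  p / sum(p)
}
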