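test_that("empty model predicts uniformly and validates its configuration", {
  m <- new_ppm(20)
  expect_equal(predictive_distribution(m, integer(0)), rep(1 / 20, 20))
  expect_equal(predictive_distribution(m, c(3L, 5L)), rep(1 / 20, 20))
  m2 <- new_ppm(2)
  expect_equal(information_content(predictive_distribution(m2), 1L), 1)
  expect_error(new_ppm(20, order_bound = -1), "order_bound")
  expect_error(new_ppm(1), "alphabet_size")
  expect_error(observe_symbol(new_ppm(3), 4L), "alphabet")
})

test_that("observing symbols stores the expected n-gram counts", {
  m <- new_ppm(3, order_bound = 2)
  observe_symbol(m, 1L)
  expect_equal(symbol_counts(m), c(1L, 0L, 0L))
  # "a b a": count of a after context b, and b after context a
  m <- new_ppm(3, order_bound = 2)
  for (s in c(1L, 2L, 1L)) observe_symbol(m, s)
  expect_equal(m$counts[["k2"]], c(1L, 0L, 0L))   # P(a | b) count
  expect_equal(m$counts[["k1"]], c(0L, 1L, 0L))   # P(b | a) count
  # total stored (k+1)-gram mass at order k is max(0, n - k)
  set.seed(1)
  m <- new_ppm(4, order_bound = 10)
  n <- 23
  for (s in sample.int(4, n, replace = TRUE)) observe_symbol(m, s)
  keys <- ls(m$counts)
  order_of <- function(key) if (key == "k") 0L else
    length(strsplit(substring(key, 2), ".", fixed = TRUE)[[1]])
  for (k in 0:10) {
    mass <- sum(vapply(keys[vapply(keys, order_of, integer(1)) == k],
                       function(key) sum(m$counts[[key]]), numeric(1)))
    expect_equal(mass, max(0, n - k))
  }
})

test_that("blended probabilities match the brute-force escape recursion", {
  set.seed(42)
  for (case in 1:60) {
    a_size <- sample(2:3, 1)
    n_hist <- sample(1:8, 1)
    ob <- sample(0:2, 1)
    excl <- sample(c(TRUE, FALSE), 1)
    sd_flag <- sample(c(TRUE, FALSE), 1)
    esc <- sample(c("c", "a"), 1)
    hist <- sample.int(a_size, n_hist, replace = TRUE)
    ctx <- sample.int(a_size, sample(0:4, 1), replace = TRUE)
    m <- new_ppm(a_size, order_bound = ob, escape = esc, exclusion = excl,
                 shortest_deterministic = sd_flag)
    for (s in hist) observe_symbol(m, s)
    got <- predictive_distribution(m, ctx)
    want <- oracle_ppm_distribution(hist, ctx, a_size, ob, esc, excl,
                                    sd_flag)
    expect_equal(got, want, tolerance = 1e-12,
                 label = sprintf("case %d (A=%d, hist=%s, ctx=%s)", case,
                                 a_size, paste(hist, collapse = ""),
                                 paste(ctx, collapse = "")))
  }
})

test_that("hand-expanded escape-C arithmetic matches on 'a b a b a'", {
  # alphabet {a=1, b=2}, order 2, escape C, exclusion off, no shortest-
  # deterministic shortcut: predict b after context "...a".
  m <- new_ppm(2, order_bound = 2, exclusion = FALSE,
               shortest_deterministic = FALSE)
  for (s in c(1L, 2L, 1L, 2L, 1L)) observe_symbol(m, s)
  # context "b a" (last two symbols): order-2 counts after (b,a): {b: 1}
  # order-1 counts after (a): {b: 2}; order-0 counts: {a: 3, b: 2}
  # p2(b) = 1/2 + 1/2 * p1(b); p1(b) = 2/3 + 1/3 * p0(b)
  # p0(b) = 2/7 + 2/7 * 1/2
  p0 <- 2 / 7 + (2 / 7) * (1 / 2)
  p1 <- 2 / 3 + (1 / 3) * p0
  p2 <- 1 / 2 + (1 / 2) * p1
  d <- predictive_distribution(m, c(2L, 1L))
  expect_equal(d[2], p2, tolerance = 1e-12)
  expect_equal(p2, 19 / 21)
})

test_that("every predictive distribution sums to one", {
  set.seed(7)
  for (i in 1:25) {
    a_size <- sample(2:6, 1)
    m <- new_ppm(a_size, order_bound = sample(0:10, 1),
                 exclusion = sample(c(TRUE, FALSE), 1))
    for (s in sample.int(a_size, sample(1:60, 1), replace = TRUE))
      observe_symbol(m, s)
    d <- predictive_distribution(m,
                                 sample.int(a_size, sample(0:12, 1),
                                            replace = TRUE))
    expect_true(all(d > 0))
    expect_lt(abs(sum(d) - 1), 1e-9)
  }
})

test_that("information content is -log2 p and monotone in p", {
  expect_equal(information_content(c(0.5, 0.5), 1L), 1)
  expect_equal(information_content(rep(1 / 20, 20), 3L), log2(20))
  p <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(-log2(p)) < 0))
})

test_that("online learning lowers surprisal on repeating patterns", {
  m <- new_ppm(2, order_bound = 5)
  tr <- process_trial(m, rep(c(1L, 2L), 12))
  cyc <- matrix(tr$ic_bits, nrow = 2)       # columns are period-2 cycles
  cycle_means <- colMeans(cyc)
  expect_true(all(diff(cycle_means[1:6]) < 0))
  # re-processing the same trial: lower total IC than the first pass
  pool <- make_frequency_pool()
  trial <- generate_reg_trial(pool, seed = 9)
  m2 <- new_ppm(20)
  first <- sum(process_trial(m2, trial$tones)$ic_bits)
  begin_sequence(m2)
  second <- sum(process_trial(m2, trial$tones)$ic_bits)
  expect_lt(second, first)
})

test_that("IC approaches the entropy rate on iid uniform input", {
  set.seed(11)
  m <- new_ppm(4, order_bound = 4)
  tr <- process_trial(m, sample.int(4, 4000, replace = TRUE))
  expect_lt(abs(mean(tr$ic_bits[3001:4000]) - 2), 0.1)
})

test_that("clearing a model restores the empty state", {
  m <- new_ppm(8)
  for (s in c(1L, 2L, 3L)) observe_symbol(m, s)
  clear_ppm(m)
  expect_equal(predictive_distribution(m), rep(1 / 8, 8))
  expect_equal(information_content(predictive_distribution(m), 5L), log2(8))
  clear_ppm(m)                                   # idempotent
  expect_equal(symbol_counts(m), integer(8))
})

test_that("permuting alphabet labels permutes predictions identically", {
  set.seed(3)
  perm <- sample(1:4)
  hist <- sample.int(4, 30, replace = TRUE)
  ctx <- sample.int(4, 3, replace = TRUE)
  m1 <- new_ppm(4); m2 <- new_ppm(4)
  for (s in hist) observe_symbol(m1, s)
  for (s in perm[hist]) observe_symbol(m2, s)
  d1 <- predictive_distribution(m1, ctx)
  d2 <- predictive_distribution(m2, perm[ctx])
  expect_equal(d2[perm], d1, tolerance = 1e-12)
})

test_that("begin_sequence clears context but keeps learned counts", {
  m <- new_ppm(4, order_bound = 3)
  for (s in c(1L, 2L, 3L)) observe_symbol(m, s)
  begin_sequence(m)
  expect_equal(length(ppm_history(m)), 0L)
  expect_equal(sum(symbol_counts(m)), 3L)
})

test_that("ic traces export to csv", {
  m <- new_ppm(4)
  tr <- process_trial(m, c(1L, 2L, 3L))
  path <- tempfile(fileext = ".csv")
  write_ic_trace(tr, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 3)
  expect_equal(back$ic_bits, tr$ic_bits)
})
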