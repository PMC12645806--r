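test_that("frequency pool is log-spaced between its endpoints", {
  pool <- make_frequency_pool(20, 222, 2000)
  expect_length(pool, 20)
  expect_equal(pool[1], 222)
  expect_equal(pool[20], 2000)
  ratios <- pool[-1] / pool[-20]
  expect_equal(ratios, rep((2000 / 222)^(1 / 19), 19), tolerance = 1e-12)
  expect_equal(make_frequency_pool(2, 100, 400), c(100, 400))
  expect_error(make_frequency_pool(20, -1, 2000), "f_min")
  expect_error(make_frequency_pool(20, 2000, 222), "f_min")
  expect_error(make_frequency_pool(1, 100, 200), "n")
})

test_that("regular trials cycle a fixed set of tones", {
  pool <- make_frequency_pool()
  tr <- generate_reg_trial(pool, 10, 70, seed = 1)
  expect_length(tr$tones, 70)
  expect_equal(length(unique(tr$tones)), 10)
  expect_equal(tr$tones[1:60], tr$tones[11:70])   # period 10
  expect_equal(length(tr$tones) * tr$tone_duration_ms, 3500)
  const <- generate_reg_trial(pool, 1, 10, seed = 2)
  expect_equal(length(unique(const$tones)), 1)
  draws <- vapply(1:50, function(s)
    paste(generate_reg_trial(pool, seed = s)$tones, collapse = ","),
    character(1))
  expect_gt(length(unique(draws)), 45)
  expect_error(generate_reg_trial(pool, cycle_length = 21), "cycle_length")
})

test_that("pattern-transition trials use disjoint tone sets", {
  pool <- make_frequency_pool()
  tr <- generate_regxregy_trial(pool, seed = 4)
  x <- unique(tr$tones[1:40])
  y <- unique(tr$tones[41:70])
  expect_length(intersect(x, y), 0)
  expect_setequal(union(x, y), seq_along(pool))
  expect_equal(tr$tones[1:30], tr$tones[11:40])     # REGx cycles for 2 s
  expect_equal(tr$tones[41:60], tr$tones[51:70])    # REGy cycles for 1.5 s
  expect_false(tr$tones[41] %in% tr$tones[1:40])    # tone 41 novel
  expect_error(generate_regxregy_trial(pool[1:15]), "pool size")
})

test_that("interrupted trials resume the same pattern at cycle start", {
  pool <- make_frequency_pool()
  tr0 <- generate_int_trial(pool, 0, seed = 5)
  expect_equal(tr0$tones[1:60], tr0$tones[11:70])
  expect_length(tr0$interruption_span, 0)
  for (n_int in c(1, 3, 5)) {
    tr <- generate_int_trial(pool, n_int, seed = 5 + n_int)
    expect_length(tr$tones, 70)
    expect_equal(tr$interruption_span, 41:(40 + n_int))
    cyc <- tr$tones[1:10]
    expect_equal(tr$tones[1:40], rep(cyc, 4))       # 4 cycles then interruption
    resumed <- tr$tones[(41 + n_int):70]
    expect_equal(resumed, rep_len(cyc, 30 - n_int)) # restart at position 1
    expect_equal(length(resumed) * 50, 1500 - 50 * n_int)
    expect_length(intersect(tr$tones[tr$interruption_span], cyc), 0)
  }
  expect_error(generate_int_trial(pool, 2), "n_int")
  tr2 <- generate_int_trial(pool, 2, strict = FALSE, seed = 1)
  expect_equal(tr2$interruption_span, 41:42)
})

test_that("interruption tones never collide with the REG set", {
  pool <- make_frequency_pool()
  ok <- vapply(1:10000, function(s) {
    tr <- generate_int_trial(pool, sample(c(1, 3, 5), 1), seed = s)
    length(intersect(tr$tones[tr$interruption_span],
                     tr$tones[1:40])) == 0
  }, logical(1))
  expect_true(all(ok))
})

test_that("post-interruption cycle onsets land at the phantom positions", {
  for (n_int in c(1, 3, 5)) {
    onsets <- 41 + n_int + 10 * (1:2)
    expect_equal(onsets, switch(as.character(n_int),
                                "1" = c(52, 62), "3" = c(54, 64),
                                "5" = c(56, 66)))
    tr <- generate_int_trial(make_frequency_pool(), n_int, seed = n_int)
    expect_equal(tr$tones[onsets], rep(tr$tones[1], 2))
  }
})

test_that("waveform synthesis produces ramped gap-free tone pips", {
  pool <- make_frequency_pool()
  tr <- generate_reg_trial(pool, seed = 6)
  w <- synthesize_waveform(tr, sample_rate = 44100)
  expect_length(w, 154350)                            # 3.5 s at 44.1 kHz
  n_pip <- 44100 * 50 / 1000
  starts <- seq(1, length(w), by = n_pip)
  expect_true(all(abs(w[starts]) < 1e-12))            # raised cosine onset
  freqs <- trial_frequencies(tr)
  for (i in c(1, 35, 70)) {
    seg <- w[((i - 1) * n_pip + 1):(i * n_pip)]
    spec <- Mod(fft(seg))[1:(n_pip / 2)]
    f_peak <- (which.max(spec) - 1) * 44100 / n_pip
    expect_lt(abs(f_peak - freqs[i]), 44100 / n_pip + 1e-9)
  }
  expect_error(synthesize_waveform(tr, sample_rate = 3000), "Nyquist")
})

test_that("sessions are randomized, jittered, and reproducible", {
  ses <- build_session(exp2_config(5), seed = 10)
  expect_length(ses$trials, 20)
  expect_equal(as.vector(table(session_conditions(ses))), rep(5, 4))
  expect_true(all(ses$isi_ms >= 2500 & ses$isi_ms <= 3000))
  ses2 <- build_session(exp2_config(5), seed = 10)
  expect_identical(lapply(ses$trials, `[[`, "tones"),
                   lapply(ses2$trials, `[[`, "tones"))
  expect_identical(ses$isi_ms, ses2$isi_ms)
  ses3 <- build_session(exp2_config(5), seed = 11)
  expect_false(identical(lapply(ses$trials, `[[`, "tones"),
                         lapply(ses3$trials, `[[`, "tones")))
  # canonical designs
  expect_equal(sum(exp1_config()), 240)
  expect_equal(sum(exp2_config()), 600)
  expect_equal(unname(exp2_config()["INT3"]), 150)
  expect_error(build_session(c(REG = 0)), "counts")
})

test_that("session export writes csv rows and json metadata", {
  ses <- build_session(c(REG = 2, INT1 = 2), seed = 3)
  dir <- tempfile()
  paths <- write_session(ses, dir)
  rows <- read.csv(paths["csv"])
  expect_equal(nrow(rows), 4 * 70)
  expect_setequal(unique(rows$condition), c("REG", "INT1"))
  expect_equal(max(rows$onset_ms), 69 * 50)
  meta <- jsonlite::read_json(paths["json"], simplifyVector = TRUE)
  expect_equal(meta$seed, 3)
  expect_length(meta$isi_ms, 4)
})

test_that("wav export writes a valid 16-bit RIFF header", {
  w <- sin(2 * pi * 440 * seq(0, 0.05, by = 1 / 8000))
  path <- tempfile(fileext = ".wav")
  write_trial_wav(w, path, sample_rate = 8000)
  con <- file(path, "rb")
  on.exit(close(con))
  expect_equal(readChar(con, 4), "RIFF")
  invisible(readBin(con, integer(), 1, size = 4))
  expect_equal(readChar(con, 8), "WAVEfmt ")
  expect_equal(readBin(con, integer(), 1, size = 4, endian = "little"), 16L)
  fmt <- readBin(con, integer(), 2, size = 2, endian = "little")
  expect_equal(fmt, c(1L, 1L))                      # PCM, mono
  rates <- readBin(con, integer(), 2, size = 4, endian = "little")
  expect_equal(rates, c(8000L, 16000L))             # sample and byte rate
  block <- readBin(con, integer(), 2, size = 2, endian = "little")
  expect_equal(block, c(2L, 16L))                   # block align, bits
  expect_equal(readChar(con, 4), "data")
  n_bytes <- readBin(con, integer(), 1, size = 4, endian = "little")
  expect_equal(n_bytes, 2L * length(w))
})
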