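make_rec <- function(epochs, fs = 256, start = 0) {
  n <- dim(epochs)[3]
  structure(list(epochs = epochs, fs = fs,
                 times = start + (seq_len(n) - 1) / fs,
                 conditions = rep("A", dim(epochs)[1])),
            class = "subject_recording")
}

# one trial whose channels are the rows of `m`
rec_from_channels <- function(m, fs = 256, start = 0) {
  ep <- array(0, c(1, nrow(m), ncol(m)))
  ep[1, , ] <- m
  make_rec(ep, fs, start)
}

test_that("zero-phase Butterworth filtering matches its analytic response", {
  fs <- 256
  n <- 1024
  t <- (seq_len(n) - 1) / fs
  rec <- rec_from_channels(matrix(1, 2, n), fs)
  lp <- filter_spec("lowpass", 30, 5)
  out <- filter_epochs(rec, lp)
  expect_equal(out$epochs[1, 1, 100:900], rep(1, 801), tolerance = 1e-6)
  # 60 Hz sinusoid attenuated by the squared single-pass magnitude response
  x <- sin(2 * pi * 60 * t)
  rec2 <- rec_from_channels(rbind(x, x), fs)
  out2 <- filter_epochs(rec2, lp)
  bf <- signal::butter(5, 30 / (fs / 2), "low")
  z <- exp(1i * 2 * pi * 60 / fs)
  H <- Mod(sum(bf$b * z^(-(0:5))) / sum(bf$a * z^(-(0:5))))
  emp <- max(abs(out2$epochs[1, 1, 300:700]))
  expect_lt(abs(emp / H^2 - 1), 0.01)
  # symmetric pulse keeps its peak sample (zero phase)
  pulse <- exp(-(t - 2)^2 / (2 * 0.05^2))
  rec3 <- rec_from_channels(matrix(pulse, 1), fs)
  out3 <- filter_epochs(rec3, lp)
  expect_equal(which.max(out3$epochs[1, 1, ]), which.max(pulse))
  expect_error(filter_epochs(rec, filter_spec("lowpass", 200, 5)), "Nyquist")
  expect_error(filter_spec("lowpass", 30, 0), "order")
})

test_that("matrix filtering matches signal::filtfilt column by column", {
  set.seed(7)
  x <- matrix(rnorm(512 * 4), 512, 4)
  bf <- signal::butter(4, 0.1, "high")
  mine <- regmem:::zero_phase_matrix(bf$b, bf$a, x)
  ref <- vapply(1:4, function(j) signal::filtfilt(bf, x[, j]), numeric(512))
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("linear detrending removes exactly the fitted line", {
  fs <- 128
  t <- (seq_len(256) - 1) / fs
  line <- 2 + 3 * t
  sine <- sin(2 * pi * 7 * t)
  rec <- rec_from_channels(rbind(line, line + sine), fs)
  out <- detrend_linear(rec)
  expect_equal(max(abs(out$epochs[1, 1, ])), 0, tolerance = 1e-9)
  # line + sinusoid: sinusoid recovered up to its own tiny linear component
  resid <- out$epochs[1, 2, ]
  x <- cbind(1, seq_len(256))
  sine_detrended <- sine - x %*% solve(crossprod(x), crossprod(x, sine))
  expect_equal(resid, as.numeric(sine_detrended), tolerance = 1e-9)
  # idempotent
  out2 <- detrend_linear(out)
  expect_equal(out2$epochs, out$epochs, tolerance = 1e-9)
})

test_that("downsampling preserves in-band content", {
  fs <- 2048
  n <- 2 * fs
  t <- (seq_len(n) - 1) / fs
  rec <- rec_from_channels(rbind(rep(1, n), sin(2 * pi * 10 * t)), fs)
  out <- resample_recording(rec, 256)
  expect_equal(dim(out$epochs)[3], n / 8)
  expect_equal(out$fs, 256)
  expect_equal(out$epochs[1, 1, 20:400], rep(1, 381), tolerance = 1e-4)
  amp <- max(abs(out$epochs[1, 2, 100:400]))
  expect_lt(abs(amp - 1), 0.01)
  expect_error(resample_recording(rec, 300), "unsupported ratio")
})

test_that("baseline correction zeroes the window mean and is idempotent", {
  set.seed(8)
  rec <- make_rec(array(rnorm(4 * 3 * 256) + 5, c(4, 3, 256)), 256, start = -0.5)
  out <- baseline_correct(rec, c(-0.5, 0))
  idx <- which(out$times <= 0)
  for (i in 1:4) for (j in 1:3)
    expect_equal(mean(out$epochs[i, j, idx]), 0, tolerance = 1e-12)
  out2 <- baseline_correct(out, c(-0.5, 0))
  expect_equal(out2$epochs, out$epochs, tolerance = 1e-12)
  const <- make_rec(array(3, c(1, 1, 64)), 256, start = -0.25)
  expect_true(all(baseline_correct(const, c(-0.25, 0))$epochs == 0))
  expect_error(baseline_correct(rec, c(5, 6)), "window")
})

test_that("DSS recovers a planted reproducible source", {
  set.seed(9)
  sust <- list(INT0 = sustained_params())
  rec <- simulate_subject(rep("INT0", 40), sust, noise_spec(0, 1, 0, 1),
                          n_channels = 16, n1_amplitude = 0,
                          mmn_amplitude = 0, seed = 10)
  d <- dss(rec, window = c(0, 4), n_keep = 1)
  comp1 <- colMeans(dss_component(d, rec, 1))
  expect_gt(abs(cor(comp1, rec$ground_truth$envelopes[["INT0"]])), 0.9)
  expect_true(all(diff(d$scores) <= 1e-9))         # scores non-increasing
  # identical trials: kept reconstruction equals the input
  rec2 <- simulate_subject(rep("INT0", 4), sust, noise_spec(0, 1, 0, 0),
                           n_channels = 8, seed = 11)
  d2 <- dss(rec2, window = c(0, 4), n_keep = 3)
  rel <- max(abs(d2$recording$epochs - rec2$epochs)) / max(abs(rec2$epochs))
  expect_lt(rel, 1e-6)
  expect_error(dss(make_rec(array(1, c(1, 2, 64)), 256), c(0, 0.1)),
               "2 trials")
})

test_that("channel selection finds the planted dipole", {
  set.seed(12)
  topo <- c(3, -2.5, 2, -1.5, 1, -0.8, 0.5, -0.4, 0.2, -0.1, 0.05, -0.02)
  n1 <- make_transient(0.1, 60, -1, 256, 0, 1)
  ga <- outer(topo, n1)
  times <- seq(0, 1 - 1 / 256, by = 1 / 256)
  sel <- select_channels(ga, times, "n1", c(0.05, 0.2), n_each = 5)
  expect_length(sel, 10)
  expect_setequal(as.integer(sel), order(-abs(topo))[1:10])
  pos <- topo[sel] > 0
  expect_equal(sum(pos), 5)                        # 5 positive + 5 negative
  # mmn rule: most negative mean in window
  # the planted transient is negative, so the most negative mean activation
  # belongs to the channels with the largest positive weights
  sel2 <- select_channels(ga, times, "mmn", c(0.05, 0.2), n_each = 5)
  expect_setequal(as.integer(sel2), order(-topo)[1:10])
  # exactly 10 channels returns all 10
  sel3 <- select_channels(ga[1:10, ], times, "n1", c(0.05, 0.2))
  expect_setequal(as.integer(sel3), 1:10)
  # tie at the selection rank: lower channel index wins
  topo_tie <- c(5, 4, 3, 2, 1, 1, 1, -5, -4, -3, -2, -1)
  ga_tie <- outer(topo_tie, -n1)                  # positive deflection
  sel4 <- select_channels(ga_tie, times, "n1", c(0.05, 0.2))
  expect_true(5 %in% sel4 && !(6 %in% sel4) && !(7 %in% sel4))
  expect_error(select_channels(ga[1:4, ], times, "n1", c(0.05, 0.2)),
               "fewer channels")
})

test_that("RMS across channels is polarity-free instantaneous power", {
  avg <- matrix(2, 4, 10)
  expect_equal(rms_over_channels(avg, 1:4), rep(2, 10))
  avg2 <- rbind(sin(1:10), -sin(1:10))
  expect_equal(rms_over_channels(avg2, 1:2), abs(sin(1:10)))
  expect_equal(rms_over_channels(avg2, 1), abs(sin(1:10)))
  expect_error(rms_over_channels(avg, integer(0)), "empty")
})

test_that("phantom epoching cuts baselined segments around model peaks", {
  fs <- 256
  times <- epoch_time(fs)
  sig <- make_transient(2.55, 50, 1, fs) + make_transient(3.05, 50, 1, fs)
  ga <- outer(rep(1, 4), sig)
  peaks <- tone_onset_s(c(52, 62))                 # 2.55 s and 3.05 s
  expect_equal(peaks, c(2.55, 3.05))
  pe <- phantom_epoching(ga, times, peaks, selection = 1:4)
  expect_equal(ncol(pe$epochs), round(0.4 * fs) + round(0.2 * fs))
  expect_lt(abs(ncol(pe$epochs) / fs - 0.6), 1.5 / fs)  # 600 ms epochs
  n_base <- round(0.2 * fs)
  for (i in 1:2)
    expect_equal(mean(pe$epochs[i, seq_len(n_base)]), 0, tolerance = 1e-12)
  # the peak sits at lag zero of the segment
  expect_equal(pe$times[which.max(pe$mean)], 0, tolerance = 1e-9)
  expect_error(phantom_epoching(ga, times, 4.95, 1:4), "out of range")
})

test_that("outlier epochs are rejected by the MAD rule", {
  set.seed(13)
  ep <- array(rnorm(20 * 4 * 128), c(20, 4, 128))
  ep[3, 2, ] <- ep[3, 2, ] * 60
  rec <- make_rec(ep, 256)
  out <- reject_outlier_epochs(rec, k = 6)
  expect_equal(dim(out$epochs)[1], 19)
})
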