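# Shared fixture builders for the statistics and pipeline tests.

# subjects x timepoints matrix of smooth (lowpassed) zero-mean noise
smooth_noise_series <- function(n_subjects, n_samples, sd0 = 0.1, fs = 256,
                                cutoff = 20) {
  bf <- signal::butter(4, cutoff / (fs / 2), "low")
  x <- regmem:::zero_phase_matrix(bf$b, bf$a,
                                  matrix(stats::rnorm(n_samples * n_subjects),
                                         n_samples, n_subjects))
  t(x / rep(apply(x, 2, stats::sd), each = n_samples) * sd0)
}

# difference series with a deficit -A ramping back to zero at sample t_end
planted_deficit_series <- function(n_subjects, n_samples, t_end, ramp = 26,
                                   amp = 1, sd0 = 0.1, fs = 256) {
  d <- numeric(n_samples)
  d[1:(t_end - ramp)] <- -amp
  d[(t_end - ramp):t_end] <- -amp * seq(1, 0, length.out = ramp + 1)
  sweep(smooth_noise_series(n_subjects, n_samples, sd0, fs), 2, -d)
}

# simulate one cohort, preprocess it, and return prepped subjects
simulate_prepped_cohort <- function(n_subjects, conds, sust, noise,
                                    n_channels = 10, fs = 256, seed = 1,
                                    epoch_end_s = 2.5, detrend = FALSE) {
  lapply(seq_len(n_subjects), function(s) {
    rec <- simulate_subject(conds, sust, noise, n_channels = n_channels,
                            fs = fs, seed = seed * 100 + s,
                            epoch_start_s = -0.5, epoch_end_s = epoch_end_s)
    preprocess_subject(rec, dss_window = c(0, epoch_end_s),
                       baseline_window = c(-0.4, 0), detrend = detrend)
  })
}

# one full null-pipeline simulation: two identically distributed conditions,
# main comparison vs the split-half cluster threshold from the control
null_pipeline_sim <- function(seed, n_subjects = 8, n_trials = 10,
                              n_splits = 50, fs = 256) {
  set.seed(seed)
  sust <- list(A = sustained_params(), B = sustained_params())
  conds <- rep(c("A", "B"), each = n_trials)
  preps <- simulate_prepped_cohort(n_subjects, conds, sust, noise_spec(),
                                   seed = seed)
  diffs <- cohort_difference(preps, "B", "A")
  bt <- bootstrap_sign_test(diffs, n_iter = 200, alpha = 0.01)
  obs <- regmem:::max_cluster_stat(find_clusters(bt, fs))
  control <- lapply(preps, subject_trial_epochs, condition = "A")
  nd <- null_cluster_distribution(control, n_splits = n_splits,
                                  cluster_alpha = 0.05, n_iter = 100,
                                  fs = fs, statistic = rms_statistic)
  c(obs = obs, thr = nd$threshold)
}

# planted persistent post-interruption deficit, as in the interrupted-
# regularity design: detected when the main cluster exceeds the threshold
power_pipeline_sim <- function(seed, n_subjects = 8, n_trials = 16,
                               offset = -0.4, fs = 256) {
  set.seed(seed)
  sust <- list(INT0 = sustained_params(),
               INT5 = sustained_params(post_offset = offset))
  conds <- rep(c("INT0", "INT5"), each = n_trials)
  preps <- simulate_prepped_cohort(n_subjects, conds, sust,
                                   noise_spec(0.5, 1, 0.3, 0.3),
                                   seed = seed, epoch_end_s = 3.5)
  diffs <- cohort_difference(preps, "INT5", "INT0",
                             rms_baseline = c(1.5, 2))
  bt <- bootstrap_sign_test(diffs, n_iter = 200, alpha = 0.01)
  obs <- regmem:::max_cluster_stat(find_clusters(bt, fs))
  control <- lapply(preps, subject_trial_epochs, condition = "INT0")
  nd <- null_cluster_distribution(control, n_splits = 50,
                                  cluster_alpha = 0.05, n_iter = 100,
                                  fs = fs, statistic = rms_statistic)
  c(obs = obs, thr = nd$threshold)
}
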