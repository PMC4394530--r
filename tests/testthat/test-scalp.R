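test_that("peak detection finds constructed extrema with exact latencies", {
  times <- seq(-100, 400, by = 1)
  w <- gauss_bump(times, 100, -3) + gauss_bump(times, 180, 5)
  ev <- make_evoked(list(w), times, intensities = 75)
  pk <- detect_n1_p2_peaks(ev)
  expect_equal(pk$n1_amplitude, -3, tolerance = 1e-9)
  expect_equal(pk$n1_latency, 100)
  expect_equal(pk$p2_amplitude, 5, tolerance = 1e-9)
  expect_equal(pk$p2_latency, 180)
  expect_equal(pk$peak_to_peak, 8, tolerance = 1e-9)
  expect_false(pk$flat)
})

test_that("flat waveforms flag and degenerate extrema are zero", {
  times <- seq(-100, 400, by = 2)
  ev <- make_evoked(list(rep(0, length(times))), times, intensities = 75)
  pk <- detect_n1_p2_peaks(ev)
  expect_true(pk$flat)
  expect_equal(pk$n1_amplitude, 0)
  expect_equal(pk$p2_amplitude, 0)
})

test_that("time-shifted waveforms shift latencies, not amplitudes", {
  times <- seq(-100, 400, by = 1)
  w <- gauss_bump(times, 100, -3) + gauss_bump(times, 180, 5)
  w5 <- gauss_bump(times, 105, -3) + gauss_bump(times, 185, 5)
  p0 <- detect_n1_p2_peaks(make_evoked(list(w), times, intensities = 75))
  p5 <- detect_n1_p2_peaks(make_evoked(list(w5), times, intensities = 75))
  expect_equal(p5$n1_latency - p0$n1_latency, 5)
  expect_equal(p5$p2_latency - p0$p2_latency, 5)
  expect_equal(p5$n1_amplitude, p0$n1_amplitude, tolerance = 1e-9)
  expect_equal(p5$p2_amplitude, p0$p2_amplitude, tolerance = 1e-9)
})

test_that("windows outside the epoch are rejected", {
  times <- seq(-100, 400, by = 2)
  ev <- make_evoked(list(rep(0, length(times))), times, intensities = 75)
  expect_error(detect_n1_p2_peaks(ev, p2_window = c(130, 500)), "outside")
  expect_error(detect_n1_p2_peaks(ev, channel = "Fz"), "Fz")
})

test_that("noiseless simulated subjects recover true slopes to machine precision", {
  run <- noiseless_scalp_run(slope_n1 = -0.4, slope_p2 = 0.9,
                             n_events = 25, srate = 500)
  res <- compute_scalp_ldaep(run$evoked)
  expect_equal(unname(res$slopes), c(-0.4, 0.9, 1.3), tolerance = 1e-9)
  expect_s3_class(res$fits$n1p2, "ldaep")
  expect_output(print(res), "Scalp LDAEP")
})

test_that("the N1/P2 slope decomposition identity holds on arbitrary peak data", {
  set.seed(88)
  for (i in 1:100) {
    n1 <- rnorm(5, -5, 2)
    p2 <- rnorm(5, 6, 2)
    f_n1 <- fit_ldaep_slope(n1)
    f_p2 <- fit_ldaep_slope(p2)
    f_pp <- fit_ldaep_slope(p2 - n1)
    expect_equal(f_pp[["slope"]], f_p2[["slope"]] - f_n1[["slope"]],
                 tolerance = 1e-9)
  }
})

test_that("printed group means obey the decomposition identity to rounding", {
  s <- reference_cohort_tables()$summaries
  combos <- unique(s[s$variable %in% c("pre_n1", "post_n1"),
                     c("stratification", "group")])
  for (phase in c("pre", "post")) {
    for (i in seq_len(nrow(combos))) {
      g <- function(v) reference_group(s, combos$stratification[i],
                                       paste0(phase, "_", v),
                                       combos$group[i])$mean
      expect_equal(g("n1p2"), g("p2") - g("n1"), tolerance = 0.016)
    }
  }
})

test_that("estimated slopes track ground truth across a noisy cohort", {
  set.seed(19)
  n_sub <- 12
  true_n1 <- rnorm(n_sub, -0.4, 0.3)
  true_p2 <- rnorm(n_sub, 0.85, 0.4)
  est <- matrix(NA_real_, n_sub, 2)
  for (i in seq_len(n_sub)) {
    seq <- generate_stimulus_sequence(40, seed = 100 + i)
    truth <- ground_truth(slope_n1 = true_n1[i], slope_p2 = true_p2[i],
                          amp_n1_75 = -14, amp_p2_75 = 24,
                          noise_sd = 4, blink_rate = 10,
                          artifact_epoch_fraction = 0.03)
    raw <- simulate_subject_eeg(seq, truth, seed = 200 + i, srate = 250)
    cfg <- pipeline_config(srate = 250, n_events = 40)
    ev <- suppressWarnings(preprocess_recording(raw, cfg))
    est[i, ] <- compute_scalp_ldaep(ev)$slopes[c("n1", "p2")]
  }
  expect_gt(cor(true_p2 - true_n1, est[, 2] - est[, 1]), 0.9)
})
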