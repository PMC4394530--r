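test_that("simulation is deterministic and validates its montage", {
  seq <- generate_stimulus_sequence(8, seed = 2)
  truth <- ground_truth(noise_sd = 2, blink_rate = 10,
                        artifact_epoch_fraction = 0.1)
  a <- simulate_subject_eeg(seq, truth, seed = 5, srate = 250)
  b <- simulate_subject_eeg(seq, truth, seed = 5, srate = 250)
  expect_identical(a$data, b$data)
  c <- simulate_subject_eeg(seq, truth, seed = 6, srate = 250)
  expect_false(identical(a$data, c$data))
  mont <- standard_montage()
  expect_error(
    simulate_subject_eeg(seq, truth, mont[mont$label != "Cz", ], seed = 1),
    "Cz")
})

test_that("ground truth validates and derives the N1/P2 slope", {
  gt <- ground_truth(slope_n1 = -0.4, slope_p2 = 0.9)
  expect_equal(gt$slope_n1p2, 1.3)
  expect_error(ground_truth(noise_sd = -1))
  expect_error(ground_truth(artifact_epoch_fraction = 1.2))
})

test_that("noiseless averages reproduce the injected vertex template exactly", {
  run <- noiseless_scalp_run(n_events = 10, srate = 250, seed = 21)
  ev <- run$evoked
  cz <- match("Cz", ev$channels)
  for (k in seq_along(ev$intensities)) {
    di <- ev$intensities[k] - 75
    expected <- gauss_bump(ev$times, 100, run$truth$amp_n1_75 +
                             run$truth$slope_n1 * di) +
      gauss_bump(ev$times, 180, run$truth$amp_p2_75 +
                   run$truth$slope_p2 * di)
    expect_equal(ev$data[[k]][cz, ], expected, tolerance = 1e-9)
  }
})

test_that("the configured artifact fraction drives the downstream rejection rate", {
  seq <- generate_stimulus_sequence(250, seed = 13)
  truth <- ground_truth(slope_n1 = -0.4, slope_p2 = 0.9,
                        noise_sd = 3, blink_rate = 10,
                        artifact_epoch_fraction = 0.04)
  raw <- simulate_subject_eeg(seq, truth, seed = 14, srate = 250)
  raw <- set_reference(raw, "linked_mastoid")
  ep <- suppressWarnings(reject_artifact_epochs(extract_epochs(raw)))
  rate <- mean(ep$rejected)
  # 10 injected artifact epochs out of 250; allow binomial-scale slack
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.06)
})

test_that("cohort demographics hit configured counts exactly", {
  ch <- generate_cohort(cohort_spec(n_subjects = 41, seed = 3))
  t <- ch$table
  expect_equal(sum(t$sex == "male"), 7L)
  expect_equal(sum(t$sex == "female"), 34L)
  expect_equal(sum(t$episode == "first"), 15L)
  expect_equal(sum(t$smoker), 10L)
  expect_equal(sum(t$hypnotic), 21L)
  expect_equal(sum(t$ldaep_group == "low"), 20L)
  expect_true(all(t$bdi_post >= 0 & t$bdi_post == round(t$bdi_post)))
  expect_true(all(t$bdi_change_pct_drawn >= -50 &
                    t$bdi_change_pct_drawn <= 100))
  # deterministic
  ch2 <- generate_cohort(cohort_spec(n_subjects = 41, seed = 3))
  expect_identical(ch$table, ch2$table)
  expect_error(generate_cohort(cohort_spec(n_subjects = 0)), "positive")
})

test_that("zero coupling SD makes response purely group-determined", {
  sp <- cohort_spec(n_subjects = 40, seed = 9,
                    reduction = list(low = c(37.2, 0), high = c(70.2, 0)))
  ch <- generate_cohort(sp)
  st <- stratify_cohort(ch$table)
  # stratification here uses the drawn slopes; groups match the generator's
  expect_true(all(st$responder[st$ldaep_group == "high"]))
  expect_true(!any(st$responder[st$ldaep_group == "low"]))
})

test_that("large cohorts converge to configured moments (3 SE)", {
  n <- 4000
  ch <- generate_cohort(cohort_spec(n_subjects = n, seed = 17))
  t <- ch$table
  for (g in c("low", "high")) {
    sub <- t[t$ldaep_group == g, ]
    m <- nrow(sub)
    cfg_red <- ch$spec$reduction[[g]]
    se_mean <- cfg_red[2] / sqrt(m)
    expect_lt(abs(mean(sub$bdi_change_pct_drawn) - cfg_red[1]), 3 * se_mean)
    se_sd <- cfg_red[2] / sqrt(2 * m)
    expect_lt(abs(sd(sub$bdi_change_pct_drawn) - cfg_red[2]), 3 * se_sd)
    for (comp in c("n1", "p2", "n1p2")) {
      cfg <- ch$spec$ldaep_groups[[g]][[comp]]
      vals <- sub[[paste0("ldaep_", comp)]]
      expect_lt(abs(mean(vals) - cfg[1]), 3 * cfg[2] / sqrt(m))
      expect_lt(abs(sd(vals) - cfg[2]), 3 * cfg[2] / sqrt(2 * m))
    }
  }
})
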