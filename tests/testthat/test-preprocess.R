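make_raw <- function(x, srate = 1000) {
  mont <- standard_montage()
  data <- matrix(rep(x, each = nrow(mont)), nrow(mont), byrow = FALSE)
  eeg_recording(data, srate, mont,
                data.frame(onset_s = min(2, length(x) / srate / 2),
                           intensity_db = 75))
}

test_that("band-pass filtering passes 10 Hz, removes DC and 50 Hz, zero phase", {
  srate <- 1000
  t <- (0:5999) / srate
  trim <- 1001:5000
  dc <- bandpass_filter(make_raw(rep(1, 6000)))
  expect_lt(max(abs(dc$data[1, trim])), 0.01)
  s10 <- bandpass_filter(make_raw(sin(2 * pi * 10 * t)))
  g10 <- max(abs(s10$data[1, trim]))
  expect_true(g10 > 0.95 && g10 < 1.05)
  s50 <- bandpass_filter(make_raw(sin(2 * pi * 50 * t)))
  expect_lt(max(abs(s50$data[1, trim])), 0.1)
  # zero phase: symmetric bump latency preserved
  bump <- exp(-(t - 3)^2 / (2 * 0.05^2))
  fb <- bandpass_filter(make_raw(bump))
  expect_lte(abs(which.max(fb$data[1, ]) - which.max(bump)), 1)
  # event markers untouched
  expect_identical(fb$events, make_raw(bump)$events)
})

test_that("filter band outside Nyquist errors", {
  r <- make_raw(rep(0, 1000))
  expect_error(bandpass_filter(r, 1, 600), "Nyquist")
  expect_error(bandpass_filter(r, 0, 30), "invalid")
})

test_that("epoching counts samples and baseline-corrects", {
  r <- noise_recording(n_events = 10, srate = 1000)
  ep <- extract_epochs(r, c(-100, 400), c(-100, 0))
  expect_equal(dim(ep$epochs)[1], 10L)
  expect_equal(dim(ep$epochs)[3], 501L)  # inclusive endpoints at 1000 Hz
  bsel <- ep$times >= -100 & ep$times <= 0
  expect_equal(max(abs(rowMeans(ep$epochs[3, , bsel]))), 0, tolerance = 1e-10)
})

test_that("events too close to the edge are flagged, not dropped", {
  mont <- standard_montage()
  data <- matrix(0, nrow(mont), 1000)
  r <- eeg_recording(data, 1000, mont,
                     data.frame(onset_s = c(0.05, 0.5, 0.95),
                                intensity_db = c(55, 65, 75)))
  ep <- extract_epochs(r)
  expect_equal(ep$rejected, c(TRUE, FALSE, TRUE))
  expect_equal(ep$reject_reason[c(1, 3)], c("edge", "edge"))
  expect_error(extract_epochs(r, window = c(0, 200)), "230")
})

test_that("ocular correction is identity for flat EOG and removes known blinks", {
  r <- noise_recording(n_events = 5, srate = 250, noise_sd = 0, seed = 2)
  out <- remove_ocular_artifacts(r)
  expect_equal(out$data, r$data)
  expect_identical(out$events, r$events)

  # blink with known propagation 0.3 to Cz
  seq <- generate_stimulus_sequence(10, seed = 3)
  truth <- ground_truth(amp_n1_75 = 0, amp_p2_75 = 0, slope_n1 = 0,
                        slope_p2 = 0, noise_sd = 0.3, blink_rate = 30,
                        artifact_epoch_fraction = 0)
  raw <- simulate_subject_eeg(seq, truth, seed = 8, srate = 250,
                              blink_propagation = c(Cz = 0.3))
  cz <- match("Cz", raw$channels$label)
  veog <- match("VEOGU", raw$channels$label)
  blink_samples <- abs(raw$data[veog, ]) > 50
  expect_gt(sum(blink_samples), 20)   # blinks present at this seed
  injected <- max(abs(raw$data[cz, blink_samples]))
  corr <- remove_ocular_artifacts(raw)
  residual <- max(abs(corr$data[cz, blink_samples]))
  expect_lt(residual, 0.05 * injected)
})

test_that("amplitude rejection follows the threshold definition", {
  r <- noise_recording(n_events = 10, srate = 250, noise_sd = 0, seed = 4)
  on1 <- as.integer(r$events$onset_s[3] * 250) + 10
  r$data[5, on1] <- 80    # one 80 uV spike inside epoch 3
  ep <- extract_epochs(r)
  rej <- suppressWarnings(reject_artifact_epochs(ep, 70))
  expect_true(rej$rejected[3])
  expect_equal(sum(rej$rejected), 1L)
  # all epochs under threshold: nothing rejected
  r2 <- noise_recording(n_events = 10, srate = 250, noise_sd = 0, seed = 4)
  r2$data[] <- 69
  ep2 <- extract_epochs(r2)
  expect_equal(sum(reject_artifact_epochs(ep2, 70)$rejected), 0L)
  # EOG channels are exempt
  r3 <- noise_recording(n_events = 10, srate = 250, noise_sd = 0, seed = 4)
  eog <- which(r3$channels$type == "eog")[1]
  r3$data[eog, ] <- 200
  expect_equal(sum(reject_artifact_epochs(extract_epochs(r3), 70)$rejected),
               0L)
  expect_error(reject_artifact_epochs(ep, -1), "> 0")
})

test_that("rejecting every epoch of an intensity is a hard error", {
  r <- noise_recording(n_events = 5, srate = 250, noise_sd = 0, seed = 4)
  sel <- which(r$events$intensity_db == 55)
  for (i in sel) {
    r$data[4, as.integer(r$events$onset_s[i] * 250) + 20] <- 500
  }
  expect_error(suppressWarnings(
    reject_artifact_epochs(extract_epochs(r), 70)), "55")
})

test_that("averaging is the arithmetic mean over retained epochs only", {
  r <- noise_recording(n_events = 10, srate = 250, noise_sd = 2, seed = 6)
  ep <- extract_epochs(r)
  # corrupt epoch 1 (intensity 55); its content must not affect the average
  ep2 <- ep
  ep2$epochs[1, , ] <- 1e4
  ep2$rejected[1] <- TRUE
  ev <- average_by_intensity(ep2)
  ep3 <- ep
  ep3$rejected[1] <- TRUE
  ev3 <- average_by_intensity(ep3)
  expect_equal(ev$data, ev3$data)
  # two identical epochs average to themselves
  ep4 <- ep
  ep4$epochs[6, , ] <- ep4$epochs[1, , ]   # both intensity 55
  m <- average_by_intensity(ep4)
  i55 <- which(m$intensities == 55)
  expect_equal(m$data[[i55]],
               (ep4$epochs[1, , ] + ep4$epochs[6, , ]) / 2)
})

test_that("averaging noise attenuates like 1/sqrt(n)", {
  set.seed(12)
  n_ep <- 200
  noise_sd <- 5
  ep <- structure(
    list(epochs = array(rnorm(n_ep * 1 * 100, sd = noise_sd),
                        c(n_ep, 1, 100)),
         times = seq(0, 396, by = 4),
         intensity = rep(75, n_ep),
         rejected = rep(FALSE, n_ep),
         reject_reason = rep(NA_character_, n_ep),
         baseline = c(-100, 0),
         channels = data.frame(label = "Cz", type = "eeg",
                               mastoid = FALSE),
         srate = 250, reference = "none"),
    class = "epoch_set")
  ev <- average_by_intensity(ep)
  rms <- sqrt(mean(ev$data[[1]]^2))
  expect_equal(rms, noise_sd / sqrt(n_ep), tolerance = 0.25)
})

test_that("preprocessing is bit-reproducible", {
  r <- noise_recording(n_events = 6, srate = 250, noise_sd = 3, seed = 9)
  cfg <- pipeline_config(n_events = 6, srate = 250)
  a <- preprocess_recording(r, cfg)
  b <- preprocess_recording(r, cfg)
  expect_identical(a, b)
})
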