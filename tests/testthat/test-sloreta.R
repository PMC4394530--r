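hm_small <- build_head_model(n_sources = 60)

test_that("zero sensor data gives zero standardized power", {
  op <- compute_sloreta_transform(hm_small)
  act <- source_activity(op, matrix(0, 62, 3), times = c(0, 4, 8))
  expect_true(all(act$power == 0))
})

test_that("noiseless single sources are localized exactly (all grid points)", {
  op <- compute_sloreta_transform(hm_small, alpha = 0)
  for (i in seq_len(ncol(hm_small$L))) {
    act <- source_activity(op, hm_small$L[, i])
    expect_equal(which.max(act$power[, 1]), i)
  }
})

test_that("standardized power is quadratic in the data and reference-invariant", {
  op <- compute_sloreta_transform(hm_small)
  set.seed(44)
  v <- rnorm(62)
  p1 <- source_activity(op, v)$power
  p3 <- source_activity(op, 3 * v)$power
  expect_equal(p3, 9 * p1, tolerance = 1e-10)
  expect_true(all(p1 >= 0))
  p_shift <- source_activity(op, v + 12.5)$power
  expect_equal(p_shift, p1, tolerance = 1e-8)
})

test_that("forward-inverse gain cancels: scaled lead field with matching data", {
  hm2 <- hm_small
  hm2$L <- hm_small$L * 5
  set.seed(3)
  j <- rnorm(ncol(hm_small$L))
  p1 <- source_activity(compute_sloreta_transform(hm_small),
                        hm_small$L %*% j)$power
  p2 <- source_activity(compute_sloreta_transform(hm2), hm2$L %*% j)$power
  expect_equal(p1, p2, tolerance = 1e-8)
})

test_that("free-orientation standardization runs with 3x3 blocks", {
  hm <- build_head_model(n_sources = 20, orientation = "free")
  op <- compute_sloreta_transform(hm)
  expect_true(all(op$valid))
  set.seed(5)
  act <- source_activity(op, rnorm(62))
  expect_true(all(act$power >= -1e-12))
})

test_that("ROI means follow mean/linearity identities", {
  act <- structure(
    list(power = matrix(2, 10, 5), times = seq(0, 16, by = 4), alpha = 0),
    class = "source_activity")
  expect_equal(roi_mean_current_density(act, 1:4, c(0, 16)), 2)
  act$power <- matrix(rep(1:10, 5), 10, 5)
  m1 <- roi_mean_current_density(act, 1:4, c(0, 16))
  act2 <- act
  act2$power <- act$power * 2
  expect_equal(roi_mean_current_density(act2, 1:4, c(0, 16)), 2 * m1)
  # equal-sized ROIs: mean of means equals pooled mean
  ml <- roi_mean_current_density(act, 1:3, c(0, 16))
  mr <- roi_mean_current_density(act, 8:10, c(0, 16))
  expect_equal(roi_mean_current_density(act, c(1:3, 8:10), c(0, 16)),
               (ml + mr) / 2)
  expect_error(roi_mean_current_density(act, integer(0), c(0, 16)), "empty")
  expect_error(roi_mean_current_density(act, 1:2, c(900, 950)), "window")
})

make_source_evoked <- function(model, gains, side = "both") {
  # sensor data from an ROI source whose amplitude scales with intensity
  src_l <- model$roi$left[1]
  src_r <- model$roi$right[1]
  times <- seq(-100, 400, by = 4)
  on_win <- times >= 60 & times <= 240
  data <- lapply(gains, function(g) {
    v <- numeric(nrow(model$L))
    if (side %in% c("both", "left")) v <- v + g * model$L[, src_l]
    if (side %in% c("both", "right")) v <- v + g * model$L[, src_r]
    m <- matrix(0, nrow(model$L), length(times))
    m[, on_win] <- v
    m
  })
  structure(
    list(data = data, intensities = c(55, 65, 75, 85, 95),
         n_epochs_used = rep(1L, 5), rejection_rate = rep(0, 5),
         times = times, channels = model$sensors, srate = 250,
         reference = "average"),
    class = "evoked_set")
}

test_that("source LDAEP tracks injected intensity dependence", {
  ev <- make_source_evoked(hm_small, gains = 1 + 0.02 * c(-20, -10, 0, 10, 20))
  res <- compute_source_ldaep(ev, hm_small)
  expect_true(all(res$slopes$avg > 0))
  # intensity-independent source: slope ~ 0
  ev0 <- make_source_evoked(hm_small, gains = rep(1, 5))
  res0 <- compute_source_ldaep(ev0, hm_small)
  expect_lt(max(abs(res0$slopes$avg)), 1e-10)
  # left-only dependence lateralizes the slope
  evl <- make_source_evoked(hm_small, gains = 1 + 0.02 * c(-20, -10, 0, 10, 20),
                            side = "left")
  resl <- compute_source_ldaep(evl, hm_small)
  expect_true(all(resl$slopes$left > resl$slopes$right))
  # avg series is the mean of the hemisphere series
  rm <- res$roi_means
  expect_equal(rm$avg, (rm$left + rm$right) / 2)
})
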