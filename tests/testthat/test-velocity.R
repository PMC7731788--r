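test_that("track partitioning follows the remainder-merging rule", {
  expect_identical(partition_track(30, 15), list(1:15, 16:30))
  expect_identical(partition_track(17, 15), list(1:17)) # remainder of 2 merged
  expect_identical(partition_track(2, 15), list())
  expect_identical(partition_track(33, 15), list(1:15, 16:30, 31:33)) # remainder >= 3 kept
  expect_identical(partition_track(4, 15), list(1:4)) # short track, one segment
  expect_error(partition_track(10, 2))
})

test_that("noiseless linear motion is recovered exactly, any weights", {
  t <- (0:14) / 30
  x <- 3 + 2 * t
  y <- rep(7, 15)
  for (w in list(NULL, rep(1, 15), runif(15, 0.2, 1))) {
    v <- fit_segment_velocity(t, x, y, weights = w, pixel_size = 2)
    expect_equal(v$vx_um_s, 2, tolerance = 1e-12)
    expect_equal(v$vy_um_s, 0, tolerance = 1e-12)
    expect_equal(v$residual_rms_um, 0, tolerance = 1e-12)
    expect_equal(v$weight, 1) # zero residual, full confidence
  }
  s <- fit_segment_velocity(t, rep(1, 15), rep(2, 15), pixel_size = 2)
  expect_identical(c(s$vx_um_s, s$vy_um_s), c(0, 0))
})

test_that("quadratic motion matches the direct normal-equation oracle", {
  t <- (0:14) / 30
  x <- t^2
  y <- sin(t)
  w <- rep(1, 15)
  v <- fit_segment_velocity(t, x, y, weights = w, pixel_size = 2)
  ## independent direct summation of the WLS slope
  tb <- sum(w * t) / sum(w)
  slope_x <- sum(w * (t - tb) * x) / sum(w * (t - tb)^2)
  slope_y <- sum(w * (t - tb) * y) / sum(w * (t - tb)^2)
  expect_equal(v$vx_um_s, slope_x, tolerance = 1e-12)
  expect_equal(v$vy_um_s, slope_y, tolerance = 1e-12)
})

test_that("a zero-weight outlier does not change the fit", {
  set.seed(41)
  t <- (0:9) / 30
  x <- 1 + 4 * t + rnorm(10, 0, 0.05)
  y <- 2 - t + rnorm(10, 0, 0.05)
  x_out <- c(x, 500); y_out <- c(y, -300); t_out <- c(t, 10 / 30)
  w <- c(rep(1, 10), 0)
  full <- fit_segment_velocity(t_out, x_out, y_out, weights = w, pixel_size = 2)
  clean <- fit_segment_velocity(t, x, y, weights = rep(1, 10), pixel_size = 2)
  expect_equal(full$vx_um_s, clean$vx_um_s, tolerance = 1e-12)
  expect_equal(full$vy_um_s, clean$vy_um_s, tolerance = 1e-12)
  expect_equal(full$x_um, clean$x_um, tolerance = 1e-12)
})

test_that("invalid weights are rejected", {
  t <- (0:4) / 30
  expect_error(fit_segment_velocity(t, t, t, weights = rep(0, 5)), "weights")
  expect_error(fit_segment_velocity(rep(1, 5), 1:5, 1:5), "distinct frames")
})

test_that("halving the frame interval while doubling the window leaves velocity unchanged", {
  mk <- function(dt, n) data.frame(track_id = 1L, frame = 0:(n - 1),
                                   x_um = 5 + 3 * dt * (0:(n - 1)), y_um = 4, quality = 1)
  v1 <- collect_vectors(mk(1 / 30, 15), 1 / 30, 2, window_frames = 15)
  v2 <- collect_vectors(mk(1 / 60, 30), 1 / 60, 2, window_frames = 30)
  expect_equal(v1$vx_um_s, v2$vx_um_s, tolerance = 1e-10)
  expect_equal(v1$vx_um_s, 3, tolerance = 1e-10)
})

test_that("vector collection counts windows and applies the ROI filter", {
  expect_identical(nrow(collect_vectors(data.frame(track_id = integer(0), frame = integer(0),
                                                   x_um = numeric(0), y_um = numeric(0),
                                                   quality = numeric(0)), 1 / 30, 2)), 0L)
  tracks <- do.call(rbind, lapply(1:10, function(id)
    data.frame(track_id = id, frame = 0:29, x_um = 10 + id, y_um = 20, quality = 1)))
  vec <- collect_vectors(tracks, 1 / 30, 2, window_frames = 15)
  expect_identical(nrow(vec), 20L)
  ## ROI mask excluding everything drops all vectors
  roi <- matrix(FALSE, 30, 30)
  expect_identical(nrow(collect_vectors(tracks, 1 / 30, 2, window_frames = 15,
                                        roi_mask = roi)), 0L)
})

test_that("uniform flow speed is recovered from noisy tracks within 10%", {
  set.seed(42)
  ps <- 2
  tracks <- do.call(rbind, lapply(1:40, function(id) {
    n <- 30
    x0 <- runif(1, 0, 50); y0 <- runif(1, 0, 50)
    data.frame(track_id = id, frame = 0:(n - 1),
               x_um = x0 + 5 * (0:(n - 1)) / 30 + rnorm(n, 0, 0.5 * ps),
               y_um = y0 + rnorm(n, 0, 0.5 * ps), quality = 1)
  }))
  ## full-second windows: at this localization noise the half-second window
  ## inflates vector norms; the longer window averages it down
  vec <- collect_vectors(tracks, 1 / 30, ps, window_frames = 30)
  med <- median(sqrt(vec$vx_um_s^2 + vec$vy_um_s^2))
  expect_equal(med, 5, tolerance = 0.10)
})
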