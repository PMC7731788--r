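const_vectors <- function(n = 25, vx = 7, vy = 0, seed = 51) {
  set.seed(seed)
  data.frame(track_id = seq_len(n),
             x_um = runif(n, 0, 100), y_um = runif(n, 0, 100),
             vx_um_s = vx, vy_um_s = vy, t_mid_s = 0.25,
             n_points = 15L, residual_rms_um = 0, weight = 1)
}

test_that("a constant field is interpolated exactly in the noise-free limit", {
  vec <- const_vectors(vx = 7)
  kp <- list(lengthscale = 40, signal_sd = 5, noise_sd = 1e-6)
  p <- fit_gpr_component(vec, "vx", kernel_params = kp)
  ## query points inside the convex hull of the data
  q <- cbind(runif(50, 25, 75), runif(50, 25, 75))
  pred <- predict(p, q)
  expect_true(all(abs(pred$mean - 7) < 1e-6))
})

test_that("near-zero noise reproduces observed values at observation sites", {
  set.seed(52)
  vec <- const_vectors(n = 6)
  vec$vx_um_s <- rnorm(6, 0, 3)
  kp <- list(lengthscale = 30, signal_sd = 5, noise_sd = 1e-7)
  p <- fit_gpr_component(vec, "vx", kernel_params = kp)
  pred <- predict(p, cbind(vec$x_um, vec$y_um))
  expect_equal(pred$mean, vec$vx_um_s, tolerance = 1e-4)
  expect_true(all(pred$sd < 0.01))
})

test_that("a smooth sinusoidal field is recovered below the noise level", {
  set.seed(53)
  n <- 200; L <- 20
  x <- runif(n, 0, 100); y <- runif(n, 0, 100)
  truth <- function(x) sin(x / L)
  vec <- data.frame(track_id = seq_len(n), x_um = x, y_um = y,
                    vx_um_s = truth(x) + rnorm(n, 0, 0.1),
                    vy_um_s = 0, t_mid_s = 0, n_points = 15L,
                    residual_rms_um = 0, weight = 1)
  p <- fit_gpr_component(vec, "vx", seed = 2)
  gx <- seq(10, 90, by = 4); gy <- seq(10, 90, by = 8)
  q <- as.matrix(expand.grid(gx, gy))
  pred <- predict(p, q)
  rmse <- sqrt(mean((pred$mean - truth(q[, 1]))^2))
  expect_lt(rmse, 0.1)
})

test_that("posterior sd is small at data and grows towards the prior far away", {
  vec <- const_vectors(n = 30, seed = 54)
  kp <- list(lengthscale = 15, signal_sd = 4, noise_sd = 0.5)
  p <- fit_gpr_component(vec, "vx", kernel_params = kp)
  at_data <- predict(p, cbind(vec$x_um[1], vec$y_um[1]))
  far <- predict(p, cbind(1e4, 1e4))
  expect_lt(at_data$sd, far$sd)
  expect_equal(far$sd, 4, tolerance = 1e-6) # prior sd recovered far from data
})

test_that("raising observation noise never shrinks the posterior sd", {
  vec <- const_vectors(n = 20, seed = 55)
  q <- cbind(c(30, 50, 200), c(30, 50, 200))
  sds <- lapply(c(0.1, 1, 3), function(ns) {
    kp <- list(lengthscale = 20, signal_sd = 3, noise_sd = ns)
    predict(fit_gpr_component(vec, "vx", kernel_params = kp), q)$sd
  })
  expect_true(all(sds[[2]] >= sds[[1]] - 1e-9))
  expect_true(all(sds[[3]] >= sds[[2]] - 1e-9))
})

test_that("input validation rejects unusable vector sets", {
  vec <- const_vectors(n = 4)
  expect_error(fit_gpr_component(vec, "vx"), "insufficient")
  bad <- const_vectors(n = 10)
  bad$vx_um_s[3] <- NaN
  expect_error(fit_gpr_component(bad, "vx"), "finite")
})

test_that("dense prediction fills exactly the masked pixels", {
  vec <- const_vectors(n = 12, vx = 3, vy = 4, seed = 56)
  kp <- list(lengthscale = 50, signal_sd = 5, noise_sd = 1e-6)
  pvx <- fit_gpr_component(vec, "vx", kernel_params = kp)
  pvy <- fit_gpr_component(vec, "vy", kernel_params = kp)
  mask <- matrix(FALSE, 30, 30)
  mask[10:20, 10:20] <- TRUE
  fld <- predict_field(pvx, pvy, mask, pixel_size = 4)
  expect_identical(is.na(fld$vx), !mask)
  expect_equal(fld$speed[15, 15], 5, tolerance = 1e-4) # 3-4-5 inside the hull
  expect_equal(fld$speed, sqrt(fld$vx^2 + fld$vy^2))

  one <- matrix(FALSE, 30, 30); one[15, 15] <- TRUE
  f1 <- predict_field(pvx, pvy, one, pixel_size = 4)
  expect_identical(sum(!is.na(f1$vx)), 1L)
  expect_error(predict_field(pvx, pvy, matrix(FALSE, 5, 5), 4), "empty")
})

test_that("masked pixels far from any vector have larger sd than pixels at the data", {
  set.seed(57)
  vec <- const_vectors(n = 15, seed = 57)
  vec$x_um <- runif(15, 0, 40); vec$y_um <- runif(15, 0, 40) # data in one corner
  kp <- list(lengthscale = 8, signal_sd = 3, noise_sd = 0.3)
  pvx <- fit_gpr_component(vec, "vx", kernel_params = kp)
  pvy <- fit_gpr_component(vec, "vy", kernel_params = kp)
  mask <- matrix(TRUE, 50, 50) # pixel size 4: grid spans 200 um
  fld <- predict_field(pvx, pvy, mask, pixel_size = 4)
  near_idx <- cbind(floor(vec$y_um / 4) + 1, floor(vec$x_um / 4) + 1)
  sd_near <- min(fld$sd_vx[near_idx])
  sd_far <- fld$sd_vx[50, 50] # > 5 lengthscales from all vectors
  expect_gte(sd_far, sd_near)
  expect_gte(sd_far, max(fld$sd_vx[near_idx]))
})
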