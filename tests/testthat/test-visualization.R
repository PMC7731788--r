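# A tiny movie with one bright particle moving left to right along a row.
moving_dot_movie <- function(n_frames = 12, nr = 21, nc = 40, bg = 100, amp = 800,
                             reverse = FALSE) {
  a <- array(bg, dim = c(nr, nc, n_frames))
  xs <- round(seq(6, nc - 6, length.out = n_frames))
  if (reverse) xs <- rev(xs)
  for (f in seq_len(n_frames)) a[11, xs[f], f] <- bg + amp
  as_oct_movie(a, pixel_size = 2, frame_interval = 1 / 30)
}

# index of the nearest colormap entry for each tinted pixel along the trail
trail_colormap_index <- function(rgb_img, row, cols, colors) {
  cm <- t(grDevices::col2rgb(colors) / 255)
  vapply(cols, function(cc) {
    px <- rgb_img[row, cc, ]
    which.min(colSums((t(cm) - px)^2))
  }, 0L)
}

test_that("a static movie projects to its grayscale background", {
  a <- array(rep(matrix(100 + 50 * diag(15), 15, 15), 6), dim = c(15, 15, 6))
  mv <- as_oct_movie(a, 2, 1 / 30)
  pr <- temporal_color_projection(mv)
  expect_equal(pr[, , 1], pr[, , 2], tolerance = 1e-12) # no colour anywhere
  expect_equal(pr[, , 2], pr[, , 3], tolerance = 1e-12)
  expect_equal(pr[, , 1], unclass(mv)[, , 1] / max(a), tolerance = 1e-12)
})

test_that("trail hue ordering follows time and reverses with frame order", {
  mv <- moving_dot_movie()
  cols <- grDevices::hcl.colors(12, "viridis")
  pr <- temporal_color_projection(mv, colormap = cols)
  xs <- round(seq(6, 34, length.out = 12))
  idx <- trail_colormap_index(pr, 11, xs, cols)
  expect_true(all(diff(idx) > 0)) # hue order increases along +x

  mv_rev <- moving_dot_movie(reverse = TRUE)
  pr_rev <- temporal_color_projection(mv_rev, colormap = cols)
  idx_rev <- trail_colormap_index(pr_rev, 11, xs, cols)
  expect_true(all(diff(idx_rev) < 0))
})

test_that("single-frame ranges tint with a single colour and bad ranges error", {
  mv <- moving_dot_movie()
  pr <- temporal_color_projection(mv, frame_range = c(3, 3))
  expect_identical(dim(pr), c(21L, 40L, 3L))
  expect_error(temporal_color_projection(mv, frame_range = c(5, 2)), "frame_range")
  expect_error(temporal_color_projection(mv, frame_range = c(0, 99)), "frame_range")
})

test_that("kymographs of static movies have identical columns", {
  a <- array(0, dim = c(20, 30, 40))
  for (f in 1:40) a[, , f] <- outer(1:20, 1:30)
  mv <- as_oct_movie(a, 2, 1 / 30)
  k <- compute_kymograph(mv, rbind(c(2, 3), c(25, 17)))
  expect_true(all(abs(k$image - k$image[, 1]) < 1e-9))
  expect_identical(ncol(k$image), 40L)
  expect_error(compute_kymograph(mv, rbind(c(5, 5), c(5, 5))), "zero-length")
})

test_that("a travelling pattern leaves stripes with the configured speed", {
  ## a single Gaussian bump travelling at s px/frame: the kymograph crest
  ## advances by s rows per column, i.e. stripes of slope 1/s frames per px
  nr <- 9; nc <- 70; nf <- 30; s <- 1.5
  a <- array(100, dim = c(nr, nc, nf))
  xs <- seq_len(nc) - 0.5
  for (f in seq_len(nf)) {
    prof <- 100 + 500 * exp(-(xs - (8 + s * f))^2 / (2 * 2^2))
    a[, , f] <- matrix(prof, nr, nc, byrow = TRUE)
  }
  mv <- as_oct_movie(a, 2, 1 / 30)
  k <- compute_kymograph(mv, rbind(c(2, 4.5), c(66, 4.5)), width = 3)
  crest <- apply(k$image, 2L, which.max) # crest position (px along line) per frame
  slope <- unname(coef(lm(crest ~ seq_len(nf)))[2])
  expect_equal(slope, s, tolerance = 0.05)
})

test_that("width = 1 means no transverse averaging", {
  set.seed(71)
  a <- array(runif(20 * 20 * 35, 0, 100), dim = c(20, 20, 35))
  mv <- as_oct_movie(a, 2, 1 / 30)
  line <- rbind(c(4, 4), c(16, 14))
  k1 <- compute_kymograph(mv, line, width = 1)
  k3 <- compute_kymograph(mv, line, width = 3)
  expect_false(isTRUE(all.equal(k1$image, k3$image)))
  expect_identical(k1$image, compute_kymograph(mv, line)$image)
})

test_that("beat frequency finds a 5 Hz modulation and rejects silence", {
  nf <- 128; dt <- 1 / 30
  tt <- (seq_len(nf) - 1) * dt
  img <- outer(rep(1, 30), 100 + 40 * sin(2 * pi * 5 * tt))
  k <- structure(list(image = img, line = rbind(c(0, 0), c(0, 29)), width = 1,
                      frame_interval = dt), class = "kymograph")
  f <- beat_frequency(k)
  expect_lt(abs(f - 5), 30 / nf) # within one FFT bin
  ## intensity scaling leaves the estimate unchanged
  k2 <- k; k2$image <- 7.3 * k$image
  expect_equal(beat_frequency(k2), f)
  ## amplitude -> 0 (beating stops): the no-beat criterion returns 0
  set.seed(72)
  k0 <- k; k0$image <- matrix(100, 30, nf) + matrix(rnorm(30 * nf, 0, 1e-3), 30, nf)
  expect_identical(beat_frequency(k0), 0)
  kshort <- k; kshort$image <- k$image[, 1:20]
  expect_error(beat_frequency(kshort), "32 frames")
})
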