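test_that("vortex sampler hits its median-speed target over uniform samples", {
  cp <- compartment_spec("V", "vortex", median_speed_target = 10,
                         center = c(100, 100), radius = 80)
  f <- build_vortex_field(cp)
  set.seed(1)
  n <- 1e5
  th <- runif(n, 0, 2 * pi)
  r <- 80 * sqrt(runif(n))
  v <- f(100 + r * cos(th), 100 + r * sin(th), 0)
  expect_equal(median(sqrt(v$vx^2 + v$vy^2)), 10, tolerance = 0.01)
})

test_that("vortex sampler respects polarity and the static limit", {
  cw <- compartment_spec("V", "vortex", median_speed_target = 10,
                         center = c(50, 50), radius = 40)
  f <- build_vortex_field(cw)
  v <- f(80, 50, 0) # right of centre
  expect_lt(v$vy, 0) # moves towards smaller y (row-down image coordinates)
  expect_equal(v$vx, 0, tolerance = 1e-12)
  ccw <- compartment_spec("V", "vortex", median_speed_target = 10,
                          center = c(50, 50), radius = 40,
                          polarity = "counterclockwise")
  expect_gt(build_vortex_field(ccw)(80, 50, 0)$vy, 0)

  z <- compartment_spec("Z", "vortex", median_speed_target = 0,
                        center = c(50, 50), radius = 40)
  fz <- build_vortex_field(z)
  v0 <- fz(c(50, 60, 85), c(50, 55, 50), 0)
  expect_true(all(v0$vx == 0) && all(v0$vy == 0))
})

test_that("degenerate regions are rejected", {
  expect_error(compartment_spec("V", "vortex", median_speed_target = 1,
                                center = c(0, 0), radius = -1),
               "radius")
  expect_error(compartment_spec("U", "uniform", median_speed_target = 1,
                                region = cbind(c(0, 1, 2), c(0, 0, 0))),
               "degenerate")
})

test_that("uniform flow advances truth positions by v * dt each frame", {
  cp <- compartment_spec("U", "uniform", median_speed_target = 5,
                         region = rect_polygon(c(0, 200), c(0, 100)),
                         direction = 0)
  spec <- flow_spec(list(cp), image_shape = c(50, 100), pixel_size = 2,
                    frame_interval = 1 / 30, n_frames = 6,
                    particle_density = 1, survival_prob = 1, seed = 2)
  sim <- simulate_movie(spec)
  tr <- sim$ground_truth$tracks
  for (id in unique(tr$track_id)) {
    p <- tr[tr$track_id == id, ]
    if (nrow(p) < 2) next
    expect_equal(diff(p$x_um), rep(5 / 30, nrow(p) - 1), tolerance = 1e-9)
    expect_equal(diff(p$y_um), rep(0, nrow(p) - 1), tolerance = 1e-9)
  }
})

test_that("static scenes yield zero-displacement tracks and zero true median speed", {
  cp <- compartment_spec("S", "static", region = rect_polygon(c(10, 110), c(10, 90)))
  spec <- flow_spec(list(cp), image_shape = c(50, 60), pixel_size = 2,
                    n_frames = 5, particle_density = 2, survival_prob = 1, seed = 4)
  sim <- simulate_movie(spec)
  tr <- sim$ground_truth$tracks
  disp <- tapply(seq_len(nrow(tr)), tr$track_id, function(ix)
    max(abs(diff(tr$x_um[ix]))) + max(abs(diff(tr$y_um[ix]))))
  expect_true(all(disp == 0))
  expect_identical(true_median_speed(sim$ground_truth, "S"), 0)
  expect_identical(unname(sim$ground_truth$true_median_speed["S"]), 0)
})

test_that("pulsatile displacement cancels over whole periods", {
  ## zero steady flow, pure sinusoidal pulsation at 2 Hz for exactly 2 s
  cp <- compartment_spec("V", "vortex", median_speed_target = 0,
                         center = c(100, 60), radius = 50)
  spec <- flow_spec(list(cp), image_shape = c(60, 100), pixel_size = 2,
                    frame_interval = 1 / 30, n_frames = 61,
                    particle_density = 1, survival_prob = 1,
                    pulsatile_amplitude = 5, pulsatile_freq = 2, seed = 5)
  sim <- simulate_movie(spec)
  tr <- sim$ground_truth$tracks
  for (id in unique(tr$track_id)) {
    p <- tr[tr$track_id == id, ]
    ## frames 0 and 60 are an integer number of pulsation periods apart
    expect_equal(p$x_um[p$frame == 60], p$x_um[p$frame == 0], tolerance = 1e-6)
    expect_equal(p$y_um[p$frame == 60], p$y_um[p$frame == 0], tolerance = 1e-6)
  }
})

test_that("identical seeds give bit-identical movies and ground truth", {
  spec <- small_vortex_scene(seed = 11, n_frames = 8, n_particles = 10)
  s1 <- simulate_movie(spec)
  s2 <- simulate_movie(spec)
  expect_identical(unclass(s1$movie), unclass(s2$movie))
  expect_identical(s1$ground_truth$tracks, s2$ground_truth$tracks)
})

test_that("per-compartment particle counts stay stationary across frames", {
  spec <- small_vortex_scene(seed = 6, n_frames = 50, n_particles = 25)
  sim <- simulate_movie(spec)
  counts <- table(sim$ground_truth$tracks$frame)
  expect_lt((max(counts) - min(counts)) / mean(counts), 0.2)
})

test_that("true median speed matches the configured vortex target", {
  ## dense particle sample so the track-sampled median is a tight estimate
  ## of the uniform-sample median the vortex is scaled to (tracking is not
  ## run here, so the overlap warning is expected and irrelevant)
  spec <- vortex_scene(c(V = 33.2), radius_um = 200, n_frames = 2,
                       n_particles = 20000, seed = 8, survival_prob = 1)
  sim <- suppressWarnings(simulate_movie(spec))
  cp <- spec$compartments[[1]]
  expect_equal(true_median_speed(sim$ground_truth, cp$region), 33.2, tolerance = 0.01)
  expect_error(true_median_speed(sim$ground_truth, circle_polygon(c(1e5, 1e5), 5)),
               "no ground-truth samples")
})

test_that("overly dense scenes warn that tracking is ill-posed", {
  cp <- compartment_spec("V", "vortex", median_speed_target = 1,
                         center = c(30, 30), radius = 25)
  spec <- flow_spec(list(cp), image_shape = c(30, 30), pixel_size = 2,
                    n_frames = 2, particle_density = 300, particle_sigma = 3,
                    seed = 1)
  expect_warning(simulate_movie(spec), "ill-posed")
})

test_that("flow specifications round-trip losslessly through JSON", {
  spec <- vortex_scene(c(A = 3.5, B = 12), radius_um = 50, n_frames = 10, seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  write_flow_spec(spec, path)
  back <- read_flow_spec(path)
  expect_equal(back, spec)
})

test_that("movies round-trip through 16-bit TIFF with calibration sidecar", {
  spec <- small_vortex_scene(seed = 13, n_frames = 4, n_particles = 8)
  sim <- simulate_movie(spec)
  path <- file.path(withr::local_tempdir(), "movie.tif")
  write_movie(sim$movie, path)
  back <- validate_movie(path)
  expect_identical(as.vector(unclass(back)), as.vector(unclass(sim$movie)))
  expect_identical(dim(back), dim(sim$movie))
  expect_equal(attr(back, "pixel_size"), attr(sim$movie, "pixel_size"))
  expect_equal(attr(back, "frame_interval"), attr(sim$movie, "frame_interval"))
})
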