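## Synthetic OCT-like movie generator. Particles are advected through the
## scene's velocity fields by sub-stepped forward Euler, rendered as
## isotropic Gaussian blobs on a noisy background, and persist with a
## per-frame survival probability; dead or escaped particles are replaced at
## uniform-random in-compartment positions so the density stays stationary.

#' Simulate a particle movie with exported ground truth
#'
#' @param spec a [flow_spec()] scene description.
#' @return a list with elements
#'   \describe{
#'     \item{movie}{an `oct_movie`: integer `rows x cols x n_frames` array
#'       with calibration attributes (see [as_oct_movie()]).}
#'     \item{ground_truth}{a `ground_truth` object: exact sub-pixel particle
#'       tracks (`track_id`, `frame`, `x_um`, `y_um`, `compartment`), the
#'       scene field sampler, per-compartment true median speeds and the
#'       compartment specs.}
#'   }
#' Identical specs (including `seed`) give bit-identical output.
#' @export
simulate_movie <- function(spec) {
  stopifnot(inherits(spec, "flow_spec"))
  set.seed(spec$seed)
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  ps <- spec$pixel_size; dt <- spec$frame_interval
  ncomp <- length(spec$compartments)
  samplers <- lapply(spec$compartments, compartment_field)

  ## target per-compartment particle counts from density (per 1000 px^2)
  area_px <- vapply(spec$compartments, function(cp) polygon_area(cp$region) / ps^2, 0)
  n_target <- pmax(1L, as.integer(round(spec$particle_density * area_px / 1000)))

  ## ill-posedness warning: expected NN distance below 2 * particle_sigma
  dens_px2 <- n_target / area_px
  nn_px <- 0.5 / sqrt(dens_px2)                 # mean NN distance of a Poisson process
  if (any(nn_px * ps < 2 * spec$particle_sigma))
    warning("particle density so high that mean nearest-neighbour distance < 2*particle_sigma; tracking may be ill-posed")

  ## per-compartment maximum speed for sub-step sizing
  max_speed <- vapply(seq_len(ncomp), function(k) {
    ms <- attr(samplers[[k]], "max_speed")
    if (!is.null(ms)) return(ms)
    pts <- polygon_grid_points(spec$compartments[[k]]$region, n_min = 2000)
    v <- samplers[[k]](pts[, 1], pts[, 2], 0)
    max(sqrt(v$vx^2 + v$vy^2))
  }, 0) + spec$pulsatile_amplitude
  n_sub <- pmax(1L, as.integer(ceiling(max_speed * dt / (0.25 * ps))))

  ## particle state
  comp_of <- rep.int(seq_len(ncomp), n_target)
  npart <- length(comp_of)
  pos <- matrix(0, npart, 2L)
  for (k in seq_len(ncomp)) {
    idx <- which(comp_of == k)
    pos[idx, ] <- region_runif_points(spec$compartments[[k]], length(idx))
  }
  amp <- spec$particle_amplitude *
    (1 + runif(npart, -spec$amplitude_jitter, spec$amplitude_jitter))
  track_id <- seq_len(npart)
  next_id <- npart + 1L

  frames <- array(0L, dim = c(nr, nc, spec$n_frames))
  rec <- matrix(0, npart * spec$n_frames, 5L) # track_id, frame, x, y, comp

  render_frame <- function(pos, amp) {
    img <- matrix(spec$background_level, nr, nc)
    sig_px <- spec$particle_sigma / ps
    half <- ceiling(3 * sig_px)
    cx <- pos[, 1] / ps; cy <- pos[, 2] / ps # px units, continuous
    for (i in seq_len(nrow(pos))) {
      c0 <- floor(cx[i] - half); c1 <- ceiling(cx[i] + half)
      r0 <- floor(cy[i] - half); r1 <- ceiling(cy[i] + half)
      cs <- max(1L, c0 + 1L):min(nc, c1 + 1L)
      rs <- max(1L, r0 + 1L):min(nr, r1 + 1L)
      if (!length(cs) || !length(rs) || cs[1] > tail(cs, 1) || rs[1] > tail(rs, 1)) next
      gx <- exp(-((cs - 0.5) - cx[i])^2 / (2 * sig_px^2))
      gy <- exp(-((rs - 0.5) - cy[i])^2 / (2 * sig_px^2))
      img[rs, cs] <- img[rs, cs] + amp[i] * outer(gy, gx)
    }
    img
  }

  pulse_vel <- function(t) spec$pulsatile_amplitude * sin(2 * pi * spec$pulsatile_freq * t)

  for (f in seq_len(spec$n_frames)) {
    t_now <- (f - 1L) * dt
    rec[(f - 1L) * npart + seq_len(npart), ] <-
      cbind(track_id, f - 1L, pos[, 1], pos[, 2], comp_of)
    img <- render_frame(pos, amp)
    img <- img + matrix(rnorm(nr * nc, 0, spec$background_noise_sd), nr, nc)
    frames[, , f] <- clamp_u16(img)
    if (f == spec$n_frames) break

    ## advance to next frame by sub-stepped forward Euler
    for (k in seq_len(ncomp)) {
      idx <- which(comp_of == k)
      if (!length(idx)) next
      cp <- spec$compartments[[k]]
      m <- n_sub[k]; h <- dt / m
      p <- pos[idx, , drop = FALSE]
      for (s in seq_len(m)) {
        ts <- t_now + (s - 1L) * h
        v <- samplers[[k]](p[, 1], p[, 2], ts)
        pv <- pulse_vel(ts)
        p[, 1] <- p[, 1] + (v$vx + pv * cos(cp$pulsatile_axis)) * h
        p[, 2] <- p[, 2] + (v$vy + pv * sin(cp$pulsatile_axis)) * h
      }
      pos[idx, ] <- p
    }

    ## survival, escape, replacement (single sequential RNG stream)
    dies <- runif(npart) > spec$survival_prob
    for (k in seq_len(ncomp)) {
      idx <- which(comp_of == k)
      if (!length(idx)) next
      esc <- !region_contains(spec$compartments[[k]], pos[idx, 1], pos[idx, 2])
      dies[idx][esc] <- TRUE
    }
    for (i in which(dies)) {
      pos[i, ] <- region_runif_points(spec$compartments[[comp_of[i]]], 1L)
      amp[i] <- spec$particle_amplitude *
        (1 + runif(1L, -spec$amplitude_jitter, spec$amplitude_jitter))
      track_id[i] <- next_id
      next_id <- next_id + 1L
    }
  }

  labels <- vapply(spec$compartments, `[[`, "", "label")
  tracks <- data.frame(track_id = as.integer(rec[, 1]), frame = as.integer(rec[, 2]),
                       x_um = rec[, 3], y_um = rec[, 4],
                       compartment = labels[rec[, 5]])
  tracks <- tracks[order(tracks$track_id, tracks$frame), ]
  rownames(tracks) <- NULL

  sampler <- scene_field_sampler(spec$compartments, samplers)
  true_med <- vapply(seq_len(ncomp), function(k) {
    cp <- spec$compartments[[k]]
    if (isTRUE(cp$is_circle)) {
      r <- cp$radius * sqrt((seq_len(1e5) - 0.5) / 1e5)
      pts <- cbind(cp$center[1] + r, rep(cp$center[2], length(r)))
    } else {
      pts <- polygon_grid_points(cp$region, n_min = 1e4)
    }
    v <- samplers[[k]](pts[, 1], pts[, 2], 0)
    median(sqrt(v$vx^2 + v$vy^2))
  }, 0)
  names(true_med) <- vapply(spec$compartments, `[[`, "", "label")

  gt <- structure(list(tracks = tracks, field_sampler = sampler,
                       true_median_speed = true_med,
                       compartments = spec$compartments,
                       frame_interval = dt, pixel_size = ps),
                  class = "ground_truth")
  movie <- as_oct_movie(frames, pixel_size = ps, frame_interval = dt)
  list(movie = movie, ground_truth = gt)
}

## clamp + round to the 16-bit range, returning integers
clamp_u16 <- function(img) {
  as.integer(pmax(0, pmin(65535, round(img))))
}

#' Construct a calibrated movie object
#'
#' @param frames numeric or integer `rows x cols x n_frames` array.
#' @param pixel_size pixel size, µm/px.
#' @param frame_interval frame interval, s.
#' @return an `oct_movie`: the array with calibration attributes.
#' @export
as_oct_movie <- function(frames, pixel_size, frame_interval) {
  stopifnot(length(dim(frames)) == 3L, pixel_size > 0, frame_interval > 0)
  structure(frames, pixel_size = pixel_size, frame_interval = frame_interval,
            class = "oct_movie")
}

#' @export
print.oct_movie <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("oct_movie: %d x %d px, %d frames, %.3g um/px, %.4g s/frame\n",
              d[1], d[2], d[3], attr(x, "pixel_size"), attr(x, "frame_interval")))
  invisible(x)
}

#' @export
dim.oct_movie <- function(x) dim(unclass(x))

n_frames <- function(movie) dim(unclass(movie))[3]
movie_frame <- function(movie, f) unclass(movie)[, , f] # f is 1-based internally
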