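## Seeded end-to-end recovery experiments: synthetic scenes with known
## median speeds are pushed through the full pipeline and the estimated
## compartmental median speeds are compared with the generating truth.
## These experiments stand in for the study's raw movies, which are not
## publicly deposited.

#' Build a multi-compartment vortex scene
#'
#' Lays out one circular vortex compartment per requested speed along the
#' x (rostro-caudal) axis with alternating polarity, emulating the embryo's
#' caudo-rostral arrangement of recirculating flow fields.
#'
#' @param speeds named numeric vector of median-speed targets, µm/s
#'   (rostral first); names become compartment labels.
#' @param radius_um compartment radius, µm.
#' @param pixel_size µm/px.
#' @param n_frames frames at `frame_interval`.
#' @param frame_interval s.
#' @param n_particles concurrent particles per compartment.
#' @param snr peak particle amplitude over background noise SD.
#' @param survival_prob per-frame persistence probability.
#' @param seed RNG seed.
#' @return a [flow_spec()].
#' @export
vortex_scene <- function(speeds, radius_um = 180, pixel_size = 2,
                         n_frames = 150L, frame_interval = 1 / 30,
                         n_particles = 75L, snr = 10, survival_prob = 0.99,
                         seed = 1L) {
  stopifnot(length(speeds) >= 1L, all(speeds >= 0))
  if (is.null(names(speeds))) names(speeds) <- paste0("C", seq_along(speeds))
  margin <- 10 * pixel_size
  pitch <- 2 * radius_um + margin
  rows_px <- as.integer(ceiling((2 * radius_um + 2 * margin) / pixel_size))
  cols_px <- as.integer(ceiling((pitch * length(speeds) + margin) / pixel_size))
  comps <- lapply(seq_along(speeds), function(k) {
    ctr <- c(margin + radius_um + (k - 1) * pitch, margin + radius_um)
    compartment_spec(names(speeds)[k],
                     flow_model = if (speeds[k] > 0) "vortex" else "static",
                     median_speed_target = speeds[k],
                     center = ctr, radius = radius_um,
                     polarity = if (k %% 2 == 1) "clockwise" else "counterclockwise")
  })
  area_px <- pi * (radius_um / pixel_size)^2
  noise_sd <- 100
  flow_spec(compartments = comps, image_shape = c(rows_px, cols_px),
            pixel_size = pixel_size, frame_interval = frame_interval,
            n_frames = n_frames,
            particle_density = n_particles / area_px * 1000,
            particle_sigma = pixel_size, # sigma 2 um: FWHM ~4.7 um, the OCT lateral resolution scale
            particle_amplitude = snr * noise_sd,
            background_noise_sd = noise_sd,
            survival_prob = survival_prob, seed = seed)
}

## Sensible stage parameters for a synthetic scene: link radius from the
## fastest compartment's expected per-frame displacement.
scene_link_params <- function(spec, min_link_um = NULL) {
  max_med <- max(vapply(spec$compartments, `[[`, 0, "median_speed_target"))
  max_speed <- max_med * sqrt(2) / RIM_FRACTION # solid-body: max ~ sqrt(2) x median
  link <- max(default_link_distance(max_speed, spec$frame_interval),
              if (is.null(min_link_um)) 2 * spec$pixel_size else min_link_um)
  link_params(max_link_distance = link, max_gap_frames = 2L,
              max_gap_distance = 1.5 * link)
}

## In-memory pipeline on a simulated scene: detect -> track -> vectors
## (-> GPR dense field). Returns the stages a recovery analysis needs.
analyze_scene <- function(sim, spec, use_gpr = TRUE, gpr_seed = 1L,
                          window_frames = NULL, n_max_condition = 2000L) {
  movie <- sim$movie
  ps <- attr(movie, "pixel_size"); dt <- attr(movie, "frame_interval")
  mask <- compartments_mask(spec$compartments, dim(movie)[1:2], ps)
  roi <- mask$labels > 0L
  blob_radius <- spec$particle_sigma * sqrt(2)
  detections <- detect_movie(movie, blob_radius = blob_radius)
  tracks <- build_tracks(detections, scene_link_params(spec))
  vectors <- collect_vectors(tracks, dt, ps, window_frames = window_frames, roi_mask = roi)
  field <- NULL
  if (use_gpr && nrow(vectors) >= 5L) {
    pvx <- fit_gpr_component(vectors, "vx", seed = gpr_seed, n_max_condition = n_max_condition)
    pvy <- fit_gpr_component(vectors, "vy", seed = gpr_seed, n_max_condition = n_max_condition)
    field <- predict_field(pvx, pvy, roi, ps)
  }
  list(movie = movie, mask = mask, detections = detections, tracks = tracks,
       vectors = vectors, field = field)
}

#' Parameter-recovery experiment over known compartment speeds
#'
#' Builds a vortex scene with the given median-speed targets, simulates a
#' movie, runs the full pipeline (detection, LAP tracking, windowed WLS,
#' GPR dense field) and reports estimated versus true median speed per
#' compartment.
#'
#' @param speeds_by_compartment named numeric vector of median-speed
#'   targets, µm/s.
#' @param n_tracks minimum ground-truth tracks per compartment the
#'   simulation must deliver (>= 100 recommended for stable medians).
#' @param seed RNG seed for the whole experiment.
#' @param source `"dense"` (GPR field pixels) or `"sparse"` (Stage-2
#'   vectors) median.
#' @param ... scene overrides passed to [vortex_scene()].
#' @return data frame with one row per compartment: `compartment`,
#'   `true_median_speed`, `estimated_median_speed`, `relative_error`,
#'   `n_tracks`, `seed`.
#' @export
run_recovery_experiment <- function(speeds_by_compartment, n_tracks = 150L, seed = 1L,
                                    source = c("dense", "sparse"), ...) {
  source <- match.arg(source)
  stopifnot(all(speeds_by_compartment >= 0), n_tracks >= 100L)
  dots <- list(...)
  ## concurrent particles sized so the expected track count comfortably
  ## exceeds n_tracks (births at rate (1 - survival) per particle-frame)
  surv <- if (!is.null(dots$survival_prob)) dots$survival_prob else 0.99
  nfr <- if (!is.null(dots$n_frames)) dots$n_frames else 150L
  n_part <- as.integer(ceiling(n_tracks / (1 + (1 - surv) * (nfr - 1)) * 1.3))
  args <- c(list(speeds = speeds_by_compartment, seed = seed, n_particles = n_part), dots)
  spec <- do.call(vortex_scene, args)
  sim <- simulate_movie(spec)
  gt_first <- sim$ground_truth$tracks[!duplicated(sim$ground_truth$tracks$track_id), ]
  tr_counts <- table(gt_first$compartment)
  if (any(tr_counts[names(speeds_by_compartment)] < n_tracks))
    warning("fewer ground-truth tracks than requested in some compartment")
  res <- analyze_scene(sim, spec, use_gpr = (source == "dense"), gpr_seed = seed)
  ps <- spec$pixel_size
  out <- lapply(names(speeds_by_compartment), function(lab) {
    k <- match(lab, vapply(spec$compartments, `[[`, "", "label"))
    poly <- spec$compartments[[k]]$region
    est <- if (source == "dense") {
      sel <- res$mask$labels == k
      median_speed(res$field, sel, region_label = lab)$median_speed
    } else {
      median_speed(res$vectors, poly, region_label = lab)$median_speed
    }
    tru <- sim$ground_truth$true_median_speed[[lab]]
    data.frame(compartment = lab, true_median_speed = tru,
               estimated_median_speed = est,
               relative_error = if (tru > 0) abs(est - tru) / tru else NA_real_,
               n_tracks = as.integer(tr_counts[[lab]]), seed = seed)
  })
  res_df <- do.call(rbind, out)
  rownames(res_df) <- NULL
  res_df
}

#' The five-compartment median speeds used for recovery fixtures
#'
#' Rostral-to-caudal targets (µm/s) for the lateral, third, midbrain,
#' anterior-fourth and posterior-fourth ventricle compartments of the
#' stage-46 tadpole scene.
#' @return named numeric vector.
#' @export
embryo_speeds <- function() {
  c(LatV = 3.5, III = 6.2, M = 6.6, IVa = 11.8, IVp = 33.2)
}

#' Paired pre/post experiment on simulated animals
#'
#' Simulates `n_animals` small single-vortex scenes twice each — a "pre"
#' and a "post" movie with fresh particle placements — computes each
#' animal's compartmental median speed from the sparse Stage-2 vectors, and
#' compares pre versus post with the exact Wilcoxon signed-rank test. With
#' `post_speed_scale = 1` this emulates an intervention that leaves flow
#' unchanged (expected non-significant); with `post_speed_scale = 0` it
#' emulates complete loss of flow (expected significant at n = 8).
#'
#' @param seed RNG seed.
#' @param n_animals number of paired animals (>= 5 for the test).
#' @param post_speed_scale multiplier on every compartment speed in the
#'   post condition.
#' @param base_speed nominal pre-condition median speed, µm/s; each animal
#'   draws its own speed within ±20% of this.
#' @param n_particles,n_frames,radius_um scene size knobs (kept small so
#'   repeated calibration runs are cheap).
#' @return list with `p`, `statistic`, `significant` and `per_animal`
#'   (data frame of pre/post medians).
#' @export
run_ablation_null_experiment <- function(seed, n_animals = 8L, post_speed_scale = 1,
                                         base_speed = 10, n_particles = 12L,
                                         n_frames = 36L, radius_um = 48) {
  set.seed(seed)
  animal_speed <- runif(n_animals, 0.8, 1.2) * base_speed
  scene_seeds <- sample.int(2^30, 2L * n_animals)
  med_of <- function(speed, sc_seed) {
    spec <- vortex_scene(c(V = speed), radius_um = radius_um, n_frames = n_frames,
                         n_particles = n_particles, seed = sc_seed)
    sim <- simulate_movie(spec)
    res <- analyze_scene(sim, spec, use_gpr = FALSE)
    if (!nrow(res$vectors)) return(NA_real_)
    median_speed(res$vectors, spec$compartments[[1]]$region)$median_speed
  }
  pre <- post <- numeric(n_animals)
  for (a in seq_len(n_animals)) {
    pre[a] <- med_of(animal_speed[a], scene_seeds[2 * a - 1])
    post[a] <- med_of(animal_speed[a] * post_speed_scale, scene_seeds[2 * a])
  }
  cmp <- compare_paired(pre, post)
  list(p = cmp$p, statistic = cmp$statistic, significant = cmp$significant,
       per_animal = data.frame(animal = seq_len(n_animals), pre = pre, post = post))
}
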