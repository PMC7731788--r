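## Scene specifications for the synthetic movie generator. A flow_spec
## describes the acquisition (grid, calibration, noise) and a list of
## compartment_spec regions, each carrying its own flow model.

#' Compartment specification for synthetic flow scenes
#'
#' Describes one fluid compartment (e.g. a ventricle) of a synthetic scene:
#' its region polygon and the flow model that advects particles inside it.
#'
#' @param label compartment name; the conventional ventricular labels are
#'   `"LatV"`, `"III"`, `"M"`, `"IVa"`, `"IVp"` but any string is accepted.
#' @param region polygon in µm (n x 2 matrix); defaults to a circle built
#'   from `center` and `radius` for vortex compartments.
#' @param flow_model one of `"vortex"`, `"uniform"`, `"static"`.
#' @param polarity `"clockwise"` or `"counterclockwise"` (vortex only). The
#'   convention follows the package-wide image coordinates (y down): a
#'   clockwise vortex moves towards smaller y (up-screen) at points to the
#'   right of its centre.
#' @param median_speed_target target median speed over the region, µm/s.
#'   Must be 0 for static compartments.
#' @param center,radius vortex centre (µm, length-2) and radius (µm).
#' @param direction flow direction in radians for uniform compartments
#'   (0 = +x); ignored otherwise.
#' @param pulsatile_axis axis (radians) of the zero-mean pulsatile velocity
#'   component for this compartment; defaults to the rostro-caudal image
#'   axis (+x).
#' @return an object of class `compartment_spec`.
#' @export
compartment_spec <- function(label,
                             flow_model = c("vortex", "uniform", "static"),
                             median_speed_target = 0,
                             center = NULL, radius = NULL,
                             region = NULL,
                             polarity = c("clockwise", "counterclockwise"),
                             direction = 0,
                             pulsatile_axis = 0) {
  flow_model <- match.arg(flow_model)
  polarity <- match.arg(polarity)
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop("label must be a non-empty string")
  median_speed_target <- unname(as.numeric(median_speed_target))
  if (!is.finite(median_speed_target) || median_speed_target < 0)
    stop("median_speed_target must be >= 0")
  if (flow_model == "static" && median_speed_target != 0)
    stop("static compartments must have median_speed_target = 0")
  if (flow_model == "vortex") {
    if (is.null(center) || is.null(radius))
      stop("vortex compartments need center and radius")
    if (radius <= 0) stop("vortex radius must be > 0")
  }
  is_circle <- FALSE
  if (is.null(region)) {
    if (is.null(center) || is.null(radius))
      stop("a compartment needs either a region polygon or center and radius")
    region <- circle_polygon(center, radius)
    is_circle <- TRUE # exact disk geometry used instead of the polygon approximation
  }
  region <- as_polygon(region)
  if (polygon_area(region) <= 0) stop("degenerate region (zero area)")
  structure(list(label = label, region = region, flow_model = flow_model,
                 polarity = polarity, median_speed_target = median_speed_target,
                 center = center, radius = radius, direction = direction,
                 pulsatile_axis = pulsatile_axis, is_circle = is_circle),
            class = "compartment_spec")
}

#' Synthetic scene specification
#'
#' All parameters a synthetic movie needs: grid and calibration, particle
#' photometry and dynamics, noise, and the compartments with their flow
#' models. The peak-amplitude-to-noise ratio of a rendered particle is
#' `particle_amplitude / background_noise_sd`.
#'
#' @param compartments list of [compartment_spec()] objects with pairwise
#'   disjoint regions.
#' @param image_shape integer `(rows, cols)` in pixels.
#' @param pixel_size pixel size, µm/px.
#' @param frame_interval frame interval, s (30 fps movies use 1/30).
#' @param n_frames number of frames (>= 2).
#' @param particle_density particles per 1000 px² of compartment area.
#' @param particle_sigma Gaussian point-spread width, µm; must be at least
#'   `pixel_size / 2` so blobs are resolvable.
#' @param particle_amplitude peak intensity of a particle above background.
#' @param amplitude_jitter relative per-particle intensity jitter (±).
#' @param background_level constant background intensity offset.
#' @param background_noise_sd additive Gaussian noise SD, intensity units.
#' @param survival_prob per-frame particle persistence probability in (0, 1].
#' @param pulsatile_amplitude amplitude of the zero-mean sinusoidal velocity
#'   component, µm/s.
#' @param pulsatile_freq pulsation frequency, Hz.
#' @param seed integer RNG seed; identical specs (including seed) produce
#'   bit-identical movies and ground truth.
#' @return an object of class `flow_spec`.
#' @export
flow_spec <- function(compartments,
                      image_shape,
                      pixel_size = 2,
                      frame_interval = 1 / 30,
                      n_frames = 150L,
                      particle_density = 3,
                      particle_sigma = 2,
                      particle_amplitude = 1000,
                      amplitude_jitter = 0.2,
                      background_level = 400,
                      background_noise_sd = 100,
                      survival_prob = 0.99,
                      pulsatile_amplitude = 0,
                      pulsatile_freq = 2,
                      seed = 1L) {
  if (inherits(compartments, "compartment_spec")) compartments <- list(compartments)
  stopifnot(length(compartments) >= 1L)
  if (!all(vapply(compartments, inherits, TRUE, "compartment_spec")))
    stop("compartments must be compartment_spec objects")
  labs <- vapply(compartments, `[[`, "", "label")
  if (anyDuplicated(labs)) stop("compartment labels must be unique")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (n_frames < 2L) stop("n_frames must be >= 2")
  if (survival_prob <= 0 || survival_prob > 1) stop("survival_prob must be in (0, 1]")
  if (particle_sigma < pixel_size / 2) stop("particle_sigma must be >= pixel_size / 2")
  if (length(image_shape) != 2L || any(image_shape < 8L)) stop("image_shape must be (rows, cols), each >= 8")
  ## disjointness check on vertex containment + centroid containment
  if (length(compartments) > 1L) {
    for (i in seq_along(compartments)) for (j in seq_along(compartments)) {
      if (i == j) next
      pi_ <- compartments[[i]]$region
      if (any(points_in_polygon(compartments[[j]]$region, pi_[, 1], pi_[, 2])))
        stop(sprintf("compartment regions '%s' and '%s' overlap", labs[i], labs[j]))
    }
  }
  structure(list(compartments = compartments, image_shape = as.integer(image_shape),
                 pixel_size = pixel_size, frame_interval = frame_interval,
                 n_frames = as.integer(n_frames), particle_density = particle_density,
                 particle_sigma = particle_sigma, particle_amplitude = particle_amplitude,
                 amplitude_jitter = amplitude_jitter, background_level = background_level,
                 background_noise_sd = background_noise_sd, survival_prob = survival_prob,
                 pulsatile_amplitude = pulsatile_amplitude, pulsatile_freq = pulsatile_freq,
                 seed = as.integer(seed)),
            class = "flow_spec")
}

#' @export
print.flow_spec <- function(x, ...) {
  cat(sprintf("flow_spec: %d x %d px @ %.3g um/px, %d frames @ %.4g s\n",
              x$image_shape[1], x$image_shape[2], x$pixel_size, x$n_frames, x$frame_interval))
  for (cp in x$compartments)
    cat(sprintf("  %-6s %-7s target %.3g um/s\n", cp$label, cp$flow_model, cp$median_speed_target))
  invisible(x)
}

#' Write / read a flow specification as JSON
#'
#' The JSON form round-trips losslessly through [read_flow_spec()].
#'
#' @param spec a [flow_spec()] object.
#' @param path file path.
#' @return `write_flow_spec` returns `path` invisibly; `read_flow_spec`
#'   returns the reconstructed `flow_spec`.
#' @export
write_flow_spec <- function(spec, path) {
  stopifnot(inherits(spec, "flow_spec"))
  comp <- lapply(spec$compartments, function(cp) {
    list(label = cp$label, flow_model = cp$flow_model, polarity = cp$polarity,
         median_speed_target = cp$median_speed_target,
         center = cp$center, radius = cp$radius, direction = cp$direction,
         pulsatile_axis = cp$pulsatile_axis,
         region = if (cp$is_circle) NULL else unname(apply(cp$region, 1L, as.list)))
  })
  body <- spec[setdiff(names(spec), "compartments")]
  jsonlite::write_json(c(body, list(compartments = comp)), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_flow_spec
#' @export
read_flow_spec <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  comps <- lapply(j$compartments, function(cp) {
    reg <- if (is.null(cp$region)) NULL
           else do.call(rbind, lapply(cp$region, function(v) c(v[[1]], v[[2]])))
    compartment_spec(label = cp$label, flow_model = cp$flow_model,
                     median_speed_target = cp$median_speed_target,
                     center = if (is.null(cp$center)) NULL else unlist(cp$center),
                     radius = cp$radius, region = reg, polarity = cp$polarity,
                     direction = cp$direction, pulsatile_axis = cp$pulsatile_axis)
  })
  flow_spec(compartments = comps,
            image_shape = unlist(j$image_shape), pixel_size = j$pixel_size,
            frame_interval = j$frame_interval, n_frames = j$n_frames,
            particle_density = j$particle_density, particle_sigma = j$particle_sigma,
            particle_amplitude = j$particle_amplitude, amplitude_jitter = j$amplitude_jitter,
            background_level = j$background_level, background_noise_sd = j$background_noise_sd,
            survival_prob = j$survival_prob, pulsatile_amplitude = j$pulsatile_amplitude,
            pulsatile_freq = j$pulsatile_freq, seed = j$seed)
}
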