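## Ground-truth velocity fields. A field sampler is a function
## f(x, y, t) -> list(vx, vy) in µm/s, vectorized over points.

RIM_FRACTION <- 0.85 # solid-body core out to RIM_FRACTION * radius, linear taper to 0 at the rim

#' Build a recirculating (vortex) velocity sampler for a compartment
#'
#' Solid-body rotation with a smooth rim: the tangential speed grows
#' linearly with radius out to 85% of the compartment radius and tapers
#' linearly to zero at the rim, so particles never cross the boundary. The
#' profile is scaled so that the median speed over a dense quasi-uniform
#' sample of in-region points equals `median_speed_target` (within the
#' sampling resolution, well under 1%).
#'
#' Orientation: with image coordinates (y down), a `"clockwise"` vortex has
#' a negative y-velocity at points to the right of its centre.
#'
#' @param spec a [compartment_spec()] with `flow_model = "vortex"`.
#' @return a field sampler `function(x, y, t)` returning `list(vx, vy)`,
#'   with a `"max_speed"` attribute (µm/s).
#' @export
build_vortex_field <- function(spec) {
  stopifnot(inherits(spec, "compartment_spec"))
  if (spec$flow_model != "vortex") stop("build_vortex_field needs flow_model = 'vortex'")
  if (is.null(spec$radius) || spec$radius <= 0) stop("vortex radius must be > 0")
  if (polygon_area(spec$region) <= 0) stop("degenerate region (zero area)")
  R <- spec$radius; ctr <- spec$center
  r0 <- RIM_FRACTION * R
  ## unscaled tangential speed: r in the core, linear taper to 0 at the rim;
  ## the taper branch exceeds r exactly when r < r0, so a single pmin works
  profile <- function(r) pmin(r, r0 * pmax(R - r, 0) / (R - r0))
  if (spec$median_speed_target == 0) {
    f <- function(x, y, t = 0) list(vx = rep_len(0, length(x)), vy = rep_len(0, length(x)))
    attr(f, "max_speed") <- 0
    return(f)
  }
  if (isTRUE(spec$is_circle)) {
    ## exact disk median: solve P(v <= c) = 1/2 with the area measure,
    ## where the sub-level set is {r <= c} plus the rim annulus
    ## {r >= R - c (R - r0)/r0}; quadratic in c
    a <- (R - r0) / r0
    med_unscaled <- R * (-a + sqrt(a^2 + (1 - a^2) / 2)) / (1 - a^2)
  } else {
    pts <- polygon_grid_points(spec$region, n_min = 2e4)
    r_pts <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
    med_unscaled <- median(profile(r_pts))
  }
  if (med_unscaled <= 0) stop("degenerate region (zero area)")
  scale <- spec$median_speed_target / med_unscaled
  sgn <- if (spec$polarity == "clockwise") 1 else -1
  f <- function(x, y, t = 0) {
    dx <- x - ctr[1]; dy <- y - ctr[2]
    r <- sqrt(dx^2 + dy^2)
    inv <- scale * profile(r) / pmax(r, 1e-300) # tangential speed / r; 0 at the centre
    ## "clockwise" tangent (convention: negative vy right of centre): (dy, -dx)/r
    list(vx = sgn * inv * dy, vy = -sgn * inv * dx)
  }
  attr(f, "max_speed") <- scale * r0
  f
}

build_uniform_field <- function(spec) {
  s <- spec$median_speed_target; th <- spec$direction
  f <- function(x, y, t = 0) list(vx = rep_len(s * cos(th), length(x)),
                                  vy = rep_len(s * sin(th), length(x)))
  attr(f, "max_speed") <- s
  f
}

build_static_field <- function(spec) {
  f <- function(x, y, t = 0) list(vx = rep_len(0, length(x)), vy = rep_len(0, length(x)))
  attr(f, "max_speed") <- 0
  f
}

## region membership with an exact-disk fast path
region_contains <- function(cp, x, y) {
  if (isTRUE(cp$is_circle))
    (x - cp$center[1])^2 + (y - cp$center[2])^2 <= cp$radius^2
  else points_in_polygon(cp$region, x, y)
}

## uniform random in-region points from the current RNG stream
region_runif_points <- function(cp, n) {
  if (isTRUE(cp$is_circle)) {
    r <- cp$radius * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
    cbind(x = cp$center[1] + r * cos(th), y = cp$center[2] + r * sin(th))
  } else polygon_runif_points(cp$region, n)
}

compartment_field <- function(spec) {
  switch(spec$flow_model,
         vortex = build_vortex_field(spec),
         uniform = build_uniform_field(spec),
         static = build_static_field(spec))
}

## Sampler over a whole scene: points outside every compartment get (0, 0).
scene_field_sampler <- function(compartments, samplers) {
  force(compartments); force(samplers)
  function(x, y, t = 0) {
    n <- length(x)
    vx <- numeric(n); vy <- numeric(n)
    for (k in seq_along(compartments)) {
      inside <- region_contains(compartments[[k]], x, y)
      if (any(inside)) {
        v <- samplers[[k]](x[inside], y[inside], t)
        vx[inside] <- v$vx; vy[inside] <- v$vy
      }
    }
    list(vx = vx, vy = vy)
  }
}

#' True median speed of the generating field over a region
#'
#' Evaluates the ground-truth field sampler at the recorded truth-track
#' sample points that fall inside `region` and returns the median speed.
#' Serves as the oracle for parameter-recovery experiments.
#'
#' @param gt a `ground_truth` object from [simulate_movie()].
#' @param region a polygon (µm) or a compartment label present in the scene.
#' @return median speed in µm/s.
#' @export
true_median_speed <- function(gt, region) {
  stopifnot(inherits(gt, "ground_truth"))
  if (is.character(region)) {
    k <- match(region, vapply(gt$compartments, `[[`, "", "label"))
    if (is.na(k)) stop(sprintf("unknown compartment label '%s'", region))
    region <- gt$compartments[[k]]$region
  }
  tr <- gt$tracks
  inside <- points_in_polygon(region, tr$x_um, tr$y_um)
  if (!any(inside)) stop("no ground-truth samples in region")
  v <- gt$field_sampler(tr$x_um[inside], tr$y_um[inside], tr$frame[inside] * gt$frame_interval)
  median(sqrt(v$vx^2 + v$vy^2))
}
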