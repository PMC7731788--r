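# Shared fixtures, all built in code.

# A small single-vortex scene for fast end-to-end checks.
small_vortex_scene <- function(speed = 10, seed = 3L, n_frames = 40L,
                               n_particles = 20L, radius_um = 70, snr = 10) {
  vortex_scene(setNames(speed, "V"), radius_um = radius_um, n_frames = n_frames,
               n_particles = n_particles, snr = snr, seed = seed)
}

# Render one synthetic Gaussian blob (amplitude over constant background,
# additive Gaussian noise) at sub-pixel position (x0, y0) in px units.
render_blob_frame <- function(nr = 64, nc = 64, x0 = 20.3, y0 = 41.7,
                              amp = 1000, sigma_px = 1.5, bg = 400, noise_sd = 0) {
  cs <- seq_len(nc); rs <- seq_len(nr)
  gx <- exp(-((cs - 0.5) - x0)^2 / (2 * sigma_px^2))
  gy <- exp(-((rs - 0.5) - y0)^2 / (2 * sigma_px^2))
  img <- bg + amp * outer(gy, gx)
  if (noise_sd > 0) img <- img + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
  img
}

# Brute-force oracle for frame-pair linking: enumerate every injective
# partial matching and return the minimal objective (link costs plus the
# per-detection no-link alternative).
brute_force_link_cost <- function(d1, d2, max_dist, alt_factor = 1.05) {
  n <- nrow(d1); m <- nrow(d2)
  d2m <- outer(d1$x_um, d2$x_um, "-")^2 + outer(d1$y_um, d2$y_um, "-")^2
  feas <- d2m <= max_dist^2
  alt <- if (any(feas)) alt_factor * max(d2m[feas]) else 0
  best <- Inf
  rec <- function(i, used, cost, L) {
    if (i > n) {
      tot <- cost + alt * (n - L) + alt * (m - L)
      if (tot < best) best <<- tot
      return(invisible())
    }
    rec(i + 1L, used, cost, L)
    for (j in seq_len(m)) if (!used[j] && feas[i, j]) {
      used[j] <- TRUE
      rec(i + 1L, used, cost + d2m[i, j], L + 1L)
      used[j] <- FALSE
    }
  }
  rec(1L, logical(m), 0, 0L)
  best
}

# Exact two-sided signed-rank p by enumeration of all 2^n sign patterns
# (midranks on |d|, W+ = rank sum of positive differences).
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  W_all <- signs %*% r
  lo <- mean(W_all <= W_obs)
  hi <- mean(W_all >= W_obs)
  min(1, 2 * min(lo, hi))
}

# Exact two-sided Mann-Whitney p by enumeration of all group labelings.
enumerate_mann_whitney_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  Ra_obs <- sum(r[seq_len(na)])
  combs <- utils::combn(na + nb, na)
  Ra_all <- apply(combs, 2L, function(ix) sum(r[ix]))
  lo <- mean(Ra_all <= Ra_obs)
  hi <- mean(Ra_all >= Ra_obs)
  min(1, 2 * min(lo, hi))
}
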