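## Stage 2: window-wise weighted-least-squares velocimetry. Each trajectory
## is partitioned into sub-second windows; within a window, x(t) and y(t)
## are fit by independent weighted linear regressions whose slopes give the
## window's velocity vector.

#' Partition a track into fitting windows
#'
#' Consecutive non-overlapping windows of `window_frames` points. A trailing
#' remainder of at least 3 points becomes a final shorter segment; a shorter
#' remainder is merged into the previous window. Tracks with fewer than 3
#' points yield nothing.
#'
#' @param n_points number of points in the track.
#' @param window_frames window length in points (>= 3).
#' @return list of integer index vectors into the track's points.
#' @export
partition_track <- function(n_points, window_frames) {
  stopifnot(window_frames >= 3L)
  n <- as.integer(n_points)
  if (n < 3L) return(list())
  k <- n %/% window_frames
  rem <- n %% window_frames
  if (k == 0L) return(list(seq_len(n)))
  segs <- lapply(seq_len(k), function(s) seq.int((s - 1L) * window_frames + 1L, s * window_frames))
  if (rem >= 3L) {
    segs[[k + 1L]] <- seq.int(k * window_frames + 1L, n)
  } else if (rem > 0L) {
    segs[[k]] <- seq.int((k - 1L) * window_frames + 1L, n)
  }
  segs
}

#' Fit one window's velocity vector by weighted least squares
#'
#' Independent weighted linear regressions of `x(t)` and `y(t)` by
#' closed-form normal equations; the slope pair is the velocity, the
#' weighted centroid the vector's position. The fit confidence is
#' `weight = 1 / (1 + residual_rms / pixel_size)`.
#'
#' @param t times, s (must span >= 2 distinct values).
#' @param x,y positions, µm.
#' @param weights nonnegative observation weights; not all zero.
#' @param pixel_size µm/px, used to scale the residual term of the
#'   confidence weight.
#' @return one-row data frame: `x_um, y_um, vx_um_s, vy_um_s, t_mid_s,
#'   n_points, residual_rms_um, weight`.
#' @export
fit_segment_velocity <- function(t, x, y, weights = NULL, pixel_size = 1) {
  n <- length(t)
  stopifnot(length(x) == n, length(y) == n, n >= 3L)
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || !all(is.finite(weights))) stop("weights must be finite and nonnegative")
  v <- wls_fit_core(t, x, y, weights, pixel_size)
  data.frame(x_um = v[1], y_um = v[2], vx_um_s = v[3], vy_um_s = v[4], t_mid_s = v[5],
             n_points = as.integer(v[6]), residual_rms_um = v[7], weight = v[8])
}

## closed-form weighted normal equations; returns
## c(xb, yb, vx, vy, tb, n, rms, weight)
wls_fit_core <- function(t, x, y, weights, pixel_size) {
  sw <- sum(weights)
  if (sw <= 0) stop("all weights are zero")
  if (length(unique(t[weights > 0])) < 2L) stop("segment must span >= 2 distinct frames")
  tb <- sum(weights * t) / sw
  xb <- sum(weights * x) / sw
  yb <- sum(weights * y) / sw
  stt <- sum(weights * (t - tb)^2)
  vx <- sum(weights * (t - tb) * (x - xb)) / stt
  vy <- sum(weights * (t - tb) * (y - yb)) / stt
  rx <- x - (xb + vx * (t - tb))
  ry <- y - (yb + vy * (t - tb))
  rms <- sqrt(sum(weights * (rx^2 + ry^2)) / (2 * sw))
  c(xb, yb, vx, vy, tb, length(t), rms, 1 / (1 + rms / pixel_size))
}

#' Collect velocity vectors from all tracks
#'
#' Applies [partition_track()] and [fit_segment_velocity()] to every track.
#' Vectors whose centroid falls outside the ROI mask (if given) are
#' discarded.
#'
#' @param tracks track table (`track_id, frame, x_um, y_um, quality`).
#' @param frame_interval frame interval, s.
#' @param pixel_size µm/px.
#' @param window_frames points per window; the default is the half-second
#'   window `round(0.5 / frame_interval)`.
#' @param weight_scheme `"quality"` (detection quality normalized to (0, 1]
#'   per segment) or `"uniform"`.
#' @param roi_mask optional logical matrix; vectors outside it are dropped.
#' @return data frame of velocity vectors with a `track_id` column.
#' @export
collect_vectors <- function(tracks, frame_interval, pixel_size,
                            window_frames = NULL,
                            weight_scheme = c("quality", "uniform"),
                            roi_mask = NULL) {
  weight_scheme <- match.arg(weight_scheme)
  if (is.null(window_frames)) window_frames <- max(3L, as.integer(round(0.5 / frame_interval)))
  empty <- data.frame(track_id = integer(0), x_um = numeric(0), y_um = numeric(0),
                      vx_um_s = numeric(0), vy_um_s = numeric(0), t_mid_s = numeric(0),
                      n_points = integer(0), residual_rms_um = numeric(0), weight = numeric(0))
  if (!nrow(tracks)) return(empty)
  ord <- order(tracks$track_id, tracks$frame)
  idx_by_track <- split(ord, tracks$track_id[ord])
  rows <- vector("list", 0L)
  has_q <- !is.null(tracks$quality)
  for (tid in names(idx_by_track)) {
    ti <- idx_by_track[[tid]]
    for (seg in partition_track(length(ti), window_frames)) {
      si <- ti[seg]
      w <- if (weight_scheme == "quality" && has_q && all(is.finite(tracks$quality[si])) &&
               max(tracks$quality[si]) > 0) tracks$quality[si] / max(tracks$quality[si])
           else rep(1, length(si))
      v <- wls_fit_core(tracks$frame[si] * frame_interval, tracks$x_um[si], tracks$y_um[si],
                        w, pixel_size)
      rows[[length(rows) + 1L]] <- c(as.numeric(tid), v)
    }
  }
  if (!length(rows)) return(empty)
  m <- do.call(rbind, rows)
  res <- data.frame(track_id = as.integer(m[, 1]), x_um = m[, 2], y_um = m[, 3],
                    vx_um_s = m[, 4], vy_um_s = m[, 5], t_mid_s = m[, 6],
                    n_points = as.integer(m[, 7]), residual_rms_um = m[, 8],
                    weight = m[, 9])
  if (!is.null(roi_mask)) {
    cc <- floor(res$x_um / pixel_size) + 1L
    rr <- floor(res$y_um / pixel_size) + 1L
    ok <- rr >= 1L & rr <= nrow(roi_mask) & cc >= 1L & cc <= ncol(roi_mask)
    ok[ok] <- roi_mask[cbind(rr[ok], cc[ok])]
    res <- res[ok, , drop = FALSE]
    rownames(res) <- NULL
  }
  res
}

#' Write velocity vectors as CSV
#' @param vectors vector table from [collect_vectors()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_vectors_csv <- function(vectors, path) {
  cols <- c("x_um", "y_um", "vx_um_s", "vy_um_s", "t_mid_s", "n_points", "weight", "track_id")
  write_table_fixed(vectors[, cols], path)
}
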