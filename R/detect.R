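## Stage 1a: per-frame particle detection. Scale-matched Laplacian-of-
## Gaussian blob detection with quadratic sub-pixel refinement, the detector
## family used for sub-resolution bright particles in TrackMate-style
## pipelines. The LoG response is computed by a compiled separable
## convolution (see src/log_filter.cpp) over whole frame blocks.

log_response_stack <- function(a, sigma_px) {
  storage.mode(a) <- "double"
  .log_response(a, sigma_px)
}

## Detections from a response stack (nr x nc x nf). Returns a list of
## per-frame data frames (x_um, y_um, quality).
find_blobs_in_response <- function(resp, thr, br_px, pixel_size) {
  d <- dim(resp)
  nr <- d[1]; nc <- d[2]; nf <- d[3]
  out <- rep(list(empty_detections()), nf)
  if (nr < 3L || nc < 3L) return(out)
  inner <- resp[2:(nr - 1), 2:(nc - 1), , drop = FALSE]
  sh <- function(dr, dc) resp[(2 + dr):(nr - 1 + dr), (2 + dc):(nc - 1 + dc), , drop = FALSE]
  ## strict '>' against lexicographically earlier neighbours, '>=' otherwise:
  ## deterministic plateau tie-break keeping the smallest (row, col)
  is_max <- inner > thr &
    inner >  sh(-1, -1) & inner >  sh(-1, 0) & inner >  sh(-1, 1) &
    inner >  sh(0, -1) &
    inner >= sh(0, 1) &
    inner >= sh(1, -1) & inner >= sh(1, 0) & inner >= sh(1, 1)
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx)) return(out)
  rows <- idx[, 1] + 1L; cols <- idx[, 2] + 1L; frs <- idx[, 3]
  ## border policy: discard maxima within one blob_radius of the border
  keep <- rows - 1 >= br_px & nr - rows >= br_px & cols - 1 >= br_px & nc - cols >= br_px
  rows <- rows[keep]; cols <- cols[keep]; frs <- frs[keep]
  for (f in unique(frs)) {
    sel <- frs == f
    out[[f]] <- localize_frame(resp[, , f], rows[sel], cols[sel], br_px, pixel_size)
  }
  out
}

## NMS + quadratic sub-pixel refinement for one frame's candidate maxima
localize_frame <- function(resp, rows, cols, br_px, pixel_size) {
  q <- resp[cbind(rows, cols)]
  ## non-maximum suppression at one blob_radius, higher quality wins;
  ## ties resolved by (row, col) order
  ord <- order(-q, rows, cols)
  rows <- rows[ord]; cols <- cols[ord]; q <- q[ord]
  kept <- logical(length(q))
  for (i in seq_along(q)) {
    if (i == 1L) { kept[1L] <- TRUE; next }
    prev <- which(kept[seq_len(i - 1L)])
    d2 <- (rows[i] - rows[prev])^2 + (cols[i] - cols[prev])^2
    kept[i] <- all(d2 >= br_px^2)
  }
  rows <- rows[kept]; cols <- cols[kept]; q <- q[kept]
  n <- length(q)
  dr <- dc <- numeric(n)
  for (i in seq_len(n)) {
    r <- rows[i]; c <- cols[i]
    denr <- resp[r - 1, c] - 2 * resp[r, c] + resp[r + 1, c]
    denc <- resp[r, c - 1] - 2 * resp[r, c] + resp[r, c + 1]
    dr[i] <- if (denr < 0) 0.5 * (resp[r - 1, c] - resp[r + 1, c]) / denr else 0
    dc[i] <- if (denc < 0) 0.5 * (resp[r, c - 1] - resp[r, c + 1]) / denc else 0
  }
  dr <- pmax(-0.5, pmin(0.5, dr)); dc <- pmax(-0.5, pmin(0.5, dc))
  ## pixel (r, c) 1-based has centre ((c - 0.5) * ps, (r - 0.5) * ps) µm
  out <- data.frame(x_um = (cols + dc - 0.5) * pixel_size,
                    y_um = (rows + dr - 0.5) * pixel_size,
                    quality = q)
  out[order(out$y_um, out$x_um), , drop = FALSE]
}

empty_detections <- function() {
  data.frame(x_um = numeric(0), y_um = numeric(0), quality = numeric(0))
}

#' Detect bright particles in a single frame
#'
#' Laplacian-of-Gaussian blob detection with `sigma = blob_radius / sqrt(2)`
#' (the LoG radius-matching relation), strict deterministic local-maximum
#' selection (plateau ties keep the lexicographically smallest `(row, col)`),
#' non-maximum suppression at one `blob_radius`, border exclusion of one
#' `blob_radius`, and quadratic 3x3 sub-pixel interpolation of the response
#' peak.
#'
#' @param frame_image numeric matrix (one movie frame), finite-valued.
#' @param pixel_size µm/px.
#' @param blob_radius expected particle radius, µm; must be >= `pixel_size`.
#' @param quality_threshold minimum blob response; the default `"auto"` uses
#'   `5 * mad(response)`, a robust noise-floor multiple.
#' @return data frame with columns `x_um, y_um, quality` (positions of blob
#'   centres in µm, image coordinates).
#' @export
detect_particles <- function(frame_image, pixel_size, blob_radius,
                             quality_threshold = "auto") {
  if (!all(is.finite(frame_image))) stop("frame contains non-finite values")
  if (blob_radius < pixel_size) stop("blob_radius must be >= pixel_size")
  sigma_px <- blob_radius / sqrt(2) / pixel_size
  resp <- log_response_stack(as.matrix(frame_image), sigma_px)
  thr <- if (identical(quality_threshold, "auto")) 5 * mad(resp) else quality_threshold
  res <- find_blobs_in_response(array(resp, c(dim(resp), 1L)), thr,
                                blob_radius / pixel_size, pixel_size)
  res[[1L]]
}

#' Detect particles in every frame of a movie
#'
#' Same detector as [detect_particles()], run block-wise over the stack.
#' With `quality_threshold = "auto"` the threshold is `5 * mad(response)`
#' over the whole movie (noise is assumed stationary across frames).
#'
#' @param movie an `oct_movie`.
#' @param blob_radius expected particle radius, µm.
#' @param quality_threshold response threshold or `"auto"`.
#' @param block frames filtered per block (memory control).
#' @return data frame `frame, x_um, y_um, quality` with 0-based frames.
#' @export
detect_movie <- function(movie, blob_radius, quality_threshold = "auto", block = 32L) {
  stopifnot(inherits(movie, "oct_movie"))
  ps <- attr(movie, "pixel_size")
  if (blob_radius < ps) stop("blob_radius must be >= pixel_size")
  a <- unclass(movie)
  if (!all(is.finite(a))) stop("movie contains non-finite values")
  nf <- dim(a)[3]
  sigma_px <- blob_radius / sqrt(2) / ps
  br_px <- blob_radius / ps
  starts <- seq(1L, nf, by = block)
  thr <- if (identical(quality_threshold, "auto")) {
    ## noise scale from a spread of sample frames (noise assumed stationary)
    sample_fr <- unique(c(1L, nf %/% 2 + 1L, nf))
    rs <- log_response_stack(a[, , sample_fr, drop = FALSE], sigma_px)
    5 * mad(rs)
  } else quality_threshold
  out <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    fr <- starts[b]:min(starts[b] + block - 1L, nf)
    resp <- log_response_stack(a[, , fr, drop = FALSE], sigma_px)
    dets <- find_blobs_in_response(resp, thr, br_px, ps)
    out[[b]] <- do.call(rbind, lapply(seq_along(fr), function(i) {
      d <- dets[[i]]
      if (nrow(d)) cbind(frame = fr[i] - 1L, d)
      else data.frame(frame = integer(0), x_um = numeric(0), y_um = numeric(0), quality = numeric(0))
    }))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write detections as CSV
#' @param detections data frame from [detect_movie()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_detections_csv <- function(detections, path) {
  write_table_fixed(detections[, c("frame", "x_um", "y_um", "quality")], path)
}
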