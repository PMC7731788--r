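## Temporal colour-coded polarity projections (moving particles leave
## time-coloured trails over a grayscale background) and line kymographs
## with a ciliary beat-frequency readout.

#' Temporal colour-coded projection of particle motion
#'
#' Splits each frame into a static background (per-pixel temporal median
#' over the range) and foreground (excess over background above a
#' threshold), tints the foreground by a time-indexed colormap, and takes
#' the maximum projection across frames: each pixel shows the colour of the
#' frame in which its foreground was strongest. The background is rendered
#' grayscale.
#'
#' @param movie an `oct_movie`.
#' @param frame_range integer length-2, 0-based inclusive frame range.
#' @param colormap vector of R colours indexed over time, or a function
#'   `n -> colours`; default is the viridis ramp.
#' @param fg_threshold foreground threshold in intensity units; `"auto"`
#'   uses 3 x the movie noise scale (MAD of frame-to-frame differences).
#' @return `rows x cols x 3` RGB array in [0, 1].
#' @export
temporal_color_projection <- function(movie, frame_range = NULL, colormap = NULL,
                                      fg_threshold = "auto") {
  stopifnot(inherits(movie, "oct_movie"))
  nt <- n_frames(movie)
  if (is.null(frame_range)) frame_range <- c(0L, nt - 1L)
  if (length(frame_range) != 2L || frame_range[1] > frame_range[2] ||
      frame_range[1] < 0L || frame_range[2] > nt - 1L)
    stop("invalid frame_range")
  fr <- seq.int(frame_range[1] + 1L, frame_range[2] + 1L)
  a <- unclass(movie)[, , fr, drop = FALSE]
  nfr <- length(fr)
  cols <- if (is.null(colormap)) hcl.colors(max(nfr, 2L), "viridis")
          else if (is.function(colormap)) colormap(max(nfr, 2L)) else colormap
  if (length(cols) < nfr) cols <- rep_len(cols, nfr)
  bg <- apply(a, c(1, 2), median)
  if (identical(fg_threshold, "auto")) {
    fg_threshold <- if (nfr > 1L) 3 * mad(a[, , -1, drop = FALSE] - a[, , -nfr, drop = FALSE]) else 0
  }
  fg <- sweep(a, c(1, 2), bg, "-") - fg_threshold
  fg[fg < 0] <- 0
  fgmax <- apply(fg, c(1, 2), max)
  tstar <- apply(fg, c(1, 2), which.max)
  gray <- bg / max(bg, 1)
  rgbk <- col2rgb(cols[seq_len(nfr)]) / 255
  alpha <- fgmax / max(fgmax, .Machine$double.eps)
  if (all(fgmax == 0)) alpha[] <- 0
  out <- array(0, dim = c(dim(gray), 3L))
  for (ch in 1:3) {
    tint <- matrix(rgbk[ch, tstar], nrow(gray), ncol(gray))
    out[, , ch] <- gray * (1 - alpha) + tint * alpha
  }
  out[out > 1] <- 1
  out
}

#' Kymograph along a polyline
#'
#' Samples intensity by bilinear interpolation at unit-pixel steps along the
#' polyline for every frame, averaging `width` transverse samples (unit
#' spacing, centred on the line). Rows are positions along the line,
#' columns are frames.
#'
#' @param movie an `oct_movie`.
#' @param line polyline in pixel coordinates, `k x 2` matrix (columns x, y),
#'   0-based.
#' @param width transverse averaging width in pixels (odd counts centre on
#'   the line; `width = 1` means no transverse averaging).
#' @return a `kymograph`: list with `image` (distance x time), `line`,
#'   `width`, `frame_interval`.
#' @export
compute_kymograph <- function(movie, line, width = 1L) {
  stopifnot(inherits(movie, "oct_movie"))
  line <- as.matrix(line)
  if (ncol(line) != 2L || nrow(line) < 2L) stop("line must be a k x 2 polyline")
  seglen <- sqrt(diff(line[, 1])^2 + diff(line[, 2])^2)
  L <- sum(seglen)
  if (L <= 0) stop("zero-length line")
  n_pos <- max(2L, as.integer(round(L)))
  s <- seq(0, L, length.out = n_pos)
  cum <- c(0, cumsum(seglen))
  seg <- pmin(findInterval(s, cum, rightmost.closed = TRUE), nrow(line) - 1L)
  frac <- (s - cum[seg]) / pmax(seglen[seg], .Machine$double.eps)
  px <- line[seg, 1] + frac * (line[seg + 1L, 1] - line[seg, 1])
  py <- line[seg, 2] + frac * (line[seg + 1L, 2] - line[seg, 2])
  ## unit tangent and normal per sample
  tx <- (line[seg + 1L, 1] - line[seg, 1]) / pmax(seglen[seg], .Machine$double.eps)
  ty <- (line[seg + 1L, 2] - line[seg, 2]) / pmax(seglen[seg], .Machine$double.eps)
  nx <- -ty; ny <- tx
  offs <- seq_len(width) - (width + 1) / 2
  nt <- n_frames(movie)
  img <- matrix(0, n_pos, nt)
  for (f in seq_len(nt)) {
    fr <- movie_frame(movie, f)
    acc <- numeric(n_pos)
    for (o in offs) acc <- acc + bilinear_sample(fr, px + o * nx, py + o * ny)
    img[, f] <- acc / length(offs)
  }
  structure(list(image = img, line = line, width = width,
                 frame_interval = attr(movie, "frame_interval")),
            class = "kymograph")
}

## bilinear interpolation at 0-based pixel coordinates (x = col, y = row);
## pixel centres at (c + 0.5, r + 0.5), border-clamped
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  gx <- pmin(pmax(x - 0.5, 0), nc - 1)
  gy <- pmin(pmax(y - 0.5, 0), nr - 1)
  c0 <- pmin(floor(gx), nc - 2); r0 <- pmin(floor(gy), nr - 2)
  fx <- gx - c0; fy <- gy - r0
  i00 <- cbind(r0 + 1, c0 + 1); i01 <- cbind(r0 + 1, c0 + 2)
  i10 <- cbind(r0 + 2, c0 + 1); i11 <- cbind(r0 + 2, c0 + 2)
  (1 - fy) * ((1 - fx) * img[i00] + fx * img[i01]) +
    fy * ((1 - fx) * img[i10] + fx * img[i11])
}

#' Dominant beat frequency of a kymograph
#'
#' Mean one-sided power spectrum over positions (per-position temporal mean
#' removed), excluding DC. Returns the frequency of the strongest peak, or
#' 0 Hz when that peak is weaker than 3 x the spectral median (the no-beat
#' criterion: "beating stops").
#'
#' @param kymo a `kymograph` with at least 32 frames.
#' @return frequency in Hz.
#' @export
beat_frequency <- function(kymo) {
  stopifnot(inherits(kymo, "kymograph"))
  if (is.null(kymo$frame_interval) || !is.finite(kymo$frame_interval))
    stop("frame_interval unknown")
  img <- kymo$image
  nt <- ncol(img)
  if (nt < 32L) stop("beat_frequency needs at least 32 frames")
  centred <- img - rowMeans(img)
  pw <- abs(t(apply(centred, 1L, fft)))^2
  mean_pw <- colMeans(pw)
  half <- 2:floor(nt / 2 + 1) # one-sided, DC excluded
  spec <- mean_pw[half]
  k <- which.max(spec)
  if (spec[k] <= 3 * median(spec)) return(0) # no-beat criterion (zero spectra included)
  k / (nt * kymo$frame_interval)
}

#' Write an RGB or grayscale image as PNG
#' @param img matrix or `rows x cols x 3` array in [0, 1].
#' @param path PNG path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  img[!is.finite(img)] <- 0
  img <- pmin(pmax(img, 0), 1)
  png::writePNG(img, path)
  invisible(path)
}
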