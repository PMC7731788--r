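## Movie and table I/O. Movies travel as 16-bit multi-page TIFF with a JSON
## calibration sidecar (<stem>.json next to the TIFF); tables as CSV with
## fixed float formatting so reruns are byte-identical.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write a movie as 16-bit multi-page TIFF plus calibration sidecar
#'
#' @param movie an `oct_movie`.
#' @param path output TIFF path; a sidecar JSON
#'   `{pixel_size_um, frame_interval_s}` is written next to it.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "oct_movie"))
  a <- unclass(movie)
  pages <- lapply(seq_len(dim(a)[3]), function(f) a[, , f] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(list(pixel_size_um = attr(movie, "pixel_size"),
                            frame_interval_s = attr(movie, "frame_interval")),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load and validate a movie TIFF
#'
#' Reads a multi-page TIFF and resolves calibration from the JSON sidecar
#' and/or explicit arguments; explicitly supplied values win over the
#' sidecar (with a warning when they conflict).
#'
#' @param path TIFF path.
#' @param pixel_size,frame_interval optional calibration overrides (µm/px, s).
#' @return an `oct_movie` with integer intensities in 0..65535.
#' @export
validate_movie <- function(path, pixel_size = NULL, frame_interval = NULL) {
  if (!file.exists(path)) stop(sprintf("movie file not found: %s", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stop(sprintf("unreadable TIFF '%s': %s", path, conditionMessage(e))))
  if (is.matrix(pages)) pages <- list(pages)
  if (length(pages) < 2L) stop("movie must have at least 2 frames")
  d <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), d), TRUE)))
    stop("movie frames differ in shape")
  side <- list()
  sp <- sidecar_path(path)
  if (file.exists(sp)) side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  resolve <- function(explicit, sidecar_val, what) {
    if (!is.null(explicit)) {
      if (!is.null(sidecar_val) && length(sidecar_val) && !isTRUE(all.equal(explicit, sidecar_val)))
        warning(sprintf("%s: config value %.6g overrides sidecar value %.6g", what, explicit, sidecar_val))
      return(explicit)
    }
    if (!is.null(sidecar_val) && length(sidecar_val)) return(sidecar_val)
    stop(sprintf("missing calibration: %s not in sidecar and not supplied", what))
  }
  ps <- as.numeric(resolve(pixel_size, side$pixel_size_um, "pixel_size"))
  dt <- as.numeric(resolve(frame_interval, side$frame_interval_s, "frame_interval"))
  a <- array(0L, dim = c(d[1], d[2], length(pages)))
  for (f in seq_along(pages)) a[, , f] <- as.integer(pages[[f]])
  as_oct_movie(a, pixel_size = ps, frame_interval = dt)
}

fmt_num <- function(x, digits = 6L) {
  ifelse(is.na(x), "NA", formatC(x, format = "f", digits = digits))
}

## CSV writer with fixed-precision floats (reproducible bytes across runs)
write_table_fixed <- function(df, path, digits = 6L) {
  out <- df
  for (nm in names(out)) if (is.double(out[[nm]])) out[[nm]] <- fmt_num(out[[nm]], digits)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read ground-truth tracks as CSV
#'
#' Columns: `track_id, frame, x_um, y_um, compartment` (frame 0-based).
#'
#' @param gt a `ground_truth` object (or any data frame with those columns).
#' @param path CSV path.
#' @return the path (write) or a data frame (read).
#' @export
write_truth_tracks <- function(gt, path) {
  df <- if (inherits(gt, "ground_truth")) gt$tracks else gt
  write_table_fixed(df[, c("track_id", "frame", "x_um", "y_um", "compartment")], path)
}

#' @rdname write_truth_tracks
#' @export
read_truth_tracks <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' Write tracks in TrackMate-compatible CSV form
#'
#' Columns `TRACK_ID, FRAME, POSITION_X, POSITION_Y, QUALITY` with positions
#' in µm and 0-based frames.
#'
#' @param tracks track table from [build_tracks()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  df <- data.frame(TRACK_ID = tracks$track_id, FRAME = tracks$frame,
                   POSITION_X = tracks$x_um, POSITION_Y = tracks$y_um,
                   QUALITY = tracks$quality)
  write_table_fixed(df, path)
}

#' Read / write a label mask
#'
#' A mask is an integer matrix of region labels (0 = outside). On disk it is
#' either a single-page TIFF of label values or a polygon JSON
#' `{"labels": [{"label": .., "polygon": [[x, y], ...]}], ...}` in µm, which
#' is rasterized against the movie grid.
#'
#' @param path mask file (.tif/.tiff or .json).
#' @param image_shape `(rows, cols)`; required for polygon masks.
#' @param pixel_size µm/px; required for polygon masks.
#' @return list with `labels` (integer matrix) and `names` (label names
#'   indexed by integer value).
#' @export
read_mask <- function(path, image_shape = NULL, pixel_size = NULL) {
  if (!file.exists(path)) stop(sprintf("mask file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    m <- tiff::readTIFF(path, as.is = TRUE)
    if (is.list(m)) m <- m[[1]]
    storage.mode(m) <- "integer"
    vals <- sort(setdiff(unique(as.vector(m)), 0L))
    return(list(labels = m, names = setNames(as.character(vals), vals)))
  }
  if (ext == "json") {
    if (is.null(image_shape) || is.null(pixel_size))
      stop("polygon masks need image_shape and pixel_size to rasterize")
    j <- jsonlite::read_json(path, simplifyVector = FALSE)
    m <- matrix(0L, image_shape[1], image_shape[2])
    nms <- character(0)
    for (k in seq_along(j$labels)) {
      entry <- j$labels[[k]]
      poly <- do.call(rbind, lapply(entry$polygon, function(v) c(v[[1]], v[[2]])))
      m[polygon_mask(poly, image_shape, pixel_size)] <- k
      nms[k] <- entry$label
    }
    return(list(labels = m, names = setNames(nms, seq_along(nms))))
  }
  stop(sprintf("unsupported mask format: .%s", ext))
}

#' Build a label mask from compartment polygons
#'
#' @param compartments list of [compartment_spec()] objects.
#' @param image_shape `(rows, cols)` in px.
#' @param pixel_size µm/px.
#' @return list with `labels` matrix and `names`, as [read_mask()].
#' @export
compartments_mask <- function(compartments, image_shape, pixel_size) {
  m <- matrix(0L, image_shape[1], image_shape[2])
  nms <- character(length(compartments))
  for (k in seq_along(compartments)) {
    m[polygon_mask(compartments[[k]]$region, image_shape, pixel_size)] <- k
    nms[k] <- compartments[[k]]$label
  }
  list(labels = m, names = setNames(nms, seq_along(compartments)))
}

write_mask_json <- function(compartments, path) {
  jsonlite::write_json(
    list(labels = lapply(compartments, function(cp)
      list(label = cp$label, polygon = unname(apply(cp$region, 1L, as.list))))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
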