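## Stage 1b: frame-to-frame linking and gap closing by linear assignment
## ("simple LAP" semantics: no splitting or merging). Costs are squared
## Euclidean distances, pruned at a maximum link distance; every detection
## also has a "no-link" alternative priced at alt_cost_factor times the
## maximum observed allowed cost. The globally cost-minimal partial matching
## is found exactly: the pruned candidate graph is split into connected
## components (valid because alternatives are per-detection) and each
## component's augmented square assignment problem is solved by the compiled
## Jonker-Volgenant solver.

BIG_COST <- 1e12

#' Linking parameters
#'
#' @param max_link_distance maximum frame-to-frame link distance, µm.
#' @param max_gap_frames maximum number of missed frames a closed gap may
#'   span (0 disables gap closing).
#' @param max_gap_distance maximum end-to-start distance across a gap, µm;
#'   must be >= `max_link_distance` when gaps are enabled.
#' @param alt_cost_factor multiplier (> 1) on the maximum observed allowed
#'   cost that prices the no-link alternative.
#' @return a `link_params` list.
#' @export
link_params <- function(max_link_distance, max_gap_frames = 2L,
                        max_gap_distance = max_link_distance,
                        alt_cost_factor = 1.05) {
  stopifnot(max_link_distance > 0, max_gap_frames >= 0, alt_cost_factor > 1)
  if (max_gap_frames > 0 && max_gap_distance < max_link_distance)
    stop("max_gap_distance must be >= max_link_distance when gap closing is enabled")
  structure(list(max_link_distance = max_link_distance,
                 max_gap_frames = as.integer(max_gap_frames),
                 max_gap_distance = max_gap_distance,
                 alt_cost_factor = alt_cost_factor),
            class = "link_params")
}

## Exact minimal-cost partial matching between two point sets.
## cost(i,j) = squared distance, feasible iff distance <= max_dist;
## objective = sum of link costs + alt * (#unmatched points), with
## alt = alt_factor * max feasible cost in the instance.
lap_match <- function(x1, y1, x2, y2, max_dist, alt_factor) {
  n <- length(x1); m <- length(x2)
  if (n == 0L || m == 0L) return(cbind(i = integer(0), j = integer(0)))
  d2 <- outer(x1, x2, "-")^2 + outer(y1, y2, "-")^2
  feas <- d2 <= max_dist^2
  if (!any(feas)) return(cbind(i = integer(0), j = integer(0)))
  alt <- alt_factor * max(d2[feas])
  if (alt <= 0) alt <- alt_factor # all-zero costs: any positive alt ranks links first
  lap_match_masked(d2, feas, alt)
}

#' Link detections between two consecutive frames
#'
#' Solves the pruned rectangular assignment problem exactly: squared
#' Euclidean link costs, candidates pruned at `max_link_distance`, and a
#' per-detection no-link alternative priced at
#' `alt_cost_factor * max(allowed cost)`. Deterministic.
#'
#' @param dets_t,dets_t1 detection data frames (`x_um`, `y_um`) for frames
#'   t and t+1.
#' @param max_link_distance maximum link distance, µm.
#' @param alt_cost_factor no-link alternative multiplier (> 1).
#' @return matrix with columns `i`, `j`: row indices into `dets_t` and
#'   `dets_t1` of the matched pairs.
#' @export
link_frames <- function(dets_t, dets_t1, max_link_distance, alt_cost_factor = 1.05) {
  stopifnot(all(is.finite(dets_t$x_um)), all(is.finite(dets_t1$x_um)))
  lap_match(dets_t$x_um, dets_t$y_um, dets_t1$x_um, dets_t1$y_um,
            max_link_distance, alt_cost_factor)
}

## total objective value of a matching, for cross-checks against enumeration
matching_cost <- function(dets_t, dets_t1, match, max_link_distance, alt_cost_factor = 1.05) {
  d2 <- outer(dets_t$x_um, dets_t1$x_um, "-")^2 + outer(dets_t$y_um, dets_t1$y_um, "-")^2
  feas <- d2 <= max_link_distance^2
  alt <- if (any(feas)) alt_cost_factor * max(d2[feas]) else 0
  link_cost <- if (nrow(match)) sum(d2[match]) else 0
  link_cost + alt * (nrow(dets_t) - nrow(match)) + alt * (nrow(dets_t1) - nrow(match))
}

#' Build trajectories from per-frame detections
#'
#' Frame-to-frame linking over all consecutive frame pairs followed by a
#' gap-closing assignment pass joining track ends to later track starts
#' (frame difference between 2 and `max_gap_frames + 1`, distance at most
#' `max_gap_distance`). Tracks with fewer than 2 detections are dropped.
#' Track ids are renumbered 1..n in order of (first frame, y, x).
#'
#' @param detections data frame `frame, x_um, y_um, quality`, frames 0-based.
#' @param params a [link_params()] object.
#' @return data frame `track_id, frame, x_um, y_um, quality` sorted by
#'   track and frame.
#' @export
build_tracks <- function(detections, params) {
  stopifnot(inherits(params, "link_params"))
  if (!nrow(detections)) return(data.frame(track_id = integer(0), frame = integer(0),
                                           x_um = numeric(0), y_um = numeric(0), quality = numeric(0)))
  det <- detections[order(detections$frame, detections$y_um, detections$x_um), , drop = FALSE]
  rownames(det) <- NULL
  frames <- sort(unique(det$frame))
  det$track <- NA_integer_
  next_id <- 1L
  by_frame <- split(seq_len(nrow(det)), det$frame)

  for (fi in seq_along(frames)) {
    rows_t1 <- by_frame[[as.character(frames[fi])]]
    if (fi == 1L || frames[fi] - frames[fi - 1L] != 1L) {
      det$track[rows_t1] <- seq.int(next_id, length.out = length(rows_t1))
      next_id <- next_id + length(rows_t1)
      next
    }
    rows_t <- by_frame[[as.character(frames[fi - 1L])]]
    m <- link_frames(det[rows_t, ], det[rows_t1, ], params$max_link_distance, params$alt_cost_factor)
    linked_t1 <- logical(length(rows_t1))
    if (nrow(m)) {
      det$track[rows_t1[m[, "j"]]] <- det$track[rows_t[m[, "i"]]]
      linked_t1[m[, "j"]] <- TRUE
    }
    n_new <- sum(!linked_t1)
    det$track[rows_t1[!linked_t1]] <- seq.int(next_id, length.out = n_new)
    next_id <- next_id + n_new
  }

  ## gap closing on track ends/starts
  if (params$max_gap_frames > 0L) {
    ord <- order(det$track, det$frame)
    first_idx <- ord[!duplicated(det$track[ord])]
    last_idx <- rev(ord)[!duplicated(det$track[rev(ord)])]
    starts <- det[first_idx, ]; ends <- det[last_idx, ]
    ## candidates: 2 <= frame diff <= max_gap_frames + 1
    dfr <- outer(ends$frame, starts$frame, function(a, b) b - a)
    d2 <- outer(ends$x_um, starts$x_um, "-")^2 + outer(ends$y_um, starts$y_um, "-")^2
    feas <- dfr >= 2 & dfr <= params$max_gap_frames + 1L & d2 <= params$max_gap_distance^2
    if (any(feas)) {
      alt <- params$alt_cost_factor * max(d2[feas])
      ## reuse lap_match on a masked instance: encode infeasible pairs by
      ## pushing them beyond the distance cutoff is awkward here (the frame
      ## constraint is not metric), so solve components directly
      m <- lap_match_masked(d2, feas, alt)
      if (nrow(m)) {
        ## union ends -> starts; chains are followed transitively
        map <- seq_len(next_id - 1L)
        relabel <- function(id) { while (map[id] != id) id <- map[id]; id }
        ord_gap <- order(ends$frame[m[, 1]])
        for (g in ord_gap) {
          from <- relabel(ends$track[m[g, 1]])
          to <- starts$track[m[g, 2]]
          map[to] <- from
        }
        det$track <- vapply(det$track, relabel, 0L)
      }
    }
  }

  det <- det[order(det$track, det$frame), ]
  keep <- ave(det$track, det$track, FUN = length) >= 2
  det <- det[keep, , drop = FALSE]
  if (!nrow(det)) return(data.frame(track_id = integer(0), frame = integer(0),
                                    x_um = numeric(0), y_um = numeric(0), quality = numeric(0)))
  ## renumber deterministically by (first frame, y, x)
  firsts <- det[!duplicated(det$track), ]
  new_id <- setNames(order(order(firsts$frame, firsts$y_um, firsts$x_um)), firsts$track)
  det$track_id <- new_id[as.character(det$track)]
  out <- det[order(det$track_id, det$frame), c("track_id", "frame", "x_um", "y_um", "quality")]
  rownames(out) <- NULL
  out
}

## assignment with an explicit feasibility mask (non-metric constraints)
lap_match_masked <- function(d2, feas, alt) {
  n <- nrow(d2); m <- ncol(d2)
  if (!any(feas)) return(cbind(i = integer(0), j = integer(0)))
  parent <- seq_len(n + m)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  pairs <- which(feas, arr.ind = TRUE)
  for (p in seq_len(nrow(pairs))) {
    a <- find(pairs[p, 1]); b <- find(n + pairs[p, 2])
    if (a != b) parent[a] <- b
  }
  comp_row <- vapply(seq_len(n), find, 0L)
  comp_col <- vapply(seq_len(m), function(j) find(n + j), 0L)
  links <- vector("list", 0L)
  for (cid in unique(c(comp_row, comp_col))) {
    ri <- which(comp_row == cid); ci <- which(comp_col == cid)
    if (!length(ri) || !length(ci)) next
    if (length(ri) == 1L && length(ci) == 1L) {
      if (feas[ri, ci] && d2[ri, ci] <= 2 * alt) links[[length(links) + 1L]] <- c(ri, ci)
      next
    }
    nr <- length(ri); nc <- length(ci)
    C <- matrix(BIG_COST, nr + nc, nc + nr)
    sub <- d2[ri, ci, drop = FALSE]
    sub[!feas[ri, ci, drop = FALSE]] <- BIG_COST
    C[seq_len(nr), seq_len(nc)] <- sub
    for (a in seq_len(nr)) C[a, nc + a] <- alt
    for (b in seq_len(nc)) C[nr + b, b] <- alt
    lr <- matrix(BIG_COST, nc, nr)
    lr[t(feas[ri, ci, drop = FALSE])] <- 0
    C[nr + seq_len(nc), nc + seq_len(nr)] <- lr
    assign_col <- .lap_solve_dense(C)
    for (a in seq_len(nr)) {
      j <- assign_col[a] + 1L
      if (j <= nc && C[a, j] < BIG_COST) links[[length(links) + 1L]] <- c(ri[a], ci[j])
    }
  }
  if (!length(links)) return(cbind(i = integer(0), j = integer(0)))
  out <- do.call(rbind, links)
  colnames(out) <- c("i", "j")
  out[order(out[, 1]), , drop = FALSE]
}

#' Default maximum link distance from the expected fastest motion
#'
#' Twice the per-frame displacement of the fastest expected speed — a
#' conservative search radius for frame-to-frame linking.
#'
#' @param max_speed fastest expected compartment speed, µm/s.
#' @param frame_interval frame interval, s.
#' @return distance in µm.
#' @export
default_link_distance <- function(max_speed, frame_interval) {
  2 * max_speed * frame_interval
}
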