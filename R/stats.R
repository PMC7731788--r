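## Compartmental summaries and nonparametric group comparisons. Both tests
## use exact conditional distributions at small sample sizes: a sign-flip
## dynamic program over doubled midranks for the Wilcoxon signed-rank test,
## and a rank-sum subset-count dynamic program for the Mann-Whitney test.
## Significance follows the study convention alpha = 0.01.

#' Median speed of a vector set or dense field in a subregion
#'
#' Collects the vectors inside the subregion and returns the median of
#' their Euclidean norms (midpoint convention at even counts). The default
#' source is the dense-field pixels; a table of sparse Stage-2 vectors is
#' accepted as well, in which case per-sample counts reflect data rather
#' than grid resolution.
#'
#' @param x a `dense_field` or a velocity-vector data frame
#'   (`x_um, y_um, vx_um_s, vy_um_s`).
#' @param subregion `NULL` (whole support), a polygon in µm, or a logical
#'   pixel mask (dense fields only).
#' @param region_label label recorded in the report.
#' @return a `speed_report` list: `region_label`, `n_vectors`,
#'   `median_speed` (µm/s).
#' @export
median_speed <- function(x, subregion = NULL, region_label = "ROI") {
  if (inherits(x, "dense_field")) {
    sel <- x$roi_mask
    if (!is.null(subregion)) {
      if (is.matrix(subregion) && is.logical(subregion)) sel <- sel & subregion
      else sel <- sel & polygon_mask(subregion, dim(x$vx), x$pixel_size)
    }
    sp <- x$speed[sel]
    sp <- sp[is.finite(sp)]
  } else {
    stopifnot(is.data.frame(x))
    keep <- rep(TRUE, nrow(x))
    if (!is.null(subregion)) {
      if (is.matrix(subregion) && is.logical(subregion))
        stop("pixel-mask subregions apply to dense fields; give a polygon for sparse vectors")
      keep <- points_in_polygon(subregion, x$x_um, x$y_um)
    }
    sp <- sqrt(x$vx_um_s[keep]^2 + x$vy_um_s[keep]^2)
  }
  if (!length(sp)) stop("empty region: no vectors in subregion")
  structure(list(region_label = region_label, n_vectors = length(sp),
                 median_speed = median(sp)),
            class = "speed_report")
}

#' @export
print.speed_report <- function(x, ...) {
  cat(sprintf("%s: median speed %.4g um/s over %d vectors\n",
              x$region_label, x$median_speed, x$n_vectors))
  invisible(x)
}

#' Cross-sectional area of a labelled region
#'
#' @param mask integer label matrix, or a list as returned by [read_mask()].
#' @param label label to measure (name or integer value).
#' @param pixel_size µm/px.
#' @return an `area_report` list: `region_label`, `pixel_count`, `area`
#'   (µm², equal to `pixel_count * pixel_size^2`).
#' @export
region_area <- function(mask, label, pixel_size) {
  names_map <- NULL
  if (is.list(mask) && !is.null(mask$labels)) { names_map <- mask$names; mask <- mask$labels }
  val <- label
  if (is.character(label) && !is.null(names_map)) {
    hit <- names(names_map)[match(label, names_map)]
    if (is.na(hit)) stop(sprintf("unknown label '%s'", label))
    val <- as.integer(hit)
  }
  val <- suppressWarnings(as.integer(val))
  if (is.na(val)) stop(sprintf("unknown label '%s'", label))
  n <- sum(mask == val)
  if (n == 0L) stop(sprintf("label '%s' not present in mask", as.character(label)))
  structure(list(region_label = as.character(label), pixel_count = n,
                 area = n * pixel_size^2),
            class = "area_report")
}

## Exact distribution of the doubled signed-rank statistic 2*W+ over all
## 2^n sign patterns, by convolution. `ranks2` are doubled midranks
## (integers). Returns probabilities over 0..sum(ranks2).
signed_rank_exact_dist <- function(ranks2) {
  total <- sum(ranks2)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (r in ranks2) {
    g <- f
    g[(r + 1L):(total + 1L)] <- g[(r + 1L):(total + 1L)] + f[1L:(total + 1L - r)]
    f <- g
  }
  f / 2^length(ranks2)
}

#' Paired comparison by the Wilcoxon signed-rank test
#'
#' Exact conditional distribution for n <= 25 informative pairs
#' (zero differences dropped, ties midranked, two-sided p by doubling the
#' smaller tail); normal approximation with tie correction above that.
#' Significance is declared at p < 0.01.
#'
#' @param before,after paired per-sample values (e.g. per-animal
#'   compartment medians), equal lengths >= 5.
#' @return list with `statistic` (W+, rank sum of positive differences),
#'   `p`, `significant`, `n_used` (informative pairs) and `method`.
#' @export
compare_paired <- function(before, after) {
  stopifnot(length(before) == length(after))
  if (length(before) < 5L) stop("paired comparison needs at least 5 pairs")
  d <- after - before
  d <- d[d != 0]
  if (!length(d)) stop("degenerate input: all paired differences are zero")
  n <- length(d)
  r <- rank(abs(d)) # midranks
  W <- sum(r[d > 0])
  if (n <= 25L) {
    ranks2 <- as.integer(round(2 * r))
    dist <- signed_rank_exact_dist(ranks2)
    w2 <- as.integer(round(2 * W))
    lo <- sum(dist[seq_len(w2 + 1L)])            # P(2W+ <= w2)
    hi <- sum(dist[(w2 + 1L):length(dist)])      # P(2W+ >= w2)
    p <- min(1, 2 * min(lo, hi))
    method <- "exact signed-rank (midranks)"
  } else {
    mu <- sum(r) / 2
    sig2 <- sum(r^2) / 4 # midrank-aware variance of W+
    z <- (W - mu) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(statistic = W, p = p, significant = p < 0.01, n_used = n, method = method)
}

## Exact null distribution of the rank sum of group A (size na) when the
## pooled ranks are 1..N with no ties: counts of subsets of each sum.
rank_sum_exact_dist <- function(N, na) {
  smax <- sum((N - na + 1L):N)
  ## f[k+1, s+1] = number of k-subsets of {1..j} with sum s, built j = 1..N
  f <- matrix(0, na + 1L, smax + 1L)
  f[1L, 1L] <- 1
  for (j in seq_len(N)) {
    for (k in min(na, j):1L) {
      smin_k <- sum(seq_len(k - 1L))
      reach <- seq.int(smin_k + j, smax)
      f[k + 1L, reach + 1L] <- f[k + 1L, reach + 1L] + f[k, reach - j + 1L]
    }
  }
  f[na + 1L, ] / choose(N, na)
}

#' Unpaired comparison by the Mann-Whitney U test
#'
#' Two-sided. Exact distribution when both groups have at most 10
#' observations and there are no ties; otherwise the normal approximation
#' with tie correction and continuity correction. Significance at p < 0.01.
#'
#' @param group_a,group_b numeric samples, each of size >= 3.
#' @return list with `U` (Mann-Whitney U of `group_a`), `p`, `significant`
#'   and `method`.
#' @export
compare_unpaired <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 3L || nb < 3L) stop("each group needs at least 3 observations")
  if (!all(is.finite(c(group_a, group_b)))) stop("non-finite values")
  pooled <- c(group_a, group_b)
  r <- rank(pooled)
  Ra <- sum(r[seq_len(na)])
  U <- Ra - na * (na + 1) / 2
  ties <- any(duplicated(pooled))
  if (!ties && na <= 10L && nb <= 10L) {
    dist <- rank_sum_exact_dist(na + nb, na)
    ra <- as.integer(round(Ra))
    lo <- sum(dist[seq_len(ra + 1L)])
    hi <- sum(dist[(ra + 1L):length(dist)])
    p <- min(1, 2 * min(lo, hi))
    method <- "exact rank-sum"
  } else {
    N <- na + nb
    mu <- na * nb / 2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sig2 <- na * nb / 12 * ((N + 1) - tie_term)
    if (sig2 <= 0) return(list(U = U, p = 1, significant = FALSE,
                               method = "normal approximation (all tied)"))
    z <- (abs(U - mu) - 0.5) / sqrt(sig2)
    z <- max(z, 0)
    p <- 2 * pnorm(-z)
    p <- min(1, p)
    method <- "normal approximation with tie correction"
  }
  list(U = U, p = p, significant = p < 0.01, method = method)
}
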