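## Stage 3: dense velocity field by Gaussian process regression. Each
## velocity component is a scalar GP over 2D position with an isotropic
## squared-exponential kernel, a constant mean basis (the weighted mean of
## the observations) and heteroscedastic noise: observation i has noise
## variance noise_var / weight_i. Hyperparameters are either supplied or
## selected by maximizing the log marginal likelihood with a seeded
## multi-start quasi-Newton search.

se_kernel <- function(D2, lengthscale, signal_var) signal_var * exp(-D2 / (2 * lengthscale^2))

cross_dist2 <- function(A, B) {
  ## squared Euclidean distances between rows of A (n x 2) and B (m x 2)
  outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2
}

gp_lml <- function(log_par, X, y, w, D2) {
  ls <- exp(log_par[1]); sf2 <- exp(2 * log_par[2]); sn2 <- exp(2 * log_par[3])
  n <- length(y)
  K <- se_kernel(D2, ls, sf2)
  diag(K) <- diag(K) + sn2 / w + 1e-10 * sf2
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  alpha <- backsolve(L, forwardsolve(t(L), y))
  0.5 * sum(y * alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
}

#' Fit a Gaussian-process regressor to one velocity component
#'
#' @param vectors velocity-vector table from [collect_vectors()] (needs
#'   `x_um`, `y_um`, the component column, and `weight`).
#' @param component `"vx"` or `"vy"` (columns `vx_um_s` / `vy_um_s`).
#' @param kernel_params `NULL` for automatic selection, or a list with
#'   `lengthscale` (µm), `signal_sd` (µm/s) and `noise_sd` (µm/s).
#' @param restarts number of seeded optimizer restarts for automatic
#'   hyperparameter selection.
#' @param seed integer seed controlling the restarts and any subsampling.
#' @param n_max_fit maximum observations used for hyperparameter selection
#'   (seeded subsample above this).
#' @param n_max_condition maximum observations the predictor conditions on
#'   (seeded subsample above this; exact GP cost is cubic).
#' @return a `gpr_predictor`: call `predict(p, Xq)` with query positions
#'   (µm, `m x 2`) to get a data frame `mean`, `sd`.
#' @export
fit_gpr_component <- function(vectors, component = c("vx", "vy"),
                              kernel_params = NULL, restarts = 3L, seed = 1L,
                              n_max_fit = 400L, n_max_condition = 2000L) {
  component <- match.arg(component)
  col <- if (component == "vx") "vx_um_s" else "vy_um_s"
  X <- cbind(vectors$x_um, vectors$y_um)
  y <- vectors[[col]]
  w <- if (!is.null(vectors$weight)) vectors$weight else rep(1, length(y))
  if (length(y) < 5L) stop("insufficient data: GPR needs at least 5 vectors")
  if (!all(is.finite(X)) || !all(is.finite(y)) || !all(is.finite(w)) || any(w <= 0))
    stop("non-finite positions, values or weights")

  ## seeded subsample for conditioning if needed
  if (length(y) > n_max_condition) {
    idx <- withr_seed_sample(seed, length(y), n_max_condition)
    X <- X[idx, , drop = FALSE]; y <- y[idx]; w <- w[idx]
  }

  beta <- sum(w * y) / sum(w) # constant mean basis
  r <- y - beta

  if (is.null(kernel_params)) {
    fit_idx <- if (length(r) > n_max_fit) withr_seed_sample(seed + 1L, length(r), n_max_fit) else seq_along(r)
    Xf <- X[fit_idx, , drop = FALSE]; rf <- r[fit_idx]; wf <- w[fit_idx]
    D2f <- cross_dist2(Xf, Xf)
    span <- max(sqrt(max(D2f)), .Machine$double.eps)
    s_r <- max(sd(rf), 1e-8)
    med_d <- sqrt(median(D2f[upper.tri(D2f)]))
    starts <- list(c(log(med_d / 2), log(s_r), log(s_r / 2)),
                   c(log(med_d), log(s_r), log(s_r / 10)),
                   c(log(med_d / 4), log(s_r * 2), log(s_r)))
    starts <- starts[seq_len(min(restarts, length(starts)))]
    lower <- c(log(span * 0.02), log(s_r * 1e-3), log(s_r * 1e-3))
    upper <- c(log(span * 5), log(s_r * 1e3), log(s_r * 10))
    best <- NULL
    for (s0 in starts) {
      s0 <- pmin(pmax(s0, lower), upper)
      o <- tryCatch(optim(s0, gp_lml, X = Xf, y = rf, w = wf, D2 = D2f,
                          method = "L-BFGS-B", lower = lower, upper = upper,
                          control = list(maxit = 60)),
                    error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) stop("hyperparameter optimization failed")
    kernel_params <- list(lengthscale = exp(best$par[1]),
                          signal_sd = exp(best$par[2]),
                          noise_sd = exp(best$par[3]))
  }
  ls <- kernel_params$lengthscale; sf2 <- kernel_params$signal_sd^2
  sn2 <- kernel_params$noise_sd^2
  K <- se_kernel(cross_dist2(X, X), ls, sf2)
  diag(K) <- diag(K) + sn2 / w + 1e-10 * max(sf2, 1e-12)
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), r))
  structure(list(X = X, L = L, alpha = alpha, beta = beta,
                 lengthscale = ls, signal_var = sf2, noise_var = sn2,
                 component = component, n_obs = length(y)),
            class = "gpr_predictor")
}

#' @export
print.gpr_predictor <- function(x, ...) {
  cat(sprintf("gpr_predictor (%s): n = %d, lengthscale = %.4g um, signal sd = %.4g, noise sd = %.4g um/s\n",
              x$component, x$n_obs, x$lengthscale, sqrt(x$signal_var), sqrt(x$noise_var)))
  invisible(x)
}

#' Posterior mean and sd of a fitted GP component
#'
#' @param object a `gpr_predictor`.
#' @param newdata query positions, `m x 2` matrix (µm).
#' @param ... unused.
#' @return data frame with columns `mean` and `sd` (µm/s). The sd is the
#'   posterior standard deviation of the latent field (estimate
#'   uncertainty), without the observation-noise term.
#' @export
predict.gpr_predictor <- function(object, newdata, ...) {
  Xq <- as.matrix(newdata)
  stopifnot(ncol(Xq) == 2L)
  Ks <- se_kernel(cross_dist2(Xq, object$X), object$lengthscale, object$signal_var)
  mu <- object$beta + as.vector(Ks %*% object$alpha)
  v <- forwardsolve(t(object$L), t(Ks))
  var_post <- pmax(object$signal_var - colSums(v^2), 0)
  data.frame(mean = mu, sd = sqrt(var_post))
}

#' Evaluate both GP components on every masked pixel
#'
#' @param predictor_vx,predictor_vy fitted `gpr_predictor`s for the two
#'   velocity components.
#' @param roi_mask logical matrix; pixels outside are left `NA`.
#' @param pixel_size µm/px.
#' @param chunk pixels per prediction block (memory control).
#' @return a `dense_field`: list of matrices `vx`, `vy`, `sd_vx`, `sd_vy`,
#'   `speed` (µm/s, `NA` off-mask), the mask, pixel size and both
#'   components' hyperparameters.
#' @export
predict_field <- function(predictor_vx, predictor_vy, roi_mask, pixel_size, chunk = 4000L) {
  stopifnot(inherits(predictor_vx, "gpr_predictor"), inherits(predictor_vy, "gpr_predictor"))
  if (!any(roi_mask)) stop("empty ROI mask")
  nr <- nrow(roi_mask); nc <- ncol(roi_mask)
  idx <- which(roi_mask, arr.ind = TRUE)
  qx <- (idx[, 2] - 0.5) * pixel_size
  qy <- (idx[, 1] - 0.5) * pixel_size
  n <- nrow(idx)
  mvx <- svx <- mvy <- svy <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    Q <- cbind(qx[s:e], qy[s:e])
    px <- predict(predictor_vx, Q)
    py <- predict(predictor_vy, Q)
    mvx[s:e] <- px$mean; svx[s:e] <- px$sd
    mvy[s:e] <- py$mean; svy[s:e] <- py$sd
  }
  blank <- matrix(NA_real_, nr, nc)
  vx <- vy <- sdx <- sdy <- blank
  vx[idx] <- mvx; vy[idx] <- mvy; sdx[idx] <- svx; sdy[idx] <- svy
  speed <- sqrt(vx^2 + vy^2)
  structure(list(vx = vx, vy = vy, sd_vx = sdx, sd_vy = sdy, speed = speed,
                 roi_mask = roi_mask, pixel_size = pixel_size,
                 hyperparams = list(
                   vx = list(lengthscale = predictor_vx$lengthscale,
                             signal_sd = sqrt(predictor_vx$signal_var),
                             noise_sd = sqrt(predictor_vx$noise_var)),
                   vy = list(lengthscale = predictor_vy$lengthscale,
                             signal_sd = sqrt(predictor_vy$signal_var),
                             noise_sd = sqrt(predictor_vy$noise_var)))),
            class = "dense_field")
}

#' @export
print.dense_field <- function(x, ...) {
  cat(sprintf("dense_field: %d x %d px, %d masked pixels, median speed %.3g um/s\n",
              nrow(x$vx), ncol(x$vx), sum(x$roi_mask),
              median(x$speed[x$roi_mask])))
  invisible(x)
}

## seeded subsample that does not disturb the caller's RNG stream
withr_seed_sample <- function(seed, n, size) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  sort(sample.int(n, size))
}
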