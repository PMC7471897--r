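# Attenuation density curves, the log-quantile-density (LQD) transform, and
# functional PCA of the cohort's LQD curves.
#
# A nodule's HU histogram is smoothed into a density f on an HU grid. The
# LQD representation psi(t) = -log f(Q(t)) on t in [0,1] (Q the quantile
# function) maps densities into an unconstrained function space where
# ordinary functional PCA applies; scores on the first two components are
# the FPC1/FPC2 features.

#' Attenuation density curve
#'
#' Validating constructor: strictly increasing HU grid, strictly positive
#' density (apply a floor before calling if needed), trapezoid integral 1
#' (renormalized by default, checked to 1e-6 otherwise).
#'
#' @param hu_grid increasing numeric grid (HU).
#' @param density positive values of the same length.
#' @param renormalize divide by the trapezoid integral first?
#' @return object of class `attenuation_curve` with elements `hu_grid`,
#'   `density`.
#' @export
attenuation_curve <- function(hu_grid, density, renormalize = TRUE) {
  hu_grid <- as.numeric(hu_grid)
  density <- as.numeric(density)
  if (length(hu_grid) != length(density) || length(hu_grid) < 2L)
    stop("hu_grid and density must be equal-length vectors (>= 2)")
  if (any(diff(hu_grid) <= 0)) stop("hu_grid must be strictly increasing")
  if (any(!is.finite(density)) || any(density <= 0))
    stop("density must be strictly positive and finite; apply a floor first")
  I <- .trapz(hu_grid, density)
  if (renormalize) density <- density / I
  else if (abs(I - 1) > 1e-6)
    stop("density does not integrate to 1 (trapezoid integral = ", format(I), ")")
  structure(list(hu_grid = hu_grid, density = density),
            class = "attenuation_curve")
}

#' Smooth a nodule HU sample or histogram into a density curve
#'
#' Gaussian-kernel density estimate on a 1-HU grid spanning `hu_range`,
#' floored at `floor_delta` and renormalized, so that the LQD transform is
#' finite everywhere. Bandwidth `"auto"` is Silverman's rule
#' ([stats::bw.nrd0()]) on the HU sample.
#'
#' @param hu numeric HU vector (>= 10 values) or `(hu_bin_left, count)`
#'   histogram data frame (bin midpoints are used).
#' @param bandwidth positive bandwidth in HU, or `"auto"`.
#' @param hu_range grid span; values outside are an error.
#' @param floor_delta density floor per HU before renormalization.
#' @return an [attenuation_curve()].
#' @export
histogram_to_density <- function(hu, bandwidth = "auto",
                                 hu_range = c(-1024, 400),
                                 floor_delta = 1e-6) {
  if (is.data.frame(hu)) hu <- .expand_histogram(hu)
  hu <- as.numeric(hu)
  if (length(hu) < 10L) stop("need at least 10 HU values to smooth")
  if (any(hu < hu_range[1] | hu > hu_range[2]))
    stop("HU values outside [", hu_range[1], ", ", hu_range[2], "]")
  if (var(hu) == 0)
    stop("all HU values identical: zero-variance density unsupported ",
         "(consider adding +/-0.5 HU jitter)")
  bw <- if (identical(bandwidth, "auto")) bw.nrd0(hu) else as.numeric(bandwidth)
  if (!is.finite(bw) || bw <= 0) stop("bandwidth must be positive")
  grid <- seq(hu_range[1], hu_range[2], by = 1)
  kd <- density(hu, bw = bw, from = hu_range[1], to = hu_range[2],
                n = length(grid))
  f <- pmax(kd$y, floor_delta)
  attenuation_curve(grid, f, renormalize = TRUE)
}

#' Log-quantile-density transform of a density curve
#'
#' Computes `psi(t) = -log f(Q(t))` on an equally spaced `t` grid, with the
#' quantile function `Q` obtained by numerically inverting the trapezoid
#' CDF of the curve. The strictly positive density guarantees a strictly
#' increasing CDF, hence a finite psi.
#'
#' @param curve an [attenuation_curve()].
#' @param t_grid probability grid (default 101 points 0, 0.01, ..., 1).
#' @return object of class `lqd_curve` with `t_grid`, `lqd` and the support
#'   start `q0 = Q(0)` (needed to invert the transform).
#' @export
lqd_transform <- function(curve, t_grid = seq(0, 1, by = 0.01)) {
  stopifnot(inherits(curve, "attenuation_curve"))
  x <- curve$hu_grid
  f <- curve$density
  I <- .trapz(x, f)
  if (abs(I - 1) > 1e-6) stop("density does not integrate to 1")
  cdf <- .cumtrapz(x, f)
  cdf <- cdf / cdf[length(cdf)]
  Q <- approx(cdf, x, xout = t_grid, ties = "ordered", rule = 2)$y
  fq <- approx(x, f, xout = Q, rule = 2)$y
  structure(list(t_grid = t_grid, lqd = -log(fq), q0 = Q[1]),
            class = "lqd_curve")
}

#' Invert the log-quantile-density transform
#'
#' Reconstructs the density from psi: the quantile function is
#' `Q(t) = q0 + integral of exp(psi)` and the density at `Q(t)` is
#' `exp(-psi(t))`.
#'
#' @param lqd an `lqd_curve` (or a list with `t_grid`, `lqd`, `q0`).
#' @return list with `hu` (the reconstructed quantile positions) and
#'   `density` at those positions.
#' @export
lqd_inverse <- function(lqd) {
  t <- lqd$t_grid
  # integrate the quantile density exp(psi) on a spline-refined grid: exp(psi)
  # varies over orders of magnitude, so trapezoid steps at the psi resolution
  # lose accuracy
  fine <- seq(min(t), max(t), length.out = 20L * (length(t) - 1L) + 1L)
  qd <- exp(stats::spline(t, lqd$lqd, xout = fine)$y)
  Qf <- lqd$q0 + .cumtrapz(fine, qd)
  Q <- approx(fine, Qf, xout = t)$y
  list(hu = Q, density = exp(-lqd$lqd))
}

# Stack lqd curves (list of lqd_curve or a matrix) into an n x m matrix and
# check the common t grid.
.lqd_matrix <- function(curves, t_grid = NULL) {
  if (is.matrix(curves)) {
    if (!is.null(t_grid) && ncol(curves) != length(t_grid))
      stop("grid mismatch: curve length differs from model t_grid")
    return(curves)
  }
  if (inherits(curves, "lqd_curve")) curves <- list(curves)
  tg <- curves[[1]]$t_grid
  if (!is.null(t_grid) &&
      (length(tg) != length(t_grid) || max(abs(tg - t_grid)) > 1e-12))
    stop("grid mismatch: curves are not on the model t_grid")
  for (cu in curves)
    if (length(cu$t_grid) != length(tg) || max(abs(cu$t_grid - tg)) > 1e-12)
      stop("grid mismatch: curves are on different t grids")
  t(vapply(curves, function(cu) cu$lqd, numeric(length(tg))))
}

#' Functional PCA of log-quantile-density curves
#'
#' Eigendecomposition of the sample covariance operator discretized with
#' trapezoid quadrature weights. Eigenfunctions are orthonormal under the
#' weighted inner product; variance fractions are eigenvalues over the total
#' trace. The sign of each component is fixed so that its score vector
#' correlates positively with `q875` when supplied (the clinical direction:
#' high scores = heterogeneous, high-attenuation curves), falling back to a
#' positive integral of the eigenfunction on t in [0.75, 1].
#'
#' @param curves list of [lqd_transform()] results on a common grid, or an
#'   `n x m` matrix of LQD values.
#' @param K number of components to retain (default 2).
#' @param q875 optional per-curve Q.875 feature used for sign fixing.
#' @param t_grid required when `curves` is a matrix.
#' @return object of class `fpca_model`: `t_grid`, `mean_lqd`,
#'   `eigenfunctions` (m x K), `eigenvalues` (length K, non-increasing),
#'   `variance_fraction`, `total_variance` and the centered training
#'   `scores` (n x K).
#' @export
fit_fpca <- function(curves, K = 2L, q875 = NULL, t_grid = NULL) {
  L <- .lqd_matrix(curves, t_grid)
  if (is.null(t_grid))
    t_grid <- if (is.matrix(curves)) seq(0, 1, length.out = ncol(L))
              else curves[[1]]$t_grid
  n <- nrow(L)
  if (n < K + 1) stop("need at least K + 1 curves")
  w <- .trapz_weights(t_grid)
  mu <- colMeans(L)
  C <- sweep(L, 2, mu)
  Sig <- crossprod(C) / (n - 1)
  sw <- sqrt(w)
  e <- eigen(Sig * outer(sw, sw), symmetric = TRUE)
  lam <- pmax(e$values, 0)
  total <- sum(lam)
  if (total > 0) {
    avail <- sum(lam > lam[1] * 1e-10)
    if (K > avail)
      stop("K = ", K, " exceeds the available rank (", avail, ")")
  }
  phi <- e$vectors[, seq_len(K), drop = FALSE] / sw
  scores <- C %*% (w * phi)
  for (k in seq_len(K)) {
    s <- scores[, k]
    ref <- NA_real_
    if (!is.null(q875) && stats::sd(s) > 0 && stats::sd(q875) > 0)
      ref <- cor(s, q875)
    if (!is.finite(ref) || ref == 0)
      ref <- sum((w * phi[, k])[t_grid >= 0.75])
    if (is.finite(ref) && ref < 0) {
      phi[, k] <- -phi[, k]
      scores[, k] <- -scores[, k]
    }
  }
  colnames(scores) <- colnames(phi) <- paste0("FPC", seq_len(K))
  structure(list(t_grid = t_grid, mean_lqd = mu,
                 eigenfunctions = phi,
                 eigenvalues = lam[seq_len(K)],
                 variance_fraction = if (total > 0) lam[seq_len(K)] / total
                                     else rep(0, K),
                 total_variance = total,
                 scores = scores),
            class = "fpca_model")
}

#' Project LQD curves onto a fitted FPCA basis
#'
#' Score k is the quadrature inner product of the centered curve with
#' eigenfunction k; projecting the model mean gives all-zero scores.
#'
#' @param model an [fit_fpca()] result.
#' @param curves `lqd_curve`, list of them, or an LQD matrix on the model
#'   grid (grid mismatch is an error).
#' @return numeric matrix of scores (n x K).
#' @export
project_fpca <- function(model, curves) {
  stopifnot(inherits(model, "fpca_model"))
  L <- .lqd_matrix(curves, model$t_grid)
  w <- .trapz_weights(model$t_grid)
  S <- sweep(L, 2, model$mean_lqd) %*% (w * model$eigenfunctions)
  colnames(S) <- colnames(model$eigenfunctions)
  S
}

#' Append FPC scores to a cohort feature table
#'
#' Smooths each nodule's HU values into a density, maps to LQD space, fits
#' the cohort FPCA (sign-fixed against the table's `q875_hu` column when
#' present) and appends the scores as `FPC1`, `FPC2`, ...
#'
#' @param features cohort feature table (one row per nodule).
#' @param hu_list list of per-nodule HU vectors (or histogram data frames),
#'   same order/length as `features`.
#' @param K number of components (default 2).
#' @param bandwidth passed to [histogram_to_density()].
#' @return list with the augmented `features` table and the `model`.
#' @export
add_fpc_scores <- function(features, hu_list, K = 2L, bandwidth = "auto") {
  if (length(hu_list) != nrow(features))
    stop("hu_list length must match the feature table")
  curves <- lapply(hu_list, function(h)
    lqd_transform(histogram_to_density(h, bandwidth = bandwidth)))
  model <- fit_fpca(curves, K = K, q875 = features$q875_hu)
  for (k in seq_len(K)) features[[paste0("FPC", k)]] <- model$scores[, k]
  list(features = features, model = model)
}

#' Serialize an FPCA model to JSON
#'
#' @param model an `fpca_model`.
#' @param path output file.
#' @export
write_fpca_model <- function(model, path) {
  jsonlite::write_json(
    list(t_grid = model$t_grid, mean_lqd = model$mean_lqd,
         eigenfunctions = model$eigenfunctions,
         eigenvalues = model$eigenvalues,
         variance_fraction = model$variance_fraction),
    path, digits = NA)
  invisible(path)
}
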