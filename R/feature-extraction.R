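# First-order CT features of a segmented nodule: geometry from the binary
# mask, attenuation statistics from the in-mask HU values (or from a
# precomputed HU histogram).

# In-mask voxel centers in mm (n x 3), array-order.
.mask_points_mm <- function(mask, spacing_mm) {
  idx <- which(mask, arr.ind = TRUE)
  sweep(idx, 2, spacing_mm, `*`)
}

# Voxels with at least one 6-neighbour outside the mask (or on the array
# boundary). The max-distance pair of a voxel set lies on this surface, so
# the pairwise search can be restricted to it.
.surface_mask <- function(mask) {
  d <- dim(mask)
  nb <- array(0L, d)
  shift_add <- function(nb, axis, by) {
    src <- dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    n <- d[axis]
    if (by > 0) { dst[[axis]] <- 2:n;       src[[axis]] <- 1:(n - 1) }
    else        { dst[[axis]] <- 1:(n - 1); src[[axis]] <- 2:n }
    add <- array(0L, d)
    add[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
    nb + add
  }
  for (axis in 1:3) for (by in c(-1L, 1L)) nb <- shift_add(nb, axis, by)
  mask & nb < 6L
}

# Exact maximum pairwise Euclidean distance, chunked to bound memory.
.max_pairwise_dist <- function(P) {
  n <- nrow(P)
  if (n < 2L) return(0)
  sq <- rowSums(P^2)
  best <- 0
  chunk <- 512L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    D2 <- outer(sq[s:e], sq, `+`) - 2 * tcrossprod(P[s:e, , drop = FALSE], P)
    m <- max(D2)
    if (m > best) best <- m
  }
  sqrt(max(best, 0))
}

# Smallest extent of the PCA-aligned bounding box of the voxel centers.
.min_pca_extent <- function(P) {
  Pc <- sweep(P, 2, colMeans(P))
  ev <- eigen(crossprod(Pc) / max(1, nrow(P) - 1), symmetric = TRUE)$vectors
  proj <- Pc %*% ev
  min(apply(proj, 2, function(z) diff(range(z))))
}

#' Geometric features of a segmented nodule
#'
#' Volume is voxel count times voxel volume; the maximum diameter is the
#' largest pairwise distance between in-mask voxel centers in 3-D; the
#' minimum diameter is the smallest axis of the PCA-aligned bounding box of
#' the voxel centers. `volume_log` is the base-10 logarithm of the volume,
#' and the consolidation ratio is the solid-component maximum diameter over
#' the nodule maximum diameter.
#'
#' @param mask 3-D logical (or 0/1) array with at least 8 `TRUE` voxels.
#' @param spacing_mm positive voxel edge lengths (mm), length 3.
#' @param solid_diameter_mm solid-component maximum diameter (0 for a
#'   non-solid nodule); must not exceed the nodule maximum diameter.
#' @return list of class `geometric_features` with elements
#'   `min_diameter_mm`, `max_diameter_mm`, `average_diameter_mm`,
#'   `maxmin_ratio`, `consolidation_ratio`, `volume_mm3`, `volume_log`.
#' @export
compute_geometric_features <- function(mask, spacing_mm,
                                       solid_diameter_mm = 0) {
  if (length(dim(mask)) != 3L) stop("mask must be a 3-D array")
  if (any(spacing_mm <= 0) || length(spacing_mm) != 3L)
    stop("spacing_mm must be 3 positive lengths")
  mask <- mask > 0
  nv <- sum(mask)
  if (nv == 0L) stop("empty mask")
  if (nv < 8L) stop("mask must contain at least 8 voxels")
  if (solid_diameter_mm < 0) stop("solid_diameter_mm must be non-negative")
  volume <- nv * prod(spacing_mm)
  P <- .mask_points_mm(mask, spacing_mm)
  S <- .mask_points_mm(.surface_mask(mask), spacing_mm)
  maxd <- .max_pairwise_dist(S)
  mind <- .min_pca_extent(P)
  if (solid_diameter_mm > maxd + 1e-9)
    stop("inconsistent input: solid diameter exceeds nodule maximum diameter")
  structure(list(min_diameter_mm = mind,
                 max_diameter_mm = maxd,
                 average_diameter_mm = (mind + maxd) / 2,
                 maxmin_ratio = maxd / mind,
                 consolidation_ratio = solid_diameter_mm / maxd,
                 volume_mm3 = volume,
                 volume_log = log10(volume)),
            class = "geometric_features")
}

# Expand a (hu_bin_left, count) histogram to bin-midpoint pseudo-samples.
.expand_histogram <- function(h) {
  if (!all(c("hu_bin_left", "count") %in% names(h)))
    stop("histogram must have columns hu_bin_left and count")
  left <- h$hu_bin_left
  width <- if (length(left) > 1) min(diff(sort(unique(left)))) else 1
  rep(left + width / 2, h$count)
}

#' First-order attenuation features from nodule HU values
#'
#' Sample moments (skewness `m3/m2^1.5`, non-excess kurtosis `m4/m2^2`, so a
#' normal sample sits near 3) and linear-interpolation quantiles at
#' probabilities `(k-1)/(n-1)` (R type 7). Accepts either the raw voxel HU
#' vector or a `(hu_bin_left, count)` histogram, in which case bin midpoints
#' weighted by counts are used.
#'
#' @param hu numeric HU vector (length >= 4) or histogram data frame.
#' @return list of class `attenuation_features` with `mean_hu`, `sd_hu`,
#'   `skewness`, `kurtosis`, `q50_hu`, `q75_hu`, `q875_hu`, `iqr_hu`.
#'   Skewness/kurtosis are `NaN` for a zero-variance sample.
#' @export
compute_attenuation_features <- function(hu) {
  if (is.data.frame(hu)) hu <- .expand_histogram(hu)
  hu <- as.numeric(hu)
  if (length(hu) < 4L)
    stop("need at least 4 HU values (kurtosis undefined below that)")
  n <- length(hu)
  m <- mean(hu)
  d <- hu - m
  m2 <- mean(d^2)
  skew <- if (m2 > 0) mean(d^3) / m2^1.5 else NaN
  kurt <- if (m2 > 0) mean(d^4) / m2^2 else NaN
  q <- quantile(hu, c(0.25, 0.5, 0.75, 0.875), type = 7, names = FALSE)
  structure(list(mean_hu = m, sd_hu = sd(hu),
                 skewness = skew, kurtosis = kurt,
                 q50_hu = q[2], q75_hu = q[3], q875_hu = q[4],
                 iqr_hu = q[3] - q[1]),
            class = "attenuation_features")
}

#' Cohort feature table
#'
#' Computes the geometric and attenuation features for every nodule of a
#' cohort and assembles the analysis table (one row per nodule, plus the
#' ordinal `class` column).
#'
#' @param cohort a `nodule_cohort` (list of [nodule_sample()]s).
#' @return data frame with one row per nodule.
#' @export
extract_cohort_features <- function(cohort) {
  rows <- lapply(seq_along(cohort), function(i) {
    s <- cohort[[i]]
    if (is.null(s$mask))
      stop("nodule ", i, " has no mask; geometric features need one")
    g <- compute_geometric_features(s$mask, s$spacing_mm, s$solid_diameter_mm)
    a <- compute_attenuation_features(s$hu_values)
    data.frame(nodule_id = i,
               class = as.character(s$class_label),
               min_diameter_mm = g$min_diameter_mm,
               max_diameter_mm = g$max_diameter_mm,
               average_diameter_mm = g$average_diameter_mm,
               maxmin_ratio = g$maxmin_ratio,
               consolidation_ratio = g$consolidation_ratio,
               volume_mm3 = g$volume_mm3,
               volume_log = g$volume_log,
               mean_hu = a$mean_hu, sd_hu = a$sd_hu,
               skewness = a$skewness, kurtosis = a$kurtosis,
               iqr_hu = a$iqr_hu, q50_hu = a$q50_hu,
               q75_hu = a$q75_hu, q875_hu = a$q875_hu)
  })
  out <- do.call(rbind, rows)
  out$class <- factor(out$class, levels = c("H1", "H2", "H3"), ordered = TRUE)
  out
}
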