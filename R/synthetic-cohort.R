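# Synthetic nodule cohorts.
#
# Two generators: a mechanistic one that emulates the voxel-level structure
# the analysis assumes (class-conditional lognormal volumes, two-component
# ground-glass/solid HU mixtures with class-increasing solid fraction,
# ellipsoidal masks), and a direct proportional-odds generator with known
# coefficients for parameter-recovery and calibration studies.

#' Configuration for the mechanistic synthetic nodule cohort
#'
#' Defaults encode the cohort the generator emulates: 31/64/132 nodules in
#' invasiveness classes H1/H2/H3, class-median volumes 1362/1297/3436 mm^3
#' with a lognormal (base-10) spread of 0.46, and a two-component HU mixture
#' (ground-glass N(-700, 60^2), solid N(-100, 80^2), truncated to
#' [-1024, 400]) whose solid fraction increases with class.
#'
#' @param n_per_class integer vector of length 3: nodule counts for H1, H2, H3.
#' @param volume_median_mm3 per-class median nodule volume in mm^3.
#' @param volume_log_sd standard deviation of log10(volume).
#' @param gg_mean_hu,gg_sd_hu mean/sd (HU) of the ground-glass component.
#' @param solid_mean_hu,solid_sd_hu mean/sd (HU) of the solid component.
#' @param solid_fraction_range 3 x 2 matrix of per-class `[lo, hi]` intervals
#'   for the solid voxel fraction; interval midpoints must be non-decreasing
#'   across classes.
#' @param volume_solid_cor latent Gaussian correlation between nodule volume
#'   and solid fraction within a class (default 0.3).
#' @param maxmin_ratio_range range of the ellipsoid max/min axis ratio.
#' @param voxel_spacing_mm voxel edge lengths (mm), length 3.
#' @param seed integer RNG seed; one stream drives the whole cohort.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_class = c(H1 = 31L, H2 = 64L, H3 = 132L),
                          volume_median_mm3 = c(1362, 1297, 3436),
                          volume_log_sd = 0.46,
                          gg_mean_hu = -700, gg_sd_hu = 60,
                          solid_mean_hu = -100, solid_sd_hu = 80,
                          solid_fraction_range = rbind(H1 = c(0, 0.17),
                                                       H2 = c(0.10, 0.34),
                                                       H3 = c(0.25, 0.65)),
                          volume_solid_cor = 0.3,
                          maxmin_ratio_range = c(1.2, 1.9),
                          voxel_spacing_mm = c(0.7, 0.7, 1.0),
                          seed = 1L) {
  n_per_class <- as.integer(n_per_class)
  if (length(n_per_class) != 3L || any(n_per_class < 0L))
    stop("configuration error: n_per_class must be 3 non-negative counts")
  if (length(volume_median_mm3) != 3L || any(volume_median_mm3 <= 0))
    stop("configuration error: volume medians must be positive")
  if (volume_log_sd <= 0) stop("configuration error: volume_log_sd must be positive")
  sfr <- matrix(as.numeric(solid_fraction_range), 3L, 2L)
  if (any(sfr < 0) || any(sfr > 1) || any(sfr[, 1] > sfr[, 2]))
    stop("configuration error: solid_fraction_range intervals must lie in [0,1]")
  mids <- rowMeans(sfr)
  if (is.unsorted(mids))
    stop("configuration error: solid-fraction midpoints must be class-ordered H1 <= H2 <= H3")
  for (v in c(gg_mean_hu, solid_mean_hu))
    if (v < -1024 || v > 400)
      stop("configuration error: component mean HU outside [-1024, 400]")
  if (gg_sd_hu <= 0 || solid_sd_hu <= 0)
    stop("configuration error: HU component sds must be positive")
  if (abs(volume_solid_cor) >= 1)
    stop("configuration error: volume_solid_cor must be in (-1, 1)")
  if (length(voxel_spacing_mm) != 3L || any(voxel_spacing_mm <= 0))
    stop("configuration error: voxel spacing must be 3 positive lengths")
  if (maxmin_ratio_range[1] < 1 || maxmin_ratio_range[2] < maxmin_ratio_range[1])
    stop("configuration error: invalid maxmin_ratio_range")
  structure(list(n_per_class = n_per_class,
                 volume_median_mm3 = as.numeric(volume_median_mm3),
                 volume_log_sd = volume_log_sd,
                 gg_mean_hu = gg_mean_hu, gg_sd_hu = gg_sd_hu,
                 solid_mean_hu = solid_mean_hu, solid_sd_hu = solid_sd_hu,
                 solid_fraction_range = sfr,
                 volume_solid_cor = volume_solid_cor,
                 maxmin_ratio_range = as.numeric(maxmin_ratio_range),
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Truncated-normal draws by cdf inversion (exact, no rejection loop).
.rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (n == 0L) return(numeric(0))
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# Axis-aligned ellipsoid mask whose continuous volume equals `volume_mm3`
# and whose max/min axis ratio is `ratio`. Semi-axes are prolate (a = r c,
# b = c) and randomly permuted over the array axes. Returns the logical
# array plus the squared normalized radius of each in-mask voxel (array
# order), used to carve a central solid core.
.ellipsoid_mask <- function(volume_mm3, ratio, spacing_mm) {
  c_ax <- (3 * volume_mm3 / (4 * pi * ratio))^(1 / 3)
  semi <- c(ratio * c_ax, c_ax, c_ax)[sample.int(3L)]
  dims <- pmax(ceiling(2 * semi / spacing_mm) + 2L, 3L)
  centers <- lapply(1:3, function(k) {
    (seq_len(dims[k]) - (dims[k] + 1) / 2) * spacing_mm[k]
  })
  a2 <- (centers[[1]] / semi[1])^2
  b2 <- (centers[[2]] / semi[2])^2
  c2 <- (centers[[3]] / semi[3])^2
  r2 <- outer(outer(a2, b2, `+`), c2, `+`)
  mask <- r2 <= 1
  list(mask = mask, r2 = r2[mask])
}

#' One synthetic segmented nodule
#'
#' Container for a nodule's in-mask HU values, binary mask, voxel spacing,
#' solid-component maximum diameter and ordinal class label. Histogram-only
#' nodules (no mask) are allowed.
#'
#' @param hu_values numeric vector, one HU value per in-mask voxel.
#' @param mask 3-D logical array or `NULL`; when present its `TRUE` count
#'   must equal `length(hu_values)`.
#' @param spacing_mm voxel edge lengths (mm).
#' @param solid_diameter_mm solid-component maximum diameter; 0 for a
#'   non-solid nodule.
#' @param class_label one of `"H1"`, `"H2"`, `"H3"`.
#' @param ... extra scalar fields (e.g. the generator records the drawn
#'   solid fraction).
#' @return An object of class `nodule_sample`.
#' @export
nodule_sample <- function(hu_values, mask = NULL, spacing_mm = c(1, 1, 1),
                          solid_diameter_mm = 0, class_label, ...) {
  if (!length(hu_values)) stop("hu_values must be non-empty")
  if (solid_diameter_mm < 0) stop("solid_diameter_mm must be non-negative")
  if (!is.null(mask)) {
    if (length(dim(mask)) != 3L) stop("mask must be a 3-D array")
    if (sum(mask) != length(hu_values))
      stop("mask voxel count must equal length(hu_values)")
  }
  class_label <- factor(class_label, levels = c("H1", "H2", "H3"),
                        ordered = TRUE)
  if (anyNA(class_label)) stop("class_label must be one of H1, H2, H3")
  structure(list(hu_values = as.numeric(hu_values), mask = mask,
                 spacing_mm = as.numeric(spacing_mm),
                 solid_diameter_mm = solid_diameter_mm,
                 class_label = class_label, ...),
            class = "nodule_sample")
}

#' Generate a mechanistic synthetic nodule cohort
#'
#' Per nodule: volume drawn lognormal around its class median (redrawn while
#' the implied voxel count is below 8), an ellipsoidal mask matching that
#' volume, a solid fraction drawn from the class interval (correlated with
#' volume through a latent Gaussian pair), HU values from the two-component
#' mixture with the solid component placed in the nodule core, and the
#' solid-component diameter taken as the equivalent-sphere diameter of the
#' solid subvolume (0 when the solid fraction is 0).
#'
#' @param config a [cohort_config()].
#' @return A list of [nodule_sample()] objects (class `nodule_cohort`), in
#'   class order H1, H2, H3; deterministic given `config$seed`.
#' @export
generate_mechanistic_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  spacing <- config$voxel_spacing_mm
  voxvol <- prod(spacing)
  rho <- config$volume_solid_cor
  labels <- c("H1", "H2", "H3")
  samples <- vector("list", sum(config$n_per_class))
  pos <- 0L
  for (k in 1:3) {
    med <- config$volume_median_mm3[k]
    sfr <- config$solid_fraction_range[k, ]
    for (i in seq_len(config$n_per_class[k])) {
      # correlated latent pair: z1 -> volume, z2 -> solid fraction
      z1 <- rnorm(1)
      z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(1)
      tries <- 0L
      repeat {
        vol <- 10^(log10(med) + config$volume_log_sd * z1)
        if (round(vol / voxvol) >= 8) break
        tries <- tries + 1L
        if (tries > 1000L)
          stop("configuration error: volume distribution cannot reach 8 voxels")
        z1 <- rnorm(1)   # redraw the volume only; fraction latent kept
      }
      sfrac <- stats::qunif(pnorm(z2), sfr[1], sfr[2])
      ratio <- runif(1, config$maxmin_ratio_range[1], config$maxmin_ratio_range[2])
      em <- .ellipsoid_mask(vol, ratio, spacing)
      nv <- sum(em$mask)
      n_solid <- round(sfrac * nv)
      hu <- .rtrunc_norm(nv, config$gg_mean_hu, config$gg_sd_hu, -1024, 400)
      sd_mm <- 0
      if (n_solid > 0) {
        core <- order(em$r2)[seq_len(n_solid)]
        hu[core] <- .rtrunc_norm(n_solid, config$solid_mean_hu,
                                 config$solid_sd_hu, -1024, 400)
        sd_mm <- 2 * (3 * n_solid * voxvol / (4 * pi))^(1 / 3)
      }
      pos <- pos + 1L
      samples[[pos]] <- nodule_sample(hu_values = hu, mask = em$mask,
                                      spacing_mm = spacing,
                                      solid_diameter_mm = sd_mm,
                                      class_label = labels[k],
                                      solid_fraction = sfrac)
    }
  }
  structure(samples, class = "nodule_cohort", config = config)
}

#' Per-nodule HU histogram
#'
#' Integer-bin (1 HU by default) histogram of a nodule's voxel values, in
#' the `(hu_bin_left, count)` layout used for histogram-only inputs.
#'
#' @param x a [nodule_sample()] or numeric HU vector.
#' @param binwidth bin width in HU.
#' @return data frame with columns `hu_bin_left` and `count`.
#' @export
nodule_histogram <- function(x, binwidth = 1) {
  hu <- if (inherits(x, "nodule_sample")) x$hu_values else as.numeric(x)
  left <- floor(hu / binwidth) * binwidth
  tab <- table(left)
  data.frame(hu_bin_left = as.numeric(names(tab)),
             count = as.integer(tab))
}

#' Configuration for the direct proportional-odds generator
#'
#' Ground-truth generator for parameter recovery: features are drawn from
#' `predictor_sampler` and the ordinal class from the cumulative-logit model
#' `P(Y <= j | x) = plogis(intercepts[j] - x %*% beta)`.
#'
#' @param n sample size (>= 3).
#' @param beta named or unnamed slope vector.
#' @param intercepts strictly increasing cumulative intercepts; `length + 1`
#'   classes are generated.
#' @param predictor_sampler `NULL` for iid standard normal features, or a
#'   function `function(n) matrix` returning an `n x length(beta)` matrix.
#' @param seed integer RNG seed.
#' @return An object of class `po_sim_config`.
#' @export
po_sim_config <- function(n, beta = c(1.4, 3.6), intercepts = c(-1, 1),
                          predictor_sampler = NULL, seed = 1L) {
  if (n < 3) stop("configuration error: n must be at least 3")
  if (length(intercepts) < 1 || is.unsorted(intercepts, strictly = TRUE))
    stop("configuration error: intercepts must be strictly increasing")
  if (!is.null(predictor_sampler) && !is.function(predictor_sampler))
    stop("configuration error: predictor_sampler must be NULL or a function")
  structure(list(n = as.integer(n), beta = beta,
                 intercepts = as.numeric(intercepts),
                 predictor_sampler = predictor_sampler,
                 seed = as.integer(seed)),
            class = "po_sim_config")
}

#' Generate a feature table from the proportional-odds model
#'
#' @param config a [po_sim_config()].
#' @return data frame with one column per predictor and an ordered factor
#'   `class` (levels `H1 < H2 < ...`); the generating parameters are kept in
#'   `attr(, "truth")`. Deterministic given `config$seed`.
#' @export
generate_po_cohort <- function(config) {
  stopifnot(inherits(config, "po_sim_config"))
  set.seed(config$seed)
  n <- config$n
  p <- length(config$beta)
  X <- if (is.null(config$predictor_sampler)) {
    matrix(rnorm(n * p), n, p)
  } else {
    m <- config$predictor_sampler(n)
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != p)
      stop("predictor_sampler must return an n x length(beta) matrix")
    m
  }
  nm <- names(config$beta)
  if (is.null(nm)) nm <- paste0("x", seq_len(p))
  colnames(X) <- nm
  eta <- drop(X %*% as.numeric(config$beta))
  J1 <- length(config$intercepts)
  cum <- plogis(outer(-eta, config$intercepts, `+`))   # n x J1, P(Y <= j)
  u <- runif(n)
  y <- 1L + rowSums(u > cum)
  lev <- paste0("H", seq_len(J1 + 1L))
  out <- data.frame(X, class = factor(lev[y], levels = lev, ordered = TRUE))
  attr(out, "truth") <- list(beta = setNames(as.numeric(config$beta), nm),
                             intercepts = config$intercepts)
  out
}
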