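# Shared fixtures, all generated in code.

t_grid_101 <- seq(0, 1, by = 0.01)

trapz_w <- function(t) {
  n <- length(t)
  d <- diff(t)
  c(d[1] / 2, (d[-1] + d[-(n - 1)]) / 2, d[n - 1] / 2)
}

# Two functions orthonormalized under the trapezoid inner product on t_grid.
planted_modes <- function(t = t_grid_101) {
  w <- trapz_w(t)
  p1 <- sin(2 * pi * t)
  p2 <- cos(2 * pi * t)
  p1 <- p1 / sqrt(sum(w * p1^2))
  p2 <- p2 - p1 * sum(w * p1 * p2)
  p2 <- p2 / sqrt(sum(w * p2^2))
  cbind(p1, p2)
}

# Digital ellipsoid mask with given semi-axes (mm) and isotropic spacing.
ellipsoid_fixture <- function(semi_mm, spacing = 0.5) {
  dims <- ceiling(2 * semi_mm / spacing) + 3
  centers <- lapply(1:3, function(k) (seq_len(dims[k]) - (dims[k] + 1) / 2) * spacing)
  r2 <- outer(outer((centers[[1]] / semi_mm[1])^2,
                    (centers[[2]] / semi_mm[2])^2, `+`),
              (centers[[3]] / semi_mm[3])^2, `+`)
  r2 <= 1
}

# Planted score vectors with exact sample variances 4 and 1 and exactly
# zero sample correlation, so the planted modes are the exact sample
# eigenstructure.
planted_scores <- function(n) {
  a <- rnorm(n)
  a <- (a - mean(a)) / sd(a) * 2
  b <- rnorm(n)
  b <- b - mean(b)
  b <- b - a * sum(a * b) / sum(a * a)
  b <- b / sd(b)
  list(a = a, b = b)
}

# Small three-class ordinal dataset drawn from the package generator.
po_data <- function(n = 400, beta = c(1.4, 3.6), intercepts = c(-1, 1),
                    seed = 42) {
  generate_po_cohort(po_sim_config(n = n, beta = beta,
                                   intercepts = intercepts, seed = seed))
}

# Small mechanistic cohort + feature table, cached per session.
small_cohort_features <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- generate_mechanistic_cohort(
        cohort_config(n_per_class = c(15, 25, 40), seed = 20))
      ft <- extract_cohort_features(co)
      fp <- add_fpc_scores(ft, lapply(co, `[[`, "hu_values"))
      cache <<- list(cohort = co, features = fp$features, fpca = fp$model)
    }
    cache
  }
})
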