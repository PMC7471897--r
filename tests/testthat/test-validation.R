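test_that("stratified splits use round-half-up sizes and partition exactly", {
  y <- factor(rep(c("H1", "H2", "H3"), c(31, 64, 132)), ordered = TRUE)
  sp <- stratified_split(y, 0.8, seed = 71)
  expect_identical(as.integer(table(y[sp$test])), c(6L, 13L, 26L))
  expect_identical(sort(c(sp$train, sp$test)), seq_along(y))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, stratified_split(y, 0.8, seed = 71))
  # minimum one test sample per class, and small classes are rejected
  sp2 <- stratified_split(factor(rep(c("a", "b"), c(3, 40))), 0.9, seed = 1)
  expect_gte(sum(factor(rep(c("a", "b"), c(3, 40)))[sp2$test] == "a"), 1)
  expect_error(stratified_split(factor(c("a", "b", "b")), 0.8), "at least 2")
})

test_that("Brier score and its scaled version match hand arithmetic", {
  expect_equal(brier_score(c(0.8, 0.4), c(1, 0)), 0.10)
  expect_equal(brier_score(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(brier_score(rep(0.5, 10), rep(c(0, 1), 5)), 0.25)
  expect_error(brier_score(c(1.2, 0.5), c(1, 0)), "outside")

  expect_equal(scaled_brier_pct(c(0.8, 0.4), c(1, 0)), 60.0)
  out <- rep(c(1, 0), c(3, 7))
  expect_equal(scaled_brier_pct(rep(0.3, 10), out), 0)      # prevalence predictor
  expect_equal(scaled_brier_pct(out, out), 100)             # perfect predictor
  expect_error(scaled_brier_pct(rep(0.5, 5), rep(1, 5)), "both outcome levels")
})

test_that("EAVG is near zero when calibrated and tracks planted shifts", {
  set.seed(72)
  p <- runif(5000, 0.05, 0.95)
  o <- rbinom(5000, 1, p)
  e0 <- calibration_error_eavg(p, o)
  expect_lt(e0, 0.03)
  expect_gte(e0, 0)
  ps <- pmin(1, p + 0.2)
  expect_lt(abs(calibration_error_eavg(ps, o) - 0.2), 0.05)
  expect_warning(ed <- calibration_error_eavg(rep(0.3, 30), rbinom(30, 1, 0.5)),
                 "identical")
  expect_error(calibration_error_eavg(rep(0.3, 5), rep(1, 5)), "at least 20")
})

test_that("Monte-Carlo CV is deterministic and within metric bounds", {
  d <- po_data(n = 250, seed = 73)
  cfg <- cv_config("class ~ x1 + x2", n_repeats = 30, seed = 3)
  a <- monte_carlo_cv(d, cfg)
  b <- monte_carlo_cv(d, cfg)
  expect_identical(a$per_repeat, b$per_repeat)
  pr <- a$per_repeat
  expect_true(all(pr$auc1 >= 0 & pr$auc1 <= 1, na.rm = TRUE))
  expect_true(all(pr$brier1_scaled_pct <= 100, na.rm = TRUE))
  expect_true(all(pr$eavg1 >= 0 & pr$eavg1 <= 1, na.rm = TRUE))
  expect_true(all(unlist(a$summary["2.5%", ]) <= unlist(a$summary["97.5%", ])))
})

test_that("ordinal and per-cutoff logistic classifiers agree on PO data", {
  d <- po_data(n = 500, seed = 74)
  c1 <- monte_carlo_cv(d, cv_config("class ~ x1 + x2", n_repeats = 50,
                                    seed = 4, classifier = "ordinal"))
  c2 <- monte_carlo_cv(d, cv_config("class ~ x1 + x2", n_repeats = 50,
                                    seed = 4, classifier = "binary_logit_pair"))
  expect_lt(abs(c1$summary["mean", "auc1"] - c2$summary["mean", "auc1"]), 0.02)
  expect_lt(abs(c1$summary["mean", "auc2"] - c2$summary["mean", "auc2"]), 0.02)
})

test_that("cross-validated AUC matches the generator's brute-force truth", {
  beta <- c(1.4, 3.6)
  d <- generate_po_cohort(po_sim_config(n = 1000, beta = beta,
                                        intercepts = c(-1, 1), seed = 75))
  cv <- monte_carlo_cv(d, cv_config("class ~ x1 + x2", n_repeats = 100,
                                    seed = 6))
  big <- generate_po_cohort(po_sim_config(n = 2e5, beta = beta,
                                          intercepts = c(-1, 1), seed = 76))
  eta <- as.matrix(big[c("x1", "x2")]) %*% beta
  true1 <- nodulord:::.auc_mw(eta, as.integer(big$class) >= 2)
  true2 <- nodulord:::.auc_mw(eta, as.integer(big$class) == 3)
  expect_lt(abs(cv$summary["mean", "auc1"] - true1), 0.02)
  expect_lt(abs(cv$summary["mean", "auc2"] - true2), 0.02)
})

test_that("multiclass report finds separable classes and a null under permutation", {
  # perfectly separable classes
  set.seed(77)
  X <- rbind(matrix(rnorm(120, 0, 0.1), 60, 2),
             matrix(rnorm(120, 3, 0.1), 60, 2),
             matrix(rnorm(120, 6, 0.1), 60, 2))
  d <- data.frame(x1 = X[, 1], x2 = X[, 2],
                  class = factor(rep(c("H1", "H2", "H3"), each = 60),
                                 ordered = TRUE))
  mr <- multiclass_report(d, cv_config("class ~ x1 + x2", n_repeats = 10,
                                       seed = 7))
  expect_true(all(mr$auc_mean > 0.999))
  # label permutation: AUCs near 0.5
  dp <- d
  set.seed(78)
  dp$class <- sample(dp$class)
  mrp <- multiclass_report(dp, cv_config("class ~ x1 + x2", n_repeats = 20,
                                         seed = 8))
  expect_true(all(mrp$auc_mean > 0.4 & mrp$auc_mean < 0.6))
})

test_that("the middle class is hardest to separate one-vs-rest on PO data", {
  d <- po_data(n = 600, seed = 79)
  mr <- multiclass_report(d, cv_config("class ~ x1 + x2", n_repeats = 30,
                                       seed = 9))
  for (clf in unique(mr$classifier)) {
    m <- mr[mr$classifier == clf, ]
    expect_lt(m$auc_mean[m$class == "H2"], m$auc_mean[m$class == "H1"])
    expect_lt(m$auc_mean[m$class == "H2"], m$auc_mean[m$class == "H3"])
  }
})

test_that("YAML round-trips a CV configuration", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("model_spec: class ~ x1 + x2", "n_repeats: 25",
               "train_fraction: 0.8", "stratified: yes",
               "classifier: ordinal", "seed: 12"), path)
  cfg <- read_cv_config(path)
  expect_s3_class(cfg, "cv_config")
  expect_identical(cfg$n_repeats, 25L)
  expect_identical(cfg$seed, 12L)
})
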