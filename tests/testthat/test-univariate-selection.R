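test_that("AUC matches hand-counted and brute-force pair counting", {
  r <- roc_auc(c(1, 2, 2, 3), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.875)
  brute <- function(s, y) {
    cs <- s[y == 1]; ct <- s[y == 0]
    mean(outer(cs, ct, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  set.seed(41)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    s <- sample(round(rnorm(n), sample(0:2, 1)))   # induces ties
    y <- rbinom(n, 1, 0.5)
    if (sum(y) %in% c(0, n)) next
    expect_equal(roc_auc(s, y)$auc, max(brute(s, y), 1 - brute(s, y)),
                 tolerance = 1e-12)
  }
})

test_that("perfect separation gives AUC 1 with perfect operating point", {
  r <- roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity_pct, 100)
  expect_equal(r$specificity_pct, 100)
  expect_equal(r$direction, "greater")
})

test_that("negating scores flips the direction but not the magnitude", {
  set.seed(42)
  s <- rnorm(80)  # tie-free
  y <- rbinom(80, 1, 0.5)
  a <- roc_auc(s, y)
  b <- roc_auc(-s, y)
  expect_equal(a$auc, b$auc, tolerance = 1e-12)
  expect_false(a$direction == b$direction)
  expect_error(roc_auc(s, rep(1, 80)), "both classes")
})

test_that("DeLong interval agrees with pROC", {
  set.seed(43)
  s <- c(rnorm(60, 1), rnorm(80))
  y <- rep(c(1, 0), c(60, 80))
  r <- roc_auc(s, y)
  pr <- pROC::roc(y, s, direction = "<", quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  expect_equal(c(r$ci_low, r$ci_high), ci[c(1, 3)], tolerance = 1e-6)
})

test_that("Youden threshold equals exhaustive midpoint search", {
  set.seed(44)
  for (i in 1:20) {
    s <- round(rnorm(50), 1)
    y <- rbinom(50, 1, 0.5)
    if (sum(y) %in% c(0, 50)) next
    r <- roc_auc(s, y)
    sor <- if (r$direction == "greater") s else -s
    su <- sort(unique(sor))
    thr <- c(min(su) - 1, (su[-1] + su[-length(su)]) / 2)
    J <- vapply(thr, function(t) mean(sor[y == 1] > t) + mean(sor[y == 0] <= t) - 1,
                0)
    bt <- if (r$direction == "greater") r$best_threshold else -r$best_threshold
    expect_equal(mean(sor[y == 1] > bt) + mean(sor[y == 0] <= bt) - 1, max(J),
                 tolerance = 1e-12)
  }
})

test_that("screening ranks by AUC, flags noise and keeps a perfect feature", {
  sc <- small_cohort_features()
  ft <- sc$features
  set.seed(45)
  ft$noise <- rnorm(nrow(ft))
  ft$oracle <- as.integer(ft$class)
  for (cutoff in 1:2) {
    scr <- screen_features(ft, cutoff)
    expect_true(all(diff(scr$auc) <= 0))
    expect_equal(scr$auc[scr$parameter == "oracle"], 1)
    expect_true(scr$excluded[scr$parameter == "noise"])
    expect_false(scr$excluded[scr$parameter == "q875_hu"])
  }
})

test_that("pure-noise features are flagged excluded across seeds", {
  hits <- 0
  for (s in 1:20) {
    set.seed(700 + s)
    d <- data.frame(noise = rnorm(200),
                    class = factor(rep(c("H1", "H2", "H3"), c(40, 60, 100)),
                                   ordered = TRUE))
    scr <- screen_features(d, 1, features = "noise")
    hits <- hits + scr$excluded[1]
  }
  expect_gte(hits / 20, 0.9)
})

test_that("attenuation features outrank volume in the mechanistic cohort", {
  sc <- small_cohort_features()
  scr <- screen_features(sc$features, 2)
  expect_gt(scr$auc[scr$parameter == "q875_hu"],
            scr$auc[scr$parameter == "volume_log"])
  expect_gt(scr$auc[scr$parameter == "FPC1"],
            scr$auc[scr$parameter == "volume_log"])
})

test_that("confounder coordinates behave like a rank similarity", {
  sc <- small_cohort_features()
  ft <- sc$features
  set.seed(46)
  ft$noise <- rnorm(nrow(ft))
  cd <- confounder_plot_data(ft, reference = "volume_log",
                             features = c("q875_hu", "FPC1", "volume_mm3",
                                          "noise"))
  # the reference against itself
  self <- confounder_plot_data(ft, reference = "volume_log",
                               features = "volume_log")
  expect_equal(self$sim_reference, 1)
  # monotone invariance: a strictly monotone transform changes nothing
  ft2 <- ft
  ft2$q875_hu <- exp(ft2$q875_hu / 200)
  cd2 <- confounder_plot_data(ft2, reference = "volume_log",
                              features = c("q875_hu", "FPC1", "volume_mm3",
                                           "noise"))
  expect_equal(cd$sim_response, cd2$sim_response, tolerance = 1e-12)
  expect_equal(cd$sim_reference, cd2$sim_reference, tolerance = 1e-12)
  # volume_mm3 is monotone in volume_log, so its reference similarity is 1
  expect_equal(cd$sim_reference[cd$feature_name == "volume_mm3"], 1)
  # constant feature warns and gets similarity 0
  ft$flat <- 1
  w <- capture_warnings(cdf <- confounder_plot_data(ft, reference = "volume_log",
                                                    features = "flat"))
  expect_true(all(grepl("constant", w)) && length(w) >= 1)
  expect_equal(cdf$sim_response, 0)
})

test_that("independent noise has small similarities across seeds", {
  hits <- 0
  for (s in 1:20) {
    set.seed(800 + s)
    d <- data.frame(ref = rnorm(500), noise = rnorm(500),
                    class = factor(sample(rep(c("H1", "H2", "H3"),
                                              c(100, 150, 250))),
                                   ordered = TRUE))
    cd <- confounder_plot_data(d, reference = "ref", features = "noise")
    hits <- hits + (cd$sim_response < 0.15 && cd$sim_reference < 0.15)
  }
  expect_gte(hits / 20, 0.95)
})
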