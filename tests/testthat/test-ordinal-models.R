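test_that("two-class fits reduce to binary logistic regression", {
  set.seed(51)
  x <- rnorm(300)
  y <- rbinom(300, 1, plogis(-0.5 + 1.2 * x))
  f2 <- factor(ifelse(y == 1, "H3", "H1"), ordered = TRUE)
  fit <- fit_proportional_odds(data.frame(x = x), f2)
  g <- glm(y ~ x, family = binomial())
  expect_lt(abs(fit$beta[["x"]] - coef(g)[["x"]]), 1e-6)
  # three classes with H2 collapsed into H3 behave the same way
  d <- po_data(n = 500, seed = 510)
  y3 <- factor(ifelse(d$class == "H1", "H1", "H3"), ordered = TRUE)
  fit3 <- fit_proportional_odds(d[c("x1", "x2")], y3)
  gg <- glm(I(d$class != "H1") ~ x1 + x2, family = binomial(), data = d)
  expect_lt(max(abs(fit3$beta - coef(gg)[c("x1", "x2")])), 1e-6)
})

test_that("the fit agrees with MASS::polr on centered predictors", {
  d <- po_data(n = 800, seed = 52)
  fit <- fit_proportional_odds(d[c("x1", "x2")], d$class)
  Xc <- scale(as.matrix(d[c("x1", "x2")]), scale = FALSE)
  pf <- MASS::polr(d$class ~ Xc, Hess = TRUE)
  expect_lt(max(abs(fit$beta - coef(pf))), 1e-4)
  expect_lt(max(abs(fit$intercepts - pf$zeta)), 1e-4)
  expect_lt(abs(fit$deviance - pf$deviance), 1e-6)
})

test_that("intercept-only fit equals the closed-form cumulative logits", {
  y <- factor(rep(c("H1", "H2", "H3"), c(31, 64, 132)), ordered = TRUE)
  fit <- fit_proportional_odds(NULL, y)
  expect_equal(fit$intercepts, qlogis(c(31, 95) / 227), tolerance = 1e-8)
})

test_that("convergence and covariance contracts hold", {
  d <- po_data(n = 500, seed = 53)
  fit <- fit_proportional_odds(d[c("x1", "x2")], d$class)
  expect_true(fit$converged)
  V <- fit$covariance
  expect_lt(max(abs(V - t(V))), 1e-12)
  expect_true(all(eigen(V, symmetric = TRUE, only.values = TRUE)$values > 0))
  # complete separation raises an explicit error
  xs <- c(rep(0, 20), rep(5, 30), rep(10, 50))
  ys <- factor(rep(c("H1", "H2", "H3"), c(20, 30, 50)), ordered = TRUE)
  expect_error(fit_proportional_odds(data.frame(x = xs), ys), "separation")
})

test_that("odds ratios exponentiate coefficients and their Wald limits", {
  d <- po_data(n = 500, seed = 54)
  fit <- fit_proportional_odds(d[c("x1", "x2")], d$class)
  or <- odds_ratios(fit)
  expect_equal(or$or, exp(or$coefficient), tolerance = 1e-12)
  expect_equal(or$ci_low, unname(exp(or$coefficient - 1.959964 * fit$se[1:2])),
               tolerance = 1e-6)
  # zero coefficient maps to OR 1
  fit$beta[] <- 0
  expect_equal(odds_ratios(fit)$or, c(1, 1))
})

test_that("class probabilities are a simplex matching closed forms", {
  y <- factor(rep(c("H1", "H2", "H3"), c(20, 40, 40)), ordered = TRUE)
  fit <- fit_proportional_odds(NULL, y)
  P <- predict_class_probs(fit, data.frame(row.names = 1))
  expect_equal(as.numeric(P), c(0.2, 0.4, 0.4), tolerance = 1e-6)
  d <- po_data(n = 300, seed = 55)
  fit <- fit_proportional_odds(d[c("x1", "x2")], d$class)
  P <- predict_class_probs(fit, d[c("x1", "x2")])
  expect_true(all(P >= 0))
  expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
  # saturation along a positive slope
  hi <- predict_class_probs(fit, c(x1 = 0, x2 = 50))
  expect_gt(hi[1, "H3"], 1 - 1e-6)
  expect_error(predict_class_probs(fit, c(x1 = 0)), "missing feature")
})

test_that("monotone ordinality: P(H3) increases along a positive slope", {
  d <- po_data(n = 400, seed = 56)
  fit <- fit_proportional_odds(d[c("x1", "x2")], d$class)
  grid <- seq(-3, 3, length.out = 25)
  p3 <- predict_class_probs(fit, cbind(x1 = grid, x2 = 0))[, "H3"]
  expect_true(all(diff(p3) > 0))
})

test_that("centering by the caller does not change predictions", {
  d <- po_data(n = 300, seed = 57)
  X <- d[c("x1", "x2")]
  fit_raw <- fit_proportional_odds(X, d$class)
  Xc <- as.data.frame(scale(X, scale = FALSE))
  fit_cen <- fit_proportional_odds(Xc, d$class)
  P1 <- predict_class_probs(fit_raw, X)
  P2 <- predict_class_probs(fit_cen, Xc)
  expect_lt(max(abs(P1 - P2)), 1e-9)
})

test_that("diagnostics accept PO data and flag per-cutoff slope splits", {
  ok <- 0
  for (s in 1:10) {
    d <- po_data(n = 800, seed = 580 + s)
    dg <- po_diagnostics(d[c("x1", "x2")], d$class)
    ok <- ok + !any(dg$cutoff_slopes$flag)
  }
  expect_gte(ok / 10, 0.9)
  # non-PO data: cutoff slopes 1 vs 3
  hits <- 0
  for (s in 1:5) {
    set.seed(590 + s)
    n <- 5000
    x <- rnorm(n)
    c1 <- plogis(-1 - 1.0 * x)
    c2 <- pmax(c1, plogis(1 - 3.0 * x))
    u <- runif(n)
    y <- factor(paste0("H", 1L + (u > c1) + (u > c2)), ordered = TRUE)
    dg <- po_diagnostics(data.frame(x = x), y)
    hits <- hits + any(dg$cutoff_slopes$flag)
  }
  expect_gte(hits / 5, 0.9)
  # ordinality table tracks observed class-conditional means under PO
  d <- po_data(n = 2000, seed = 58)
  dg <- po_diagnostics(d[c("x1", "x2")], d$class)
  expect_lt(max(abs(dg$ordinality$observed_mean - dg$ordinality$implied_mean)),
            0.15)
})

test_that("diagnostics survive deterministic separation", {
  x <- c(rep(0, 10), rep(1, 10), rep(2, 10))
  y <- factor(rep(c("H1", "H2", "H3"), each = 10), ordered = TRUE)
  dg <- po_diagnostics(data.frame(x = x), y)
  expect_true(dg$separation)
  expect_s3_class(dg$cutoff_slopes, "data.frame")
})

test_that("deviance test is null on PO-equivalent fits and powerful otherwise", {
  d <- po_data(n = 1000, seed = 59)
  dt <- deviance_test(d[c("x1", "x2")], d$class)
  expect_gte(dt$chi2, 0)
  expect_equal(dt$df, 2)
  expect_gt(dt$p_value, 0.001)   # generated under PO
  # strong non-PO signal
  set.seed(595)
  n <- 5000
  x <- rnorm(n)
  c1 <- plogis(-1 - 1.0 * x)
  c2 <- pmax(c1, plogis(1 - 3.0 * x))
  u <- runif(n)
  y <- factor(paste0("H", 1L + (u > c1) + (u > c2)), ordered = TRUE)
  dt2 <- deviance_test(data.frame(x = x), y)
  expect_lt(dt2$p_value, 1e-6)
})

test_that("quartile probability changes are seeded, signed and calibrated", {
  d <- po_data(n = 1000, beta = c(0, 3.6), seed = 60)
  fit <- fit_proportional_odds(d[c("x1", "x2")], d$class)
  # null predictor: negligible change, large p
  ch0 <- quartile_probability_change(fit, d, "x1", seed = 9)
  expect_lt(max(abs(ch0$delta)), 0.05)
  expect_true(all(ch0$p_values > 0.05))
  # strong positive predictor: H3 up, H1 down, significant
  ch1 <- quartile_probability_change(fit, d, "x2", seed = 9)
  expect_gt(ch1$delta[["H3"]], 0)
  expect_lt(ch1$delta[["H1"]], 0)
  expect_lt(max(ch1$p_values[c("H1", "H3")]), 0.05)
  expect_lt(max(abs(rowSums(cbind(ch1$class_probs_at_q1)))), Inf)
  expect_lt(abs(sum(ch1$class_probs_at_q1) - 1), 1e-9)
  expect_equal(ch1$delta, ch1$class_probs_at_q3 - ch1$class_probs_at_q1,
               tolerance = 1e-12)
  # determinism
  expect_identical(ch1, quartile_probability_change(fit, d, "x2", seed = 9))
  expect_error(quartile_probability_change(fit, d, "x2", n_draws = 10), "100")
})

test_that("LDA matches its Gaussian-rule contracts and MASS::lda", {
  # identical class distributions: posteriors equal priors exactly
  set.seed(61)
  Xa <- matrix(rnorm(100), 50, 2)
  X <- rbind(Xa, Xa)
  y <- rep(c("a", "b"), each = 50)
  fit <- fit_lda(X, y)
  P <- predict_lda(fit, X)
  expect_lt(max(abs(sweep(P, 2, fit$priors))), 1e-9)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
  # well-separated spherical classes: near-perfect training accuracy
  set.seed(62)
  X <- rbind(matrix(rnorm(200, 0), 100, 2), matrix(rnorm(200, 6), 100, 2),
             matrix(rnorm(200, 12), 100, 2))
  y <- rep(c("H1", "H2", "H3"), each = 100)
  fit <- fit_lda(X, y)
  acc <- mean(fit$levels[max.col(predict_lda(fit, X))] == y)
  expect_gt(acc, 0.99)
  # posterior cross-check against MASS
  ml <- MASS::lda(X, grouping = y)
  pm <- predict(ml, X)$posterior
  expect_lt(max(abs(predict_lda(fit, X) - pm)), 1e-6)
  # singular pooled covariance
  Xs <- cbind(X[, 1], X[, 1])
  expect_error(fit_lda(Xs, y), "singular")
})
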