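# Predictive validation: stratified Monte-Carlo cross-validation with
# per-cutoff AUC, scaled Brier score and average calibration error (EAVG),
# plus a per-class one-vs-rest multiclass report.

#' Cross-validation configuration
#'
#' @param model_spec formula string, e.g. `"class ~ volume_log + FPC1"`.
#' @param n_repeats number of Monte-Carlo repeats (default 200).
#' @param train_fraction training fraction per repeat (default 0.8).
#' @param stratified preserve class frequencies in each split?
#' @param classifier `"ordinal"` (proportional odds),
#'   `"binary_logit_pair"` (one logistic fit per cutoff) or `"lda"`.
#' @param seed integer seed driving all splits.
#' @return list of class `cv_config`.
#' @export
cv_config <- function(model_spec, n_repeats = 200L, train_fraction = 0.8,
                      stratified = TRUE,
                      classifier = c("ordinal", "binary_logit_pair", "lda"),
                      seed = 1L) {
  classifier <- match.arg(classifier)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  if (n_repeats < 1) stop("n_repeats must be at least 1")
  structure(list(model_spec = model_spec, n_repeats = as.integer(n_repeats),
                 train_fraction = train_fraction, stratified = stratified,
                 classifier = classifier, seed = as.integer(seed)),
            class = "cv_config")
}

#' Read a cross-validation configuration from YAML
#'
#' Keys are exactly the [cv_config()] fields.
#'
#' @param path YAML file.
#' @return a `cv_config`.
#' @export
read_cv_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(cv_config, y)
}

#' Stratified train/test split
#'
#' Per class, the test size is `round-half-up(count * (1 - train_fraction))`
#' with a minimum of one test sample; the split partitions the indices.
#' Uses the current RNG state unless `seed` is given.
#'
#' @param labels class labels (factor); each class needs >= 2 members.
#' @param train_fraction training fraction.
#' @param seed optional seed.
#' @return list with integer vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_fraction = 0.8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- factor(labels)
  if (any(table(labels) < 2L)) stop("every class needs at least 2 members")
  test <- integer(0)
  for (l in levels(labels)) {
    idx <- which(labels == l)
    n_test <- max(1L, floor(length(idx) * (1 - train_fraction) + 0.5))
    test <- c(test, sample(idx, n_test))
  }
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test)
}

#' Brier score
#'
#' Mean squared difference between predicted probabilities and the binary
#' outcome.
#'
#' @param probs predicted probabilities in `[0, 1]`.
#' @param outcomes binary outcomes (0/1 or logical).
#' @return scalar in `[0, 1]`.
#' @export
brier_score <- function(probs, outcomes) {
  probs <- as.numeric(probs)
  outcomes <- as.numeric(outcomes)
  if (length(probs) != length(outcomes) || !length(probs))
    stop("probs and outcomes must be equal non-zero length")
  if (any(probs < 0 | probs > 1)) stop("probabilities outside [0, 1]")
  if (!all(outcomes %in% c(0, 1))) stop("outcomes must be binary")
  mean((probs - outcomes)^2)
}

#' Scaled (normalized) Brier score, percent
#'
#' `100 * (1 - Brier / Brier_max)` with `Brier_max = p(1 - p)` the score of
#' the prevalence-only predictor: 0 percent = non-informative, 100 percent
#' = perfect.
#'
#' @inheritParams brier_score
#' @return scalar (percent, at most 100).
#' @export
scaled_brier_pct <- function(probs, outcomes) {
  outcomes <- as.numeric(outcomes)
  pbar <- mean(outcomes)
  if (pbar %in% c(0, 1))
    stop("both outcome levels must be present (Brier_max = 0 otherwise)")
  100 * (1 - brier_score(probs, outcomes) / (pbar * (1 - pbar)))
}

#' Average calibration error (EAVG)
#'
#' Mean absolute difference between the predicted probabilities and a
#' locally smoothed observed-frequency curve ([stats::lowess()], span 2/3)
#' evaluated at the predictions. Degenerate all-equal predictions return
#' `|mean(outcomes) - prob|` with a warning.
#'
#' @inheritParams brier_score
#' @param min_n minimum sample size the smoother needs (default 20).
#' @return non-negative scalar.
#' @export
calibration_error_eavg <- function(probs, outcomes, min_n = 20L) {
  probs <- as.numeric(probs)
  outcomes <- as.numeric(outcomes)
  if (length(probs) < min_n)
    stop("need at least ", min_n, " observations for the calibration smoother")
  if (any(probs < 0 | probs > 1)) stop("probabilities outside [0, 1]")
  if (diff(range(probs)) < 1e-12) {
    warning("all predictions identical; returning |mean(outcome) - prob|")
    return(abs(mean(outcomes) - probs[1]))
  }
  # iter = 0: the robustness iterations of lowess would downweight the 0/1
  # outcomes as outliers and distort the observed-frequency curve
  lw <- lowess(probs, outcomes, f = 2 / 3, iter = 0)
  cal <- approx(lw$x, lw$y, xout = probs, rule = 2, ties = mean)$y
  cal <- pmin(1, pmax(0, cal))
  mean(abs(probs - cal))
}

# Fit the configured classifier on the training rows and return the two
# cutoff probabilities P(Y >= 2) and P(Y = 3) on the test rows, plus the
# full class-probability matrix.
.cv_fit_predict <- function(X, y, train, test, classifier) {
  J <- nlevels(y)
  if (classifier == "ordinal") {
    fit <- fit_proportional_odds(X[train, , drop = FALSE], y[train])
    P <- predict_class_probs(fit, X[test, , drop = FALSE])
  } else if (classifier == "lda") {
    fit <- fit_lda(X[train, , drop = FALSE], y[train])
    P <- predict_lda(fit, X[test, , drop = FALSE])
  } else {
    yi <- as.integer(y)
    df <- as.data.frame(X)
    cum_hi <- sapply(seq_len(J - 1L), function(j) {
      g <- suppressWarnings(glm(ind ~ ., family = binomial(),
                                data = cbind(ind = as.integer(yi[train] > j),
                                             df[train, , drop = FALSE])))
      suppressWarnings(
        stats::predict(g, newdata = df[test, , drop = FALSE], type = "response"))
    })
    cum_hi <- matrix(cum_hi, ncol = J - 1L)
    # successive differences of P(Y > j); clamp tiny negatives from the
    # unconstrained per-cutoff fits
    up <- cbind(1, cum_hi)
    lo <- cbind(cum_hi, 0)
    P <- pmax(up - lo, 0)
    P <- P / rowSums(P)
  }
  yi_test <- as.integer(y[test])
  list(P = P,
       p1 = 1 - P[, 1],                         # P(Y >= 2)
       p2 = P[, J],                              # P(Y = J)
       o1 = as.integer(yi_test >= 2L),
       o2 = as.integer(yi_test == J))
}

.safe_metric <- function(expr) {
  tryCatch(suppressWarnings(expr), error = function(e) NA_real_)
}

#' Monte-Carlo cross-validation of a nodule classification model
#'
#' Per repeat: stratified 80/20 split, refit on the training rows (feature
#' centering recomputed on the training data only), predictions on the
#' test rows. Cutoff-1 metrics compare `P(H2) + P(H3)` with the indicator
#' `Y >= H2`; cutoff-2 metrics compare `P(H3)` with `Y = H3`. Metrics from
#' degenerate repeats (single-class test outcome at a cutoff) are recorded
#' missing and excluded from the summaries, with the exclusion counts
#' logged. Summaries are the mean and the 2.5/97.5 linear-interpolation
#' percentiles across repeats. Deterministic given `config$seed`.
#'
#' @param table cohort feature table.
#' @param config a [cv_config()].
#' @return object of class `cv_result`: `per_repeat` data frame (`auc1`,
#'   `auc2`, `brier1_scaled_pct`, `brier2_scaled_pct`, `eavg1`, `eavg2`),
#'   `summary` data frame (rows mean / 2.5 percent / 97.5 percent),
#'   `n_excluded` per metric, and the `config`.
#' @export
monte_carlo_cv <- function(table, config) {
  stopifnot(inherits(config, "cv_config"))
  ms <- .parse_model_spec(config$model_spec)
  y <- .as_ordinal(table[[ms$response]])
  X <- .feature_matrix(table, ms$features)
  set.seed(config$seed)
  metrics <- c("auc1", "auc2", "brier1_scaled_pct", "brier2_scaled_pct",
               "eavg1", "eavg2")
  out <- matrix(NA_real_, config$n_repeats, length(metrics),
                dimnames = list(NULL, metrics))
  for (r in seq_len(config$n_repeats)) {
    sp <- if (config$stratified) {
      stratified_split(y, config$train_fraction)
    } else {
      n_test <- max(1L, floor(length(y) * (1 - config$train_fraction) + 0.5))
      test <- sort(sample(seq_along(y), n_test))
      list(train = setdiff(seq_along(y), test), test = test)
    }
    pr <- tryCatch(.cv_fit_predict(X, y, sp$train, sp$test, config$classifier),
                   error = function(e) NULL)
    if (is.null(pr)) next   # separated/degenerate training fold: exclude-and-log
    out[r, "auc1"] <- .safe_metric(.auc_mw(pr$p1, pr$o1 == 1L))
    out[r, "auc2"] <- .safe_metric(.auc_mw(pr$p2, pr$o2 == 1L))
    out[r, "brier1_scaled_pct"] <- .safe_metric(scaled_brier_pct(pr$p1, pr$o1))
    out[r, "brier2_scaled_pct"] <- .safe_metric(scaled_brier_pct(pr$p2, pr$o2))
    out[r, "eavg1"] <- .safe_metric(calibration_error_eavg(pr$p1, pr$o1))
    out[r, "eavg2"] <- .safe_metric(calibration_error_eavg(pr$p2, pr$o2))
  }
  # a one-class test side makes the AUC NaN rather than an error
  out[is.nan(out)] <- NA_real_
  summary <- rbind(
    mean = colMeans(out, na.rm = TRUE),
    `2.5%` = apply(out, 2, quantile, 0.025, na.rm = TRUE, type = 7),
    `97.5%` = apply(out, 2, quantile, 0.975, na.rm = TRUE, type = 7))
  structure(list(per_repeat = as.data.frame(out),
                 summary = as.data.frame(summary),
                 n_excluded = colSums(is.na(out)),
                 config = config),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Monte-Carlo CV (", x$config$n_repeats, " repeats, ",
      x$config$classifier, "): ", x$config$model_spec, "\n", sep = "")
  print(round(x$summary, 3))
  if (any(x$n_excluded > 0)) {
    cat("Excluded (degenerate) repeats per metric:\n")
    print(x$n_excluded[x$n_excluded > 0])
  }
  invisible(x)
}

#' Cross-validated one-vs-rest multiclass report
#'
#' For the ordinal and LDA classifiers: per-class one-vs-rest AUC of the
#' cross-validated posterior probabilities, summarized across repeats.
#'
#' @param table cohort feature table.
#' @param config a [cv_config()] (its `classifier` field is ignored; both
#'   classifiers are reported).
#' @return data frame with `classifier`, `class`, `auc_mean`, `auc_2.5`,
#'   `auc_97.5`, `n_excluded`.
#' @export
multiclass_report <- function(table, config) {
  stopifnot(inherits(config, "cv_config"))
  ms <- .parse_model_spec(config$model_spec)
  y <- .as_ordinal(table[[ms$response]])
  X <- .feature_matrix(table, ms$features)
  J <- nlevels(y)
  rows <- list()
  for (clf in c("ordinal", "lda")) {
    set.seed(config$seed)
    aucs <- matrix(NA_real_, config$n_repeats, J)
    for (r in seq_len(config$n_repeats)) {
      sp <- stratified_split(y, config$train_fraction)
      pr <- tryCatch(.cv_fit_predict(X, y, sp$train, sp$test, clf),
                     error = function(e) NULL)
      if (is.null(pr)) next
      yi <- as.integer(y[sp$test])
      for (k in seq_len(J))
        aucs[r, k] <- .safe_metric(.auc_mw(pr$P[, k], yi == k))
    }
    aucs[is.nan(aucs)] <- NA_real_
    for (k in seq_len(J)) {
      rows[[length(rows) + 1L]] <- data.frame(
        classifier = clf, class = levels(y)[k],
        auc_mean = mean(aucs[, k], na.rm = TRUE),
        `auc_2.5` = quantile(aucs[, k], 0.025, na.rm = TRUE, type = 7,
                             names = FALSE),
        `auc_97.5` = quantile(aucs[, k], 0.975, na.rm = TRUE, type = 7,
                              names = FALSE),
        n_excluded = sum(is.na(aucs[, k])),
        check.names = FALSE)
    }
  }
  do.call(rbind, rows)
}
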