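# Univariate feature screening: binary ROC-AUC (tie-corrected Mann-Whitney)
# with DeLong confidence intervals and Youden-optimal thresholds, at both
# ordinal cutoffs; plus the confounder-plot coordinates (rank similarity to
# the response vs to a reference predictor).

# AUC as the tie-corrected Mann-Whitney statistic U / (n1 n0).
.auc_mw <- function(scores, pos) {
  n1 <- as.numeric(sum(pos))
  n0 <- as.numeric(sum(!pos))
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong variance of the AUC via placement values (midrank form, handles
# ties).
.delong_var <- function(scores, pos) {
  x <- scores[pos]
  y <- scores[!pos]
  n1 <- length(x)
  n0 <- length(y)
  r_all <- rank(c(x, y))
  v10 <- (r_all[seq_len(n1)] - rank(x)) / n0
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - rank(y)) / n1
  var(v10) / n1 + var(v01) / n0
}

.as_binary <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) {
    if (nlevels(labels) != 2L) stop("labels must have exactly 2 levels")
    return(as.integer(labels) == 2L)
  }
  u <- sort(unique(labels))
  if (length(u) == 1L) stop("both classes must be present")
  if (length(u) != 2L) stop("labels must take exactly 2 values")
  labels == u[2]
}

#' ROC-AUC of a score against a binary label
#'
#' AUC equals the tie-corrected Mann-Whitney statistic. The direction is
#' auto-chosen so AUC >= 0.5: `"greater"` means high scores predict the
#' positive class (threshold reported as "score > t"), `"less_or_equal"`
#' the reverse ("score <= t"). The confidence interval and the test of
#' AUC = 0.5 use the DeLong variance with a normal approximation. The
#' reported threshold maximizes Youden's J on the empirical ROC; among ties
#' the more sensitive threshold is reported.
#'
#' @param scores numeric feature values.
#' @param labels binary outcome (logical, 2-level factor, or 2 values; the
#'   higher level is the positive class). Both classes must be present.
#' @param conf_level confidence level for the AUC interval.
#' @return list of class `auc_result`: `auc`, `ci_low`, `ci_high`, `se`,
#'   `p_value` (two-sided, AUC = 0.5), `sensitivity_pct`,
#'   `specificity_pct`, `best_threshold`, `direction`.
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95) {
  pos <- .as_binary(labels)
  if (!any(pos) || all(pos)) stop("both classes must be present")
  scores <- as.numeric(scores)
  if (anyNA(scores)) stop("missing score values")
  auc_raw <- .auc_mw(scores, pos)
  se <- sqrt(.delong_var(scores, pos))
  z <- (auc_raw - 0.5) / se
  p_value <- if (se == 0) 0 else 2 * pnorm(-abs(z))
  direction <- if (auc_raw >= 0.5) "greater" else "less_or_equal"
  s <- if (direction == "greater") scores else -scores
  auc <- max(auc_raw, 1 - auc_raw)
  zq <- qnorm(1 - (1 - conf_level) / 2)
  ci <- c(max(0, auc - zq * se), min(1, auc + zq * se))

  # Youden search over midpoints between consecutive distinct scores.
  su <- sort(unique(s))
  thr <- if (length(su) > 1) (su[-1] + su[-length(su)]) / 2 else su - 1
  thr <- c(min(su) - 1, thr)           # "everything positive" endpoint
  sens <- vapply(thr, function(t) mean(s[pos] > t), numeric(1))
  spec <- vapply(thr, function(t) mean(s[!pos] <= t), numeric(1))
  J <- sens + spec - 1
  best <- which(J >= max(J) - 1e-12)
  best <- best[which.max(sens[best])]  # tie-break: higher sensitivity
  best_threshold <- if (direction == "greater") thr[best] else -thr[best]
  structure(list(auc = auc, ci_low = ci[1], ci_high = ci[2], se = se,
                 p_value = p_value,
                 sensitivity_pct = 100 * sens[best],
                 specificity_pct = 100 * spec[best],
                 best_threshold = best_threshold,
                 direction = direction),
            class = "auc_result")
}

# Binary label for an ordinal cutoff: 1 = H1 vs (H2 or H3), 2 = (H1 or H2)
# vs H3; positive class is the more invasive side.
.cutoff_label <- function(y, cutoff) {
  yi <- as.integer(.as_ordinal(y))
  if (cutoff == 1L) yi >= 2L else yi == max(yi)
}

#' Screen features by ROC-AUC at an ordinal cutoff
#'
#' One [roc_auc()] per feature, sorted by descending AUC. Features whose
#' AUC is not significantly above 0.5 (DeLong test, `p >= alpha`) are
#' flagged `excluded`.
#'
#' @param table cohort feature table with an ordinal class column.
#' @param cutoff 1 (H1 vs H2 or H3) or 2 (H1 or H2 vs H3).
#' @param features feature column names; default: all numeric columns
#'   except `nodule_id` and the response.
#' @param response name of the class column.
#' @param alpha significance level of the exclusion rule (default 0.001).
#' @return data frame of class `screening_result` with columns `parameter`,
#'   `auc`, `ci_low`, `ci_high`, `sensitivity`, `specificity` (integer
#'   percent), `threshold`, `direction`, `p_value`, `excluded`.
#' @export
screen_features <- function(table, cutoff = 1L, features = NULL,
                            response = "class", alpha = 0.001) {
  if (is.null(features)) {
    num <- vapply(table, is.numeric, logical(1))
    features <- setdiff(names(table)[num], c("nodule_id", response))
  }
  X <- .feature_matrix(table, features)
  lab <- .cutoff_label(table[[response]], cutoff)
  rows <- lapply(features, function(f) {
    r <- roc_auc(X[, f], lab)
    data.frame(parameter = f, auc = r$auc,
               ci_low = r$ci_low, ci_high = r$ci_high,
               sensitivity = round(r$sensitivity_pct),
               specificity = round(r$specificity_pct),
               threshold = r$best_threshold, direction = r$direction,
               p_value = r$p_value,
               excluded = !(r$auc > 0.5 && r$p_value < alpha))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$auc), ]
  rownames(out) <- NULL
  class(out) <- c("screening_result", class(out))
  out
}

# Absolute Spearman rank correlation; 0 with a warning for a constant
# argument.
.rank_similarity <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant feature: similarity set to 0")
    return(0)
  }
  abs(cor(a, b, method = "spearman"))
}

#' Confounder-plot coordinates for feature selection
#'
#' For each candidate feature: similarity to the ordinal response (absolute
#' Spearman correlation with the class rank) and similarity to a reference
#' predictor (absolute Spearman correlation). Both are invariant to
#' strictly monotone transforms. Features above the response-similarity
#' median and below the reference-similarity median are flagged
#' `recommended` (high predictive value, low collinearity with the
#' reference).
#'
#' @param table cohort feature table.
#' @param reference name of the reference predictor (e.g. `volume_log`).
#' @param features candidate columns; default all numeric except
#'   `nodule_id`, the response and the reference.
#' @param response class column name.
#' @return data frame of class `confounder_data` with `feature_name`,
#'   `sim_response`, `sim_reference`, `recommended`.
#' @export
confounder_plot_data <- function(table, reference, features = NULL,
                                 response = "class") {
  if (!reference %in% names(table))
    stop("reference feature '", reference, "' not in table")
  if (is.null(features)) {
    num <- vapply(table, is.numeric, logical(1))
    features <- setdiff(names(table)[num], c("nodule_id", response, reference))
  }
  yr <- as.integer(.as_ordinal(table[[response]]))
  ref <- table[[reference]]
  out <- do.call(rbind, lapply(features, function(f) {
    data.frame(feature_name = f,
               sim_response = .rank_similarity(table[[f]], yr),
               sim_reference = .rank_similarity(table[[f]], ref))
  }))
  out$recommended <- out$sim_response > median(out$sim_response) &
                     out$sim_reference < median(out$sim_reference)
  class(out) <- c("confounder_data", class(out))
  out
}
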