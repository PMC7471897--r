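# Proportional-odds cumulative-logit model: fitting, odds ratios, class
# probabilities, proportionality diagnostics, deviance comparison against
# the non-proportional cumulative-logit relaxation, and Monte-Carlo
# quartile probability changes.

#' Fit a cumulative-logit proportional-odds model
#'
#' Predictors are centered by their training means (stored in the fit;
#' predictions fold the centers back in, so pre-centering by the caller
#' changes nothing). The model is
#' `P(Y <= j | x) = plogis(alpha_j - x' beta)`, fitted by Newton-Raphson
#' with analytic gradient/Hessian and step-halving; convergence when the
#' maximal score component is below `tol`. The covariance is the inverse
#' observed information. With two classes the fit reduces to binary
#' logistic regression.
#'
#' @param x feature data frame/matrix (or `NULL` for an intercept-only
#'   fit). No missing values.
#' @param y ordinal class labels; every level non-empty.
#' @param tol Newton convergence tolerance on the score (default 1e-8).
#' @param maxit maximum Newton iterations.
#' @return object of class `po_fit`: `feature_names`, `centers`, `beta`,
#'   `intercepts` (increasing cumulative intercepts, centered-predictor
#'   scale), `coefficients` (slopes then intercepts), `covariance`, `se`,
#'   `wald_z`, `wald_p`, `deviance`, `loglik`, `levels`, `n`.
#' @export
fit_proportional_odds <- function(x, y, tol = 1e-8, maxit = 200L) {
  y <- .as_ordinal(y)
  J <- nlevels(y)
  yi <- as.integer(y)
  if (is.null(x) || (!is.null(ncol(x)) && ncol(x) == 0L)) {
    Xc <- NULL
    centers <- numeric(0)
    nm <- character(0)
  } else {
    X <- as.matrix(as.data.frame(x))
    storage.mode(X) <- "double"
    if (anyNA(X)) stop("missing values in predictors")
    if (length(yi) != nrow(X)) stop("x and y lengths differ")
    nm <- colnames(X)
    if (is.null(nm)) nm <- paste0("x", seq_len(ncol(X)))
    centers <- colMeans(X)
    Xc <- sweep(X, 2, centers)
  }
  fit <- .cl_fit(Xc, yi, J, proportional = TRUE, tol = tol, maxit = maxit)
  J1 <- J - 1L
  p <- length(nm)
  if (p > 0L) {
    # scale-free separation check: a slope above 30 per predictor SD means
    # essentially deterministic class assignment along that feature
    std_slope <- abs(fit$theta[J1 + seq_len(p)]) * apply(Xc, 2, sd)
    if (any(std_slope > 30))
      stop("complete separation: standardized slope diverging (|beta|*sd > 30)")
  }
  alpha <- fit$theta[seq_len(J1)]
  beta <- if (p) fit$theta[J1 + seq_len(p)] else numeric(0)
  ord <- c(J1 + seq_len(p), seq_len(J1))          # report slopes first
  est <- fit$theta[ord]
  V <- fit$vcov[ord, ord, drop = FALSE]
  names(est) <- c(nm, paste0("alpha", seq_len(J1)))
  dimnames(V) <- list(names(est), names(est))
  se <- sqrt(diag(V))
  z <- est / se
  structure(list(feature_names = nm, centers = setNames(centers, nm),
                 beta = setNames(beta, nm), intercepts = alpha,
                 coefficients = est, covariance = V, se = se,
                 wald_z = z, wald_p = 2 * pnorm(-abs(z)),
                 deviance = fit$deviance, loglik = fit$loglik,
                 levels = levels(y), n = length(yi),
                 niter = fit$niter, converged = fit$converged),
            class = "po_fit")
}

#' @export
print.po_fit <- function(x, ...) {
  cat("Cumulative-logit proportional-odds fit (", x$n, " obs, ",
      length(x$levels), " classes)\n", sep = "")
  tab <- data.frame(estimate = x$coefficients, se = x$se,
                    z = x$wald_z, p = signif(x$wald_p, 3))
  print(tab, digits = 4)
  cat("Deviance:", format(x$deviance, digits = 6), "\n")
  invisible(x)
}

# Align prediction input (named vector, matrix or data frame) with the
# fit's features; missing feature -> error.
.predict_matrix <- function(fit, x) {
  nm <- fit$feature_names
  if (is.null(dim(x))) {
    if (length(nm) == 1L && is.null(names(x))) {
      x <- matrix(as.numeric(x), ncol = 1, dimnames = list(NULL, nm))
    } else {
      if (!all(nm %in% names(x)))
        stop("missing feature(s): ", paste(setdiff(nm, names(x)), collapse = ", "))
      x <- matrix(as.numeric(x[nm]), nrow = 1, dimnames = list(NULL, nm))
    }
  } else {
    x <- as.matrix(as.data.frame(x))
    if (!all(nm %in% colnames(x)))
      stop("missing feature(s): ", paste(setdiff(nm, colnames(x)), collapse = ", "))
    x <- x[, nm, drop = FALSE]
    storage.mode(x) <- "double"
  }
  if (anyNA(x)) stop("missing values in prediction input")
  x
}

#' Class probabilities from a proportional-odds fit
#'
#' Successive differences of the cumulative logits; each row is a
#' probability vector over the ordinal classes (sums to 1).
#'
#' @param fit a [fit_proportional_odds()] result.
#' @param x named numeric vector (one observation) or data frame/matrix
#'   containing the fit's features.
#' @return numeric matrix, one row per observation, one column per class.
#' @export
predict_class_probs <- function(fit, x) {
  if (length(fit$feature_names)) {
    X <- .predict_matrix(fit, x)
    eta <- drop(sweep(X, 2, fit$centers) %*% fit$beta)
  } else {
    nr <- if (is.null(dim(x))) 1L else nrow(x)
    eta <- rep(0, nr)
  }
  cum <- plogis(outer(-eta, fit$intercepts, `+`))
  P <- cbind(cum, 1) - cbind(0, cum)
  colnames(P) <- fit$levels
  P
}

#' Odds ratios from a proportional-odds fit
#'
#' OR = exp(coefficient); the Wald interval is
#' `exp(coefficient +/- z * SE)`.
#'
#' @param fit a `po_fit`.
#' @param conf_level confidence level (default 0.95, z = 1.96).
#' @return data frame with `feature`, `coefficient`, `ci_low_coef`,
#'   `ci_high_coef`, `or`, `ci_low`, `ci_high`, `wald_p`.
#' @export
odds_ratios <- function(fit, conf_level = 0.95) {
  p <- length(fit$beta)
  if (!p) return(data.frame())
  se <- fit$se[seq_len(p)]
  zq <- qnorm(1 - (1 - conf_level) / 2)
  lo <- fit$beta - zq * se
  hi <- fit$beta + zq * se
  data.frame(feature = fit$feature_names,
             coefficient = unname(fit$beta),
             ci_low_coef = unname(lo), ci_high_coef = unname(hi),
             or = unname(exp(fit$beta)),
             ci_low = unname(exp(lo)), ci_high = unname(exp(hi)),
             wald_p = unname(fit$wald_p[seq_len(p)]))
}

#' Proportional-odds diagnostics
#'
#' Two numeric checks, no graphics: (a) per-cutoff binary logistic slopes
#' (indicators Y > j) and their spread -- under proportional odds the
#' cutoff-specific slopes agree, so a per-feature difference beyond two
#' pooled standard errors raises a flag; (b) an ordinality table comparing
#' observed class-conditional feature means with the means implied by the
#' fitted model. If the proportional-odds fit itself fails through complete
#' separation, the binary-slope table is still returned and the condition
#' reported in `separation`.
#'
#' @param x feature data frame/matrix.
#' @param y ordinal class labels (3+ levels for a meaningful check).
#' @return list of class `po_diagnostics`: `cutoff_slopes` (per feature and
#'   cutoff: slope, se, plus `diff`, `pooled_se`, `flag`), `ordinality`,
#'   `separation`.
#' @export
po_diagnostics <- function(x, y) {
  y <- .as_ordinal(y, min_levels = 3L)
  yi <- as.integer(y)
  J <- nlevels(y)
  Xdf <- as.data.frame(x)
  nm <- names(Xdf)
  slopes <- ses <- matrix(NA_real_, length(nm), J - 1L,
                          dimnames = list(nm, paste0("cutoff", seq_len(J - 1L))))
  for (j in seq_len(J - 1L)) {
    ind <- as.integer(yi > j)
    g <- suppressWarnings(glm(ind ~ ., data = Xdf, family = binomial()))
    cf <- summary(g)$coefficients
    slopes[, j] <- cf[nm, "Estimate"]
    ses[, j] <- cf[nm, "Std. Error"]
  }
  cutoff_slopes <- data.frame(feature = nm, slope = slopes, se = ses)
  cutoff_slopes$diff <- apply(slopes, 1, function(b) max(b) - min(b))
  cutoff_slopes$pooled_se <- sqrt(rowSums(ses^2))
  cutoff_slopes$flag <- cutoff_slopes$diff > 2 * cutoff_slopes$pooled_se

  fit <- tryCatch(fit_proportional_odds(Xdf, y), error = function(e) e)
  separation <- inherits(fit, "error")
  ordinality <- NULL
  if (!separation) {
    P <- predict_class_probs(fit, Xdf)
    ordinality <- do.call(rbind, lapply(nm, function(f) {
      obs <- tapply(Xdf[[f]], y, mean)
      imp <- colSums(Xdf[[f]] * P) / colSums(P)
      data.frame(feature = f, class = levels(y),
                 observed_mean = as.numeric(obs),
                 implied_mean = as.numeric(imp))
    }))
  }
  structure(list(cutoff_slopes = cutoff_slopes, ordinality = ordinality,
                 separation = separation,
                 note = if (separation) conditionMessage(fit)),
            class = "po_diagnostics")
}

#' Deviance test of proportional odds
#'
#' Likelihood-ratio comparison of the proportional-odds fit against the
#' non-proportional cumulative-logit model (one slope vector per cutoff),
#' fitted with the same Newton engine under the constraint that all
#' category probabilities stay positive. `chi2 = D_PO - D_nonPO` on
#' `(J - 2) * p` degrees of freedom.
#'
#' @param x feature data frame/matrix.
#' @param y ordinal class labels.
#' @return list of class `po_deviance_test`: `chi2`, `df`, `p_value`,
#'   `deviance_po`, `deviance_npo`.
#' @export
deviance_test <- function(x, y) {
  y <- .as_ordinal(y, min_levels = 3L)
  yi <- as.integer(y)
  J <- nlevels(y)
  X <- as.matrix(as.data.frame(x))
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("missing values in predictors")
  p <- ncol(X)
  centers <- colMeans(X)
  Xc <- sweep(X, 2, centers)
  po <- .cl_fit(Xc, yi, J, proportional = TRUE)
  start <- c(po$theta[seq_len(J - 1L)], rep(po$theta[J - 1L + seq_len(p)], J - 1L))
  npo <- .cl_fit(Xc, yi, J, proportional = FALSE, start = start)
  chi2 <- po$deviance - npo$deviance
  if (chi2 < -1e-6)
    stop("complex-model deviance exceeds the simple model's: non-nested fit ",
         "or optimization failure")
  chi2 <- max(chi2, 0)
  df <- (J - 2L) * p
  p_value <- if (df > 0) pchisq(chi2, df, lower.tail = FALSE) else 1
  structure(list(chi2 = chi2, df = df, p_value = p_value,
                 deviance_po = po$deviance, deviance_npo = npo$deviance),
            class = "po_deviance_test")
}

#' Monte-Carlo quartile probability change
#'
#' Simulation-based interpretation of one predictor: parameter vectors are
#' drawn from the multivariate normal with mean the estimates and
#' covariance the fit covariance; for each draw the class probabilities are
#' evaluated with the predictor at its cohort 3rd vs 1st quartile, the
#' other predictors held at their cohort means. Reports the mean change
#' per class, a 95 percent percentile interval and the two-sided
#' simulation p-value `2 * min(Pr(delta > 0), Pr(delta < 0))`.
#'
#' @param fit a `po_fit`.
#' @param table the cohort feature table the quartiles/means come from.
#' @param predictor name of the predictor of interest.
#' @param n_draws number of parameter draws (>= 100; default 1000).
#' @param seed RNG seed; output is deterministic given it.
#' @return list of class `class_prob_profile`: `predictor`, `q1`, `q3`,
#'   `class_probs_at_q1`, `class_probs_at_q3`, `delta`, `delta_ci_low`,
#'   `delta_ci_high`, `p_values`.
#' @export
quartile_probability_change <- function(fit, table, predictor,
                                        n_draws = 1000L, seed = 1L) {
  if (!predictor %in% fit$feature_names)
    stop("predictor '", predictor, "' is not in the fit")
  if (n_draws < 100L) stop("n_draws must be at least 100")
  q <- quantile(table[[predictor]], c(0.25, 0.75), type = 7, names = FALSE)
  xv <- setNames(numeric(length(fit$feature_names)), fit$feature_names)
  for (o in setdiff(fit$feature_names, predictor)) xv[o] <- mean(table[[o]])
  x1 <- x3 <- xv
  x1[predictor] <- q[1]
  x3[predictor] <- q[2]

  V <- fit$covariance
  ch <- tryCatch(chol(V), error = function(e)
    stop("singular covariance: cannot draw parameters"))
  set.seed(seed)
  d <- length(fit$coefficients)
  TH <- matrix(rnorm(n_draws * d), n_draws, d) %*% ch
  TH <- sweep(TH, 2, fit$coefficients, `+`)
  p <- length(fit$feature_names)
  J1 <- length(fit$intercepts)
  B <- TH[, seq_len(p), drop = FALSE]
  A <- TH[, p + seq_len(J1), drop = FALSE]
  prob_at <- function(x) {
    eta <- drop(B %*% (x - fit$centers))
    cum <- plogis(A - eta)
    cbind(cum, 1) - cbind(0, cum)
  }
  P1 <- prob_at(x1)
  P3 <- prob_at(x3)
  D <- P3 - P1
  ci <- apply(D, 2, quantile, probs = c(0.025, 0.975), type = 7)
  pgt <- colMeans(D > 0)
  lev <- fit$levels
  out <- list(predictor = predictor, q1 = q[1], q3 = q[2],
              class_probs_at_q1 = setNames(colMeans(P1), lev),
              class_probs_at_q3 = setNames(colMeans(P3), lev),
              delta = setNames(colMeans(D), lev),
              delta_ci_low = setNames(ci[1, ], lev),
              delta_ci_high = setNames(ci[2, ], lev),
              p_values = setNames(pmin(1, 2 * pmin(pgt, 1 - pgt)), lev),
              n_draws = n_draws, seed = seed)
  class(out) <- "class_prob_profile"
  out
}
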