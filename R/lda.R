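# Linear discriminant analysis comparator: class means, pooled within-class
# covariance, empirical priors, Gaussian posterior rule.

#' Fit a linear discriminant classifier
#'
#' @param x feature data frame/matrix.
#' @param y class labels (factor); each class needs at least `p + 1`
#'   samples so the pooled covariance has full rank.
#' @return object of class `lda_fit`: `class_means` (K x p),
#'   `pooled_covariance`, `priors`, `levels`, `feature_names`.
#' @export
fit_lda <- function(x, y) {
  y <- factor(y)
  X <- as.matrix(as.data.frame(x))
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("missing values in predictors")
  p <- ncol(X)
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("x", seq_len(p))
  nk <- table(y)
  if (any(nk < p + 1))
    stop("each class needs at least p + 1 = ", p + 1, " samples")
  K <- nlevels(y)
  n <- nrow(X)
  means <- t(vapply(levels(y), function(l)
    colMeans(X[y == l, , drop = FALSE]), numeric(p)))
  S <- matrix(0, p, p)
  for (l in levels(y)) {
    Xl <- X[y == l, , drop = FALSE]
    S <- S + crossprod(sweep(Xl, 2, colMeans(Xl)))
  }
  S <- S / (n - K)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= max(ev) * 1e-10) stop("singular pooled covariance")
  dimnames(means) <- list(levels(y), nm)
  dimnames(S) <- list(nm, nm)
  structure(list(class_means = means, pooled_covariance = S,
                 priors = as.numeric(nk) / n, levels = levels(y),
                 feature_names = nm),
            class = "lda_fit")
}

#' Posterior class probabilities from an LDA fit
#'
#' Gaussian discriminant rule with the pooled covariance:
#' `delta_k(x) = x' S^{-1} mu_k - mu_k' S^{-1} mu_k / 2 + log prior_k`,
#' normalized by a stable softmax.
#'
#' @param fit an [fit_lda()] result.
#' @param x data frame/matrix (or named vector) with the fit's features.
#' @return matrix of posterior probabilities, one row per observation.
#' @export
predict_lda <- function(fit, x) {
  if (is.null(dim(x)))
    x <- matrix(as.numeric(x[fit$feature_names]), nrow = 1,
                dimnames = list(NULL, fit$feature_names))
  X <- as.matrix(as.data.frame(x))[, fit$feature_names, drop = FALSE]
  storage.mode(X) <- "double"
  Sinv <- chol2inv(chol(fit$pooled_covariance))
  M <- fit$class_means
  lin <- X %*% Sinv %*% t(M)                      # n x K
  const <- -0.5 * rowSums((M %*% Sinv) * M) + log(fit$priors)
  sc <- sweep(lin, 2, const, `+`)
  sc <- sc - apply(sc, 1, max)
  P <- exp(sc) / rowSums(exp(sc))
  colnames(P) <- fit$levels
  P
}
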