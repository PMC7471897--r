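# Small shared helpers: ordinal label coercion, trapezoid quadrature,
# model-formula parsing.

# Coerce class labels to an ordered factor. Accepts ordered factors, plain
# factors (level order kept), or character/integer vectors (sorted unique
# order). Every level must be observed: a cutoff with an empty side has no
# likelihood contribution and the cumulative model is unidentified there.
.as_ordinal <- function(y, min_levels = 2L) {
  if (is.ordered(y)) {
    f <- y
  } else if (is.factor(y)) {
    f <- factor(y, levels = levels(y), ordered = TRUE)
  } else {
    f <- factor(y, ordered = TRUE)
  }
  if (anyNA(f)) stop("class labels contain missing values")
  if (nlevels(f) < min_levels)
    stop("need at least ", min_levels, " ordered classes")
  if (any(tabulate(f, nlevels(f)) == 0L))
    stop("every class level must be non-empty; drop unused levels first")
  f
}

# Trapezoid quadrature weights for an arbitrary increasing grid.
.trapz_weights <- function(x) {
  n <- length(x)
  if (n < 2L) stop("grid needs at least two points")
  d <- diff(x)
  if (any(d <= 0)) stop("grid must be strictly increasing")
  c(d[1] / 2, (d[-1] + d[-(n - 1)]) / 2, d[n - 1] / 2)
}

.trapz <- function(x, y) sum(.trapz_weights(x) * y)

# Cumulative trapezoid integral, anchored at zero.
.cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(x)))
}

# Parse "class ~ volume_log + FPC1" into response and feature names.
.parse_model_spec <- function(spec) {
  f <- stats::as.formula(spec)
  if (length(f) != 3L) stop("model spec must have the form 'response ~ f1 + f2'")
  list(response = all.vars(f[[2]]), features = all.vars(f[[3]]))
}

# Pull a numeric feature matrix out of a data frame, with error reporting
# for missing values (spec contract for screening/fitting inputs).
.feature_matrix <- function(table, features) {
  missing_cols <- setdiff(features, names(table))
  if (length(missing_cols))
    stop("features not found in table: ", paste(missing_cols, collapse = ", "))
  X <- as.matrix(as.data.frame(table)[features])
  storage.mode(X) <- "double"
  if (anyNA(X)) {
    bad <- which(rowSums(is.na(X)) > 0)
    stop("missing feature values in rows: ",
         paste(utils::head(bad, 20), collapse = ", "))
  }
  X
}
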