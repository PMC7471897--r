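# Cumulative-logit maximum likelihood engine, shared by the proportional-odds
# fit and its non-proportional (per-cutoff slope) relaxation.
#
# Convention: P(Y <= j | x) = plogis(alpha_j - eta_j(x)), eta_j = x' beta_j,
# with beta_j == beta shared across cutoffs under proportional odds. A
# positive slope therefore shifts probability mass toward higher (more
# invasive) classes, matching odds ratios > 1 for risk-increasing features.
#
# Newton-Raphson with analytic gradient and Hessian, step-halving when a
# full step would decrease the log-likelihood or leave the feasible region
# (category probabilities must stay positive, which for per-cutoff slopes is
# not automatic).

.cl_npar <- function(p, J1, proportional) J1 + if (proportional) p else p * J1

.cl_unpack <- function(theta, p, J1, proportional) {
  alpha <- theta[seq_len(J1)]
  B <- NULL
  if (p > 0L) {
    B <- if (proportional)
      matrix(theta[J1 + seq_len(p)], p, J1)     # shared column, recycled
    else
      matrix(theta[J1 + seq_len(p * J1)], p, J1)
  }
  list(alpha = alpha, B = B)
}

# Log-likelihood and (optionally) analytic gradient/Hessian at theta.
# y is an integer vector in 1..J; X an n x p matrix (NULL for intercept-only).
.cl_eval <- function(theta, X, y, J, proportional, want_deriv = TRUE) {
  n <- length(y)
  J1 <- J - 1L
  p <- if (is.null(X)) 0L else ncol(X)
  par <- .cl_unpack(theta, p, J1, proportional)
  U <- matrix(par$alpha, n, J1, byrow = TRUE)
  if (p > 0L) U <- U - X %*% par$B

  # gamma_j = F(u_j), g = F', h = F'' for the logistic cdf
  up <- y <= J1
  lo <- y >= 2L
  iu <- cbind(which(up), y[up])
  il <- cbind(which(lo), y[lo] - 1L)
  gam_u <- rep(1, n); g_u <- h_u <- numeric(n)
  gam_l <- g_l <- h_l <- numeric(n)
  gu <- plogis(U[iu])
  gam_u[up] <- gu
  g_u[up] <- gu * (1 - gu)
  h_u[up] <- g_u[up] * (1 - 2 * gu)
  gl <- plogis(U[il])
  gam_l[lo] <- gl
  g_l[lo] <- gl * (1 - gl)
  h_l[lo] <- g_l[lo] * (1 - 2 * gl)

  pv <- gam_u - gam_l
  if (any(!is.finite(pv)) || any(pv <= 0))
    return(list(loglik = -Inf))
  ll <- sum(log(pv))
  if (!want_deriv) return(list(loglik = ll))

  d <- length(theta)
  Zu <- matrix(0, n, d)
  Zl <- matrix(0, n, d)
  Zu[iu] <- 1
  Zl[il] <- 1
  if (p > 0L) {
    if (proportional) {
      bc <- J1 + seq_len(p)
      Zu[up, bc] <- -X[up, , drop = FALSE]
      Zl[lo, bc] <- -X[lo, , drop = FALSE]
    } else {
      for (cc in seq_len(J1)) {
        bc <- J1 + (cc - 1L) * p + seq_len(p)
        ru <- up & y == cc
        rl <- lo & (y - 1L) == cc
        Zu[ru, bc] <- -X[ru, , drop = FALSE]
        Zl[rl, bc] <- -X[rl, , drop = FALSE]
      }
    }
  }

  # d log p / d theta = (g_u z_u - g_l z_l) / p
  Gm <- (g_u * Zu - g_l * Zl) / pv
  grad <- colSums(Gm)
  # d2 log p = (h_u z_u z_u' - h_l z_l z_l') / p - grad_i grad_i'
  H <- crossprod(Zu, Zu * (h_u / pv)) -
       crossprod(Zl, Zl * (h_l / pv)) -
       crossprod(Gm)
  list(loglik = ll, grad = grad, hess = H)
}

.cl_fit <- function(X, y, J, proportional = TRUE, start = NULL,
                    maxit = 200L, tol = 1e-8) {
  J1 <- J - 1L
  p <- if (is.null(X)) 0L else ncol(X)
  if (is.null(start)) {
    cum <- cumsum(tabulate(y, J))[seq_len(J1)] / length(y)
    start <- c(qlogis(cum), rep(0, .cl_npar(p, J1, proportional) - J1))
  }
  theta <- start
  ev <- .cl_eval(theta, X, y, J, proportional)
  if (!is.finite(ev$loglik))
    stop("invalid starting values for cumulative-logit fit")

  check_separation <- function(theta, gmax) {
    if (p == 0L) return(invisible())
    slopes <- theta[-seq_len(J1)]
    if (any(abs(slopes) > 30) && gmax > 1e-3)
      stop("complete separation: slope diverging with non-vanishing gradient")
  }

  it <- 0L
  repeat {
    it <- it + 1L
    gmax <- max(abs(ev$grad))
    check_separation(theta, gmax)
    if (gmax < tol || it > maxit) break
    step <- tryCatch(solve(ev$hess, ev$grad), error = function(e) NULL)
    if (is.null(step)) stop("singular Hessian in cumulative-logit fit")
    lam <- 1
    improved <- FALSE
    for (h in 1:40) {
      cand <- theta - lam * step
      evc <- .cl_eval(cand, X, y, J, proportional)
      if (is.finite(evc$loglik) && evc$loglik >= ev$loglik - 1e-12) {
        improved <- TRUE
        break
      }
      lam <- lam / 2
    }
    if (!improved) break   # stalled: likelihood flat to machine precision
    theta <- cand
    ev <- evc
  }
  gfin <- max(abs(ev$grad))
  converged <- gfin < tol
  if (!converged && gfin < 1e-5) {
    # step-halving stalled at the likelihood's machine-precision floor (can
    # happen with raw-scale features, e.g. HU in the hundreds); the score is
    # still numerically negligible
    converged <- TRUE
  }
  if (!converged) {
    check_separation(theta, gfin)
    warning("cumulative-logit fit did not reach gradient tolerance (|g|max = ",
            format(gfin), ")")
  }
  vcov <- tryCatch(solve(-ev$hess), error = function(e) {
    warning("observed information is singular; covariance unavailable")
    matrix(NA_real_, length(theta), length(theta))
  })
  list(theta = theta, loglik = ev$loglik, deviance = -2 * ev$loglik,
       vcov = vcov, grad = ev$grad, niter = it, converged = converged)
}
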