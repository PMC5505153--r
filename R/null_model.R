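#' Fit the covariates-only logistic null model
#'
#' Maximum-likelihood fit of \code{logit P(Y=1|X) = X'beta} by
#' Newton-Raphson with step-halving, stopping on the score norm.  The
#' fitted object carries everything the kernel statistics need: fitted
#' null means, residuals \code{Y - mu0}, the weight diagonal
#' \code{mu0 (1 - mu0)}, and cached projection factors for the
#' covariate-adjusted designs.
#'
#' The score equations \code{X'(Y - mu0) = 0} hold at convergence (to
#' \code{tol}); this is what makes the downstream score statistics valid.
#' Fitted probabilities escaping \code{[1e-10, 1 - 1e-10]} indicate
#' (quasi-)separation and raise an error, since the weight matrix becomes
#' numerically singular in the kernels.
#'
#' @param cohort An \code{\link{cohort}} object.
#' @param tol Convergence tolerance on the max-norm of the score vector.
#' @param max_iter Maximum Newton iterations.
#' @return An object of class \code{"null_model"}.
#' @export
fit_null <- function(cohort, tol = 1e-10, max_iter = 100L) {
  if (!inherits(cohort, "itegs_cohort")) stop("`cohort` must be an itegs_cohort")
  x <- cohort$x
  y <- cohort$y
  n <- length(y)
  beta <- numeric(ncol(x))
  mu <- rep.int(0.5, n)
  score <- crossprod(x, y - mu)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    w <- mu * (1 - mu)
    h <- crossprod(x, x * w)
    step <- tryCatch(solve(h, score), error = function(e)
      stop("singular information matrix in the null fit; reduce covariates"))
    # step-halving on the score norm
    s0 <- max(abs(score))
    for (k in 0:30) {
      beta_new <- beta + step / 2^k
      mu_new <- plogis(drop(x %*% beta_new))
      score_new <- crossprod(x, y - mu_new)
      if (max(abs(score_new)) < s0 || k == 30) break
    }
    beta <- beta_new; mu <- mu_new; score <- score_new
  }
  if (!converged && max(abs(score)) >= tol)
    stop("null model did not converge: possible separation; reduce covariates")
  if (any(mu < 1e-10) || any(mu > 1 - 1e-10))
    stop("fitted null probabilities at the boundary (quasi-separation); reduce covariates")

  w <- mu * (1 - mu)
  sw <- sqrt(w)
  xw <- x * w
  xtwx <- crossprod(x, xw)
  # orthonormal basis of the weighted covariate column space, for the
  # half-projection P0^{1/2} v = (I - H) W^{1/2} v
  qx <- qr.Q(qr(x * sw))
  structure(list(
    beta = drop(beta), mu0 = mu, residuals = y - mu, w_diag = w,
    x = x, n = n, sw = sw, xw = xw, xtwx = xtwx,
    xtwx_chol = chol(xtwx), qx = qx,
    score_norm = max(abs(score)), iterations = it
  ), class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf("logistic null model: n = %d, %d covariate(s), score norm %.2e (%d iterations)\n",
              x$n, ncol(x$x), x$score_norm, x$iterations))
  print(round(x$beta, 4))
  invisible(x)
}

# Covariate-adjusted design: V - X (X'WX)^{-1} X'W V.  Rows of its
# transpose are what the perturbation multiplies into r * N^(b).
proj_ztil <- function(null, v) {
  v <- as.matrix(v)
  a <- crossprod(null$xw, v)
  a <- backsolve(null$xtwx_chol, backsolve(null$xtwx_chol, a, transpose = TRUE))
  v - null$x %*% a
}

# Half-projection: returns Phalf V with (Phalf V)'(Phalf V) = V' P0 V,
# P0 = W - WX (X'WX)^{-1} X'W.
proj_phalf <- function(null, v) {
  sv <- as.matrix(v) * null$sw
  sv - null$qx %*% crossprod(null$qx, sv)
}
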