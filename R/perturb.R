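#' Perturbation engine: shared standard-normal draws
#'
#' Draws the n x B matrix of independent standard normals once per
#' analysis.  The same draws are reused for every gene and every disease
#' model, which is what makes the omnibus min-p null distributions jointly
#' valid: the b-th perturbation of each statistic comes from one common
#' realization of the residual noise.  This sharing is structural, not
#' optional.
#'
#' The engine pre-multiplies the draws by the null residuals, so a
#' perturbed score for a design column z is simply \code{z' (r * N^(b))}.
#'
#' @param null A \code{\link{fit_null}} object.
#' @param b Number of perturbations B (values below 100 give coarse
#'   p-value resolution and trigger a warning).
#' @param seed Optional integer seed; when \code{NULL} the current RNG
#'   stream is used.
#' @return Object of class \code{"perturb_engine"}.
#' @export
perturbation_engine <- function(null, b = 1000L, seed = NULL) {
  if (!inherits(null, "null_model")) stop("`null` must be a null_model")
  b <- as.integer(b)
  if (b < 100L) warning("fewer than 100 perturbations: p-value resolution is coarse")
  if (!is.null(seed)) set.seed(seed)
  n <- null$n
  normals <- matrix(rnorm(n * b), n, b)
  structure(list(normals = normals, rn = normals * null$residuals,
                 b = b, n = n, seed = seed),
            class = "perturb_engine")
}

#' @export
print.perturb_engine <- function(x, ...) {
  cat(sprintf("perturbation engine: n = %d, B = %d\n", x$n, x$b))
  invisible(x)
}

#' Perturbation sample of a kernel statistic
#'
#' For each perturbation b, the realization
#' \code{Q^(b) = || Ztil' (r * N^(b)) ||^2 / n}, where \code{Ztil} is the
#' covariate-adjusted weighted design of the test.  This is the quadratic
#' form \code{sum_l (A_l' eps^(b))^2} of the asymptotic representation,
#' with \code{eps^(b) = n^{-1/2} sum_i U_i' r_i N_i^(b)}.
#'
#' @param test A \code{\link{build_kernel}} object.
#' @param engine A \code{\link{perturbation_engine}} built from the same
#'   null model.
#' @return Numeric vector of B perturbed statistics.
#' @export
perturb_q <- function(test, engine) {
  if (engine$n != test$n) stop("engine and test were built on different cohorts")
  colSums(crossprod(test$ztil, engine$rn)^2) / test$n
}
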