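#' Satterthwaite p-value for a mixture of chi-squares
#'
#' Matches the first two moments of \code{sum_l lambda_l chi^2_1} by a
#' scaled chi-square \code{kappa * chi^2_nu} with
#' \code{kappa = sum(lambda^2) / sum(lambda)} and
#' \code{nu = sum(lambda)^2 / sum(lambda^2)}, and returns the upper tail
#' at \code{q_obs}.  Exact when all weights are equal.
#'
#' @param q_obs Observed statistic.
#' @param lambda Non-negative mixture weights, not all zero.
#' @return Upper-tail p-value.
#' @export
satterthwaite_p <- function(q_obs, lambda) {
  lambda <- check_lambda(lambda)
  s1 <- sum(lambda)
  s2 <- sum(lambda^2)
  stats::pchisq(q_obs * s1 / s2, df = s1^2 / s2, lower.tail = FALSE)
}

#' Characteristic-function inversion p-value for a mixture of chi-squares
#'
#' Computes \code{P(sum_l lambda_l chi^2_1 > q_obs)} by numerical
#' inversion of the characteristic function (Imhof's integral), accurate
#' to roughly \code{acc}.  If the quadrature fails the Satterthwaite
#' approximation is returned with a warning.  The result is clipped into
#' \code{(1e-12, 1]}.
#'
#' @param q_obs Observed statistic (p = 1 when \code{q_obs <= 0}).
#' @param lambda Non-negative mixture weights, not all zero.
#' @param acc Target absolute accuracy of the inversion.
#' @return Upper-tail p-value.
#' @export
davies_p <- function(q_obs, lambda, acc = 1e-6) {
  lambda <- check_lambda(lambda)
  if (q_obs <= 0) return(1)
  # one component: the mixture is exactly a scaled chi-square(1)
  if (length(lambda) == 1L)
    return(stats::pchisq(q_obs / lambda, df = 1, lower.tail = FALSE))
  integrand <- function(u) {
    lu <- outer(lambda, u)
    theta <- 0.5 * colSums(atan(lu)) - 0.5 * q_obs * u
    log_rho <- 0.25 * colSums(log1p(lu^2))
    ifelse(u == 0, 0.5 * (sum(lambda) - q_obs), sin(theta) * exp(-log_rho) / u)
  }
  # adaptive quadrature works whenever the integrand decays fast enough
  # (many components); with few components it can fail to converge, in
  # which case a midpoint rule with explicit truncation and aliasing
  # bounds takes over.
  p <- tryCatch({
    it <- stats::integrate(integrand, 0, Inf, abs.tol = acc,
                           rel.tol = acc, subdivisions = 1000L,
                           stop.on.error = TRUE)
    0.5 + it$value / pi
  }, error = function(e) NA_real_)
  if (is.na(p)) p <- imhof_midpoint(q_obs, lambda, acc, integrand)
  if (is.na(p) || p < -1e-4 || p > 1 + 1e-4) {
    warning("characteristic-function inversion failed; falling back to Satterthwaite")
    p <- satterthwaite_p(q_obs, lambda)
  }
  min(max(p, 1e-12), 1)
}

# Midpoint-rule inversion of the mixture characteristic function.
# Truncation point U: the integrand oscillates at rate ~ q/2 with
# envelope exp(-0.25 sum log1p(lambda^2 u^2)) / u, so the truncated tail
# is bounded by ~ 2 * envelope(U) / (pi * q/2).  Step size: aliasing of
# the midpoint rule is bounded by the mixture tail beyond q + 2*pi/step,
# placed far out via an inflated Satterthwaite quantile.
imhof_midpoint <- function(q_obs, lambda, acc, integrand) {
  envelope <- function(u) exp(-0.25 * sum(log1p(lambda^2 * u^2))) / u
  omega <- 0.5 * max(q_obs, 0.05 * sum(lambda))
  target <- acc * pi * omega / 2
  u_hi <- 1 / max(lambda)
  while (envelope(u_hi) > target && u_hi < 1e12) u_hi <- u_hi * 2
  s1 <- sum(lambda); s2 <- sum(lambda^2)
  far <- 3 * (s2 / s1) * stats::qchisq(1e-12, df = s1^2 / s2, lower.tail = FALSE) + s1
  step <- 2 * pi / (q_obs + far)
  n_pts <- ceiling(u_hi / step)
  if (n_pts > 5e6) return(NA_real_)
  u <- (seq_len(n_pts) - 0.5) * step
  0.5 + step * sum(integrand(u)) / pi
}

check_lambda <- function(lambda) {
  if (length(lambda) == 0L) stop("empty mixture weight vector")
  if (any(lambda < -1e-8)) stop("negative mixture weights")
  lambda <- pmax(lambda, 0)
  if (all(lambda == 0)) stop("all mixture weights are zero")
  lambda[lambda > 0]
}

#' Empirical (perturbation) p-value
#'
#' Add-one proportion of null draws at least as extreme as the observed
#' statistic: \code{p = (1 + #\{draws >= q_obs\}) / (B + 1)}.  The add-one
#' rule keeps p strictly positive, so downstream min-p transforms are
#' well defined; the smallest attainable value is \code{1 / (B + 1)}.
#'
#' @param q_obs Observed statistic.
#' @param q_null Vector of B null draws.
#' @return Empirical upper-tail p-value.
#' @export
empirical_p <- function(q_obs, q_null) {
  b <- length(q_null)
  if (b < 1L) stop("need at least one null draw")
  (1 + sum(q_null >= q_obs)) / (b + 1)
}

# Leave-self-in empirical p-values for every draw of a null sample,
# on the same add-one scale as the observed p: for draw b,
# p_b = #{b': q[b'] >= q[b]} / (B + 1).
perturbed_p <- function(q_null) {
  b <- length(q_null)
  (b + 1 - rank(q_null, ties.method = "min")) / (b + 1)
}

#' Chi-square(1) quantile of a tail probability
#'
#' Maps a p-value to the chi-square(1) statistic with that upper-tail
#' probability, the transform used to pool minimum p-values across genes.
#'
#' @param p Probability in (0, 1].
#' @return Non-negative chi-square(1) quantile (0 when \code{p = 1}).
#' @export
min_p_transform <- function(p) {
  if (any(p <= 0) || any(p > 1)) stop("p must lie in (0, 1]")
  stats::qchisq(p, df = 1, lower.tail = FALSE)
}
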