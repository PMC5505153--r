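#' Per-gene score statistics and component weights
#'
#' Computes, for the components a gene block carries, the score statistics
#' of the variance-component test: \code{U_tau_M = r' M M' r} for the CpG
#' block, \code{U_beta_G = G' r} for expression, and
#' \code{U_tau_C = r' C C' r} for the within-gene interactions, where
#' \code{r = Y - mu0} are the null-model residuals.  The component weights
#' \code{a1, a2, a3} are the inverse square roots of the null variances of
#' \code{U_tau_M}, \code{U_beta_G^2} and \code{U_tau_C}, so the three
#' pieces enter the Q statistic on a common scale.
#'
#' Analytic weights (the default) use the null covariance of the residuals,
#' \code{P0 = W - WX (X'WX)^{-1} X'W}: \code{Var(U_tau_M) = 2 tr((P0 MM')^2)},
#' \code{Var(U_beta_G^2) = 2 (G'P0G)^2}, and analogously for \code{C}.
#' With \code{weights = "perturbation"} the variances are instead the
#' sample variances of the perturbed component statistics (a sensitivity
#' option; requires \code{engine}).
#'
#' @param block A \code{\link{gene_block}}.
#' @param null A \code{\link{fit_null}} object.
#' @param weights \code{"analytic"} (default) or \code{"perturbation"}.
#' @param engine A \code{\link{perturbation_engine}}, only for
#'   \code{weights = "perturbation"}.
#' @return List of class \code{"score_components"} with the statistics and
#'   weights (absent components are \code{NA}).
#' @export
score_components <- function(block, null, weights = c("analytic", "perturbation"),
                             engine = NULL) {
  weights <- match.arg(weights)
  if (weights == "perturbation" && is.null(engine))
    stop("perturbation-based weights need a perturbation engine")
  r <- null$residuals
  n <- null$n
  out <- list(u_tau_m = NA_real_, u_beta_g = NA_real_, u_tau_c = NA_real_,
              a1 = NA_real_, a2 = NA_real_, a3 = NA_real_)

  comp_var <- function(v, label) {
    bad <- which(apply(as.matrix(v), 2, stats::var) <= 0)
    if (length(bad))
      stop(sprintf("zero-variance column(s) in %s (%s): weight undefined",
                   label, paste(colnames(as.matrix(v))[bad], collapse = ", ")))
    if (weights == "analytic") {
      cp <- crossprod(proj_phalf(null, v))
      2 * sum(cp^2)
    } else {
      zt <- proj_ztil(null, v)
      ub <- colSums(crossprod(zt, engine$rn)^2)
      stats::var(ub)
    }
  }

  if (!is.null(block$m)) {
    out$u_tau_m <- sum(crossprod(block$m, r)^2)
    vv <- comp_var(block$m, sprintf("methylation of %s", block$gene_id))
    if (vv <= 0) stop("degenerate methylation component")
    out$a1 <- 1 / sqrt(vv)
  }
  if (!is.null(block$g)) {
    out$u_beta_g <- sum(block$g * r)
    if (weights == "analytic") {
      sig <- sum(proj_phalf(null, block$g)^2)
      if (sig <= 0) stop(sprintf("zero-variance expression for %s", block$gene_id))
      out$a2 <- 1 / sqrt(2 * sig^2)
    } else {
      zt <- proj_ztil(null, block$g)
      ub <- colSums(crossprod(zt, engine$rn)^2)
      out$a2 <- 1 / stats::sd(ub)
    }
  }
  if (!is.null(block$c)) {
    out$u_tau_c <- sum(crossprod(block$c, r)^2)
    vv <- comp_var(block$c, sprintf("interactions of %s", block$gene_id))
    out$a3 <- 1 / sqrt(vv)
  }
  structure(out, class = "score_components")
}

# Weighted per-gene design V = (sqrt(a1) M, sqrt(a2) G, sqrt(a3) C)
# restricted to a disease model; the gene kernel is V V'.
model_design <- function(block, sc, model) {
  parts <- list()
  if (model %in% c("M", "MG", "MGC")) parts$m <- sqrt(sc$a1) * block$m
  if (model %in% c("G", "MG", "MGC")) parts$g <- sqrt(sc$a2) * matrix(block$g, ncol = 1)
  if (model == "MGC") parts$c <- sqrt(sc$a3) * block$c
  do.call(cbind, parts)
}

model_q <- function(sc, model, n) {
  q <- 0
  if (model %in% c("M", "MG", "MGC")) q <- q + sc$a1 * sc$u_tau_m
  if (model %in% c("G", "MG", "MGC")) q <- q + sc$a2 * sc$u_beta_g^2
  if (model == "MGC") q <- q + sc$a3 * sc$u_tau_c
  q / n
}

#' Build a single-gene kernel test
#'
#' Assembles the model-restricted kernel
#' \code{K = a1 MM' + a2 GG' + a3 CC'} (terms as allowed by \code{model}),
#' the observed statistic \code{Q = r' K r / n}, and the mixture weights
#' \code{lambda} of the asymptotic null distribution (eigenvalues of
#' \code{V' P0 V / n}; small negatives clipped at zero).
#'
#' @param block A \code{\link{gene_block}}.
#' @param null A \code{\link{fit_null}} object.
#' @param model One of \code{"M"}, \code{"G"}, \code{"MG"}, \code{"MGC"}.
#' @param a_weights Optional fixed weights \code{c(a1, a2, a3)} overriding
#'   the variance-based ones (used e.g. to compare nested models on a
#'   common scale).
#' @param keep_kernel Store the n x n kernel matrix itself (default TRUE;
#'   the set-level code paths avoid it).
#' @return Object of class \code{"kernel_test"}.
#' @export
build_kernel <- function(block, null, model = c("MGC", "MG", "M", "G"),
                         a_weights = NULL, keep_kernel = TRUE) {
  model <- match.arg(model)
  if (!model %in% block_models(block))
    stop(sprintf("gene %s lacks the data for model %s", block$gene_id, model))
  sc <- score_components(block, null)
  if (!is.null(a_weights)) {
    sc$a1 <- a_weights[1]; sc$a2 <- a_weights[2]; sc$a3 <- a_weights[3]
  }
  v <- model_design(block, sc, model)
  n <- null$n
  q_obs <- sum(crossprod(v, null$residuals)^2) / n
  phalf <- proj_phalf(null, v)
  lambda <- gram_eigenvalues(phalf, n)
  structure(list(
    gene_id = block$gene_id, model = model, q_obs = q_obs,
    kernel = if (keep_kernel) tcrossprod(v) else NULL,
    v = v, ztil = proj_ztil(null, v), phalf = phalf,
    lambda = lambda, n = n,
    a_weights = c(a1 = sc$a1, a2 = sc$a2, a3 = sc$a3),
    components = sc
  ), class = "kernel_test")
}

#' @export
print.kernel_test <- function(x, ...) {
  cat(sprintf("kernel test (%s, model %s): Q = %.4g, %d mixture component(s)\n",
              x$gene_id, x$model, x$q_obs, length(x$lambda)))
  invisible(x)
}

# Non-negligible eigenvalues of phalf'phalf / n, computed on the smaller
# Gram side; tiny/negative values from finite precision are dropped.
gram_eigenvalues <- function(phalf, n) {
  gram <- if (ncol(phalf) <= nrow(phalf)) crossprod(phalf) else tcrossprod(phalf)
  ev <- eigen(gram / n, symmetric = TRUE, only.values = TRUE)$values
  ev[ev < 0] <- 0
  tol <- max(ev) * 1e-12
  ev[ev > tol]
}

#' Mixture weights of a kernel test's null distribution
#'
#' The statistic is asymptotically \code{sum_l lambda_l chi^2_1}; the
#' \code{lambda} are the non-zero eigenvalues of the covariate-projected
#' kernel \code{V' P0 V / n} (equivalently of \code{A D A'} in the
#' perturbation notation).  Negative round-off eigenvalues are clipped to
#' zero.
#'
#' @param test A \code{\link{build_kernel}} object.
#' @param null The matching \code{\link{fit_null}} object.
#' @return Numeric vector of non-negative mixture weights.
#' @export
mixture_weights <- function(test, null) {
  gram_eigenvalues(proj_phalf(null, test$v), null$n)
}
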