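#' Define a simulation scenario
#'
#' Parameterizes one synthetic study: a cohort of \code{cohort_n} subjects
#' with \code{j_genes} genes of \code{p_per_gene} CpG loci each, CpG
#' blocks with exchangeable latent correlation \code{rho_within} mapped to
#' the (0, 1) beta-value scale, expression driven by one causal CpG per
#' gene with equicorrelated multivariate-normal residuals
#' (between-gene covariance \code{rho_between_expr}), a logistic disease
#' model over the causal genes with effect multiplier \code{kappa}, and a
#' case-control subsample.
#'
#' The seven standard disease-model mixtures for the causal genes are:
#' 1 all M; 2 all MG; 3 all MGC; 4 M/MG half each; 5 M/MGC; 6 MG/MGC;
#' 7 one-third each of M, MG, MGC (as even as possible, remainders to the
#' earlier models in the order given).
#'
#' @param j_genes Number of genes J.
#' @param p_per_gene CpG loci per gene.
#' @param rho_within Exchangeable correlation of the latent Gaussian CpG
#'   block, in [0, 1).
#' @param rho_between_expr Between-gene covariance of the expression
#'   residuals (unit variances), in [0, 1).
#' @param cohort_n Cohort size from which cases/controls are drawn.
#' @param n_cases,n_controls Case-control subsample sizes.
#' @param signal_density Fraction of genes that are causal, in (0, 1].
#' @param model_mix Scenario index 1-7 or a character subset of
#'   \code{c("M", "MG", "MGC")} naming the mixture components.
#' @param kappa Effect multiplier applied to all causal coefficients
#'   (\code{kappa = 0} is the global null).
#' @param beta_m,beta_g,beta_c Base effect sizes of the causal CpG, the
#'   expression, and their interaction in the disease model.
#' @param delta0,delta Intercept and slope of the expression-on-causal-CpG
#'   regression.
#' @param base_prevalence Target cohort prevalence; the disease-model
#'   intercept is solved numerically to achieve it.
#' @return Object of class \code{"sim_scenario"}.
#' @export
sim_scenario <- function(j_genes = 50L, p_per_gene = 11L, rho_within = 0.8,
                         rho_between_expr = 0.7, cohort_n = 681L,
                         n_cases = 100L, n_controls = 100L,
                         signal_density = 0.2, model_mix = 1L, kappa = 0,
                         beta_m = 0.5, beta_g = 0.5, beta_c = 0.5,
                         delta0 = 0, delta = 1, base_prevalence = 0.3) {
  mixes <- list(`1` = "M", `2` = "MG", `3` = "MGC", `4` = c("M", "MG"),
                `5` = c("M", "MGC"), `6` = c("MG", "MGC"),
                `7` = c("M", "MG", "MGC"))
  if (is.numeric(model_mix)) {
    model_mix <- mixes[[as.character(as.integer(model_mix))]]
    if (is.null(model_mix)) stop("scenario index must be 1..7")
  }
  if (!all(model_mix %in% c("M", "MG", "MGC")))
    stop("model_mix components must be M, MG or MGC")
  stopifnot(signal_density > 0, signal_density <= 1,
            rho_within >= 0, rho_within < 1,
            rho_between_expr >= 0, rho_between_expr < 1,
            n_cases + n_controls <= cohort_n,
            base_prevalence > 0, base_prevalence < 1)
  structure(list(
    j_genes = as.integer(j_genes), p_per_gene = as.integer(p_per_gene),
    rho_within = rho_within, rho_between_expr = rho_between_expr,
    cohort_n = as.integer(cohort_n), n_cases = as.integer(n_cases),
    n_controls = as.integer(n_controls), signal_density = signal_density,
    model_mix = model_mix, kappa = kappa,
    beta_m = beta_m, beta_g = beta_g, beta_c = beta_c,
    delta0 = delta0, delta = delta, base_prevalence = base_prevalence
  ), class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(paste0("simulation scenario: J = %d genes x %d CpGs, cohort %d ",
                     "(%d+%d case-control)\n  kappa = %g, density = %g, mix = %s\n"),
              x$j_genes, x$p_per_gene, x$cohort_n, x$n_cases, x$n_controls,
              x$kappa, x$signal_density, paste(x$model_mix, collapse = "/")))
  invisible(x)
}

#' Simulate correlated CpG methylation blocks
#'
#' Per gene, an exchangeable-correlation latent Gaussian block
#' (correlation \code{rho_within}) mapped to the (0, 1) beta-value scale
#' by the logistic function.  The first locus of each gene is the
#' designated causal CpG that drives expression and (for causal genes)
#' disease risk.
#'
#' @param scn A \code{\link{sim_scenario}}.
#' @return List of J methylation matrices (\code{cohort_n} x
#'   \code{p_per_gene}), with attribute \code{causal_locus = 1}.
#' @export
simulate_methylation <- function(scn) {
  n <- scn$cohort_n; p <- scn$p_per_gene; rho <- scn$rho_within
  meth <- vector("list", scn$j_genes)
  for (j in seq_len(scn$j_genes)) {
    z0 <- rnorm(n)
    z <- sqrt(rho) * z0 + sqrt(1 - rho) * matrix(rnorm(n * p), n, p)
    m <- plogis(z)
    dimnames(m) <- list(paste0("S", seq_len(n)),
                        sprintf("g%03d_cg%02d", j, seq_len(p)))
    meth[[j]] <- m
  }
  names(meth) <- sprintf("gene%03d", seq_len(scn$j_genes))
  attr(meth, "causal_locus") <- 1L
  meth
}

#' Simulate expression from the causal CpG of each gene
#'
#' \code{G_j = delta0 + delta * M_causal_j + eps_j} with residual rows
#' multivariate normal: unit variances and constant between-gene
#' covariance \code{rho_between_expr} (generated from a shared factor, so
#' the covariance matrix is positive definite for any value in [0, 1)).
#'
#' @param meth Output of \code{\link{simulate_methylation}}.
#' @param scn The matching \code{\link{sim_scenario}}.
#' @return Expression matrix, \code{cohort_n} x J.
#' @export
simulate_expression <- function(meth, scn) {
  n <- scn$cohort_n; jg <- scn$j_genes; rho <- scn$rho_between_expr
  cl <- attr(meth, "causal_locus")
  m_causal <- vapply(meth, function(m) m[, cl], numeric(n))
  u0 <- rnorm(n)
  eps <- sqrt(rho) * u0 + sqrt(1 - rho) * matrix(rnorm(n * jg), n, jg)
  expr <- scn$delta0 + scn$delta * m_causal + eps
  dimnames(expr) <- list(paste0("S", seq_len(n)), names(meth))
  expr
}

# Even split of n_causal genes over the mixture components: floor each,
# remainders assigned to the earlier models in mixture order.
mix_assignment <- function(n_causal, mix) {
  k <- length(mix)
  counts <- rep(n_causal %/% k, k) + (seq_len(k) <= n_causal %% k)
  rep(mix, times = counts)
}

#' Simulate disease outcomes and draw the case-control sample
#'
#' Causal genes are drawn at random per \code{signal_density} and
#' assigned disease models per \code{model_mix}.  The cohort linear
#' predictor sums, over causal genes, \code{kappa * beta_m * M_causal}
#' (all models), \code{+ kappa * beta_g * G} (MG, MGC), and
#' \code{+ kappa * beta_c * M_causal * G} (MGC).  The intercept is solved
#' numerically so the realized cohort prevalence matches
#' \code{base_prevalence}, outcomes are Bernoulli draws, and
#' \code{n_cases + n_controls} subjects are sampled without replacement.
#'
#' @param meth,expr Outputs of the two generators above.
#' @param scn The matching \code{\link{sim_scenario}}.
#' @return List: \code{cohort} (the case-control
#'   \code{\link{cohort}}, intercept-only covariates), \code{idx} (cohort
#'   row indices sampled), \code{causal} (tibble gene/model), \code{beta0}
#'   and the realized cohort prevalence.
#' @export
simulate_outcome <- function(meth, expr, scn) {
  n <- scn$cohort_n
  cl <- attr(meth, "causal_locus")
  n_causal <- max(1L, round(scn$signal_density * scn$j_genes))
  causal_idx <- sort(sample(scn$j_genes, n_causal))
  assignment <- mix_assignment(n_causal, scn$model_mix)

  eta <- numeric(n)
  if (scn$kappa != 0) {
    for (k in seq_len(n_causal)) {
      j <- causal_idx[k]
      mc <- meth[[j]][, cl]
      eta <- eta + scn$kappa * scn$beta_m * mc
      if (assignment[k] %in% c("MG", "MGC"))
        eta <- eta + scn$kappa * scn$beta_g * expr[, j]
      if (assignment[k] == "MGC")
        eta <- eta + scn$kappa * scn$beta_c * mc * expr[, j]
    }
  }
  beta0 <- uniroot(function(b0) mean(plogis(b0 + eta)) - scn$base_prevalence,
                   interval = c(-40, 40), tol = 1e-10)$root
  y <- rbinom(n, 1L, plogis(beta0 + eta))
  cases <- which(y == 1L); controls <- which(y == 0L)
  if (length(cases) < scn$n_cases || length(controls) < scn$n_controls)
    stop(sprintf(paste0("cohort produced %d cases / %d controls; need %d + %d. ",
                        "Adjust base_prevalence or the cohort size."),
                 length(cases), length(controls), scn$n_cases, scn$n_controls))
  idx <- sort(c(sample(cases, scn$n_cases), sample(controls, scn$n_controls)))
  co <- cohort(y[idx], subject_ids = paste0("S", idx))
  list(cohort = co, idx = idx,
       causal = tibble::tibble(gene = names(meth)[causal_idx],
                               model = assignment),
       beta0 = beta0, prevalence = mean(y))
}

#' Simulate one complete case-control dataset
#'
#' Runs the three generators in sequence and packages the case-control
#' subsample as ready-to-test \code{\link{gene_block}}s.
#'
#' @param scn A \code{\link{sim_scenario}}.
#' @param seed Optional seed; when \code{NULL} the current RNG stream is
#'   used (so studies can drive many replicates from one seed).
#' @return List of class \code{"sim_dataset"}: \code{cohort},
#'   \code{blocks}, \code{causal}, \code{meth}, \code{expr}, \code{idx},
#'   \code{scn}.
#' @export
simulate_dataset <- function(scn, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  meth <- simulate_methylation(scn)
  expr <- simulate_expression(meth, scn)
  out <- simulate_outcome(meth, expr, scn)
  blocks <- lapply(seq_len(scn$j_genes), function(j) {
    gene_block(names(meth)[j],
               m = meth[[j]][out$idx, , drop = FALSE],
               g = expr[out$idx, j])
  })
  structure(list(cohort = out$cohort, blocks = blocks, causal = out$causal,
                 meth = meth, expr = expr, idx = out$idx, beta0 = out$beta0,
                 prevalence = out$prevalence, scn = scn),
            class = "sim_dataset")
}
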