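# In-code fixtures and independent oracles used across the suite.

# Small random cohort + blocks (all platforms present).
toy_data <- function(n = 60, j = 3, p = 4, seed = 1, r_cov = 0) {
  set.seed(seed)
  x <- if (r_cov > 0) cbind(1, matrix(rnorm(n * r_cov), n)) else NULL
  co <- cohort(rbinom(n, 1, 0.5), x = x)
  # regenerate until both classes present with a sane split
  while (sum(co$y) < 5 || sum(co$y) > n - 5)
    co <- cohort(rbinom(n, 1, 0.5), x = x)
  blocks <- lapply(seq_len(j), function(jj) {
    gene_block(sprintf("g%d", jj),
               m = matrix(rnorm(n * p), n, p),
               g = rnorm(n))
  })
  list(cohort = co, blocks = blocks)
}

# Independent Newton-Raphson logistic MLE (dense, no step control).
oracle_logistic <- function(y, x, iter = 50) {
  beta <- numeric(ncol(x))
  for (i in seq_len(iter)) {
    mu <- plogis(drop(x %*% beta))
    beta <- beta + solve(crossprod(x, x * (mu * (1 - mu))),
                         crossprod(x, y - mu))
  }
  drop(beta)
}

# Dense-matrix oracle for the mixture weights: eigenvalues of A D A'
# built literally from the partitioned D = U'WU / n,
# A = [-D_XV' D_XX^{-1}, I].
oracle_mixture_weights <- function(x, v, w, n) {
  u <- cbind(x, v)
  d <- crossprod(u, u * w) / n
  ix <- seq_len(ncol(x))
  d_xx <- d[ix, ix, drop = FALSE]
  d_xv <- d[ix, -ix, drop = FALSE]
  a <- cbind(-t(d_xv) %*% solve(d_xx), diag(ncol(v)))
  ev <- eigen(a %*% d %*% t(a), symmetric = TRUE, only.values = TRUE)$values
  ev[ev > max(ev) * 1e-12]
}

# Literal perturbation: eps^(b) = n^{-1/2} U'(r * N_b); Q^(b) = ||A eps||^2.
oracle_perturb <- function(x, v, w, r, normals, n) {
  u <- cbind(x, v)
  d <- crossprod(u, u * w) / n
  ix <- seq_len(ncol(x))
  a <- cbind(-t(d[ix, -ix, drop = FALSE]) %*% solve(d[ix, ix, drop = FALSE]),
             diag(ncol(v)))
  apply(normals, 2, function(nb) {
    eps <- crossprod(u, r * nb) / sqrt(n)
    sum((a %*% eps)^2)
  })
}

# Monte-Carlo tail of a chi-square mixture.
mc_mixture_tail <- function(q, lambda, n_draws = 1e6, seed = 1234) {
  set.seed(seed)
  draws <- colSums(matrix(rchisq(n_draws * length(lambda), df = 1),
                          nrow = length(lambda)) * lambda)
  mean(draws > q)
}
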