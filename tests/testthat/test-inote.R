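# Literal reference implementation of both omnibus algorithms, written as
# a plain double loop over genes and models straight from their
# definitions, sharing the engine's normal draws.  Used as an oracle for
# the vectorized implementation.
reference_inote <- function(blocks, nm, eng) {
  b <- eng$b
  models <- c("M", "G", "MG", "MGC")
  q_obs <- list(); q_per <- list()
  for (jj in seq_along(blocks)) {
    for (mod in intersect(models, block_models(blocks[[jj]]))) {
      kt <- build_kernel(blocks[[jj]], nm, mod)
      key <- paste(jj, mod)
      q_obs[[key]] <- kt$q_obs
      q_per[[key]] <- oracle_perturb(nm$x, kt$v, nm$w_diag, nm$residuals,
                                     eng$normals, nm$n)
    }
  }
  p_of <- function(q, draws) (1 + sum(draws >= q)) / (b + 1)
  pb_of <- function(draws) vapply(draws, function(d) sum(draws >= d) / (b + 1),
                                  numeric(1))
  # chi branch
  t_obs <- 0; t_b <- numeric(b)
  for (jj in seq_along(blocks)) {
    mods <- intersect(models, block_models(blocks[[jj]]))
    pmin_obs <- Inf; pmin_b <- rep(Inf, b)
    for (mod in mods) {
      key <- paste(jj, mod)
      pmin_obs <- min(pmin_obs, p_of(q_obs[[key]], q_per[[key]]))
      pmin_b <- pmin(pmin_b, pb_of(q_per[[key]]))
    }
    t_obs <- t_obs + qchisq(pmin_obs, 1, lower.tail = FALSE)
    t_b <- t_b + qchisq(pmin_b, 1, lower.tail = FALSE)
  }
  p_chi <- (1 + sum(t_b >= t_obs)) / (b + 1)
  # uni branch: per-model pooled statistics with analytic SD weights
  p_net <- c(); pminb <- rep(Inf, b)
  for (mod in models) {
    ok <- vapply(blocks, function(x) mod %in% block_models(x), logical(1))
    if (!any(ok)) next
    qn <- 0; qnb <- numeric(b)
    for (jj in which(ok)) {
      key <- paste(jj, mod)
      kt <- build_kernel(blocks[[jj]], nm, mod)
      ph <- itegs:::proj_phalf(nm, kt$v)
      w_j <- nm$n / sqrt(2 * sum(crossprod(ph)^2))
      qn <- qn + w_j * q_obs[[key]]
      qnb <- qnb + w_j * q_per[[key]]
    }
    p_net[mod] <- p_of(qn, qnb)
    pminb <- pmin(pminb, pb_of(qnb))
  }
  p_uni <- (1 + sum(pminb <= min(p_net))) / (b + 1)
  list(p_chi = p_chi, p_uni = p_uni, t_obs = t_obs,
       selected = names(p_net)[which.min(p_net)])
}

test_that("both omnibus tests match a literal double-loop reference", {
  for (seed in c(5, 23)) {
    td <- toy_data(n = 50, j = 3, p = 3, seed = seed, r_cov = 1)
    nm <- fit_null(td$cohort)
    # mixed availability: add an expression-only gene
    set.seed(seed + 100)
    blocks <- c(td$blocks, list(gene_block("gonly", g = rnorm(50))))
    eng <- perturbation_engine(nm, b = 150, seed = seed)
    res <- suppressMessages(inote_test(blocks, nm, engine = eng))
    ref <- suppressMessages(reference_inote(blocks, nm, eng))
    expect_equal(res$table$p_inote_chi, ref$p_chi)
    expect_equal(res$table$p_inote_uni, ref$p_uni)
    expect_equal(res$table$t_net_obs, ref$t_obs, tolerance = 1e-10)
    expect_identical(res$table$selected_model, ref$selected)
  }
})

test_that("T_net equals the sum of per-gene chi-square(1) quantiles", {
  td <- toy_data(n = 40, j = 3, p = 2, seed = 6)
  nm <- fit_null(td$cohort)
  res <- inote_test(td$blocks, nm, b = 200, seed = 9)
  p_min <- tapply(res$per_gene$p, res$per_gene$gene_id, min)
  expect_equal(res$table$t_net_obs,
               sum(min_p_transform(p_min)), tolerance = 1e-10)
  # p-values respect the add-one floor
  expect_gte(res$table$p_inote_chi, 1 / 201)
  expect_gte(res$table$p_inote_uni, 1 / 201)
})

test_that("a single gene with a single model degenerates to that model's p", {
  set.seed(51)
  n <- 60
  co <- cohort(rbinom(n, 1, 0.5))
  nm <- fit_null(co)
  bl <- gene_block("solo", m = matrix(rnorm(n * 3), n))  # model M only
  eng <- perturbation_engine(nm, b = 400, seed = 3)
  res <- suppressMessages(inote_test(list(bl), nm, engine = eng))
  kt <- build_kernel(bl, nm, "M")
  p_m <- empirical_p(kt$q_obs, perturb_q(kt, eng))
  # both branches reduce to that model's p up to add-one resolution
  expect_lt(abs(res$table$p_inote_uni - p_m), 2 / (eng$b + 1) + 1e-12)
  expect_lt(abs(res$table$p_inote_chi - p_m), 2 / (eng$b + 1) + 1e-12)
  expect_identical(res$table$selected_model, "M")
})

test_that("model ties in the uni branch break in fixed order M, G, MG, MGC", {
  machs <- list(
    M  = list(gene_ids = "g", n_t = 1L, q_gene = 1, w = 1, q_net = 5,
              qb_gene = matrix(1:10 / 10, 1), qb_net = 1:10 / 10),
    G  = list(gene_ids = "g", n_t = 1L, q_gene = 1, w = 1, q_net = 5,
              qb_gene = matrix(1:10 / 10, 1), qb_net = 1:10 / 10))
  eng <- list(b = 10L)
  res <- itegs:::inote_from_machinery(machs, eng, n0 = 1L)
  expect_identical(res$table$selected_model, "M")
})

test_that("omnibus p-values are invariant to gene order", {
  td <- toy_data(n = 40, j = 4, p = 2, seed = 27)
  nm <- fit_null(td$cohort)
  eng <- perturbation_engine(nm, b = 150, seed = 12)
  r1 <- inote_test(td$blocks, nm, engine = eng)
  r2 <- inote_test(rev(td$blocks), nm, engine = eng)
  expect_equal(r1$table$p_inote_chi, r2$table$p_inote_chi)
  expect_equal(r1$table$p_inote_uni, r2$table$p_inote_uni)
  expect_equal(r1$table$t_net_obs, r2$table$t_net_obs, tolerance = 1e-10)
})
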