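test_that("methylation blocks have the requested latent correlation", {
  scn0 <- sim_scenario(j_genes = 3, rho_within = 0, cohort_n = 681)
  set.seed(61)
  meth <- simulate_methylation(scn0)
  cors <- cor(qlogis(meth[[1]]))
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.1)

  scn8 <- sim_scenario(j_genes = 3, rho_within = 0.8, cohort_n = 681)
  set.seed(62)
  meth8 <- simulate_methylation(scn8)
  cors8 <- cor(qlogis(meth8[[2]]))
  expect_lt(abs(mean(cors8[upper.tri(cors8)]) - 0.8), 0.05)
  # beta-value scale
  expect_true(all(meth8[[1]] > 0 & meth8[[1]] < 1))
})

test_that("expression residuals carry the between-gene covariance", {
  scn <- sim_scenario(j_genes = 8, cohort_n = 681, delta = 0)
  set.seed(63)
  meth <- simulate_methylation(scn)
  expr <- simulate_expression(meth, scn)
  cc <- cov(expr)
  expect_lt(abs(mean(cc[upper.tri(cc)]) - 0.7), 0.05)
  expect_lt(abs(mean(diag(cc)) - 1), 0.1)
})

test_that("expression tracks the causal CpG when the slope dominates", {
  scn <- sim_scenario(j_genes = 4, rho_within = 0, cohort_n = 681, delta = 5)
  set.seed(64)
  meth <- simulate_methylation(scn)
  expr <- simulate_expression(meth, scn)
  for (j in 1:4) expect_gt(cor(expr[, j], meth[[j]][, 1]), 0.65)
})

test_that("the intercept solver hits the target prevalence at kappa = 0", {
  scn <- sim_scenario(j_genes = 2, kappa = 0, base_prevalence = 0.3)
  set.seed(65)
  meth <- simulate_methylation(scn)
  expr <- simulate_expression(meth, scn)
  out <- simulate_outcome(meth, expr, scn)
  expect_lt(abs(out$prevalence - 0.3), 0.05)
  expect_equal(sum(out$cohort$y), scn$n_cases)
  expect_equal(sum(1 - out$cohort$y), scn$n_controls)
  # too-ambitious case-control demand errors out
  scn_bad <- sim_scenario(j_genes = 2, kappa = 0, base_prevalence = 0.05,
                          n_cases = 300, n_controls = 300)
  set.seed(66)
  meth_b <- simulate_methylation(scn_bad)
  expr_b <- simulate_expression(meth_b, scn_bad)
  expect_error(simulate_outcome(meth_b, expr_b, scn_bad), "cases")
})

test_that("causal-gene counts and model mixtures split as evenly as possible", {
  expect_identical(itegs:::mix_assignment(10, c("M", "MG", "MGC")),
                   c(rep("M", 4), rep("MG", 3), rep("MGC", 3)))
  expect_identical(itegs:::mix_assignment(9, c("M", "MG", "MGC")),
                   rep(c("M", "MG", "MGC"), each = 3))
  expect_identical(itegs:::mix_assignment(5, c("M", "MGC")),
                   c(rep("M", 3), rep("MGC", 2)))
  scn <- sim_scenario(j_genes = 50, signal_density = 0.2, model_mix = 7,
                      kappa = 0.5)
  set.seed(67)
  dat <- simulate_dataset(scn)
  expect_equal(nrow(dat$causal), 10)
  expect_equal(unname(table(dat$causal$model)[c("M", "MG", "MGC")]),
               c(4, 3, 3), ignore_attr = TRUE)
})

test_that("datasets are reproducible under a fixed seed", {
  scn <- sim_scenario(j_genes = 3, kappa = 0.5, signal_density = 1)
  d1 <- simulate_dataset(scn, seed = 68)
  d2 <- simulate_dataset(scn, seed = 68)
  expect_identical(d1$expr, d2$expr)
  expect_identical(d1$cohort$y, d2$cohort$y)
  expect_identical(d1$blocks[[2]]$m, d2$blocks[[2]]$m)
  expect_identical(d1$causal, d2$causal)
})

test_that("blocks carry the case-control subsample consistently", {
  scn <- sim_scenario(j_genes = 2, kappa = 0)
  dat <- simulate_dataset(scn, seed = 69)
  expect_length(dat$cohort$y, 200)
  expect_equal(nrow(dat$blocks[[1]]$m), 200)
  expect_identical(dat$blocks[[1]]$m,
                   dat$meth[[1]][dat$idx, , drop = FALSE])
  expect_identical(dat$blocks[[2]]$g, unname(dat$expr[dat$idx, 2]))
  expect_identical(dat$blocks[[1]]$c, dat$blocks[[1]]$m * dat$blocks[[1]]$g)
})

test_that("scenario validation rejects impossible settings", {
  expect_error(sim_scenario(model_mix = 9), "1..7")
  expect_error(sim_scenario(signal_density = 0), "signal_density")
  expect_error(sim_scenario(rho_within = 1), "rho_within")
  expect_error(sim_scenario(n_cases = 400, n_controls = 400, cohort_n = 681))
})
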