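test_that("GMT parsing, dedup and malformed-line errors", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SETA\tdesc\tG1\tG2",
               "SETB\tdesc\tG1\tG1\tG2"), f)
  expect_warning(sets <- read_gmt(f), "duplicated")
  expect_named(sets, c("SETA", "SETB"))
  expect_identical(sets$SETA$gene_ids, c("G1", "G2"))
  expect_identical(sets$SETB$gene_ids, c("G1", "G2"))

  writeLines(c("SETA\tdesc\tG1", "SETC\tdesc"), f)
  expect_error(read_gmt(f), "line 2")
})

test_that("GMT round-trip preserves set names and gene order", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\td1\tB\tA\tC", "S2\td2\tZ\tY"), f)
  sets <- read_gmt(f)
  f2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, f2)
  sets2 <- read_gmt(f2)
  expect_identical(lapply(sets2, `[[`, "gene_ids"),
                   lapply(sets, `[[`, "gene_ids"))
  expect_identical(names(sets2), names(sets))
})

test_that("cohort validation enforces its invariants", {
  expect_error(cohort(rep(1, 10)), "both cases")
  expect_error(cohort(c(0, 1, NA, 0)), "0/1")
  x_bad <- cbind(2, rnorm(10))
  expect_error(cohort(rep(c(0, 1), 5), x = x_bad), "intercept")
  x_def <- cbind(1, 1:10, 2 * (1:10))
  expect_error(cohort(rep(c(0, 1), 5), x = x_def), "rank deficient")
  co <- cohort(rep(c(0, 1), 5))
  expect_s3_class(co, "itegs_cohort")
  expect_equal(ncol(co$x), 1)
})

test_that("gene_block derives interactions exactly and refuses NAs", {
  m <- matrix(1:6 / 2, 3, 2, dimnames = list(NULL, c("cpg1", "cpg2")))
  g <- c(-1, 0, 2)
  bl <- gene_block("g1", m = m, g = g)
  expect_identical(bl$c, m * g)
  for (i in 1:3) for (l in 1:2)
    expect_identical(unname(bl$c[i, l]), unname(g[i] * m[i, l]))
  expect_error(gene_block("g2", m = matrix(c(1, NA), 2, 1)), "missing")
  expect_error(gene_block("g3"), "methylation, expression, or both")
  expect_identical(block_models(gene_block("g4", m = m)), "M")
  expect_identical(block_models(gene_block("g5", g = g)), "G")
})

test_that("assemble_blocks aligns subjects, excludes, and flags untestable sets", {
  set.seed(11)
  n <- 30
  ids <- paste0("P", 1:n)
  co <- cohort(rep(c(0, 1), n / 2), subject_ids = ids)
  meth <- matrix(runif(5 * n), 5, n,
                 dimnames = list(paste0("cg", 1:5), ids))
  expr <- matrix(rnorm(2 * n), 2, n, dimnames = list(c("GA", "GB"), ids))
  map <- data.frame(locus = paste0("cg", 1:5),
                    gene = c("GA", "GA", "GA", "GC", "GC"))

  asm <- assemble_blocks(co, meth, map, expr, c("GA", "GB", "GC", "GD"))
  expect_false(asm$untestable)
  got <- vapply(asm$blocks, `[[`, character(1), "gene_id")
  expect_setequal(got, c("GA", "GB", "GC"))
  ga <- asm$blocks[[match("GA", got)]]
  expect_equal(ncol(ga$m), 3)       # three mapped CpGs
  expect_false(is.null(ga$g))
  expect_false(is.null(ga$c))
  gb <- asm$blocks[[match("GB", got)]]
  expect_null(gb$m)                  # expression only -> model G only
  gc_ <- asm$blocks[[match("GC", got)]]
  expect_null(gc_$g)                 # CpGs only -> model M only
  expect_identical(asm$excluded$gene_id, "GD")

  asm2 <- assemble_blocks(co, meth, map, expr, c("GX", "GY"))
  expect_true(asm2$untestable)

  # zero subject overlap is an error
  co2 <- cohort(rep(c(0, 1), 5), subject_ids = paste0("Q", 1:10))
  expect_error(assemble_blocks(co2, meth, map, expr, "GA"), "overlapping")
})

test_that("assemble_blocks is invariant to subject permutation up to row order", {
  set.seed(12)
  n <- 24
  ids <- paste0("P", 1:n)
  co <- cohort(rep(c(0, 1), n / 2), subject_ids = ids)
  meth <- matrix(runif(3 * n), 3, n,
                 dimnames = list(paste0("cg", 1:3), ids))
  expr <- matrix(rnorm(n), 1, n, dimnames = list("GA", ids))
  map <- data.frame(locus = paste0("cg", 1:3), gene = "GA")
  perm <- sample(n)
  co_p <- cohort(co$y[perm], subject_ids = ids[perm])
  a1 <- assemble_blocks(co, meth, map, expr, "GA")
  a2 <- assemble_blocks(co_p, meth, map, expr, "GA")
  ord <- match(a1$cohort$subject_ids, a2$cohort$subject_ids)
  expect_equal(a2$blocks[[1]]$m[ord, ], a1$blocks[[1]]$m)
  expect_equal(a2$blocks[[1]]$g[ord], a1$blocks[[1]]$g)
  expect_equal(a2$cohort$y[ord], a1$cohort$y)
})
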