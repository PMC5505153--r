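# Shared component machinery.  The weighted score columns sqrt(a1) M_j,
# sqrt(a2) G_j, sqrt(a3) C_j are identical in every disease model that
# uses them, so their covariate projections, observed squared scores, and
# perturbation scores are computed once over the stacked design and
# reassembled per model by column selection.  This matters: the
# perturbation crossproduct over all components costs half of what four
# per-model designs would.
component_machinery <- function(blocks, null, engine = NULL,
                                comps = c("m", "g", "c")) {
  n <- null$n
  vlist <- vector("list", length(blocks))
  has <- vector("list", length(blocks))
  colgene <- integer(0)
  colcomp <- character(0)
  for (j in seq_along(blocks)) {
    bl <- blocks[[j]]
    sc <- score_components(bl, null)
    parts <- list()
    if ("m" %in% comps && !is.null(bl$m)) parts$m <- sqrt(sc$a1) * bl$m
    if ("g" %in% comps && !is.null(bl$g))
      parts$g <- sqrt(sc$a2) * matrix(bl$g, ncol = 1)
    if ("c" %in% comps && !is.null(bl$c)) parts$c <- sqrt(sc$a3) * bl$c
    vlist[[j]] <- if (length(parts)) do.call(cbind, parts)
                  else matrix(0, n, 0)
    has[[j]] <- c(if (!is.null(bl$m)) "m", if (!is.null(bl$g)) "g",
                  if (!is.null(bl$c)) "c")
    colgene <- c(colgene, rep.int(j, ncol(vlist[[j]])))
    if (length(parts))
      colcomp <- c(colcomp, rep(names(parts), vapply(parts, ncol, 1L)))
  }
  v_all <- do.call(cbind, vlist)
  phalf <- proj_phalf(null, v_all)
  tv <- drop(crossprod(v_all, null$residuals))^2
  t2 <- if (!is.null(engine))
    crossprod(proj_ztil(null, v_all), engine$rn)^2 else NULL
  cp_gene <- lapply(seq_along(blocks), function(j)
    crossprod(phalf[, colgene == j, drop = FALSE]))
  list(n = n, gene_ids = vapply(blocks, `[[`, character(1), "gene_id"),
       has = has, comps = comps, phalf = phalf, tv = tv, t2 = t2,
       colgene = colgene, colcomp = colcomp, cp_gene = cp_gene)
}

model_comps <- function(model)
  switch(model, M = "m", G = "g", MG = c("m", "g"), MGC = c("m", "g", "c"))

# Per-model set machinery: per-gene statistics Q_j = ||V_j' r||^2 / n,
# analytic SD(Q_j) = sqrt(2 tr((P0 K_j)^2)) / n, gene weights
# w_j = 1/SD(Q_j), the pooled Q_net = sum_j w_j Q_j, the mixture weights
# of the pooled kernel, and the joint perturbation sample -- all carved
# out of the shared component machinery.
set_machinery <- function(blocks, null, model, engine = NULL,
                          need_lambda = TRUE, cm = NULL) {
  if (is.null(cm))
    cm <- component_machinery(blocks, null, engine, comps = model_comps(model))
  comps <- model_comps(model)
  if (!all(comps %in% cm$comps))
    stop("component machinery was built without the components this model needs")
  ok <- vapply(cm$has, function(h) all(comps %in% h), logical(1))
  if (sum(!ok) > 0L)
    message(sprintf("model %s: dropping %d gene(s) lacking the required data",
                    model, sum(!ok)))
  if (!any(ok)) return(NULL)
  n <- cm$n
  genes <- which(ok)
  sel <- cm$colgene %in% genes & cm$colcomp %in% comps
  group <- match(cm$colgene[sel], genes)

  q_gene <- drop(rowsum(cm$tv[sel], group)) / n
  sd_gene <- vapply(genes, function(j) {
    in_model <- cm$colcomp[cm$colgene == j] %in% comps
    cp <- cm$cp_gene[[j]][in_model, in_model, drop = FALSE]
    sqrt(2 * sum(cp^2)) / n
  }, numeric(1))
  if (any(sd_gene <= 0)) stop("degenerate gene kernel (zero variance)")
  w <- 1 / sd_gene
  q_net <- sum(w * q_gene)

  lambda <- NULL
  if (need_lambda) {
    phw <- cm$phalf[, sel, drop = FALSE] * rep(sqrt(w)[group], each = n)
    lambda <- gram_eigenvalues(phw, n)
  }

  qb_gene <- qb_net <- NULL
  if (!is.null(cm$t2)) {
    qb_gene <- rowsum(cm$t2[sel, , drop = FALSE], group) / n   # J x B
    qb_net <- drop(w %*% qb_gene)
  }

  list(model = model, gene_ids = cm$gene_ids[genes],
       n_t = length(genes), q_gene = q_gene, w = w, q_net = q_net,
       lambda = lambda, qb_gene = qb_gene, qb_net = qb_net, n = n)
}

#' Integrated total-effect test of a gene set (iTEGS)
#'
#' Tests the self-contained null hypothesis that no gene in the set has
#' any effect -- methylation, expression, or interaction, as allowed by
#' the chosen disease model -- on the outcome.  The statistic is the
#' weighted sum of per-gene kernel statistics,
#' \code{Q_net = sum_j w_j Q_j = r' (sum_j w_j K_j) r / n}, with gene
#' weights \code{w_j} equal to the inverse standard deviation of
#' \code{Q_j} so every gene contributes on a comparable scale.  Under the
#' null \code{Q_net} follows a mixture of chi-squares; p-values come from
#' the Satterthwaite approximation, characteristic-function inversion,
#' and/or the perturbation sample.
#'
#' Genes lacking the data the model needs are dropped with a message (and
#' never contribute weight); a set with no testable gene yields an
#' untestable result rather than an error.  Under model \code{"G"} with
#' expression only, the procedure reduces to the single-platform
#' total-effect gene-set test (TEGS) with working independence.
#'
#' @param blocks List of \code{\link{gene_block}} objects.
#' @param null A \code{\link{fit_null}} object.
#' @param model Disease model: \code{"MGC"}, \code{"MG"}, \code{"M"} or
#'   \code{"G"}.
#' @param methods Subset of \code{c("davies", "satterthwaite",
#'   "perturbation")}.
#' @param engine Optional \code{\link{perturbation_engine}}; built on the
#'   fly (using \code{b}, \code{seed}) when perturbation is requested
#'   without one.
#' @param b,seed Perturbation count and seed for an auto-built engine.
#' @return Object of class \code{"itegs_result"}: a one-row tibble
#'   \code{table} (q_net, n0, n_t, p-values, b) plus per-gene detail.
#' @export
itegs_test <- function(blocks, null, model = c("MGC", "MG", "M", "G"),
                       methods = c("davies", "satterthwaite"),
                       engine = NULL, b = 1000L, seed = NULL) {
  model <- match.arg(model)
  methods <- match.arg(methods, c("davies", "satterthwaite", "perturbation"),
                       several.ok = TRUE)
  want_perturb <- "perturbation" %in% methods
  if (want_perturb && is.null(engine))
    engine <- perturbation_engine(null, b = b, seed = seed)
  mach <- set_machinery(blocks, null, model,
                        engine = if (want_perturb) engine else NULL,
                        need_lambda = any(c("davies", "satterthwaite") %in% methods))
  n0 <- length(blocks)
  if (is.null(mach)) {
    tab <- tibble::tibble(model = model, n0 = n0, n_t = 0L,
                          q_net = NA_real_, p_satterthwaite = NA_real_,
                          p_davies = NA_real_, p_perturbation = NA_real_,
                          b = if (want_perturb) engine$b else NA_integer_,
                          untestable = TRUE)
    return(structure(list(table = tab, genes = NULL, lambda = NULL),
                     class = "itegs_result"))
  }
  p_satt <- if ("satterthwaite" %in% methods)
    satterthwaite_p(mach$q_net, mach$lambda) else NA_real_
  p_dav <- if ("davies" %in% methods)
    davies_p(mach$q_net, mach$lambda) else NA_real_
  p_per <- if (want_perturb) empirical_p(mach$q_net, mach$qb_net) else NA_real_
  tab <- tibble::tibble(model = model, n0 = n0, n_t = mach$n_t,
                        q_net = mach$q_net, p_satterthwaite = p_satt,
                        p_davies = p_dav, p_perturbation = p_per,
                        b = if (want_perturb) engine$b else NA_integer_,
                        untestable = FALSE)
  genes <- tibble::tibble(gene_id = mach$gene_ids, q = mach$q_gene, w = mach$w)
  structure(list(table = tab, genes = genes, lambda = mach$lambda),
            class = "itegs_result")
}

#' @export
print.itegs_result <- function(x, ...) {
  tab <- x$table
  if (isTRUE(tab$untestable)) {
    cat(sprintf("iTEGS-%s: untestable (no gene with the required data)\n", tab$model))
    return(invisible(x))
  }
  cat(sprintf("iTEGS-%s: Q_net = %.4g over %d/%d gene(s)\n",
              tab$model, tab$q_net, tab$n_t, tab$n0))
  for (m in c("p_satterthwaite", "p_davies", "p_perturbation")) {
    if (!is.na(tab[[m]]))
      cat(sprintf("  %-16s %s\n", sub("p_", "", m), format_p(tab[[m]], tab$b)))
  }
  invisible(x)
}

# p-value formatting used by print methods and the CLI: 3 significant
# digits, with perturbation floors shown as "< 1/(B+1)".
format_p <- function(p, b = NA) {
  if (is.na(p)) return("NA")
  if (!is.na(b) && p <= 1 / (b + 1)) return(sprintf("< %.2e", 1 / (b + 1)))
  sprintf("%.3g", p)
}
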