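#' Scan a collection of gene sets
#'
#' Aligns the cohort with the molecular matrices once, fits the logistic
#' null model once, and then tests every gene set with the requested
#' iTEGS models/methods and (optionally) both iNOTE omnibus tests.  Each
#' set gets its own perturbation engine seeded by \code{seed + set index},
#' so a set's p-values do not depend on which other sets are scanned.
#' Sets whose genes all lack both platforms are reported as untestable
#' rather than failing the scan.
#'
#' @param cohort An \code{\link{cohort}} object.
#' @param methylation Loci x subjects matrix (or \code{NULL}).
#' @param locus_map Two-column locus-to-gene map (with methylation).
#' @param expression Genes x subjects matrix (or \code{NULL}).
#' @param gene_sets List of \code{"gene_set"} objects, e.g. from
#'   \code{\link{read_gmt}}.
#' @param models iTEGS disease models to run.
#' @param methods Subset of \code{c("davies", "satterthwaite",
#'   "perturbation")}.
#' @param inote Also run iNOTE-chi and iNOTE-uni (logical).
#' @param b Perturbations per set.
#' @param seed Global scan seed.
#' @param alpha Significance threshold for the flag columns.
#' @param bonferroni Add significance flags at \code{alpha / #sets}.
#' @param standardize Passed to \code{\link{assemble_blocks}}.
#' @return Tibble with one row per gene set: \code{set_id}, \code{n0},
#'   \code{n_t}, \code{untestable}, one p-value column per
#'   model x method (and the iNOTE columns), plus significance flags.
#'   Exclusion details are attached as attribute \code{"exclusions"}.
#' @export
scan_gene_sets <- function(cohort, methylation = NULL, locus_map = NULL,
                           expression = NULL, gene_sets,
                           models = c("M", "MG", "MGC"),
                           methods = c("davies", "satterthwaite"),
                           inote = TRUE, b = 1000L, seed = 1L,
                           alpha = 0.05, bonferroni = TRUE,
                           standardize = FALSE) {
  if (inherits(gene_sets, "gene_set")) gene_sets <- list(gene_sets)
  n_sets <- length(gene_sets)
  if (n_sets == 0L) stop("no gene sets to scan")
  want_perturb <- inote || "perturbation" %in% methods

  rows <- vector("list", n_sets)
  exclusions <- vector("list", n_sets)
  null <- NULL
  for (k in seq_len(n_sets)) {
    gs <- gene_sets[[k]]
    asm <- assemble_blocks(cohort, methylation, locus_map, expression, gs,
                           standardize = standardize)
    if (is.null(null)) null <- fit_null(asm$cohort)
    exclusions[[k]] <- asm$excluded
    row <- tibble::tibble(set_id = gs$set_id, n0 = length(gs$gene_ids),
                          n_t = length(asm$blocks),
                          untestable = asm$untestable)
    if (asm$untestable) {
      rows[[k]] <- row
      next
    }
    engine <- if (want_perturb)
      perturbation_engine(null, b = b, seed = seed + k) else NULL
    for (mod in models) {
      res <- itegs_test(asm$blocks, null, model = mod, methods = methods,
                        engine = engine)
      row[[paste0("n_t_", mod)]] <- res$table$n_t
      for (meth in methods) {
        col <- paste0("p_itegs_", mod, "_",
                      switch(meth, davies = "davies",
                             satterthwaite = "satt", perturbation = "perm"))
        row[[col]] <- res$table[[paste0("p_", meth)]]
      }
    }
    if (inote) {
      res <- inote_test(asm$blocks, null, engine = engine)
      row$p_inote_chi <- res$table$p_inote_chi
      row$p_inote_uni <- res$table$p_inote_uni
      row$inote_selected_model <- res$table$selected_model
    }
    row$b <- if (want_perturb) as.integer(b) else NA_integer_
    rows[[k]] <- row
  }
  out <- do.call(rbind, lapply(rows, pad_row,
                               all_cols = Reduce(union, lapply(rows, names))))
  if (bonferroni) {
    thr <- alpha / n_sets
    pcols <- grep("^p_", names(out), value = TRUE)
    for (pc in pcols) out[[paste0("sig_", sub("^p_", "", pc))]] <- out[[pc]] <= thr
    attr(out, "bonferroni_threshold") <- thr
  }
  attr(out, "exclusions") <- stats::setNames(exclusions,
                                             vapply(gene_sets, `[[`, character(1), "set_id"))
  attr(out, "seed") <- seed
  out
}

# bind rows with heterogeneous columns (untestable sets have no p columns)
pad_row <- function(row, all_cols) {
  for (cc in setdiff(all_cols, names(row))) row[[cc]] <- NA
  row[, all_cols]
}
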