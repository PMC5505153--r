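#' Omnibus gene-set tests without a pre-specified disease model (iNOTE)
#'
#' Runs both omnibus procedures from one shared set of perturbation draws:
#'
#' \strong{iNOTE-chi} (per-gene model-adaptive).  For every gene and every
#' disease model its data support, the observed statistic and its
#' perturbation sample give an empirical p-value; the gene's minimum p
#' over models is mapped to the chi-square(1) quantile with that tail
#' probability, and the quantiles are summed over the set into
#' \code{T_net}.  The same construction applied to each perturbation draw
#' (each draw's p computed by its leave-self-in rank within the full
#' sample, on the same add-one scale) yields the null sample of
#' \code{T_net}, and the reported p-value is the add-one proportion of
#' null draws at least as large.
#'
#' \strong{iNOTE-uni} (consensus-model).  The pooled statistic
#' \code{Q_net} is computed under each of the four uniform models, with
#' an empirical p-value each; the observed minimum p over models is
#' compared with the perturbation null of that minimum (smaller = more
#' extreme).  The model achieving the minimum is reported as
#' \code{selected_model} (ties broken in the fixed order M, G, MG, MGC);
#' the label is descriptive, not inferential.
#'
#' Genes contribute only the models their data support; a gene testable
#' under a single model enters through that model's p alone.  Because all
#' statistics are perturbed with the same normal draws, within- and
#' between-gene correlation is preserved in both omnibus nulls.
#'
#' Note on B: the chi branch sums per-gene quantities whose empirical
#' p-values each carry O(1/B) rank bias, so its size is strongly
#' B-dependent for large sets -- too few perturbations (a few hundred
#' draws with dozens of genes) visibly distort it in either direction.
#' Use B of 2000 or more for omnibus results on sets of dozens of genes.
#'
#' @param blocks List of \code{\link{gene_block}} objects.
#' @param null A \code{\link{fit_null}} object.
#' @param engine Optional \code{\link{perturbation_engine}} (built from
#'   \code{b}, \code{seed} when absent).
#' @param b,seed Perturbation count and seed for an auto-built engine.
#' @param models Candidate disease models for the omnibus search.
#' @return Object of class \code{"inote_result"} with a one-row
#'   \code{table} (both omnibus p-values, \code{t_net_obs},
#'   \code{selected_model}, B), \code{per_model} (pooled Q and p per
#'   uniform model) and \code{per_gene} (per gene-model Q and p).
#' @export
inote_test <- function(blocks, null, engine = NULL, b = 1000L, seed = NULL,
                       models = c("M", "G", "MG", "MGC")) {
  models <- match.arg(models, c("M", "G", "MG", "MGC"), several.ok = TRUE)
  if (is.null(engine)) engine <- perturbation_engine(null, b = b, seed = seed)
  cm <- component_machinery(blocks, null, engine,
                            comps = unique(unlist(lapply(models, model_comps))))
  machs <- list()
  for (mod in models) {
    mm <- set_machinery(blocks, null, mod, engine = engine,
                        need_lambda = FALSE, cm = cm)
    if (!is.null(mm)) machs[[mod]] <- mm
  }
  if (length(machs) == 0L) stop("no gene testable under any requested model")
  inote_from_machinery(machs, engine, n0 = length(blocks))
}

# Both omnibus tests from precomputed per-model machinery sharing one
# engine.  Split out so size/power studies can reuse the machinery for
# the uniform-model tests without recomputation.
inote_from_machinery <- function(machs, engine, n0) {
  b <- engine$b
  models <- names(machs)

  ## ---- per-gene empirical p-values, observed and perturbed -------------
  gene_ids <- unique(unlist(lapply(machs, `[[`, "gene_ids")))
  t_obs_sum <- 0
  tb_sum <- numeric(b)
  per_gene <- list()
  single_model_genes <- 0L
  for (gid in gene_ids) {
    p_obs <- c()
    pb_min <- rep(1, b)
    first <- TRUE
    for (mod in models) {
      mm <- machs[[mod]]
      jj <- match(gid, mm$gene_ids)
      if (is.na(jj)) next
      qb <- mm$qb_gene[jj, ]
      p_obs[mod] <- (1 + sum(qb >= mm$q_gene[jj])) / (b + 1)
      pb <- perturbed_p(qb)
      pb_min <- if (first) pb else pmin(pb_min, pb)
      first <- FALSE
    }
    if (length(p_obs) < 2L) single_model_genes <- single_model_genes + 1L
    p_min <- min(p_obs)
    t_obs_sum <- t_obs_sum + min_p_transform(p_min)
    tb_sum <- tb_sum + min_p_transform(pb_min)
    per_gene[[gid]] <- tibble::tibble(gene_id = gid, model = names(p_obs),
                                      p = unname(p_obs))
  }
  if (single_model_genes > 0L)
    message(sprintf("%d gene(s) testable under a single model: min taken over available models",
                    single_model_genes))
  p_chi <- (1 + sum(tb_sum >= t_obs_sum)) / (b + 1)

  ## ---- uniform-model (set-level) branch --------------------------------
  p_net_obs <- vapply(machs, function(mm)
    (1 + sum(mm$qb_net >= mm$q_net)) / (b + 1), numeric(1))
  pb_net <- vapply(machs, function(mm) perturbed_p(mm$qb_net),
                   numeric(b))
  pb_net_min <- apply(pb_net, 1, min)
  p_net_min <- min(p_net_obs)
  selected <- models[which.min(p_net_obs)]  # which.min = first on ties (M, G, MG, MGC order)
  p_uni <- (1 + sum(pb_net_min <= p_net_min)) / (b + 1)

  tab <- tibble::tibble(
    p_inote_chi = p_chi, p_inote_uni = p_uni, t_net_obs = t_obs_sum,
    selected_model = selected, n0 = n0,
    n_t = max(vapply(machs, `[[`, integer(1), "n_t")), b = b)
  per_model <- tibble::tibble(
    model = models,
    q_net = vapply(machs, `[[`, numeric(1), "q_net"),
    p_net = unname(p_net_obs),
    n_t = vapply(machs, `[[`, integer(1), "n_t"))
  structure(list(table = tab, per_model = per_model,
                 per_gene = do.call(rbind, per_gene)),
            class = "inote_result")
}

#' @export
print.inote_result <- function(x, ...) {
  tab <- x$table
  cat(sprintf("iNOTE omnibus tests over %d/%d gene(s), B = %d\n",
              tab$n_t, tab$n0, tab$b))
  cat(sprintf("  iNOTE-chi  p = %s  (T_net = %.3f)\n",
              format_p(tab$p_inote_chi, tab$b), tab$t_net_obs))
  cat(sprintf("  iNOTE-uni  p = %s  (consensus model %s)\n",
              format_p(tab$p_inote_uni, tab$b), tab$selected_model))
  invisible(x)
}
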