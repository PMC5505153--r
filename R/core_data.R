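#' Construct a study cohort
#'
#' Bundles the binary outcome, the covariate matrix (first column must be
#' the intercept), and subject identifiers.  All downstream tests condition
#' on this object through the logistic null model.
#'
#' @param y Binary outcome vector (0/1); both classes must be present.
#' @param x Covariate matrix with \code{n} rows whose first column is the
#'   constant intercept.  Defaults to an intercept-only design.
#' @param subject_ids Optional character vector of subject labels; defaults
#'   to \code{S1..Sn}.
#' @return An object of class \code{"itegs_cohort"} with elements \code{y},
#'   \code{x} and \code{subject_ids}.
#' @examples
#' co <- cohort(rep(c(0, 1), 10))
#' @export
cohort <- function(y, x = NULL, subject_ids = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop("`y` must be a 0/1 vector without missing values")
  if (sum(y) == 0L || sum(y) == n)
    stop("`y` must contain both cases (1) and controls (0)")
  if (is.null(x)) {
    x <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
  }
  if (nrow(x) != n) stop("`x` must have one row per subject")
  if (anyNA(x)) stop("missing values in covariates are not supported")
  if (any(x[, 1] != 1))
    stop("the first column of `x` must be the intercept (constant 1)")
  if (qr(x)$rank < ncol(x)) stop("covariate matrix is rank deficient")
  if (n < ncol(x) + 2L)
    stop("need at least r + 2 subjects for r covariates")
  if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(n))
  if (length(subject_ids) != n || anyDuplicated(subject_ids))
    stop("`subject_ids` must be unique and match the outcome length")
  structure(list(y = y, x = x, subject_ids = as.character(subject_ids)),
            class = "itegs_cohort")
}

#' @export
print.itegs_cohort <- function(x, ...) {
  cat(sprintf("itegs cohort: n = %d (%d cases / %d controls), %d covariate column(s)\n",
              length(x$y), sum(x$y), sum(1 - x$y), ncol(x$x)))
  invisible(x)
}

#' Construct a per-gene data block
#'
#' Holds one gene's methylation matrix \code{m} (subjects x CpG loci), its
#' expression vector \code{g}, and the derived interaction matrix
#' \code{c = g * m} (within-gene cross-products).  At least one of
#' \code{m}, \code{g} must be present; \code{c} exists only when both do.
#' Missing values are refused -- imputation is the caller's responsibility.
#'
#' @param gene_id Gene label.
#' @param m Methylation matrix (n x p) or \code{NULL}.
#' @param g Expression vector (length n) or \code{NULL}.
#' @return An object of class \code{"gene_block"}.
#' @export
gene_block <- function(gene_id, m = NULL, g = NULL) {
  if (is.null(m) && is.null(g))
    stop("gene block needs methylation, expression, or both")
  if (!is.null(m)) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    if (ncol(m) < 1L) stop("methylation matrix must have at least one locus")
    if (anyNA(m)) stop(sprintf("missing methylation values for gene %s", gene_id))
    if (is.null(colnames(m))) colnames(m) <- paste0("cpg", seq_len(ncol(m)))
  }
  if (!is.null(g)) {
    g <- as.numeric(g)
    if (anyNA(g)) stop(sprintf("missing expression values for gene %s", gene_id))
    if (!is.null(m) && length(g) != nrow(m))
      stop(sprintf("gene %s: expression length does not match methylation rows", gene_id))
  }
  cc <- if (!is.null(m) && !is.null(g)) m * g else NULL
  structure(list(gene_id = as.character(gene_id), m = m, g = g, c = cc),
            class = "gene_block")
}

#' @export
print.gene_block <- function(x, ...) {
  cat(sprintf("gene block %s: %s%s\n", x$gene_id,
              if (is.null(x$m)) "no methylation" else sprintf("%d CpG loci", ncol(x$m)),
              if (is.null(x$g)) ", no expression" else ", expression present"))
  invisible(x)
}

#' Disease models a block can be tested under
#'
#' @param block A \code{\link{gene_block}}.
#' @return Character vector drawn from \code{c("M", "G", "MG", "MGC")}.
#' @export
block_models <- function(block) {
  has_m <- !is.null(block$m)
  has_g <- !is.null(block$g)
  if (has_m && has_g) c("M", "G", "MG", "MGC") else if (has_m) "M" else "G"
}

#' Read gene sets from a GMT file
#'
#' Tab-separated MSigDB dialect: set name, description, then one or more
#' gene symbols per line.  Duplicate symbols within a line are dropped with
#' a warning; lines with fewer than three fields are an error.
#'
#' @param path Path to the GMT file.
#' @return Named list of \code{"gene_set"} objects (fields \code{set_id},
#'   \code{description}, \code{gene_ids}).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop(sprintf("GMT parse error at line %d: fewer than 3 tab-separated fields", i))
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("gene set %s (line %d): dropping %d duplicated gene symbol(s)",
                      fields[1], i, sum(duplicated(genes))))
      genes <- unique(genes)
    }
    if (length(genes) == 0L)
      stop(sprintf("GMT parse error at line %d: no gene symbols", i))
    sets[[i]] <- structure(
      list(set_id = fields[1], description = fields[2], gene_ids = genes),
      class = "gene_set")
  }
  names(sets) <- vapply(sets, `[[`, character(1), "set_id")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets List of \code{"gene_set"} objects (as from \code{\link{read_gmt}}).
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$set_id, s$description, s$gene_ids), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Assemble per-gene blocks for a gene set
#'
#' Aligns subjects across the cohort and the molecular matrices (inner join
#' on subject IDs, cohort order preserved) and builds one
#' \code{\link{gene_block}} per gene that has data on at least one
#' platform.  Genes lacking both platforms are excluded and reported; a
#' set with no viable gene is flagged untestable.
#'
#' @param cohort An \code{\link{cohort}} object.
#' @param methylation Matrix of methylation values, loci x subjects
#'   (row names = locus IDs, column names = subject IDs), or \code{NULL}.
#' @param locus_map Two-column data frame mapping \code{locus} to
#'   \code{gene}; required when \code{methylation} is given.
#' @param expression Matrix of expression values, genes x subjects, or
#'   \code{NULL}.
#' @param gene_set A \code{"gene_set"} object or character vector of gene IDs.
#' @param standardize If \code{TRUE}, centre and scale each methylation
#'   column and the expression vector (default \code{FALSE}; the component
#'   weights already equalise scales across data types).
#' @return List with elements \code{blocks} (list of gene blocks),
#'   \code{cohort} (subset to the aligned subjects), \code{excluded}
#'   (tibble of dropped genes with reasons) and \code{untestable} (logical).
#' @export
assemble_blocks <- function(cohort, methylation = NULL, locus_map = NULL,
                            expression = NULL, gene_set,
                            standardize = FALSE) {
  if (!inherits(cohort, "itegs_cohort")) stop("`cohort` must be an itegs_cohort")
  if (is.null(methylation) && is.null(expression))
    stop("need at least one molecular platform")
  if (!is.null(methylation) && is.null(locus_map))
    stop("`locus_map` (locus, gene) is required with methylation data")
  genes <- if (inherits(gene_set, "gene_set")) gene_set$gene_ids else as.character(gene_set)

  ids <- cohort$subject_ids
  for (mat in list(methylation, expression)) {
    if (!is.null(mat)) ids <- ids[ids %in% colnames(mat)]
  }
  n_drop <- length(cohort$subject_ids) - length(ids)
  if (length(ids) == 0L) stop("no overlapping subjects across cohort and molecular data")
  if (n_drop > 0L)
    message(sprintf("dropping %d cohort subject(s) without molecular data", n_drop))
  keep <- match(ids, cohort$subject_ids)
  co <- cohort(cohort$y[keep], cohort$x[keep, , drop = FALSE], ids)

  scale1 <- function(v) as.vector(scale(v))
  blocks <- list()
  excl <- list()
  for (gid in genes) {
    m <- g <- NULL
    if (!is.null(methylation)) {
      loci <- as.character(locus_map[[1]][as.character(locus_map[[2]]) == gid])
      loci <- loci[loci %in% rownames(methylation)]
      if (length(loci) > 0L) {
        m <- t(methylation[loci, ids, drop = FALSE])
        if (standardize) m <- apply(m, 2, scale1)
      }
    }
    if (!is.null(expression) && gid %in% rownames(expression)) {
      g <- as.numeric(expression[gid, ids])
      if (standardize) g <- scale1(g)
    }
    if (is.null(m) && is.null(g)) {
      excl[[gid]] <- "no methylation probes and no expression data"
    } else {
      blocks[[gid]] <- gene_block(gid, m = m, g = g)
    }
  }
  excluded <- if (length(excl)) {
    tibble::tibble(gene_id = names(excl), reason = unlist(excl, use.names = FALSE))
  } else {
    tibble::tibble(gene_id = character(0), reason = character(0))
  }
  if (nrow(excluded) > 0L)
    message(sprintf("excluded %d gene(s) lacking both platforms", nrow(excluded)))
  list(blocks = unname(blocks), cohort = co, excluded = excluded,
       untestable = length(blocks) == 0L)
}

#' Read a delimited numeric matrix with row and column labels
#'
#' Convenience reader for the TSV/CSV matrix layout used throughout:
#' first column = row labels (loci, genes, or subjects), header = column
#' labels.
#'
#' @param path File path.
#' @param sep Field separator (default tab).
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_file <- function(path, sep = "\t") {
  df <- utils::read.delim(path, sep = sep, row.names = 1, check.names = FALSE)
  as.matrix(df)
}
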