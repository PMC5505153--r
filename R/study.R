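#' Empirical size / power study
#'
#' Repeatedly simulates a case-control dataset from a scenario, runs the
#' requested tests, and tabulates rejection proportions at \code{alpha}
#' with binomial standard errors.  With \code{kappa = 0} in the scenario
#' the rates are empirical type-I errors; with \code{kappa > 0} they are
#' power.  One perturbation engine per replicate is shared by all
#' perturbation-based tests, as the omnibus procedures require.
#'
#' @param scn A \code{\link{sim_scenario}}.
#' @param n_reps Number of simulation replicates.
#' @param alpha Significance threshold.
#' @param b Perturbations per replicate for the resampling-based tests.
#' @param seed Seed for the whole study (drives both data generation and
#'   perturbation draws through one RNG stream).
#' @param itegs_models iTEGS disease models to run (may be empty).
#' @param itegs_methods Subset of \code{c("davies", "satterthwaite",
#'   "perturbation")} for the iTEGS tests.
#' @param inote Subset of \code{c("chi", "uni")} selecting the omnibus
#'   tests (empty = skip them).
#' @param inote_models Candidate models for the omnibus search.
#' @return List of class \code{"size_power_study"}: \code{p_values}
#'   (tibble rep/test/method/p), \code{rejection} (tibble with rates and
#'   SEs), and the study settings.
#' @export
run_size_power_study <- function(scn, n_reps, alpha = 0.05, b = 500L,
                                 seed = 1L,
                                 itegs_models = c("M", "MG", "MGC"),
                                 itegs_methods = "davies",
                                 inote = character(0),
                                 inote_models = c("M", "G", "MG", "MGC")) {
  stopifnot(n_reps >= 1)
  inote <- as.character(inote)
  if (length(inote)) inote <- match.arg(inote, c("chi", "uni"), several.ok = TRUE)
  need_engine <- length(inote) > 0L || "perturbation" %in% itegs_methods
  need_lambda <- any(c("davies", "satterthwaite") %in% itegs_methods)
  set.seed(seed)
  rows <- vector("list", n_reps)
  for (rep_i in seq_len(n_reps)) {
    dat <- simulate_dataset(scn)
    null <- fit_null(dat$cohort)
    engine <- if (need_engine) perturbation_engine(null, b = b) else NULL

    # machinery per model, shared between iTEGS and iNOTE; the expensive
    # projections/perturbations are computed once over all components
    models_needed <- union(itegs_models, if (length(inote)) inote_models)
    cm <- component_machinery(
      dat$blocks, null, engine,
      comps = unique(unlist(lapply(models_needed, model_comps))))
    machs <- list()
    for (mod in models_needed) {
      machs[[mod]] <- set_machinery(
        dat$blocks, null, mod, engine = engine,
        need_lambda = need_lambda && mod %in% itegs_models, cm = cm)
    }

    out <- list()
    for (mod in itegs_models) {
      mm <- machs[[mod]]
      if ("davies" %in% itegs_methods)
        out[[paste0("iTEGS-", mod, "|davies")]] <- davies_p(mm$q_net, mm$lambda)
      if ("satterthwaite" %in% itegs_methods)
        out[[paste0("iTEGS-", mod, "|satterthwaite")]] <-
          satterthwaite_p(mm$q_net, mm$lambda)
      if ("perturbation" %in% itegs_methods)
        out[[paste0("iTEGS-", mod, "|perturbation")]] <-
          empirical_p(mm$q_net, mm$qb_net)
    }
    if (length(inote)) {
      res <- inote_from_machinery(machs[inote_models], engine,
                                  n0 = length(dat$blocks))
      if ("chi" %in% inote)
        out[["iNOTE-chi|perturbation"]] <- res$table$p_inote_chi
      if ("uni" %in% inote)
        out[["iNOTE-uni|perturbation"]] <- res$table$p_inote_uni
    }
    rows[[rep_i]] <- tibble::tibble(rep = rep_i, test = names(out),
                                    p = unlist(out, use.names = FALSE))
  }
  p_values <- do.call(rbind, rows)
  parts <- strsplit(p_values$test, "|", fixed = TRUE)
  p_values$method <- vapply(parts, `[`, character(1), 2)
  p_values$test <- vapply(parts, `[`, character(1), 1)
  rejection <- stats::aggregate(p ~ test + method, data = p_values,
                                FUN = function(p) mean(p <= alpha))
  names(rejection)[names(rejection) == "p"] <- "rate"
  rejection$n_reps <- n_reps
  rejection$se <- sqrt(rejection$rate * (1 - rejection$rate) / n_reps)
  structure(list(p_values = tibble::as_tibble(p_values),
                 rejection = tibble::as_tibble(rejection),
                 scn = scn, alpha = alpha, b = b, seed = seed,
                 n_reps = n_reps),
            class = "size_power_study")
}

#' @export
print.size_power_study <- function(x, ...) {
  cat(sprintf("size/power study: %d replicates, alpha = %g, B = %d, kappa = %g\n",
              x$n_reps, x$alpha, x$b, x$scn$kappa))
  print(as.data.frame(x$rejection), row.names = FALSE)
  invisible(x)
}

#' Power curve over an effect-multiplier grid
#'
#' Convenience wrapper running \code{\link{run_size_power_study}} at each
#' value of \code{kappas} and binding the rejection tables.
#'
#' @param scn Base scenario (its \code{kappa} is overridden).
#' @param kappas Numeric grid of effect multipliers.
#' @param ... Passed to \code{\link{run_size_power_study}}; each grid
#'   point uses \code{seed + i - 1}.
#' @param seed Base seed.
#' @return Tibble of rejection rates with a \code{kappa} column.
#' @export
run_power_curve <- function(scn, kappas, seed = 1L, ...) {
  out <- vector("list", length(kappas))
  for (i in seq_along(kappas)) {
    scn_i <- scn
    scn_i$kappa <- kappas[i]
    st <- run_size_power_study(scn_i, seed = seed + i - 1L, ...)
    st$rejection$kappa <- kappas[i]
    out[[i]] <- st$rejection
  }
  do.call(rbind, out)
}
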