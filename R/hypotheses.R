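# Five-hypothesis competition: per-hypothesis RAC-BRT fits, hybrid variable
# selection, and AUC ranking.

#' Registry of the four single-factor hypotheses
#'
#' Maps hypothesis codes to their candidate variable sets: H1 landcover
#' composition, H2 anthropogenic disturbance, H3 environmental abiotic
#' factors (topography, lithology, soils), H4 climate. H5 — the hybrid — has
#' no fixed set: its variables come from [select_hybrid_variables()].
#'
#' @return Named list of character vectors.
#' @export
hypothesis_registry <- function() {
  list(
    H1 = c("Deciduous", "Coniferous", "Agroforestry", "Eucalyptus", "Exotic",
           "Shrublands", "Wetlands", "Herbaceous", "Food", "Artificial", "H"),
    H2 = c("Highways", "Roads", "Unpaved_roads", "Human_pop", "PA", "Hunting",
           "Cattle", "Goat&sheep", "Pigs"),
    H3 = c("Alt_mean", "Alt_range", "Sediment", "Sediment/Metamorph",
           "Eruptive", "Podzols", "Luvisols", "Lithosols", "Cambisols"),
    H4 = c("Ann_Prec", "Prec_season", "Ann_Temp", "Temp_season")
  )
}

#' Select hybrid-hypothesis candidate variables from per-hypothesis influences
#'
#' For each single-factor hypothesis, the RAC term is excluded, the remaining
#' variables are ranked by relative influence, and the selection rule is
#' applied; the union across hypotheses forms the hybrid (H5) candidate set.
#' The default rule keeps the shortest prefix whose cumulative influence
#' reaches 50% of the non-RAC total. Alternatives: `"top_half"` (the better
#' half of the variables by count) and `"top_k"` (a fixed number). The
#' selection is invariant to uniform rescaling of the influences.
#'
#' @param results Named list of [rac_brt()] fits *or* of named influence
#'   vectors (a `RAC` entry, if present, is dropped).
#' @param rule `"cumulative"`, `"top_half"`, or `"top_k"`.
#' @param k Number of variables for `rule = "top_k"`.
#' @param cum_frac Cumulative-influence fraction for `rule = "cumulative"`.
#' @return Character vector of selected variables (union, first-seen order).
#' @export
select_hybrid_variables <- function(results, rule = c("cumulative",
                                                      "top_half", "top_k"),
                                    k = 2, cum_frac = 0.5) {
  rule <- match.arg(rule)
  picked <- character(0)
  for (res in results) {
    infl <- if (inherits(res, "rac_brt")) relative_influence(res) else res
    if (!is.numeric(infl) || length(infl) == 0L)
      stop("empty influence table")
    infl <- infl[setdiff(names(infl), "RAC")]
    if (length(infl) == 0L) stop("no non-RAC variables in influence table")
    infl <- sort(infl, decreasing = TRUE)
    sel <- switch(rule,
      cumulative = names(infl)[seq_len(
        which(cumsum(infl) >= cum_frac * sum(infl))[1L])],
      top_half = names(infl)[seq_len(ceiling(length(infl) / 2))],
      top_k = names(infl)[seq_len(min(k, length(infl)))])
    picked <- c(picked, setdiff(sel, picked))
  }
  picked
}

#' Rank competing hypotheses by cross-validated AUC
#'
#' @param results Named list of [rac_brt()] fits, or a named numeric vector
#'   of AUC values; optionally `se` and `deviance` vectors alongside.
#' @param se,deviance Optional named numeric vectors when `results` is a
#'   plain AUC vector.
#' @return A `hypothesis_comparison` data frame sorted by decreasing AUC
#'   (ties broken by name and flagged), with the best hypothesis first and
#'   recorded in attribute `"best"`.
#' @export
compare_hypotheses <- function(results, se = NULL, deviance = NULL) {
  if (is.list(results) && all(vapply(results, inherits, TRUE, "rac_brt"))) {
    auc <- vapply(results, function(r) r$final_model$cv_auc, 0)
    se <- vapply(results, function(r) r$final_model$cv_auc_se, 0)
    deviance <- vapply(results, function(r)
      r$final_model$deviance_explained_pct, 0)
  } else {
    auc <- unlist(results)
  }
  if (length(auc) < 2L && length(auc) != 1L) stop("need at least one result")
  nm <- names(auc)
  ord <- order(-auc, nm)
  out <- data.frame(hypothesis = nm[ord], cv_auc = unname(auc[ord]),
                    se = if (is.null(se)) NA_real_ else unname(se[ord]),
                    deviance_explained_pct = if (is.null(deviance))
                      NA_real_ else unname(deviance[ord]))
  out$best <- seq_len(nrow(out)) == 1L
  out$tied_with_next <- c(diff(out$cv_auc) == 0, FALSE)
  structure(out, class = c("hypothesis_comparison", "data.frame"),
            best = out$hypothesis[1L])
}

#' @export
print.hypothesis_comparison <- function(x, ...) {
  cat("Hypothesis ranking by cross-validated AUC (best first):\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  if (any(x$tied_with_next)) cat("note: exact AUC ties present\n")
  invisible(x)
}

#' Fit and compare the five competing hypotheses
#'
#' Runs the full competition: a [rac_brt()] fit per single-factor hypothesis
#' (H1-H4), hybrid variable selection from their influence tables, a fresh
#' VIF screen and RAC-BRT fit for the hybrid (H5), and the AUC ranking.
#'
#' @param data Cell table (response + covariates, one row per grid cell).
#' @param grid The [sdm_grid()].
#' @param response Name of the binary response column (`NA` = unsampled).
#' @param hypotheses Named list of candidate variable sets
#'   (default [hypothesis_registry()]).
#' @param weights Optional [spatial_weights()] shared by all fits.
#' @param hybrid_rule Selection rule for [select_hybrid_variables()].
#' @param ... Passed on to [rac_brt()] (control, tuning, tolerances...).
#' @return A `hypothesis_set`: list with `results` (named list of `rac_brt`
#'   fits, H5 included), `hybrid_variables`, and `comparison`.
#' @export
fit_hypotheses <- function(data, grid, response = "presence",
                           hypotheses = hypothesis_registry(),
                           weights = NULL, hybrid_rule = "cumulative", ...) {
  if (is.null(weights)) weights <- spatial_weights(grid, "queen")
  results <- list()
  for (h in names(hypotheses)) {
    f <- stats::reformulate(sprintf("`%s`", hypotheses[[h]]),
                            response = as.name(response))
    results[[h]] <- rac_brt(f, data, grid, weights = weights,
                            hypothesis = h, ...)
  }
  hybrid <- select_hybrid_variables(results, rule = hybrid_rule)
  f5 <- stats::reformulate(sprintf("`%s`", hybrid),
                           response = as.name(response))
  results$H5 <- rac_brt(f5, data, grid, weights = weights,
                        hypothesis = "H5", ...)
  structure(list(results = results, hybrid_variables = hybrid,
                 comparison = compare_hypotheses(results)),
            class = "hypothesis_set")
}

#' @export
print.hypothesis_set <- function(x, ...) {
  cat("RAC-BRT hypothesis competition\n")
  cat("hybrid (H5) variables:", paste(x$hybrid_variables, collapse = ", "),
      "\n\n")
  print(x$comparison)
  invisible(x)
}
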