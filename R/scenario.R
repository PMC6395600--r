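# Landcover/climate scenario definition, application, projection, and range
# shift summary.

#' Define a covariate-change scenario
#'
#' A scenario bundles per-variable change rules applied cell-wise to a
#' covariate table: climate rules are multiplicative and/or additive deltas
#' (`list(Ann_Prec = list(multiply = 0.9), Ann_Temp = list(add = 1.5))` is the
#' 2040 A1B default: -10% precipitation, +1.5 degrees C); landcover rules
#' either replace a column with a supplied per-cell layer or regroup it as the
#' sum of supplied source layers. Frozen variables (default `Eucalyptus`,
#' whose cover is capped by plantation legislation) must not appear in any
#' rule and are guaranteed unchanged.
#'
#' @param name Scenario label (e.g. `"A1_2040"`).
#' @param climate Named list of `list(multiply =, add =)` deltas.
#' @param replace Character vector of variables to replace by columns of the
#'   `landcover_layers` table passed to [apply_scenario()].
#' @param regroup Named list: target variable -> character vector of source
#'   column names in `landcover_layers` whose cell-wise sum becomes the new
#'   value.
#' @param frozen Variables asserted unchanged.
#' @return A `scenario` object.
#' @export
scenario <- function(name, climate = list(), replace = character(0),
                     regroup = list(), frozen = "Eucalyptus") {
  ruled <- c(names(climate), replace, names(regroup))
  dup <- unique(ruled[duplicated(ruled)])
  if (length(dup)) stop("variable(s) in more than one rule: ",
                        paste(dup, collapse = ", "))
  bad <- intersect(ruled, frozen)
  if (length(bad)) stop("frozen variable(s) under a rule: ",
                        paste(bad, collapse = ", "))
  structure(list(name = name, climate = climate, replace = replace,
                 regroup = regroup, frozen = frozen), class = "scenario")
}

#' 2040 climate scenario under the A1B emissions pathway
#'
#' The national-average 2040 climate deltas: annual precipitation reduced by
#' 10% and annual mean temperature increased by 1.5 degrees C, with
#' `Eucalyptus` cover frozen. Landcover regrouping (one of the four 2040
#' land-use storylines) can be layered on via `replace`/`regroup`.
#'
#' @inheritParams scenario
#' @return A `scenario`.
#' @export
scenario_a1b_2040 <- function(name = "A1B_2040", replace = character(0),
                              regroup = list(), frozen = "Eucalyptus") {
  scenario(name,
           climate = list(Ann_Prec = list(multiply = 0.9),
                          Ann_Temp = list(add = 1.5)),
           replace = replace, regroup = regroup, frozen = frozen)
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("scenario %s: %d climate rule(s), %d replacement(s), %d regroup(s); frozen: %s\n",
              x$name, length(x$climate), length(x$replace),
              length(x$regroup), paste(x$frozen, collapse = ", ")))
  invisible(x)
}

#' Apply a scenario to a covariate table
#'
#' @param covariates Cell covariate table (with `cell_id`).
#' @param scn A [scenario()].
#' @param landcover_layers Optional data frame keyed by `cell_id` supplying
#'   replacement/regroup source columns.
#' @return The modified covariate table; frozen variables are bit-identical
#'   to the input. Pure multiplicative/additive rules are exactly invertible
#'   by the inverse deltas.
#' @export
apply_scenario <- function(covariates, scn, landcover_layers = NULL) {
  out <- covariates
  for (v in names(scn$climate)) {
    if (!v %in% names(out)) stop("rule for unknown variable: ", v)
    r <- scn$climate[[v]]
    if (!is.null(r$multiply)) out[[v]] <- out[[v]] * r$multiply
    if (!is.null(r$add)) out[[v]] <- out[[v]] + r$add
  }
  if (length(scn$replace) || length(scn$regroup)) {
    if (is.null(landcover_layers))
      stop("scenario has landcover rules but no landcover_layers given")
    i <- match(out$cell_id, landcover_layers$cell_id)
    if (any(is.na(i))) stop("landcover_layers missing cell(s)")
    for (v in scn$replace) {
      if (!v %in% names(out)) stop("rule for unknown variable: ", v)
      if (!v %in% names(landcover_layers))
        stop("landcover_layers lacks column: ", v)
      out[[v]] <- landcover_layers[[v]][i]
    }
    for (v in names(scn$regroup)) {
      if (!v %in% names(out)) stop("rule for unknown variable: ", v)
      src <- scn$regroup[[v]]
      miss <- setdiff(src, names(landcover_layers))
      if (length(miss)) stop("landcover_layers lacks column(s): ",
                             paste(miss, collapse = ", "))
      out[[v]] <- rowSums(landcover_layers[i, src, drop = FALSE])
    }
  }
  stopifnot(identical(out[scn$frozen], covariates[scn$frozen]))
  out
}

#' Project a fitted model under a scenario
#'
#' Applies the scenario to the covariates and re-maps favourability with the
#' model's *original* training prevalence, so baseline and scenario maps are
#' on the same favourability scale.
#'
#' @param model A [rac_brt()] fit.
#' @param covariates Baseline covariates for every grid cell.
#' @param scn A [scenario()].
#' @param landcover_layers Passed to [apply_scenario()].
#' @param n1,n0 Prevalence counts (default the model's).
#' @param rac_policy Passed to [predict.rac_brt()].
#' @return A [favourability_map()] labelled with the scenario name.
#' @export
project_scenario <- function(model, covariates, scn,
                             landcover_layers = NULL,
                             n1 = model$n1, n0 = model$n0,
                             rac_policy = "mean") {
  sc_cov <- apply_scenario(covariates, scn, landcover_layers)
  favourability_map(model, sc_cov, n1 = n1, n0 = n0,
                    rac_policy = rac_policy, model_id = scn$name)
}

#' Summarize the favourability shift across scenario projections
#'
#' Computes, for the baseline map and each scenario map: the percentage of
#' cells favourable (`F >= 0.5`); the mean increase of that percentage across
#' scenarios relative to baseline; a chi-square homogeneity test of the
#' favourable/unfavourable counts across the scenario maps
#' (`df = n_scenarios - 1`); and, within an optional region mask, the count
#' of highly favourable cells (`F >= 0.75`) and the mean favourability.
#'
#' @param baseline Baseline [favourability_map()].
#' @param scenarios Named list of scenario maps (same grid/cell order).
#' @param region_mask Optional logical vector (per cell) or vector of
#'   `cell_id`s delimiting a sub-region (e.g. south of a river).
#' @param high_threshold Threshold for the "highly favourable" count (0.75).
#' @return A `shift_summary` list.
#' @export
summarize_shift <- function(baseline, scenarios, region_mask = NULL,
                            high_threshold = 0.75) {
  for (m in scenarios)
    if (!identical(m$cell_id, baseline$cell_id))
      stop("scenario map not aligned with baseline grid")
  pct <- function(m) 100 * mean(m$F >= 0.5)
  pct_base <- pct(baseline)
  pct_sc <- vapply(scenarios, pct, 0)
  counts <- vapply(scenarios, function(m)
    c(fav = sum(m$F >= 0.5), unfav = sum(m$F < 0.5)), c(fav = 0, unfav = 0))
  chi <- if (length(scenarios) >= 2L && all(rowSums(counts) > 0)) {
    suppressWarnings(stats::chisq.test(t(counts), correct = FALSE))
  } else NULL
  region <- NULL
  if (!is.null(region_mask)) {
    sel <- if (is.logical(region_mask)) region_mask
           else baseline$cell_id %in% region_mask
    region <- list(
      counts_high = c(baseline = sum(baseline$F[sel] >= high_threshold),
                      vapply(scenarios, function(m)
                        sum(m$F[sel] >= high_threshold), 0)),
      mean_F = c(baseline = mean(baseline$F[sel]),
                 vapply(scenarios, function(m) mean(m$F[sel]), 0)))
  }
  structure(list(
    pct_favourable_baseline = pct_base,
    pct_favourable_per_scenario = pct_sc,
    mean_increase = mean(pct_sc) - pct_base,
    chi2 = if (is.null(chi)) NA_real_ else unname(chi$statistic),
    chi2_df = if (is.null(chi)) NA_integer_ else unname(chi$parameter),
    p = if (is.null(chi)) NA_real_ else chi$p.value,
    region = region, high_threshold = high_threshold),
    class = "shift_summary")
}

#' @export
print.shift_summary <- function(x, ...) {
  cat(sprintf("favourable (F >= 0.5): baseline %.2f%%; scenarios %s\n",
              x$pct_favourable_baseline,
              paste(sprintf("%s %.2f%%", names(x$pct_favourable_per_scenario),
                            x$pct_favourable_per_scenario), collapse = ", ")))
  cat(sprintf("mean increase %.2f points; chi2 = %.3f (df %d), p = %.3f\n",
              x$mean_increase, x$chi2, x$chi2_df, x$p))
  if (!is.null(x$region)) {
    cat(sprintf("region: cells F >= %.2f: %s\n", x$high_threshold,
                paste(sprintf("%s %d", names(x$region$counts_high),
                              x$region$counts_high), collapse = ", ")))
    cat(sprintf("region mean F: %s\n",
                paste(sprintf("%s %.3f", names(x$region$mean_F),
                              x$region$mean_F), collapse = ", ")))
  }
  invisible(x)
}

#' Aggregate a fine-grid cell table to the coarse grid
#'
#' Mean of each numeric column over the subcells of every coarse cell
#' (e.g. 5 km covariates to 10 km cells for coarse-grid projection).
#'
#' @param fine_table Cell table on the fine grid (with `cell_id`).
#' @param grid Coarse [sdm_grid()].
#' @param fine Fine grid from [refine_grid()].
#' @param factor Subdivision factor used in [refine_grid()].
#' @return Cell table on the coarse grid.
#' @export
aggregate_to_coarse <- function(fine_table, grid, fine, factor = 2L) {
  num <- names(fine_table)[vapply(fine_table, is.numeric, TRUE)]
  num <- setdiff(num, "cell_id")
  rows <- lapply(grid$cells$cell_id, function(id) {
    sub <- subcell_ids(grid, fine, id, factor)
    i <- match(sub, fine_table$cell_id)
    i <- i[!is.na(i)]
    c(cell_id = id, colMeans(fine_table[i, num, drop = FALSE]))
  })
  out <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  out
}
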