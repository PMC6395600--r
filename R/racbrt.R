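#' Fit a spatially corrected boosted regression tree (RAC-BRT) model
#'
#' The core model of the package. For one ecological hypothesis (a named set
#' of covariates) the pipeline is: iterative VIF screening of the candidate
#' variables; (optionally) learning-rate/tree-complexity tuning; a boosted
#' regression tree fit with 10-fold CV ensemble-size selection; backwards
#' simplification; computation of response-scale residuals
#' (observed - predicted probability) on the sampled cells; a residuals
#' autocovariate (RAC) layer — the neighbourhood mean of those residuals —
#' added as an extra predictor; a refit (and re-simplification, with the RAC
#' term protected); and Moran's I tests of the residuals before and after the
#' correction. The RAC term absorbs residual spatial autocorrelation so the
#' environmental effects are estimated free of it.
#'
#' @param formula Model formula, e.g. `presence ~ Herbaceous + Eucalyptus`;
#'   `presence ~ .` uses every column of `data` except the response and the
#'   bookkeeping columns (`cell_id`, `row`, `col`, `x_km`, `y_km`, `sampled`,
#'   `latent_prob`, `latent_occupancy`).
#' @param data Cell table with one row per grid cell, aligned with
#'   `grid$cells` (same `cell_id` order); the response may be `NA` on
#'   unsampled cells.
#' @param grid The [sdm_grid()] the cells live on.
#' @param weights Optional [spatial_weights()]; default queen contiguity,
#'   row-standardized.
#' @param control A [brt_control()].
#' @param tune If `TRUE`, run [tune_brt()] over `lr_grid`/`tc_grid` before
#'   fitting.
#' @param lr_grid,tc_grid Tuning grids (used when `tune = TRUE`).
#' @param vif_threshold VIF screening threshold (5).
#' @param simplify Run backwards simplification (default `TRUE`).
#' @param tol_auc,tol_dev Simplification tolerances, see [simplify_brt()].
#' @param residual_type `"response"` (observed minus predicted probability,
#'   the default) or `"deviance"` residuals for the RAC computation.
#' @param hypothesis Optional hypothesis label carried through reports.
#' @return An object of class `rac_brt` with components `final_model` (a
#'   [brt()] including the `RAC` predictor), `pre_rac_model`, `rac` (the RAC
#'   layer over all grid cells), `vif_report`, `moran_pre` and
#'   `moran_residual` (Moran tests of pre- and post-correction residuals),
#'   `sampled_idx`, `n1`/`n0` (training prevalence counts), and bookkeeping.
#' @seealso [predict.rac_brt()], [favourability_map()], [fit_hypotheses()]
#' @export
rac_brt <- function(formula, data, grid, weights = NULL,
                    control = brt_control(), tune = FALSE,
                    lr_grid = c(0.1, 0.05, 0.01, 0.005, 0.001),
                    tc_grid = c(1, 2, 3, 5),
                    vif_threshold = 5, simplify = TRUE,
                    tol_auc = 0.005, tol_dev = 0.5,
                    residual_type = c("response", "deviance"),
                    hypothesis = NULL) {
  residual_type <- match.arg(residual_type)
  cl <- match.call()
  response <- all.vars(formula[[2L]])
  bookkeeping <- c("cell_id", "row", "col", "x_km", "y_km", "sampled",
                   "latent_prob", "latent_occupancy", response)
  vars <- if (identical(all.vars(formula[[3L]]), "."))
    setdiff(names(data), bookkeeping)
  else all.vars(formula[[3L]])
  miss <- setdiff(c(response, vars), names(data))
  if (length(miss)) stop("variable(s) not in data: ",
                         paste(miss, collapse = ", "))
  if (nrow(data) != nrow(grid$cells))
    stop("data must have one row per grid cell")
  if ("RAC" %in% vars) stop("'RAC' is a reserved variable name")

  sampled_idx <- which(!is.na(data[[response]]))
  y <- as.integer(data[[response]][sampled_idx])
  xs <- data[sampled_idx, vars, drop = FALSE]

  stage <- function(tag, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", tag, conditionMessage(e)), call. = FALSE))
  }

  vrep <- stage("vif", if (length(vars) >= 2L)
    vif_filter(xs, vif_threshold)
  else list(rounds = list(), removed = character(0), retained = vars,
            threshold = vif_threshold))
  xs <- xs[vrep$retained]

  if (tune)
    control <- stage("tune",
      tune_brt(xs, y, lr_grid = lr_grid, tc_grid = tc_grid,
               control = control))
  m0 <- stage("fit", {
    f <- if (tune) attr(control, "fit") else NULL
    if (!is.null(f)) f else brt(xs, y, control)
  })
  if (simplify && length(m0$variables) >= 2L)
    m0 <- stage("simplify", simplify_brt(m0, tol_auc, tol_dev))

  if (is.null(weights)) weights <- spatial_weights(grid, "queen")
  p0 <- predict(m0, xs)
  res0 <- if (residual_type == "response") y - p0 else {
    eps <- 1e-12
    sign(y - p0) * sqrt(pmax(0, -2 * (y * log(pmax(p0, eps)) +
                                        (1 - y) * log(pmax(1 - p0, eps)))))
  }
  rac <- stage("rac", residual_autocovariate(res0, sampled_idx, weights))

  x1 <- cbind(m0$x[m0$variables], RAC = rac[sampled_idx])
  m1 <- stage("refit", brt(x1, y, control))
  if (simplify && length(m1$variables) >= 2L)
    m1 <- stage("simplify", simplify_brt(m1, tol_auc, tol_dev,
                                         protect = "RAC"))

  w_s <- subset_weights(weights, sampled_idx)
  res1 <- y - predict(m1, m1$x)
  moran_pre <- stage("moran", morans_i(res0, w_s))
  moran_res <- stage("moran", morans_i(res1, w_s))

  structure(list(
    call = cl, hypothesis = hypothesis, formula = formula,
    variables = vrep$retained, vif_report = vrep,
    pre_rac_model = m0, final_model = m1, control = control,
    rac = rac, weights_scheme = weights$scheme,
    residual_type = residual_type,
    residuals_pre = res0, residuals_final = res1,
    moran_pre = moran_pre, moran_residual = moran_res,
    sampled_idx = sampled_idx, cell_id = data$cell_id,
    n1 = sum(y == 1L), n0 = sum(y == 0L)), class = "rac_brt")
}

#' @export
print.rac_brt <- function(x, ...) {
  cat("RAC-BRT model")
  if (!is.null(x$hypothesis)) cat(" [", x$hypothesis, "]", sep = "")
  cat("\n")
  m <- x$final_model
  cat(sprintf("  %d sampled cells (%d presences / %d absences)\n",
              length(x$sampled_idx), x$n1, x$n0))
  cat(sprintf("  final model: %d trees, variables: %s\n", m$n_trees,
              paste(m$variables, collapse = ", ")))
  cat(sprintf("  CV AUC %.3f (SE %.3f), %.2f%% CV deviance explained\n",
              m$cv_auc, m$cv_auc_se, m$deviance_explained_pct))
  cat(sprintf("  residual Moran's I: %.4f (p = %.3g) before RAC, %.4f (p = %.3g) after\n",
              x$moran_pre$I, x$moran_pre$p_value,
              x$moran_residual$I, x$moran_residual$p_value))
  invisible(x)
}

#' @export
summary.rac_brt <- function(object, ...) {
  structure(list(model = object,
                 influence = relative_influence(object),
                 vif = object$vif_report,
                 drop_log_pre = attr(object$pre_rac_model, "drop_log"),
                 drop_log_final = attr(object$final_model, "drop_log")),
            class = "summary.rac_brt")
}

#' @export
print.summary.rac_brt <- function(x, ...) {
  print(x$model)
  cat("\nRelative influence (%):\n")
  print(round(x$influence, 2))
  if (length(x$vif$removed))
    cat("\nVIF-removed:", paste(x$vif$removed, collapse = ", "), "\n")
  invisible(x)
}

#' @export
relative_influence.rac_brt <- function(object) {
  relative_influence(object$final_model)
}

#' @export
residuals.rac_brt <- function(object, type = c("final", "pre_rac"), ...) {
  switch(match.arg(type), final = object$residuals_final,
         pre_rac = object$residuals_pre)
}

#' Predict presence probability over a grid from a RAC-BRT model
#'
#' Grid-wide interpolation of the fitted model. The RAC predictor is not
#' observable off the training cells, so sampled cells use their computed RAC
#' value and unsampled cells receive, under the default `"mean"` policy, the
#' mean RAC over sampled cells (near zero for a calibrated model); the
#' `"layer"` policy uses the full neighbourhood-interpolated RAC layer.
#'
#' @param object A [rac_brt()] model.
#' @param newdata Cell table with covariates for every grid cell, aligned
#'   with the grid the model was fitted on (same `cell_id` order).
#' @param rac_policy `"mean"` or `"layer"` (see above).
#' @param type `"response"` (probability) or `"link"`.
#' @param ... Unused.
#' @return Numeric vector of predictions, one per row of `newdata`.
#' @export
predict.rac_brt <- function(object, newdata, rac_policy = c("mean", "layer"),
                            type = c("response", "link"), ...) {
  rac_policy <- match.arg(rac_policy)
  type <- match.arg(type)
  newdata <- as.data.frame(newdata, check.names = FALSE)
  if (nrow(newdata) != length(object$rac))
    stop("newdata must have one row per grid cell (",
         length(object$rac), ")")
  rac_col <- switch(rac_policy,
    layer = as.numeric(object$rac),
    mean = {
      v <- rep(mean(object$rac[object$sampled_idx]), nrow(newdata))
      v[object$sampled_idx] <- object$rac[object$sampled_idx]
      v
    })
  nd <- newdata
  nd$RAC <- rac_col
  predict(object$final_model, nd, type = type)
}

#' Partial-dependence plots for the most influential predictors
#'
#' @param x A [rac_brt()] model.
#' @param n_vars Number of top-influence variables to plot (RAC included if
#'   among them).
#' @param scale Passed to [partial_dependence()].
#' @param ... Additional graphics parameters.
#' @return The model, invisibly.
#' @export
plot.rac_brt <- function(x, n_vars = 6, scale = "link", ...) {
  infl <- relative_influence(x)
  vars <- utils::head(names(infl), n_vars)
  op <- graphics::par(mfrow = grDevices::n2mfrow(length(vars)),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (v in vars) {
    pd <- partial_dependence(x$final_model, v, scale = scale)
    plot(pd, main = sprintf("%s (%.1f%%)", v, infl[[v]]), ...)
  }
  invisible(x)
}
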