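# Boosted regression trees for presence/absence, built on the xgboost
# booster. The procedure implemented here is the SDM workflow: the ensemble
# size is chosen by minimum mean 10-fold cross-validated Bernoulli deviance,
# the learning rate / tree complexity pair by the "largest lr, smallest tc
# reaching >= min_trees" rule, backwards simplification drops the least
# influential variable while neither cross-validated AUC nor explained
# deviance degrades, and relative influences are split-gain importances
# rescaled to sum 100.

#' Control parameters for a boosted regression tree fit
#'
#' @param learning_rate Shrinkage (`lr`) applied to each tree, in (0, 1].
#' @param tree_complexity Maximum interaction depth (`tc`) of each tree, >= 1.
#' @param bag_fraction Fraction of the data subsampled for each tree.
#' @param n_folds Cross-validation folds (>= 2; 10 in the reference workflow).
#' @param max_trees Upper bound on the ensemble size searched by CV.
#' @param min_trees Minimum acceptable CV-selected ensemble size, used by
#'   [tune_brt()] (1000 in the reference workflow; reduce for small fixtures).
#' @param seed Integer seed controlling fold assignment and the booster's
#'   subsampling; identical seed + data + control reproduces the fit exactly.
#' @return A `brt_control` list.
#' @export
brt_control <- function(learning_rate = 0.05, tree_complexity = 2,
                        bag_fraction = 0.5, n_folds = 10, max_trees = 2000,
                        min_trees = 1000, seed = 1) {
  stopifnot(learning_rate > 0, learning_rate <= 1, tree_complexity >= 1,
            bag_fraction > 0, bag_fraction <= 1, n_folds >= 2, max_trees >= 1)
  structure(list(learning_rate = learning_rate,
                 tree_complexity = as.integer(tree_complexity),
                 bag_fraction = bag_fraction, n_folds = as.integer(n_folds),
                 max_trees = as.integer(max_trees),
                 min_trees = as.integer(min_trees),
                 seed = as.integer(seed)),
            class = "brt_control")
}

xgb_params <- function(control) {
  list(objective = "binary:logistic", eval_metric = "logloss",
       eta = control$learning_rate, max_depth = control$tree_complexity,
       subsample = control$bag_fraction, nthread = 1,
       seed = control$seed, lambda = 0, tree_method = "exact")
}

#' Fit a boosted regression tree presence/absence model
#'
#' Gradient-boosted trees on Bernoulli deviance. The ensemble size is the
#' minimizer of the mean held-out deviance across `n_folds` cross-validation
#' folds; `cv_auc` is the mean held-out AUC at that size and `cv_auc_se` its
#' standard error across folds; `deviance_explained_pct` is
#' `100 * (1 - CV deviance / null deviance)`, i.e. computed on held-out
#' predictions (a training-data version is in `train_deviance_explained_pct`).
#'
#' @param x Data frame or matrix of numeric/binary predictors.
#' @param y Binary 0/1 response with both classes present.
#' @param control A [brt_control()].
#' @return An object of class `brt` with the fitted booster, `n_trees`,
#'   `relative_influence` (sums to 100), `cv_auc`, `cv_auc_se`, `fold_auc`,
#'   `deviance_explained_pct`, and the training data (kept for partial
#'   dependence and simplification).
#' @export
brt <- function(x, y, control = brt_control()) {
  x <- as.data.frame(x, check.names = FALSE)
  y <- as.integer(y)
  if (any(is.na(y)) || !all(y %in% c(0L, 1L))) stop("y must be binary 0/1")
  if (length(unique(y)) < 2L) stop("y must contain both classes")
  n <- length(y)
  if (n < control$n_folds) stop("fewer observations than folds")
  if (nrow(x) != n) stop("x and y differ in length")
  xm <- as.matrix(x)
  storage.mode(xm) <- "double"
  set.seed(control$seed)
  folds <- sample(rep_len(seq_len(control$n_folds), n))
  params <- xgb_params(control)
  ll <- matrix(NA_real_, control$max_trees, control$n_folds)
  fold_models <- vector("list", control$n_folds)
  for (k in seq_len(control$n_folds)) {
    tr <- folds != k
    dtr <- xgboost::xgb.DMatrix(xm[tr, , drop = FALSE], label = y[tr])
    dte <- xgboost::xgb.DMatrix(xm[!tr, , drop = FALSE], label = y[!tr])
    m <- xgboost::xgb.train(params = params, data = dtr,
                            nrounds = control$max_trees,
                            evals = list(test = dte), verbose = 0)
    ll[, k] <- attr(m, "evaluation_log")$test_logloss
    fold_models[[k]] <- m
  }
  mean_ll <- rowMeans(ll)
  n_trees <- which.min(mean_ll)
  # held-out predictions and per-fold AUC at the selected ensemble size
  cv_pred <- numeric(n)
  fold_auc <- numeric(control$n_folds)
  for (k in seq_len(control$n_folds)) {
    te <- folds == k
    p <- predict(fold_models[[k]],
                 xgboost::xgb.DMatrix(xm[te, , drop = FALSE]),
                 iterationrange = c(1, n_trees))
    cv_pred[te] <- p
    fold_auc[k] <- auc_mw(y[te], p)
  }
  cv_auc <- mean(fold_auc, na.rm = TRUE)
  cv_auc_se <- stats::sd(fold_auc, na.rm = TRUE) /
    sqrt(sum(!is.na(fold_auc)))
  pbar <- mean(y)
  null_dev <- bernoulli_deviance(y, rep(pbar, n))
  cv_dev <- bernoulli_deviance(y, cv_pred)
  dall <- xgboost::xgb.DMatrix(xm, label = y)
  booster <- xgboost::xgb.train(params = params, data = dall,
                                nrounds = n_trees, verbose = 0)
  train_dev <- bernoulli_deviance(y, predict(booster, dall))
  obj <- structure(list(
    booster = booster, control = control, variables = colnames(xm),
    n_trees = as.integer(n_trees),
    relative_influence = influence_from_booster(booster, colnames(xm)),
    cv_auc = cv_auc, cv_auc_se = cv_auc_se, fold_auc = fold_auc,
    deviance_explained_pct = 100 * (1 - cv_dev / null_dev),
    train_deviance_explained_pct = 100 * (1 - train_dev / null_dev),
    cv_pred = cv_pred, folds = folds, x = x, y = y,
    null_deviance = null_dev, cv_deviance = cv_dev), class = "brt")
  obj
}

# split-gain importance rescaled to sum 100; unused variables get 0
influence_from_booster <- function(booster, variables) {
  imp <- tryCatch(xgboost::xgb.importance(model = booster),
                  error = function(e) NULL)
  out <- stats::setNames(rep(0, length(variables)), variables)
  if (!is.null(imp) && nrow(imp) > 0) {
    out[imp$Feature] <- imp$Gain
    out <- 100 * out / sum(out)
  } else {
    out[] <- 100 / length(variables)  # degenerate: no split ever made
  }
  out
}

#' Relative influence of each predictor
#'
#' Split-improvement (gain) importance of every variable in the ensemble,
#' rescaled to sum to 100.
#'
#' @param object A [brt()] or [rac_brt()] model.
#' @return Named numeric vector summing to 100, in decreasing order.
#' @export
relative_influence <- function(object) UseMethod("relative_influence")

#' @export
relative_influence.brt <- function(object) {
  sort(object$relative_influence, decreasing = TRUE)
}

#' @export
print.brt <- function(x, ...) {
  cat(sprintf("brt: %d trees (lr %g, tc %d), %d variables\n", x$n_trees,
              x$control$learning_rate, x$control$tree_complexity,
              length(x$variables)))
  cat(sprintf("  CV AUC %.3f (SE %.3f), %.2f%% CV deviance explained\n",
              x$cv_auc, x$cv_auc_se, x$deviance_explained_pct))
  invisible(x)
}

#' @export
predict.brt <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata, check.names = FALSE)
  miss <- setdiff(object$variables, names(newdata))
  if (length(miss)) stop("missing predictor column(s): ",
                         paste(miss, collapse = ", "))
  xm <- as.matrix(newdata[object$variables])
  storage.mode(xm) <- "double"
  predict(object$booster, xgboost::xgb.DMatrix(xm),
          outputmargin = (type == "link"))
}

#' Select learning rate and tree complexity by the minimum-ensemble-size rule
#'
#' Walks tree complexity upwards and learning rate downwards, returning the
#' first (smallest-`tc`, then largest-`lr`) combination whose CV-selected
#' ensemble size reaches `min_trees`: shrinking the learning rate forces more,
#' smaller steps, and the rule keeps the model as simple and as coarsely
#' stepped as the data allow while still fitting at least `min_trees` trees.
#'
#' @param x,y As in [brt()].
#' @param lr_grid Learning rates, sorted descending.
#' @param tc_grid Tree complexities, sorted ascending.
#' @param control Base [brt_control()]; `min_trees` and `max_trees` are taken
#'   from here.
#' @return The winning `brt_control`, with the successful fit attached as
#'   attribute `"fit"`. If no combination reaches `min_trees`, the smallest
#'   lr / largest tc combination is returned with a warning.
#' @export
tune_brt <- function(x, y, lr_grid = c(0.1, 0.05, 0.01, 0.005, 0.001),
                     tc_grid = c(1, 2, 3, 5), control = brt_control()) {
  if (!length(lr_grid) || !length(tc_grid)) stop("empty tuning grid")
  lr_grid <- sort(lr_grid, decreasing = TRUE)
  tc_grid <- sort(tc_grid)
  last <- NULL
  for (tc in tc_grid) for (lr in lr_grid) {
    ctl <- brt_control(learning_rate = lr, tree_complexity = tc,
                       bag_fraction = control$bag_fraction,
                       n_folds = control$n_folds,
                       max_trees = control$max_trees,
                       min_trees = control$min_trees, seed = control$seed)
    fit <- brt(x, y, ctl)
    last <- list(ctl = ctl, fit = fit)
    if (fit$n_trees >= control$min_trees)
      return(structure(ctl, fit = fit))
  }
  warning("no lr/tc combination reached min_trees = ", control$min_trees,
          "; returning smallest lr / largest tc")
  structure(last$ctl, fit = last$fit)
}

#' Backwards simplification of a boosted regression tree model
#'
#' Repeatedly drops the least influential (non-protected) variable and
#' refits; a drop is kept only while neither the cross-validated AUC nor the
#' explained deviance degrades by more than its tolerance ("no change", made
#' operational). Stops at the first rejected drop or when a single droppable
#' variable remains.
#'
#' @param model A fitted [brt()].
#' @param tol_auc Largest acceptable decrease in CV AUC per drop (0.005).
#' @param tol_dev Largest acceptable decrease in CV explained deviance,
#'   percentage points (0.5).
#' @param protect Variables never dropped (the RAC term, in the pipeline).
#' @return The simplified `brt`, with attribute `"drop_log"` (data frame of
#'   accepted/rejected drops).
#' @export
simplify_brt <- function(model, tol_auc = 0.005, tol_dev = 0.5,
                         protect = character(0)) {
  log <- data.frame(variable = character(0), cv_auc = numeric(0),
                    deviance_explained_pct = numeric(0),
                    accepted = logical(0))
  repeat {
    droppable <- setdiff(model$variables, protect)
    if (length(droppable) < 2L && length(protect) == 0L) break
    if (length(droppable) < 1L || length(model$variables) < 2L) break
    infl <- model$relative_influence[droppable]
    cand <- droppable[which.min(infl)]
    refit <- brt(model$x[setdiff(model$variables, cand)], model$y,
                 model$control)
    ok <- refit$cv_auc >= model$cv_auc - tol_auc &&
      refit$deviance_explained_pct >=
        model$deviance_explained_pct - tol_dev
    log <- rbind(log, data.frame(variable = cand, cv_auc = refit$cv_auc,
                                 deviance_explained_pct =
                                   refit$deviance_explained_pct,
                                 accepted = ok))
    if (!ok) break
    model <- refit
    if (length(model$variables) < 2L) break
  }
  attr(model, "drop_log") <- log
  model
}

#' Partial dependence of the model on one variable
#'
#' Mean model prediction over the training data with the variable clamped to
#' each of a sequence of grid values, on the link (log-odds) scale by default.
#'
#' @param model A [brt()] (or the final model of a [rac_brt()]).
#' @param variable Variable name present in the model.
#' @param grid_points Number of evaluation points over the observed range, or
#'   a numeric vector of explicit values.
#' @param scale `"link"` or `"response"`.
#' @param data Data at which to average (defaults to the training data).
#' @return Data frame `value`, `yhat` of class `partial_dependence`.
#' @export
partial_dependence <- function(model, variable, grid_points = 25,
                               scale = c("link", "response"),
                               data = model$x) {
  scale <- match.arg(scale)
  if (!variable %in% model$variables) stop("unknown variable: ", variable)
  data <- as.data.frame(data, check.names = FALSE)
  vals <- if (length(grid_points) > 1L) grid_points else
    seq(min(data[[variable]]), max(data[[variable]]),
        length.out = grid_points)
  yhat <- vapply(vals, function(v) {
    d <- data
    d[[variable]] <- v
    mean(predict(model, d, type = if (scale == "link") "link" else "response"))
  }, 0)
  structure(data.frame(value = vals, yhat = yhat),
            class = c("partial_dependence", "data.frame"),
            variable = variable, scale = scale)
}

#' @export
plot.partial_dependence <- function(x, ...) {
  graphics::plot(x$value, x$yhat, type = "l",
                 xlab = attr(x, "variable"),
                 ylab = sprintf("fitted function (%s)", attr(x, "scale")),
                 ...)
  invisible(x)
}
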