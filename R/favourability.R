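# Favourability transform, mapping, classification, and independent
# validation.

#' Favourability transform of predicted probabilities
#'
#' Converts a predicted probability `P` into favourability
#' `F = (P/(1-P)) / (n1/n0 + P/(1-P))`, the prevalence-corrected index: `F`
#' is strictly increasing in `P`, equals 0.5 exactly where `P` equals the
#' overall prevalence `n1/(n1+n0)`, and is extended continuously to `F = 0`
#' at `P = 0` and `F = 1` at `P = 1`. Because the prevalence is divided out,
#' favourability is comparable across models and regions with different
#' prevalences.
#'
#' @param p Probabilities in `[0, 1]` (vectorized).
#' @param n1,n0 Positive counts of presences and absences in the training
#'   data.
#' @return Favourability values in `[0, 1]`.
#' @examples
#' favourability(0.5, 50, 50)   # 0.5 at prevalence
#' favourability(0.7, 95, 177)  # 0.813
#' @export
favourability <- function(p, n1, n0) {
  if (n1 <= 0 || n0 <= 0) stop("n1 and n0 must be positive")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must lie in [0, 1]")
  odds <- p / (1 - p)
  f <- odds / (n1 / n0 + odds)
  f[p == 1] <- 1
  f[p == 0] <- 0
  f
}

#' Grid-wide favourability map from a RAC-BRT model
#'
#' Predicts presence probability for every grid cell (see
#' [predict.rac_brt()] for how the RAC term is filled in off the training
#' cells) and applies the favourability transform at the model's training
#' prevalence.
#'
#' @param model A [rac_brt()] fit.
#' @param newdata Covariates for every grid cell, aligned with the fitting
#'   grid.
#' @param n1,n0 Prevalence counts; default the model's training counts.
#' @param rac_policy Passed to [predict.rac_brt()].
#' @param model_id Label stored with the map.
#' @return A `favourability_map`: data frame `cell_id`, `P`, `F` with
#'   attributes `n1`, `n0`, `model_id`.
#' @export
favourability_map <- function(model, newdata, n1 = model$n1, n0 = model$n0,
                              rac_policy = "mean", model_id = "model") {
  p <- predict(model, newdata, rac_policy = rac_policy)
  out <- data.frame(cell_id = model$cell_id, P = p,
                    F = favourability(p, n1, n0))
  structure(out, class = c("favourability_map", "data.frame"),
            n1 = n1, n0 = n0, model_id = model_id)
}

#' @export
print.favourability_map <- function(x, ...) {
  cat(sprintf(
    "favourability_map [%s]: %d cells, prevalence %d/%d, %.1f%% favourable (F >= 0.5)\n",
    attr(x, "model_id"), nrow(x), attr(x, "n1"),
    attr(x, "n1") + attr(x, "n0"), 100 * mean(x$F >= 0.5)))
  invisible(x)
}

#' Classify cells by favourability thresholds
#'
#' The boundary convention is inclusive everywhere: a cell is favourable at
#' threshold `t` when `F >= t`.
#'
#' @param f Favourability values, or a [favourability_map()].
#' @param thresholds Numeric thresholds (default the working set
#'   0.50 / 0.75 / 0.45).
#' @return A `favourability_classes` list: logical matrix `layers`
#'   (cell x threshold) and integer `counts` per threshold.
#' @export
classify_favourable <- function(f, thresholds = c(0.50, 0.75, 0.45)) {
  if (inherits(f, "favourability_map")) f <- f$F
  layers <- matrix(FALSE, length(f), length(thresholds),
                   dimnames = list(NULL, sprintf("F>=%.2f", thresholds)))
  for (j in seq_along(thresholds)) layers[, j] <- f >= thresholds[j]
  structure(list(layers = layers, counts = colSums(layers),
                 thresholds = thresholds), class = "favourability_classes")
}

#' @export
print.favourability_classes <- function(x, ...) {
  cat("favourable cell counts:\n")
  print(x$counts)
  invisible(x)
}

#' Validate a favourability map against independent presence records
#'
#' Compares independently recorded presence cells (not used in model fitting)
#' with the map: the share identified as favourable (`F >= 0.50`), the share
#' added by near-threshold cells (`0.45 <= F < 0.50`), and the
#' false-negative percentage (presence cells the map calls unfavourable,
#' `100 - pct_favourable`).
#'
#' @param fav_map A [favourability_map()] (or any data frame with `cell_id`
#'   and `F`).
#' @param presence_cells `cell_id`s with independent presence records; must
#'   all be on the map.
#' @return A `validation_report` with counts and percentages (percentages at
#'   full precision; round for display).
#' @export
validate_independent <- function(fav_map, presence_cells) {
  if (length(presence_cells) == 0L) stop("empty presence set")
  i <- match(presence_cells, fav_map$cell_id)
  if (any(is.na(i))) stop("presence cells not on the map: ",
                          paste(presence_cells[is.na(i)], collapse = ", "))
  f <- fav_map$F[i]
  n <- length(f)
  n_fav <- sum(f >= 0.50)
  n_near <- sum(f >= 0.45 & f < 0.50)
  structure(list(
    n_test_cells = n, n_favourable = n_fav, n_near_threshold = n_near,
    pct_favourable = 100 * n_fav / n,
    pct_with_near = 100 * (n_fav + n_near) / n,
    false_negative_pct = 100 * (1 - n_fav / n)), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "independent validation: %d test cells; %d (%.0f%%) favourable (F >= 0.50); +%d near-threshold -> %.0f%%; false negatives %.0f%%\n",
    x$n_test_cells, x$n_favourable, x$pct_favourable, x$n_near_threshold,
    x$pct_with_near, x$false_negative_pct))
  invisible(x)
}
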