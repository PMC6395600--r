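# Spatial weights, Moran's I, and the residuals autocovariate (RAC).

#' Neighbourhood weights on a grid
#'
#' Builds the spatial weights used for Moran's I and the residuals
#' autocovariate. `rook` links orthogonal neighbours, `queen` adds diagonals
#' (the default throughout the package, matching the focal-mean formulation of
#' the RAC correction), and `inverse_distance` weights every pair of cells
#' within `cutoff_km` by 1/distance.
#'
#' @param grid An [sdm_grid()].
#' @param scheme `"queen"`, `"rook"`, or `"inverse_distance"`.
#' @param row_standardize Scale each cell's weights to sum to 1 (default).
#' @param cutoff_km Distance cutoff for `inverse_distance`; `Inf` links all
#'   pairs.
#' @return A `spatial_weights` object: parallel lists `nb` (integer indices
#'   into `grid$cells`) and `w` (weights), plus bookkeeping fields. Cells with
#'   no neighbour trigger a warning.
#' @export
spatial_weights <- function(grid, scheme = c("queen", "rook",
                                             "inverse_distance"),
                            row_standardize = TRUE, cutoff_km = Inf) {
  scheme <- match.arg(scheme)
  cells <- grid$cells
  n <- nrow(cells)
  if (n == 0L) stop("grid has no cells")
  nb <- vector("list", n)
  w <- vector("list", n)
  if (scheme %in% c("queen", "rook")) {
    off <- if (scheme == "rook") {
      cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
    } else {
      as.matrix(expand.grid(dr = -1:1, dc = -1:1)[-5, ])
    }
    key <- cells$row * (grid$n_cols + 2L) + cells$col
    lut <- structure(seq_len(n), names = key)
    for (i in seq_len(n)) {
      kk <- (cells$row[i] + off[, 1L]) * (grid$n_cols + 2L) +
        (cells$col[i] + off[, 2L])
      ok <- cells$row[i] + off[, 1L] >= 0 & cells$col[i] + off[, 2L] >= 0 &
        cells$row[i] + off[, 1L] < grid$n_rows &
        cells$col[i] + off[, 2L] < grid$n_cols
      j <- lut[as.character(kk[ok])]
      j <- unname(j[!is.na(j)])
      nb[[i]] <- j
      w[[i]] <- rep(1, length(j))
    }
  } else {
    for (i in seq_len(n)) {
      d <- sqrt((cells$x_km - cells$x_km[i])^2 +
                  (cells$y_km - cells$y_km[i])^2)
      j <- which(d > 0 & d <= cutoff_km)
      nb[[i]] <- j
      w[[i]] <- 1 / d[j]
    }
  }
  if (any(lengths(nb) == 0L))
    warning(sum(lengths(nb) == 0L), " cell(s) have no neighbours")
  if (row_standardize)
    w <- lapply(w, function(x) if (length(x)) x / sum(x) else x)
  structure(list(scheme = scheme, nb = nb, w = w,
                 row_standardized = row_standardize,
                 cell_id = cells$cell_id, n = n),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("spatial_weights: %s, %d cells, %s, mean %.1f neighbours\n",
              x$scheme, x$n,
              if (x$row_standardized) "row-standardized" else "raw",
              mean(lengths(x$nb))))
  invisible(x)
}

#' Restrict spatial weights to a subset of cells
#'
#' Keeps only the links among the cells at positions `idx` (e.g. the sampled
#' cells), preserving the original link weights and re-standardizing rows if
#' the parent object was row-standardized. Used to run Moran tests on
#' residuals that exist only on sampled cells.
#'
#' @param weights A [spatial_weights()].
#' @param idx Integer positions (into the parent grid's cells) to keep.
#' @return A `spatial_weights` over the `length(idx)` kept cells.
#' @export
subset_weights <- function(weights, idx) {
  pos <- match(seq_len(weights$n), idx)  # old index -> new index or NA
  nb <- vector("list", length(idx))
  w <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    keep <- !is.na(pos[weights$nb[[i]]])
    nb[[k]] <- pos[weights$nb[[i]]][keep]
    ww <- weights$w[[i]][keep]
    if (weights$row_standardized && length(ww)) ww <- ww / sum(ww)
    w[[k]] <- ww
  }
  structure(list(scheme = weights$scheme, nb = nb, w = w,
                 row_standardized = weights$row_standardized,
                 cell_id = weights$cell_id[idx], n = length(idx)),
            class = "spatial_weights")
}

# raw Moran's I and its building blocks for a weights list
moran_stat <- function(z, weights) {
  n <- length(z)
  num <- 0
  for (i in seq_len(n))
    num <- num + sum(weights$w[[i]] * z[weights$nb[[i]]]) * z[i]
  S0 <- sum(unlist(weights$w))
  (n / S0) * num / sum(z^2)
}

#' Moran's I test of spatial autocorrelation
#'
#' Computes Moran's I by the standard cross-product formula
#' `I = (N / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z` the deviations
#' from the mean, and tests it either by the normal approximation under the
#' randomization assumption or by a permutation test.
#'
#' @param values Numeric vector, one value per weights cell (>= 3,
#'   non-constant).
#' @param weights A [spatial_weights()] on the same cells.
#' @param p_method `"normal"` (randomization variance) or `"permutation"`.
#' @param n_perm Number of permutations for `p_method = "permutation"`.
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @param seed Seed for the permutation test.
#' @return A `moran_test` object: observed `I`, `expected` (= -1/(N-1)),
#'   `sd`, `z`, `p_value`, and `n`.
#' @export
morans_i <- function(values, weights, p_method = c("normal", "permutation"),
                     n_perm = 999, alternative = c("two.sided", "greater"),
                     seed = 1) {
  p_method <- match.arg(p_method)
  alternative <- match.arg(alternative)
  n <- length(values)
  if (n != weights$n) stop("values and weights differ in length")
  if (n < 3L) stop("need at least 3 values")
  if (stats::sd(values) == 0) stop("values are constant; Moran's I undefined")
  z <- values - mean(values)
  I <- moran_stat(z, weights)
  EI <- -1 / (n - 1)
  # randomization variance (standard S1/S2/kurtosis formula)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) W[i, weights$nb[[i]]] <- weights$w[[i]]
  S0 <- sum(W)
  S1 <- 0.5 * sum((W + t(W))^2)
  S2 <- sum((rowSums(W) + colSums(W))^2)
  b2 <- n * sum(z^4) / sum(z^2)^2
  VI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
           b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  zscore <- (I - EI) / sqrt(VI)
  if (p_method == "normal") {
    p <- if (alternative == "two.sided") 2 * stats::pnorm(-abs(zscore))
         else stats::pnorm(zscore, lower.tail = FALSE)
  } else {
    set.seed(stage_seed(seed, "moran_perm"))
    Iperm <- replicate(n_perm, moran_stat(sample(z), weights))
    p <- if (alternative == "two.sided") {
      (1 + sum(abs(Iperm - EI) >= abs(I - EI))) / (n_perm + 1)
    } else {
      (1 + sum(Iperm >= I)) / (n_perm + 1)
    }
  }
  structure(list(I = I, expected = EI, sd = sqrt(VI), z = zscore,
                 p_value = p, n = n, p_method = p_method,
                 alternative = alternative),
            class = "moran_test")
}

#' @export
print.moran_test <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (expected %.4f, sd %.4f), z = %.3f, p = %.4g [%s, %s]\n",
              x$I, x$expected, x$sd, x$z, x$p_value, x$p_method,
              x$alternative))
  invisible(x)
}

#' Residuals autocovariate (RAC) layer
#'
#' The spatial correction term of the RAC-BRT method: each cell's value is the
#' weighted mean of the model residuals of its *sampled* neighbours (weights
#' renormalized over the sampled neighbours). Cells with no sampled neighbour
#' receive the global mean residual, so the layer is defined for every grid
#' cell and can feed grid-wide prediction.
#'
#' @param residuals Numeric residuals for the sampled cells, in the order of
#'   `sampled_idx`.
#' @param sampled_idx Integer positions of the sampled cells in the weights
#'   object (i.e. in `grid$cells`).
#' @param weights [spatial_weights()] over the full grid.
#' @return Numeric vector, one RAC value per grid cell, with attribute
#'   `"scheme"`.
#' @export
residual_autocovariate <- function(residuals, sampled_idx, weights) {
  if (length(residuals) == 0L) stop("empty residual set")
  if (length(residuals) != length(sampled_idx))
    stop("residuals and sampled_idx differ in length")
  res_at <- rep(NA_real_, weights$n)
  res_at[sampled_idx] <- residuals
  gm <- mean(residuals)
  rac <- numeric(weights$n)
  for (i in seq_len(weights$n)) {
    j <- weights$nb[[i]]
    ok <- !is.na(res_at[j])
    if (any(ok)) {
      ww <- weights$w[[i]][ok]
      rac[i] <- sum(ww * res_at[j][ok]) / sum(ww)
    } else {
      rac[i] <- gm
    }
  }
  structure(rac, scheme = weights$scheme)
}
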