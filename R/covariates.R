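# Synthetic spatially autocorrelated covariate fields.
#
# Fields are Gaussian-kernel-smoothed white noise, standardized over the study
# region, pushed through the probability integral transform and a power map so
# each variable hits its target mean while staying inside its stated range
# (cover fractions and densities are strongly right-skewed, which the power
# map reproduces). Collinear variables are affine combinations of already
# generated sources plus smoothed noise, then clipped to range.

# Smoothed standard-normal-ish field over the full lattice, using the current
# RNG state. range_cells is the Gaussian kernel sd in cell units; 0 = white
# noise. Values are standardized to mean 0, sd 1 over the whole lattice.
smooth_noise <- function(n_rows, n_cols, range_cells) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  if (range_cells > 0) {
    k1 <- function(n) {
      r <- max(1L, ceiling(3 * range_cells))
      idx <- seq_len(n)
      K <- outer(idx, idx, function(i, j)
        exp(-((i - j)^2) / (2 * range_cells^2)))
      K[abs(outer(idx, idx, "-")) > r] <- 0
      K / rowSums(K)
    }
    z <- k1(n_rows) %*% z %*% t(k1(n_cols))
  }
  (z - mean(z)) / stats::sd(z)
}

#' Specification of one synthetic covariate field
#'
#' @param name Variable name (kept verbatim, may contain `&` or `/`).
#' @param group Hypothesis group, one of `"H1_landcover"`, `"H2_disturbance"`,
#'   `"H3_abiotic"`, `"H4_climate"`.
#' @param mean Target mean over the study region.
#' @param min,max Range limits; simulated values are clipped to `[min, max]`.
#' @param spatial_range_cells Gaussian correlation length in cell units
#'   (0 = spatially independent noise).
#' @param collinear_with Optional list `list(sources=, weights=, intercept=,
#'   noise_sd=)` making this variable a (noisy) affine combination of earlier
#'   variables — used to exercise collinearity screening.
#' @param binary If `TRUE` the field is thresholded at its target prevalence
#'   `mean` into 0/1.
#' @return A `covariate_spec` list.
#' @export
covariate_spec <- function(name, group, mean, min, max,
                           spatial_range_cells = 2,
                           collinear_with = NULL, binary = FALSE) {
  if (!(min <= mean && mean <= max)) stop("need min <= mean <= max: ", name)
  if (spatial_range_cells < 0) stop("spatial_range_cells must be >= 0")
  structure(list(name = name, group = group, mean = mean, min = min,
                 max = max, spatial_range_cells = spatial_range_cells,
                 collinear_with = collinear_with, binary = binary),
            class = "covariate_spec")
}

#' Default synthetic covariate catalogue
#'
#' The 33 per-cell variables used to characterise 5 x 5 km cells in the badger
#' survey, grouped by working hypothesis (landcover composition, anthropogenic
#' disturbance, abiotic environment, climate), with their published means and
#' ranges. Spatial correlation lengths are synthetic choices: climate varies
#' smoothly (8 cells), topography/geology at intermediate scale (5), landcover
#' and disturbance at fine scale (2). `Sediment` is built as a noisy scaled
#' complement of the other two lithology shares (mirroring the constraint
#' that the shares sum to ~100%), reproducing the collinearity that gets it
#' screened out by the VIF filter; the damped weights keep range clipping
#' rare so the affine structure survives.
#'
#' @return Named list of [covariate_spec()] objects.
#' @export
default_covariate_specs <- function() {
  s <- list(
    # H1 - landcover composition (% of cell area except H)
    covariate_spec("Deciduous",    "H1_landcover", 10.3, 0, 62.9),
    covariate_spec("Coniferous",   "H1_landcover", 11.3, 0, 68.1),
    covariate_spec("Agroforestry", "H1_landcover",  4.7, 0, 71.2),
    covariate_spec("Eucalyptus",   "H1_landcover",  6.4, 0, 55.3),
    covariate_spec("Exotic",       "H1_landcover",  0.009, 0, 2.4),
    covariate_spec("Shrublands",   "H1_landcover", 15.6, 0, 75.9),
    covariate_spec("Wetlands",     "H1_landcover",  1.1, 0, 42.4),
    covariate_spec("Herbaceous",   "H1_landcover", 12.7, 0, 78.4),
    covariate_spec("Food",         "H1_landcover", 17.0, 0, 75.0),
    covariate_spec("Artificial",   "H1_landcover",  4.8, 0, 56.3),
    covariate_spec("H",            "H1_landcover",  1.55, 0.70, 2.10, 3),
    # H2 - anthropogenic disturbance
    covariate_spec("Highways",      "H2_disturbance", 0.08, 0, 0.95),
    covariate_spec("Roads",         "H2_disturbance", 1.63, 0, 12.29),
    covariate_spec("Unpaved_roads", "H2_disturbance", 1.23, 0, 6.96),
    covariate_spec("Human_pop",     "H2_disturbance", 165.3, 0, 8435.76),
    covariate_spec("PA",            "H2_disturbance", 21.8, 0, 100),
    covariate_spec("Hunting",       "H2_disturbance", 0.5, 0, 1, 2,
                   binary = TRUE),
    covariate_spec("Cattle",        "H2_disturbance", 1.25, 0, 62.20),
    covariate_spec("Goat&sheep",    "H2_disturbance", 1.83, 0.25, 9.42),
    covariate_spec("Pigs",          "H2_disturbance", 2.28, 0, 129.40),
    # H3 - environmental abiotic factors
    covariate_spec("Alt_mean",  "H3_abiotic", 347.73, 5.84, 1297.59, 5),
    covariate_spec("Alt_range", "H3_abiotic", 286.97, 14.00, 1350.00, 5),
    covariate_spec("Sediment/Metamorph", "H3_abiotic", 36.2, 0, 100, 5),
    covariate_spec("Eruptive",  "H3_abiotic", 28.6, 0, 100, 5),
    covariate_spec("Sediment",  "H3_abiotic", 34.0, 0, 100, 5,
                   collinear_with = list(
                     sources = c("Sediment/Metamorph", "Eruptive"),
                     weights = c(-0.3, -0.3), intercept = 53.44,
                     noise_sd = 2)),
    covariate_spec("Podzols",   "H3_abiotic", 12.4, 0, 100, 5),
    covariate_spec("Luvisols",  "H3_abiotic", 13.7, 0, 100, 5),
    covariate_spec("Lithosols", "H3_abiotic", 13.9, 0, 100, 5),
    covariate_spec("Cambisols", "H3_abiotic", 50.2, 0, 100, 5),
    # H4 - climate
    covariate_spec("Ann_Prec",    "H4_climate", 907.93, 526.63, 1614.83, 8),
    covariate_spec("Prec_season", "H4_climate", 55.43, 41.59, 67.74, 8),
    covariate_spec("Ann_Temp",    "H4_climate", 14.13, 9.33, 17.00, 8),
    covariate_spec("Temp_season", "H4_climate", 42.83, 30.00, 50.77, 8)
  )
  names(s) <- vapply(s, `[[`, "", "name")
  s
}

#' Simulate spatially autocorrelated covariate fields on a grid
#'
#' Each independent variable is a smoothed-noise field mapped so that its
#' expected mean equals the spec mean and its values lie inside the spec
#' range; variables with a `collinear_with` rule are affine combinations of
#' previously generated sources plus smoothed noise, clipped to range.
#'
#' @param grid An [sdm_grid()].
#' @param specs List of [covariate_spec()]s (default [default_covariate_specs()]).
#' @param seed Integer seed; identical seed and specs give identical output.
#' @return Data frame with `cell_id` and one column per variable
#'   (`check.names` is not applied, so names like `Goat&sheep` survive).
#' @export
simulate_covariates <- function(grid, specs = default_covariate_specs(),
                                seed = 1) {
  if (length(specs) == 0L) stop("specs must be non-empty")
  nms <- vapply(specs, `[[`, "", "name")
  out <- data.frame(cell_id = grid$cells$cell_id)
  idx <- cbind(grid$cells$row + 1L, grid$cells$col + 1L)
  set.seed(stage_seed(seed, "covariates"))
  for (sp in specs[order(!vapply(specs, function(s) is.null(s$collinear_with),
                                 TRUE))]) {
    if (is.null(sp$collinear_with)) {
      f <- smooth_noise(grid$n_rows, grid$n_cols, sp$spatial_range_cells)
      z <- f[idx]
      z <- (z - mean(z)) / stats::sd(z)
      u <- clamp(stats::pnorm(z), 1e-9, 1 - 1e-9)
      if (sp$binary) {
        v <- as.numeric(u >= 1 - sp$mean / (sp$max - sp$min + (sp$max == sp$min)))
        v <- sp$min + (sp$max - sp$min) * v
      } else {
        # power map: E[u^a] = 1/(a+1) for u ~ U(0,1), so a places the mean
        a <- (sp$max - sp$min) / (sp$mean - sp$min) - 1
        a <- max(a, 1e-9)
        v <- sp$min + (sp$max - sp$min) * u^a
      }
    } else {
      cw <- sp$collinear_with
      miss <- setdiff(cw$sources, names(out))
      if (length(miss))
        stop("collinear_with references unknown variable(s): ",
             paste(miss, collapse = ", "))
      v <- (cw$intercept %||% 0) +
        as.matrix(out[cw$sources]) %*% cw$weights
      if ((cw$noise_sd %||% 0) > 0) {
        f <- smooth_noise(grid$n_rows, grid$n_cols, sp$spatial_range_cells)
        v <- v + cw$noise_sd * f[idx]
      }
      v <- as.numeric(v)
    }
    out[[sp$name]] <- clamp(v, sp$min, sp$max)
  }
  out[c("cell_id", nms)]
}
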