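# Synthetic survey design and presence/absence generator.

#' Two-stage grid survey design
#'
#' Mirrors the badger survey layout: coarse (10 km) cells picked by regular
#' knight's-move selection, two distinct fine (5 km) quadrants surveyed per
#' selected coarse cell, and a fixed number of walked line transects per
#' surveyed quadrant.
#'
#' @param grid Coarse [sdm_grid()] (e.g. 10 km cells).
#' @param fine Refined grid from [refine_grid()] (e.g. 5 km cells).
#' @param selected Coarse `cell_id`s chosen for survey (e.g. from
#'   [knight_move_select()]).
#' @param n_surveyed Optional number of coarse cells actually surveyed; when
#'   smaller than `length(selected)` the cells nearest the south-east corner
#'   are dropped first, emulating survey drop-out concentrated in one region.
#' @param subcells_per_cell Fine quadrants surveyed per coarse cell (2).
#' @param transects_per_subcell Line transects walked per surveyed quadrant (5).
#' @param transect_length_km Length of one transect in km (0.5).
#' @param seed Seed for the random choice of quadrants.
#' @return A `survey_design` object with the surveyed coarse cells, the
#'   sampled fine `cell_id`s, and the transect allocation.
#' @export
survey_design <- function(grid, fine, selected,
                          n_surveyed = NULL, subcells_per_cell = 2L,
                          transects_per_subcell = 5L,
                          transect_length_km = 0.5, seed = 1) {
  stopifnot(transects_per_subcell >= 1L, subcells_per_cell >= 1L)
  if (!is.null(n_surveyed) && n_surveyed < length(selected)) {
    i <- match(selected, grid$cells$cell_id)
    # drop-out concentrated towards the south-east corner of the region
    ord <- order(grid$cells$row[i] + grid$cells$col[i], decreasing = TRUE)
    selected <- selected[-ord[seq_len(length(selected) - n_surveyed)]]
  }
  set.seed(stage_seed(seed, "survey"))
  sampled <- integer(0)
  kept <- integer(0)
  for (id in selected) {
    sub <- subcell_ids(grid, fine, id)
    if (length(sub) < subcells_per_cell) next  # mostly-masked coarse cell
    sampled <- c(sampled, sort(sample(sub, subcells_per_cell)))
    kept <- c(kept, id)
  }
  structure(list(selected_coarse = kept, sampled_cells = sampled,
                 subcells_per_cell = as.integer(subcells_per_cell),
                 transects_per_subcell = as.integer(transects_per_subcell),
                 transect_length_km = transect_length_km),
            class = "survey_design")
}

#' @export
print.survey_design <- function(x, ...) {
  cat(sprintf(
    "survey_design: %d coarse cells, %d sampled fine cells, %d transects of %g km (%.1f km total)\n",
    length(x$selected_coarse), length(x$sampled_cells),
    length(x$sampled_cells) * x$transects_per_subcell,
    x$transect_length_km, survey_effort(x)))
  invisible(x)
}

#' Total walked survey effort in km
#'
#' Either pass a [survey_design()] or the transect count and length directly
#' (e.g. `survey_effort(n_transects = 1315)` for a survey of 1315 transects of
#' 500 m gives 657.5 km).
#'
#' @param design A `survey_design`, or `NULL` when using the explicit form.
#' @param n_transects,transect_length_km Explicit transect count and length.
#' @return Effort in km.
#' @export
survey_effort <- function(design = NULL, n_transects = NULL,
                          transect_length_km = 0.5) {
  if (!is.null(design)) {
    n_transects <- length(design$sampled_cells) * design$transects_per_subcell
    transect_length_km <- design$transect_length_km
  }
  n_transects * transect_length_km
}

#' Specification of the synthetic presence response
#'
#' Defines the latent occupancy model: per-variable partial effects as
#' piecewise-linear curves on the logit scale, an intercept (or a target
#' prevalence to which the intercept is calibrated), spatially autocorrelated
#' logit noise, and a per-transect detection probability.
#'
#' @param effects Named list; each element a 2-column matrix/data frame
#'   `(x, effect)` defining a piecewise-linear curve on the variable's scale
#'   (flat extrapolation beyond the endpoints).
#' @param intercept Logit-scale intercept, or `NULL` to calibrate it so the
#'   expected observed prevalence over sampled cells equals
#'   `target_prevalence`.
#' @param target_prevalence Calibration target for the intercept (0.35, the
#'   observed share of positive survey cells).
#' @param spatial_noise_sd,spatial_noise_range_cells Logit-scale sd and
#'   correlation length of the latent spatial noise field.
#' @param detection_prob_per_transect Probability one transect in an occupied
#'   cell detects the species (0 < p <= 1).
#' @return A `response_spec` object.
#' @export
response_spec <- function(effects, intercept = NULL, target_prevalence = 0.35,
                          spatial_noise_sd = 1.25,
                          spatial_noise_range_cells = 3,
                          detection_prob_per_transect = 0.8) {
  stopifnot(detection_prob_per_transect > 0, detection_prob_per_transect <= 1)
  effects <- lapply(effects, function(e) {
    e <- as.matrix(e)
    if (ncol(e) != 2L || any(!is.finite(e))) stop("effect curves must be finite 2-column (x, effect)")
    e[order(e[, 1L]), , drop = FALSE]
  })
  structure(list(effects = effects, intercept = intercept,
                 target_prevalence = target_prevalence,
                 spatial_noise_sd = spatial_noise_sd,
                 spatial_noise_range_cells = spatial_noise_range_cells,
                 detection_prob_per_transect = detection_prob_per_transect),
            class = "response_spec")
}

#' Default synthetic presence response
#'
#' Threshold-shaped partial effects emulating the published partial-dependence
#' shapes for the badger (optimum herbaceous and shrubland cover around
#' 5--10%, a Eucalyptus penalty above ~15% cover, podzols and eruptive
#' substrates favourable above ~50%, sheep/goat density favourable above
#' ~4 ind/km2 and avoided below ~2, cattle avoided above ~0.5 ind/km2,
#' precipitation optimum 800--1000 mm, temperature optimum 15--16 C). The
#' curve values themselves are synthetic calibration choices, not published
#' numbers.
#'
#' @inheritParams response_spec
#' @return A `response_spec`.
#' @export
default_response_spec <- function(target_prevalence = 0.35,
                                  spatial_noise_sd = 1.25,
                                  spatial_noise_range_cells = 3,
                                  detection_prob_per_transect = 0.8) {
  eff <- list(
    Herbaceous   = cbind(c(0, 5, 10, 20, 40), c(-0.6, 1.0, 1.0, -0.2, -0.8)),
    Shrublands   = cbind(c(0, 5, 10, 15, 40), c(-0.4, 0.9, 0.9, -0.1, -0.8)),
    Eucalyptus   = cbind(c(0, 15, 30, 55),    c(0.3, 0.1, -1.2, -1.6)),
    Podzols      = cbind(c(0, 40, 50, 100),   c(-0.4, -0.1, 0.9, 1.1)),
    Eruptive     = cbind(c(0, 40, 50, 100),   c(-0.3, 0.0, 0.7, 0.9)),
    `Goat&sheep` = cbind(c(0.25, 2, 4, 9.4),  c(-0.9, -0.3, 0.8, 0.9)),
    Cattle       = cbind(c(0, 0.5, 2, 10),    c(0.3, 0.0, -0.8, -1.0)),
    Ann_Prec     = cbind(c(527, 700, 800, 1000, 1200, 1615),
                         c(-0.9, -0.2, 0.8, 0.8, -0.3, -1.0)),
    Ann_Temp     = cbind(c(9.3, 12, 15, 16, 17), c(-1.0, -0.3, 0.8, 0.8, 0.4))
  )
  response_spec(eff, intercept = NULL,
                target_prevalence = target_prevalence,
                spatial_noise_sd = spatial_noise_sd,
                spatial_noise_range_cells = spatial_noise_range_cells,
                detection_prob_per_transect = detection_prob_per_transect)
}

# piecewise-linear effect evaluation, flat beyond the endpoints
eval_effect <- function(curve, x) {
  stats::approx(curve[, 1L], curve[, 2L], xout = x, rule = 2)$y
}

#' Simulate latent occupancy and observed survey presence
#'
#' Latent occupancy is Bernoulli with probability
#' `plogis(intercept + sum of partial effects + spatial noise)`; a surveyed
#' cell is recorded present iff it is occupied and at least one of its
#' transects detects the species (independent Bernoulli detections). Both the
#' latent truth and the observed record are returned so recovery tests have a
#' known answer.
#'
#' @param grid The [sdm_grid()] the covariates live on.
#' @param covariates Output of [simulate_covariates()] (or any cell table with
#'   the variables named in the response).
#' @param response A [response_spec()].
#' @param design A [survey_design()] giving the sampled cells and transects.
#' @param seed Integer seed.
#' @return Data frame with `cell_id`, `sampled`, `latent_prob`,
#'   `latent_occupancy`, `presence` (`NA` for unsampled cells).
#' @export
simulate_presence <- function(grid, covariates, response, design, seed = 1) {
  miss <- setdiff(names(response$effects), names(covariates))
  if (length(miss))
    stop("missing covariate for response term(s): ", paste(miss, collapse = ", "))
  set.seed(stage_seed(seed, "presence"))
  eta <- rep(0, nrow(covariates))
  for (v in names(response$effects))
    eta <- eta + eval_effect(response$effects[[v]], covariates[[v]])
  if (response$spatial_noise_sd > 0) {
    f <- smooth_noise(grid$n_rows, grid$n_cols,
                      response$spatial_noise_range_cells)
    idx <- cbind(grid$cells$row + 1L, grid$cells$col + 1L)
    eta <- eta + response$spatial_noise_sd * f[idx]
  }
  sampled <- covariates$cell_id %in% design$sampled_cells
  p_det <- 1 - (1 - response$detection_prob_per_transect)^design$transects_per_subcell
  a <- response$intercept
  if (is.null(a)) {
    # calibrate so expected *observed* prevalence over sampled cells hits target
    a <- stats::uniroot(function(c0)
      mean(stats::plogis(c0 + eta[sampled])) * p_det - response$target_prevalence,
      c(-30, 30))$root
  }
  latent_prob <- stats::plogis(a + eta)
  occ <- stats::rbinom(length(eta), 1L, latent_prob)
  detected <- stats::rbinom(length(eta), 1L, p_det)
  presence <- ifelse(sampled, occ * detected, NA_integer_)
  data.frame(cell_id = covariates$cell_id, sampled = sampled,
             latent_prob = latent_prob, latent_occupancy = occ,
             presence = as.integer(presence))
}

#' Generate a full synthetic study landscape
#'
#' Convenience wrapper reproducing the structure of the badger grid survey at
#' its published scale: a 33 x 30 lattice of 10 km cells masked to a 987-cell
#' country-like region, knight's-move selection of coarse survey cells,
#' drop-out to 136 surveyed coarse cells (concentrated in the south-east),
#' two 5 km quadrants surveyed per coarse cell (272 sampled fine cells, five
#' 500 m transects each), 33 spatially autocorrelated covariates with the
#' published means/ranges (including the built-in `Sediment` collinearity),
#' and threshold-shaped presence responses calibrated to ~35% observed
#' prevalence.
#'
#' @param seed Integer seed driving every stochastic stage.
#' @param n_rows,n_cols,region_cells Coarse lattice shape and region size.
#' @param n_surveyed_coarse Coarse cells actually surveyed.
#' @param specs,response Covariate and response specifications.
#' @return List with `grid` (fine grid), `coarse_grid`, `design`, `cells`
#'   (covariates + survey columns, one row per fine cell), `specs`,
#'   `response`, and the training prevalence counts `n1`, `n0`.
#' @export
simulate_landscape <- function(seed = 1, n_rows = 33, n_cols = 30,
                               region_cells = 987, n_surveyed_coarse = 136,
                               specs = default_covariate_specs(),
                               response = default_response_spec()) {
  mask <- synthetic_region_mask(n_rows, n_cols, region_cells,
                                seed = stage_seed(seed, "mask"))
  coarse <- sdm_grid(n_rows, n_cols, cell_size_km = 10, mask = mask)
  fine <- refine_grid(coarse, 2L)
  sel <- knight_move_select(coarse)
  design <- survey_design(coarse, fine, sel, n_surveyed = n_surveyed_coarse,
                          seed = seed)
  cov <- simulate_covariates(fine, specs, seed = seed)
  pres <- simulate_presence(fine, cov, response, design, seed = seed)
  cells <- merge(pres, cov, by = "cell_id", sort = TRUE)
  cells <- cells[order(cells$cell_id), ]
  rownames(cells) <- NULL
  n1 <- sum(cells$presence == 1L, na.rm = TRUE)
  n0 <- sum(cells$presence == 0L, na.rm = TRUE)
  list(grid = fine, coarse_grid = coarse, design = design, cells = cells,
       specs = specs, response = response, n1 = n1, n0 = n0)
}
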