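# scenario application, projection, and shift summary

test_that("scenario deltas follow the 2040 A1B arithmetic exactly", {
  cov <- data.frame(cell_id = 1:3, Ann_Prec = c(1000, 600, 1500),
                    Ann_Temp = c(14.13, 10, 16), Eucalyptus = c(5, 0, 20))
  scn <- scenario_a1b_2040()
  out <- apply_scenario(cov, scn)
  expect_equal(out$Ann_Prec, c(900, 540, 1350))
  expect_equal(out$Ann_Temp, c(15.63, 11.5, 17.5))
  expect_identical(out$Eucalyptus, cov$Eucalyptus)  # frozen, bit-identical

  null_scn <- scenario("null")
  expect_identical(apply_scenario(cov, null_scn), cov)

  # exact invertibility of pure multiplicative/additive rules
  inv <- scenario("inv", climate = list(Ann_Prec = list(multiply = 1 / 0.9),
                                        Ann_Temp = list(add = -1.5)))
  back <- apply_scenario(out, inv)
  expect_equal(back$Ann_Prec, cov$Ann_Prec, tolerance = 1e-12)
  expect_equal(back$Ann_Temp, cov$Ann_Temp, tolerance = 1e-12)

  expect_error(apply_scenario(cov, scenario("bad", climate =
    list(ghost = list(add = 1)))), "unknown variable")
  expect_error(scenario("dup", climate = list(a = list(add = 1)),
                        replace = "a"), "more than one rule")
  expect_error(scenario("frozenrule",
                        climate = list(Eucalyptus = list(add = 1))),
               "frozen")
})

test_that("landcover replacement and regrouping pull from supplied layers", {
  cov <- data.frame(cell_id = 1:4, Shrublands = 1:4, Herbaceous = 4:1,
                    Eucalyptus = rep(2, 4))
  layers <- data.frame(cell_id = 4:1, semi_natural = c(1, 1, 1, 1),
                       abandoned = c(2, 2, 2, 2), Herbaceous = c(9, 9, 9, 9))
  scn <- scenario("lc", replace = "Herbaceous",
                  regroup = list(Shrublands = c("semi_natural", "abandoned")))
  out <- apply_scenario(cov, scn, layers)
  expect_equal(out$Herbaceous, rep(9, 4))
  expect_equal(out$Shrublands, rep(3, 4))
  expect_error(apply_scenario(cov, scn), "no landcover_layers")
})

test_that("null-scenario projection reproduces the baseline map exactly", {
  land <- small_landscape(1)
  fit <- small_fit(1)
  base <- favourability_map(fit, land$cells)
  proj <- project_scenario(fit, land$cells, scenario("null"))
  expect_identical(proj$P, base$P)
  expect_identical(proj$F, base$F)
})

test_that("improving a single positive-effect driver cannot lower mean F", {
  # monotone fixture: presence driven upward by one variable
  g <- sdm_grid(8, 8, 5)
  cov <- simulate_covariates(g, list(
    covariate_spec("x", "H4_climate", 0, -3, 3, 2)), seed = 14)
  set.seed(14)
  dat <- cbind(cov, presence = rbinom(64, 1, plogis(1.5 * cov$x)))
  fit <- rac_brt(presence ~ x, dat, g, control = test_control(n_folds = 5),
                 simplify = FALSE)
  base <- favourability_map(fit, dat)
  up <- scenario("up", climate = list(x = list(add = 10)), frozen = NULL)
  proj <- project_scenario(fit, dat, up)
  expect_gte(mean(proj$F), mean(base$F) - 1e-12)
  expect_false(any(is.na(proj$F)))
})

test_that("shift summaries recompute the worked percentages and chi-square", {
  mk_map <- function(n_fav, n = 10000) {
    f <- c(rep(0.6, n_fav), rep(0.4, n - n_fav))
    structure(data.frame(cell_id = seq_len(n), P = f, F = f),
              class = c("favourability_map", "data.frame"))
  }
  base <- mk_map(2273)
  scns <- list(A1_2040 = mk_map(2471), A2_2040 = mk_map(2517),
               B1_2040 = mk_map(2586), B2_2040 = mk_map(2619))
  sh <- summarize_shift(base, scns)
  expect_equal(sh$pct_favourable_baseline, 22.73)
  expect_equal(unname(sh$pct_favourable_per_scenario),
               c(24.71, 25.17, 25.86, 26.19))
  expect_equal(sh$mean_increase, 2.7525)
  expect_equal(sh$chi2_df, 3L)
  expect_gte(sh$chi2, 0)

  # identical scenario maps: no heterogeneity at all
  same <- summarize_shift(base, list(a = base, b = base, c = base,
                                     d = base))
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)

  # regional summary on a fixture with known high-favourability counts
  region_map <- function(n_high, n = 100) {
    f <- c(rep(0.8, n_high), rep(0.2, n - n_high))
    structure(data.frame(cell_id = seq_len(n), P = f, F = f),
              class = c("favourability_map", "data.frame"))
  }
  base_r <- region_map(35)
  scn_r <- list(s1 = region_map(16), s2 = region_map(15),
                s3 = region_map(17), s4 = region_map(18))
  sh_r <- summarize_shift(base_r, scn_r, region_mask = rep(TRUE, 100))
  expect_equal(unname(sh_r$region$counts_high),
               c(35, 16, 15, 17, 18))
  expect_equal(mean(sh_r$region$counts_high[-1]), 16.5)

  expect_error(summarize_shift(base, list(x = mk_map(10, n = 50))),
               "not aligned")
})

test_that("aggregation to the coarse grid averages subcell values", {
  g <- sdm_grid(2, 2, 10)
  f <- refine_grid(g, 2)
  tab <- data.frame(cell_id = f$cells$cell_id,
                    v = as.numeric(f$cells$row))
  agg <- aggregate_to_coarse(tab, g, f)
  expect_equal(nrow(agg), 4L)
  expect_equal(agg$v[agg$cell_id == g$cells$cell_id[1]], 0.5)
})
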