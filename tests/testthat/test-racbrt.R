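# the rac_brt() fitting pipeline and its methods

test_that("a single-variable hypothesis runs end-to-end with the RAC term", {
  land <- small_landscape(1)
  fit <- rac_brt(presence ~ Herbaceous, land$cells, land$grid,
                 control = test_control(), simplify = FALSE)
  expect_s3_class(fit, "rac_brt")
  expect_setequal(fit$final_model$variables, c("Herbaceous", "RAC"))
  expect_equal(sum(fit$final_model$relative_influence), 100,
               tolerance = 1e-6)
  expect_s3_class(fit$moran_residual, "moran_test")
  expect_output(print(fit), "RAC-BRT")
})

test_that("the final variable set is nested in the VIF-retained set plus RAC", {
  fit <- small_fit(1)
  expect_true("RAC" %in% fit$final_model$variables)
  expect_true(all(setdiff(fit$final_model$variables, "RAC") %in%
                    fit$vif_report$retained))
  expect_length(fit$rac, n_cells(small_landscape(1)$grid))
  expect_true(all(is.finite(fit$rac)))
})

test_that("the pipeline is deterministic end-to-end", {
  land <- small_landscape(1)
  args <- list(presence ~ Herbaceous + Ann_Prec + Roads, land$cells,
               land$grid, control = test_control(seed = 7))
  f1 <- do.call(rac_brt, args)
  f2 <- do.call(rac_brt, args)
  expect_identical(f1$final_model$relative_influence,
                   f2$final_model$relative_influence)
  expect_identical(f1$moran_residual$I, f2$moran_residual$I)
  expect_identical(predict(f1, land$cells), predict(f2, land$cells))
})

test_that("simplification inside the pipeline never drops the RAC term", {
  land <- small_landscape(1)
  fit <- rac_brt(presence ~ Herbaceous + Roads + Pigs + Luvisols,
                 land$cells, land$grid, control = test_control(),
                 simplify = TRUE, tol_auc = Inf, tol_dev = Inf)
  expect_true("RAC" %in% fit$final_model$variables)
})

test_that("spatially unstructured responses leave uncorrelated residuals", {
  passes <- 0
  rac_small <- 0
  n_runs <- 5
  for (s in seq_len(n_runs)) {
    set.seed(100 + s)
    g <- sdm_grid(9, 9, 5)
    cov <- simulate_covariates(g, list(
      covariate_spec("a", "H4_climate", 0, -3, 3, 0),
      covariate_spec("b", "H4_climate", 0, -3, 3, 0)), seed = 100 + s)
    dat <- cbind(cov, presence = rbinom(81, 1, 0.4))
    fit <- rac_brt(presence ~ a + b, dat, g,
                   control = test_control(seed = s, n_folds = 5),
                   simplify = FALSE)
    passes <- passes + (fit$moran_residual$p_value > 0.05)
    rac_small <- rac_small +
      (fit$final_model$relative_influence[["RAC"]] < 50)
  }
  expect_gte(passes, n_runs - 1)
  expect_gte(rac_small, n_runs - 1)
})

test_that("grid prediction honours the RAC policy and matches fit on sampled cells", {
  land <- small_landscape(1)
  fit <- small_fit(1)
  p_mean <- predict(fit, land$cells, rac_policy = "mean")
  p_layer <- predict(fit, land$cells, rac_policy = "layer")
  expect_true(all(p_mean >= 0 & p_mean <= 1))
  si <- fit$sampled_idx
  expect_equal(p_mean[si], p_layer[si])  # sampled cells use their own RAC
  expect_equal(p_mean[si],
               unname(predict(fit$final_model, fit$final_model$x)))

  # when every cell is sampled the policy is irrelevant
  g <- sdm_grid(7, 7, 5)
  cov <- simulate_covariates(g, list(
    covariate_spec("a", "H4_climate", 0, -3, 3, 2)), seed = 3)
  set.seed(3)
  dat <- cbind(cov, presence = rbinom(49, 1, plogis(cov$a)))
  fit_all <- rac_brt(presence ~ a, dat, g,
                     control = test_control(n_folds = 5), simplify = FALSE)
  expect_equal(predict(fit_all, dat, rac_policy = "mean"),
               predict(fit_all, dat, rac_policy = "layer"))
})

test_that("grid predictions recover the latent occupancy ranking", {
  rho <- vapply(1:3, function(s) {
    land <- small_landscape(s)
    fit <- rac_brt(presence ~ Herbaceous + Eucalyptus + `Goat&sheep` +
                     Ann_Prec + Ann_Temp + Podzols,
                   land$cells, land$grid, control = test_control(seed = s),
                   simplify = FALSE)
    p <- predict(fit, land$cells)
    cor(p, land$cells$latent_prob, method = "spearman")
  }, 0)
  expect_gt(mean(rho), 0.5)
})

test_that("stage errors carry their stage tag", {
  land <- small_landscape(1)
  dat <- land$cells
  dat$presence[!is.na(dat$presence)] <- 1L  # single class
  expect_error(rac_brt(presence ~ Herbaceous, dat, land$grid,
                       control = test_control()), "\\[fit\\]")
  expect_error(rac_brt(presence ~ nonexistent, land$cells, land$grid),
               "not in data")
})
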