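# spatial weights, Moran's I (with brute-force and ape oracles), and the RAC

test_that("contiguity and inverse-distance weights match hand geometry", {
  g2 <- sdm_grid(2, 2, 5)
  w_rook <- spatial_weights(g2, "rook", row_standardize = FALSE)
  expect_true(all(lengths(w_rook$nb) == 2L))

  g3 <- sdm_grid(3, 3, 5)
  w_q <- spatial_weights(g3, "queen")
  centre <- which(g3$cells$row == 1 & g3$cells$col == 1)
  expect_length(w_q$nb[[centre]], 8L)
  expect_equal(sum(w_q$w[[centre]]), 1)  # row-standardized

  w_id <- spatial_weights(g2, "inverse_distance", row_standardize = FALSE)
  expect_true(all(lengths(w_id$nb) == 3L))
  i <- 1L  # NW cell; neighbours: E and S at 5 km, SE at 5*sqrt(2)
  d_ord <- order(w_id$w[[i]], decreasing = TRUE)
  expect_equal(w_id$w[[i]][d_ord][3] / w_id$w[[i]][d_ord][1], 1 / sqrt(2))
})

test_that("Moran's I equals hand values and the closed-form expectation", {
  g2 <- sdm_grid(2, 2, 5)
  w <- spatial_weights(g2, "rook", row_standardize = FALSE)
  # checkerboard: cells (0,0),(1,1) = 1 and (0,1),(1,0) = 0
  v <- ifelse((g2$cells$row + g2$cells$col) %% 2 == 0, 1, 0)
  m <- morans_i(v, w)
  expect_equal(m$I, -1)
  expect_equal(m$expected, -1 / 3)

  set.seed(1)
  g5 <- sdm_grid(5, 4, 5)
  m2 <- morans_i(rnorm(20), spatial_weights(g5, "queen"))
  expect_equal(m2$expected, -1 / 19)

  expect_error(morans_i(rep(1, 20), spatial_weights(g5, "queen")),
               "constant")
})

test_that("Moran's I matches the brute-force double sum to 1e-12", {
  set.seed(7)
  for (dims in list(c(3, 3), c(4, 5), c(6, 6))) {
    g <- sdm_grid(dims[1], dims[2], 5)
    for (scheme in c("queen", "rook", "inverse_distance")) {
      for (std in c(TRUE, FALSE)) {
        w <- spatial_weights(g, scheme, row_standardize = std)
        v <- rnorm(n_cells(g))
        expect_equal(morans_i(v, w)$I, moran_bruteforce(v, w),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("Moran's I agrees with ape on statistic, sd and p", {
  skip_if_not_installed("ape")
  set.seed(11)
  g <- sdm_grid(6, 6, 5)
  w <- spatial_weights(g, "queen")
  v <- rnorm(36) + 0.3 * g$cells$row
  m <- morans_i(v, w)
  W <- matrix(0, 36, 36)
  for (i in 1:36) W[i, w$nb[[i]]] <- w$w[[i]]
  a <- ape::Moran.I(v, W)
  expect_equal(m$I, a$observed, tolerance = 1e-10)
  expect_equal(m$expected, a$expected, tolerance = 1e-10)
  expect_equal(m$sd, a$sd, tolerance = 1e-8)
  expect_equal(m$p_value, a$p.value, tolerance = 1e-6)
})

test_that("a smooth gradient is significantly autocorrelated by permutation", {
  g <- sdm_grid(10, 10, 5)
  w <- spatial_weights(g, "queen")
  v <- g$cells$row + 0.5 * g$cells$col
  m <- morans_i(v, w, p_method = "permutation", n_perm = 499, seed = 3)
  expect_gt(m$I, 0)
  expect_lt(m$p_value, 0.05)
})

test_that("permutation and normal-approximation p agree on null data", {
  set.seed(21)
  g <- sdm_grid(10, 10, 5)
  w <- spatial_weights(g, "queen")
  for (s in 1:5) {
    v <- rnorm(100)
    p_norm <- morans_i(v, w)$p_value
    p_perm <- morans_i(v, w, p_method = "permutation", n_perm = 1999,
                       seed = s)$p_value
    expect_lt(abs(p_norm - p_perm), 0.05)
  }
})

test_that("the residuals autocovariate is a neighbourhood mean of residuals", {
  g3 <- sdm_grid(3, 3, 5)
  w <- spatial_weights(g3, "queen")
  all_idx <- seq_len(9)

  rac_const <- residual_autocovariate(rep(4.2, 9), all_idx, w)
  expect_equal(as.numeric(rac_const), rep(4.2, 9))

  res <- rep(0, 9)
  centre <- which(g3$cells$row == 1 & g3$cells$col == 1)
  res[centre] <- 9
  rac <- residual_autocovariate(res, all_idx, w)
  corner <- which(g3$cells$row == 0 & g3$cells$col == 0)
  expect_equal(rac[[corner]], 3)  # neighbours: two zeros + the 9, mean 3
  expect_equal(rac[[centre]], 0)

  # linearity: RAC(a r) = a RAC(r)
  set.seed(2)
  r <- rnorm(9)
  expect_equal(as.numeric(residual_autocovariate(3.5 * r, all_idx, w)),
               3.5 * as.numeric(residual_autocovariate(r, all_idx, w)))
})

test_that("RAC handles partial sampling and preserves the residual mean", {
  g <- sdm_grid(8, 8, 5)
  w <- spatial_weights(g, "queen")
  set.seed(5)
  for (s in 1:10) {
    idx <- sort(sample(64, 20))
    r <- rnorm(20)
    rac <- residual_autocovariate(r, idx, w)
    expect_true(all(is.finite(rac)))
    expect_lt(abs(mean(rac) - mean(r)), 3 * sd(r) / sqrt(20))
  }
  # a cell with no sampled neighbour falls back to the global mean
  rac1 <- residual_autocovariate(c(1, 3), c(1, 2), w)
  far <- 64  # SE corner, far from cells 1 and 2
  expect_equal(rac1[[far]], 2)
  expect_error(residual_autocovariate(numeric(0), integer(0), w), "empty")
})
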