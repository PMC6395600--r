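# Shared fixtures, built in code. Heavy objects are cached for the test run.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, expr, envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# reduced BRT settings used throughout the tests: same procedure, smaller
# ensemble search so the suite stays fast
test_control <- function(seed = 1, ...) {
  brt_control(learning_rate = 0.05, tree_complexity = 2, max_trees = 400,
              min_trees = 100, seed = seed, ...)
}

# a small but non-trivial landscape: 12 x 12 coarse cells, ~120-cell region
small_landscape <- function(seed = 1) {
  cached(sprintf("land_%d", seed), simulate_landscape(
    seed = seed, n_rows = 12, n_cols = 12, region_cells = 120,
    n_surveyed_coarse = 50))
}

# a fitted RAC-BRT on the small landscape with a compact driver formula
small_fit <- function(seed = 1) {
  cached(sprintf("fit_%d", seed), {
    land <- small_landscape(seed)
    rac_brt(presence ~ Herbaceous + Eucalyptus + `Goat&sheep` + Ann_Prec +
              Ann_Temp + Podzols + Roads,
            land$cells, land$grid, control = test_control(seed),
            simplify = FALSE)
  })
}

# deterministic low-dimensional supervised fixture: y driven by x1, x2; x3
# pure noise
toy_xy <- function(n = 160, seed = 1) {
  set.seed(seed)
  x <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  p <- plogis(1.6 * x$x1 - 1.2 * x$x2)
  list(x = x, y = rbinom(n, 1, p))
}

# brute-force Moran's I oracle: explicit double sum over the weight matrix
moran_bruteforce <- function(values, weights) {
  n <- length(values)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) W[i, weights$nb[[i]]] <- weights$w[[i]]
  z <- values - mean(values)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}
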