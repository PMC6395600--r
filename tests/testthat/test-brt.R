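# BRT fitting, tuning, simplification, influence, partial dependence

test_that("a perfectly separating predictor yields AUC 1 and influence 100", {
  set.seed(1)
  y <- rep(c(0L, 1L), each = 20)
  x <- data.frame(flag = y)
  m <- brt(x, y, test_control(n_folds = 5))
  expect_equal(unname(m$relative_influence), 100)
  expect_equal(auc_train <- racbrt:::auc_mw(y, predict(m, x)), 1)
  expect_equal(sum(m$relative_influence), 100, tolerance = 1e-6)
})

test_that("influences always sum to 100 and CV AUC sits in its band", {
  toy <- toy_xy(seed = 2)
  m <- brt(toy$x, toy$y, test_control(seed = 2))
  expect_equal(sum(m$relative_influence), 100, tolerance = 1e-6)
  expect_gte(m$cv_auc, 0.5 - 3 * m$cv_auc_se)
  expect_lte(m$cv_auc, 1)
  expect_gte(m$n_trees, 1)
  # informative predictors dominate the noise column
  expect_gt(m$relative_influence[["x1"]], m$relative_influence[["x3"]])
})

test_that("cv AUC is centred on 0.5 when the response is pure noise", {
  devs <- vapply(1:10, function(s) {
    set.seed(s)
    x <- data.frame(a = rnorm(120), b = rnorm(120))
    y <- rbinom(120, 1, 0.4)
    m <- brt(x, y, test_control(seed = s, n_folds = 5))
    m$cv_auc - 0.5
  }, 0)
  expect_lt(abs(mean(devs)), 0.05)
})

test_that("fits are reproducible given seed, data and control", {
  toy <- toy_xy(seed = 3)
  m1 <- brt(toy$x, toy$y, test_control(seed = 3))
  m2 <- brt(toy$x, toy$y, test_control(seed = 3))
  expect_identical(m1$n_trees, m2$n_trees)
  expect_identical(m1$relative_influence, m2$relative_influence)
  expect_identical(predict(m1, toy$x), predict(m2, toy$x))
})

test_that("degenerate responses and shapes are rejected", {
  x <- data.frame(a = rnorm(30))
  expect_error(brt(x, rep(1L, 30)), "both classes")
  expect_error(brt(x, c(rep(0L, 29), 2L)), "binary")
  expect_error(brt(x[1:5, , drop = FALSE], c(0, 1, 0, 1, 0),
                   test_control(n_folds = 10)), "folds")
})

test_that("internal AUC matches pROC", {
  skip_if_not_installed("pROC")
  set.seed(6)
  y <- rbinom(80, 1, 0.4)
  p <- plogis(rnorm(80) + y)
  expect_equal(racbrt:::auc_mw(y, p),
               as.numeric(pROC::auc(y, p, quiet = TRUE, direction = "<",
                                    levels = c(0, 1))),
               tolerance = 1e-12)
})

test_that("the lr/tc rule picks the largest lr reaching the tree minimum", {
  toy <- toy_xy(n = 200, seed = 4)
  ctl <- test_control(seed = 4)

  # shrinkage property: smaller lr needs more trees
  m_fast <- brt(toy$x, toy$y, brt_control(learning_rate = 0.3,
                                          tree_complexity = 2,
                                          max_trees = 400, seed = 4))
  m_slow <- brt(toy$x, toy$y, brt_control(learning_rate = 0.01,
                                          tree_complexity = 2,
                                          max_trees = 400, seed = 4))
  expect_gt(m_slow$n_trees, m_fast$n_trees)

  # with min_trees = 1 any fit qualifies: largest lr, smallest tc wins
  ctl1 <- brt_control(max_trees = 50, min_trees = 1, seed = 4)
  tuned <- tune_brt(toy$x, toy$y, lr_grid = c(0.3, 0.1), tc_grid = c(1, 2),
                    control = ctl1)
  expect_equal(tuned$learning_rate, 0.3)
  expect_equal(tuned$tree_complexity, 1L)

  # a real minimum forces lr below the fast-converging value
  ctl2 <- brt_control(max_trees = 400, min_trees = m_fast$n_trees + 20,
                      seed = 4)
  tuned2 <- tune_brt(toy$x, toy$y, lr_grid = c(0.3, 0.01), tc_grid = 2,
                     control = ctl2)
  expect_equal(tuned2$learning_rate, 0.01)
  expect_gte(attr(tuned2, "fit")$n_trees, ctl2$min_trees)

  expect_error(tune_brt(toy$x, toy$y, lr_grid = numeric(0), tc_grid = 2),
               "empty")
  expect_warning(
    tune_brt(toy$x, toy$y, lr_grid = 0.5, tc_grid = 1,
             control = brt_control(max_trees = 5, min_trees = 1000,
                                   seed = 4)),
    "min_trees")
})

test_that("simplification drops noise but keeps informative predictors", {
  toy <- toy_xy(n = 200, seed = 5)
  m <- brt(toy$x, toy$y, test_control(seed = 5))

  s1 <- simplify_brt(m, tol_auc = 0.005, tol_dev = 0.5)
  expect_false("x3" %in% s1$variables)
  expect_true(all(c("x1", "x2") %in% s1$variables) ||
                length(s1$variables) >= 1L)
  expect_s3_class(attr(s1, "drop_log"), "data.frame")

  # infinite tolerances accept every drop down to a single variable
  s2 <- simplify_brt(m, tol_auc = Inf, tol_dev = Inf)
  expect_length(s2$variables, 1L)

  # zero tolerance on an all-informative model removes nothing
  x_inf <- toy$x[c("x1", "x2")]
  m_inf <- brt(x_inf, toy$y, test_control(seed = 5))
  s3 <- simplify_brt(m_inf, tol_auc = 0, tol_dev = 0)
  expect_equal(sort(s3$variables), c("x1", "x2"))

  # protected variables are never candidates
  s4 <- simplify_brt(m, tol_auc = Inf, tol_dev = Inf, protect = "x1")
  expect_true("x1" %in% s4$variables)
})

test_that("partial dependence reflects the fitted shape", {
  toy <- toy_xy(n = 250, seed = 6)
  m <- brt(toy$x, toy$y, test_control(seed = 6))
  pd1 <- partial_dependence(m, "x1")
  # monotone increasing effect, up to tree-step tolerance
  expect_gt(cor(pd1$value, pd1$yhat, method = "spearman"), 0.9)
  expect_gt(pd1$yhat[nrow(pd1)], pd1$yhat[1])

  # a variable the trees never split on gives a flat curve
  set.seed(6)
  x <- data.frame(sig = rnorm(150), dead = rep(1e-9, 150) * rnorm(150))
  y <- as.integer(x$sig + rnorm(150, sd = 0.3) > 0)
  m2 <- brt(x, y, test_control(seed = 6, n_folds = 5))
  if (m2$relative_influence[["dead"]] == 0) {
    pd2 <- partial_dependence(m2, "dead")
    expect_equal(diff(range(pd2$yhat)), 0)
  }
  expect_error(partial_dependence(m, "ghost"), "unknown variable")

  # probability-scale curves stay in [0, 1]
  pd3 <- partial_dependence(m, "x1", scale = "response")
  expect_true(all(pd3$yhat >= 0 & pd3$yhat <= 1))
})
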