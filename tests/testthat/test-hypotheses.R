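# hybrid-variable selection and hypothesis ranking

test_that("the cumulative-50% rule reproduces published selections", {
  ref <- badger_reference_summary()
  expect_equal(select_hybrid_variables(ref$influence["H1"]),
               c("Herbaceous", "Eucalyptus", "Shrublands"))
  expect_equal(select_hybrid_variables(ref$influence["H2"]),
               c("Goat&sheep", "Cattle"))
  expect_equal(select_hybrid_variables(ref$influence["H4"]),
               c("Ann_Temp", "Ann_Prec"))
  # H3 is the documented exception: the rule keeps a third variable
  expect_equal(select_hybrid_variables(ref$influence["H3"]),
               c("Podzols", "Eruptive", "Alt_mean"))
})

test_that("selection drops RAC, unions across hypotheses, respects rules", {
  infl <- list(h = c(RAC = 60, a = 25, b = 10, c = 5))
  expect_equal(select_hybrid_variables(infl), "a")  # 25 >= half of 40
  expect_equal(select_hybrid_variables(list(h = c(only = 100))), "only")
  expect_equal(select_hybrid_variables(infl, rule = "top_k", k = 1), "a")
  expect_equal(select_hybrid_variables(infl, rule = "top_half"),
               c("a", "b"))
  two <- list(h1 = c(a = 60, b = 40), h2 = c(b = 70, c = 30))
  expect_equal(select_hybrid_variables(two), c("a", "b"))
  expect_error(select_hybrid_variables(list(h = numeric(0))), "empty")
})

test_that("selection is invariant to uniform rescaling of influences", {
  set.seed(12)
  for (i in 1:20) {
    v <- sort(runif(6), decreasing = TRUE)
    names(v) <- letters[1:6]
    base <- select_hybrid_variables(list(h = v))
    expect_equal(select_hybrid_variables(list(h = v * 1000)), base)
    expect_equal(select_hybrid_variables(list(h = v / 37)), base)
  }
})

test_that("hypotheses are ranked by AUC with stable tie-breaking", {
  ref <- badger_reference_summary()
  cmp <- compare_hypotheses(ref$auc, se = ref$auc_se,
                            deviance = ref$deviance)
  expect_equal(cmp$hypothesis, c("H5", "H1", "H3", "H2", "H4"))
  expect_equal(attr(cmp, "best"), "H5")
  expect_true(cmp$best[1])

  tied <- compare_hypotheses(c(B = 0.8, A = 0.8, C = 0.7))
  expect_equal(tied$hypothesis, c("A", "B", "C"))  # name order on ties
  expect_true(tied$tied_with_next[1])

  one <- compare_hypotheses(c(H1 = 0.9))
  expect_equal(attr(one, "best"), "H1")
})

test_that("the registry mirrors the published variable grouping", {
  reg <- hypothesis_registry()
  expect_length(reg$H1, 11L)
  expect_length(reg$H2, 9L)
  expect_length(reg$H3, 9L)
  expect_length(reg$H4, 4L)
  specs <- default_covariate_specs()
  expect_true(all(unlist(reg) %in% names(specs)))
})

test_that("the five-hypothesis competition runs end-to-end on a small grid", {
  land <- small_landscape(1)
  hyp <- list(H1 = c("Herbaceous", "Eucalyptus", "Shrublands"),
              H4 = c("Ann_Prec", "Ann_Temp"))
  hs <- fit_hypotheses(land$cells, land$grid, hypotheses = hyp,
                       control = test_control(), simplify = FALSE)
  expect_named(hs$results, c("H1", "H4", "H5"))
  expect_true(all(hs$hybrid_variables %in% unlist(hyp)))
  expect_s3_class(hs$comparison, "hypothesis_comparison")
  expect_true(attr(hs$comparison, "best") %in% names(hs$results))
  # H5 variables are a product of selection, not hand-set
  expect_setequal(setdiff(hs$results$H5$final_model$variables, "RAC"),
                  hs$hybrid_variables)
})
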