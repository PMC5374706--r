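test_that("discriminant is the aligned dot product minus the threshold", {
  m <- classifier_model(c("a", "b", "c"), c(2, -1, 0.5), 0.25)
  expect_equal(discriminant(m, c(a = 1, b = 1, c = 2)), 2 - 1 + 1 - 0.25)
  expect_equal(discriminant(classifier_model("f", 1, 0), 0.5), 0.5)
  # column order in the input must not matter
  X <- matrix(c(1, 2, 3), 1, dimnames = list(NULL, c("c", "a", "b")))
  expect_equal(discriminant(m, X), 2 * 2 - 3 + 0.5 - 0.25)
  expect_error(discriminant(m, c(a = 1, b = 2)), "lacks model feature.*c")
  set.seed(13)
  w <- rnorm(9)
  mdl <- classifier_model(letters[1:9], w, 0.7)
  V <- matrix(rnorm(27), 3, dimnames = list(NULL, letters[1:9]))
  expect_equal(discriminant(mdl, V), drop(V %*% w) - 0.7, tolerance = 1e-12)
})

test_that("prediction thresholds at zero and maps the boundary to negative", {
  m <- classifier_model(c("a", "b"), c(1, 1), 0)
  X <- rbind(c(a = 2, b = 0.3), c(a = -0.05, b = -0.05), c(a = 1, b = -1))
  expect_warning(pred <- predict(m, X), "boundary")
  expect_equal(as.numeric(pred), c(1, -1, -1))
  expect_equal(attr(pred, "discriminant"), c(2.3, -0.1, 0))
})

test_that("contingency tabulation counts each cell and checks inputs", {
  # the independent-cohort configuration with the ambiguous sample positive
  actual <- c(rep(1, 9), rep(-1, 19))
  predicted <- c(rep(1, 8), -1, rep(1, 4), rep(-1, 15))
  tab <- tabulate_predictions(predicted, actual)
  expect_identical(unlist(tab[c("tp", "fn", "fp", "tn")]),
                   c(tp = 8L, fn = 1L, fp = 4L, tn = 15L))
  tab2 <- tabulate_predictions(c(1, 1, -1, -1), c(1, 1, -1, -1))
  expect_identical(unlist(tab2[c("tp", "fn", "fp", "tn")]),
                   c(tp = 2L, fn = 0L, fp = 0L, tn = 2L))
  set.seed(17)
  for (i in 1:5) {
    pr <- sample(c(-1, 1), 30, replace = TRUE)
    ac <- sample(c(-1, 1), 30, replace = TRUE)
    tb <- tabulate_predictions(pr, ac)
    expect_identical(tb$tp, sum(pr == 1 & ac == 1))
    expect_identical(tb$tn, sum(pr == -1 & ac == -1))
    expect_identical(tb$tp + tb$fn + tb$fp + tb$tn, 30L)
  }
  expect_error(tabulate_predictions(c(1, -1), c(1)), "length")
  expect_error(contingency_2x2(-1, 0, 0, 1), "nonnegative")
})

test_that("metrics follow their defining ratios, NA on empty denominators", {
  met <- classification_metrics(contingency_2x2(1, 0, 0, 1))
  expect_equal(unlist(met), c(accuracy = 1, sensitivity = 1,
                              specificity = 1, predicted_negative_error = 0))
  met2 <- classification_metrics(contingency_2x2(7, 2, 4, 15))
  expect_equal(met2$accuracy, 22 / 28)
  expect_equal(met2$sensitivity, 7 / 9)
  met3 <- classification_metrics(contingency_2x2(0, 0, 3, 5))
  expect_true(is.na(met3$sensitivity))
  expect_equal(met3$specificity, 5 / 8)
})

test_that("metrics are scale-invariant but the exact tests are not", {
  t1 <- contingency_2x2(8, 1, 4, 15)
  t3 <- contingency_2x2(24, 3, 12, 45)
  expect_equal(classification_metrics(t1), classification_metrics(t3))
  expect_lt(fisher_exact_two_sided(t3), fisher_exact_two_sided(t1))
  expect_lt(barnard_exact(t3), barnard_exact(t1))
})

test_that("Fisher enumeration agrees with stats::fisher.test everywhere", {
  expect_equal(fisher_exact_two_sided(contingency_2x2(1, 1, 1, 1)), 1)
  set.seed(19)
  for (i in 1:25) {
    cts <- as.integer(rmultinom(1, sample(6:40, 1), prob = runif(4, 0.05, 1)))
    if (sum(cts) == 0) next
    tab <- contingency_2x2(cts[1], cts[2], cts[3], cts[4])
    ref <- fisher.test(matrix(cts, 2, byrow = TRUE))$p.value
    expect_equal(fisher_exact_two_sided(tab), min(ref, 1), tolerance = 1e-10)
  }
  # degenerate margins
  expect_equal(fisher_exact_two_sided(contingency_2x2(0, 0, 3, 4)), 1)
  expect_equal(fisher_exact_two_sided(contingency_2x2(2, 0, 3, 0)), 1)
})

test_that("Barnard test is a valid, powerful unconditional test", {
  # identical row proportions carry no evidence
  expect_equal(barnard_exact(contingency_2x2(2, 2, 2, 2)), 1,
               tolerance = 1e-6)
  set.seed(23)
  for (i in 1:10) {
    cts <- as.integer(rmultinom(1, sample(8:30, 1), prob = runif(4, 0.05, 1)))
    tab <- contingency_2x2(cts[1], cts[2], cts[3], cts[4])
    p1 <- barnard_exact(tab)
    p2 <- barnard_exact(tab, alternative = "two.sided")
    expect_gt(p1, 0); expect_lte(p1, 1)
    expect_gte(p2 + 1e-12, p1)       # two-sided tail is a superset
  }
  # more powerful than Fisher on the published cohort tables
  for (tb in list(contingency_2x2(8, 1, 4, 15), contingency_2x2(7, 2, 4, 15)))
    expect_lt(barnard_exact(tb), fisher_exact_two_sided(tb))
  expect_equal(barnard_exact(contingency_2x2(0, 0, 2, 3)), 1)
})

test_that("evaluate_classifier ties the pieces together", {
  spec <- synthetic_spec(m1 = 10, m2 = 10, n = 8, k_true = 2, effect = 2.5,
                         rho = 0, block_size = 4, seed = 8)
  sim <- simulate_cohort(spec)
  nf <- normalize_features(sim$dataset)
  sol <- solve_combined_norm_svm(nf$dataset$X, nf$dataset$y,
                                 lonestar_params())
  model <- classifier_model(sim$dataset$features, sol$w, sol$theta,
                            normalization = nf$stats)
  ev <- evaluate_classifier(model, sim$dataset)
  expect_identical(ev$table$tp + ev$table$fn, 10L)
  expect_equal(ev$accuracy,
               (ev$table$tp + ev$table$tn) / 20)
  expect_length(ev$discriminant, 20)
  expect_lt(ev$fisher_p, 0.05)
})
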