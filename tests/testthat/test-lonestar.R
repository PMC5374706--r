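test_that("split plans are balanced partitions, deterministic in the seed", {
  plan <- make_split_plan(43, 43, 80, seed = 7)
  expect_length(plan, 80)
  expect_identical(attr(plan, "k1"), 21)
  expect_identical(attr(plan, "k2"), 21)
  for (sp in plan) {
    expect_length(sp$train_pos, 21)
    expect_length(sp$train_neg, 21)
    expect_identical(sort(c(sp$train_pos, sp$val_pos)), 1:43)
    expect_identical(sort(c(sp$train_neg, sp$val_neg)), 1:43)
    expect_length(intersect(sp$train_pos, sp$val_pos), 0)
  }
  expect_identical(make_split_plan(43, 43, 80, seed = 7), plan)
  expect_false(identical(make_split_plan(43, 43, 80, seed = 8), plan))
  # extending l preserves the earlier splits
  longer <- make_split_plan(43, 43, 120, seed = 7)
  expect_identical(longer[1:80], plan[1:80])
  expect_error(make_split_plan(3, 43, 10, seed = 1), "too small")
})

test_that("rfe_step signals termination when no feature can be dropped", {
  sol <- function(w) structure(list(w = w), class = "svm_solution")
  feats <- c("a", "b", "c")
  # nonzero counts {3, 2} -> ceil(2.5) = 3 = s -> stop, set unchanged
  st <- rfe_step(list(sol(c(1, 2, 3)), sol(c(0, 1, 2))), feats)
  expect_true(st$terminated)
  expect_identical(st$retained, feats)
  expect_error(rfe_step(list(), feats), "empty")
  expect_error(rfe_step(list(sol(c(0, 0, 0))), feats), "vanished")
})

test_that("rfe_step arithmetic matches the worked fixtures", {
  sol <- function(w) structure(list(w = w), class = "svm_solution")
  feats <- c("a", "b", "c", "d")
  # nonzero counts {3, 4} -> r = ceil(3.5) = 4 = s -> stop
  st <- rfe_step(list(sol(c(1, 2, 3, 0)), sol(c(1, 1, 1, 1))), feats)
  expect_identical(st$r, 4L)
  expect_true(st$terminated)
  # averaging (0,2,0) and (0,1,1) gives (0,1.5,0.5); r = 1 keeps "b"
  st2 <- rfe_step(list(sol(c(0, 2, 0)), sol(c(0, 1, 1))), c("a", "b", "c"))
  expect_equal(unname(st2$avg_w), c(0, 1.5, 0.5))
  expect_identical(st2$r, 2L)
  expect_identical(st2$retained, c("b", "c"))
})

test_that("the full pipeline shrinks the panel, stays sparse and reproduces", {
  spec <- synthetic_spec(m1 = 12, m2 = 12, n = 40, k_true = 4, effect = 1.6,
                         rho = 0.3, block_size = 8, seed = 2)
  sim <- simulate_cohort(spec)
  params <- lonestar_params(splits = 12, top = 4, seed = 9)
  fit <- run_lonestar(sim$dataset, params)
  it <- fit$trace$iterations
  expect_true(all(diff(it$s) < 0))               # strict decrease
  expect_identical(it$r[nrow(it)], it$s[nrow(it)])
  expect_lt(length(fit$model$features), nrow(sim$dataset$X))
  expect_true(all(fit$model$features %in% sim$dataset$features))

  # identical seed: identical model, bit for bit
  fit2 <- run_lonestar(sim$dataset, params)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_model(fit$model, f1); write_model(fit2$model, f2)
  expect_identical(readLines(f1), readLines(f2))

  # the model reproduces the training accuracy recorded in its trace
  ev <- evaluate_classifier(fit$model, sim$dataset)
  expect_equal(ev$accuracy, fit$trace$training_accuracy)
})

test_that("finalize_classifier averages the best-ranked split classifiers", {
  spec <- synthetic_spec(m1 = 10, m2 = 10, n = 12, k_true = 3, effect = 1.8,
                         rho = 0, block_size = 4, seed = 5)
  sim <- simulate_cohort(spec)
  nf <- normalize_features(sim$dataset)
  feats <- sim$dataset$features[1:5]
  params <- lonestar_params(splits = 6, top = 1, seed = 4)
  model <- finalize_classifier(nf$dataset, feats, params,
                               normalization = nf$stats)
  sel <- attr(model, "selection")
  expect_identical(nrow(sel), 6L)
  expect_identical(sum(sel$selected), 1L)
  # with top = 1 the model must equal the single best split classifier
  # (up to dropping exactly-zero weights, which carry no information)
  best <- which(sel$selected)
  rounds <- lonestar:::fit_round(nf$dataset, feats, params, stage = 101L)
  bw <- rounds[[best]]$solution$w
  expect_equal(model$weights, unname(bw[model$features]))
  expect_true(all(bw[setdiff(feats, model$features)] == 0))
  expect_equal(model$threshold, rounds[[best]]$solution$theta)
  # ranking is by weighted error, ties by sensitivity then index
  expect_identical(best,
                   order(sel$weighted_error, -sel$sensitivity, sel$split)[1])
  expect_error(finalize_classifier(nf$dataset, feats,
                                   lonestar_params(splits = 4, top = 10)),
               "top")
  expect_error(finalize_classifier(nf$dataset, character(), params),
               "non-empty")
})

test_that("averaging over more best classifiers keeps validation quality", {
  spec <- synthetic_spec(m1 = 14, m2 = 14, n = 30, k_true = 4, effect = 1.6,
                         rho = 0.3, block_size = 6, seed = 12)
  sim <- simulate_cohort(spec)
  nf <- normalize_features(sim$dataset)
  feats <- sim$truth$features
  params <- lonestar_params(splits = 16, top = 4, seed = 3)
  model <- finalize_classifier(nf$dataset, feats, params,
                               normalization = nf$stats)
  hold <- simulate_cohort(spec, seed = 999, m1 = 100, m2 = 100)
  ev <- evaluate_classifier(model, hold$dataset)
  expect_gt(ev$accuracy, 0.75)
})
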