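#' Plan random balanced training/validation splits
#'
#' Draws `l` independent random subsamples: `k1` of the `m1` positive and
#' `k2` of the `m2` negative samples train, the complement validates.
#' Defaults take `k1 = k2 = floor(min(m1, m2) / 2)`, i.e. both roughly
#' equal to half the smaller class. Each split draws from its own derived
#' seed, so plans are deterministic and extending `l` never reshuffles
#' earlier splits.
#'
#' @param m1,m2 Positive / negative class sizes (each >= 4 by default
#'   requirements downstream).
#' @param l Number of splits.
#' @param seed Integer seed.
#' @param k1,k2 Optional training subsample sizes per class.
#' @return Object of class `split_plan`: list of `l` elements, each with
#'   integer vectors `train_pos`, `train_neg` (indices within the positive
#'   / negative class, 1..m1 and 1..m2) and `val_pos`, `val_neg`
#'   (complements).
#' @export
make_split_plan <- function(m1, m2, l, seed, k1 = NULL, k2 = NULL) {
  if (l < 1) stop("l must be a positive integer")
  kdef <- floor(min(m1, m2) / 2)
  if (is.null(k1)) k1 <- kdef
  if (is.null(k2)) k2 <- kdef
  if (k1 < 2 || k2 < 2)
    stop("classes too small: need k1, k2 >= 2 (m1 = ", m1, ", m2 = ", m2, ")")
  if (k1 > m1 || k2 > m2) stop("k1/k2 cannot exceed the class sizes")
  splits <- lapply(seq_len(l), function(j) {
    with_seed(derive_seed(seed, 0L, j), {
      tp <- sort(sample.int(m1, k1))
      tn <- sort(sample.int(m2, k2))
      list(train_pos = tp, train_neg = tn,
           val_pos = setdiff(seq_len(m1), tp),
           val_neg = setdiff(seq_len(m2), tn))
    })
  })
  structure(splits, class = "split_plan",
            m1 = m1, m2 = m2, k1 = k1, k2 = k2, seed = seed)
}

#' One recursive-feature-elimination step
#'
#' Aggregates the `l` per-split solutions of one stability-selection
#' round: `r` is the mean nonzero-weight count rounded upward, the weight
#' vectors are averaged arithmetically, and the `r` features with the
#' largest average absolute weight are retained (dataset column order is
#' preserved within the retained set; ties resolve to the earlier
#' column). `r` equal to the current feature count signals termination.
#'
#' @param solutions List of [solve_combined_norm_svm()] results sharing
#'   one feature list.
#' @param features Character vector of the current features.
#' @param nonzero_tol Tolerance for [count_nonzero()].
#' @return List with `retained` (features), `r`, `avg_w` (named average
#'   weight vector over `features`), `terminated` (logical).
#' @export
rfe_step <- function(solutions, features, nonzero_tol = 1e-6) {
  if (length(solutions) == 0) stop("empty solution list")
  s <- length(features)
  W <- vapply(solutions, function(z) {
    if (length(z$w) != s) stop("solutions do not share the feature list")
    as.numeric(z$w)
  }, numeric(s))
  W <- matrix(W, nrow = s)
  counts <- vapply(solutions, function(z) count_nonzero(z$w, nonzero_tol), 0L)
  r <- as.integer(ceiling(mean(counts)))
  if (r == 0)
    stop("all weight vectors vanished; cannot retain 0 features")
  avg_w <- rowMeans(W)
  names(avg_w) <- features
  if (r >= s)
    return(list(retained = features, r = s, avg_w = avg_w, terminated = TRUE))
  ord <- order(-abs(avg_w), seq_len(s))
  keep <- sort(ord[seq_len(r)])
  list(retained = features[keep], r = r, avg_w = avg_w, terminated = FALSE)
}

# Fit one stability round: l solves restricted to `features`, plus
# per-split validation of the resulting classifiers.
fit_round <- function(ds, features, params, stage) {
  pos <- which(ds$y == 1); neg <- which(ds$y == -1)
  plan <- make_split_plan(length(pos), length(neg), params$splits,
                          derive_seed(params$seed, stage))
  Xf <- ds$X[, features, drop = FALSE]
  lapply(seq_along(plan), function(j) {
    sp <- plan[[j]]
    tr <- c(pos[sp$train_pos], neg[sp$train_neg])
    sol <- solve_combined_norm_svm(Xf[tr, , drop = FALSE], ds$y[tr], params)
    vp <- pos[sp$val_pos]; vn <- neg[sp$val_neg]
    fv <- drop(Xf[c(vp, vn), , drop = FALSE] %*% sol$w) - sol$theta
    pred <- ifelse(fv > 0, 1, -1)
    yv <- c(rep(1, length(vp)), rep(-1, length(vn)))
    fn_ <- sum(pred == -1 & yv == 1)
    fp_ <- sum(pred == 1 & yv == -1)
    list(solution = sol,
         val_weighted_error = params$alpha * fn_ + (1 - params$alpha) * fp_,
         val_accuracy = mean(pred == yv),
         val_sensitivity = 1 - fn_ / length(vp))
  })
}

#' Final classifier generation by best-classifier averaging
#'
#' With the feature panel fixed, fits `l` classifiers on fresh random
#' balanced splits, scores each on its held-out samples, ranks them by
#' alpha-weighted validation error (at `alpha = 0.5` this is the accuracy
#' ranking; ties break toward higher sensitivity, then lower split index),
#' and averages the weights and thresholds of the best `q = top`.
#' Features whose averaged weight is exactly zero are dropped from the
#' returned panel: they contribute nothing to the discriminant.
#'
#' @param dataset Normalized [labeled_dataset()] containing `features`.
#' @param features Non-empty character vector: the final panel.
#' @param params A [lonestar_params()] (`top <= splits`).
#' @param normalization Optional stats from [normalize_features()], frozen
#'   into the returned model.
#' @param stage Internal stage index for seed derivation.
#' @return A [classifier_model()]; attribute `"selection"` holds the
#'   per-split validation ranking.
#' @export
finalize_classifier <- function(dataset, features, params,
                                normalization = NULL, stage = 101L) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (length(features) == 0) stop("final feature set must be non-empty")
  if (!all(features %in% dataset$features))
    stop("features absent from dataset: ",
         paste(setdiff(features, dataset$features), collapse = ", "))
  rounds <- fit_round(dataset, features, params, stage)
  werr <- vapply(rounds, `[[`, 0, "val_weighted_error")
  sens <- vapply(rounds, `[[`, 0, "val_sensitivity")
  ord <- order(werr, -sens, seq_along(rounds))
  top <- ord[seq_len(params$top)]
  W <- vapply(rounds[top], function(z) as.numeric(z$solution$w),
              numeric(length(features)))
  W <- matrix(W, nrow = length(features))
  thetas <- vapply(rounds[top], function(z) z$solution$theta, 0)
  avg_w <- rowMeans(W)
  # a feature whose averaged weight is exactly zero contributes nothing to
  # the discriminant; it is not part of the panel
  live <- avg_w != 0
  if (any(live) && !all(live)) {
    features <- features[live]
    avg_w <- avg_w[live]
  }
  norm_sub <- NULL
  if (!is.null(normalization)) {
    idx <- match(features, normalization$features)
    norm_sub <- list(features = features,
                     mean = normalization$mean[idx],
                     scale = normalization$scale[idx])
  }
  model <- classifier_model(features = features, weights = avg_w,
                            threshold = mean(thetas),
                            normalization = norm_sub,
                            params = list(lambda = params$lambda,
                                          alpha = params$alpha,
                                          gamma = params$gamma,
                                          splits = params$splits,
                                          top = params$top),
                            seed = params$seed)
  attr(model, "selection") <-
    data.frame(split = seq_along(rounds),
               weighted_error = werr,
               accuracy = vapply(rounds, `[[`, 0, "val_accuracy"),
               sensitivity = sens,
               selected = seq_along(rounds) %in% top)
  model
}

#' Fit the full sparse-panel selection pipeline
#'
#' The complete procedure: per-feature normalization (optional t-test
#' prefilter first), then repeated rounds of stability selection --- `l`
#' random balanced subsamples, one combined-norm SVM solve each --- and
#' recursive feature elimination until the retained count `r` stops
#' shrinking, and finally best-classifier averaging over a fresh round of
#' splits on the surviving panel. Fully reproducible from
#' `params$seed`.
#'
#' @param dataset A [labeled_dataset()] with >= 4 samples per class. Raw
#'   log2 expression unless `normalize = FALSE` (then columns must already
#'   be centered with unit norm).
#' @param params A [lonestar_params()].
#' @param normalize Apply [normalize_features()] first (default `TRUE`).
#' @param ttest_alpha `NULL` (default: no prefilter) or a p-value cutoff
#'   for [ttest_filter()], applied before normalization.
#' @param max_rfe_iter Hard cap on elimination rounds.
#' @param verbose Print one line per round.
#' @return Object of class `lonestar_fit`: list with `model` (a
#'   [classifier_model()]) and `trace` (per-round feature counts `s`,
#'   retained counts `r`, mean validation error, retained feature sets,
#'   final-round ranking, training accuracy).
#' @export
run_lonestar <- function(dataset, params = lonestar_params(),
                         normalize = TRUE, ttest_alpha = NULL,
                         max_rfe_iter = 100L, verbose = FALSE) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  cs <- class_sizes(dataset)
  if (cs["m1"] < 4 || cs["m2"] < 4)
    stop("need at least 4 samples in each class")
  if (!is.null(ttest_alpha))
    dataset <- ttest_filter(dataset, ttest_alpha)
  stats <- NULL
  if (normalize) {
    nf <- normalize_features(dataset)
    dataset <- nf$dataset
    stats <- nf$stats
  }
  features <- dataset$features
  iters <- list()
  feats_per_iter <- list()
  terminated <- FALSE
  for (i in seq_len(max_rfe_iter)) {
    rounds <- fit_round(dataset, features, params, stage = i)
    step <- rfe_step(lapply(rounds, `[[`, "solution"), features,
                     params$nonzero_tol)
    iters[[i]] <- data.frame(
      iter = i, s = length(features), r = step$r,
      mean_val_error = mean(vapply(rounds, `[[`, 0, "val_weighted_error")),
      mean_val_accuracy = mean(vapply(rounds, `[[`, 0, "val_accuracy")))
    feats_per_iter[[i]] <- features
    if (verbose)
      message(sprintf("round %d: s = %d, r = %d, mean validation accuracy %.3f",
                      i, length(features), step$r,
                      iters[[i]]$mean_val_accuracy))
    if (step$terminated) { terminated <- TRUE; break }
    features <- step$retained
  }
  if (!terminated)
    stop("recursive elimination did not terminate within ", max_rfe_iter,
         " rounds")
  m <- nrow(dataset$X)
  if (length(features) >= m)
    stop("sparsity contract violated: |F| = ", length(features),
         " is not smaller than m = ", m)
  model <- finalize_classifier(dataset, features, params,
                               normalization = stats,
                               stage = length(iters) + 1L)
  f_train <- drop(dataset$X[, model$features, drop = FALSE] %*%
                    model$weights) - model$threshold
  train_acc <- mean(ifelse(f_train > 0, 1, -1) == dataset$y)
  trace <- list(iterations = do.call(rbind, iters),
                features_per_iter = feats_per_iter,
                final_features = model$features,
                selection = attr(model, "selection"),
                training_accuracy = train_acc)
  structure(list(model = model, trace = trace), class = "lonestar_fit")
}

#' @export
print.lonestar_fit <- function(x, ...) {
  it <- x$trace$iterations
  cat(sprintf("lonestar_fit: %d -> %d features over %d elimination rounds\n",
              it$s[1], length(x$model$features), nrow(it)))
  cat(sprintf("training accuracy %.4f; mean validation accuracy (final round) %.4f\n",
              x$trace$training_accuracy, it$mean_val_accuracy[nrow(it)]))
  invisible(x)
}
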