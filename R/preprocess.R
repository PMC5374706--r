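#' Per-feature normalization to zero mean and unit Euclidean norm
#'
#' Centers every feature column on its mean over all `m` samples and scales
#' it so the centered column has Euclidean norm one. This equals the column
#' Z-scores (population standard deviation) divided by `sqrt(m)`. The
#' per-feature mean and scale are returned so the identical transform can
#' be replayed on an independent cohort with [apply_normalization()].
#'
#' @param dataset A [labeled_dataset()] with at least 2 samples.
#' @param drop_degenerate Drop (with a warning) features whose centered
#'   norm is below tolerance instead of raising an error.
#' @param tol Relative tolerance declaring a feature degenerate.
#' @return List with elements `dataset` (normalized copy) and `stats`
#'   (list `features`, `mean`, `scale`).
#' @export
normalize_features <- function(dataset, drop_degenerate = FALSE, tol = 1e-12) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  X <- dataset$X
  if (nrow(X) < 2) stop("normalization requires at least 2 samples")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sc <- sqrt(colSums(Xc^2))
  degen <- sc <= tol * pmax(1, sqrt(colSums(X^2)))
  if (any(degen)) {
    ids <- dataset$features[degen]
    if (!drop_degenerate)
      stop("degenerate (constant) features: ", paste(ids, collapse = ", "))
    warning("dropping ", length(ids), " degenerate feature(s): ",
            paste(ids, collapse = ", "))
    keep <- !degen
    Xc <- Xc[, keep, drop = FALSE]
    sc <- sc[keep]
    mu <- mu[keep]
    dataset <- labeled_dataset(dataset$X[, keep, drop = FALSE], dataset$y,
                               dataset$samples, dataset$features[keep],
                               require_both_classes = FALSE)
  }
  Xn <- sweep(Xc, 2, sc, "/")
  out <- labeled_dataset(Xn, dataset$y, dataset$samples, dataset$features,
                         require_both_classes = FALSE)
  list(dataset = out,
       stats = list(features = dataset$features,
                    mean = unname(mu), scale = unname(sc)))
}

#' Apply stored normalization statistics to a raw matrix
#'
#' Transforms each column as `(x - mean) / scale` using statistics frozen
#' at training time; nothing is refitted. This is how a classifier trained
#' on one cohort is applied to another (including a single new sample).
#'
#' @param X Numeric matrix (samples in rows) or vector; columns are matched
#'   to `stats$features` by name when available, otherwise by position.
#' @param stats The `stats` element returned by [normalize_features()],
#'   optionally restricted to a feature subset.
#' @param features Optional subset of features to return, in that order.
#' @return The transformed matrix with columns `features` (or all of
#'   `stats$features`).
#' @export
apply_normalization <- function(X, stats, features = NULL) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1, dimnames = list(NULL, names(X)))
  X <- as.matrix(X)
  want <- if (is.null(features)) stats$features else as.character(features)
  idx_stats <- match(want, stats$features)
  if (anyNA(idx_stats))
    stop("no stored normalization for feature(s): ",
         paste(want[is.na(idx_stats)], collapse = ", "))
  if (!is.null(colnames(X))) {
    idx <- match(want, colnames(X))
    if (anyNA(idx))
      stop("input matrix lacks feature(s): ",
           paste(want[is.na(idx)], collapse = ", "))
    X <- X[, idx, drop = FALSE]
  } else if (ncol(X) != length(want)) {
    stop("unnamed input has ", ncol(X), " columns but ", length(want),
         " features are expected")
  }
  Xn <- sweep(sweep(X, 2, stats$mean[idx_stats]), 2, stats$scale[idx_stats], "/")
  colnames(Xn) <- want
  Xn
}

#' Per-feature two-sample Student t-test
#'
#' Pooled-variance (equal-variance) two-sample t statistic for each
#' feature, comparing the positive against the negative class, with
#' two-sided p-values from the t distribution on `m - 2` degrees of
#' freedom. A Welch variant is available behind `var_equal = FALSE`.
#'
#' @param dataset A [labeled_dataset()]; both classes need >= 2 samples.
#' @param var_equal Use the pooled-variance Student statistic (default)
#'   or Welch's unequal-variance statistic.
#' @return `data.frame` with columns `feature`, `t`, `p` in column order.
#' @export
ttest_features <- function(dataset, var_equal = TRUE) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  pos <- dataset$y == 1
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 < 2 || n2 < 2)
    stop("both classes need at least 2 samples for the t-test")
  X1 <- dataset$X[pos, , drop = FALSE]
  X2 <- dataset$X[!pos, , drop = FALSE]
  mu1 <- colMeans(X1); mu2 <- colMeans(X2)
  v1 <- colSums(sweep(X1, 2, mu1)^2) / (n1 - 1)
  v2 <- colSums(sweep(X2, 2, mu2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- ifelse(se > 0, (mu1 - mu2) / se, 0)
  p <- ifelse(se > 0, 2 * pt(-abs(t), df), 1)
  data.frame(feature = dataset$features, t = unname(t), p = unname(p),
             stringsAsFactors = FALSE)
}

#' Filter features by t-test p-value
#'
#' Optional prefilter applied before fitting when the initial feature
#' count is very large; retains exactly the features with `p <= p_cutoff`,
#' preserving column order. Off by default in [run_lonestar()].
#'
#' @param dataset A [labeled_dataset()].
#' @param p_cutoff Retention threshold in (0, 1].
#' @param var_equal Passed to [ttest_features()].
#' @return The reduced [labeled_dataset()].
#' @export
ttest_filter <- function(dataset, p_cutoff = 0.05, var_equal = TRUE) {
  if (!is.numeric(p_cutoff) || p_cutoff <= 0 || p_cutoff > 1)
    stop("p_cutoff must be in (0, 1]")
  tt <- ttest_features(dataset, var_equal = var_equal)
  keep <- tt$p <= p_cutoff
  if (!any(keep))
    stop("no features survive p <= ", p_cutoff,
         "; raise the cutoff or disable the t-test filter")
  labeled_dataset(dataset$X[, keep, drop = FALSE], dataset$y,
                  dataset$samples, dataset$features[keep])
}
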