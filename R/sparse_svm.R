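#' Fitting parameters for the sparse combined-norm classifier
#'
#' @param lambda Regularization mix in (0, 1); the loss is weighted by
#'   `1 - lambda` and the penalty by `lambda`. Meant to be close to zero
#'   but not exactly zero; default 0.05.
#' @param alpha Class-asymmetry weight in (0, 1): positive-class slacks are
#'   weighted `alpha`, negative-class slacks `1 - alpha`. 0.5 treats
#'   sensitivity and specificity equally; smaller values emphasise
#'   sensitivity.
#' @param gamma Penalty mix in \[0, 1\]: `gamma` on the l1-norm (sparsity),
#'   `1 - gamma` on the un-squared l2-norm (grouping of correlated
#'   features). Default 0.5; see [tune_gamma()] for 2-fold cross-validated
#'   selection.
#' @param splits Number `l` of random balanced subsamples used for
#'   stability selection (default 80).
#' @param top Number `q <= splits` of best-performing classifiers averaged
#'   into the final model (default 20).
#' @param nonzero_tol Relative tolerance below which solver weights are
#'   snapped to exact zero.
#' @param seed Integer seed making the whole fit reproducible.
#' @param solver_tol Relative ADMM convergence tolerance.
#' @param solver_max_iter ADMM iteration cap per solve.
#' @return An object of class `lonestar_params`.
#' @export
lonestar_params <- function(lambda = 0.05, alpha = 0.5, gamma = 0.5,
                            splits = 80L, top = 20L, nonzero_tol = 1e-6,
                            seed = 1L, solver_tol = 1e-7,
                            solver_max_iter = 50000L) {
  if (!(lambda > 0 && lambda < 1)) stop("lambda must lie strictly in (0, 1)")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie strictly in (0, 1)")
  if (!(gamma >= 0 && gamma <= 1)) stop("gamma must lie in [0, 1]")
  splits <- as.integer(splits); top <- as.integer(top)
  if (splits < 1) stop("splits must be a positive integer")
  if (top < 1 || top > splits) stop("top must satisfy 1 <= top <= splits")
  if (nonzero_tol <= 0) stop("nonzero_tol must be positive")
  structure(list(lambda = lambda, alpha = alpha, gamma = gamma,
                 splits = splits, top = top, nonzero_tol = nonzero_tol,
                 seed = as.integer(seed), solver_tol = solver_tol,
                 solver_max_iter = as.integer(solver_max_iter)),
            class = "lonestar_params")
}

#' Objective value of the combined-norm SVM
#'
#' Recomputes, by direct formula, the quantity the solver minimizes:
#' `(1-lambda) * [alpha * sum(slack_pos) + (1-alpha) * sum(slack_neg)] +
#'  lambda * [gamma * sum(|w|) + (1-gamma) * sqrt(sum(w^2))]`
#' with hinge slacks derived from `(w, theta)`.
#'
#' @param w Weight vector.
#' @param theta Threshold.
#' @param X Training matrix (rows samples).
#' @param y Labels -1/+1.
#' @param lambda,alpha,gamma As in [lonestar_params()].
#' @return Scalar objective value.
#' @export
svm_objective <- function(w, theta, X, y, lambda, alpha, gamma) {
  f <- drop(as.matrix(X) %*% w) - theta
  sp <- pmax(0, 1 - f[y > 0])
  sn <- pmax(0, 1 + f[y < 0])
  (1 - lambda) * (alpha * sum(sp) + (1 - alpha) * sum(sn)) +
    lambda * (gamma * sum(abs(w)) + (1 - gamma) * sqrt(sum(w^2)))
}

#' Solve the combined l1/l2-norm soft-margin SVM
#'
#' Minimizes an asymmetric hinge loss plus a convex combination of the
#' l1-norm and the *un-squared* l2-norm of the weights (distinct from the
#' Elastic Net, which squares the l2 term):
#' \deqn{(1-\lambda)[\alpha \sum_{j \in P} y_j + (1-\alpha)\sum_{j \in N} z_j]
#'   + \lambda[\gamma \|w\|_1 + (1-\gamma)\|w\|_2]}
#' subject to `w'x_j - theta + y_j >= 1` on positives,
#' `w'x_j - theta - z_j <= -1` on negatives, slacks nonnegative. The
#' problem is a second-order-cone program solved by ADMM with closed-form
#' proximal maps; the l1 proximal step returns exact zeros, and weights
#' below `nonzero_tol * max(|w|)` are additionally snapped to zero.
#'
#' @param X Training matrix, samples in rows (columns normalized).
#' @param y Labels, -1/+1, both classes present.
#' @param params A [lonestar_params()].
#' @param tol,max_iter Optional overrides of `params$solver_tol` and
#'   `params$solver_max_iter`.
#' @return An object of class `svm_solution`: list with `w`, `theta`,
#'   `slack_pos`, `slack_neg`, `objective`, `iterations`, `converged`.
#' @export
solve_combined_norm_svm <- function(X, y, params = lonestar_params(),
                                    tol = NULL, max_iter = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop("labels must be -1/+1")
  if (!any(y == 1) || !any(y == -1))
    stop("training input must contain both classes")
  if (ncol(X) < 1) stop("at least one feature is required")
  if (is.null(tol)) tol <- params$solver_tol
  if (is.null(max_iter)) max_iter <- params$solver_max_iter
  res <- admm_combined_svm(X, y, params$lambda, params$alpha, params$gamma,
                           rho = 0.1, max_iter = as.integer(max_iter),
                           tol_abs = 1e-12, tol_rel = tol,
                           over_relax = 1.6, adapt_until = 2000L)
  if (!res$converged && res$primal_residual > 1e-4)
    stop(sprintf(paste0("combined-norm SVM solver failed to converge: ",
                        "primal residual %.3g, dual residual %.3g after %d iterations"),
                 res$primal_residual, res$dual_residual, res$iterations))
  w <- drop(res$w)
  mx <- max(abs(w))
  if (mx > 0) w[abs(w) < params$nonzero_tol * mx] <- 0
  names(w) <- colnames(X)
  theta <- res$theta
  f <- drop(X %*% w) - theta
  slack_pos <- pmax(0, 1 - f[y > 0])
  slack_neg <- pmax(0, 1 + f[y < 0])
  structure(list(w = w, theta = theta,
                 slack_pos = slack_pos, slack_neg = slack_neg,
                 objective = svm_objective(w, theta, X, y, params$lambda,
                                           params$alpha, params$gamma),
                 iterations = res$iterations, converged = res$converged),
            class = "svm_solution")
}

#' @export
print.svm_solution <- function(x, ...) {
  cat(sprintf("svm_solution: %d/%d nonzero weights, theta %.6g, objective %.6g (%d iterations)\n",
              sum(x$w != 0), length(x$w), x$theta, x$objective, x$iterations))
  invisible(x)
}

#' Count effectively nonzero weights
#'
#' An entry counts as nonzero when `|w_i| >= tol * max(1, max(|w|))`.
#'
#' @param w Weight vector.
#' @param nonzero_tol Positive relative tolerance.
#' @return Integer count.
#' @export
count_nonzero <- function(w, nonzero_tol = 1e-6) {
  if (nonzero_tol <= 0) stop("nonzero_tol must be positive")
  if (length(w) == 0) return(0L)
  sum(abs(w) >= nonzero_tol * max(1, max(abs(w))))
}

#' Tune the penalty mix gamma by 2-fold cross-validation
#'
#' Splits each class in half, fits on one half and scores on the other
#' (both directions), and returns the grid value with the smallest mean
#' alpha-weighted validation error. Ties resolve to the smaller gamma.
#'
#' @param dataset A normalized [labeled_dataset()].
#' @param params Base [lonestar_params()]; everything but `gamma` is kept.
#' @param grid Candidate gamma values.
#' @param folds Number of folds (default 2, as used for the cohort fits).
#' @return List with `gamma` (selected) and `errors` (named mean errors).
#' @export
tune_gamma <- function(dataset, params = lonestar_params(),
                       grid = seq(0.1, 0.9, by = 0.1), folds = 2L) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  pos <- which(dataset$y == 1); neg <- which(dataset$y == -1)
  fold_of <- function(idx) with_seed(derive_seed(params$seed, 9999L),
                                     sample(rep_len(seq_len(folds), length(idx))))
  fp <- fold_of(pos); fn_ <- fold_of(neg)
  errs <- vapply(grid, function(g) {
    p2 <- lonestar_params(params$lambda, params$alpha, g, params$splits,
                          params$top, params$nonzero_tol, params$seed,
                          params$solver_tol, params$solver_max_iter)
    fold_err <- vapply(seq_len(folds), function(f) {
      tr <- c(pos[fp != f], neg[fn_ != f])
      va <- c(pos[fp == f], neg[fn_ == f])
      sol <- solve_combined_norm_svm(dataset$X[tr, , drop = FALSE],
                                     dataset$y[tr], p2)
      fv <- drop(dataset$X[va, , drop = FALSE] %*% sol$w) - sol$theta
      pred <- ifelse(fv > 0, 1, -1)
      yv <- dataset$y[va]
      params$alpha * sum(pred == -1 & yv == 1) +
        (1 - params$alpha) * sum(pred == 1 & yv == -1)
    }, 0)
    mean(fold_err)
  }, 0)
  names(errs) <- as.character(grid)
  list(gamma = grid[which.min(errs)], errors = errs)
}
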