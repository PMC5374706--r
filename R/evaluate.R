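#' Discriminant values of a classifier
#'
#' Computes `f(x) = x . w - theta` for each row of `X`. Columns are
#' aligned to the model's feature panel by name; unnamed input must
#' already match the panel's width and order. No normalization is applied
#' here --- pass raw data through [predict.classifier_model()] or
#' [apply_normalization()] when the model stores training statistics.
#'
#' @param model A [classifier_model()].
#' @param X Matrix (samples in rows) or a single feature vector.
#' @return Numeric vector of discriminant values.
#' @export
discriminant <- function(model, X) {
  stopifnot(inherits(model, "classifier_model"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1, dimnames = list(NULL, names(X)))
  X <- as.matrix(X)
  if (!is.null(colnames(X))) {
    idx <- match(model$features, colnames(X))
    if (anyNA(idx))
      stop("input lacks model feature(s): ",
           paste(model$features[is.na(idx)], collapse = ", "))
    X <- X[, idx, drop = FALSE]
  } else if (ncol(X) != length(model$features)) {
    stop("unnamed input has ", ncol(X), " columns; model uses ",
         length(model$features), " features")
  }
  drop(X %*% model$weights) - model$threshold
}

#' Predict class labels
#'
#' A sample with a positive discriminant value is predicted positive
#' (at metastatic risk), otherwise negative. An exact zero maps to the
#' negative class and raises a boundary warning. When the model carries
#' stored training normalization statistics they are applied to the raw
#' input first; prediction on a platform other than the training one
#' reuses those frozen statistics, which is flagged in the documentation
#' rather than silently refit.
#'
#' @param object A [classifier_model()].
#' @param newdata Matrix of raw (or, if `normalize = FALSE`, pre-normalized)
#'   expression values, samples in rows.
#' @param normalize Apply the model's stored normalization; defaults to
#'   `TRUE` whenever statistics are stored.
#' @param ... Unused.
#' @return Numeric vector of -1/+1 predictions, with the discriminant
#'   values in attribute `"discriminant"`.
#' @export
predict.classifier_model <- function(object, newdata,
                                     normalize = !is.null(object$normalization),
                                     ...) {
  if (normalize) {
    if (is.null(object$normalization))
      stop("model stores no normalization statistics")
    newdata <- apply_normalization(newdata, object$normalization,
                                   features = object$features)
  }
  f <- discriminant(object, newdata)
  if (any(f == 0))
    warning(sum(f == 0), " sample(s) fall exactly on the decision boundary; ",
            "assigned to the negative class")
  pred <- ifelse(f > 0, 1, -1)
  attr(pred, "discriminant") <- f
  pred
}

#' Construct a 2x2 contingency table of classification results
#'
#' Rows are the actual classes (positive/negative), columns the predicted
#' ones: `tp` and `fn` split the actual positives, `fp` and `tn` the
#' actual negatives.
#'
#' @param tp,fn,fp,tn Nonnegative integer counts.
#' @return Object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("all counts must be nonnegative integers")
  if (sum(counts) == 0) stop("table total must be positive")
  structure(as.list(setNames(as.integer(counts), names(counts))),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, byrow = TRUE,
              dimnames = list(c("actual +", "actual -"),
                              c("pred +", "pred -")))
  print(m)
  invisible(x)
}

#' Cross-tabulate predictions against actual labels
#'
#' @param predicted,actual Equal-length -1/+1 vectors.
#' @return A [contingency_2x2()].
#' @export
tabulate_predictions <- function(predicted, actual) {
  predicted <- as.numeric(predicted); actual <- as.numeric(actual)
  if (length(predicted) != length(actual))
    stop("predicted and actual labels differ in length")
  if (length(predicted) < 1) stop("need at least one sample")
  if (!all(c(predicted, actual) %in% c(-1, 1)))
    stop("labels must be -1/+1")
  contingency_2x2(tp = sum(predicted == 1 & actual == 1),
                  fn = sum(predicted == -1 & actual == 1),
                  fp = sum(predicted == 1 & actual == -1),
                  tn = sum(predicted == -1 & actual == -1))
}

#' Classification metrics from a 2x2 table
#'
#' Accuracy `(tp+tn)/total`, sensitivity `tp/(tp+fn)`, specificity
#' `tn/(tn+fp)`, and the error rate among predicted negatives
#' `fn/(fn+tn)` --- the fraction of patients cleared by the classifier who
#' are actually at risk, the clinically critical error when a negative
#' call spares surgery. (Some reports tabulate this last quantity under
#' the label "false discovery rate"; the arithmetic here is the
#' predicted-negative error.) Metrics with a zero denominator are `NA`.
#'
#' @param table A [contingency_2x2()].
#' @return Named list: `accuracy`, `sensitivity`, `specificity`,
#'   `predicted_negative_error`.
#' @export
classification_metrics <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  tot <- table$tp + table$fn + table$fp + table$tn
  sdiv <- function(a, b) if (b > 0) a / b else NA_real_
  list(accuracy = sdiv(table$tp + table$tn, tot),
       sensitivity = sdiv(table$tp, table$tp + table$fn),
       specificity = sdiv(table$tn, table$tn + table$fp),
       predicted_negative_error = sdiv(table$fn, table$fn + table$tn))
}

#' Evaluate a classifier on a labeled cohort
#'
#' Applies the model, tabulates the predictions, and reports the metrics
#' together with Fisher and Barnard exact-test p-values for the
#' association between predicted and actual status.
#'
#' @param model A [classifier_model()].
#' @param dataset A [labeled_dataset()] with raw expression (normalized
#'   through the model's stored statistics) unless `normalize = FALSE`.
#' @param normalize Passed to [predict.classifier_model()].
#' @return Object of class `lonestar_evaluation`: list with
#'   `discriminant`, `predicted`, `table`, metrics, `fisher_p`,
#'   `barnard_p`.
#' @export
evaluate_classifier <- function(model, dataset,
                                normalize = !is.null(model$normalization)) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  pred <- predict(model, dataset$X, normalize = normalize)
  tab <- tabulate_predictions(pred, dataset$y)
  met <- classification_metrics(tab)
  res <- c(list(discriminant = setNames(attr(pred, "discriminant"),
                                        dataset$samples),
                predicted = setNames(as.numeric(pred), dataset$samples),
                table = tab),
           met,
           list(fisher_p = fisher_exact_two_sided(tab),
                barnard_p = barnard_exact(tab)))
  structure(res, class = "lonestar_evaluation")
}

#' @export
print.lonestar_evaluation <- function(x, ...) {
  print(x$table)
  cat(sprintf("accuracy %.4f, sensitivity %.4f, specificity %.4f, predicted-negative error %.4f\n",
              x$accuracy, x$sensitivity, x$specificity,
              x$predicted_negative_error))
  cat(sprintf("Fisher exact p = %.4g, Barnard exact p = %.4g\n",
              x$fisher_p, x$barnard_p))
  invisible(x)
}
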