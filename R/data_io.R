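#' Construct a labeled expression dataset
#'
#' Bundles an `m x n` expression matrix (samples in rows, log2 units
#' expected), its sample and feature identifiers, and binary class labels
#' coded as -1/+1, validating the joint invariants.
#'
#' @param X Numeric matrix, samples in rows, features in columns.
#' @param y Labels, one per sample, each exactly -1 or +1.
#' @param samples Sample identifiers; defaults to `rownames(X)`.
#' @param features Feature identifiers; defaults to `colnames(X)`.
#' @param require_both_classes If `TRUE` (default) both classes must be
#'   present, as required for training.
#' @return An object of class `labeled_dataset`: a list with elements
#'   `X`, `y`, `samples`, `features`.
#' @export
labeled_dataset <- function(X, y, samples = rownames(X), features = colnames(X),
                            require_both_classes = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(X)))
  if (is.null(features)) features <- paste0("F", seq_len(ncol(X)))
  samples <- as.character(samples)
  features <- as.character(features)
  y <- as.numeric(y)
  if (nrow(X) != length(samples) || nrow(X) != length(y))
    stop("row count of X must equal the number of samples and labels")
  if (ncol(X) != length(features))
    stop("column count of X must equal the number of feature identifiers")
  if (!all(y %in% c(-1, 1)))
    stop("labels must be exactly -1 or +1")
  if (require_both_classes && (!any(y == 1) || !any(y == -1)))
    stop("both classes must be non-empty for training use")
  if (anyDuplicated(samples))
    stop("duplicate sample identifiers: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (anyDuplicated(features))
    stop("duplicate feature identifiers: ",
         paste(unique(features[duplicated(features)]), collapse = ", "))
  if (!all(is.finite(X)))
    stop("expression matrix contains non-finite values")
  dimnames(X) <- list(samples, features)
  structure(list(X = X, y = y, samples = samples, features = features),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d samples x %d features (%d positive, %d negative)\n",
              nrow(x$X), ncol(x$X), sum(x$y == 1), sum(x$y == -1)))
  invisible(x)
}

#' Number of samples per class
#'
#' @param dataset A [labeled_dataset()].
#' @return Named vector `c(m1 = <positives>, m2 = <negatives>)`.
#' @export
class_sizes <- function(dataset) {
  c(m1 = sum(dataset$y == 1), m2 = sum(dataset$y == -1))
}

# Map an arbitrary two-level label vector onto -1/+1.
coerce_labels <- function(raw, positive_class = NULL) {
  lv <- unique(raw)
  if (length(lv) != 2)
    stop("label column must contain exactly two distinct values, found: ",
         paste(lv, collapse = ", "))
  if (!is.null(positive_class)) {
    if (!positive_class %in% lv)
      stop("positive_class '", positive_class, "' not present among labels")
    return(ifelse(raw == positive_class, 1, -1))
  }
  num <- suppressWarnings(as.numeric(lv))
  if (!anyNA(num) && setequal(num, c(-1, 1)))
    return(as.numeric(raw))
  if (!anyNA(num) && setequal(num, c(0, 1)))
    return(ifelse(as.numeric(raw) == 1, 1, -1))
  stop("labels are neither {-1,+1} nor {0,1}; supply positive_class to ",
       "declare which of {", paste(lv, collapse = ", "), "} is positive")
}

#' Read a labeled expression table
#'
#' Parses a delimited text matrix of expression values with identifiers in
#' the first row and column, plus one label column (or row), into a
#' [labeled_dataset()]. The reader is delimiter-explicit and expects the
#' decimal point (no locale-dependent parsing).
#'
#' @param path Path to a TSV (default) or CSV file.
#' @param label_column Name of the column holding class labels
#'   (samples-in-rows orientation) or of the row holding them
#'   (features-in-rows orientation). Default `"label"`.
#' @param sep Field delimiter, `"tab"` or `"comma"`.
#' @param orientation `"samples"` when samples are rows (default) or
#'   `"features"` when features are rows.
#' @param positive_class Optional label value to treat as the positive
#'   class when labels are not already -1/+1 or 0/1.
#' @return A [labeled_dataset()].
#' @export
read_expression_table <- function(path, label_column = "label",
                                  sep = c("tab", "comma"),
                                  orientation = c("samples", "features"),
                                  positive_class = NULL) {
  sep <- match.arg(sep)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  dl <- if (sep == "tab") "\t" else ","
  tab <- read.delim(path, sep = dl, header = TRUE, row.names = 1,
                    check.names = FALSE, colClasses = "character",
                    stringsAsFactors = FALSE)
  if (orientation == "features") tab <- as.data.frame(t(as.matrix(tab)),
                                                      stringsAsFactors = FALSE)
  if (anyDuplicated(colnames(tab)))   # before data.frame subsetting renames
    stop("duplicate feature identifiers: ",
         paste(unique(colnames(tab)[duplicated(colnames(tab))]),
               collapse = ", "))
  if (!label_column %in% colnames(tab))
    stop("label column '", label_column, "' not found in ", path)
  raw_labels <- tab[[label_column]]
  expr <- tab[, colnames(tab) != label_column, drop = FALSE]
  X <- matrix(NA_real_, nrow(expr), ncol(expr),
              dimnames = list(rownames(expr), colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    v <- suppressWarnings(as.numeric(expr[[j]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("non-numeric expression cell at sample '%s', feature '%s': '%s'",
                   rownames(expr)[bad[1]], colnames(expr)[j], expr[[j]][bad[1]]))
    X[, j] <- v
  }
  y <- coerce_labels(raw_labels, positive_class)
  labeled_dataset(X, y, samples = rownames(expr), features = colnames(expr))
}

#' Write a labeled expression table
#'
#' Inverse of [read_expression_table()] in the samples-in-rows orientation;
#' the labels are written as a `label` column of -1/+1 values.
#'
#' @param dataset A [labeled_dataset()].
#' @param path Output path.
#' @param sep Field delimiter, `"tab"` or `"comma"`.
#' @return Invisibly, `path`.
#' @export
write_expression_table <- function(dataset, path, sep = c("tab", "comma")) {
  sep <- match.arg(sep)
  dl <- if (sep == "tab") "\t" else ","
  df <- data.frame(id = dataset$samples, label = dataset$y,
                   dataset$X, check.names = FALSE)
  colnames(df)[1] <- ""
  write.table(df, path, sep = dl, quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

MODEL_SCHEMA_VERSION <- 1L

#' Construct a serializable linear classifier
#'
#' A fitted classifier is the selected feature panel `F`, one weight per
#' feature, a decision threshold, and (optionally) the per-feature
#' normalization statistics frozen at training time so that prediction on
#' a new cohort is self-contained. The discriminant is
#' `f(x) = x . w - theta`; positive values predict the positive class.
#'
#' @param features Ordered selected feature identifiers.
#' @param weights Numeric weights aligned with `features`.
#' @param threshold Scalar decision threshold.
#' @param normalization `NULL`, or a list with elements `features`, `mean`,
#'   `scale` recording the training transform (see [normalize_features()]).
#' @param params List of fitting parameter values (free-form metadata).
#' @param seed Seed used for fitting, or `NA`.
#' @return An object of class `classifier_model`.
#' @export
classifier_model <- function(features, weights, threshold,
                             normalization = NULL, params = list(),
                             seed = NA_integer_) {
  features <- as.character(features)
  weights <- as.numeric(weights)
  if (length(features) != length(weights))
    stop("features and weights must have equal length")
  if (length(features) == 0) stop("feature set must be non-empty")
  if (anyDuplicated(features)) stop("duplicate features in model")
  if (length(threshold) != 1 || !is.finite(threshold))
    stop("threshold must be a finite scalar")
  if (!is.null(normalization)) {
    need <- c("features", "mean", "scale")
    if (!all(need %in% names(normalization)))
      stop("normalization must have fields: ", paste(need, collapse = ", "))
    if (!all(features %in% normalization$features))
      stop("normalization statistics missing for some model features")
  }
  structure(list(features = features, weights = weights,
                 threshold = as.numeric(threshold),
                 normalization = normalization, params = params,
                 seed = seed),
            class = "classifier_model")
}

#' @export
print.classifier_model <- function(x, ...) {
  cat(sprintf("classifier_model: %d features, threshold %.6g%s\n",
              length(x$features), x$threshold,
              if (is.null(x$normalization)) " (no stored normalization)" else ""))
  df <- data.frame(feature = x$features, weight = x$weights)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Serialize a classifier to JSON
#'
#' Writes a versioned JSON document with full double precision, so that
#' [read_model()] reproduces weights and threshold bit-exactly.
#'
#' @param model A [classifier_model()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "classifier_model"))
  doc <- list(schema_version = MODEL_SCHEMA_VERSION,
              features = model$features,
              weights = model$weights,
              threshold = model$threshold,
              normalization = model$normalization,
              params = model$params,
              seed = model$seed)
  # digits = I(17): full IEEE-754 significand, so doubles round-trip
  # bit-exactly through the text representation
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a serialized classifier
#'
#' @param path Path to a JSON file written by [write_model()].
#' @return A [classifier_model()].
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("model schema error: not valid JSON (", conditionMessage(e), ")"))
  need <- c("schema_version", "features", "weights", "threshold")
  miss <- setdiff(need, names(doc))
  if (length(miss))
    stop("model schema error: missing fields ", paste(miss, collapse = ", "))
  if (!identical(as.integer(doc$schema_version), MODEL_SCHEMA_VERSION))
    stop("model schema error: schema_version ", doc$schema_version,
         " not supported (expected ", MODEL_SCHEMA_VERSION, ")")
  norm <- doc$normalization
  if (!is.null(norm) && length(norm) == 0) norm <- NULL
  if (!is.null(norm))
    norm <- list(features = as.character(norm$features),
                 mean = as.numeric(norm$mean),
                 scale = as.numeric(norm$scale))
  seed <- doc$seed
  if (is.null(seed) || length(seed) == 0) seed <- NA_integer_
  classifier_model(features = doc$features, weights = doc$weights,
                   threshold = doc$threshold, normalization = norm,
                   params = as.list(doc$params), seed = seed)
}
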