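#' Confusion matrix from paired label sequences
#'
#' Rows are true classes, columns predicted classes, both in `class_names`
#' order.
#'
#' @param true_labels,predicted_labels Equal-length character vectors.
#' @param class_names Ordered class names; defaults to the sorted union of
#'   observed labels.
#' @return A `confusion_matrix` (integer matrix with class dimnames).
#' @export
confusion <- function(true_labels, predicted_labels,
                      class_names = sort(unique(c(true_labels,
                                                  predicted_labels)))) {
  if (length(true_labels) != length(predicted_labels)) {
    stop_fm("label", "true and predicted label sequences differ in length")
  }
  bad <- setdiff(unique(c(true_labels, predicted_labels)), class_names)
  if (length(bad)) {
    stop_fm("label", sprintf("label(s) outside class_names: %s",
                             paste(bad, collapse = ", ")))
  }
  m <- table(factor(true_labels, levels = class_names),
             factor(predicted_labels, levels = class_names))
  out <- matrix(as.integer(m), nrow = length(class_names),
                dimnames = list(true = class_names, predicted = class_names))
  structure(out, class = c("confusion_matrix", class(out)))
}

#' Classification metrics from a confusion matrix
#'
#' True-positive accuracy (trace over total) plus per-class precision,
#' recall and F1, aggregated with support weights (each class weighted by
#' its true-label count). Support weighting makes the weighted recall equal
#' the TP accuracy exactly — an algebraic identity. A class never predicted
#' has undefined precision; it contributes 0 and sets `undefined_precision`.
#'
#' @param matrix_ A `confusion_matrix` (or plain square count matrix).
#' @return A `metrics_report`: `tp_accuracy`, weighted `precision`,
#'   `recall`, `f1`, and a `per_class` data frame.
#' @export
compute_metrics <- function(matrix_) {
  m <- unclass(matrix_)
  if (nrow(m) != ncol(m)) stop_fm("data", "confusion matrix must be square")
  total <- sum(m)
  if (total == 0) stop_fm("data", "all-zero confusion matrix")
  support <- rowSums(m)
  predicted <- colSums(m)
  tp <- diag(m)
  undefined <- predicted == 0
  precision <- ifelse(undefined, 0, tp / pmax(predicted, 1))
  recall <- ifelse(support == 0, 0, tp / pmax(support, 1))
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  w <- support / total
  per_class <- data.frame(
    class = rownames(m) %||% as.character(seq_len(nrow(m))),
    support = as.integer(support), precision = precision, recall = recall,
    f1 = f1, row.names = NULL)
  structure(list(tp_accuracy = sum(tp) / total,
                 precision = sum(w * precision),
                 recall = sum(w * recall),
                 f1 = sum(w * f1),
                 per_class = per_class,
                 undefined_precision = any(undefined & support > 0)),
            class = "metrics_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> TP accuracy %.2f%%, precision %.2f%%, recall %.2f%%, F1 %.2f%%\n",
    100 * x$tp_accuracy, 100 * x$precision, 100 * x$recall, 100 * x$f1))
  invisible(x)
}

#' Try-again repetition statistics with Hazen quartile summary
#'
#' For each expression class, the "Try Again!" feedback count is expressed
#' as a percentage of the maximum possible attempts,
#' `participants * max_attempts`. The summary reports the median and the
#' 25th/75th percentiles of the per-class percentages using midpoint (Hazen)
#' interpolation — sorted position `h = n * p + 0.5` — and their IQR.
#'
#' @param counts Named integer vector of try-again counts per class.
#' @param participants Number of study participants.
#' @param max_attempts Attempt cap per expression per participant.
#' @return A `repetition_stats`: `per_class` data frame (`class`, `count`,
#'   `percent_of_max`), `median`, `q1`, `q3`, `iqr` (all on the percent
#'   scale) and the `denominator`.
#' @export
repetition_stats <- function(counts, participants, max_attempts = 3L) {
  if (participants < 1 || max_attempts < 1) {
    stop_fm("config", "participants and max_attempts must be >= 1")
  }
  counts <- unlist(counts)
  if (any(counts < 0)) stop_fm("data", "negative try-again count")
  denom <- participants * max_attempts
  if (any(counts > denom)) {
    stop_fm("data", sprintf(
      "a try-again count exceeds the denominator %d (participants x max_attempts)",
      denom))
  }
  pct <- 100 * counts / denom
  qs <- stats::quantile(pct, probs = c(0.25, 0.5, 0.75), type = 5, names = FALSE)
  structure(list(
    per_class = data.frame(
      class = names(counts) %||% as.character(seq_along(counts)),
      count = as.integer(counts), percent_of_max = as.numeric(pct),
      row.names = NULL),
    median = qs[2], q1 = qs[1], q3 = qs[3], iqr = qs[3] - qs[1],
    denominator = denom),
    class = "repetition_stats")
}

#' @export
print.repetition_stats <- function(x, ...) {
  cat(sprintf(
    "<repetition_stats> median %.2f%% (IQR %.2f%%: Q1 %.2f%% - Q3 %.2f%%), denominator %d\n",
    x$median, x$iqr, x$q1, x$q3, x$denominator))
  print(transform(x$per_class, percent_of_max = round(percent_of_max, 2)))
  invisible(x)
}

#' Two-component PCA map of a feature space
#'
#' Features are z-scored, then projected onto the leading principal
#' components. Zero-variance features are dropped with a warning before
#' standardization.
#'
#' @param features Feature data frame (columns `R_*`, `theta_*`; a `label`
#'   column, if present, is carried into the output) or numeric matrix.
#' @param components Number of components to keep.
#' @return A `pca_map`: `scores` (n x components), `explained` variance
#'   shares (non-increasing, summing to <= 1), `rotation`, and optional
#'   `labels`.
#' @export
pca_map <- function(features, components = 2L) {
  labels <- NULL
  if (is.data.frame(features)) {
    if ("label" %in% names(features)) labels <- features$label
    feat_cols <- grep("^(R_|theta_)", names(features), value = TRUE)
    if (!length(feat_cols)) feat_cols <- setdiff(names(features), "label")
    X <- as.matrix(features[, feat_cols, drop = FALSE])
  } else {
    X <- as.matrix(features)
  }
  storage.mode(X) <- "double"
  if (nrow(X) < 2) stop_fm("data", "PCA needs at least 2 observations")
  vars <- apply(X, 2, stats::var)
  if (any(vars == 0)) {
    warning(sprintf("dropping zero-variance feature(s): %s",
                    paste(colnames(X)[vars == 0], collapse = ", ")))
    X <- X[, vars > 0, drop = FALSE]
  }
  if (components > ncol(X)) {
    stop_fm("config", "more components requested than usable features")
  }
  fit <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  shares <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(scores = fit$x[, seq_len(components), drop = FALSE],
                 explained = shares[seq_len(components)],
                 rotation = fit$rotation[, seq_len(components), drop = FALSE],
                 labels = labels),
            class = "pca_map")
}

#' @export
print.pca_map <- function(x, ...) {
  cat(sprintf("<pca_map> %d points, %d components explaining %s of variance\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = " + ")))
  invisible(x)
}

# ---- report writers ---------------------------------------------------------

#' Write evaluation reports to CSV / JSON
#'
#' @param x A `confusion_matrix`, `metrics_report` or `repetition_stats`.
#' @param path Output file path (`.csv` or `.json` inferred from extension).
#' @export
write_report <- function(x, path) {
  as_list <- function(x) {
    if (inherits(x, "confusion_matrix")) {
      list(class_names = rownames(x), counts = unclass(x))
    } else if (inherits(x, "metrics_report")) {
      list(tp_accuracy = x$tp_accuracy, precision = x$precision,
           recall = x$recall, f1 = x$f1, per_class = x$per_class)
    } else if (inherits(x, "repetition_stats")) {
      list(per_class = x$per_class, median = x$median, q1 = x$q1, q3 = x$q3,
           iqr = x$iqr, denominator = x$denominator)
    } else stop_fm("config", "unsupported report object")
  }
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as_list(x), path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  } else if (inherits(x, "confusion_matrix")) {
    utils::write.csv(as.data.frame(unclass(x)), path)
  } else {
    utils::write.csv(as_list(x)$per_class, path, row.names = FALSE)
  }
  invisible(path)
}
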