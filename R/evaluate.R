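# One-vs-rest confusion accounting and evaluation metrics: per-class
# precision/recall/F1, overall accuracy and Hamming loss, and
# Kruskal-Wallis comparisons of metric groups.

#' One-vs-rest confusion counts for one class
#'
#' Treats \code{target} as the positive class and everything else as
#' negative.
#'
#' @param y_true,y_pred equal-length label vectors
#' @param target the positive class label
#' @return list with TP, FP, FN, TN
#' @examples
#' oneVsRestCounts(c("A", "A", "B"), c("A", "A", "B"), "A")  # TP 2, TN 1
#' @export
oneVsRestCounts <- function(y_true, y_pred, target) {
  if (length(y_true) != length(y_pred))
    .stopInvalid("y_true and y_pred lengths differ")
  pt <- y_true == target
  pp <- y_pred == target
  list(TP = sum(pt & pp), FP = sum(!pt & pp),
       FN = sum(pt & !pp), TN = sum(!pt & !pp))
}

#' Precision, recall and F1 from confusion counts
#'
#' Precision = TP/(TP+FP), recall = TP/(TP+FN), F1 the harmonic mean of
#' the two. A zero denominator yields 0 by convention, so the scores
#' stay defined on degenerate folds.
#'
#' @param counts list with TP, FP, FN (as from
#'   \code{oneVsRestCounts}); \code{f1Score} alternatively accepts
#'   precision and recall directly via \code{precision}/\code{recall}
#' @return scalar in [0, 1]
#' @examples
#' precisionScore(list(TP = 9, FP = 1))          # 0.9
#' f1Score(precision = 0.67, recall = 0.45)      # 0.5384
#' @export
precisionScore <- function(counts) {
  den <- counts$TP + counts$FP
  if (den == 0) 0 else counts$TP / den
}

#' @rdname precisionScore
#' @export
recallScore <- function(counts) {
  den <- counts$TP + counts$FN
  if (den == 0) 0 else counts$TP / den
}

#' @rdname precisionScore
#' @param precision,recall direct inputs to the harmonic mean (used
#'   when \code{counts} is missing)
#' @export
f1Score <- function(counts, precision = NULL, recall = NULL) {
  if (missing(counts)) {
    p <- precision; r <- recall
  } else {
    p <- precisionScore(counts); r <- recallScore(counts)
  }
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

#' Overall accuracy
#'
#' Fraction of exact label matches.
#'
#' @param y_true,y_pred equal-length label vectors
#' @return scalar in [0, 1]
#' @export
accuracyScore <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    .stopInvalid("y_true and y_pred lengths differ")
  mean(y_true == y_pred)
}

#' Hamming loss on one-hot label matrices
#'
#' Per sample, the fraction of the N class indicators on which the
#' predicted and true one-hot vectors disagree; reported as the mean
#' over samples. For single-label one-hot data every misclassification
#' flips exactly two indicators, so the Hamming loss equals
#' 2 (1 - accuracy) / N.
#'
#' @param Y_true,Y_pred one-hot matrices of identical shape, one row
#'   per sample, rows summing to 1
#' @return scalar in [0, 1]
#' @examples
#' # 7 classes at accuracy 0.976 -> 2 * 0.024 / 7 = 0.00686
#' @export
hammingLoss <- function(Y_true, Y_pred) {
  Y_true <- as.matrix(Y_true); Y_pred <- as.matrix(Y_pred)
  if (!all(dim(Y_true) == dim(Y_pred)))
    .stopInvalid("one-hot matrices must have identical shape")
  if (any(rowSums(Y_true) != 1) || any(rowSums(Y_pred) != 1))
    .stopInvalid("rows must be one-hot (sum to 1)")
  mean(rowMeans(Y_true != Y_pred))
}

#' Kruskal-Wallis rank test over groups
#'
#' Rank-based H statistic with tie correction and a chi-square p value
#' on groups - 1 degrees of freedom (delegated to
#' \code{stats::kruskal.test}).
#'
#' @param groups list of numeric vectors, one per group
#' @return list with \code{H}, \code{df}, \code{p}, \code{sizes}
#' @examples
#' kruskalWallis(list(1:3, 4:6))  # H = 3.857
#' @export
kruskalWallis <- function(groups) {
  if (length(groups) < 2L)
    .stopInvalid("at least two groups are required")
  if (any(!lengths(groups))) .stopInvalid("groups must be non-empty")
  if (length(unique(unlist(groups))) == 1L) {
    # every observation tied: the tie-corrected statistic degenerates
    # to 0/0; by convention there is no evidence of a group effect
    return(list(H = 0, df = length(groups) - 1L, p = 1,
                sizes = lengths(groups)))
  }
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, sizes = lengths(groups))
}

#' Build a hold-out evaluation report
#'
#' Computes the one-vs-rest precision/recall/F1 for every class of the
#' camera position, plus overall accuracy and Hamming loss.
#'
#' @param y_true,y_pred integer class labels (indices into
#'   \code{classes})
#' @param classes class names in index order
#' @param method "knn" or "nn"
#' @param position camera position tag
#' @return A \code{MetricsReport}.
#' @export
metricsReport <- function(y_true, y_pred, classes, method, position) {
  n <- length(classes)
  per <- data.frame(class = classes, precision = NA_real_,
                    recall = NA_real_, f1 = NA_real_)
  for (i in seq_len(n)) {
    cc <- oneVsRestCounts(y_true, y_pred, i)
    per$precision[i] <- precisionScore(cc)
    per$recall[i] <- recallScore(cc)
    per$f1[i] <- f1Score(cc)
  }
  onehot <- function(y) {
    m <- matrix(0L, length(y), n)
    m[cbind(seq_along(y), y)] <- 1L
    m
  }
  new("MetricsReport", perClass = per,
      accuracy = accuracyScore(y_true, y_pred),
      hammingLoss = hammingLoss(onehot(y_true), onehot(y_pred)),
      method = method, position = position)
}

#' Kruskal-Wallis comparison of evaluation reports
#'
#' Pools the per-class one-vs-rest metrics of the given reports and
#' tests, per metric, whether the grouping factor (classification
#' method, or camera position) has an effect.
#'
#' @param reports list of \code{MetricsReport}
#' @param by group by "method" or "position"
#' @return named list (precision, recall, f1) of \code{kruskalWallis}
#'   results
#' @export
compareReports <- function(reports, by = c("method", "position")) {
  by <- match.arg(by)
  keys <- vapply(reports, function(r)
    if (by == "method") r@method else r@position, character(1))
  if (length(unique(keys)) < 2L)
    .stopInvalid("need at least two distinct %s groups", by)
  classSets <- lapply(reports, function(r) r@perClass$class)
  if (by == "method" && length(unique(vapply(classSets, paste,
                                             character(1), collapse = ","))) > 1L)
    .stopInvalid("method comparison requires identical class sets")
  out <- list()
  for (metric in c("precision", "recall", "f1")) {
    groups <- lapply(split(reports, keys), function(rs)
      unlist(lapply(rs, function(r) r@perClass[[metric]])))
    out[[metric]] <- kruskalWallis(groups)
  }
  out
}

#' Serialise evaluation reports
#'
#' \code{writeMetricsJSON} stores one report as JSON;
#' \code{reportsToCSV} lays several reports out as a metric x position
#' table with one column per class and method, the package's standard
#' tabular form (accuracy and Hamming loss printed to 3 decimals,
#' per-class metrics to 2, rounding half away from zero).
#'
#' @param report a \code{MetricsReport}
#' @param reports list of \code{MetricsReport}
#' @param path output file path
#' @return the path, invisibly
#' @export
writeMetricsJSON <- function(report, path) {
  jsonlite::write_json(list(method = report@method,
                            position = report@position,
                            accuracy = report@accuracy,
                            hamming_loss = report@hammingLoss,
                            per_class = report@perClass),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# round half away from zero at `digits` decimals
.roundHalfAway <- function(x, digits) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @rdname writeMetricsJSON
#' @export
reportsToCSV <- function(reports, path) {
  rows <- list()
  for (r in reports) {
    rows[[length(rows) + 1L]] <- data.frame(
      metric = "Accuracy", position = r@position, method = r@method,
      class = "all", value = sprintf("%.3f", .roundHalfAway(r@accuracy, 3)))
    rows[[length(rows) + 1L]] <- data.frame(
      metric = "Ha.loss", position = r@position, method = r@method,
      class = "all", value = sprintf("%.3f", .roundHalfAway(r@hammingLoss, 3)))
    for (i in seq_len(nrow(r@perClass)))
      for (metric in c("precision", "recall", "f1"))
        rows[[length(rows) + 1L]] <- data.frame(
          metric = metric, position = r@position, method = r@method,
          class = r@perClass$class[i],
          value = sprintf("%.2f", .roundHalfAway(r@perClass[[metric]][i], 2)))
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
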