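# k-nearest-neighbour classification: stored exemplars, majority vote
# with deterministic tie rules, and cross-validated grid search over k
# with SMOTE applied inside every fold.

#' Fit a kNN classifier
#'
#' Stores the training features and labels verbatim together with the
#' neighbourhood size k.
#'
#' @param x numeric feature matrix (standardised, 5 columns in the
#'   pipeline)
#' @param y class labels (integer indices or factor)
#' @param k number of neighbours
#' @param classes optional class names; defaults to the sorted labels
#' @return A \code{KnnModel}.
#' @export
knnFit <- function(x, y, k, classes = NULL) {
  x <- as.matrix(x)
  if (k < 1L) .stopInvalid("k must be >= 1")
  if (k > nrow(x)) .stopInvalid("k exceeds the number of training samples")
  if (is.factor(y)) {
    classes <- levels(y)
    y <- as.integer(y)
  } else {
    y <- as.integer(y)
    if (is.null(classes)) classes <- as.character(sort(unique(y)))
  }
  if (length(y) != nrow(x)) .stopInvalid("x and y lengths differ")
  new("KnnModel", x = x, y = y, k = as.integer(k), classes = classes)
}

# majority vote over the first k columns of an ordered neighbour-label
# matrix (k x nq, nearest first). Vote ties are resolved in favour of
# the tied class holding the single nearest neighbour; exact distance
# ties were already broken towards lower stored-row indices in the
# search.
.voteFromNeighbours <- function(nbrLabels, k, nClasses) {
  nq <- ncol(nbrLabels)
  out <- integer(nq)
  lab <- nbrLabels[seq_len(k), , drop = FALSE]
  for (i in seq_len(nq)) {
    tab <- tabulate(lab[, i], nbins = nClasses)
    best <- which(tab == max(tab))
    if (length(best) == 1L) out[i] <- best
    else out[i] <- lab[match(TRUE, lab[, i] %in% best), i]
  }
  out
}

#' Predict with a kNN classifier
#'
#' Each query is assigned the most frequent class among its k nearest
#' stored samples (Euclidean distance). A tied vote goes to the tied
#' class that owns the single nearest neighbour; an exact distance tie
#' is broken towards the lower stored-row index, so prediction is fully
#' deterministic.
#'
#' @param model a \code{KnnModel}
#' @param queries numeric matrix on the training feature scale
#' @return integer class labels (indices into \code{model@classes})
#' @export
knnPredict <- function(model, queries) {
  queries <- as.matrix(queries)
  if (ncol(queries) != ncol(model@x))
    .stopInvalid("query feature dimension (%d) does not match training (%d)",
                 ncol(queries), ncol(model@x))
  res <- .knnSearchCpp(model@x, queries, model@k)
  nbrLabels <- matrix(model@y[res$idx], nrow = model@k)
  .voteFromNeighbours(nbrLabels, model@k, length(model@classes))
}

#' Grid search over k with five-fold cross-validation
#'
#' Tunes the neighbourhood size over \code{ks} (default 1..20): the
#' training table is split into \code{folds} equally large random
#' parts; for each fold, SMOTE balances the other folds' rows only (the
#' evaluation fold is never oversampled), a kNN classifier is fitted
#' and its accuracy measured on the held-out fold. The chosen k
#' maximises the mean accuracy over folds, ties broken towards the
#' smallest k. If the plain random split leaves a class unusable in
#' some fold (absent, or a single training sample), a warning is issued
#' and the split is redrawn stratified.
#'
#' @param x standardised feature matrix
#' @param y integer class labels
#' @param ks candidate neighbourhood sizes
#' @param folds number of cross-validation folds
#' @param seed integer seed (fold assignment and SMOTE)
#' @param smote a \code{smoteConfig()}; its seed is re-derived per fold
#' @return list with \code{chosen_k}, \code{mean_accuracy} (named per
#'   k), and the per-fold accuracy matrix \code{fold_accuracy}
#' @export
knnGridSearch <- function(x, y, ks = 1:20, folds = 5L, seed = 1L,
                          smote = smoteConfig()) {
  x <- as.matrix(x)
  y <- as.integer(y)
  n <- nrow(x)
  if (min(table(y)) < folds)
    .stopInvalid("every class needs at least %d samples for %d-fold CV",
                 folds, folds)
  assign_folds <- function(stratified) .withSeed(seed, {
    if (!stratified) {
      sample(rep_len(seq_len(folds), n))
    } else {
      f <- integer(n)
      for (cl in unique(y)) {
        rows <- which(y == cl)
        f[rows] <- sample(rep_len(seq_len(folds), length(rows)))
      }
      f
    }
  })
  foldid <- assign_folds(FALSE)
  bad <- any(vapply(seq_len(folds), function(f)
    min(tabulate(y[foldid != f], nbins = max(y))[unique(y)]) < 2L,
    logical(1)))
  if (bad) {
    warning("random folds left a class with < 2 training samples; ",
            "re-splitting stratified")
    foldid <- assign_folds(TRUE)
  }
  kmax <- max(ks)
  acc <- matrix(NA_real_, nrow = folds, ncol = length(ks),
                dimnames = list(NULL, as.character(ks)))
  for (f in seq_len(folds)) {
    tr <- foldid != f
    bal <- smoteOversample(x[tr, , drop = FALSE], y[tr],
                           smoteConfig(smote$k_neighbors,
                                       seed = smote$seed + 7L * f,
                                       target = smote$target))
    res <- .knnSearchCpp(bal$x, x[!tr, , drop = FALSE], min(kmax, nrow(bal$x)))
    nbrLabels <- matrix(bal$y[res$idx], nrow = nrow(res$idx))
    truth <- y[!tr]
    for (j in seq_along(ks)) {
      pred <- .voteFromNeighbours(nbrLabels, ks[j], max(y))
      acc[f, j] <- mean(pred == truth)
    }
  }
  meanAcc <- colMeans(acc)
  chosen <- ks[which.max(meanAcc)]  # which.max takes the first (smallest k)
  list(chosen_k = chosen, mean_accuracy = meanAcc, fold_accuracy = acc)
}

#' Serialise / restore a kNN model as JSON
#'
#' @param model a \code{KnnModel}
#' @param path JSON file path
#' @return \code{writeKnnModel}: the path, invisibly;
#'   \code{readKnnModel}: a \code{KnnModel}.
#' @export
writeKnnModel <- function(model, path) {
  jsonlite::write_json(list(k = model@k, classes = model@classes,
                            y = model@y, x = model@x),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeKnnModel
#' @export
readKnnModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("KnnModel", x = as.matrix(obj$x), y = as.integer(obj$y),
      k = as.integer(obj$k), classes = as.character(obj$classes))
}
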