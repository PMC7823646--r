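# Synthetic minority oversampling (SMOTE): equalise class counts by
# interpolating between a minority sample and one of its k nearest
# same-class neighbours, x_new = x_i + lambda * (x_j - x_i),
# lambda ~ U[0, 1].

#' SMOTE configuration
#'
#' @param k_neighbors number of same-class nearest neighbours a
#'   synthetic sample may interpolate towards (default 5, the canonical
#'   SMOTE choice)
#' @param seed integer seed for the interpolation draws
#' @param target per-class target count; \code{NA} (default) balances
#'   up to the majority-class count
#' @return list of class \code{smoteConfig}
#' @export
smoteConfig <- function(k_neighbors = 5L, seed = 1L, target = NA_integer_) {
  if (k_neighbors < 1L) .stopInvalid("k_neighbors must be >= 1")
  structure(list(k_neighbors = as.integer(k_neighbors),
                 seed = as.integer(seed),
                 target = as.integer(target)),
            class = "smoteConfig")
}

#' Oversample minority classes with SMOTE
#'
#' Brings every class up to the target count (by default the
#' majority-class count). Each synthetic sample interpolates between an
#' original minority sample x_i and one of its \code{k_neighbors}
#' nearest same-class neighbours x_j (Euclidean distance):
#' x_new = x_i + lambda (x_j - x_i) with lambda uniform on [0, 1].
#' Original rows are preserved unchanged and come first in the output;
#' synthetic rows follow, grouped by class. Deterministic per seed.
#' Intended for standardised features, and must only ever see training
#' rows — the classifier fitting routines in this package call it
#' inside each fold/validation split.
#'
#' @param x numeric feature matrix (rows = samples)
#' @param y integer class labels
#' @param config a \code{smoteConfig()}
#' @return list with the augmented \code{x} and \code{y}
#' @examples
#' x <- rbind(matrix(rnorm(20), 10), matrix(rnorm(6, 3), 3))
#' out <- smoteOversample(x, c(rep(1L, 10), rep(2L, 3)), smoteConfig(seed = 1))
#' table(out$y)  # 10, 10
#' @export
smoteOversample <- function(x, y, config = smoteConfig()) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (!nrow(x)) .stopInvalid("empty input to SMOTE")
  if (nrow(x) != length(y)) .stopInvalid("x and y lengths differ")
  counts <- table(y)
  target <- if (is.na(config$target)) max(counts) else config$target
  if (target < max(counts))
    .stopInvalid("target must be at least the majority-class count")
  deficits <- target - counts
  if (all(deficits == 0)) return(list(x = x, y = y))
  short <- names(counts)[counts < target & counts < 2L]
  if (length(short))
    .stopInvalid("class %s has fewer than 2 samples; cannot interpolate",
                 paste(short, collapse = ","))
  .withSeed(config$seed, {
    newx <- list(); newy <- list()
    for (cl in names(counts)) {
      need <- target - counts[[cl]]
      if (need == 0L) next
      rows <- which(y == as.integer(cl))
      xc <- x[rows, , drop = FALSE]
      nc <- nrow(xc)
      k <- min(config$k_neighbors, nc - 1L)
      # k+1 neighbours of each minority point against its own class,
      # then drop the self match
      res <- .knnSearchCpp(xc, xc, k + 1L)
      nbr <- matrix(0L, k, nc)
      for (i in seq_len(nc)) {
        col <- res$idx[, i]
        col <- col[col != i]
        nbr[, i] <- col[seq_len(k)]
      }
      basec <- 1L + (seq_len(need) - 1L) %% nc  # cycle the originals
      pick <- nbr[cbind(sample.int(k, need, replace = TRUE), basec)]
      lambda <- stats::runif(need)
      xi <- xc[basec, , drop = FALSE]
      xj <- xc[pick, , drop = FALSE]
      newx[[cl]] <- xi + lambda * (xj - xi)
      newy[[cl]] <- rep(as.integer(cl), need)
    }
    list(x = rbind(x, do.call(rbind, newx)),
         y = c(y, unlist(newy, use.names = FALSE)))
  })
}
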