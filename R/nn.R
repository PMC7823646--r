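# Dense feed-forward network: a plain stack of equal-width ReLU layers
# with 15% dropout after every second hidden layer, softmax output,
# Adam optimisation of the categorical cross entropy, linear
# learning-rate decay and early stopping on the validation loss.

#' Neural-network configuration
#'
#' Defaults follow the training protocol used throughout the package:
#' Adam with initial learning rate 0.001 decayed linearly per epoch to
#' a floor of lr0/100, batch size 256, at most 100 epochs, early
#' stopping after 5 epochs without validation-loss improvement, 15\%
#' dropout after every second hidden layer, and a 30\% validation split
#' taken before SMOTE balancing.
#'
#' @param n_hidden_layers number of hidden layers, 0..16
#' @param n_neurons width of every hidden layer, one of
#'   {10, 50, 100, 150, 200, 250, 300} in the tuning grid (any positive
#'   value is accepted here)
#' @param dropout_rate dropout fraction (default 0.15)
#' @param dropout_every dropout after every this-many hidden layers
#'   (default 2)
#' @param learning_rate initial Adam learning rate
#' @param max_epochs training epoch cap
#' @param batch_size mini-batch size
#' @param patience early-stopping patience in epochs
#' @param val_fraction validation fraction in (0, 1)
#' @param seed integer seed (initialisation, splits, SMOTE, shuffling,
#'   dropout)
#' @return list of class \code{nnConfig}
#' @export
nnConfig <- function(n_hidden_layers = 2L, n_neurons = 50L,
                     dropout_rate = 0.15, dropout_every = 2L,
                     learning_rate = 0.001, max_epochs = 100L,
                     batch_size = 256L, patience = 5L,
                     val_fraction = 0.3, seed = 1L) {
  if (n_hidden_layers < 0L || n_hidden_layers > 16L)
    .stopInvalid("n_hidden_layers must lie in 0..16")
  if (n_neurons < 1L) .stopInvalid("n_neurons must be positive")
  if (val_fraction <= 0 || val_fraction >= 1)
    .stopInvalid("val_fraction must lie in (0, 1)")
  if (dropout_rate < 0 || dropout_rate >= 1)
    .stopInvalid("dropout_rate must lie in [0, 1)")
  structure(list(n_hidden_layers = as.integer(n_hidden_layers),
                 n_neurons = as.integer(n_neurons),
                 dropout_rate = dropout_rate,
                 dropout_every = as.integer(dropout_every),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "nnConfig")
}

#' The full architecture tuning grid
#'
#' All pairs of hidden-layer count 0..16 and layer width
#' {10, 50, 100, 150, 200, 250, 300}: 17 x 7 = 119 configurations.
#'
#' @return data.frame with columns \code{layers} and \code{neurons}
#' @export
fullNnGrid <- function() {
  expand.grid(layers = 0:16, neurons = c(10L, 50L, 100L, 150L, 200L, 250L, 300L))
}

#' Build a dense network with seeded Glorot-uniform weights
#'
#' Architecture: 5 inputs, \code{n_hidden_layers} ReLU layers of
#' \code{n_neurons} each, softmax output of \code{n_classes} nodes
#' (7 for camera position 'U', 8 otherwise). With 0 hidden layers the
#' model is a multinomial logistic regression.
#'
#' @param config an \code{nnConfig()}
#' @param n_classes output width
#' @return An \code{NnModel} with freshly initialised weights.
#' @export
nnBuild <- function(config, n_classes) {
  widths <- c(5L, rep(config$n_neurons, config$n_hidden_layers),
              as.integer(n_classes))
  .withSeed(config$seed, {
    weights <- list(); biases <- list()
    for (i in seq_len(length(widths) - 1L)) {
      fin <- widths[i]; fout <- widths[i + 1L]
      lim <- sqrt(6 / (fin + fout))  # Glorot uniform
      weights[[i]] <- matrix(stats::runif(fin * fout, -lim, lim), fin, fout)
      biases[[i]] <- numeric(fout)
    }
    new("NnModel", weights = weights, biases = biases,
        nClasses = as.integer(n_classes), config = unclass(config))
  })
}

.softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# forward pass; when training, applies inverted dropout after hidden
# layers dropout_every, 2*dropout_every, ... and returns cached
# activations for backprop
.nnForward <- function(weights, biases, x, config = NULL, training = FALSE) {
  nl <- length(weights)
  acts <- vector("list", nl + 1L)
  masks <- vector("list", nl)
  acts[[1L]] <- x
  a <- x
  for (i in seq_len(nl)) {
    z <- sweep(a %*% weights[[i]], 2, biases[[i]], "+")
    if (i < nl) {
      a <- pmax(z, 0)
      if (training && config$dropout_rate > 0 &&
          i %% config$dropout_every == 0L) {
        keep <- 1 - config$dropout_rate
        m <- matrix(stats::runif(length(a)) < keep, nrow(a), ncol(a)) / keep
        a <- a * m
        masks[[i]] <- m
      }
    } else {
      a <- .softmax(z)
    }
    acts[[i + 1L]] <- a
  }
  list(out = a, acts = acts, masks = masks)
}

#' Predict with a dense network
#'
#' Dropout is inactive at evaluation time. Returns the softmax
#' probability rows (summing to 1) and the argmax class label, ties
#' broken towards the lowest class index.
#'
#' @param model an \code{NnModel}
#' @param queries numeric matrix with 5 feature columns
#' @return list with \code{labels} (integer) and \code{prob} (matrix)
#' @export
nnPredict <- function(model, queries) {
  queries <- as.matrix(queries)
  if (ncol(queries) != nrow(model@weights[[1L]]))
    .stopInvalid("query feature dimension (%d) does not match the model (%d)",
                 ncol(queries), nrow(model@weights[[1L]]))
  p <- .nnForward(model@weights, model@biases, queries)$out
  list(labels = max.col(p, ties.method = "first"), prob = p)
}

#' Train a dense network
#'
#' Splits off \code{val_fraction} (default 30\%) of the rows for
#' validation, balances the remaining rows with SMOTE, and runs
#' mini-batch Adam on the categorical cross entropy with a per-epoch
#' learning rate \code{lr0 * (1 - (epoch-1)/max_epochs)} floored at
#' \code{lr0/100}. Training stops once \code{patience} epochs pass
#' without validation-loss improvement; the returned model carries the
#' best-epoch weights.
#'
#' @param model an \code{NnModel} from \code{nnBuild}
#' @param x feature matrix (standardised)
#' @param y integer class labels 1..n_classes
#' @param config an \code{nnConfig()}; defaults to the one stored in
#'   the model
#' @param smote_k SMOTE neighbourhood size
#' @return list with \code{model} (best-epoch weights) and
#'   \code{history} (data.frame epoch, train_loss, val_loss; plus
#'   \code{best_epoch}, \code{stopped_epoch})
#' @export
nnTrain <- function(model, x, y, config = NULL, smote_k = 5L) {
  if (is.null(config)) config <- do.call(nnConfig, model@config)
  x <- as.matrix(x)
  y <- as.integer(y)
  if (!nrow(x)) .stopInvalid("empty training data")
  if (max(y) > model@nClasses)
    .stopInvalid("labels exceed the model's %d classes", model@nClasses)
  nl <- length(model@weights)
  W <- model@weights; B <- model@biases
  .withSeed(config$seed + 1L, {
    n <- nrow(x)
    vi <- sample.int(n, round(config$val_fraction * n))
    if (!length(vi) || length(vi) == n)
      .stopInvalid("validation split left an empty portion")
    xv <- x[vi, , drop = FALSE]; yv <- y[vi]
    xt <- x[-vi, , drop = FALSE]; yt <- y[-vi]
    if (min(table(yt)) >= 2L) {
      bal <- smoteOversample(xt, yt, smoteConfig(smote_k, seed = config$seed + 2L))
      xt <- bal$x; yt <- bal$y
    }
    nt <- nrow(xt)
    Yt <- matrix(0, nt, model@nClasses); Yt[cbind(seq_len(nt), yt)] <- 1
    Yv <- matrix(0, nrow(xv), model@nClasses)
    Yv[cbind(seq_len(nrow(xv)), yv)] <- 1
    xent <- function(P, Y) -mean(rowSums(Y * log(pmax(P, 1e-12))))

    mW <- lapply(W, function(w) w * 0); vW <- mW
    mB <- lapply(B, function(b) b * 0); vB <- mB
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; tstep <- 0
    bestVal <- Inf; bestEpoch <- 0L
    bestW <- W; bestB <- B
    hist <- data.frame(epoch = integer(), train_loss = numeric(),
                       val_loss = numeric())
    stopped <- config$max_epochs
    for (epoch in seq_len(config$max_epochs)) {
      lr <- max(config$learning_rate * (1 - (epoch - 1) / config$max_epochs),
                config$learning_rate / 100)
      ord <- sample.int(nt)
      starts <- seq(1L, nt, by = config$batch_size)
      for (s in starts) {
        rows <- ord[s:min(s + config$batch_size - 1L, nt)]
        xb <- xt[rows, , drop = FALSE]
        yb <- Yt[rows, , drop = FALSE]
        fw <- .nnForward(W, B, xb, config, training = TRUE)
        m <- nrow(xb)
        delta <- (fw$out - yb) / m  # softmax + cross-entropy gradient
        for (i in rev(seq_len(nl))) {
          gW <- crossprod(fw$acts[[i]], delta)
          gB <- colSums(delta)
          if (i > 1L) {
            delta <- delta %*% t(W[[i]])
            delta <- delta * (fw$acts[[i]] > 0)
            if (!is.null(fw$masks[[i - 1L]])) delta <- delta * fw$masks[[i - 1L]]
          }
          tW <- tstep + 1
          mW[[i]] <- b1 * mW[[i]] + (1 - b1) * gW
          vW[[i]] <- b2 * vW[[i]] + (1 - b2) * gW * gW
          mB[[i]] <- b1 * mB[[i]] + (1 - b1) * gB
          vB[[i]] <- b2 * vB[[i]] + (1 - b2) * gB * gB
          W[[i]] <- W[[i]] - lr * (mW[[i]] / (1 - b1^tW)) /
            (sqrt(vW[[i]] / (1 - b2^tW)) + eps)
          B[[i]] <- B[[i]] - lr * (mB[[i]] / (1 - b1^tW)) /
            (sqrt(vB[[i]] / (1 - b2^tW)) + eps)
        }
        tstep <- tstep + 1
      }
      trainLoss <- xent(.nnForward(W, B, xt)$out, Yt)
      valLoss <- xent(.nnForward(W, B, xv)$out, Yv)
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = trainLoss,
                                     val_loss = valLoss))
      if (!is.finite(trainLoss) || !is.finite(valLoss)) {
        cond <- structure(class = c("trainingFailure", "error", "condition"),
                          list(message = "training diverged (non-finite loss)",
                               call = NULL, history = hist))
        stop(cond)
      }
      if (valLoss < bestVal) {
        bestVal <- valLoss; bestEpoch <- epoch
        bestW <- W; bestB <- B
      } else if (epoch - bestEpoch >= config$patience) {
        stopped <- epoch
        break
      }
      stopped <- epoch
    }
    trained <- new("NnModel", weights = bestW, biases = bestB,
                   nClasses = model@nClasses, config = unclass(config))
    list(model = trained,
         history = structure(hist, best_epoch = bestEpoch,
                             stopped_epoch = stopped,
                             best_val_loss = bestVal))
  })
}

#' Architecture grid search
#'
#' Trains one network per (layers, neurons) pair and returns the
#' configuration with the smallest best validation loss; ties are
#' broken towards fewer layers, then fewer neurons (the iteration
#' order). Training failures are recorded and excluded from the argmin.
#'
#' @param x feature matrix
#' @param y integer class labels
#' @param n_classes output width
#' @param grid data.frame with columns \code{layers}, \code{neurons};
#'   default a small desk-scale grid, \code{fullNnGrid()} for the full
#'   17 x 7 sweep
#' @param config base \code{nnConfig()}; layers/neurons are overridden
#'   per cell, the seed is shared so cells differ only in architecture
#' @return list with \code{best_config}, \code{best} (row index),
#'   \code{val_loss} per cell, and \code{results} (per-cell history
#'   attributes)
#' @export
nnGridSearch <- function(x, y, n_classes,
                         grid = expand.grid(layers = 0:2,
                                            neurons = c(10L, 50L)),
                         config = nnConfig()) {
  if (!nrow(grid)) .stopInvalid("empty architecture grid")
  grid <- grid[order(grid$layers, grid$neurons), , drop = FALSE]
  losses <- rep(NA_real_, nrow(grid))
  results <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- config
    cfg$n_hidden_layers <- as.integer(grid$layers[i])
    cfg$n_neurons <- as.integer(grid$neurons[i])
    fit <- tryCatch(nnTrain(nnBuild(cfg, n_classes), x, y, cfg),
                    trainingFailure = function(e) e)
    if (inherits(fit, "trainingFailure")) {
      results[[i]] <- list(failed = TRUE, message = conditionMessage(fit))
    } else {
      losses[i] <- attr(fit$history, "best_val_loss")
      results[[i]] <- list(failed = FALSE,
                           best_epoch = attr(fit$history, "best_epoch"),
                           stopped_epoch = attr(fit$history, "stopped_epoch"),
                           val_loss = losses[i])
    }
  }
  if (all(is.na(losses))) .stopInvalid("every grid cell failed to train")
  best <- which.min(losses)  # first minimum: fewest layers, then neurons
  bestCfg <- config
  bestCfg$n_hidden_layers <- as.integer(grid$layers[best])
  bestCfg$n_neurons <- as.integer(grid$neurons[best])
  list(best_config = bestCfg, best = best, grid = grid,
       val_loss = losses, results = results)
}

#' Serialise / restore a dense network as JSON
#'
#' @param fit an \code{NnModel}
#' @param path JSON file path
#' @return \code{writeNnModel}: the path, invisibly;
#'   \code{readNnModel}: an \code{NnModel}.
#' @export
writeNnModel <- function(fit, path) {
  jsonlite::write_json(list(n_classes = fit@nClasses, config = fit@config,
                            weights = fit@weights, biases = fit@biases),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeNnModel
#' @export
readNnModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("NnModel",
      weights = lapply(obj$weights, function(w) {
        w <- as.matrix(w)
        if (!is.numeric(w)) storage.mode(w) <- "double"
        w
      }),
      biases = lapply(obj$biases, as.numeric),
      nClasses = as.integer(obj$n_classes),
      config = as.list(obj$config))
}
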