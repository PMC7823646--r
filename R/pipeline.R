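# End-to-end experiment orchestration: simulate labelled scenes,
# extract and standardise features, tune and train both classifiers,
# and evaluate them one-vs-rest on the 30% hold-out — per camera
# position, from a single seeded configuration.

#' Experiment configuration
#'
#' A single master seed deterministically derives every stage seed
#' (fixed offsets per position and stage), so any stage can be re-run
#' in isolation and the whole experiment is reproducible bit-for-bit.
#'
#' The default sizes are desk scale: 3 cows per position, about 11,000
#' sampled pixels per scene (about 1e5 feature rows over the three
#' positions), a capped grid-search table and a reduced NN architecture
#' grid. \code{full_nn_grid = TRUE} requests the full 17 x 7
#' architecture sweep.
#'
#' @param positions camera positions to run (subset of U, N, S)
#' @param n_cows cows (= scenes) per position
#' @param sacrum_heights range the cow heights are drawn from, metres
#' @param body_lengths range the body lengths are drawn from, metres
#' @param noise_sigma depth noise, mm
#' @param pixels_per_scene eligible pixels sampled from each scene
#' @param holdout_fraction hold-out fraction (default 0.3)
#' @param scale_on_train fit the MinMax scaler on the training portion
#'   only (default); \code{FALSE} fits it on the full table before the
#'   split
#' @param smote_k SMOTE neighbourhood size
#' @param ks kNN grid
#' @param folds cross-validation folds
#' @param grid_cap row cap for the grid-search table
#' @param train_cap row cap (before SMOTE) for final classifier training
#' @param nn_grid data.frame(layers, neurons) architecture grid
#' @param full_nn_grid use \code{fullNnGrid()} instead of
#'   \code{nn_grid}
#' @param nn nn training settings, an \code{nnConfig()}
#' @param seed master seed
#' @return list of class \code{runConfig}
#' @export
runConfig <- function(positions = c("U", "N", "S"), n_cows = 3L,
                      sacrum_heights = c(1.43, 1.49),
                      body_lengths = c(2.2, 2.6),
                      noise_sigma = 2, pixels_per_scene = 11000L,
                      holdout_fraction = 0.3, scale_on_train = TRUE,
                      smote_k = 5L, ks = 1:20, folds = 5L,
                      grid_cap = 8000L, train_cap = 20000L,
                      nn_grid = expand.grid(layers = 1:2, neurons = c(10L, 50L)),
                      full_nn_grid = FALSE,
                      nn = nnConfig(max_epochs = 30L), seed = 1L) {
  bad <- character()
  if (!all(positions %in% c("U", "N", "S"))) bad <- c(bad, "positions")
  if (holdout_fraction <= 0 || holdout_fraction >= 1) bad <- c(bad, "holdout_fraction")
  if (noise_sigma < 0) bad <- c(bad, "noise_sigma")
  if (n_cows < 1L) bad <- c(bad, "n_cows")
  if (length(bad))
    .stopInvalid("invalid configuration keys: %s", paste(bad, collapse = ", "))
  structure(list(positions = positions, n_cows = as.integer(n_cows),
                 sacrum_heights = sacrum_heights, body_lengths = body_lengths,
                 noise_sigma = noise_sigma,
                 pixels_per_scene = as.integer(pixels_per_scene),
                 holdout_fraction = holdout_fraction,
                 scale_on_train = scale_on_train,
                 smote_k = as.integer(smote_k), ks = ks,
                 folds = as.integer(folds), grid_cap = as.integer(grid_cap),
                 train_cap = as.integer(train_cap), nn_grid = nn_grid,
                 full_nn_grid = full_nn_grid, nn = nn,
                 seed = as.integer(seed)),
            class = "runConfig")
}

# fixed per-position seed base; stage seeds are small offsets from it
.posSeed <- function(seed, position) {
  seed + 1000L * match(position, c("U", "N", "S"))
}

#' Simulate the labelled scenes of one camera position
#'
#' Renders \code{n_cows} scenes, one random cow each, from the
#' position's preset pose.
#'
#' @param config a \code{runConfig()}
#' @param position one of "U", "N", "S"
#' @return list of \code{DepthScene}
#' @export
simulateScenes <- function(config, position) {
  base <- .posSeed(config$seed, position)
  intr <- cameraIntrinsics()
  pose <- presetPose(position)
  lapply(seq_len(config$n_cows), function(i) {
    dims <- .withSeed(base + i, c(
      stats::runif(1, config$sacrum_heights[1], config$sacrum_heights[2]),
      stats::runif(1, config$body_lengths[1], config$body_lengths[2])))
    cow <- buildCow(dims[1], dims[2], seed = base + i)
    renderDepth(cow, intr, pose, noise_sigma = config$noise_sigma,
                seed = base + 50L + i)
  })
}

#' Feature table of one camera position
#'
#' Extracts per-pixel features from every scene, subsamples
#' \code{pixels_per_scene} rows per scene (seeded), and stacks them.
#'
#' @param config a \code{runConfig()}
#' @param scenes list of \code{DepthScene} (from
#'   \code{simulateScenes})
#' @param position camera position tag
#' @return A \code{FeatureTable}.
#' @export
positionFeatureTable <- function(config, scenes, position) {
  base <- .posSeed(config$seed, position)
  parts <- lapply(seq_along(scenes), function(i) {
    tab <- extractFeatures(scenes[[i]])
    df <- tab@data
    if (nrow(df) > config$pixels_per_scene) {
      keep <- .withSeed(base + 60L + i,
                        sort(sample.int(nrow(df), config$pixels_per_scene)))
      df <- df[keep, , drop = FALSE]
    }
    df
  })
  new("FeatureTable", data = do.call(rbind, parts), position = position)
}

# class indices 1..n_classes of a table, relative to the position's
# class set (no Ud column for position U)
.classIndices <- function(table) {
  classes <- .positionClasses(table@position)
  global <- partLabels(table)
  y <- match(.BODY_PARTS[global], classes)
  if (anyNA(y)) .stopInvalid("table contains classes outside the position's set")
  list(y = as.integer(y), classes = classes)
}

.capRows <- function(df, y, cap, seed) {
  if (nrow(df) <= cap) return(seq_len(nrow(df)))
  .withSeed(seed, {
    # proportional stratified thinning, at least 2 rows per class
    keep <- integer(0)
    for (cl in unique(y)) {
      rows <- which(y == cl)
      take <- max(2L, round(cap * length(rows) / nrow(df)))
      keep <- c(keep, if (length(rows) <= take) rows else sample(rows, take))
    }
    sort(keep)
  })
}

#' Run one camera position end to end
#'
#' Simulates, extracts, standardises, splits off the hold-out, tunes
#' and trains both classifiers (SMOTE strictly inside each fold or
#' validation split) and evaluates them one-vs-rest on the hold-out.
#'
#' @param config a \code{runConfig()}
#' @param position one of "U", "N", "S"
#' @return list with the hold-out reports for both methods, the chosen
#'   kNN k and per-k CV accuracies, the chosen NN architecture, row
#'   counts, and the fitted models
#' @export
runPosition <- function(config, position) {
  base <- .posSeed(config$seed, position)
  scenes <- simulateScenes(config, position)
  table <- positionFeatureTable(config, scenes, position)
  if (!config$scale_on_train)  # leakage variant: scale before splitting
    table <- minmaxApply(table, minmaxFit(table))
  split <- splitHoldout(table, config$holdout_fraction, seed = base + 70L)
  if (config$scale_on_train) {
    params <- minmaxFit(split$train)
    split$train <- minmaxApply(split$train, params)
    split$holdout <- minmaxApply(split$holdout, params)
  }
  tr <- .classIndices(split$train)
  ho <- .classIndices(split$holdout)
  xtr <- as.matrix(split$train@data[, .featureCols])
  xho <- as.matrix(split$holdout@data[, .featureCols])

  # kNN: tune on a capped subsample, refit on the capped training set
  gi <- .capRows(split$train@data, tr$y, config$grid_cap, base + 80L)
  grid <- knnGridSearch(xtr[gi, , drop = FALSE], tr$y[gi], ks = config$ks,
                        folds = config$folds, seed = base + 81L,
                        smote = smoteConfig(config$smote_k, seed = base + 82L))
  ti <- .capRows(split$train@data, tr$y, config$train_cap, base + 83L)
  bal <- smoteOversample(xtr[ti, , drop = FALSE], tr$y[ti],
                         smoteConfig(config$smote_k, seed = base + 84L))
  knn <- knnFit(bal$x, bal$y, grid$chosen_k, classes = tr$classes)
  knnPred <- knnPredict(knn, xho)
  knnReport <- metricsReport(ho$y, knnPred, tr$classes, "knn", position)

  # NN: architecture search, then final training (its own val split +
  # SMOTE live inside nnTrain)
  nnCfg <- config$nn
  nnCfg$seed <- base + 90L
  nnGrid <- if (config$full_nn_grid) fullNnGrid() else config$nn_grid
  search <- nnGridSearch(xtr[gi, , drop = FALSE], tr$y[gi],
                         n_classes = length(tr$classes),
                         grid = nnGrid, config = nnCfg)
  bestCfg <- search$best_config
  fit <- nnTrain(nnBuild(bestCfg, length(tr$classes)),
                 xtr[ti, , drop = FALSE], tr$y[ti], bestCfg,
                 smote_k = config$smote_k)
  nnPred <- nnPredict(fit$model, xho)$labels
  nnReport <- metricsReport(ho$y, nnPred, tr$classes, "nn", position)

  list(position = position, n_train = nrow(xtr), n_holdout = nrow(xho),
       chosen_k = grid$chosen_k, knn_cv_accuracy = grid$mean_accuracy,
       knn_report = knnReport, nn_report = nnReport,
       nn_architecture = c(layers = bestCfg$n_hidden_layers,
                           neurons = bestCfg$n_neurons),
       knn_model = knn, nn_model = fit$model, nn_history = fit$history)
}

#' Run the full experiment
#'
#' Runs every configured camera position end to end and adds the
#' Kruskal-Wallis comparisons of the per-class one-vs-rest metrics,
#' grouped by classification method and (when more than one position
#' ran) by camera position. When \code{out_dir} is given, metrics JSON,
#' a combined metrics CSV and the per-position training histories are
#' written there.
#'
#' @param config a \code{runConfig()}
#' @param out_dir optional output directory
#' @return list with per-position results (\code{positions}) and the
#'   statistical comparisons (\code{kw_method}, \code{kw_position})
#' @export
runExperiment <- function(config = runConfig(), out_dir = NULL) {
  results <- lapply(config$positions, function(p) runPosition(config, p))
  names(results) <- config$positions
  reports <- unlist(lapply(results, function(r)
    list(r$knn_report, r$nn_report)), recursive = FALSE)
  kwMethod <- lapply(config$positions, function(p)
    compareReports(list(results[[p]]$knn_report, results[[p]]$nn_report),
                   by = "method"))
  names(kwMethod) <- config$positions
  kwPosition <- NULL
  if (length(config$positions) > 1L) {
    knnReports <- lapply(results, function(r) r$knn_report)
    kwPosition <- compareReports(knnReports, by = "position")
  }
  out <- list(config = config, positions = results,
              kw_method = kwMethod, kw_position = kwPosition)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (p in config$positions) {
      writeMetricsJSON(results[[p]]$knn_report,
                       file.path(out_dir, sprintf("metrics_%s_knn.json", p)))
      writeMetricsJSON(results[[p]]$nn_report,
                       file.path(out_dir, sprintf("metrics_%s_nn.json", p)))
      utils::write.csv(results[[p]]$nn_history,
                       file.path(out_dir, sprintf("history_%s_nn.csv", p)),
                       row.names = FALSE)
    }
    reportsToCSV(reports, file.path(out_dir, "metrics.csv"))
  }
  out
}

#' File-based pipeline stages
#'
#' Thin wrappers used by the command-line interface:
#' \code{stageSimulate} writes the scenes of every configured position
#' as PGM pairs plus JSON sidecars; \code{stageExtract} turns the
#' scene files back into per-position feature CSVs;
#' \code{trainFromCSV} fits a classifier from a feature CSV (a table
#' with no rows is a validation error).
#'
#' @param config a \code{runConfig()}
#' @param dir scene / feature directory
#' @param csv feature CSV path
#' @param position camera position tag
#' @param method "knn" or "nn"
#' @return \code{stageSimulate}, \code{stageExtract}: written file
#'   stems/paths, invisibly. \code{trainFromCSV}: the fitted model.
#' @export
stageSimulate <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stems <- character(0)
  for (p in config$positions) {
    scenes <- simulateScenes(config, p)
    for (i in seq_along(scenes)) {
      stem <- file.path(dir, sprintf("scene_%s_%02d", p, i))
      sceneToPGM(scenes[[i]], stem)
      stems <- c(stems, stem)
    }
  }
  invisible(stems)
}

#' @rdname stageSimulate
#' @export
stageExtract <- function(config, dir) {
  paths <- character(0)
  for (p in config$positions) {
    stems <- sub("\\.depth\\.pgm$", "",
                 list.files(dir, sprintf("^scene_%s_.*\\.depth\\.pgm$", p),
                            full.names = TRUE))
    if (!length(stems))
      .stopInvalid("no scene files for position %s under %s", p, dir)
    scenes <- lapply(sort(stems), pgmToScene)
    table <- positionFeatureTable(config, scenes, p)
    path <- file.path(dir, sprintf("features_%s.csv", p))
    writeFeatureCSV(table, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' @rdname stageSimulate
#' @export
trainFromCSV <- function(csv, position, method = c("knn", "nn"),
                         config = runConfig()) {
  method <- match.arg(method)
  table <- readFeatureCSV(csv, position)
  if (!nrow(table@data))
    .stopInvalid("feature table %s is empty; nothing to train on", csv)
  table <- minmaxApply(table, minmaxFit(table))
  cls <- .classIndices(table)
  x <- as.matrix(table@data[, .featureCols])
  base <- .posSeed(config$seed, position)
  if (method == "knn") {
    gi <- .capRows(table@data, cls$y, config$grid_cap, base + 80L)
    grid <- knnGridSearch(x[gi, , drop = FALSE], cls$y[gi], ks = config$ks,
                          folds = config$folds, seed = base + 81L,
                          smote = smoteConfig(config$smote_k, seed = base + 82L))
    bal <- smoteOversample(x, cls$y,
                           smoteConfig(config$smote_k, seed = base + 84L))
    knnFit(bal$x, bal$y, grid$chosen_k, classes = cls$classes)
  } else {
    cfg <- config$nn
    cfg$seed <- base + 90L
    nnTrain(nnBuild(cfg, length(cls$classes)), x, cls$y, cfg,
            smote_k = config$smote_k)$model
  }
}
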