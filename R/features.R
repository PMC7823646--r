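# Per-pixel features: row/col position, depth, discrete mean curvature
# and local variance from the nine-pixel-square, plus one-hot responses,
# MinMax standardisation and hold-out splitting.

#' Gradient and Hessian of a nine-pixel depth patch
#'
#' Central differences on the 3x3 neighbourhood with unit pixel spacing:
#' the gradient holds the column- and row-direction first derivatives,
#' the Hessian the second derivatives, with the mixed term from the
#' four-corner cross difference. Central differences are exact on
#' quadratic surfaces. The patch must be background-free (no zeros).
#'
#' @param patch 3x3 numeric matrix of depth values (mm), centre pixel at
#'   [2,2]
#' @return list with \code{g} (length-2 gradient, mm/pixel) and \code{H}
#'   (2x2 symmetric Hessian, mm/pixel^2)
#' @examples
#' gradientHessian(matrix(900, 3, 3))  # flat: zero gradient and Hessian
#' @export
gradientHessian <- function(patch) {
  patch <- as.matrix(patch)
  if (!all(dim(patch) == c(3L, 3L)))
    .stopInvalid("patch must be a 3x3 matrix")
  if (any(patch == 0))
    .stopInvalid("incomplete patch: contains background (zero) pixels")
  gx <- (patch[2, 3] - patch[2, 1]) / 2
  gy <- (patch[3, 2] - patch[1, 2]) / 2
  hxx <- patch[2, 3] - 2 * patch[2, 2] + patch[2, 1]
  hyy <- patch[3, 2] - 2 * patch[2, 2] + patch[1, 2]
  hxy <- (patch[3, 3] - patch[3, 1] - patch[1, 3] + patch[1, 1]) / 4
  list(g = c(gx, gy), H = matrix(c(hxx, hxy, hxy, hyy), 2, 2))
}

#' Mean curvature from surface derivatives
#'
#' Evaluates the mean-curvature score of a depth surface from its
#' gradient g and Hessian H:
#' \deqn{(g H g^T - |g|^2 \mathrm{Tr}(H)) / (2 |g|^3)}
#' with Tr(H) the sum of the diagonal elements. A vanishing gradient
#' makes the expression 0/0; by convention the score is then 0.
#'
#' @param g length-2 gradient
#' @param H 2x2 symmetric Hessian
#' @return scalar curvature score
#' @examples
#' meanCurvature(c(1, 0), diag(2))   # -0.5
#' meanCurvature(c(0, 0), diag(2))   # 0 by convention
#' @export
meanCurvature <- function(g, H) {
  ng <- sqrt(sum(g * g))
  if (ng == 0) return(0)
  as.numeric((g %*% H %*% g - ng^2 * (H[1, 1] + H[2, 2])) / (2 * ng^3))
}

#' Local depth variance of a nine-pixel patch
#'
#' Sample variance (denominator n-1 = 8) of the nine depth values. The
#' patch must be background-free.
#'
#' @param patch 3x3 numeric matrix of depth values (mm)
#' @return variance in mm^2
#' @examples
#' localVariance(matrix(c(rep(900, 7), 901, 901), 3, 3))  # 126/648
#' @export
localVariance <- function(patch) {
  patch <- as.matrix(patch)
  if (!all(dim(patch) == c(3L, 3L)))
    .stopInvalid("patch must be a 3x3 matrix")
  if (any(patch == 0))
    .stopInvalid("incomplete patch: contains background (zero) pixels")
  stats::var(as.vector(patch))
}

#' Rasterise labelled polygons into a label mask
#'
#' Programmatic replacement for interactive polygon labelling: each
#' pixel strictly inside a polygon (even-odd rule, pixel centres at
#' integer coordinates) receives that polygon's part index; pixels in no
#' polygon stay 0; where polygons overlap, the later polygon in the list
#' wins.
#'
#' @param height,width mask dimensions in pixels
#' @param polygons list of polygons, each a list with \code{vertices}
#'   (n x 2 matrix of (row, col) points, 0-based) and \code{part} (a
#'   body-part code)
#' @return height x width integer label mask (0-based pixel (r, c) at
#'   matrix entry [r+1, c+1])
#' @examples
#' sq <- list(vertices = rbind(c(2, 2), c(2, 6), c(6, 6), c(6, 2)),
#'            part = "He")
#' mask <- labelByPolygons(10L, 10L, list(sq))
#' mask[5, 5]  # pixel (4,4) -> 1 (He)
#' @export
labelByPolygons <- function(height, width, polygons) {
  mask <- matrix(0L, nrow = height, ncol = width)
  for (poly in polygons) {
    v <- as.matrix(poly$vertices)
    if (nrow(v) < 3L)
      .stopInvalid("polygon must have at least 3 vertices")
    part <- match(poly$part, .BODY_PARTS)
    if (is.na(part)) .stopInvalid("unknown body-part code: %s", poly$part)
    rs <- v[, 1]; cs <- v[, 2]
    rmin <- max(0L, floor(min(rs))); rmax <- min(height - 1L, ceiling(max(rs)))
    cmin <- max(0L, floor(min(cs))); cmax <- min(width - 1L, ceiling(max(cs)))
    if (rmin > rmax || cmin > cmax) next
    pr <- rep(rmin:rmax, times = cmax - cmin + 1L)
    pc <- rep(cmin:cmax, each = rmax - rmin + 1L)
    inside <- rep(FALSE, length(pr))
    boundary <- rep(FALSE, length(pr))
    n <- nrow(v)
    jj <- n
    for (ii in seq_len(n)) {  # even-odd ray crossing in (row, col) plane
      r1 <- rs[ii]; c1 <- cs[ii]; r2 <- rs[jj]; c2 <- cs[jj]
      crosses <- ((c1 > pc) != (c2 > pc)) &
        (pr < (r2 - r1) * (pc - c1) / (c2 - c1) + r1)
      crosses[is.na(crosses)] <- FALSE
      inside <- xor(inside, crosses)
      # points exactly on this edge are not strictly interior
      collinear <- abs((r2 - r1) * (pc - c1) - (c2 - c1) * (pr - r1)) < 1e-9
      onseg <- collinear &
        pr >= pmin(r1, r2) - 1e-9 & pr <= pmax(r1, r2) + 1e-9 &
        pc >= pmin(c1, c2) - 1e-9 & pc <= pmax(c1, c2) + 1e-9
      boundary <- boundary | onseg
      jj <- ii
    }
    inside <- inside & !boundary
    mask[cbind(pr[inside] + 1L, pc[inside] + 1L)] <- part
  }
  mask
}

#' Extract the per-pixel feature table from a labelled scene
#'
#' Builds one row per labelled foreground pixel whose full 3x3
#' neighbourhood is foreground and inside the image: the five predictors
#' (0-based row and column index, depth in mm, mean curvature, local
#' variance) and the one-hot body-part response. Border pixels and
#' pixels whose patch touches background are skipped, so curvature and
#' variance are never contaminated by zeroed background.
#'
#' @param scene a \code{DepthScene}
#' @return A \code{FeatureTable}; empty (0 rows) if no pixel is eligible.
#' @export
extractFeatures <- function(scene) {
  d <- scene@depth
  lab <- scene@labels
  H <- nrow(d); W <- ncol(d)
  shift <- function(m, dr, dc) {
    out <- matrix(0, H, W)
    out[(1 + max(0, -dr)):(H - max(0, dr)), (1 + max(0, -dc)):(W - max(0, dc))] <-
      m[(1 + max(0, dr)):(H - max(0, -dr)), (1 + max(0, dc)):(W - max(0, -dc))]
    out
  }
  # neighbours: n/s along rows, w/e along columns
  nN <- shift(d, -1, 0); nS <- shift(d, 1, 0)
  nW <- shift(d, 0, -1); nE <- shift(d, 0, 1)
  nNW <- shift(d, -1, -1); nNE <- shift(d, -1, 1)
  nSW <- shift(d, 1, -1); nSE <- shift(d, 1, 1)
  interior <- matrix(FALSE, H, W)
  interior[2:(H - 1), 2:(W - 1)] <- TRUE
  eligible <- lab > 0 & d > 0 & interior &
    nN > 0 & nS > 0 & nW > 0 & nE > 0 &
    nNW > 0 & nNE > 0 & nSW > 0 & nSE > 0
  idx <- which(eligible)
  pos <- scene@pose@preset
  if (!length(idx)) {
    empty <- as.data.frame(matrix(numeric(0), ncol = 13,
                                  dimnames = list(NULL, c(.featureCols, .BODY_PARTS))))
    return(new("FeatureTable", data = empty, position = pos))
  }
  r <- ((idx - 1L) %% H)       # 0-based row
  c0 <- ((idx - 1L) %/% H)     # 0-based col
  f <- d[idx]
  gx <- (nE[idx] - nW[idx]) / 2
  gy <- (nS[idx] - nN[idx]) / 2
  hxx <- nE[idx] - 2 * f + nW[idx]
  hyy <- nS[idx] - 2 * f + nN[idx]
  hxy <- (nSE[idx] - nSW[idx] - nNE[idx] + nNW[idx]) / 4
  ng2 <- gx * gx + gy * gy
  ng <- sqrt(ng2)
  num <- gx * gx * hxx + 2 * gx * gy * hxy + gy * gy * hyy -
    ng2 * (hxx + hyy)
  m_curv <- ifelse(ng > 0, num / (2 * ng^3), 0)
  s1 <- f + nN[idx] + nS[idx] + nW[idx] + nE[idx] +
    nNW[idx] + nNE[idx] + nSW[idx] + nSE[idx]
  s2 <- f^2 + nN[idx]^2 + nS[idx]^2 + nW[idx]^2 + nE[idx]^2 +
    nNW[idx]^2 + nNE[idx]^2 + nSW[idx]^2 + nSE[idx]^2
  v <- (s2 - s1^2 / 9) / 8
  v[v < 0] <- 0  # guard against negative round-off on constant patches
  onehot <- matrix(0L, length(idx), 8L, dimnames = list(NULL, .BODY_PARTS))
  onehot[cbind(seq_along(idx), lab[idx])] <- 1L
  df <- data.frame(row = r, col = c0, depth = f, m_curv = m_curv, var = v)
  df <- cbind(df, as.data.frame(onehot))
  new("FeatureTable", data = df, position = pos)
}

#' Fit / apply MinMax standardisation
#'
#' \code{minmaxFit} records the per-feature minimum and maximum of the
#' five predictors; \code{minmaxApply} maps each feature to
#' (x - min) / (max - min). A constant feature maps to 0. Values outside
#' the fitted range are not clipped, so unseen data may fall outside
#' [0, 1]. Response columns are untouched.
#'
#' @param table a \code{FeatureTable}
#' @param params scaler parameters from \code{minmaxFit}
#' @return \code{minmaxFit}: list with \code{min} and \code{max}
#'   (named length-5 vectors). \code{minmaxApply}: the standardised
#'   \code{FeatureTable}.
#' @examples
#' # a feature column {2, 4, 6} maps to {0, 0.5, 1}
#' @export
minmaxFit <- function(table) {
  df <- table@data
  if (!nrow(df)) .stopInvalid("cannot fit a scaler on an empty table")
  x <- as.matrix(df[, .featureCols])
  list(min = apply(x, 2, min), max = apply(x, 2, max))
}

#' @rdname minmaxFit
#' @export
minmaxApply <- function(table, params) {
  df <- table@data
  if (nrow(df)) {
    for (col in .featureCols) {
      rng <- params$max[[col]] - params$min[[col]]
      df[[col]] <- if (rng > 0) (df[[col]] - params$min[[col]]) / rng
                   else rep(0, nrow(df))
    }
  }
  new("FeatureTable", data = df, position = table@position)
}

#' Split off a hold-out set
#'
#' Splits a feature table into disjoint, exhaustive train and hold-out
#' portions. With \code{stratified = TRUE} (default) the split is drawn
#' per class, preserving class proportions within one row per class;
#' otherwise rows are drawn at random. Deterministic per seed.
#'
#' @param table a \code{FeatureTable}
#' @param fraction hold-out fraction in (0, 1); default 0.3
#' @param seed integer seed
#' @param stratified preserve per-class proportions?
#' @return list with \code{train} and \code{holdout} feature tables
#' @export
splitHoldout <- function(table, fraction = 0.3, seed = 1L,
                         stratified = TRUE) {
  if (fraction <= 0 || fraction >= 1)
    .stopInvalid("fraction must lie strictly between 0 and 1")
  df <- table@data
  n <- nrow(df)
  cls <- partLabels(table)
  hold <- .withSeed(seed, {
    if (stratified) {
      out <- integer(0)
      for (k in sort(unique(cls))) {
        rows <- which(cls == k)
        nh <- round(fraction * length(rows))
        out <- c(out, sample(rows, nh))
      }
      sort(out)
    } else {
      sort(sample.int(n, round(fraction * n)))
    }
  })
  list(train = new("FeatureTable", data = df[setdiff(seq_len(n), hold), , drop = FALSE],
                   position = table@position),
       holdout = new("FeatureTable", data = df[hold, , drop = FALSE],
                     position = table@position))
}

#' Write / read a feature table as CSV
#'
#' The CSV carries exactly the canonical header
#' \code{No,row,col,depth,m_curv,var,He,Ru,Ba,fFL,aFL,fHL,aHL,Ud}, with
#' m_curv printed to 2 and var to 4 decimals (matching the package's
#' tabular display convention); \code{raw = TRUE} writes full precision.
#'
#' @param table a \code{FeatureTable}
#' @param path CSV file path
#' @param position camera position tag to attach on read
#' @param raw write features at full precision instead of display
#'   rounding?
#' @return \code{writeFeatureCSV}: the path, invisibly.
#'   \code{readFeatureCSV}: a \code{FeatureTable}.
#' @export
writeFeatureCSV <- function(table, path, raw = TRUE) {
  df <- table@data
  out <- cbind(No = seq_len(nrow(df)) - 1L, df)
  if (!raw && nrow(df)) {
    out$m_curv <- sprintf("%.2f", out$m_curv)
    out$var <- sprintf("%.4f", out$var)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFeatureCSV
#' @export
readFeatureCSV <- function(path, position) {
  df <- utils::read.csv(path)
  need <- c("No", .featureCols, .BODY_PARTS)
  if (!all(need %in% names(df)))
    .stopInvalid("feature CSV %s lacks the canonical header", path)
  new("FeatureTable", data = df[, c(.featureCols, .BODY_PARTS)],
      position = position)
}
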