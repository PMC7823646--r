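# Synthetic depth-scene generation: a cow-like composite of labelled
# quadric primitives rendered by analytic ray casting from the recording
# unit's three camera positions. World frame: x = walking direction,
# y = across the passage (cameras at negative y), z = up; metres.

# run expr under a temporary RNG state so generators do not clobber the
# caller's stream
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

.lookAt <- function(eye, target, flipped = FALSE) {
  z <- target - eye
  z <- z / sqrt(sum(z^2))
  up <- c(0, 0, 1)
  x <- c(z[2] * up[3] - z[3] * up[2],
         z[3] * up[1] - z[1] * up[3],
         z[1] * up[2] - z[2] * up[1])
  x <- x / sqrt(sum(x^2))
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  if (flipped) { x <- -x; y <- -y }  # 180 deg about the optical axis
  cbind(x, y, z, deparse.level = 0)
}

#' Preset camera poses of the recording unit
#'
#' Returns the rigid pose for one of the three camera position types:
#' \describe{
#'   \item{S}{side-view camera 0.6 m above ground, horizontal line of
#'     sight across the passage;}
#'   \item{N}{lower top-view camera, mounted normally, with a shallow
#'     downward-inward diagonal line of sight;}
#'   \item{U}{upper top-view camera, mounted upside down (base up), with
#'     a steep downward-inward diagonal line of sight. From this
#'     position the udder is hidden below the rump and back.}
#' }
#' The heights and pitch of the top-view cameras are configurable; the
#' defaults place N at 1.75 m looking down about 20 degrees and U at
#' 3.3 m looking down steeply (about 75 degrees).
#'
#' @param position one of "U", "N", "S"
#' @param passage_width passage width in metres (side cameras stand
#'   beyond the passage wall; default 2)
#' @param top_height mounting height of the top-view cameras in metres:
#'   c(N, U)
#' @return A \code{CameraPose}.
#' @examples
#' presetPose("S")@translation[3]  # 0.6 m
#' presetPose("U")@flipped         # TRUE
#' @export
presetPose <- function(position, passage_width = 2.0,
                       top_height = c(N = 1.75, U = 3.3)) {
  if (length(position) != 1L || !position %in% c("U", "N", "S"))
    .stopInvalid("unknown camera position code: %s",
                 paste(position, collapse = ","))
  if (passage_width <= 0) .stopInvalid("passage_width must be positive")
  half <- passage_width / 2
  if (position == "S") {
    eye <- c(0, -(half + 1.8), 0.6)
    target <- c(0, 0, 0.6)        # horizontal optical axis
    flipped <- FALSE
  } else if (position == "N") {
    eye <- c(0, -(half + 1.7), top_height[["N"]])
    target <- c(0, 0, 0.75)
    flipped <- FALSE
  } else {
    eye <- c(0, -0.45, top_height[["U"]])
    target <- c(0, 0.05, 0.95)
    flipped <- TRUE
  }
  new("CameraPose", preset = position, rotation = .lookAt(eye, target, flipped),
      translation = eye, flipped = flipped)
}

.primitive <- function(shape, center, size, part,
                       orientation = diag(3)) {
  new("Primitive", shape = shape, center = center, size = size,
      orientation = orientation, part = part)
}

#' Build a parametric cow model
#'
#' Assembles a labelled composite of quadric primitives: ellipsoids for
#' head, back (barrel), rump and udder, capped vertical cylinders for
#' the four legs. The composite is scaled so the top of the back sits at
#' \code{sacrum_height} and the horizontal extent follows
#' \code{body_length}; the seed adds a small (about 2\%) deterministic
#' shape jitter so different animals differ. The udder is tucked under
#' the rump between the hind legs, so it is occluded from steep top
#' views but visible from the side.
#'
#' @param sacrum_height height of the sacrum above ground in metres
#'   (herd range 1.43--1.49)
#' @param body_length nominal body length in metres
#' @param seed integer seed for the shape jitter
#' @return A \code{CowModel}.
#' @examples
#' cow <- buildCow(1.46, 2.4, seed = 7)
#' length(cow@primitives)
#' @export
buildCow <- function(sacrum_height = 1.46, body_length = 2.4, seed = 1L) {
  if (sacrum_height <= 0 || body_length <= 0)
    .stopInvalid("cow dimensions must be positive")
  sz <- sacrum_height / 1.46   # vertical scale
  sx <- body_length / 2.4      # longitudinal scale
  sy <- sz                     # girth follows height
  .withSeed(seed, {
    j <- function() 1 + stats::runif(1, -0.02, 0.02)
    base <- list(
      list("ellipsoid", c(-0.30, 0, 1.08), c(0.72, 0.30, 0.38), "Ba"),
      list("ellipsoid", c( 0.75, 0, 1.05), c(0.55, 0.30, 0.37), "Ru"),
      list("ellipsoid", c(-1.25, 0, 1.15), c(0.35, 0.15, 0.25), "He"),
      list("cylinder",  c(-0.72, -0.30, 0.40), c(0.07, 0.40), "fFL"),
      list("cylinder",  c(-0.72,  0.30, 0.40), c(0.07, 0.40), "aFL"),
      list("cylinder",  c( 1.00, -0.30, 0.40), c(0.07, 0.40), "fHL"),
      list("cylinder",  c( 1.00,  0.30, 0.40), c(0.07, 0.40), "aHL"),
      list("ellipsoid", c( 0.66, 0, 0.58), c(0.14, 0.12, 0.18), "Ud"))
    splay <- 14 * pi / 180   # legs lean outward so hooves clear the barrel
    prims <- lapply(base, function(b) {
      ctr <- b[[2]] * c(sx, sy, sz)
      if (b[[1]] == "ellipsoid") {
        size <- b[[3]] * c(sx, sy, sz) * c(j(), j(), j())
        ori <- diag(3)
      } else {
        size <- b[[3]] * c(sy, sz) * c(j(), j())
        a <- if (b[[2]][2] > 0) -splay else splay  # hoof swings outward
        ori <- rbind(c(1, 0, 0),
                     c(0, cos(a), -sin(a)),
                     c(0, sin(a), cos(a)))
      }
      .primitive(b[[1]], ctr, size, b[[4]], orientation = ori)
    })
    new("CowModel", primitives = prims, sacrumHeight = sacrum_height,
        bodyLength = body_length, seed = as.integer(seed))
  })
}

#' Axis-aligned bounding box of a primitive
#'
#' @param prim a \code{Primitive}
#' @return 2x3 matrix: rows min and max, columns x, y, z (metres).
#' @export
primitiveBBox <- function(prim) {
  if (prim@shape == "ellipsoid") half <- prim@size
  else half <- c(prim@size[1], prim@size[1], prim@size[2])
  # orientation is identity for all built cows; general case via corners
  M <- abs(prim@orientation) %*% half
  rbind(min = prim@center - as.vector(M), max = prim@center + as.vector(M))
}

# smallest positive root of a*t^2 + b*t + c = 0, vectorised; Inf = none
.smallestPositiveRoot <- function(a, b, c) {
  disc <- b * b - 4 * a * c
  t <- rep(Inf, length(a))
  ok <- disc >= 0 & a > 0
  sq <- sqrt(pmax(disc, 0))
  t1 <- (-b - sq) / (2 * a)
  t2 <- (-b + sq) / (2 * a)
  t[ok & t1 > 1e-9] <- t1[ok & t1 > 1e-9]
  sel <- ok & t1 <= 1e-9 & t2 > 1e-9
  t[sel] <- t2[sel]
  t
}

# ray/primitive intersection parameter for all rays; origin o (3-vector),
# dirs n x 3 (unnormalised; t is depth along the optical axis when the
# optical-axis component of dirs is 1)
.intersectPrimitive <- function(prim, o, dirs) {
  Q <- prim@orientation
  ol <- as.vector(crossprod(Q, o - prim@center))
  dl <- dirs %*% Q
  if (prim@shape == "ellipsoid") {
    s <- prim@size
    ox <- ol[1] / s[1]; oy <- ol[2] / s[2]; oz <- ol[3] / s[3]
    dx <- dl[, 1] / s[1]; dy <- dl[, 2] / s[2]; dz <- dl[, 3] / s[3]
    a <- dx * dx + dy * dy + dz * dz
    b <- 2 * (ox * dx + oy * dy + oz * dz)
    cc <- ox * ox + oy * oy + oz * oz - 1
    .smallestPositiveRoot(a, b, rep(cc, nrow(dirs)))
  } else {
    r <- prim@size[1]; h <- prim@size[2]
    ox <- ol[1]; oy <- ol[2]; oz <- ol[3]
    dx <- dl[, 1]; dy <- dl[, 2]; dz <- dl[, 3]
    a <- dx * dx + dy * dy
    b <- 2 * (ox * dx + oy * dy)
    cc <- ox * ox + oy * oy - r * r
    tside <- .smallestPositiveRoot(a, b, rep(cc, nrow(dirs)))
    zhit <- oz + tside * dz
    tside[!is.finite(tside) | abs(zhit) > h] <- Inf
    # caps
    tbest <- tside
    for (zc in c(-h, h)) {
      tc <- (zc - oz) / dz
      xc <- ox + tc * dx
      yc <- oy + tc * dy
      ok <- is.finite(tc) & tc > 1e-9 & (xc * xc + yc * yc) <= r * r
      better <- ok & tc < tbest
      tbest[better] <- tc[better]
    }
    tbest
  }
}

#' Render a labelled depth scene by ray casting
#'
#' Casts one viewing ray per pixel through the pinhole model and takes
#' the nearest analytic ray--primitive intersection. The stored depth is
#' the distance along the optical axis (z-depth) in integer millimetres,
#' with additive Gaussian noise of standard deviation \code{noise_sigma}
#' rounded to 1 mm; the label is the body part of the nearest primitive.
#' Pixels with no intersection, or whose noise-free depth falls outside
#' the working range, are background (depth 0, label 0).
#'
#' @param cow a \code{CowModel}, or a bare list of \code{Primitive}
#'   (possibly empty, giving an all-background scene)
#' @param intrinsics a \code{CameraIntrinsics}
#' @param pose a \code{CameraPose}
#' @param noise_sigma depth-noise standard deviation in mm (default 2)
#' @param seed integer seed for the noise
#' @param range working depth range in mm (default 500--4000)
#' @return A \code{DepthScene}.
#' @examples
#' sc <- renderDepth(buildCow(seed = 1), cameraIntrinsics(160L, 120L),
#'                   presetPose("S"), noise_sigma = 0, seed = 1)
#' sum(depthMap(sc) > 0)
#' @export
renderDepth <- function(cow, intrinsics, pose, noise_sigma = 2,
                        seed = 1L, range = c(500, 4000)) {
  if (noise_sigma < 0) .stopInvalid("noise_sigma must be >= 0")
  prims <- if (is(cow, "CowModel")) cow@primitives else cow
  W <- intrinsics@width; H <- intrinsics@height; f <- intrinsics@focal
  cols <- rep(seq_len(W) - 1L, each = H)
  rows <- rep(seq_len(H) - 1L, times = W)
  u <- (cols + 0.5 - W / 2) / f
  v <- (rows + 0.5 - H / 2) / f
  dirs <- cbind(u, v, 1) %*% t(pose@rotation)  # optical-axis component 1
  n <- length(u)
  tmin <- rep(Inf, n)
  lab <- integer(n)
  for (prim in prims) {
    t <- .intersectPrimitive(prim, pose@translation, dirs)
    closer <- t < tmin
    tmin[closer] <- t[closer]
    lab[closer] <- match(prim@part, .BODY_PARTS)
  }
  depth <- tmin * 1000
  bg <- !is.finite(depth) | depth < range[1] | depth > range[2]
  depth[bg] <- 0
  lab[bg] <- 0L
  if (noise_sigma > 0) {
    noise <- .withSeed(seed, stats::rnorm(n, 0, noise_sigma))
    fg <- !bg
    depth[fg] <- pmin(pmax(depth[fg] + noise[fg], range[1]), range[2])
  }
  depth <- round(depth)
  new("DepthScene",
      depth = matrix(as.integer(depth), nrow = H, ncol = W),
      labels = matrix(lab, nrow = H, ncol = W),
      pose = pose, noiseSigma = noise_sigma)
}

.writePGM <- function(mat, path, maxval, bytes) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n%d\n", ncol(mat), nrow(mat), maxval),
            con, eos = NULL)
  v <- as.integer(t(mat))  # row-major
  if (bytes == 2L) {
    raw <- as.raw(rbind(v %/% 256L, v %% 256L))  # big-endian
  } else {
    raw <- as.raw(v)
  }
  writeBin(raw, con)
  invisible(path)
}

.readPGM <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- character(0)
  buf <- character(0)
  # header tokens: magic, width, height, maxval (comments with #)
  while (length(tok) < 4L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) .stopInvalid("malformed PGM header in %s", path)
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[ \t\r\n]", ch)) {
      if (length(buf)) { tok <- c(tok, paste(buf, collapse = "")); buf <- character(0) }
    } else buf <- c(buf, ch)
  }
  if (tok[1] != "P5") .stopInvalid("not a binary PGM (P5) file: %s", path)
  w <- as.integer(tok[2]); h <- as.integer(tok[3]); maxval <- as.integer(tok[4])
  if (is.na(w) || is.na(h) || is.na(maxval) || w <= 0L || h <= 0L)
    .stopInvalid("malformed PGM header in %s", path)
  bytes <- if (maxval > 255L) 2L else 1L
  raw <- readBin(con, "raw", n = w * h * bytes)
  if (length(raw) < w * h * bytes)
    .stopInvalid("truncated PGM pixel data in %s", path)
  v <- as.integer(raw)
  if (bytes == 2L) v <- v[c(TRUE, FALSE)] * 256L + v[c(FALSE, TRUE)]
  list(mat = matrix(v, nrow = h, ncol = w, byrow = TRUE), maxval = maxval)
}

#' Write / read a depth scene as a PGM file pair
#'
#' \code{sceneToPGM} stores the depth map as a 16-bit binary PGM (P5,
#' maxval 65535, big-endian), the label mask as an 8-bit binary PGM, and
#' the pose/noise metadata in a sidecar JSON, under a common path stem.
#' \code{pgmToScene} reads the triple back; the round trip is bit-exact.
#'
#' @param scene a \code{DepthScene}
#' @param stem path stem; files \code{<stem>.depth.pgm},
#'   \code{<stem>.labels.pgm} and \code{<stem>.json} are written
#' @return \code{sceneToPGM}: the stem, invisibly. \code{pgmToScene}:
#'   a \code{DepthScene}.
#' @export
sceneToPGM <- function(scene, stem) {
  if (max(scene@depth) > 65535L) .stopInvalid("depth exceeds 16-bit range")
  .writePGM(scene@depth, paste0(stem, ".depth.pgm"), 65535L, 2L)
  .writePGM(scene@labels, paste0(stem, ".labels.pgm"), 255L, 1L)
  meta <- list(preset = scene@pose@preset,
               rotation = as.vector(scene@pose@rotation),  # column-major
               translation = scene@pose@translation,
               flipped = scene@pose@flipped,
               noise_sigma = scene@noiseSigma)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname sceneToPGM
#' @export
pgmToScene <- function(stem) {
  d <- .readPGM(paste0(stem, ".depth.pgm"))
  l <- .readPGM(paste0(stem, ".labels.pgm"))
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  pose <- new("CameraPose", preset = meta$preset,
              rotation = matrix(unlist(meta$rotation), 3L, 3L),
              translation = as.numeric(meta$translation),
              flipped = isTRUE(meta$flipped))
  new("DepthScene", depth = d$mat, labels = l$mat, pose = pose,
      noiseSigma = as.numeric(meta$noise_sigma))
}
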