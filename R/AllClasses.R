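#' Body-part codes in canonical column order
#'
#' The eight body parts distinguished by the classifiers, in the fixed
#' order used for one-hot response columns and integer label masks:
#' head (He), rump (Ru), back (Ba), facing foreleg (fFL), averted foreleg
#' (aFL), facing hindleg (fHL), averted hindleg (aHL), udder (Ud).
#' Label masks use 0 for background and 1..8 for these parts.
#'
#' @return Character vector of length 8.
#' @export
bodyParts <- function() c("He", "Ru", "Ba", "fFL", "aFL", "fHL", "aHL", "Ud")

.BODY_PARTS <- c("He", "Ru", "Ba", "fFL", "aFL", "fHL", "aHL", "Ud")

#' @title Camera intrinsics for the depth sensor
#'
#' @description Pinhole model of the structured-light depth sensor:
#' 640 x 480 resolution and a 57 degree horizontal field of view, from
#' which the focal length in pixels is derived as
#' (width/2) / tan(fov/2).
#'
#' @slot width image width in pixels
#' @slot height image height in pixels
#' @slot hfov horizontal field of view in degrees
#' @slot focal focal length in pixels (derived)
#' @exportClass CameraIntrinsics
setClass("CameraIntrinsics",
  representation(width = "integer", height = "integer",
                 hfov = "numeric", focal = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@width <= 0L || object@height <= 0L)
      msg <- c(msg, "width and height must be positive")
    if (object@hfov <= 0 || object@hfov >= 180)
      msg <- c(msg, "hfov must lie in (0, 180) degrees")
    expected <- (object@width / 2) / tan(object@hfov * pi / 360)
    if (abs(object@focal - expected) > 1e-6 * expected)
      msg <- c(msg, "focal inconsistent with width and hfov")
    if (length(msg)) msg else TRUE
  })

#' Construct camera intrinsics
#'
#' @param width image width in pixels
#' @param height image height in pixels
#' @param hfov horizontal field of view in degrees
#' @return A \code{CameraIntrinsics} object.
#' @examples
#' cameraIntrinsics()  # the sensor defaults: 640 x 480, 57 degrees
#' @export
cameraIntrinsics <- function(width = 640L, height = 480L, hfov = 57) {
  new("CameraIntrinsics", width = as.integer(width),
      height = as.integer(height), hfov = as.numeric(hfov),
      focal = (width / 2) / tan(hfov * pi / 360))
}

#' @title Camera pose (one of the recording unit's positions)
#'
#' @description Rigid camera placement in the world frame. The recording
#' unit defines three position types: 'S' (side view, 0.6 m above ground,
#' horizontal line of sight), and the top-view pair 'U' (upper camera,
#' mounted upside down) and 'N' (lower camera, mounted normally), both
#' with diagonal downward-inward lines of sight.
#'
#' @slot preset one of "U", "N", "S"
#' @slot rotation 3x3 orthonormal matrix, camera axes expressed in world
#'   coordinates (columns: camera x right, y down, z optical axis)
#' @slot translation camera centre in world coordinates, metres
#' @slot flipped logical; TRUE for 'U' (base up)
#' @exportClass CameraPose
setClass("CameraPose",
  representation(preset = "character", rotation = "matrix",
                 translation = "numeric", flipped = "logical"),
  validity = function(object) {
    msg <- character()
    if (!object@preset %in% c("U", "N", "S"))
      msg <- c(msg, "preset must be one of U, N, S")
    R <- object@rotation
    if (!all(dim(R) == c(3L, 3L)) ||
        max(abs(crossprod(R) - diag(3))) > 1e-8)
      msg <- c(msg, "rotation must be 3x3 orthonormal")
    if (length(object@translation) != 3L)
      msg <- c(msg, "translation must have length 3")
    if (length(msg)) msg else TRUE
  })

#' @title A labelled quadric primitive of the cow model
#'
#' @description One smooth surface patch of the synthetic cow: an
#' ellipsoid (head, rump, back, udder) or a capped cylinder (legs), with
#' the body-part label carried by every pixel whose nearest ray
#' intersection lies on it.
#'
#' @slot shape "ellipsoid" or "cylinder"
#' @slot center 3-vector, metres
#' @slot size for an ellipsoid the three semi-axes; for a cylinder
#'   c(radius, half_length), metres
#' @slot orientation 3x3 orthonormal matrix (local axes in world frame;
#'   a cylinder's axis is local z)
#' @slot part body-part code, one of \code{bodyParts()}
#' @exportClass Primitive
setClass("Primitive",
  representation(shape = "character", center = "numeric", size = "numeric",
                 orientation = "matrix", part = "character"),
  validity = function(object) {
    msg <- character()
    if (!object@shape %in% c("ellipsoid", "cylinder"))
      msg <- c(msg, "shape must be 'ellipsoid' or 'cylinder'")
    if (any(object@size <= 0)) msg <- c(msg, "size parameters must be > 0")
    if (!object@part %in% .BODY_PARTS)
      msg <- c(msg, "part must be one of the eight body-part codes")
    if (object@shape == "ellipsoid" && length(object@size) != 3L)
      msg <- c(msg, "ellipsoid needs three semi-axes")
    if (object@shape == "cylinder" && length(object@size) != 2L)
      msg <- c(msg, "cylinder needs c(radius, half_length)")
    if (length(msg)) msg else TRUE
  })

#' @title Parametric cow model
#'
#' @description Labelled composite of quadric primitives covering all
#' eight body parts, scaled to a sacrum height within the herd's range
#' (1.43--1.49 m) and a body length.
#'
#' @slot primitives list of \code{Primitive}
#' @slot sacrumHeight metres
#' @slot bodyLength metres
#' @slot seed integer used for the shape jitter
#' @exportClass CowModel
setClass("CowModel",
  representation(primitives = "list", sacrumHeight = "numeric",
                 bodyLength = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    parts <- vapply(object@primitives, function(p) p@part, character(1))
    missing <- setdiff(.BODY_PARTS, parts)
    if (length(missing))
      msg <- c(msg, paste("primitives missing body parts:",
                          paste(missing, collapse = ", ")))
    if (object@sacrumHeight <= 0 || object@bodyLength <= 0)
      msg <- c(msg, "dimensions must be positive")
    if (length(msg)) msg else TRUE
  })

#' @title A labelled synthetic depth scene
#'
#' @description A depth map in integer millimetres (0 = background) with
#' an aligned per-pixel body-part label mask (0 = background, 1..8 = part
#' index in \code{bodyParts()} order), the camera pose it was rendered
#' from, and the additive depth-noise level.
#'
#' @slot depth height x width integer matrix, millimetres
#' @slot labels height x width integer matrix
#' @slot pose \code{CameraPose}
#' @slot noiseSigma millimetres
#' @exportClass DepthScene
setClass("DepthScene",
  representation(depth = "matrix", labels = "matrix",
                 pose = "CameraPose", noiseSigma = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!all(dim(object@depth) == dim(object@labels)))
      msg <- c(msg, "depth and labels must have identical dimensions")
    if (any(object@depth < 0)) msg <- c(msg, "depth must be non-negative")
    if (any((object@depth == 0) != (object@labels == 0)))
      msg <- c(msg, "depth[p] == 0 must hold exactly where labels[p] == 0")
    if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' @title Per-pixel feature table
#'
#' @description One row per eligible labelled pixel, holding the five
#' predictors (row index, column index, depth in mm, mean curvature,
#' local variance) and the one-hot body-part responses. Tables from
#' camera position 'U' carry seven response classes (no udder), tables
#' from 'N' and 'S' carry eight.
#'
#' @slot data data.frame with columns row, col, depth, m_curv, var and
#'   the eight indicator columns He..Ud
#' @slot position camera position "U", "N" or "S"
#' @exportClass FeatureTable
setClass("FeatureTable",
  representation(data = "data.frame", position = "character"),
  validity = function(object) {
    msg <- character()
    need <- c("row", "col", "depth", "m_curv", "var", .BODY_PARTS)
    if (!all(need %in% names(object@data)))
      msg <- c(msg, "data must contain the five features and eight indicators")
    if (!object@position %in% c("U", "N", "S"))
      msg <- c(msg, "position must be one of U, N, S")
    if (nrow(object@data)) {
      oh <- as.matrix(object@data[, .BODY_PARTS])
      if (any(rowSums(oh) != 1))
        msg <- c(msg, "each row must have exactly one indicator equal to 1")
      if (object@position == "U" && any(object@data$Ud != 0))
        msg <- c(msg, "position U tables must not contain udder rows")
    }
    if (length(msg)) msg else TRUE
  })

#' @title Stored-exemplar k-nearest-neighbour classifier
#'
#' @description Training features (five standardised columns) and class
#' labels stored verbatim, plus the neighbourhood size k.
#'
#' @slot x numeric matrix of stored features
#' @slot y integer class labels (1..n_classes)
#' @slot k neighbourhood size
#' @slot classes character vector of class names
#' @exportClass KnnModel
setClass("KnnModel",
  representation(x = "matrix", y = "integer", k = "integer",
                 classes = "character"),
  validity = function(object) {
    msg <- character()
    if (object@k < 1L) msg <- c(msg, "k must be >= 1")
    if (object@k > nrow(object@x))
      msg <- c(msg, "k must not exceed the number of stored samples")
    if (length(object@y) != nrow(object@x))
      msg <- c(msg, "labels must match stored rows")
    if (length(msg)) msg else TRUE
  })

#' @title Dense feed-forward network
#'
#' @description A plain stack of dense layers: 5 inputs, ReLU hidden
#' layers of equal width with 15\% dropout after every second hidden
#' layer (training only), and a softmax output of 7 (position 'U') or 8
#' nodes.
#'
#' @slot weights list of weight matrices (in x out per layer)
#' @slot biases list of bias vectors
#' @slot nClasses output width
#' @slot config the \code{nnConfig()} list used to build/train it
#' @exportClass NnModel
setClass("NnModel",
  representation(weights = "list", biases = "list", nClasses = "integer",
                 config = "list"),
  validity = function(object) {
    msg <- character()
    nl <- length(object@weights)
    if (nl != length(object@biases))
      msg <- c(msg, "weights and biases must have equal length")
    if (nl) {
      if (ncol(object@weights[[nl]]) != object@nClasses)
        msg <- c(msg, "last layer width must equal nClasses")
      if (nrow(object@weights[[1L]]) != 5L)
        msg <- c(msg, "first layer must take 5 inputs")
      if (nl > 1L)
        for (i in seq_len(nl - 1L))
          if (ncol(object@weights[[i]]) != nrow(object@weights[[i + 1L]]))
            msg <- c(msg, "layer shapes must chain consistently")
    }
    if (length(msg)) msg else TRUE
  })

#' @title Hold-out evaluation report
#'
#' @description Per-class one-vs-rest precision, recall and F1 together
#' with overall accuracy and Hamming loss for one classifier on one
#' camera position.
#'
#' @slot perClass data.frame with columns class, precision, recall, f1
#' @slot accuracy overall accuracy
#' @slot hammingLoss overall Hamming loss
#' @slot method "knn" or "nn"
#' @slot position camera position
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(perClass = "data.frame", accuracy = "numeric",
                 hammingLoss = "numeric", method = "character",
                 position = "character"),
  validity = function(object) {
    msg <- character()
    vals <- c(object@accuracy, object@hammingLoss,
              object@perClass$precision, object@perClass$recall,
              object@perClass$f1)
    if (any(vals < -1e-12 | vals > 1 + 1e-12))
      msg <- c(msg, "all metrics must lie in [0, 1]")
    if (object@position == "U" && "Ud" %in% object@perClass$class)
      msg <- c(msg, "position U reports must not include Ud")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "CameraIntrinsics", function(object) {
  cat(sprintf("CameraIntrinsics: %d x %d px, hfov %.1f deg, focal %.2f px\n",
              object@width, object@height, object@hfov, object@focal))
})

setMethod("show", "CameraPose", function(object) {
  cat(sprintf("CameraPose '%s'%s at (%.2f, %.2f, %.2f) m\n", object@preset,
              if (object@flipped) " (flipped)" else "",
              object@translation[1], object@translation[2],
              object@translation[3]))
})

setMethod("show", "CowModel", function(object) {
  cat(sprintf("CowModel: %d primitives, sacrum height %.2f m, body length %.2f m (seed %d)\n",
              length(object@primitives), object@sacrumHeight,
              object@bodyLength, object@seed))
})

setMethod("show", "DepthScene", function(object) {
  fg <- sum(object@depth > 0)
  cat(sprintf("DepthScene (%s): %d x %d px, %d foreground px, %d labels, noise sigma %.1f mm\n",
              object@pose@preset, nrow(object@depth), ncol(object@depth),
              fg, length(setdiff(unique(as.vector(object@labels)), 0L)),
              object@noiseSigma))
})

setMethod("show", "FeatureTable", function(object) {
  counts <- colSums(object@data[, .BODY_PARTS, drop = FALSE])
  cat(sprintf("FeatureTable (position %s): %d rows\n", object@position,
              nrow(object@data)))
  print(counts[counts > 0])
})

setMethod("show", "KnnModel", function(object) {
  cat(sprintf("KnnModel: k = %d, %d stored samples, %d classes\n",
              object@k, nrow(object@x), length(object@classes)))
})

setMethod("show", "NnModel", function(object) {
  widths <- c(5L, vapply(object@weights, ncol, integer(1)))
  cat(sprintf("NnModel: %s (softmax output)\n",
              paste(widths, collapse = " -> ")))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport [%s, position %s]: accuracy %.3f, Hamming loss %.3f\n",
              object@method, object@position, object@accuracy,
              object@hammingLoss))
  df <- object@perClass
  df$precision <- sprintf("%.2f", df$precision)
  df$recall <- sprintf("%.2f", df$recall)
  df$f1 <- sprintf("%.2f", df$f1)
  print(df, row.names = FALSE)
})

#' @rdname accessors
#' @param object an object of one of the package's S4 classes
#' @export
setGeneric("depthMap", function(object) standardGeneric("depthMap"))
#' @rdname accessors
#' @export
setGeneric("labelMask", function(object) standardGeneric("labelMask"))
#' @rdname accessors
#' @export
setGeneric("cameraPosition", function(object) standardGeneric("cameraPosition"))
#' @rdname accessors
#' @export
setGeneric("featureData", function(object) standardGeneric("featureData"))
#' @rdname accessors
#' @export
setGeneric("partLabels", function(object) standardGeneric("partLabels"))

#' Accessors for the package's S4 containers
#'
#' \code{depthMap} and \code{labelMask} return a scene's matrices;
#' \code{cameraPosition} returns the position code of a scene, pose,
#' feature table or report; \code{featureData} returns a feature table's
#' underlying data.frame; \code{partLabels} returns the integer class
#' label (1..8) of each feature-table row.
#'
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
setMethod("depthMap", "DepthScene", function(object) object@depth)
#' @rdname accessors
setMethod("labelMask", "DepthScene", function(object) object@labels)
#' @rdname accessors
setMethod("cameraPosition", "DepthScene", function(object) object@pose@preset)
#' @rdname accessors
setMethod("cameraPosition", "CameraPose", function(object) object@preset)
#' @rdname accessors
setMethod("cameraPosition", "FeatureTable", function(object) object@position)
#' @rdname accessors
setMethod("cameraPosition", "MetricsReport", function(object) object@position)
#' @rdname accessors
setMethod("featureData", "FeatureTable", function(object) object@data)
#' @rdname accessors
setMethod("partLabels", "FeatureTable", function(object) {
  if (!nrow(object@data)) return(integer())
  oh <- as.matrix(object@data[, .BODY_PARTS])
  as.integer(max.col(oh, ties.method = "first"))
})

.featureCols <- c("row", "col", "depth", "m_curv", "var")

# classes present for a camera position: no udder for 'U'
.positionClasses <- function(position) {
  if (position == "U") .BODY_PARTS[.BODY_PARTS != "Ud"] else .BODY_PARTS
}

.stopInvalid <- function(...) stop(sprintf(...), call. = FALSE)
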