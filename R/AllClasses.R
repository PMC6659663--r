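#' @import methods
NULL

.FEATURE_NAMES <- c("SRE", "LRE", "GLN", "RLN", "RP",
                    "LGRE", "HGRE", "SRLGE", "SRHGE", "LRLGE", "LRHGE")

## classed conditions so callers can distinguish failure modes
.glrlmError <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "glrlmError")))
}

#' GrayImage: validated 2-D grayscale intensity grid
#'
#' The sole pixel container of the package. Pixels are stored as an integer
#' matrix indexed (row, column) with the origin at the top-left corner; the
#' positive x axis points right (columns) and the positive y axis points
#' down (rows). All intensities must lie in \code{[0, glResolution - 1]}.
#'
#' @slot pixels integer matrix of intensities.
#' @slot glResolution single integer, the number of gray levels G.
#'
#' @seealso [grayImage()] for the validating constructor.
#' @exportClass GrayImage
setClass("GrayImage",
  representation(pixels = "matrix", glResolution = "integer"),
  validity = function(object) {
    px <- object@pixels
    if (!is.numeric(px)) return("pixels must be a numeric matrix")
    if (nrow(px) < 1L || ncol(px) < 1L) return("image must be at least 1x1")
    if (length(object@glResolution) != 1L || object@glResolution < 1L)
      return("glResolution must be a single positive integer")
    if (any(px != floor(px))) return("pixel intensities must be integers")
    if (any(px < 0 | px >= object@glResolution))
      return(sprintf("intensities must lie in [0, %d]",
                     object@glResolution - 1L))
    TRUE
  })

#' Direction: one of the four principal run directions
#'
#' Directions are expressed as unit steps \code{(dx, dy)} with dx the column
#' step and dy the row step, y increasing downwards: horizontal 0\eqn{^\circ}
#' is (1, 0), anti-diagonal 45\eqn{^\circ} is (1, -1), vertical
#' 90\eqn{^\circ} is (0, -1) and diagonal 135\eqn{^\circ} is (-1, -1).
#'
#' @slot name one of \code{"H0"}, \code{"AD45"}, \code{"V90"}, \code{"D135"}.
#' @slot dx,dy integer unit steps (column, row).
#'
#' @exportClass Direction
setClass("Direction",
  representation(name = "character", dx = "integer", dy = "integer"),
  validity = function(object) {
    steps <- list(H0 = c(1L, 0L), AD45 = c(1L, -1L),
                  V90 = c(0L, -1L), D135 = c(-1L, -1L))
    if (!(object@name %in% names(steps)))
      return("direction name must be one of H0, AD45, V90, D135")
    if (!identical(c(object@dx, object@dy), steps[[object@name]]))
      return(sprintf("(dx, dy) inconsistent with direction %s", object@name))
    TRUE
  })

#' ROISpec: sliding-window geometry
#'
#' Describes the rectangular region of interest glided pixel by pixel over
#' the image. \code{roiLength(x)}, the key multiplier used when run lengths
#' are packed into integer keys, is \code{max(roiWidth, roiHeight)};
#' \code{nPixels(x)} is \code{roiWidth * roiHeight} (the N of the run-length
#' mass identity). \code{levelOffset} is added to raw intensities when
#' gray-level-weighted features are computed, so that intensity 0 remains
#' representable under inverse-square gray weights.
#'
#' @slot roiWidth,roiHeight integer window dimensions (columns, rows).
#' @slot levelOffset single non-negative integer, default 1.
#'
#' @exportClass ROISpec
setClass("ROISpec",
  representation(roiWidth = "integer", roiHeight = "integer",
                 levelOffset = "integer"),
  validity = function(object) {
    if (object@roiWidth < 1L || object@roiHeight < 1L)
      return("ROI dimensions must be >= 1")
    if (object@levelOffset < 0L)
      return("levelOffset must be non-negative")
    TRUE
  })

#' RunLengthArray: per-pixel forward run length along one direction
#'
#' An image-shaped integer array whose entry at pixel p is the length of the
#' maximal same-intensity run starting at p and walking along the direction
#' step, unbounded by any ROI. Entries satisfy the recurrence
#' \code{RL[p] == 1 + RL[p + (dx, dy)]} when the successor is inside the
#' image and shares p's intensity, and \code{RL[p] == 1} otherwise.
#'
#' @slot values integer matrix, same shape as the image.
#' @slot direction a [Direction-class] object.
#'
#' @exportClass RunLengthArray
setClass("RunLengthArray",
  representation(values = "matrix", direction = "Direction"),
  validity = function(object) {
    if (any(object@values < 1L)) return("run lengths must be >= 1")
    TRUE
  })

#' GLRLMSingle: one ROI's gray level run length matrix, sparse
#'
#' Only non-null entries are stored, as a data frame of
#' (gray_level, run_length, count) rows sorted by gray level then run
#' length. The run-length mass identity
#' \eqn{\sum_{i,j} j \, P_{ij} = N} (N the ROI pixel count) is enforced at
#' construction.
#'
#' @slot entries data.frame with columns gray_level, run_length, count.
#' @slot roiIndex ROI index (top_row * image_width + top_col).
#' @slot direction a [Direction-class] object.
#' @slot nPixels integer, pixels in the ROI.
#'
#' @exportClass GLRLMSingle
setClass("GLRLMSingle",
  representation(entries = "data.frame", roiIndex = "numeric",
                 direction = "Direction", nPixels = "integer"),
  validity = function(object) {
    e <- object@entries
    if (!all(c("gray_level", "run_length", "count") %in% names(e)))
      return("entries must have gray_level, run_length, count columns")
    if (nrow(e) == 0L) return("a GLRLM of a non-empty ROI has entries")
    if (any(e$count < 1)) return("stored counts must be >= 1")
    if (any(e$run_length < 1)) return("run lengths must be >= 1")
    if (sum(e$run_length * e$count) != object@nPixels)
      return("run-length mass does not equal the ROI pixel count")
    TRUE
  })

#' GLRLMBatch: sparse GLRLMs of every ROI of an image, as sorted keys
#'
#' Houses the matrices of all sliding ROIs at once: a strictly increasing
#' vector of integer-valued keys packing (ROI index, gray level, run length)
#' as \code{(roi * G + gray) * roiLength + run - 1}, and an aligned vector
#' of positive counts. Keys are stored as doubles and are exact because the
#' encoding bound is checked against 2^53 before any engine runs.
#'
#' @slot keys strictly increasing numeric vector of packed keys.
#' @slot counts aligned positive counts (the non-null entries).
#' @slot spec the [ROISpec-class] used.
#' @slot glResolution gray-level resolution G used in the encoding.
#' @slot direction a [Direction-class] object.
#' @slot imageWidth,imageHeight dimensions of the source image.
#'
#' @seealso [glrlm()], [decodeKeys()], [extractFeatures()]
#' @exportClass GLRLMBatch
setClass("GLRLMBatch",
  representation(keys = "numeric", counts = "numeric", spec = "ROISpec",
                 glResolution = "integer", direction = "Direction",
                 imageWidth = "integer", imageHeight = "integer"),
  validity = function(object) {
    k <- object@keys
    if (length(k) != length(object@counts))
      return("keys and counts must be aligned")
    if (length(k) == 0L) return(TRUE)
    if (any(diff(k) <= 0)) return("keys must be strictly increasing")
    if (any(object@counts < 1)) return("counts must be >= 1")
    ## per-ROI run-length mass identity
    L <- max(object@spec@roiWidth, object@spec@roiHeight)
    G <- object@glResolution
    run <- k %% L + 1
    roi <- (k %/% L) %/% G
    mass <- rowsum(run * object@counts, group = roi)
    if (any(mass != object@spec@roiWidth * object@spec@roiHeight))
      return("per-ROI run-length mass does not equal the ROI pixel count")
    TRUE
  })

#' FeatureTable: the 11 run-length features per ROI for one direction
#'
#' @slot roiIndex ascending ROI indices (top_row * image_width + top_col).
#' @slot values numeric matrix, one row per ROI, 11 named feature columns
#'   (SRE, LRE, GLN, RLN, RP, LGRE, HGRE, SRLGE, SRHGE, LRLGE, LRHGE).
#' @slot direction a [Direction-class] object.
#' @slot levelOffset the gray-level offset used for i-weighted features.
#' @slot spec the [ROISpec-class] used.
#' @slot imageWidth,imageHeight dimensions of the source image.
#'
#' @exportClass FeatureTable
setClass("FeatureTable",
  representation(roiIndex = "numeric", values = "matrix",
                 direction = "Direction", levelOffset = "integer",
                 spec = "ROISpec", imageWidth = "integer",
                 imageHeight = "integer"),
  validity = function(object) {
    if (!identical(colnames(object@values), .FEATURE_NAMES))
      return("feature columns must be the 11 canonical features in order")
    if (nrow(object@values) != length(object@roiIndex))
      return("one row of feature values per ROI index")
    if (is.unsorted(object@roiIndex, strictly = TRUE))
      return("roiIndex must be strictly increasing")
    TRUE
  })
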