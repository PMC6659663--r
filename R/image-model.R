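#' Construct a validated grayscale image
#'
#' Validates a rectangular integer grid against a gray-level resolution G:
#' every intensity must lie in \code{[0, G - 1]}. The grid may be an integer
#' matrix or a list of equal-length row vectors.
#'
#' @param raw a matrix of intensities, or a list of rows.
#' @param glResolution number of gray levels G (default 256).
#' @return a [GrayImage-class] object.
#' @examples
#' img <- grayImage(matrix(0:3, 2, 2), glResolution = 4)
#' dim(img)
#' @export
grayImage <- function(raw, glResolution = 256) {
  if (is.list(raw)) {
    lens <- lengths(raw)
    if (length(raw) == 0L || length(unique(lens)) != 1L)
      .glrlmError("glrlmShapeError",
                  "raw grid must be rectangular and non-empty")
    raw <- do.call(rbind, lapply(raw, as.numeric))
  }
  if (!is.matrix(raw) || nrow(raw) < 1L || ncol(raw) < 1L)
    .glrlmError("glrlmShapeError",
                "raw grid must be a non-empty matrix")
  G <- as.integer(glResolution)
  bad <- which(raw < 0 | raw >= G | raw != floor(raw))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(raw))
    .glrlmError("glrlmRangeError",
                sprintf(
                  "intensity %s at (row %d, col %d) outside [0, %d]",
                  format(raw[bad[1L]]), i[1L] - 1L, i[2L] - 1L, G - 1L))
  }
  storage.mode(raw) <- "integer"
  dimnames(raw) <- NULL
  new("GrayImage", pixels = raw, glResolution = G)
}

#' @rdname accessors
#' @export
setMethod("pixels", "GrayImage", function(x) x@pixels)

#' @rdname accessors
#' @export
setMethod("glResolution", "GrayImage", function(x) x@glResolution)

#' @describeIn grayImage image dimensions as \code{c(rows, cols)}.
#' @param x a GrayImage.
#' @export
setMethod("dim", "GrayImage", function(x) dim(x@pixels))

setMethod("show", "GrayImage", function(object) {
  cat(sprintf("GrayImage: %d x %d pixels, %d gray levels\n",
              nrow(object@pixels), ncol(object@pixels),
              object@glResolution))
})

.DIRECTION_STEPS <- list(H0 = c(1L, 0L), AD45 = c(1L, -1L),
                         V90 = c(0L, -1L), D135 = c(-1L, -1L))

#' Principal run directions
#'
#' `glrlmDirection()` builds one of the four principal directions from its
#' name or degree label; `allDirections()` returns all four in conventional
#' order (0, 45, 90, 135 degrees).
#'
#' @param name \code{"H0"}, \code{"AD45"}, \code{"V90"}, \code{"D135"}, or
#'   the degree forms \code{"0"}, \code{"45"}, \code{"90"}, \code{"135"}.
#'   A Direction object is passed through unchanged.
#' @return a [Direction-class] object (a named list of them for
#'   `allDirections()`).
#' @examples
#' directionStep(glrlmDirection("AD45"))  # c(dx = 1, dy = -1)
#' names(allDirections())
#' @export
glrlmDirection <- function(name) {
  if (is(name, "Direction")) return(name)
  degree <- c("0" = "H0", "45" = "AD45", "90" = "V90", "135" = "D135")
  nm <- as.character(name)
  if (nm %in% names(degree)) nm <- degree[[nm]]
  if (!(nm %in% names(.DIRECTION_STEPS)))
    .glrlmError("glrlmUsageError",
                sprintf("unknown direction '%s'", as.character(name)))
  st <- .DIRECTION_STEPS[[nm]]
  new("Direction", name = nm, dx = st[1L], dy = st[2L])
}

#' @rdname glrlmDirection
#' @export
allDirections <- function() {
  ds <- lapply(names(.DIRECTION_STEPS), glrlmDirection)
  names(ds) <- names(.DIRECTION_STEPS)
  ds
}

#' @rdname accessors
#' @export
setMethod("directionName", "Direction", function(x) x@name)

#' @rdname accessors
#' @export
setMethod("directionStep", "Direction",
          function(x) c(dx = x@dx, dy = x@dy))

setMethod("show", "Direction", function(object) {
  cat(sprintf("Direction %s: (dx, dy) = (%d, %d)\n",
              object@name, object@dx, object@dy))
})

#' Construct a sliding-window ROI specification
#'
#' @param roiWidth,roiHeight window dimensions in pixels (columns, rows).
#' @param levelOffset non-negative integer added to intensities when
#'   gray-level-weighted features are computed; default 1 so intensity 0 is
#'   representable under 1/i^2 weights. Offset 0 applies the feature
#'   formulas to raw intensities and raises an error when an inverse-square
#'   gray weight meets level 0.
#' @return an [ROISpec-class] object.
#' @examples
#' sp <- roiSpec(4, 4)
#' roiLength(sp)  # 4
#' nPixels(sp)    # 16
#' @export
roiSpec <- function(roiWidth, roiHeight, levelOffset = 1) {
  new("ROISpec", roiWidth = as.integer(roiWidth),
      roiHeight = as.integer(roiHeight),
      levelOffset = as.integer(levelOffset))
}

#' @rdname accessors
#' @export
setMethod("roiWidth", "ROISpec", function(x) x@roiWidth)

#' @rdname accessors
#' @export
setMethod("roiHeight", "ROISpec", function(x) x@roiHeight)

#' @rdname accessors
#' @export
setMethod("roiLength", "ROISpec", function(x) max(x@roiWidth, x@roiHeight))

#' @rdname accessors
#' @export
setMethod("nPixels", "ROISpec", function(x) x@roiWidth * x@roiHeight)

#' @rdname accessors
#' @export
setMethod("levelOffset", "ROISpec", function(x) x@levelOffset)

setMethod("show", "ROISpec", function(object) {
  cat(sprintf(
    "ROISpec: %d x %d window (roiLength %d, %d pixels), levelOffset %d\n",
    object@roiWidth, object@roiHeight, roiLength(object),
    nPixels(object), object@levelOffset))
})

.checkSpecFits <- function(image, spec) {
  d <- dim(image)
  if (spec@roiHeight > d[1L] || spec@roiWidth > d[2L])
    .glrlmError("glrlmGeometryError",
                sprintf("%dx%d ROI does not fit inside %dx%d image",
                        spec@roiHeight, spec@roiWidth, d[1L], d[2L]))
  invisible(TRUE)
}

#' Enumerate sliding-window ROI positions
#'
#' Lists every fully contained window position obtained by sliding the ROI
#' one pixel at a time, ordered by ROI index. Coordinates are 0-based; the
#' ROI index of the window with top-left pixel (i, j) is
#' \code{i * width + j}, with the full image width as stride, so indices
#' are sparse in \code{[0, width * height)} unless the ROI is 1 pixel wide
#' and tall. No padding and no partial windows: only ROIs fully contained
#' in the image are enumerated.
#'
#' @param image a [GrayImage-class].
#' @param spec an [ROISpec-class]; must fit inside the image.
#' @return a data.frame with columns \code{top_row}, \code{top_col},
#'   \code{roi_index}, one row per ROI, roi_index strictly increasing.
#' @examples
#' img <- grayImage(matrix(0L, 2, 3), 2)
#' roiPositions(img, roiSpec(2, 2))  # two ROIs, indices 0 and 1
#' @export
roiPositions <- function(image, spec) {
  .checkSpecFits(image, spec)
  d <- dim(image)
  rows <- 0:(d[1L] - spec@roiHeight)
  cols <- 0:(d[2L] - spec@roiWidth)
  top_row <- rep(rows, each = length(cols))
  top_col <- rep(cols, times = length(rows))
  data.frame(top_row = top_row, top_col = top_col,
             roi_index = as.numeric(top_row) * d[2L] + top_col)
}

#' Number of sliding ROIs of an image
#'
#' \code{(height - roiHeight + 1) * (width - roiWidth + 1)}.
#'
#' @inheritParams roiPositions
#' @return integer count of fully contained ROI positions.
#' @export
numROIs <- function(image, spec) {
  .checkSpecFits(image, spec)
  d <- dim(image)
  (d[1L] - spec@roiHeight + 1L) * (d[2L] - spec@roiWidth + 1L)
}
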