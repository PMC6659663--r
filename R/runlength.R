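#' Ending pixels of an image for a direction
#'
#' An ending pixel has no in-image successor along the direction step
#' (dx, dy): for the horizontal direction these are the last column, for
#' the vertical direction the first row, for the anti-diagonal the last
#' column together with the first row, and for the diagonal the first
#' column together with the first row. Ending pixels anchor the reverse
#' traversal that fills the run length array in one linear pass.
#'
#' @param height,width image dimensions in pixels.
#' @param direction a [Direction-class] object or direction name.
#' @return a data.frame with 0-based columns \code{row}, \code{col},
#'   ordered by (row, col); each listed pixel's successor
#'   (row + dy, col + dx) falls outside the image.
#' @examples
#' nrow(endingPixels(5, 5, "AD45"))  # 9
#' @export
endingPixels <- function(height, width, direction) {
  direction <- glrlmDirection(direction)
  h <- as.integer(height); w <- as.integer(width)
  if (h < 1L || w < 1L)
    .glrlmError("glrlmGeometryError", "image dimensions must be >= 1")
  r <- rep(0:(h - 1L), times = w)
  cl <- rep(0:(w - 1L), each = h)
  succ_r <- r + direction@dy
  succ_c <- cl + direction@dx
  out <- succ_r < 0L | succ_r >= h | succ_c < 0L | succ_c >= w
  d <- data.frame(row = r[out], col = cl[out])
  d[order(d$row, d$col), , drop = FALSE]
}

#' Whole-image forward run length array
#'
#' For every pixel p, computes the length of the maximal same-intensity run
#' starting at p along the direction step, in a single pass over the image:
#' pixels are visited reversely to the direction (anchored at the ending
#' pixels), and each entry is one more than its successor's entry when the
#' successor shares its intensity, else 1. Runs are unbounded by any ROI;
#' truncation to a window happens at lookup time. The pass is vectorized
#' one image line at a time, which satisfies the recurrence exactly.
#'
#' @param image a [GrayImage-class].
#' @param direction a [Direction-class] object or direction name.
#' @return a [RunLengthArray-class] with the same shape as the image.
#' @examples
#' img <- grayImage(matrix(c(1L, 1L, 1L, 2L, 2L), 1, 5), 4)
#' pixels(runLengthArray(img, "H0"))  # 3 2 1 2 1
#' @export
runLengthArray <- function(image, direction) {
  direction <- glrlmDirection(direction)
  px <- image@pixels
  h <- nrow(px); w <- ncol(px)
  rl <- matrix(1L, h, w)
  nm <- direction@name
  if (nm == "H0") {
    if (w > 1L) for (c in (w - 1L):1L) {
      same <- px[, c] == px[, c + 1L]
      rl[same, c] <- rl[same, c + 1L] + 1L
    }
  } else if (nm == "V90") {
    ## successor is the pixel above; fill top-down
    if (h > 1L) for (r in 2:h) {
      same <- px[r, ] == px[r - 1L, ]
      rl[r, same] <- rl[r - 1L, same] + 1L
    }
  } else if (nm == "AD45") {
    ## successor is up-right
    if (h > 1L && w > 1L) for (r in 2:h) {
      cc <- 1:(w - 1L)
      same <- px[r, cc] == px[r - 1L, cc + 1L]
      rl[r, cc[same]] <- rl[r - 1L, cc[same] + 1L] + 1L
    }
  } else { # D135, successor is up-left
    if (h > 1L && w > 1L) for (r in 2:h) {
      cc <- 2:w
      same <- px[r, cc] == px[r - 1L, cc - 1L]
      rl[r, cc[same]] <- rl[r - 1L, cc[same] - 1L] + 1L
    }
  }
  new("RunLengthArray", values = rl, direction = direction)
}

#' @rdname accessors
#' @export
setMethod("pixels", "RunLengthArray", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("directionOf", "RunLengthArray", function(x) x@direction)

setMethod("show", "RunLengthArray", function(object) {
  cat(sprintf("RunLengthArray: %d x %d, direction %s, max run %d\n",
              nrow(object@values), ncol(object@values),
              object@direction@name, max(object@values)))
})
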