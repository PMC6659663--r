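#' Embedded worked example: a 5x5 ROI with its four published GLRLMs
#'
#' A canonical 5x5 grayscale window (256 gray levels, 5 distinct
#' intensities: 0, 42, 113, 128, 255) together with the non-null entries
#' of its gray level run length matrix along each of the four principal
#' directions, transcribed from the published worked example. Every
#' expected entry set satisfies the run-length mass identity
#' \eqn{\sum_{i,j} j P_{ij} = 25}.
#'
#' @return a list with \code{name}, \code{image} (a [GrayImage-class]) and
#'   \code{expected}: a list keyed by direction name (H0, AD45, V90,
#'   D135) of data.frames with columns gray_level, run_length, count.
#' @examples
#' fx <- workedExample()
#' pixels(fx$image)
#' fx$expected$H0
#' @export
workedExample <- function() {
  img <- grayImage(matrix(c(
      0, 255, 113, 113,  42,
    255,  42, 113, 113,   0,
    128, 113, 255,   0,  42,
    113, 255,   0, 128,  42,
     42, 113, 128, 255, 255), nrow = 5, byrow = TRUE),
    glResolution = 256)
  ent <- function(gray, run, count)
    data.frame(gray_level = gray, run_length = run, count = count)
  expected <- list(
    H0 = ent(c(0, 42, 113, 113, 128, 255, 255),
             c(1, 1, 1, 2, 1, 1, 2),
             c(4, 5, 3, 2, 3, 4, 1)),
    AD45 = ent(c(0, 0, 42, 113, 113, 128, 128, 255, 255),
               c(1, 3, 1, 1, 4, 1, 2, 1, 2),
               c(1, 1, 5, 3, 1, 1, 1, 2, 2)),
    V90 = ent(c(0, 42, 42, 113, 113, 128, 255),
              c(1, 1, 2, 1, 2, 1, 1),
              c(4, 3, 1, 3, 2, 3, 6)),
    D135 = ent(c(0, 42, 113, 113, 128, 255),
               c(1, 1, 1, 2, 1, 1),
               c(4, 5, 3, 2, 3, 6)))
  list(name = "worked-example-5x5", image = img, expected = expected)
}

#' Deterministic synthetic test images
#'
#' Simple patterns with closed-form GLRLMs: a constant image (one run per
#' direction line), a two-color checkerboard (every run has length 1) and
#' vertical stripes of a given period. `synthRandom()` draws independent
#' uniform intensities from \code{0:(glResolution - 1)} using R's
#' Mersenne-Twister generator seeded with \code{seed}; the caller's RNG
#' state is left untouched, and identical seeds give identical images.
#'
#' @param height,width image dimensions in pixels.
#' @param value,v0,v1,values intensities; must lie below
#'   \code{glResolution}.
#' @param period stripe width in columns.
#' @param glResolution number of gray levels (default 256).
#' @param seed integer seed for the random image.
#' @return a [GrayImage-class].
#' @examples
#' pixels(synthStripes(2, 4, 2, c(5, 9)))
#' identical(pixels(synthRandom(8, 8, 8, 1)), pixels(synthRandom(8, 8, 8, 1)))
#' @name synthetic-images
NULL

#' @rdname synthetic-images
#' @export
synthConstant <- function(height, width, value, glResolution = 256) {
  grayImage(matrix(value, height, width), glResolution)
}

#' @rdname synthetic-images
#' @export
synthCheckerboard <- function(height, width, v0, v1, glResolution = 256) {
  parity <- (outer(0:(height - 1L), 0:(width - 1L), `+`)) %% 2L
  grayImage(matrix(ifelse(parity == 0L, v0, v1), height, width),
            glResolution)
}

#' @rdname synthetic-images
#' @export
synthStripes <- function(height, width, period, values,
                         glResolution = 256) {
  band <- ((0:(width - 1L)) %/% period) %% length(values)
  grayImage(matrix(rep(values[band + 1L], each = height), height, width),
            glResolution)
}

#' @rdname synthetic-images
#' @export
synthRandom <- function(height, width, glResolution, seed) {
  if (glResolution < 2)
    .glrlmError("glrlmUsageError", "glResolution must be >= 2")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  vals <- sample.int(as.integer(glResolution),
                     height * width, replace = TRUE) - 1L
  grayImage(matrix(vals, height, width), glResolution)
}
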