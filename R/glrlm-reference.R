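## ROI-local direction lines.
##
## A line is a maximal set of collinear ROI pixels along the direction
## step. Its starting pixel is the ROI pixel whose predecessor along
## (dx, dy) lies outside the ROI (the ROI-local analogue of an ending
## pixel, at the opposite end). Lines are enumerated in a fixed order so
## that the batch engine's scatter layout is deterministic:
##   H0   - first column, top to bottom            (h lines of length w)
##   V90  - last row, left to right                (w lines of length h)
##   AD45 - first column top to bottom, then last row left to right
##   D135 - last row left to right, then last column bottom to top
## Diagonal line lengths rise 1, 2, ..., min(w, h), plateau, then fall.
.lineStarts <- function(w, h, direction) {
  nm <- direction@name
  if (nm == "H0") {
    data.frame(y = 0:(h - 1L), x = 0L, len = w)
  } else if (nm == "V90") {
    data.frame(y = h - 1L, x = 0:(w - 1L), len = h)
  } else if (nm == "AD45") {
    y1 <- 0:(h - 1L)
    d <- data.frame(y = y1, x = 0L, len = pmin(w, y1 + 1L))
    if (w > 1L) {
      x2 <- 1:(w - 1L)
      d <- rbind(d, data.frame(y = h - 1L, x = x2, len = pmin(w - x2, h)))
    }
    d
  } else { # D135
    x1 <- 0:(w - 1L)
    d <- data.frame(y = h - 1L, x = x1, len = pmin(x1 + 1L, h))
    if (h > 1L) {
      y2 <- (h - 2L):0L
      d <- rbind(d, data.frame(y = y2, x = w - 1L, len = pmin(y2 + 1L, w)))
    }
    d
  }
}

## runs of one ROI as parallel vectors (gray, run), by direct line scans
.roiRuns <- function(px, top_row, top_col, spec, direction) {
  starts <- .lineStarts(spec@roiWidth, spec@roiHeight, direction)
  dx <- direction@dx; dy <- direction@dy
  gray <- integer(0); run <- integer(0)
  for (s in seq_len(nrow(starts))) {
    len <- starts$len[s]
    steps <- 0:(len - 1L)
    rr <- top_row + starts$y[s] + steps * dy
    cc <- top_col + starts$x[s] + steps * dx
    r <- rle(px[cbind(rr + 1L, cc + 1L)])
    gray <- c(gray, r$values)
    run <- c(run, r$lengths)
  }
  list(gray = gray, run = run)
}

#' Brute-force GLRLM of a single ROI
#'
#' Ground-truth construction: every direction line of the window is scanned
#' directly and its maximal same-intensity runs (truncated at the window
#' boundary) are tallied. Independent of the run length array and of the
#' batch key machinery; serves as the oracle the other engines are checked
#' against.
#'
#' @param image a [GrayImage-class].
#' @param topRow,topCol 0-based top-left pixel of the window.
#' @param spec an [ROISpec-class].
#' @param direction a [Direction-class] object or direction name.
#' @return a [GLRLMSingle-class] with entries sorted by (gray, run).
#' @examples
#' fx <- workedExample()
#' glrlmEntries(glrlmSingleROI(fx$image, 0, 0, roiSpec(5, 5), "H0"))
#' @export
glrlmSingleROI <- function(image, topRow, topCol, spec, direction) {
  direction <- glrlmDirection(direction)
  d <- dim(image)
  topRow <- as.integer(topRow); topCol <- as.integer(topCol)
  if (topRow < 0L || topCol < 0L ||
      topRow + spec@roiHeight > d[1L] || topCol + spec@roiWidth > d[2L])
    .glrlmError("glrlmGeometryError",
                sprintf("ROI at (%d, %d) exceeds the %dx%d image",
                        topRow, topCol, d[1L], d[2L]))
  runs <- .roiRuns(image@pixels, topRow, topCol, spec, direction)
  agg <- stats::aggregate(
    list(count = rep.int(1L, length(runs$gray))),
    by = list(gray_level = runs$gray, run_length = runs$run), FUN = sum)
  agg <- agg[order(agg$gray_level, agg$run_length), , drop = FALSE]
  rownames(agg) <- NULL
  new("GLRLMSingle", entries = agg,
      roiIndex = topRow * d[2L] + topCol,
      direction = direction, nPixels = nPixels(spec))
}

#' @rdname accessors
#' @export
setMethod("glrlmEntries", "GLRLMSingle", function(x) x@entries)

#' @rdname accessors
#' @export
setMethod("roiIndex", "GLRLMSingle", function(x) x@roiIndex)

#' @rdname accessors
#' @export
setMethod("directionOf", "GLRLMSingle", function(x) x@direction)

setMethod("show", "GLRLMSingle", function(object) {
  cat(sprintf("GLRLMSingle: ROI %d, direction %s, %d non-null entries\n",
              object@roiIndex, object@direction@name,
              nrow(object@entries)))
})

## oracle engine: per-ROI brute force assembled into a sparse batch
.glrlmOracleEngine <- function(image, spec, direction) {
  pos <- roiPositions(image, spec)
  px <- image@pixels
  G <- image@glResolution
  L <- roiLength(spec)
  keys <- vector("list", nrow(pos))
  for (p in seq_len(nrow(pos))) {
    runs <- .roiRuns(px, pos$top_row[p], pos$top_col[p], spec, direction)
    keys[[p]] <- (pos$roi_index[p] * G + runs$gray) * L + runs$run - 1
  }
  sortAndCount(unlist(keys))
}

## sequential engine: Algorithm-1 run length array plus per-line walks
## that skip ahead by the recorded run, vectorized over all ROIs in
## lockstep (each iteration advances every still-active ROI's walk on the
## current line by one whole run)
.glrlmSequentialEngine <- function(image, spec, direction) {
  pos <- roiPositions(image, spec)
  rla <- runLengthArray(image, direction)@values
  px <- image@pixels
  G <- image@glResolution
  L <- roiLength(spec)
  dx <- direction@dx; dy <- direction@dy
  starts <- .lineStarts(spec@roiWidth, spec@roiHeight, direction)
  acc <- list(); a <- 0L
  for (s in seq_len(nrow(starts))) {
    r <- pos$top_row + starts$y[s]
    c <- pos$top_col + starts$x[s]
    remaining <- rep.int(starts$len[s], nrow(pos))
    idx <- seq_len(nrow(pos))
    while (length(idx)) {
      cell <- cbind(r[idx] + 1L, c[idx] + 1L)
      ## run = min(whole-image run length, distance to the ROI boundary)
      run <- pmin(rla[cell], remaining[idx])
      a <- a + 1L
      acc[[a]] <- (pos$roi_index[idx] * G + px[cell]) * L + run - 1
      r[idx] <- r[idx] + run * dy
      c[idx] <- c[idx] + run * dx
      remaining[idx] <- remaining[idx] - run
      idx <- idx[remaining[idx] > 0L]
    }
  }
  sortAndCount(unlist(acc))
}

#' Construct the GLRLMs of all sliding ROIs of an image
#'
#' The main entry point. Builds the sparse gray level run length matrices
#' of every fully contained sliding window along one direction, with a
#' choice of three mutually validating engines that produce identical
#' output:
#' \describe{
#'   \item{\code{"batch"}}{(default) the key-encode/scatter/reduce-by-key/
#'     sort paradigm operating on all ROIs simultaneously; see
#'     [expandROIs()] and friends.}
#'   \item{\code{"sequential"}}{an optimized single-pass engine: a
#'     whole-image [runLengthArray()] is computed once, then each window
#'     line is walked with run skipping, truncating runs at the window
#'     boundary.}
#'   \item{\code{"oracle"}}{per-ROI brute force ([glrlmSingleROI()] line
#'     scans), the ground truth.}
#' }
#'
#' @param image a [GrayImage-class].
#' @param spec an [ROISpec-class]; must fit inside the image.
#' @param direction a [Direction-class] object or direction name.
#' @param engine \code{"batch"}, \code{"sequential"} or \code{"oracle"}.
#' @return a [GLRLMBatch-class].
#' @examples
#' fx <- workedExample()
#' b <- glrlm(fx$image, roiSpec(5, 5), "H0")
#' decodeKeys(b)
#' @export
glrlm <- function(image, spec, direction,
                  engine = c("batch", "sequential", "oracle")) {
  engine <- match.arg(engine)
  direction <- glrlmDirection(direction)
  .checkSpecFits(image, spec)
  .checkKeyCapacity(image, spec)
  res <- switch(engine,
    batch = .glrlmBatchEngine(image, spec, direction),
    sequential = .glrlmSequentialEngine(image, spec, direction),
    oracle = .glrlmOracleEngine(image, spec, direction))
  d <- dim(image)
  new("GLRLMBatch", keys = res$keys, counts = res$counts, spec = spec,
      glResolution = image@glResolution, direction = direction,
      imageWidth = d[2L], imageHeight = d[1L])
}
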