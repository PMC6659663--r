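## keys are IEEE doubles holding exact integers; everything must stay
## below 2^53 for %/% and %% to be exact
.KEY_CAPACITY <- 2^53

.checkKeyCapacity <- function(image, spec) {
  d <- dim(image)
  bound <- as.numeric(d[1L]) * d[2L] * image@glResolution * roiLength(spec)
  if (bound >= .KEY_CAPACITY)
    .glrlmError("glrlmCapacityError",
                sprintf(paste0(
                  "packed key bound %.4g (height x width x G x roiLength)",
                  " exceeds the exact-integer capacity %.4g"),
                  bound, .KEY_CAPACITY))
  invisible(TRUE)
}

#' Line layout of one ROI along a direction
#'
#' Sizes and prefix sums of the direction lines of a single window, in the
#' fixed enumeration order used by the batch engine's scatter. Horizontal
#' windows have \code{roiHeight} lines of length \code{roiWidth}, vertical
#' ones \code{roiWidth} lines of length \code{roiHeight}; the two diagonal
#' directions have \code{roiWidth + roiHeight - 1} lines whose lengths
#' rise 1, 2, ..., min(width, height), plateau, then fall back to 1.
#'
#' @param spec an [ROISpec-class].
#' @param direction a [Direction-class] object or direction name.
#' @return a list with \code{sizes} (\eqn{R_k}, entries of the (k+1)-th
#'   line), \code{offsets} (\eqn{N_k = \sum_{i<k} R_i}, entries in the
#'   first k lines) and \code{starts} (0-based ROI-local starting pixel of
#'   each line, data.frame y/x/len).
#' @examples
#' lineLayout(roiSpec(5, 5), "D135")$sizes  # 1 2 3 4 5 4 3 2 1
#' @export
lineLayout <- function(spec, direction) {
  direction <- glrlmDirection(direction)
  starts <- .lineStarts(spec@roiWidth, spec@roiHeight, direction)
  sizes <- starts$len
  list(sizes = sizes,
       offsets = c(0L, cumsum(sizes))[seq_along(sizes)],
       starts = starts)
}

#' Scatter all ROIs into one keyed array
#'
#' Step 1 of the batch paradigm. Every pixel is duplicated once per ROI
#' containing it and scattered so that the lines of all ROIs are
#' concatenated line-rank by line-rank: the (l+1)-th entry of the (k+1)-th
#' line of the ROI with dense rank \eqn{r} lands at address
#' \eqn{N_k \cdot \mathrm{numROIs} + R_k \cdot r + l}, a bijection onto
#' \code{[0, numROIs * nPixels)}. At the same time each intensity is tagged
#' with its ROI index as \code{key_IG = roi_index * G + gray}, where
#' \code{roi_index} is the sparse top-left index \code{i * width + j}.
#' (The scatter address uses the dense ROI rank — ranks and sparse indices
#' are in the same order — so the layout is compact for any window shape.)
#'
#' The interleaving separates the same-rank lines of different ROIs, but
#' when the image holds a single ROI consecutive lines of that ROI become
#' adjacent; the returned \code{"lineSegments"} attribute (one id per
#' (line, ROI) block) lets [reduceRuns()] stop runs at line boundaries in
#' every case.
#'
#' @param image a [GrayImage-class].
#' @param spec an [ROISpec-class].
#' @param direction a [Direction-class] object or direction name.
#' @return numeric vector of \code{key_IG} values of length
#'   \code{numROIs * nPixels}, with attribute \code{"lineSegments"}
#'   (integer segment id per element).
#' @examples
#' img <- grayImage(matrix(1:6, 2, 3, byrow = TRUE), 256)
#' as.vector(expandROIs(img, roiSpec(2, 2), "H0"))
#' # 1 2 258 259 4 5 261 262
#' @export
expandROIs <- function(image, spec, direction) {
  direction <- glrlmDirection(direction)
  .checkSpecFits(image, spec)
  .checkKeyCapacity(image, spec)
  pos <- roiPositions(image, spec)
  M <- nrow(pos)
  layout <- lineLayout(spec, direction)
  px <- image@pixels
  G <- image@glResolution
  dx <- direction@dx; dy <- direction@dy
  keys <- numeric(M * nPixels(spec))
  segments <- integer(length(keys))
  rank <- 0:(M - 1L)
  for (k in seq_along(layout$sizes)) {
    Rk <- layout$sizes[k]
    Nk <- layout$offsets[k]
    y0 <- layout$starts$y[k]; x0 <- layout$starts$x[k]
    seg <- (k - 1L) * M + rank
    for (l in 0:(Rk - 1L)) {
      addr <- Nk * M + Rk * rank + l
      rows <- pos$top_row + y0 + l * dy
      cols <- pos$top_col + x0 + l * dx
      keys[addr + 1L] <- pos$roi_index * G + px[cbind(rows + 1L, cols + 1L)]
      segments[addr + 1L] <- seg
    }
  }
  attr(keys, "lineSegments") <- segments
  keys
}

#' Count runs by collapsing adjacent equal keys
#'
#' Step 2: a reduce-by-key over a ones array. Each maximal block of equal
#' adjacent keys collapses to a single key whose associated value is the
#' block length — on the scattered \code{key_IG} array this is exactly the
#' run length of consecutive equal-intensity pixels of one ROI line. When a
#' segment vector is supplied (as produced by [expandROIs()]), blocks never
#' extend across a segment boundary, so runs cannot leak between
#' consecutive lines that happen to sit adjacently with equal keys.
#'
#' @param keys numeric vector of keys.
#' @param segments optional integer vector, same length, marking line
#'   blocks; \code{NULL} means pure adjacency semantics.
#' @return a list with \code{keys} (one per block, input order) and
#'   \code{runs} (block lengths).
#' @examples
#' reduceRuns(c(7, 7, 7, 9, 7))  # keys 7 9 7, runs 3 1 1
#' @export
reduceRuns <- function(keys, segments = NULL) {
  if (is.null(segments)) segments <- attr(keys, "lineSegments")
  n <- length(keys)
  if (n == 0L) return(list(keys = numeric(0), runs = integer(0)))
  new_block <- c(TRUE, keys[-1L] != keys[-n])
  if (!is.null(segments))
    new_block <- new_block | c(TRUE, segments[-1L] != segments[-n])
  grp <- cumsum(new_block)
  list(keys = as.numeric(keys[new_block]), runs = tabulate(grp))
}

#' Pack run lengths into the keys
#'
#' Step 3: \code{key_IGL = key_IG * roiLength + run - 1}, folding the
#' (ROI, gray, run) triple into one sortable integer.
#'
#' @param keys numeric vector of \code{key_IG} values.
#' @param runs integer run lengths, aligned with \code{keys}.
#' @param roiLength the key multiplier, \code{max(roiWidth, roiHeight)}.
#' @return numeric vector of \code{key_IGL} values.
#' @examples
#' combineKeys(773, 2, 4)  # 3093
#' @export
combineKeys <- function(keys, runs, roiLength) {
  if (length(keys) != length(runs))
    .glrlmError("glrlmConsistencyError", "keys and runs must be aligned")
  if (any(runs > roiLength))
    .glrlmError("glrlmConsistencyError",
                sprintf("run length %d exceeds roiLength %d (engine bug)",
                        max(runs), as.integer(roiLength)))
  keys * roiLength + runs - 1
}

#' Sort keys and merge equal ones with counts
#'
#' Steps 4 and 5: sorting clusters the keys of each ROI (the ROI index
#' occupies the most significant part of the key) and, within a ROI, equal
#' (gray, run) pairs; a final reduce-by-key yields the strictly increasing
#' unique keys and their occurrence counts — the sparse GLRLMs of all ROIs
#' with only non-null entries.
#'
#' @param keys numeric vector of \code{key_IGL} values, any order.
#' @return a list with \code{keys} (sorted, unique) and \code{counts}.
#' @examples
#' sortAndCount(c(14, 14, 3, 14))  # keys 3 14, counts 1 3
#' @export
sortAndCount <- function(keys) {
  if (length(keys) == 0L)
    return(list(keys = numeric(0), counts = integer(0)))
  s <- sort(keys, method = "radix")
  first <- c(TRUE, s[-1L] != s[-length(s)])
  list(keys = s[first], counts = tabulate(cumsum(first)))
}

## batch engine: scatter -> run reduce -> key pack -> sort/count
.glrlmBatchEngine <- function(image, spec, direction) {
  expanded <- expandROIs(image, spec, direction)
  reduced <- reduceRuns(expanded)
  igl <- combineKeys(reduced$keys, reduced$runs, roiLength(spec))
  sortAndCount(igl)
}

#' @rdname accessors
#' @export
setMethod("glrlmKeys", "GLRLMBatch", function(x) x@keys)

#' @rdname accessors
#' @export
setMethod("glrlmCounts", "GLRLMBatch", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("glResolution", "GLRLMBatch", function(x) x@glResolution)

#' @rdname accessors
#' @export
setMethod("directionOf", "GLRLMBatch", function(x) x@direction)

#' @rdname accessors
#' @export
setMethod("roiLength", "GLRLMBatch", function(x) roiLength(x@spec))

setMethod("show", "GLRLMBatch", function(object) {
  nroi <- (object@imageHeight - object@spec@roiHeight + 1L) *
    (object@imageWidth - object@spec@roiWidth + 1L)
  cat(sprintf(paste0(
    "GLRLMBatch: %d non-null entries over %d ROIs (%d x %d windows),",
    " direction %s, G = %d\n"),
    length(object@keys), nroi, object@spec@roiWidth,
    object@spec@roiHeight, object@direction@name, object@glResolution))
})

#' @rdname decodeKeys
#' @export
setMethod("decodeKeys", "GLRLMBatch", function(x) {
  L <- roiLength(x@spec)
  G <- x@glResolution
  ig <- x@keys %/% L
  data.frame(roi_index = ig %/% G,
             gray_level = ig %% G,
             run_length = x@keys %% L + 1,
             count = x@counts)
})

#' Extract one ROI's matrix from a batch
#'
#' @param batch a [GLRLMBatch-class].
#' @param roiIndex the sparse ROI index (top_row * image_width + top_col).
#' @return a [GLRLMSingle-class].
#' @export
glrlmFromBatch <- function(batch, roiIndex) {
  dec <- decodeKeys(batch)
  e <- dec[dec$roi_index == roiIndex,
           c("gray_level", "run_length", "count"), drop = FALSE]
  if (nrow(e) == 0L)
    .glrlmError("glrlmGeometryError",
                sprintf("no ROI with index %s in this batch",
                        format(roiIndex)))
  rownames(e) <- NULL
  new("GLRLMSingle", entries = e, roiIndex = as.numeric(roiIndex),
      direction = batch@direction, nPixels = nPixels(batch@spec))
}
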