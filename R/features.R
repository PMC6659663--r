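## Feature extraction follows three summation categories over the sorted
## sparse keys:
##   1. the shared denominator S (and RP numerator): one reduce by ROI;
##   2. the eight i/j-weighted sums (SRE, LRE, LGRE, HGRE, SRLGE, SRHGE,
##      LRLGE, LRHGE): transform each non-null entry, then reduce by ROI;
##   3. the squared marginal sums (GLN, RLN): an inner reduce over one
##      dropped key component, a square, then a reduce by ROI. Dropping
##      the run length keeps keys grouped; dropping the gray level does
##      not, so the RLN path re-sorts (ROI, run) keys first.

.WEIGHTS <- c("j2", "inv_j2", "i2", "inv_i2", "inv_i2j2",
              "i2_over_j2", "j2_over_i2", "i2j2")

#' Per-ROI run totals (the shared feature denominator)
#'
#' The total number of runs S of each ROI: the sum of its non-null counts.
#' Every feature except RP divides by S; RP divides S by the pixel count.
#'
#' @param batch a [GLRLMBatch-class].
#' @return a list with \code{roiIndex} (ascending) and \code{S} (aligned
#'   totals).
#' @examples
#' fx <- workedExample()
#' roiRunTotals(glrlm(fx$image, roiSpec(5, 5), "H0"))$S  # 22
#' @export
roiRunTotals <- function(batch) {
  roi <- (batch@keys %/% roiLength(batch@spec)) %/% batch@glResolution
  tot <- rowsum(as.numeric(batch@counts), group = roi)
  list(roiIndex = as.numeric(rownames(tot)), S = as.vector(tot))
}

.weightValues <- function(weight, gray, run, levelOffset, roi) {
  lev <- gray + levelOffset
  if (weight %in% c("inv_i2", "inv_i2j2", "j2_over_i2") && any(lev == 0)) {
    bad <- roi[which(lev == 0)[1L]]
    .glrlmError("glrlmDomainError",
                sprintf(paste0(
                  "gray level 0 with levelOffset 0 in ROI %s makes the ",
                  "1/i^2 weight undefined; use levelOffset >= 1"),
                  format(bad)))
  }
  switch(weight,
         j2         = run^2,
         inv_j2     = 1 / run^2,
         i2         = lev^2,
         inv_i2     = 1 / lev^2,
         inv_i2j2   = 1 / (lev^2 * run^2),
         i2_over_j2 = lev^2 / run^2,
         j2_over_i2 = run^2 / lev^2,
         i2j2       = lev^2 * run^2)
}

#' Weighted run-emphasis features
#'
#' Category-2 summations: each non-null entry (i, j, count), with
#' i = gray level + levelOffset and j = run length, contributes
#' \code{weight(i, j) * count}; the per-ROI sum is divided by the shared
#' denominator S. The eight weights are \code{j2} (LRE), \code{inv_j2}
#' (SRE), \code{i2} (HGRE), \code{inv_i2} (LGRE), \code{inv_i2j2} (SRLGE),
#' \code{i2_over_j2} (SRHGE), \code{j2_over_i2} (LRLGE) and \code{i2j2}
#' (LRHGE).
#'
#' @param batch a [GLRLMBatch-class].
#' @param weight one of the eight weight names above.
#' @param S per-ROI totals from [roiRunTotals()]; computed when missing.
#' @param levelOffset gray-level offset; defaults to the batch spec's.
#' @return numeric vector of per-ROI values, aligned with ascending ROI
#'   index.
#' @export
weightedFeature <- function(batch, weight = .WEIGHTS, S = NULL,
                            levelOffset = NULL) {
  weight <- match.arg(weight)
  if (is.null(S)) S <- roiRunTotals(batch)
  if (is.null(levelOffset)) levelOffset <- batch@spec@levelOffset
  dec <- decodeKeys(batch)
  w <- .weightValues(weight, dec$gray_level, dec$run_length,
                     levelOffset, dec$roi_index)
  num <- rowsum(w * dec$count, group = dec$roi_index)
  as.vector(num) / S$S
}

#' Gray level nonuniformity (GLN)
#'
#' Category-3 summation: the run length is dropped from each key
#' (\code{key \%/\% roiLength}), which leaves the keys grouped, so one
#' adjacency reduce gives the per-(ROI, gray) marginal sums; these are
#' squared, reduced by ROI and divided by S.
#'
#' @inheritParams weightedFeature
#' @return numeric vector of per-ROI GLN values.
#' @export
grayLevelNonuniformity <- function(batch, S = NULL) {
  if (is.null(S)) S <- roiRunTotals(batch)
  ig <- batch@keys %/% roiLength(batch@spec)
  n <- length(ig)
  first <- c(TRUE, ig[-1L] != ig[-n])
  inner <- rowsum(as.numeric(batch@counts), group = cumsum(first))
  roi <- ig[first] %/% batch@glResolution
  as.vector(rowsum(as.vector(inner)^2, group = roi)) / S$S
}

#' Run length nonuniformity (RLN)
#'
#' Category-3 summation over the other marginal: dropping the gray level
#' intermingles the key order, so (ROI, run) keys are re-sorted (a
#' segmented sort: the ROI index occupies the most significant part) with
#' their counts before the inner reduce, square and per-ROI reduce.
#'
#' @inheritParams weightedFeature
#' @return numeric vector of per-ROI RLN values.
#' @export
runLengthNonuniformity <- function(batch, S = NULL) {
  if (is.null(S)) S <- roiRunTotals(batch)
  L <- roiLength(batch@spec)
  roi <- (batch@keys %/% L) %/% batch@glResolution
  key_ij <- roi * L + batch@keys %% L     # ROI (+) run, gray dropped
  o <- order(key_ij)
  k <- key_ij[o]; cnt <- as.numeric(batch@counts[o])
  first <- c(TRUE, k[-1L] != k[-length(k)])
  inner <- rowsum(cnt, group = cumsum(first))
  as.vector(rowsum(as.vector(inner)^2, group = k[first] %/% L)) / S$S
}

#' Run percentage (RP)
#'
#' The ratio of the number of runs to the number of pixels of the window,
#' \code{S / N}; equals 1 exactly when every run has length 1.
#'
#' @param S per-ROI totals from [roiRunTotals()].
#' @param spec the [ROISpec-class] of the batch.
#' @return numeric vector of per-ROI RP values in (0, 1].
#' @export
runPercentage <- function(S, spec) S$S / nPixels(spec)

#' Extract the 11 run-length features of every ROI
#'
#' Computes SRE, LRE, GLN, RLN, RP, LGRE, HGRE, SRLGE, SRHGE, LRLGE and
#' LRHGE for each ROI of a sparse batch. The shared denominator S is
#' computed once and passed to every summation.
#'
#' @param batch a [GLRLMBatch-class].
#' @param levelOffset gray-level offset for the i-weighted features;
#'   defaults to the batch spec's (normally 1).
#' @return a [FeatureTable-class].
#' @examples
#' fx <- workedExample()
#' ft <- extractFeatures(glrlm(fx$image, roiSpec(5, 5), "H0"))
#' featureValues(ft)[, c("SRE", "LRE", "RP")]
#' @export
extractFeatures <- function(batch, levelOffset = NULL) {
  if (is.null(levelOffset)) levelOffset <- batch@spec@levelOffset
  levelOffset <- as.integer(levelOffset)
  S <- roiRunTotals(batch)
  wf <- function(w) weightedFeature(batch, w, S, levelOffset)
  values <- cbind(
    SRE = wf("inv_j2"), LRE = wf("j2"),
    GLN = grayLevelNonuniformity(batch, S),
    RLN = runLengthNonuniformity(batch, S),
    RP = runPercentage(S, batch@spec),
    LGRE = wf("inv_i2"), HGRE = wf("i2"),
    SRLGE = wf("inv_i2j2"), SRHGE = wf("i2_over_j2"),
    LRLGE = wf("j2_over_i2"), LRHGE = wf("i2j2"))
  new("FeatureTable", roiIndex = S$roiIndex, values = values,
      direction = batch@direction, levelOffset = levelOffset,
      spec = batch@spec, imageWidth = batch@imageWidth,
      imageHeight = batch@imageHeight)
}

#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureTable", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("roiIndex", "FeatureTable", function(x) x@roiIndex)

#' @rdname accessors
#' @export
setMethod("directionOf", "FeatureTable", function(x) x@direction)

#' @rdname accessors
#' @export
setMethod("levelOffset", "FeatureTable", function(x) x@levelOffset)

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf(
    "FeatureTable: %d ROIs x 11 features, direction %s, levelOffset %d\n",
    length(object@roiIndex), object@direction@name, object@levelOffset))
})

#' Assemble dense feature maps from a feature table
#'
#' Renders each feature as a dense 2-D grid with one cell per ROI
#' position. With the default top-left anchor, cell (i, j) of a
#' \code{(height - roiHeight + 1) x (width - roiWidth + 1)} grid holds the
#' feature of the ROI whose top-left pixel is (i, j). With
#' \code{anchor = "center"} the maps are full image-sized grids with each
#' value placed at the window's central pixel
#' (offset \code{floor((roi - 1) / 2)}) and NA outside.
#'
#' @param table a [FeatureTable-class] covering every ROI position.
#' @param features character subset of feature names; default all 11.
#' @param logDisplay if TRUE, apply a natural-log display transform to the
#'   LGRE, LRHGE, LRLGE and SRLGE maps (these features crowd near 0 or
#'   blow up, so the transform spreads their dynamic range for
#'   visualization); never applied to the other features and never a
#'   default.
#' @param anchor \code{"topleft"} (default) or \code{"center"}.
#' @return a named list of numeric matrices.
#' @examples
#' fx <- workedExample()
#' ft <- extractFeatures(glrlm(fx$image, roiSpec(5, 5), "H0"))
#' featureMaps(ft)$RP  # 1 x 1 map
#' @export
featureMaps <- function(table, features = .FEATURE_NAMES,
                        logDisplay = FALSE,
                        anchor = c("topleft", "center")) {
  anchor <- match.arg(anchor)
  features <- match.arg(features, .FEATURE_NAMES, several.ok = TRUE)
  W <- table@imageWidth; H <- table@imageHeight
  mh <- H - table@spec@roiHeight + 1L
  mw <- W - table@spec@roiWidth + 1L
  i <- table@roiIndex %/% W
  j <- table@roiIndex %% W
  if (length(table@roiIndex) != mh * mw || any(i >= mh) || any(j >= mw))
    .glrlmError("glrlmCompletenessError",
                "feature table does not cover every ROI position")
  logf <- c("LGRE", "LRHGE", "LRLGE", "SRLGE")
  out <- lapply(features, function(f) {
    v <- table@values[, f]
    if (logDisplay && f %in% logf) v <- log(v)
    m <- matrix(NA_real_, mh, mw)
    m[cbind(i + 1L, j + 1L)] <- v
    if (anchor == "center") {
      full <- matrix(NA_real_, H, W)
      oy <- (table@spec@roiHeight - 1L) %/% 2L
      ox <- (table@spec@roiWidth - 1L) %/% 2L
      full[(1L + oy):(mh + oy), (1L + ox):(mw + ox)] <- m
      m <- full
    }
    m
  })
  names(out) <- features
  out
}
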