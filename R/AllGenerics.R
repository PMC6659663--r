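#' Accessor generics
#'
#' Accessors for the package's S4 containers: pixel grid, gray-level
#' resolution, direction, ROI geometry, sparse keys/counts and feature
#' values. Slots are never accessed directly by user code.
#'
#' @param x an object of one of the package's classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("glResolution", function(x) standardGeneric("glResolution"))

#' @rdname accessors
#' @export
setGeneric("directionOf", function(x) standardGeneric("directionOf"))

#' @rdname accessors
#' @export
setGeneric("directionName", function(x) standardGeneric("directionName"))

#' @rdname accessors
#' @export
setGeneric("directionStep", function(x) standardGeneric("directionStep"))

#' @rdname accessors
#' @export
setGeneric("roiWidth", function(x) standardGeneric("roiWidth"))

#' @rdname accessors
#' @export
setGeneric("roiHeight", function(x) standardGeneric("roiHeight"))

#' @rdname accessors
#' @export
setGeneric("roiLength", function(x) standardGeneric("roiLength"))

#' @rdname accessors
#' @export
setGeneric("nPixels", function(x) standardGeneric("nPixels"))

#' @rdname accessors
#' @export
setGeneric("levelOffset", function(x) standardGeneric("levelOffset"))

#' @rdname accessors
#' @export
setGeneric("glrlmKeys", function(x) standardGeneric("glrlmKeys"))

#' @rdname accessors
#' @export
setGeneric("glrlmCounts", function(x) standardGeneric("glrlmCounts"))

#' @rdname accessors
#' @export
setGeneric("glrlmEntries", function(x) standardGeneric("glrlmEntries"))

#' @rdname accessors
#' @export
setGeneric("roiIndex", function(x) standardGeneric("roiIndex"))

#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' Decode packed keys of a sparse GLRLM batch
#'
#' Inverts the key encoding: for a packed key
#' \code{key = (roi * G + gray) * roiLength + run - 1} the decoded triple is
#' \code{roi = (key \%/\% roiLength) \%/\% G},
#' \code{gray = (key \%/\% roiLength) \%\% G} and
#' \code{run = key \%\% roiLength + 1} (integer arithmetic throughout).
#'
#' @param x a [GLRLMBatch-class] object.
#' @return a data.frame with columns \code{roi_index}, \code{gray_level},
#'   \code{run_length} and \code{count}, rows in key order.
#' @examples
#' fx <- workedExample()
#' b <- glrlm(fx$image, roiSpec(5, 5), "H0")
#' decodeKeys(b)
#' @export
setGeneric("decodeKeys", function(x) standardGeneric("decodeKeys"))
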