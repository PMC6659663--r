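#' Read a grayscale image from PNG, PGM or CSV
#'
#' Decodes an 8-bit grayscale PNG (via the png package), a PGM file (plain
#' P2 or binary P5, maxval up to 255) or a plain comma-separated integer
#' matrix, and validates it against the gray-level resolution. PNG files
#' with identical color channels are accepted as grayscale; genuinely
#' colored PNGs are rejected.
#'
#' @param path file path; format chosen by extension (.png, .pgm,
#'   anything else is parsed as CSV).
#' @param glResolution number of gray levels (default 256).
#' @return a [GrayImage-class].
#' @export
readGrayImage <- function(path, glResolution = 256) {
  if (!file.exists(path))
    .glrlmError("glrlmIOError", sprintf("cannot read '%s': no such file",
                                        path))
  ext <- tolower(tools::file_ext(path))
  raw_grid <- switch(ext,
                     png = .readPNGGray(path),
                     pgm = .readPGM(path),
                     .readCSVMatrix(path))
  tryCatch(grayImage(raw_grid, glResolution),
           glrlmRangeError = function(e)
             .glrlmError("glrlmRangeError",
                         sprintf("in '%s': %s", path, conditionMessage(e))))
}

.readPNGGray <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) {
    ch <- min(dim(a)[3L], 3L)  # ignore an alpha channel
    for (k in seq_len(ch)[-1L])
      if (any(a[, , k] != a[, , 1L]))
        .glrlmError("glrlmIOError",
                    sprintf("'%s' is not a grayscale image", path))
    a <- a[, , 1L]
  }
  round(a * 255)
}

.readPGM <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  ints <- as.integer(bytes)
  ws <- c(9L, 10L, 11L, 12L, 13L, 32L)  # ASCII whitespace
  ## header over raw bytes: magic, width, height, maxval; #-comments allowed
  tokens <- character(0); i <- 1L; n <- length(ints)
  while (length(tokens) < 4L && i <= n) {
    b <- ints[i]
    if (b == 35L) {                      # '#'
      while (i <= n && ints[i] != 10L) i <- i + 1L
    } else if (b %in% ws) {
      i <- i + 1L
    } else {
      j <- i
      while (j <= n && !(ints[j] %in% ws) && ints[j] != 35L) j <- j + 1L
      tokens <- c(tokens, rawToChar(bytes[i:(j - 1L)]))
      i <- j
    }
  }
  if (length(tokens) < 4L || !(tokens[1L] %in% c("P2", "P5")))
    .glrlmError("glrlmIOError",
                sprintf("'%s' is not a P2/P5 PGM file", path))
  w <- as.integer(tokens[2L]); h <- as.integer(tokens[3L])
  maxval <- as.integer(tokens[4L])
  if (is.na(w) || is.na(h) || is.na(maxval) || maxval > 255L)
    .glrlmError("glrlmIOError",
                sprintf("'%s': unsupported PGM header", path))
  if (tokens[1L] == "P2") {
    vals <- suppressWarnings(
      as.integer(strsplit(trimws(rawToChar(bytes[i:n])),
                          "[[:space:]]+")[[1L]]))
  } else {
    ## a single whitespace byte separates the header from binary data
    vals <- if (i < n) ints[(i + 1L):n] else integer(0)
  }
  if (length(vals) < w * h || anyNA(vals[seq_len(w * h)]))
    .glrlmError("glrlmIOError", sprintf("'%s': truncated PGM data", path))
  matrix(vals[seq_len(w * h)], nrow = h, ncol = w, byrow = TRUE)
}

.readCSVMatrix <- function(path) {
  d <- utils::read.csv(path, header = FALSE)
  m <- as.matrix(d)
  if (!is.numeric(m))
    .glrlmError("glrlmIOError",
                sprintf("'%s': non-numeric CSV matrix", path))
  dimnames(m) <- NULL
  m
}

#' Write / read a sparse batch as decoded triplets
#'
#' `writeGLRLMTriplets()` serializes a batch as a CSV with header
#' \code{roi_index,gray_level,run_length,count}, rows in key order, LF
#' line endings; all values are integers so the round trip is lossless.
#' `readGLRLMTriplets()` rebuilds the batch given the geometry the file
#' does not carry.
#'
#' @param batch a [GLRLMBatch-class].
#' @param path output (input) CSV path.
#' @param spec,glResolution,direction,imageWidth,imageHeight geometry of
#'   the original image and windows, needed to re-encode the keys.
#' @return `writeGLRLMTriplets()` returns the path invisibly;
#'   `readGLRLMTriplets()` returns a [GLRLMBatch-class].
#' @export
writeGLRLMTriplets <- function(batch, path) {
  utils::write.table(decodeKeys(batch), path, sep = ",", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname writeGLRLMTriplets
#' @export
readGLRLMTriplets <- function(path, spec, glResolution, direction,
                              imageWidth, imageHeight) {
  direction <- glrlmDirection(direction)
  d <- utils::read.csv(path)
  keys <- (d$roi_index * glResolution + d$gray_level) * roiLength(spec) +
    d$run_length - 1
  new("GLRLMBatch", keys = as.numeric(keys), counts = as.numeric(d$count),
      spec = spec, glResolution = as.integer(glResolution),
      direction = direction, imageWidth = as.integer(imageWidth),
      imageHeight = as.integer(imageHeight))
}

#' Write dense feature maps to disk
#'
#' Writes, per feature, a CSV matrix at full double precision (the
#' normative output) and optionally a min-max normalized 8-bit grayscale
#' PNG for visual inspection. File names follow
#' \code{<prefix><FEATURE>_d<degrees>.<ext>} with zero-padded degree
#' labels (d000, d045, d090, d135). When \code{logDisplay} is TRUE the
#' natural-log display transform is applied to the LGRE, LRHGE, LRLGE and
#' SRLGE maps before writing the PNGs only; CSV values are never
#' transformed.
#'
#' @param table a [FeatureTable-class].
#' @param outDir output directory, created if needed.
#' @param formats subset of \code{c("csv", "png")}.
#' @param features subset of the 11 feature names; default all.
#' @param prefix optional file-name prefix.
#' @param logDisplay apply the log display transform to the PNGs of the
#'   four wide-range features.
#' @return invisibly, the vector of files written.
#' @export
writeFeatureMaps <- function(table, outDir, formats = "csv",
                             features = .FEATURE_NAMES, prefix = "",
                             logDisplay = FALSE) {
  formats <- match.arg(formats, c("csv", "png"), several.ok = TRUE)
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    .glrlmError("glrlmIOError", sprintf("cannot create '%s'", outDir))
  deg <- c(H0 = "d000", AD45 = "d045", V90 = "d090", D135 = "d135")
  tag <- deg[[table@direction@name]]
  maps <- featureMaps(table, features = features)
  written <- character(0)
  for (f in names(maps)) {
    m <- maps[[f]]
    if ("csv" %in% formats) {
      p <- file.path(outDir, sprintf("%s%s_%s.csv", prefix, f, tag))
      ## %.17g round-trips IEEE doubles bit-exactly
      txt <- apply(m, 1L, function(r)
        paste(sprintf("%.17g", r), collapse = ","))
      writeLines(txt, p, sep = "\n")
      written <- c(written, p)
    }
    if ("png" %in% formats) {
      v <- m
      if (logDisplay && f %in% c("LGRE", "LRHGE", "LRLGE", "SRLGE"))
        v <- log(v)
      rng <- range(v)
      scaled <- if (rng[1L] == rng[2L]) v * 0 else
        (v - rng[1L]) / (rng[2L] - rng[1L])
      p <- file.path(outDir, sprintf("%s%s_%s.png", prefix, f, tag))
      png::writePNG(scaled, p)
      written <- c(written, p)
    }
  }
  invisible(written)
}
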