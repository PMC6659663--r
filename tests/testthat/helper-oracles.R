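## Independent brute-force oracles, deliberately naive: plain per-pixel
## walks and double loops over dense matrices, sharing no code with the
## package's engines.

DIR_STEPS <- list(H0 = c(1L, 0L), AD45 = c(1L, -1L),
                  V90 = c(0L, -1L), D135 = c(-1L, -1L))

## GLRLM of one window of a raw matrix, counting runs pixel by pixel
oracleGLRLM <- function(mat, top_row, top_col, w, h, dirname) {
  st <- DIR_STEPS[[dirname]]
  dx <- st[1L]; dy <- st[2L]
  inROI <- function(y, x) y >= 0L && y < h && x >= 0L && x < w
  counts <- new.env()
  bump <- function(gray, run) {
    key <- paste(gray, run)
    counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
  }
  for (y0 in 0:(h - 1L)) for (x0 in 0:(w - 1L)) {
    if (inROI(y0 + dy * -1L, x0 + dx * -1L)) next  # not a line start
    y <- y0; x <- x0
    cur <- mat[top_row + y + 1L, top_col + x + 1L]
    run <- 1L
    repeat {
      yn <- y + dy; xn <- x + dx
      if (!inROI(yn, xn)) { bump(cur, run); break }
      v <- mat[top_row + yn + 1L, top_col + xn + 1L]
      if (v == cur) run <- run + 1L else { bump(cur, run); cur <- v; run <- 1L }
      y <- yn; x <- xn
    }
  }
  keys <- ls(counts)
  parts <- do.call(rbind, lapply(strsplit(keys, " "), as.integer))
  d <- data.frame(gray_level = parts[, 1L], run_length = parts[, 2L],
                  count = vapply(keys, function(k) counts[[k]], integer(1)))
  d <- d[order(d$gray_level, d$run_length), , drop = FALSE]
  rownames(d) <- NULL
  d
}

## all-ROI oracle as a decoded triple table sorted like a batch
oracleAllROIs <- function(mat, w, h, dirname) {
  H <- nrow(mat); W <- ncol(mat)
  out <- list(); n <- 0L
  for (i in 0:(H - h)) for (j in 0:(W - w)) {
    g <- oracleGLRLM(mat, i, j, w, h, dirname)
    g$roi_index <- i * W + j
    n <- n + 1L
    out[[n]] <- g[, c("roi_index", "gray_level", "run_length", "count")]
  }
  d <- do.call(rbind, out)
  d <- d[order(d$roi_index, d$gray_level, d$run_length), , drop = FALSE]
  rownames(d) <- NULL
  d
}

## the 11 features by double loops over a dense matrix rebuilt from triples
oracleFeatures <- function(triples, N, levelOffset = 1) {
  grays <- sort(unique(triples$gray_level))
  runs <- sort(unique(triples$run_length))
  P <- matrix(0, length(grays), length(runs),
              dimnames = list(grays, runs))
  for (r in seq_len(nrow(triples)))
    P[as.character(triples$gray_level[r]),
      as.character(triples$run_length[r])] <- triples$count[r]
  S <- 0; sre <- 0; lre <- 0; lgre <- 0; hgre <- 0
  srlge <- 0; srhge <- 0; lrlge <- 0; lrhge <- 0
  for (a in seq_along(grays)) for (b in seq_along(runs)) {
    p <- P[a, b]
    i <- grays[a] + levelOffset; j <- runs[b]
    S <- S + p
    sre <- sre + p / j^2;        lre <- lre + p * j^2
    lgre <- lgre + p / i^2;      hgre <- hgre + p * i^2
    srlge <- srlge + p / (i^2 * j^2); srhge <- srhge + p * i^2 / j^2
    lrlge <- lrlge + p * j^2 / i^2;   lrhge <- lrhge + p * i^2 * j^2
  }
  gln <- 0
  for (a in seq_along(grays)) gln <- gln + sum(P[a, ])^2
  rln <- 0
  for (b in seq_along(runs)) rln <- rln + sum(P[, b])^2
  c(SRE = sre / S, LRE = lre / S, GLN = gln / S, RLN = rln / S,
    RP = S / N, LGRE = lgre / S, HGRE = hgre / S, SRLGE = srlge / S,
    SRHGE = srhge / S, LRLGE = lrlge / S, LRHGE = lrhge / S)
}

## batch as a plain decoded data.frame, for equality comparisons
batchTriples <- function(batch) {
  d <- decodeKeys(batch)
  rownames(d) <- NULL
  d
}
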