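test_that("line layout gives rectangle rows and triangular diagonals", {
  ll <- lineLayout(roiSpec(2, 2), "H0")
  expect_identical(ll$sizes, c(2L, 2L))
  expect_identical(ll$offsets, c(0L, 2L))

  d135 <- lineLayout(roiSpec(5, 5), "D135")
  expect_identical(d135$sizes, c(1L, 2L, 3L, 4L, 5L, 4L, 3L, 2L, 1L))
  expect_identical(sum(d135$sizes), 25L)
  expect_identical(d135$offsets, c(0L, cumsum(d135$sizes))[1:9])

  for (d in names(allDirections()))
    expect_identical(lineLayout(roiSpec(1, 1), d)$sizes, 1L)

  ad <- lineLayout(roiSpec(3, 5), "AD45")
  expect_identical(length(ad$sizes), 3L + 5L - 1L)
  expect_identical(max(ad$sizes), 3L)
  expect_identical(sum(ad$sizes), 15L)
})

test_that("the scatter interleaves ROI lines at the documented addresses", {
  img <- grayImage(matrix(1:6, 2, 3, byrow = TRUE), 256)
  keys <- expandROIs(img, roiSpec(2, 2), "H0")
  expect_identical(as.vector(keys), c(1, 2, 258, 259, 4, 5, 261, 262))
  ## address of entry l = 0 of line k = 1 of the second ROI:
  ## N_1 * numROIs + R_1 * rank + l = 2*2 + 2*1 + 0 = 6 (0-based)
  expect_identical(as.vector(keys)[6 + 1], 261)
  expect_identical(length(attr(keys, "lineSegments")), 8L)
})

test_that("1x1 windows scatter one entry per ROI", {
  img <- synthRandom(3, 4, 8, seed = 1)
  keys <- expandROIs(img, roiSpec(1, 1), "H0")
  pos <- roiPositions(img, roiSpec(1, 1))
  px <- pixels(img)
  want <- pos$roi_index * 8 + px[cbind(pos$top_row + 1, pos$top_col + 1)]
  expect_identical(as.vector(keys), want)
})

test_that("the scatter is a bijection onto [0, numROIs * N)", {
  ## with all intensities >= 1 no scatter slot can retain its initial 0,
  ## so full length + no leftover zeros witnesses every address written
  img <- grayImage(pixels(synthRandom(7, 9, 4, seed = 2)) + 1L, 8)
  for (d in names(allDirections())) {
    sp <- roiSpec(3, 4)
    keys <- expandROIs(img, sp, d)
    expect_identical(length(keys), numROIs(img, sp) * nPixels(sp))
    expect_true(all(keys %% 8 >= 1))
    ## multiset of scattered keys equals one copy of each ROI pixel
    pos <- roiPositions(img, sp)
    px <- pixels(img)
    want <- unlist(lapply(seq_len(nrow(pos)), function(p) {
      sub <- px[pos$top_row[p] + 1:4, pos$top_col[p] + 1:3]
      pos$roi_index[p] * 8 + as.vector(sub)
    }))
    expect_identical(sort(as.vector(keys)), sort(want))
  }
})

test_that("reduce-by-key collapses adjacent equal keys into run lengths", {
  r <- reduceRuns(c(7, 7, 7, 9, 7))
  expect_identical(r$keys, c(7, 9, 7))
  expect_identical(r$runs, c(3L, 1L, 1L))

  r2 <- reduceRuns(c(1, 2, 258, 259, 4, 5, 261, 262))
  expect_identical(r2$keys, c(1, 2, 258, 259, 4, 5, 261, 262))
  expect_true(all(r2$runs == 1L))

  r3 <- reduceRuns(numeric(0))
  expect_identical(r3$keys, numeric(0))
  expect_identical(r3$runs, integer(0))

  ## segment boundaries stop runs even when keys match across them
  r4 <- reduceRuns(c(5, 5, 5, 5), segments = c(1L, 1L, 2L, 2L))
  expect_identical(r4$runs, c(2L, 2L))
})

test_that("key packing and decoding are exact inverses", {
  expect_identical(combineKeys(773, 2, 4), 3093)
  expect_identical(combineKeys(7, 1, 2), 14)
  expect_error(combineKeys(7, 3, 2), class = "glrlmConsistencyError")

  ## exhaustive round trip at small scale
  G <- 5; L <- 4
  roi <- rep(0:40, each = G * L)
  gray <- rep(rep(0:(G - 1), each = L), times = 41)
  run <- rep(1:L, times = 41 * G)
  key <- combineKeys(roi * G + gray, run, L)
  expect_identical((key %/% L) %/% G, as.numeric(roi))
  expect_identical((key %/% L) %% G, as.numeric(gray))
  expect_identical(key %% L + 1, as.numeric(run))
})

test_that("sorting merges equal keys with occurrence counts", {
  s <- sortAndCount(c(14, 14, 3, 14))
  expect_identical(s$keys, c(3, 14))
  expect_identical(s$counts, c(1L, 3L))
  s0 <- sortAndCount(numeric(0))
  expect_identical(length(s0$keys), 0L)
})

test_that("the full batch pipeline handles a single-ROI image", {
  ## row 3 ends with the intensity row 4 starts with, so a reduce that
  ## ignored line boundaries would fuse a run across rows
  fx <- workedExample()
  for (d in names(fx$expected)) {
    got <- batchTriples(glrlm(fx$image, roiSpec(5, 5), d, engine = "batch"))
    expect_equal(got[, c("gray_level", "run_length", "count")],
                 fx$expected[[d]], ignore_attr = TRUE)
  }
})

test_that("constant image with truncating windows decodes to capped runs", {
  img <- synthConstant(3, 3, 7)
  b <- glrlm(img, roiSpec(2, 2), "H0", engine = "batch")
  d <- decodeKeys(b)
  expect_identical(nrow(d), 4L)
  expect_true(all(d$gray_level == 7 & d$run_length == 2 & d$count == 2))
})

test_that("all three engines agree exactly on randomized images", {
  cases <- expand.grid(G = c(2, 8, 256), size = c(2, 5), seed = 1:2)
  for (r in seq_len(nrow(cases))) {
    img <- synthRandom(12, 14, cases$G[r], seed = 100 + cases$seed[r])
    sp <- roiSpec(cases$size[r], cases$size[r])
    for (d in names(allDirections())) {
      b <- glrlm(img, sp, d, engine = "batch")
      s <- glrlm(img, sp, d, engine = "sequential")
      o <- glrlm(img, sp, d, engine = "oracle")
      expect_identical(glrlmKeys(b), glrlmKeys(s))
      expect_identical(glrlmCounts(b), glrlmCounts(s))
      expect_identical(glrlmKeys(b), glrlmKeys(o))
      expect_identical(glrlmCounts(b), glrlmCounts(o))
    }
  }
})

test_that("rectangular windows agree across engines too", {
  img <- synthRandom(10, 7, 8, seed = 9)
  for (d in names(allDirections())) {
    sp <- roiSpec(4, 2)
    b <- batchTriples(glrlm(img, sp, d, engine = "batch"))
    o <- oracleAllROIs(pixels(img), 4, 2, d)
    expect_equal(b, o, ignore_attr = TRUE)
  }
})

test_that("the key capacity bound is enforced up front", {
  img <- grayImage(matrix(0L, 300, 300), glResolution = 2^30)
  expect_error(glrlm(img, roiSpec(150, 150), "H0"),
               class = "glrlmCapacityError")
  expect_error(expandROIs(img, roiSpec(150, 150), "H0"),
               class = "glrlmCapacityError")
})

test_that("batch keys decode back to ROI, gray and run", {
  fx <- workedExample()
  b <- glrlm(fx$image, roiSpec(5, 5), "H0")
  d <- decodeKeys(b)
  expect_identical(names(d),
                   c("roi_index", "gray_level", "run_length", "count"))
  expect_true(all(d$roi_index == 0))
  single <- glrlmFromBatch(b, 0)
  expect_equal(glrlmEntries(single), fx$expected$H0, ignore_attr = TRUE)
  expect_error(glrlmFromBatch(b, 99), class = "glrlmGeometryError")
})
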