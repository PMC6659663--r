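test_that("worked-example features match the dense double-loop oracle", {
  fx <- workedExample()
  b <- glrlm(fx$image, roiSpec(5, 5), "H0")
  got <- featureValues(extractFeatures(b))[1, ]
  want <- oracleFeatures(fx$expected$H0, N = 25, levelOffset = 1)
  expect_equal(got, want, tolerance = 1e-12)

  ## frozen exact fractions derived from the published matrix
  expect_equal(got[["SRE"]], 19.75 / 22, tolerance = 1e-12)
  expect_equal(got[["LRE"]], 31 / 22, tolerance = 1e-12)
  expect_equal(got[["GLN"]], 100 / 22, tolerance = 1e-12)
  expect_equal(got[["RLN"]], 370 / 22, tolerance = 1e-12)
  expect_identical(got[["RP"]], 0.88)
  expect_equal(got[["HGRE"]], 451832 / 22, tolerance = 1e-12)

  S <- roiRunTotals(b)
  expect_identical(S$S, 22)
})

test_that("category-based reductions equal dense loops on random batches", {
  for (seed in 1:3) {
    img <- synthRandom(10, 12, 8, seed = 200 + seed)
    sp <- roiSpec(4, 4)
    for (d in c("H0", "AD45")) {
      b <- glrlm(img, sp, d)
      tab <- extractFeatures(b)
      dec <- decodeKeys(b)
      for (roi in roiIndex(tab)[c(1, 17, 35)]) {
        trip <- dec[dec$roi_index == roi, ]
        want <- oracleFeatures(trip, N = nPixels(sp), levelOffset = 1)
        got <- featureValues(tab)[match(roi, roiIndex(tab)), ]
        expect_equal(got, want, tolerance = 1e-12)
      }
    }
  }
})

test_that("constant windows have the closed-form feature values", {
  w <- 4; h <- 3
  img <- synthConstant(h, w, 6)
  b <- glrlm(img, roiSpec(w, h), "H0")
  v <- featureValues(extractFeatures(b))[1, ]
  expect_identical(v[["SRE"]], 1 / w^2)
  expect_identical(v[["LRE"]], w^2)
  expect_identical(v[["RP"]], 1 / w)
  expect_identical(v[["GLN"]], as.numeric(h))  # GLN = S for one gray row
  expect_identical(v[["RLN"]], as.numeric(h))
  expect_equal(v[["LGRE"]], 1 / 49, tolerance = 1e-15)  # single level 6 + 1
  expect_equal(v[["HGRE"]], 49, tolerance = 1e-15)
})

test_that("checkerboards make every run length one", {
  ## the all-runs-length-one property holds along the horizontal and
  ## vertical directions; diagonal neighbors of a checkerboard share
  ## parity, so diagonal runs span whole diagonals instead
  img <- synthCheckerboard(6, 6, 1, 3, 8)
  sp <- roiSpec(4, 4)
  for (d in c("H0", "V90")) {
    tab <- extractFeatures(glrlm(img, sp, d))
    v <- featureValues(tab)
    expect_true(all(v[, "RP"] == 1))
    expect_true(all(v[, "SRE"] == 1))
    expect_true(all(v[, "LRE"] == 1))
    expect_true(all(v[, "RLN"] == nPixels(sp)))
  }
  ## two-value checkerboard with even N: GLN = N / 2
  b <- glrlm(img, sp, "H0")
  expect_true(all(grayLevelNonuniformity(b) == nPixels(sp) / 2))
})

test_that("marginal nonuniformities match hand sums on the worked example", {
  fx <- workedExample()
  b <- glrlm(fx$image, roiSpec(5, 5), "H0")
  S <- roiRunTotals(b)
  expect_equal(grayLevelNonuniformity(b, S),
               (4^2 + 5^2 + 5^2 + 3^2 + 5^2) / 22, tolerance = 1e-12)
  expect_equal(runLengthNonuniformity(b, S), (19^2 + 3^2) / 22,
               tolerance = 1e-12)
  expect_identical(runPercentage(S, roiSpec(5, 5)), 22 / 25)
})

test_that("short and long run emphases bracket one another", {
  img <- synthRandom(9, 9, 4, seed = 77)
  for (d in names(allDirections())) {
    v <- featureValues(extractFeatures(glrlm(img, roiSpec(3, 3), d)))
    expect_true(all(v[, "SRE"] > 0 & v[, "SRE"] <= 1))
    expect_true(all(v[, "LRE"] >= 1))
    expect_true(all(v[, "RP"] > 0 & v[, "RP"] <= 1))
    expect_true(all((v[, "RP"] == 1) == (v[, "LRE"] == 1)))
  }
})

test_that("level offset zero with gray level zero raises a domain error", {
  fx <- workedExample()  # contains intensity 0
  b0 <- glrlm(fx$image, roiSpec(5, 5, levelOffset = 0), "H0")
  err <- expect_error(extractFeatures(b0), class = "glrlmDomainError")
  expect_match(conditionMessage(err), "ROI 0")
  ## weights without 1/i^2 still work at offset 0
  expect_no_error(weightedFeature(b0, "i2"))
  ## an image without zeros is fine at offset 0
  img <- grayImage(pixels(fx$image) + 1L, 257)
  bz <- glrlm(img, roiSpec(5, 5, levelOffset = 0), "H0")
  v <- featureValues(extractFeatures(bz))
  expect_equal(as.numeric(v[1, "HGRE"]), 451832 / 22, tolerance = 1e-12)
})

test_that("extraction emits exactly 11 named features per ROI", {
  img <- synthRandom(8, 8, 8, seed = 4)
  tab <- extractFeatures(glrlm(img, roiSpec(3, 3), "V90"))
  expect_identical(ncol(featureValues(tab)), 11L)
  expect_identical(colnames(featureValues(tab)),
                   c("SRE", "LRE", "GLN", "RLN", "RP", "LGRE", "HGRE",
                     "SRLGE", "SRHGE", "LRLGE", "LRHGE"))
  expect_identical(nrow(featureValues(tab)), 36L)
})

test_that("feature maps are dense grids keyed by window position", {
  fx <- workedExample()
  m1 <- featureMaps(extractFeatures(glrlm(fx$image, roiSpec(5, 5), "H0")))
  expect_identical(dim(m1$SRE), c(1L, 1L))

  img <- grayImage(matrix(1:6, 2, 3, byrow = TRUE), 256)
  m2 <- featureMaps(extractFeatures(glrlm(img, roiSpec(2, 2), "H0")))
  expect_identical(dim(m2$RP), c(1L, 2L))

  img8 <- synthConstant(8, 8, 3)
  m3 <- featureMaps(extractFeatures(glrlm(img8, roiSpec(4, 4), "H0")))
  expect_identical(dim(m3$RP), c(5L, 5L))
  expect_true(all(m3$RP == 0.25))  # RP = 1/roiWidth for constant images

  ## log display transform only touches the four wide-range features
  m4 <- featureMaps(extractFeatures(glrlm(img8, roiSpec(4, 4), "H0")),
                    logDisplay = TRUE)
  expect_equal(m4$LGRE, log(m3$LGRE))
  expect_identical(m4$SRE, m3$SRE)

  ## center anchoring pads to image shape
  m5 <- featureMaps(extractFeatures(glrlm(img8, roiSpec(4, 4), "H0")),
                    features = "RP", anchor = "center")
  expect_identical(dim(m5$RP), c(8L, 8L))
  expect_identical(sum(!is.na(m5$RP)), 25L)
})
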