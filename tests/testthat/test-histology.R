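test_that("boxSum matches a naive windowed sum", {
  set.seed(21)
  x <- matrix(runif(12 * 9), 12, 9)
  w <- 5L; h <- 2L
  naive <- matrix(0, 12, 9)
  for (i in 1:12) for (j in 1:9) {
    naive[i, j] <- sum(x[max(1, i - h):min(12, i + h),
                         max(1, j - h):min(9, j + h)])
  }
  expect_equal(ablaquant:::boxSum(x, w), naive, tolerance = 1e-12)
})

test_that("local entropy is zero on flat images and positive on texture", {
  flat <- matrix(0.5, 40, 40)
  expect_true(all(localEntropy(flat) == 0))
  set.seed(22)
  tex <- matrix(runif(40 * 40), 40, 40)
  e <- localEntropy(tex)
  expect_true(mean(e) > 0.5)
  expect_true(all(e >= 0 & e <= 1))
})

test_that("connected-component labelling honours its connectivity", {
  m <- matrix(FALSE, 4, 4); m[1, 1] <- m[2, 2] <- TRUE  # touch diagonally
  expect_equal(max(labelComponents(m, 8L)), 1L)
  expect_equal(max(labelComponents(m, 4L)), 2L)
  a <- array(FALSE, c(3, 3, 3)); a[1, 1, 1] <- a[2, 2, 2] <- TRUE
  expect_equal(max(labelComponents(a, 26L)), 1L)
  expect_equal(max(labelComponents(a, 6L)), 2L)
  # labels come out in decreasing size order
  m2 <- matrix(FALSE, 10, 10); m2[1:2, 1:2] <- TRUE; m2[8:10, 8:10] <- TRUE
  lab <- labelComponents(m2)
  expect_equal(sum(lab == 1L), 9L)
  expect_equal(sum(lab == 2L), 4L)
})

test_that("a blank slide yields empty tissue with a warning", {
  img <- array(0.8, c(120, 120, 3))
  sec <- HistologySection(img, pixelSize = 20)
  expect_warning(seg <- segmentTissue(sec, threshold = 0.3), "empty tissue")
  expect_equal(tissueArea(seg), 0)
})

test_that("tissue area of a textured disc is recovered within 3%", {
  ss <- makeSlideSeries()
  sec <- ss$sections[[4]]  # a mid-series section
  seg <- segmentTissue(sec, threshold = 0.3)
  spec <- truthRecord(ss$truth)$spec
  trueArea <- pi * prod(spec$tissueRadiiMm) * 0.01  # cm^2
  expect_lt(abs(tissueArea(seg) - trueArea) / trueArea, 0.03)
  expect_gt(length(boundaries(seg)), 0)
  # background removed from the masked copy
  expect_true(all(maskedImage(seg)[, , 3][!maskArray(seg)] == 0))
})

test_that("textured specks below the minimum region size are deleted", {
  set.seed(23)
  h <- 420L; w <- 420L
  tissue <- paintDisc(matrix(FALSE, h, w), c(160L, 160L), 110L)
  speck <- matrix(FALSE, h, w); speck[320:419, 300:399] <- TRUE  # 10,000 px
  img <- array(0.9, c(h, w, 3))
  for (ch in 1:3) {
    plane <- img[, , ch]
    base <- c(0.45, 0.5, 0.8)[ch]
    n <- sum(tissue | speck)
    plane[tissue | speck] <- pmin(pmax(
      base * (1 + rnorm(n, 0, 0.06)), 0), 1)
    img[, , ch] <- plane
  }
  seg <- segmentTissue(HistologySection(img, pixelSize = 20), threshold = 0.3)
  expect_false(any(maskArray(seg)[330:410, 310:390]))  # speck gone
  expect_gt(sum(maskArray(seg)[tissue]), 0.9 * sum(tissue))  # disc retained
})

test_that("the canonical erode-fill-dilate order preserves open slits", {
  # a C-shaped tissue: a disc with a 20-px open slit from edge to center.
  # eroding first widens the slit before hole filling, so it survives; a
  # dilate-first order would seal its mouth and hole filling would erase it.
  set.seed(24)
  h <- 360L; w <- 360L
  ctr <- c(180L, 180L)
  tissue <- paintDisc(matrix(FALSE, h, w), ctr, 140L)
  tissue[170:190, 1:180] <- FALSE  # the slit
  img <- array(0.9, c(h, w, 3))
  for (ch in 1:3) {
    plane <- img[, , ch]
    base <- c(0.45, 0.5, 0.8)[ch]
    plane[tissue] <- pmin(pmax(
      base * (1 + rnorm(sum(tissue), 0, 0.06)), 0), 1)
    img[, , ch] <- plane
  }
  seg <- segmentTissue(HistologySection(img, pixelSize = 20), threshold = 0.3)
  expect_false(any(maskArray(seg)[178:182, 40:120]))      # slit kept open
  expect_true(all(maskArray(seg)[100:120, 200:220]))       # body kept
  # dilate-first sealing for contrast: the slit would have been absorbed
  brush <- EBImage::makeBrush(31, "disc")
  sealed <- EBImage::fillHull(EBImage::dilate(tissue * 1, brush))
  sealed <- EBImage::erode(sealed, brush) > 0
  expect_true(any(sealed[178:182, 40:120]))
})

test_that("the tissue mask of a convex section is stable under opening", {
  ss <- makeSlideSeries(slideSeriesSpec(fovMm = c(9, 9),
                                        radiiMm = c(1.8, 1.8, 1.8)))
  seg <- segmentTissue(ss$sections[[3]], threshold = 0.3)
  brush <- EBImage::makeBrush(31, "disc")
  opened <- EBImage::dilate(EBImage::erode(maskArray(seg) * 1, brush),
                            brush) > 0
  expect_equal(sum(xor(opened, maskArray(seg))), 0)
})

test_that("fully viable tissue has zero necrotic area", {
  tissue <- paintDisc(matrix(FALSE, 300, 300), c(150L, 150L), 120L)
  img <- flatSlideImage(tissue, matrix(FALSE, 300, 300))
  seg <- fakeTissueSeg(img, tissue)
  nr <- segmentNecrosis(seg, threshold = 0.7)
  expect_equal(necroticArea(nr), 0)
  expect_length(rois(nr), 0)
})

test_that("an unstained ellipse inside blue tissue is recovered", {
  tissue <- paintDisc(matrix(FALSE, 400, 400), c(200L, 200L), 180L)
  nec <- paintDisc(matrix(FALSE, 400, 400), c(200L, 200L), 60L)
  img <- flatSlideImage(tissue, nec)
  seg <- fakeTissueSeg(img, tissue, pixelSizeUm = 20)
  nr <- segmentNecrosis(seg, threshold = 0.7)
  trueArea <- sum(nec) * (20e-4)^2
  expect_equal(necroticArea(nr), trueArea, tolerance = 1e-12)
  expect_length(rois(nr), 1)
  expect_gt(nrow(rois(nr)[[1]]$boundary), 0)
})

test_that("only the five largest regions are retained, matching a sort oracle", {
  h <- 700L; w <- 600L
  radii <- c(44L, 47L, 50L, 53L, 56L, 59L, 62L)
  centers <- expand.grid(row = c(100L, 280L, 460L, 620L),
                         col = c(100L, 300L, 500L))[seq_along(radii), ]
  nec <- matrix(FALSE, h, w)
  sizes <- integer(length(radii))
  for (i in seq_along(radii)) {
    one <- paintDisc(matrix(FALSE, h, w),
                     c(centers$row[i], centers$col[i]), radii[i])
    sizes[i] <- sum(one)
    nec <- nec | one
  }
  expect_true(all(sizes >= 5000))
  tissue <- matrix(TRUE, h, w)
  seg <- fakeTissueSeg(flatSlideImage(tissue, nec), tissue, pixelSizeUm = 20)
  nr <- segmentNecrosis(seg, threshold = 0.7)
  expect_length(rois(nr), 5)
  # exhaustive sort oracle: the five largest painted discs
  want <- sum(sort(sizes, decreasing = TRUE)[1:5]) * (20e-4)^2
  expect_equal(necroticArea(nr), want, tolerance = 1e-12)
})

test_that("regions below 5000 pixels are removed, at the stated boundary", {
  h <- 300L; w <- 500L
  nec <- matrix(FALSE, h, w)
  nec[50:98, 50:151] <- TRUE            # 49 x 102 = 4998 px
  nec[99, 50] <- TRUE                   # 4999th connected pixel
  nec[150:199, 300:399] <- TRUE         # 50 x 100 = 5000 px, kept
  tissue <- matrix(TRUE, h, w)
  seg <- fakeTissueSeg(flatSlideImage(tissue, nec), tissue, pixelSizeUm = 20)
  nr <- segmentNecrosis(seg, threshold = 0.7)
  expect_length(rois(nr), 1)
  expect_equal(length(rois(nr)[[1]]$pixels), 5000L)
})

test_that("user exclusions drop flagged regions from the necrotic area", {
  h <- 400L; w <- 400L
  big <- paintDisc(matrix(FALSE, h, w), c(120L, 120L), 70L)
  small <- paintDisc(matrix(FALSE, h, w), c(300L, 300L), 45L)
  tissue <- matrix(TRUE, h, w)
  seg <- fakeTissueSeg(flatSlideImage(tissue, big | small), tissue,
                       pixelSizeUm = 20)
  full <- segmentNecrosis(seg, threshold = 0.7)
  expect_length(rois(full), 2)
  # exclude the largest (index 1 in size order), e.g. a vessel
  excl <- segmentNecrosis(seg, threshold = 0.7, exclusions = 1L)
  expect_length(rois(excl), 1)
  expect_equal(necroticArea(excl), sum(small) * (20e-4)^2,
               tolerance = 1e-12)
  expect_length(excl@excluded, 1)
})

test_that("raising the necrosis threshold never decreases the area", {
  ss <- makeSlideSeries()
  seg <- segmentTissue(ss$sections[[4]], threshold = 0.3)
  areas <- vapply(seq(0.55, 0.85, by = 0.05), function(t)
    necroticArea(segmentNecrosis(seg, threshold = t)), numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("doubling the pixel size quadruples reported areas exactly", {
  tissue <- paintDisc(matrix(FALSE, 300, 300), c(150L, 150L), 120L)
  nec <- paintDisc(matrix(FALSE, 300, 300), c(150L, 150L), 50L)
  img <- flatSlideImage(tissue, nec)
  a1 <- necroticArea(segmentNecrosis(
    fakeTissueSeg(img, tissue, pixelSizeUm = 20), threshold = 0.7))
  a2 <- necroticArea(segmentNecrosis(
    fakeTissueSeg(img, tissue, pixelSizeUm = 40), threshold = 0.7))
  expect_equal(a2, 4 * a1)
})

test_that("necroticVolume sums area times step with exact unit conversion", {
  mkNr <- function(area, idx, step = 1) {
    new("NecrosisResult", rois = list(), excluded = list(),
        necroticArea = area, pixelSize = 20, sectionIndex = as.integer(idx),
        stepSize = step)
  }
  nv <- necroticVolume(list(mkNr(0.01, 1), mkNr(0.02, 2), mkNr(0.03, 3)))
  expect_equal(volumeUl(nv), 6.0)  # 0.06 cm^2 x 1 mm = 6 mm^3

  expect_equal(volumeUl(necroticVolume(list())), 0)
  expect_equal(volumeUl(necroticVolume(list(mkNr(0, 1), mkNr(0, 2)))), 0)

  a <- 0.037; s <- 1.5
  expect_equal(volumeUl(necroticVolume(list(mkNr(a, 1, s)))), 100 * a * s)

  expect_error(necroticVolume(list(mkNr(0.01, 1, 1), mkNr(0.01, 2, 2))),
               "inconsistent step")
  # areas are ordered by section index regardless of list order
  nv2 <- necroticVolume(list(mkNr(0.03, 3), mkNr(0.01, 1), mkNr(0.02, 2)))
  expect_equal(perSectionAreas(nv2), c(0.01, 0.02, 0.03))
})

test_that("compareToManual reports signed and absolute differences", {
  cm0 <- compareToManual(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  expect_equal(cm0@meanSignedDifference, 0)
  expect_equal(cm0@meanAbsoluteDifference, 0)

  cm1 <- compareToManual(c(0.11, 0.21), c(0.10, 0.20))
  expect_equal(cm1@meanSignedDifference, 0.01)
  expect_equal(cm1@meanAbsoluteDifference, 0.01)

  auto <- c(0.12, 0.18, 0.33, 0.05)
  manual <- c(0.10, 0.20, 0.30, 0.07)
  cm2 <- compareToManual(auto, manual)
  expect_equal(cm2@meanSignedDifference, mean(auto - manual))
  expect_equal(cm2@meanAbsoluteDifference, mean(abs(auto - manual)))

  expect_error(compareToManual(1:3 / 10, 1:2 / 10), "equal length")
})
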