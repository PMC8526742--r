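test_that("toConcentration maps voxels and honours the tissue sentinel", {
  m <- fitTwoPoint(60, -340.3)
  g <- array(60, c(4, 4, 4))
  cv <- toConcentration(CtVolume(g, c(1, 1, 1)), m)
  expect_true(all(gridArray(cv) == 0))
  cv1 <- toConcentration(CtVolume(array(-340.3, c(4, 4, 4))), m)
  expect_true(all(gridArray(cv1) == 1))

  tissue <- array(FALSE, c(4, 4, 4)); tissue[2:3, 2:3, 2:3] <- TRUE
  cvm <- toConcentration(CtVolume(g), m, tissue)
  expect_true(all(is.na(gridArray(cvm)[!tissue])))
  expect_true(all(gridArray(cvm)[tissue] == 0))

  expect_error(toConcentration(CtVolume(g), m, array(TRUE, c(3, 3, 3))),
               "shape")
})

test_that("noise-free phantom inclusion voxels read their true concentration exactly", {
  ph <- makeInjectionPhantom()
  tr <- truthRecord(ph$truth)
  m <- fitTwoPoint(tr$huZero, tr$huHundred)
  cv <- toConcentration(ph$ct, m, ph$tissue)
  g <- gridArray(cv)
  inside <- !is.na(g) & g > 0.5
  expect_true(all(abs(g[inside] - 0.6) < 1e-12))
})

test_that("segmentDistribution matches a brute-force oracle on small masks", {
  set.seed(101)
  for (k in 1:6) {
    dims <- sample(4:14, 3, replace = TRUE)
    spacing <- runif(3, 0.3, 2)  # anisotropic
    mask <- randomMask(dims, density = runif(1, 0.05, 0.5))
    if (!any(mask)) next
    g <- array(NA_real_, dims)
    g[mask] <- 0.5
    g[!mask] <- 0.0
    d <- segmentDistribution(concVolume(g, spacing), lower = 0.2)
    o <- bruteForceMetrics(mask, spacing)
    expect_equal(volumeUl(d), o$volume, tolerance = 1e-12)
    expect_equal(centroid(d), o$centroid, tolerance = 1e-12)
    expect_equal(radiusOfGyration(d), o$rg, tolerance = 1e-12)
    expect_equal(aspectRatio(d), o$aspect, tolerance = 1e-12)
  }
})

test_that("a digitized solid ball has aspect ratio 3/4", {
  mask <- ballMask(20)
  g <- array(0, dim(mask)); g[mask] <- 0.6
  d <- segmentDistribution(concVolume(g), lower = 0.2)
  expect_equal(aspectRatio(d), 0.75, tolerance = 0.01)
  expect_equal(nComponents(d), 1L)
})

test_that("a 1x1xN rod matches an exhaustive-sum oracle", {
  N <- 101L
  g <- array(1, c(1, 1, N))
  d <- segmentDistribution(concVolume(g), lower = 0.2)
  ctr <- (N / 2)  # physical center along the rod
  rgOracle <- mean(abs((seq_len(N) - 0.5) - ctr))
  reffOracle <- (3 * N / (4 * pi))^(1 / 3)
  expect_equal(radiusOfGyration(d), rgOracle, tolerance = 1e-12)
  expect_equal(aspectRatio(d), rgOracle / reffOracle, tolerance = 1e-12)
})

test_that("degenerate distributions are handled without exceptions", {
  g <- array(0, c(3, 3, 3))
  expect_warning(d0 <- segmentDistribution(concVolume(g)), "empty")
  expect_equal(volumeUl(d0), 0)
  expect_true(is.nan(aspectRatio(d0)))

  g[2, 2, 2] <- 0.9
  d1 <- segmentDistribution(concVolume(g))
  expect_equal(radiusOfGyration(d1), 0)
  expect_equal(aspectRatio(d1), 0)
  expect_equal(volumeUl(d1), 1)
})

test_that("all qualifying voxels are kept, including disconnected components", {
  g <- array(0, c(10, 10, 10))
  g[2, 2, 2] <- 0.5; g[8, 8, 8] <- 0.5; g[2, 8, 2] <- 1.5
  d <- segmentDistribution(concVolume(g), lower = 0.2)
  expect_equal(volumeUl(d), 3)
  expect_equal(nComponents(d), 3L)
  # the 120% upper exclusion drops the hot voxel
  d2 <- segmentDistribution(concVolume(g), lower = 0.2, upper = 1.2)
  expect_equal(volumeUl(d2), 2)
})

test_that("volume is conserved across the lower/upper partition", {
  set.seed(11)
  g <- array(runif(8^3, 0, 1.5), c(8, 8, 8))
  g[sample(length(g), 50)] <- NA  # unevaluated voxels
  cv <- concVolume(g)
  total <- sum(!is.na(g))
  below <- sum(g < 0.2, na.rm = TRUE)
  above <- sum(g > 1.2, na.rm = TRUE)
  d <- segmentDistribution(cv, lower = 0.2, upper = 1.2)
  expect_equal(volumeUl(d) + below + above, total)
})

test_that("raising the threshold never increases the volume", {
  set.seed(12)
  g <- array(runif(6^3, 0, 1.3), c(6, 6, 6))
  cv <- concVolume(g)
  vols <- vapply(seq(0, 1.2, by = 0.1), function(t)
    volumeUl(suppressWarnings(segmentDistribution(cv, lower = t))),
    numeric(1))
  expect_true(all(diff(vols) <= 0))
})

test_that("volume and aspect ratio are invariant under axis permutation and flips", {
  ph <- makeInjectionPhantom(injectionPhantomSpec(
    gridShape = c(40, 44, 36), spacing = c(0.3, 0.25, 0.35),
    inclusions = list(list(center = NULL, radii = c(2, 1.5, 2.5),
                           concentration = 0.6, profile = "uniform"))))
  tr <- truthRecord(ph$truth)
  m <- fitTwoPoint(tr$huZero, tr$huHundred)
  cv <- toConcentration(ph$ct, m, ph$tissue)
  d0 <- segmentDistribution(cv)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    gp <- aperm(gridArray(cv), perm)
    cvp <- concVolume(gp, voxelSpacing(cv)[perm])
    dp <- segmentDistribution(cvp)
    expect_equal(volumeUl(dp), volumeUl(d0), tolerance = 1e-9)
    expect_equal(aspectRatio(dp), aspectRatio(d0), tolerance = 1e-9)
  }
  # mirror flip
  gr <- gridArray(cv)[dim(gridArray(cv))[1]:1, , ]
  dr <- segmentDistribution(concVolume(gr, voxelSpacing(cv)))
  expect_equal(aspectRatio(dr), aspectRatio(d0), tolerance = 1e-9)
})

test_that("halving the voxel spacing changes ellipsoid metrics only slightly", {
  mk <- function(shape, sp) makeInjectionPhantom(injectionPhantomSpec(
    gridShape = shape, spacing = rep(sp, 3),
    inclusions = list(list(center = NULL, radii = c(2, 1.6, 2.4),
                           concentration = 0.6, profile = "uniform"))))
  coarse <- mk(c(60, 60, 60), 0.2)
  fine <- mk(c(120, 120, 120), 0.1)
  seg <- function(ph) {
    tr <- truthRecord(ph$truth)
    m <- fitTwoPoint(tr$huZero, tr$huHundred)
    segmentDistribution(toConcentration(ph$ct, m, ph$tissue))
  }
  dc <- seg(coarse); df <- seg(fine)
  expect_lt(abs(volumeUl(df) - volumeUl(dc)) / volumeUl(dc), 0.02)
  expect_lt(abs(aspectRatio(df) - aspectRatio(dc)), 0.02)
})

test_that("cumulative volume curves follow their definition", {
  # uniform 0.5 block
  g <- array(0.5, c(5, 5, 4))
  cv <- concVolume(g, c(1, 1, 1))
  curve <- cumulativeVolumeCurve(cv)
  expect_true(all(abs(volumes(curve)[thresholds(curve) <= 0.5] - 100) < 1e-9))
  expect_true(all(volumes(curve)[thresholds(curve) > 0.5] == 0))
  expect_true(all(diff(volumes(curve)) <= 0))

  # consistency with segmentDistribution at every grid point
  set.seed(13)
  g2 <- array(runif(6^3, 0, 1.4), c(6, 6, 6))
  cv2 <- concVolume(g2)
  curve2 <- cumulativeVolumeCurve(cv2)
  for (k in seq(1, length(thresholds(curve2)), by = 17)) {
    d <- suppressWarnings(
      segmentDistribution(cv2, lower = thresholds(curve2)[k]))
    expect_equal(volumes(curve2)[k], volumeUl(d))
  }
})

test_that("nested two-shell phantom yields the expected curve values", {
  # outer shell at 0.3 (total 200 uL incl. the inner), inner core at 0.8 (50 uL)
  vv <- 0.01  # voxel volume
  g <- array(NA_real_, c(40, 40, 25))
  outer_idx <- seq_len(20000); inner_idx <- seq_len(5000)
  g[outer_idx] <- 0.3
  g[inner_idx] <- 0.8
  cv <- concVolume(g, rep(vv^(1 / 3), 3))
  curve <- cumulativeVolumeCurve(cv)
  at <- function(t) volumes(curve)[which.min(abs(thresholds(curve) - t))]
  expect_equal(at(0.2), 200, tolerance = 1e-9)
  expect_equal(at(0.5), 50, tolerance = 1e-9)
})

test_that("averageCurves is the pointwise mean and rejects mismatched grids", {
  g <- array(0.5, c(5, 5, 4))
  c1 <- cumulativeVolumeCurve(concVolume(g))
  expect_equal(volumes(averageCurves(list(c1, c1))), volumes(c1))

  g0 <- array(0, c(5, 5, 4))
  c0 <- cumulativeVolumeCurve(concVolume(g0))
  avg <- averageCurves(list(c0, c1))
  expect_equal(max(volumes(avg)), max(volumes(c1)))  # threshold-0 bin counts all
  k <- which(thresholds(c1) > 0.1 & thresholds(c1) <= 0.5)
  expect_true(all(abs(volumes(avg)[k] - volumes(c1)[k] / 2) < 1e-9))

  # n = 6 replicates: mean matches exhaustive recomputation
  set.seed(14)
  curves <- lapply(1:6, function(i)
    cumulativeVolumeCurve(concVolume(array(runif(4^3), c(4, 4, 4)))))
  avg6 <- averageCurves(curves)
  manual <- Reduce(`+`, lapply(curves, volumes)) / 6
  expect_equal(volumes(avg6), manual)

  short <- new("CumulativeVolumeCurve", thresholds = c(0, 0.1),
               volumes = c(1, 0))
  expect_error(averageCurves(list(c1, short)), "identical threshold grid")
})

test_that("maximum concentration projections match an exhaustive scan", {
  # uniform volume and single-voxel cases
  u <- concVolume(array(0.4, c(3, 4, 5)))
  p <- maxConcentrationProjection(u, 1)
  expect_true(all(p@image == 0.4))

  g <- array(0, c(6, 7, 8)); g[2, 3, 4] <- 0.9
  for (ax in 1:3) {
    pr <- maxConcentrationProjection(concVolume(g), ax)
    expect_equal(sum(pr@image == 0.9), 1L)
  }

  # random volume: per-pixel maxima from an independent triple loop
  set.seed(15)
  gr <- array(runif(5 * 6 * 7, 0, 1.4), c(5, 6, 7))
  gr[sample(length(gr), 30)] <- NA
  cv <- concVolume(gr)
  for (ax in 1:3) {
    pr <- maxConcentrationProjection(cv, ax)
    keep <- setdiff(1:3, ax)
    d <- dim(gr)
    for (i in seq_len(d[keep[1]])) for (j in seq_len(d[keep[2]])) {
      ray <- switch(ax, gr[, i, j], gr[i, , j], gr[i, j, ])
      ray <- ray[!is.na(ray)]
      want <- if (length(ray)) max(ray) else NA_real_
      expect_identical(pr@image[i, j], want)
    }
  }
})

test_that("banded projections quantize to the band grid and clip to [0,1]", {
  g <- array(0, c(2, 2, 3))
  g[1, 1, ] <- c(0.05, 0.1, 0.19)   # below one band
  g[2, 1, ] <- 0.45                 # mid band
  g[1, 2, ] <- 1.35                 # above 100%
  p <- maxConcentrationProjection(concVolume(g), 3, band = 0.2)
  expect_equal(p@banded[1, 1], 0)
  expect_equal(p@banded[2, 1], 0.4)
  expect_equal(p@banded[1, 2], 1)   # clipped for display
  expect_equal(p@image[1, 2], 1.35) # continuous image untouched
})

test_that("necrosisToDistributionRatio behaves per definition", {
  expect_equal(necrosisToDistributionRatio(100, 100), 1)
  expect_equal(necrosisToDistributionRatio(326.5, 320.9), 326.5 / 320.9)
  expect_equal(necrosisToDistributionRatio(326.5, 320.9), 1.017,
               tolerance = 1e-3)
  expect_equal(necrosisToDistributionRatio(0, 50), 0)
  expect_error(necrosisToDistributionRatio(10, 0), "positive")
  # group summary is the mean of per-sample ratios, not ratio of means
  nec <- c(10, 300); dist <- c(100, 300)
  expect_equal(mean(necrosisToDistributionRatio(nec, dist)), 0.55)
})
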