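#' Specify a synthetic vial of a homogeneous ethanol-water mixture
#'
#' @param trueConcentration ethanol fraction in \[0,1\]
#' @param meanHu mean radiodensity (HU)
#' @param sdHu per-reading Gaussian noise sd (HU, >= 0)
#' @param nVoxels number of readings in the segmented region (>= 1)
#' @param label free-text identifier
#' @return A validated vial spec (plain list).
#' @export
vialSpec <- function(trueConcentration, meanHu, sdHu, nVoxels = 2000L,
                     label = sprintf("vial_%g", trueConcentration * 100)) {
  stopifnot(trueConcentration >= 0, trueConcentration <= 1,
            sdHu >= 0, nVoxels >= 1L)
  list(trueConcentration = trueConcentration, meanHu = meanHu, sdHu = sdHu,
       nVoxels = as.integer(nVoxels), label = label)
}

#' Default vial set emulating an ethanol-water calibration session
#'
#' Vials at 0, 25, 50, 75 and 100\% ethanol with replicates. Endpoint means
#' and sds match the reported water and pure-ethanol radiodensity summaries
#' (-66.5 +/- 20.3 and -340.3 +/- 29.1 HU). Intermediate concentrations are
#' slightly MORE radiodense than the two-point line predicts; the default
#' positive bias of 7.7\% of the calibration range reproduces the scale of
#' the reported systematic non-linearity error, and the intermediate sd of
#' 18.2 HU makes the average per-vial sd across all five levels 20.8 HU
#' (7.6\% of the range).
#'
#' @param huZero,huHundred session standards (HU)
#' @param intermediateBiasFrac positive HU bias at 25/50/75\% as a fraction of
#'   the calibration range (default 0.077)
#' @param sdEndpoints sds for the 0\% and 100\% vials (HU)
#' @param sdIntermediate sd for the intermediate vials (HU)
#' @param replicates vials per concentration (default 20)
#' @param nVoxels readings per vial (default 2000)
#' @return List of vial specs for [makeVials()].
#' @export
defaultVialSpecs <- function(huZero = -66.5, huHundred = -340.3,
                             intermediateBiasFrac = 0.077,
                             sdEndpoints = c(20.3, 29.1),
                             sdIntermediate = 18.2,
                             replicates = 20L, nVoxels = 2000L) {
  conc <- c(0, 0.25, 0.5, 0.75, 1)
  rng <- huHundred - huZero
  bias <- intermediateBiasFrac * abs(rng)
  specs <- list()
  for (cc in conc) {
    mid <- cc > 0 && cc < 1
    m <- huZero + cc * rng + if (mid) bias else 0
    s <- if (cc == 0) sdEndpoints[1L] else if (cc == 1) sdEndpoints[2L]
         else sdIntermediate
    for (r in seq_len(replicates))
      specs[[length(specs) + 1L]] <-
        vialSpec(cc, m, s, nVoxels,
                 label = sprintf("vial_%g_rep%02d", cc * 100, r))
  }
  specs
}

#' Generate synthetic vial readings
#'
#' Draws i.i.d. Gaussian HU readings for each vial spec; identical spec and
#' seed give bit-identical samples.
#'
#' @param specs list of vial specs (see [vialSpec()], [defaultVialSpecs()])
#' @param seed integer RNG seed
#' @return list(samples = list of [RadiodensitySample-class],
#'   truth = [SyntheticTruth-class]).
#' @export
makeVials <- function(specs = defaultVialSpecs(), seed = 1L) {
  samples <- withSeed(seed, lapply(specs, function(sp) {
    RadiodensitySample(stats::rnorm(sp$nVoxels, sp$meanHu, sp$sdHu),
                       trueConcentration = sp$trueConcentration,
                       label = sp$label)
  }))
  truth <- new("SyntheticTruth", record = list(
    trueConcentrations = vapply(specs, `[[`, numeric(1L), "trueConcentration"),
    trueMeansHu = vapply(specs, `[[`, numeric(1L), "meanHu"),
    trueSdsHu = vapply(specs, `[[`, numeric(1L), "sdHu"),
    seed = seed))
  list(samples = samples, truth = truth)
}

#' Specify a synthetic CT injection phantom
#'
#' A block of tissue submerged in buffer, with ellipsoidal injected-ethanol
#' inclusions of known concentration and optional confounders: air bubbles
#' (about -1000 HU, which map to estimated concentrations well above 120\%)
#' and naturally-low-radiodensity pockets between buffer and tissue HU.
#'
#' Default HU levels: tissue 60 (slightly above water, as for liver), buffer
#' 0, pure-ethanol standard -340.3, air -1000.
#'
#' @param gridShape integer(3) grid dimensions
#' @param spacing numeric(3) voxel spacing (mm)
#' @param tissueHu,bufferHu c(mean, sd) radiodensity of tissue and buffer
#' @param huHundred radiodensity of the 100\% ethanol standard
#' @param tissueRadii semi-axes (mm) of the ellipsoidal tissue region;
#'   default 42\% of the grid extent per axis
#' @param inclusions list of inclusions, each
#'   `list(center =  mm (NULL = grid center), radii = mm(3), concentration,
#'   profile = "uniform" | "radial-decay")`
#' @param airBubbles list of `list(center = mm, radius = mm)` set to -1000 HU
#' @param lowPockets list of `list(center = mm, radius = mm, hu = 30)`
#' @param noiseSd i.i.d. Gaussian voxel noise sd (HU; default 0 = noise-free)
#' @param seed integer RNG seed
#' @return A validated phantom spec (plain list).
#' @export
injectionPhantomSpec <- function(gridShape = c(64L, 64L, 64L),
                                 spacing = c(0.25, 0.25, 0.25),
                                 tissueHu = c(60, 0), bufferHu = c(0, 0),
                                 huHundred = -340.3,
                                 tissueRadii = NULL,
                                 inclusions = list(list(center = NULL,
                                                        radii = c(2.5, 2.5, 2.5),
                                                        concentration = 0.6,
                                                        profile = "uniform")),
                                 airBubbles = list(), lowPockets = list(),
                                 noiseSd = 0, seed = 1L) {
  gridShape <- as.integer(gridShape)
  spacing <- rep_len(as.numeric(spacing), 3L)
  extent <- gridShape * spacing
  if (is.null(tissueRadii)) tissueRadii <- 0.42 * extent
  centerOf <- function(x) if (is.null(x)) extent / 2 else rep_len(x, 3L)
  gc <- extent / 2
  for (inc in inclusions) {
    stopifnot(all(inc$radii > 0), inc$concentration >= 0)
    ctr <- centerOf(inc$center)
    slack <- tissueRadii - rep_len(inc$radii, 3L)
    if (any(slack <= 0) || sum(((ctr - gc) / slack)^2) > 1)
      stop("inclusion does not lie inside the tissue region")
  }
  list(gridShape = gridShape, spacing = spacing, tissueHu = tissueHu,
       bufferHu = bufferHu, huHundred = huHundred, tissueRadii = tissueRadii,
       inclusions = inclusions, airBubbles = airBubbles,
       lowPockets = lowPockets, noiseSd = noiseSd, seed = as.integer(seed))
}

# normalized squared ellipsoid coordinate of every voxel center
ellipsoidRho2 <- function(gridShape, spacing, center, radii) {
  ax <- lapply(1:3, function(a)
    ((seq_len(gridShape[a]) - 0.5) * spacing[a] - center[a]) / radii[a])
  outer(outer(ax[[1L]]^2, ax[[2L]]^2, "+"), ax[[3L]]^2, "+")
}

#' Generate a synthetic CT injection phantom
#'
#' Rasterizes the spec onto the voxel grid: buffer and tissue baselines,
#' inclusion voxels at `tissueHu + c * (huHundred - tissueHu)` (so the
#' in-tissue calibration with the tissue mean as the 0\% standard recovers
#' `c` exactly in the noise-free case), plus confounders and optional i.i.d.
#' Gaussian noise. Ground truth records both the analytic ellipsoid volumes
#' and the volumes of the rasterized truth masks.
#'
#' @param spec phantom spec from [injectionPhantomSpec()]
#' @return list(ct = [CtVolume-class], tissue = 3D logical mask,
#'   truth = [SyntheticTruth-class]).
#' @export
makeInjectionPhantom <- function(spec = injectionPhantomSpec()) {
  gs <- spec$gridShape; sp <- spec$spacing
  extent <- gs * sp
  gc <- extent / 2
  centerOf <- function(x) if (is.null(x)) gc else rep_len(x, 3L)

  tissue <- ellipsoidRho2(gs, sp, gc, spec$tissueRadii) <= 1
  hu <- array(spec$bufferHu[1L], gs)
  hu[tissue] <- spec$tissueHu[1L]

  vv <- prod(sp)
  cgrid <- array(0, gs)  # true concentration field (inside tissue)
  analytic <- raster <- numeric(length(spec$inclusions))
  for (i in seq_along(spec$inclusions)) {
    inc <- spec$inclusions[[i]]
    radii <- rep_len(inc$radii, 3L)
    rho2 <- ellipsoidRho2(gs, sp, centerOf(inc$center), radii)
    inside <- rho2 <= 1
    cv <- if (identical(inc$profile, "radial-decay"))
      inc$concentration * (1 - sqrt(pmin(rho2, 1))) else inc$concentration
    cgrid[inside] <- if (length(cv) > 1L) cv[inside] else cv
    analytic[i] <- 4 / 3 * pi * prod(radii)
    raster[i] <- sum(inside) * vv
  }
  inj <- cgrid > 0
  hu[inj] <- spec$tissueHu[1L] +
    cgrid[inj] * (spec$huHundred - spec$tissueHu[1L])

  for (p in spec$lowPockets) {
    ins <- ellipsoidRho2(gs, sp, centerOf(p$center), rep(p$radius, 3L)) <= 1
    hu[ins] <- if (is.null(p$hu)) 30 else p$hu
  }
  for (b in spec$airBubbles) {
    ins <- ellipsoidRho2(gs, sp, centerOf(b$center), rep(b$radius, 3L)) <= 1
    hu[ins] <- -1000
  }

  sdGrid <- array(spec$bufferHu[2L], gs)
  sdGrid[tissue] <- spec$tissueHu[2L]
  sdGrid <- sqrt(sdGrid^2 + spec$noiseSd^2)
  if (any(sdGrid > 0))
    hu <- withSeed(spec$seed,
                   hu + array(stats::rnorm(length(hu), 0, 1), gs) * sdGrid)

  truth <- new("SyntheticTruth", record = list(
    spec = spec,
    inclusionConcentrations =
      vapply(spec$inclusions, `[[`, numeric(1L), "concentration"),
    analyticVolumesUl = analytic,
    rasterVolumesUl = raster,
    trueDistributionVolumeUl = sum(cgrid >= 0.2 & tissue) * vv,
    huZero = spec$tissueHu[1L], huHundred = spec$huHundred))
  list(ct = CtVolume(hu, sp), tissue = tissue, truth = truth)
}

#' Specify a synthetic stained serial-section series
#'
#' Serial sections through an ellipsoidal necrotic solid embedded in viable
#' tissue: viable tissue is rendered blue-dominant with multiplicative
#' speckle (so the entropy-based tissue segmentation has texture signal),
#' the necrotic cross-section is unstained gray with weaker blue, the slide
#' background is a flat constant (zero entropy). Optional vessel confounders
#' are unstained discs in the viable region.
#'
#' @param radiiMm necrotic ellipsoid semi-axes (a, b, c) in mm; sections are
#'   cut perpendicular to the c axis
#' @param stepMm distance between sampled section planes (mm)
#' @param pixelSizeUm pixel size (um)
#' @param fovMm field of view (mm, 2)
#' @param marginSections blank viable sections added on each end of the series
#' @param tissueRadiiMm in-plane semi-axes of the tissue section (default
#'   max(a,b) + 1.5 mm)
#' @param viableRgb,necroticRgb base colours
#' @param speckleSd,necroticSpeckleSd multiplicative speckle sd
#' @param backgroundGray flat background level
#' @param vessels list of `list(center = mm(2) relative to tissue center,
#'   radiusMm)` rendered like necrosis within viable tissue
#' @param seed integer RNG seed
#' @return A validated slide-series spec (plain list).
#' @export
slideSeriesSpec <- function(radiiMm = c(2.5, 2.5, 2.5), stepMm = 1,
                            pixelSizeUm = 20, fovMm = c(12, 12),
                            marginSections = 1L, tissueRadiiMm = NULL,
                            viableRgb = c(0.45, 0.50, 0.80),
                            necroticRgb = c(0.74, 0.72, 0.62),
                            speckleSd = 0.06, necroticSpeckleSd = 0.05,
                            backgroundGray = 0.92, vessels = list(),
                            seed = 1L) {
  stopifnot(stepMm > 0, pixelSizeUm > 0, all(radiiMm > 0))
  if (is.null(tissueRadiiMm))
    tissueRadiiMm <- rep(max(radiiMm[1:2]) + 1.5, 2L)
  list(radiiMm = radiiMm, stepMm = stepMm, pixelSizeUm = pixelSizeUm,
       fovMm = rep_len(fovMm, 2L), marginSections = as.integer(marginSections),
       tissueRadiiMm = rep_len(tissueRadiiMm, 2L), viableRgb = viableRgb,
       necroticRgb = necroticRgb, speckleSd = speckleSd,
       necroticSpeckleSd = necroticSpeckleSd,
       backgroundGray = backgroundGray, vessels = vessels,
       seed = as.integer(seed))
}

#' Generate a synthetic stained serial-section series
#'
#' Sampled section planes run from -c to +c along the ellipsoid's third axis
#' in steps of `stepMm` (plus `marginSections` blank viable slides on each
#' end). The necrotic region on the section at height z is the ellipse with
#' semi-axes `a * sqrt(1 - (z/c)^2)`, `b * sqrt(1 - (z/c)^2)`; its analytic
#' area is recorded per slide, together with the analytic ellipsoid volume
#' and its Riemann (area x step) approximation.
#'
#' @param spec slide-series spec from [slideSeriesSpec()]
#' @return list(sections = list of [HistologySection-class],
#'   truth = [SyntheticTruth-class]).
#' @export
makeSlideSeries <- function(spec = slideSeriesSpec()) {
  a <- spec$radiiMm[1L]; b <- spec$radiiMm[2L]; cc <- spec$radiiMm[3L]
  nCore <- floor(2 * cc / spec$stepMm) + 1L
  z <- -cc + (seq_len(nCore) - 1L) * spec$stepMm
  z <- c(-cc - rev(seq_len(spec$marginSections)) * spec$stepMm, z,
         cc + seq_len(spec$marginSections) * spec$stepMm)

  pxMm <- spec$pixelSizeUm / 1000
  npx <- round(spec$fovMm / pxMm)
  xs <- (seq_len(npx[1L]) - 0.5) * pxMm - spec$fovMm[1L] / 2
  ys <- (seq_len(npx[2L]) - 0.5) * pxMm - spec$fovMm[2L] / 2
  X <- matrix(xs, npx[1L], npx[2L])
  Y <- matrix(ys, npx[1L], npx[2L], byrow = TRUE)
  tissueIn <- (X / spec$tissueRadiiMm[1L])^2 +
    (Y / spec$tissueRadiiMm[2L])^2 <= 1

  trueAreas <- numeric(length(z))
  sections <- withSeed(spec$seed, lapply(seq_along(z), function(k) {
    zz <- z[k]
    s2 <- 1 - (zz / cc)^2
    necIn <- matrix(FALSE, npx[1L], npx[2L])
    if (s2 > 0) {
      az <- a * sqrt(s2); bz <- b * sqrt(s2)
      necIn <- (X / az)^2 + (Y / bz)^2 <= 1
      trueAreas[k] <<- pi * az * bz * 0.01  # mm^2 -> cm^2
    }
    necIn <- necIn & tissueIn
    for (v in spec$vessels) {
      vin <- (X - v$center[1L])^2 + (Y - v$center[2L])^2 <= v$radiusMm^2
      necIn <- necIn | (vin & tissueIn)
    }
    img <- array(spec$backgroundGray, c(npx[1L], npx[2L], 3L))
    nViable <- sum(tissueIn & !necIn); nNec <- sum(necIn)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[tissueIn & !necIn] <- pmin(pmax(
        spec$viableRgb[ch] * (1 + stats::rnorm(nViable, 0, spec$speckleSd)),
        0), 1)
      plane[necIn] <- pmin(pmax(
        spec$necroticRgb[ch] *
          (1 + stats::rnorm(nNec, 0, spec$necroticSpeckleSd)), 0), 1)
      img[, , ch] <- plane
    }
    HistologySection(img, pixelSize = spec$pixelSizeUm, sectionIndex = k,
                     stepSize = spec$stepMm)
  }))

  analyticVol <- 4 / 3 * pi * a * b * cc  # mm^3 = uL
  truth <- new("SyntheticTruth", record = list(
    spec = spec, planeZmm = z, perSlideTrueAreaCm2 = trueAreas,
    trueNecroticVolumeUl = analyticVol,
    riemannVolumeUl = cm2mm_to_ul(sum(trueAreas), spec$stepMm)))
  list(sections = sections, truth = truth)
}
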