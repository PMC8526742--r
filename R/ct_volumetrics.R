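#' Convert a CT volume to an estimated ethanol concentration volume
#'
#' Applies the two-point calibration voxelwise. Voxels outside the tissue
#' mask are set to the sentinel `NA` ("not evaluated") and never enter
#' downstream volumes, curves or projections. When quantifying ethanol in
#' tissue the model's 0\% standard should be the mean pre-ablation tissue
#' radiodensity (tissue is slightly more radiodense than water).
#'
#' @param ct a [CtVolume-class]
#' @param model a [CalibrationModel-class]
#' @param tissue optional 3D logical array congruent with `ct`; `NULL`
#'   evaluates every voxel
#' @return A [ConcentrationVolume-class].
#' @export
toConcentration <- function(ct, model, tissue = NULL) {
  stopifnot(is(ct, "CtVolume"), is(model, "CalibrationModel"))
  g <- estimateConcentration(gridArray(ct), model)
  if (!is.null(tissue)) {
    if (!identical(dim(tissue), dim(gridArray(ct))))
      stop("tissue mask shape does not match the CT volume")
    g[!tissue] <- NA_real_
  }
  new("ConcentrationVolume", grid = g, spacing = voxelSpacing(ct),
      model = model)
}

#' Segment the cytotoxic ethanol distribution and compute its shape metrics
#'
#' Selects every evaluated voxel whose estimated ethanol concentration is at
#' least `lower` (the cytotoxic threshold; 20\% by default, as a 10-minute
#' exposure to 20\% ethanol is cytotoxic) and, if `upper` is given, at most
#' `upper` (the in-vivo 120\% exclusion for air bubbles). ALL qualifying
#' voxels are kept, including disconnected components. Centroid and distances
#' are computed on voxel centers in physical (mm) coordinates, unweighted by
#' concentration. The aspect ratio is the radius of gyration -- defined here
#' literally as the arithmetic mean of voxel distances to the centroid --
#' divided by the radius of the equal-volume sphere; under this convention a
#' uniform solid sphere scores 3/4 (carried in the result as
#' `sphereReference` for renormalization).
#'
#' @param conc a [ConcentrationVolume-class]
#' @param lower lower concentration threshold (fraction, >= 0; default 0.20)
#' @param upper optional upper threshold (> lower), e.g. 1.20 for in-vivo data
#' @param tissue optional extra logical mask to intersect with
#' @return A [DistributionResult-class]. An empty selection yields volume 0
#'   and `NaN` aspect ratio with a warning, never an error.
#' @export
segmentDistribution <- function(conc, lower = 0.20, upper = NULL,
                                tissue = NULL) {
  stopifnot(is(conc, "ConcentrationVolume"), lower >= 0)
  if (!is.null(upper) && upper <= lower)
    stop("'upper', if given, must exceed 'lower'")
  g <- gridArray(conc)
  sel <- !is.na(g) & g >= lower
  if (!is.null(upper)) sel <- sel & g <= upper
  if (!is.null(tissue)) {
    if (!identical(dim(tissue), dim(g)))
      stop("tissue mask shape does not match the volume")
    sel <- sel & tissue
  }
  sel <- array(sel, dim(g))
  maskMetrics(sel, voxelSpacing(conc))
}

# Shape metrics of a binary voxel mask in physical coordinates.
maskMetrics <- function(mask, spacing) {
  vv <- prod(spacing)
  n <- sum(mask)
  vol <- n * vv
  if (n == 0L) {
    warning("empty distribution: volume 0, aspect ratio undefined")
    return(new("DistributionResult", mask = mask, spacing = spacing,
               volume = 0, centroid = rep(NaN, 3L), radiusOfGyration = NaN,
               effectiveRadius = 0, aspectRatio = NaN, nComponents = 0L,
               sphereReference = 0.75))
  }
  co <- arrayInd(which(mask), dim(mask))
  phys <- sweep(co - 0.5, 2L, spacing, "*")
  ctr <- colMeans(phys)
  rg <- mean(sqrt(rowSums(sweep(phys, 2L, ctr, "-")^2)))
  reff <- (3 * vol / (4 * pi))^(1 / 3)
  new("DistributionResult", mask = mask, spacing = spacing, volume = vol,
      centroid = ctr, radiusOfGyration = rg, effectiveRadius = reff,
      aspectRatio = rg / reff,
      nComponents = max(labelComponents(mask, 26L)),
      sphereReference = 0.75)
}

#' Cumulative volume histogram of a concentration volume
#'
#' For a regular grid of concentration thresholds from 0, the volume (uL) of
#' evaluated tissue with estimated concentration at or above each threshold.
#' The grid spans 0 to max(1.2, observed maximum) so the above-100\% tail of
#' in-vivo data is covered.
#'
#' @param conc a [ConcentrationVolume-class]
#' @param step threshold step (fraction, > 0; default 0.01)
#' @param tissue optional extra logical mask to intersect with
#' @return A [CumulativeVolumeCurve-class]; `volumes` is non-increasing.
#' @export
cumulativeVolumeCurve <- function(conc, step = 0.01, tissue = NULL) {
  stopifnot(is(conc, "ConcentrationVolume"), step > 0)
  g <- gridArray(conc)
  if (!is.null(tissue)) g[!tissue] <- NA_real_
  vals <- g[!is.na(g)]
  hi <- max(1.2, if (length(vals)) max(vals) else 0)
  thr <- seq(0, ceiling(hi / step) * step, by = step)
  vv <- prod(voxelSpacing(conc))
  sv <- sort(vals)
  # voxels >= t: those past the insertion point of t in the sorted values
  counts <- length(sv) - findInterval(thr, sv, left.open = TRUE)
  new("CumulativeVolumeCurve", thresholds = thr, volumes = counts * vv)
}

#' Pointwise average of cumulative volume curves
#'
#' @param curves list of [CumulativeVolumeCurve-class] on identical threshold
#'   grids
#' @return A [CumulativeVolumeCurve-class] with the pointwise mean volumes.
#' @export
averageCurves <- function(curves) {
  stopifnot(length(curves) > 0L,
            all(vapply(curves, is, TRUE, "CumulativeVolumeCurve")))
  thr <- thresholds(curves[[1L]])
  for (cv in curves)
    if (!isTRUE(all.equal(thresholds(cv), thr)))
      stop("curves must share an identical threshold grid")
  vols <- rowMeans(vapply(curves, volumes, numeric(length(thr))))
  new("CumulativeVolumeCurve", thresholds = thr, volumes = vols)
}

#' Maximum concentration projection
#'
#' Projects the voxel with the highest estimated ethanol concentration along
#' one grid axis onto a 2D image (the top- or side-view used to visualize the
#' 3D distribution), plus a copy quantized to concentration bands for
#' display.
#'
#' @param conc a [ConcentrationVolume-class]
#' @param axis projection axis: 1 (transverse-slice), 2 (row) or 3 (column)
#' @param band band width for the quantized copy (fraction; default 0.20,
#'   i.e. 20-percentage-point bands); the banded image is clipped to \[0,1\]
#' @return A [ConcentrationProjection-class]; pixels whose ray contains no
#'   evaluated voxel are `NA`.
#' @export
maxConcentrationProjection <- function(conc, axis, band = 0.20) {
  stopifnot(is(conc, "ConcentrationVolume"))
  axis <- as.integer(axis)
  if (!axis %in% 1:3) stop("'axis' must be 1, 2 or 3")
  g <- gridArray(conc)
  img <- apply(g, setdiff(1:3, axis), function(v) {
    v <- v[!is.na(v)]
    if (length(v)) max(v) else NA_real_
  })
  banded <- pmin(pmax(floor(img / band) * band, 0), 1)
  new("ConcentrationProjection", image = img, axis = axis, band = band,
      banded = banded)
}

#' Ratio of necrotic volume to distribution volume
#'
#' Per-sample ratio of the pathologic necrotic volume to the CT-derived
#' ethanol distribution volume. When summarizing a group, average the
#' per-sample ratios (not the ratio of group means).
#'
#' @param necroticVolume necrotic volume(s), uL
#' @param distributionVolume distribution volume(s), uL, all > 0
#' @return necroticVolume / distributionVolume, elementwise.
#' @export
necrosisToDistributionRatio <- function(necroticVolume, distributionVolume) {
  if (any(!is.finite(distributionVolume)) || any(distributionVolume <= 0))
    stop("undefined ratio: distribution volume must be positive")
  necroticVolume / distributionVolume
}
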