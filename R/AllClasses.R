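#' Two-point radiodensity calibration model
#'
#' Affine map from CT radiodensity (Hounsfield units, HU) to estimated ethanol
#' volume fraction, anchored at the radiodensity of the 0\% ethanol standard
#' (water, or mean pre-ablation tissue when quantifying in tissue) and the
#' 100\% ethanol standard. Ethanol attenuates X-rays less than water, so the
#' 100\% standard must be less radiodense than the 0\% standard.
#'
#' @slot huZero radiodensity of the 0\% ethanol standard (HU)
#' @slot huHundred radiodensity of the 100\% ethanol standard (HU)
#'
#' @seealso [fitTwoPoint()], [estimateConcentration()]
#' @export
setClass("CalibrationModel",
  representation(huZero = "numeric", huHundred = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@huZero) != 1L || !is.finite(object@huZero))
      msg <- c(msg, "'huZero' must be a single finite number")
    if (length(object@huHundred) != 1L || !is.finite(object@huHundred))
      msg <- c(msg, "'huHundred' must be a single finite number")
    if (is.null(msg) && object@huHundred >= object@huZero)
      msg <- c(msg, "degenerate calibration: the 100% ethanol standard must be less radiodense than the 0% standard")
    if (is.null(msg)) TRUE else msg
  }
)

#' @rdname accessors
#' @export
setMethod("huZero", "CalibrationModel", function(x) x@huZero)
#' @rdname accessors
#' @export
setMethod("huHundred", "CalibrationModel", function(x) x@huHundred)
#' @rdname accessors
#' @export
setMethod("huRange", "CalibrationModel", function(x) abs(x@huZero - x@huHundred))

setMethod("show", "CalibrationModel", function(object) {
  cat("CalibrationModel (two-point HU -> ethanol fraction)\n",
      "  0% standard:   ", format(object@huZero), " HU\n",
      "  100% standard: ", format(object@huHundred), " HU\n",
      "  range:         ", format(huRange(object)), " HU\n", sep = "")
})

#' Radiodensity readings from one segmented region
#'
#' Holds the HU readings of a segmented region of interest (e.g. a cylinder
#' within a vial of an ethanol-water mixture), optionally with the region's
#' known true ethanol fraction.
#'
#' @slot label free-text identifier
#' @slot trueConcentration known ethanol volume fraction in \[0,1\], or `NA`
#'   when unknown
#' @slot values numeric vector of HU readings; non-empty, all finite
#'
#' @seealso [RadiodensitySample()], [summarizeSample()]
#' @export
setClass("RadiodensitySample",
  representation(label = "character", trueConcentration = "numeric",
                 values = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@values) == 0L)
      msg <- c(msg, "no readings: 'values' must be non-empty")
    if (length(object@values) > 0L && !all(is.finite(object@values)))
      msg <- c(msg, "all 'values' must be finite")
    tc <- object@trueConcentration
    if (length(tc) != 1L)
      msg <- c(msg, "'trueConcentration' must be a single value (NA if unknown)")
    else if (!is.na(tc) && (tc < 0 || tc > 1))
      msg <- c(msg, "'trueConcentration' must lie in [0,1] or be NA")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct a RadiodensitySample
#'
#' @param values numeric vector of HU readings
#' @param trueConcentration known ethanol fraction in \[0,1\] or `NA`
#' @param label free-text identifier
#' @return A [RadiodensitySample-class] object.
#' @export
RadiodensitySample <- function(values, trueConcentration = NA_real_,
                               label = "sample") {
  new("RadiodensitySample", label = as.character(label)[1L],
      trueConcentration = as.numeric(trueConcentration)[1L],
      values = as.numeric(values))
}

#' @rdname accessors
#' @export
setMethod("huValues", "RadiodensitySample", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("trueConcentration", "RadiodensitySample", function(x) x@trueConcentration)
#' @rdname accessors
#' @export
setMethod("sampleLabel", "RadiodensitySample", function(x) x@label)

setMethod("show", "RadiodensitySample", function(object) {
  cat("RadiodensitySample '", object@label, "': ", length(object@values),
      " readings, mean ", format(round(mean(object@values), 2)), " HU",
      if (!is.na(object@trueConcentration))
        paste0(", true concentration ", object@trueConcentration * 100, "%"),
      "\n", sep = "")
})

#' Ordinary least-squares diagnostic fit of HU on concentration
#'
#' @slot slope HU per unit concentration fraction
#' @slot intercept HU at zero ethanol
#' @slot rSquared coefficient of determination in \[0,1\]
#' @seealso [fitLinear()]
#' @export
setClass("LinearFitResult",
  representation(slope = "numeric", intercept = "numeric",
                 rSquared = "numeric"),
  validity = function(object) {
    if (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12)
      "rSquared must lie in [0,1]" else TRUE
  }
)

setMethod("show", "LinearFitResult", function(object) {
  cat("LinearFitResult: HU = ", format(round(object@intercept, 2)), " + ",
      format(round(object@slope, 2)), " x concentration,  r^2 = ",
      format(round(object@rSquared, 4)), "\n", sep = "")
})

#' Calibration error decomposition
#'
#' Systematic (non-linearity) and random (measurement variance) components of
#' the two-point calibration error, on the scales the method reports:
#' concentration percentage points for the non-linearity, HU and percent of
#' the calibration range for the variance.
#'
#' @slot nonlinearityErrorMean mean absolute predicted-minus-true error at the
#'   intermediate concentrations (percentage points)
#' @slot nonlinearityErrorSd standard deviation of those errors (points)
#' @slot varianceHuMean mean per-sample HU standard deviation
#' @slot varianceHuSd standard deviation of the per-sample HU sds
#' @slot variancePctOfRange `varianceHuMean` as percent of the calibration range
#' @seealso [calibrationErrorReport()]
#' @export
setClass("CalibrationErrorReport",
  representation(nonlinearityErrorMean = "numeric",
                 nonlinearityErrorSd = "numeric",
                 varianceHuMean = "numeric",
                 varianceHuSd = "numeric",
                 variancePctOfRange = "numeric"),
  validity = function(object) {
    v <- c(object@nonlinearityErrorMean, object@nonlinearityErrorSd,
           object@varianceHuMean, object@varianceHuSd,
           object@variancePctOfRange)
    if (any(v < 0, na.rm = TRUE)) "all error components must be >= 0" else TRUE
  }
)

setMethod("show", "CalibrationErrorReport", function(object) {
  cat("CalibrationErrorReport\n",
      "  non-linearity error: ", format(round(object@nonlinearityErrorMean, 2)),
      " +/- ", format(round(object@nonlinearityErrorSd, 2)), " points\n",
      "  measurement variance: ", format(round(object@varianceHuMean, 2)),
      " +/- ", format(round(object@varianceHuSd, 2)), " HU (",
      format(round(object@variancePctOfRange, 2)), "% of range)\n", sep = "")
})

#' A CT volume in Hounsfield units
#'
#' 3D radiodensity grid with per-axis voxel spacing in mm. Axis order is
#' (transverse slice, row, column); all geometry downstream is computed on
#' voxel centers in physical (mm) coordinates, so anisotropic spacing is
#' supported.
#'
#' @slot grid 3D numeric array of HU
#' @slot spacing numeric(3), voxel edge lengths in mm, all > 0
#' @seealso [CtVolume()], [toConcentration()]
#' @export
setClass("CtVolume",
  representation(grid = "array", spacing = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@grid)) != 3L || length(object@grid) == 0L)
      msg <- c(msg, "'grid' must be a non-empty 3D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "'spacing' must be three positive voxel edge lengths (mm)")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct a CtVolume
#'
#' @param grid 3D numeric array of radiodensity values (HU)
#' @param spacing voxel edge lengths in mm; recycled to length 3
#' @return A [CtVolume-class] object.
#' @export
CtVolume <- function(grid, spacing = c(1, 1, 1)) {
  new("CtVolume", grid = grid, spacing = rep_len(as.numeric(spacing), 3L))
}

#' @rdname accessors
#' @export
setMethod("gridArray", "CtVolume", function(x) x@grid)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "CtVolume", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelVolume", "CtVolume", function(x) prod(x@spacing))

setMethod("show", "CtVolume", function(object) {
  cat("CtVolume: ", paste(dim(object@grid), collapse = " x "),
      " voxels, spacing ", paste(format(object@spacing), collapse = " x "),
      " mm, HU in [", format(round(min(object@grid), 1)), ", ",
      format(round(max(object@grid), 1)), "]\n", sep = "")
})

#' Estimated ethanol concentration volume
#'
#' Voxelwise ethanol fraction derived from a [CtVolume-class] under a
#' [CalibrationModel-class]. Values are NOT clipped and may be negative or
#' exceed 1; voxels outside the evaluated tissue carry the sentinel `NA`
#' ("not evaluated") and never enter downstream sums, curves or projections.
#'
#' @slot grid 3D numeric array of ethanol fraction; `NA` = not evaluated
#' @slot spacing numeric(3) voxel spacing (mm)
#' @slot model the [CalibrationModel-class] used (provenance)
#' @seealso [toConcentration()], [segmentDistribution()]
#' @export
setClass("ConcentrationVolume",
  representation(grid = "array", spacing = "numeric",
                 model = "CalibrationModel"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@grid)) != 3L)
      msg <- c(msg, "'grid' must be a 3D array")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "'spacing' must be three positive lengths (mm)")
    if (is.null(msg)) TRUE else msg
  }
)

#' @rdname accessors
#' @export
setMethod("gridArray", "ConcentrationVolume", function(x) x@grid)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "ConcentrationVolume", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelVolume", "ConcentrationVolume", function(x) prod(x@spacing))

setMethod("show", "ConcentrationVolume", function(object) {
  ev <- sum(!is.na(object@grid))
  cat("ConcentrationVolume: ", paste(dim(object@grid), collapse = " x "),
      " voxels (", ev, " evaluated), spacing ",
      paste(format(object@spacing), collapse = " x "), " mm\n", sep = "")
})

#' Segmented cytotoxic distribution and its shape metrics
#'
#' Binary mask of voxels whose estimated ethanol concentration meets the
#' cytotoxic threshold, together with the distribution volume, its centroid,
#' the radius of gyration (mean voxel-center distance to the centroid, in mm),
#' the effective radius of the equal-volume sphere, and their ratio -- the
#' aspect ratio, the package's shape-asymmetry statistic (lower = more
#' localized; a uniform solid sphere scores 3/4 under this mean-distance
#' definition, exposed as `sphereReference`).
#'
#' @slot mask 3D logical array
#' @slot spacing numeric(3) voxel spacing (mm)
#' @slot volume distribution volume in uL (= mm^3)
#' @slot centroid numeric(3) physical coordinates (mm); `NaN` when empty
#' @slot radiusOfGyration mean distance to centroid (mm)
#' @slot effectiveRadius (3V / 4 pi)^(1/3) (mm)
#' @slot aspectRatio radiusOfGyration / effectiveRadius (dimensionless)
#' @slot nComponents number of 26-connected components (diagnostic)
#' @slot sphereReference aspect ratio of a uniform solid sphere under the
#'   mean-distance convention (0.75), for renormalization
#' @seealso [segmentDistribution()]
#' @export
setClass("DistributionResult",
  representation(mask = "array", spacing = "numeric", volume = "numeric",
                 centroid = "numeric", radiusOfGyration = "numeric",
                 effectiveRadius = "numeric", aspectRatio = "numeric",
                 nComponents = "integer", sphereReference = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!is.logical(object@mask) || length(dim(object@mask)) != 3L)
      msg <- c(msg, "'mask' must be a 3D logical array")
    if (object@volume < 0) msg <- c(msg, "'volume' must be >= 0")
    vv <- prod(object@spacing)
    if (abs(object@volume - sum(object@mask) * vv) > 1e-6 * max(1, object@volume))
      msg <- c(msg, "'volume' must equal (true voxels) x (voxel volume)")
    if (is.null(msg)) TRUE else msg
  }
)

#' @rdname accessors
#' @export
setMethod("maskArray", "DistributionResult", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "DistributionResult", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("volumeUl", "DistributionResult", function(x) x@volume)
#' @rdname accessors
#' @export
setMethod("centroid", "DistributionResult", function(x) x@centroid)
#' @rdname accessors
#' @export
setMethod("radiusOfGyration", "DistributionResult", function(x) x@radiusOfGyration)
#' @rdname accessors
#' @export
setMethod("effectiveRadius", "DistributionResult", function(x) x@effectiveRadius)
#' @rdname accessors
#' @export
setMethod("aspectRatio", "DistributionResult", function(x) x@aspectRatio)
#' @rdname accessors
#' @export
setMethod("nComponents", "DistributionResult", function(x) x@nComponents)

setMethod("show", "DistributionResult", function(object) {
  cat("DistributionResult\n",
      "  volume:            ", format(round(object@volume, 2)), " uL\n",
      "  aspect ratio:      ", format(round(object@aspectRatio, 3)),
      " (solid-sphere reference ", format(object@sphereReference), ")\n",
      "  radius of gyration:", format(round(object@radiusOfGyration, 3)), " mm\n",
      "  effective radius:  ", format(round(object@effectiveRadius, 3)), " mm\n",
      "  components (26-conn): ", object@nComponents, "\n", sep = "")
})

#' Cumulative volume histogram
#'
#' Tissue volume (uL) at or above each concentration threshold; the curve is
#' non-increasing in the threshold.
#'
#' @slot thresholds concentration fractions, a regular grid from 0
#' @slot volumes uL of evaluated tissue with concentration >= threshold
#' @seealso [cumulativeVolumeCurve()], [averageCurves()]
#' @export
setClass("CumulativeVolumeCurve",
  representation(thresholds = "numeric", volumes = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@thresholds) != length(object@volumes))
      msg <- c(msg, "'thresholds' and 'volumes' must have equal length")
    if (length(object@volumes) > 1L && any(diff(object@volumes) > 1e-9))
      msg <- c(msg, "'volumes' must be non-increasing in threshold")
    if (is.null(msg)) TRUE else msg
  }
)

#' @rdname accessors
#' @export
setMethod("thresholds", "CumulativeVolumeCurve", function(x) x@thresholds)
#' @rdname accessors
#' @export
setMethod("volumes", "CumulativeVolumeCurve", function(x) x@volumes)

setMethod("show", "CumulativeVolumeCurve", function(object) {
  cat("CumulativeVolumeCurve: ", length(object@thresholds),
      " thresholds in [0, ", format(max(object@thresholds)), "], volume ",
      format(round(max(object@volumes), 2)), " uL at 0\n", sep = "")
})

#' Maximum concentration projection
#'
#' 2D image whose pixels carry the maximum estimated ethanol concentration
#' along the projection axis, plus a copy quantized to concentration bands
#' (default 20-point bands, clipped to \[0,1\] for display).
#'
#' @slot image 2D numeric array of concentration fractions (`NA` where no
#'   voxel along the ray was evaluated)
#' @slot axis projection axis (1, 2 or 3)
#' @slot band band width used for `banded` (fraction)
#' @slot banded quantized copy of `image`
#' @seealso [maxConcentrationProjection()]
#' @export
setClass("ConcentrationProjection",
  representation(image = "matrix", axis = "integer", band = "numeric",
                 banded = "matrix"))

setMethod("show", "ConcentrationProjection", function(object) {
  cat("ConcentrationProjection along axis ", object@axis, ": ",
      paste(dim(object@image), collapse = " x "), " pixels, ",
      object@band * 100, "%-bands\n", sep = "")
})

#' One stained serial section
#'
#' RGB image of a viability-stained section (viable tissue stains blue,
#' necrotic tissue is unstained), with its pixel size and the step between
#' sampled section planes.
#'
#' @slot image height x width x 3 numeric array in \[0,1\]
#' @slot pixelSize um per pixel (> 0)
#' @slot sectionIndex ordinal position in the series
#' @slot stepSize mm between sampled section planes (> 0)
#' @seealso [HistologySection()], [segmentTissue()]
#' @export
setClass("HistologySection",
  representation(image = "array", pixelSize = "numeric",
                 sectionIndex = "integer", stepSize = "numeric"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@image)
    if (length(d) != 3L || d[3L] != 3L)
      msg <- c(msg, "'image' must be a height x width x 3 RGB array")
    if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
      msg <- c(msg, "'pixelSize' (um) must be a single positive number")
    if (length(object@stepSize) != 1L || object@stepSize <= 0)
      msg <- c(msg, "'stepSize' (mm) must be a single positive number")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct a HistologySection
#'
#' @param image height x width x 3 RGB array with values in \[0,1\]
#' @param pixelSize um per pixel
#' @param sectionIndex ordinal position in the serial series
#' @param stepSize mm between sampled section planes
#' @return A [HistologySection-class] object.
#' @export
HistologySection <- function(image, pixelSize, sectionIndex = 1L,
                             stepSize = 1) {
  new("HistologySection", image = image, pixelSize = as.numeric(pixelSize),
      sectionIndex = as.integer(sectionIndex), stepSize = as.numeric(stepSize))
}

#' @rdname accessors
#' @export
setMethod("sectionImage", "HistologySection", function(x) x@image)
#' @rdname accessors
#' @export
setMethod("pixelSize", "HistologySection", function(x) x@pixelSize)
#' @rdname accessors
#' @export
setMethod("sectionIndex", "HistologySection", function(x) x@sectionIndex)
#' @rdname accessors
#' @export
setMethod("stepSize", "HistologySection", function(x) x@stepSize)

setMethod("show", "HistologySection", function(object) {
  cat("HistologySection #", object@sectionIndex, ": ",
      paste(dim(object@image)[1:2], collapse = " x "), " px at ",
      object@pixelSize, " um/px, step ", object@stepSize, " mm\n", sep = "")
})

#' Tissue segmentation of a stained section
#'
#' Result of the entropy-filter tissue segmentation: the tissue mask, its
#' area, boundary outlines, and a masked copy of the original image
#' (background pixels zeroed) for the downstream necrosis step.
#'
#' @slot mask 2D logical tissue mask
#' @slot tissueArea cm^2, (true-pixel count) x pixel area
#' @slot boundaries list of closed polygonal outlines (n x 2 matrices, px)
#' @slot maskedImage RGB array with background removed
#' @slot pixelSize um per pixel (carried from the section)
#' @slot sectionIndex ordinal of the source section
#' @slot stepSize mm between section planes (carried from the section)
#' @seealso [segmentTissue()], [segmentNecrosis()]
#' @export
setClass("TissueSegmentation",
  representation(mask = "matrix", tissueArea = "numeric",
                 boundaries = "list", maskedImage = "array",
                 pixelSize = "numeric", sectionIndex = "integer",
                 stepSize = "numeric"),
  validity = function(object) {
    pa <- (object@pixelSize * 1e-4)^2
    if (abs(object@tissueArea - sum(object@mask) * pa) >
        1e-9 * max(1, object@tissueArea))
      "'tissueArea' must equal true-pixel count x pixel area" else TRUE
  }
)

#' @rdname accessors
#' @export
setMethod("maskArray", "TissueSegmentation", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("tissueArea", "TissueSegmentation", function(x) x@tissueArea)
#' @rdname accessors
#' @export
setMethod("boundaries", "TissueSegmentation", function(x) x@boundaries)
#' @rdname accessors
#' @export
setMethod("maskedImage", "TissueSegmentation", function(x) x@maskedImage)
#' @rdname accessors
#' @export
setMethod("pixelSize", "TissueSegmentation", function(x) x@pixelSize)

setMethod("show", "TissueSegmentation", function(object) {
  cat("TissueSegmentation: ", format(round(object@tissueArea, 4)),
      " cm^2 over ", sum(object@mask), " px (section #",
      object@sectionIndex, ")\n", sep = "")
})

#' Necrotic regions of one section
#'
#' At most five retained necrotic regions (largest by pixel count) after
#' small-region removal and user exclusions, with their areas and boundaries.
#'
#' @slot rois list of retained regions; each has `pixels` (linear indices),
#'   `areaCm2` and `boundary` (n x 2 matrix)
#' @slot excluded like `rois`, the user-excluded regions (e.g. vasculature)
#' @slot necroticArea cm^2, sum over retained regions
#' @slot pixelSize um per pixel
#' @slot sectionIndex ordinal of the source section
#' @slot stepSize mm between section planes
#' @seealso [segmentNecrosis()], [necroticVolume()]
#' @export
setClass("NecrosisResult",
  representation(rois = "list", excluded = "list", necroticArea = "numeric",
                 pixelSize = "numeric", sectionIndex = "integer",
                 stepSize = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@necroticArea < 0) msg <- c(msg, "'necroticArea' must be >= 0")
    if (is.null(msg)) TRUE else msg
  }
)

#' @rdname accessors
#' @export
setMethod("rois", "NecrosisResult", function(x) x@rois)
#' @rdname accessors
#' @export
setMethod("necroticArea", "NecrosisResult", function(x) x@necroticArea)
#' @rdname accessors
#' @export
setMethod("pixelSize", "NecrosisResult", function(x) x@pixelSize)
#' @rdname accessors
#' @export
setMethod("sectionIndex", "NecrosisResult", function(x) x@sectionIndex)
#' @rdname accessors
#' @export
setMethod("stepSize", "NecrosisResult", function(x) x@stepSize)

setMethod("show", "NecrosisResult", function(object) {
  cat("NecrosisResult (section #", object@sectionIndex, "): ",
      length(object@rois), " region(s), ",
      format(round(object@necroticArea, 4)), " cm^2 necrotic\n", sep = "")
})

#' Necrotic volume reconstructed from serial sections
#'
#' @slot perSectionAreas cm^2 per sampled section, in series order
#' @slot stepSize mm between sampled section planes
#' @slot volume uL; sum(area_i) x step, converted cm^2 x mm -> uL (x 100)
#' @seealso [necroticVolume()]
#' @export
setClass("NecrosisVolume",
  representation(perSectionAreas = "numeric", stepSize = "numeric",
                 volume = "numeric"),
  validity = function(object) {
    expected <- sum(object@perSectionAreas) * object@stepSize * 100
    if (abs(object@volume - expected) > 1e-9 * max(1, expected))
      "'volume' must equal sum(areas) x step x 100 (cm^2 x mm -> uL)" else TRUE
  }
)

#' @rdname accessors
#' @export
setMethod("perSectionAreas", "NecrosisVolume", function(x) x@perSectionAreas)
#' @rdname accessors
#' @export
setMethod("volumeUl", "NecrosisVolume", function(x) x@volume)
#' @rdname accessors
#' @export
setMethod("stepSize", "NecrosisVolume", function(x) x@stepSize)

setMethod("show", "NecrosisVolume", function(object) {
  cat("NecrosisVolume: ", format(round(object@volume, 2)), " uL from ",
      length(object@perSectionAreas), " sections at ", object@stepSize,
      " mm step\n", sep = "")
})

#' Comparison of automatic versus manual necrotic areas
#'
#' @slot meanSignedDifference cm^2, mean of (auto - manual)
#' @slot meanAbsoluteDifference cm^2, mean of |auto - manual|
#' @seealso [compareToManual()]
#' @export
setClass("ManualComparison",
  representation(meanSignedDifference = "numeric",
                 meanAbsoluteDifference = "numeric"))

setMethod("show", "ManualComparison", function(object) {
  cat("ManualComparison: signed ", format(object@meanSignedDifference),
      " cm^2, absolute ", format(object@meanAbsoluteDifference),
      " cm^2 (auto - manual)\n", sep = "")
})

#' Ground truth carried alongside every synthetic fixture
#'
#' A named record of the generator parameters and the analytically and/or
#' numerically derived truth (true volumes, per-slide true areas, ...).
#'
#' @slot record named list of truth entries
#' @seealso [makeVials()], [makeInjectionPhantom()], [makeSlideSeries()]
#' @export
setClass("SyntheticTruth", representation(record = "list"))

#' @rdname accessors
#' @export
setMethod("truthRecord", "SyntheticTruth", function(x) x@record)

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth with entries:",
      paste(names(object@record), collapse = ", "), "\n")
})

#' Radiologic-pathologic correlation report
#'
#' Per-sample distribution and necrotic volumes with their ratio, group
#' summary statistics, and fold-changes (ratios of group means, labelled with
#' both groups).
#'
#' @slot perSample data.frame: sample, group, distributionVolumeUl,
#'   necroticVolumeUl, ratio
#' @slot groupStats data.frame of group means/sds
#' @slot foldChanges data.frame: metric, groupA, groupB, foldChange
#' @seealso [runPipeline()], [foldChange()]
#' @export
setClass("CorrelationReport",
  representation(perSample = "data.frame", groupStats = "data.frame",
                 foldChanges = "data.frame"))

setMethod("show", "CorrelationReport", function(object) {
  cat("CorrelationReport: ", nrow(object@perSample), " sample(s), ",
      nrow(object@groupStats), " group(s)\n", sep = "")
  if (nrow(object@groupStats)) print(object@groupStats)
  if (nrow(object@foldChanges)) print(object@foldChanges)
})
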