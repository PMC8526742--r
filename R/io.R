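#' Read a CT volume from a NIfTI-1 file
#'
#' Voxel spacing (mm) is taken from the header's pixdim.
#'
#' @param path .nii or .nii.gz file of radiodensity values (HU)
#' @return A [CtVolume-class].
#' @export
readCtVolume <- function(path) {
  if (!file.exists(path)) stop("volume not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("failed to read '", path, "': ",
                                           conditionMessage(e)))
  g <- array(as.numeric(img), dim(img)[1:3])
  sp <- RNifti::pixdim(img)[1:3]
  CtVolume(g, sp)
}

#' Write a CT volume (or any 3D grid) to NIfTI-1
#'
#' @param ct a [CtVolume-class] or a 3D array (then `spacing` is required)
#' @param path output .nii or .nii.gz path
#' @param spacing voxel spacing in mm when `ct` is a bare array
#' @return `path`, invisibly.
#' @export
writeCtVolume <- function(ct, path, spacing = NULL) {
  if (is(ct, "CtVolume")) {
    g <- gridArray(ct); sp <- voxelSpacing(ct)
  } else {
    g <- ct
    sp <- spacing %||% stop("'spacing' is required for a bare array")
  }
  img <- RNifti::asNifti(g)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a tissue mask from NIfTI-1
#'
#' @param path .nii/.nii.gz of \{0,1\} values on the same grid as its volume
#' @return 3D logical array.
#' @export
readTissueMask <- function(path) {
  v <- readCtVolume(path)
  gridArray(v) > 0.5
}

#' Read a stained section image (TIFF or PNG)
#'
#' @param path image file; must have 3 colour channels
#' @param pixelSize um per pixel
#' @param sectionIndex ordinal position in the series
#' @param stepSize mm between sampled section planes
#' @return A [HistologySection-class].
#' @export
readSection <- function(path, pixelSize, sectionIndex = 1L, stepSize = 1) {
  if (!file.exists(path)) stop("section image not found: ", path)
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) != 3L || dim(a)[3L] < 3L)
    stop("'", path, "' is not an RGB image")
  HistologySection(a[, , 1:3], pixelSize = pixelSize,
                   sectionIndex = sectionIndex, stepSize = stepSize)
}

#' Write a section image to TIFF or PNG
#'
#' @param section a [HistologySection-class]
#' @param path output path (.png or .tif/.tiff)
#' @return `path`, invisibly.
#' @export
writeSection <- function(section, path) {
  EBImage::writeImage(EBImage::Image(sectionImage(section),
                                     colormode = "Color"), path)
  invisible(path)
}

#' Write a maximum concentration projection to PNG
#'
#' Writes the continuous image as 16-bit grayscale (concentration scaled so
#' 1.0 maps to 2^16 / 1.2 - 1, covering the above-100\% tail) and the banded
#' copy as 8-bit grayscale. Unevaluated pixels are written as 0.
#'
#' @param proj a [ConcentrationProjection-class]
#' @param path output path for the 16-bit image; the banded copy goes to
#'   `*_banded.png`
#' @return Character vector of the two paths, invisibly.
#' @export
writeProjectionPng <- function(proj, path) {
  img <- proj@image
  img[is.na(img)] <- 0
  img16 <- pmin(pmax(img / 1.2, 0), 1)
  png::writePNG(t(img16), path, dpi = NULL)
  banded <- proj@banded
  banded[is.na(banded)] <- 0
  bpath <- sub("\\.png$", "_banded.png", path)
  png::writePNG(t(banded), bpath)
  invisible(c(path, bpath))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read vial samples from a CSV table
#'
#' Expected columns: `label`, `true_concentration` (fraction in \[0,1\],
#' blank/NA if unknown) and either `values` (semicolon-separated inline HU
#' readings) or `volume`+`mask` (paths to a NIfTI volume and same-grid mask;
#' the readings are the volume's voxels inside the mask).
#'
#' @param path CSV file
#' @param dir base directory for relative volume/mask paths
#' @return List of [RadiodensitySample-class].
#' @export
readVialCsv <- function(path, dir = dirname(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"label" %in% names(df)) stop("vial CSV needs a 'label' column")
  lapply(seq_len(nrow(df)), function(i) {
    tc <- if ("true_concentration" %in% names(df))
      suppressWarnings(as.numeric(df$true_concentration[i])) else NA_real_
    if (!is.null(df$values) && nzchar(df$values[i])) {
      vals <- as.numeric(strsplit(df$values[i], ";")[[1L]])
    } else {
      vol <- readCtVolume(file.path(dir, df$volume[i]))
      msk <- readTissueMask(file.path(dir, df$mask[i]))
      vals <- gridArray(vol)[msk]
    }
    RadiodensitySample(vals, trueConcentration = tc, label = df$label[i])
  })
}

#' Write a calibration report to CSV and JSON
#'
#' @param model a [CalibrationModel-class]
#' @param report a [CalibrationErrorReport-class]
#' @param fit optional [LinearFitResult-class]
#' @param outStem output path stem; writes `<stem>.csv` and `<stem>.json`
#' @return Paths written, invisibly.
#' @export
writeCalibrationReport <- function(model, report, fit = NULL, outStem) {
  x <- list(
    hu_zero = huZero(model), hu_hundred = huHundred(model),
    hu_range = huRange(model),
    nonlinearity_error_mean_pct = report@nonlinearityErrorMean,
    nonlinearity_error_sd_pct = report@nonlinearityErrorSd,
    variance_hu_mean = report@varianceHuMean,
    variance_hu_sd = report@varianceHuSd,
    variance_pct_of_range = report@variancePctOfRange)
  if (!is.null(fit))
    x <- c(x, list(ols_slope = fit@slope, ols_intercept = fit@intercept,
                   ols_r_squared = fit@rSquared))
  csv <- paste0(outStem, ".csv"); js <- paste0(outStem, ".json")
  utils::write.csv(as.data.frame(x), csv, row.names = FALSE)
  jsonlite::write_json(x, js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv, js))
}

#' Read and validate a pipeline run configuration
#'
#' YAML (or JSON) configuration for [runPipeline()]. A hand-written schema
#' check validates required fields and types before any stage runs.
#'
#' @param path YAML/JSON file
#' @return Validated config list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- yaml::read_yaml(path)
  validateRunConfig(cfg)
}

#' Validate a pipeline run configuration list
#'
#' @param cfg config list (see the vignette for the layout)
#' @return The config, with defaults filled in; stops on violations.
#' @export
validateRunConfig <- function(cfg) {
  if (!is.list(cfg)) stop("config must be a mapping")
  cfg$lower <- cfg$lower %||% 0.20
  cfg$upper <- cfg$upper  # NULL = no in-vivo exclusion
  cfg$seed <- as.integer(cfg$seed %||% 1L)  # NULL outputDir = no artifacts
  if (!is.numeric(cfg$lower) || cfg$lower < 0)
    stop("config: 'lower' must be a fraction >= 0")
  if (!is.null(cfg$upper) && (!is.numeric(cfg$upper) || cfg$upper <= cfg$lower))
    stop("config: 'upper' must exceed 'lower'")
  if (is.null(cfg$samples) || !is.list(cfg$samples))
    stop("config: 'samples' must be a list (possibly empty)")
  for (s in cfg$samples) {
    if (is.null(s$name)) stop("config: every sample needs a 'name'")
    hasFiles <- !is.null(s$ct) ; hasSim <- isTRUE(s$simulate)
    if (!hasFiles && !hasSim)
      stop("config: sample '", s$name,
           "' needs either a 'ct' path or 'simulate: true'")
    if (hasFiles && is.null(s$ethanolStandard) && is.null(cfg$ethanolStandard))
      stop("config: sample '", s$name, "' needs an 'ethanolStandard' (HU)")
  }
  cfg
}
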