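#' Local entropy filter
#'
#' Shannon entropy of the intensity histogram in a square sliding window,
#' the texture statistic driving tissue segmentation (stained tissue is
#' textured, slide background is flat). Intensities in \[0,1\] are quantized
#' to `nbins` grey levels; window histograms are accumulated with cumulative
#' box sums, and windows are truncated at the image border. The result is
#' normalized by the maximum attainable entropy
#' (log2 of min(nbins, window^2)) so thresholds are fractions in \[0,1\].
#'
#' @param x numeric matrix with values in \[0,1\]
#' @param window odd window side length in pixels (default 9)
#' @param nbins number of grey levels (default 64)
#' @return Matrix of normalized local entropy in \[0,1\].
#' @export
localEntropy <- function(x, window = 9L, nbins = 64L) {
  stopifnot(is.matrix(x), window %% 2L == 1L, nbins >= 2L)
  q <- pmin(floor(pmax(x, 0) * nbins) + 1L, nbins)
  tot <- boxSum(matrix(1, nrow(x), ncol(x)), window)
  ent <- matrix(0, nrow(x), ncol(x))
  for (b in sort(unique(as.vector(q)))) {
    cb <- boxSum((q == b) * 1, window)
    p <- cb / tot
    nz <- p > 0
    ent[nz] <- ent[nz] - p[nz] * log2(p[nz])
  }
  ent / log2(min(nbins, window^2))
}

# Closed boundary outlines (n x 2 pixel coordinate matrices) of a mask.
extractBoundaries <- function(mask) {
  if (!any(mask)) return(list())
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))
  lapply(oc, function(m) m + 1)  # 0-based -> 1-based pixel coordinates
}

#' Segment tissue on a stained section
#'
#' The semi-automated tissue step: a local-entropy filter on the blue channel
#' picks up stain texture, the normalized entropy image is binarized at a
#' user-defined threshold, small components (< `minRegion` connected pixels)
#' are deleted, the regions are eroded with a flat structuring element,
#' holes are filled, and the edges are dilated with the same element. The
#' pipeline order is fixed; see the package vignette. Background pixels are
#' removed from a masked copy of the original image for the downstream
#' necrosis step.
#'
#' @param section a [HistologySection-class]
#' @param threshold user-defined threshold in (0,1) on the normalized entropy
#'   image
#' @param entropyWindow odd entropy-filter window (px; default 9)
#' @param minRegion components below this pixel count are deleted
#'   (default 15000)
#' @param erodeDilateRadius radius (px) of the flat structuring element
#'   (default 15)
#' @param elementShape `"disc"` (default, isotropic) or `"box"`
#' @return A [TissueSegmentation-class]. No surviving region yields a
#'   warning and zero area.
#' @export
segmentTissue <- function(section, threshold, entropyWindow = 9L,
                          minRegion = 15000L, erodeDilateRadius = 15L,
                          elementShape = c("disc", "box")) {
  stopifnot(is(section, "HistologySection"),
            threshold > 0, threshold < 1)
  elementShape <- match.arg(elementShape)
  img <- sectionImage(section)
  ent <- localEntropy(img[, , 3L], window = entropyWindow)
  bw <- ent > threshold
  bw <- removeSmallComponents(bw, minRegion, connectivity = 8L)
  if (any(bw)) {
    brush <- EBImage::makeBrush(2L * erodeDilateRadius + 1L,
                                shape = elementShape)
    bw <- EBImage::erode(bw * 1, brush)
    bw <- EBImage::fillHull(bw)
    bw <- EBImage::dilate(bw, brush)
    bw <- bw > 0
  }
  mask <- matrix(as.logical(bw), nrow(ent), ncol(ent))
  if (!any(mask)) warning("empty tissue: no region survived segmentation")
  masked <- img
  masked[, , 1L][!mask] <- 0
  masked[, , 2L][!mask] <- 0
  masked[, , 3L][!mask] <- 0
  new("TissueSegmentation", mask = mask,
      tissueArea = sum(mask) * pixelAreaCm2(pixelSize(section)),
      boundaries = extractBoundaries(mask), maskedImage = masked,
      pixelSize = pixelSize(section), sectionIndex = sectionIndex(section),
      stepSize = stepSize(section))
}

#' Suggested necrosis threshold (Otsu)
#'
#' Otsu's threshold on the blue channel within the tissue mask, logged as a
#' reproducibility aid; the operator-chosen per-slide threshold remains the
#' interface.
#'
#' @param seg a [TissueSegmentation-class]
#' @return A threshold in (0,1).
#' @export
suggestNecrosisThreshold <- function(seg) {
  stopifnot(is(seg, "TissueSegmentation"))
  blue <- maskedImage(seg)[, , 3L][maskArray(seg)]
  if (!length(blue)) return(0.5)
  EBImage::otsu(EBImage::Image(matrix(blue, ncol = 1L)), range = c(0, 1))
}

#' Segment necrotic regions within segmented tissue
#'
#' The viability stain colours viable tissue blue and leaves necrosis
#' unstained, so necrotic pixels are those whose blue channel falls BELOW the
#' user threshold within the tissue mask. Components below `minRegion` pixels
#' are removed, only the `keepLargest` largest (by pixel count) are retained,
#' and user-flagged regions (e.g. large vasculature caught by the same
#' threshold) are then excluded by their index in the retained size order.
#'
#' @param seg a [TissueSegmentation-class] (carries the masked image)
#' @param threshold user-defined threshold in (0,1) on the blue channel
#' @param minRegion components below this pixel count are removed
#'   (default 5000)
#' @param keepLargest number of largest regions retained (default 5)
#' @param exclusions integer indices (into the retained regions, size order)
#'   to exclude from the necrotic area
#' @return A [NecrosisResult-class]; zero surviving regions give necrotic
#'   area 0, never an error.
#' @export
segmentNecrosis <- function(seg, threshold, minRegion = 5000L,
                            keepLargest = 5L, exclusions = integer(0)) {
  stopifnot(is(seg, "TissueSegmentation"), threshold > 0, threshold < 1)
  blue <- maskedImage(seg)[, , 3L]
  nec <- maskArray(seg) & blue < threshold
  nec <- removeSmallComponents(nec, minRegion, connectivity = 8L)
  lab <- labelComponents(nec, connectivity = 8L)  # labels in size order
  k <- min(max(lab), keepLargest)
  pa <- pixelAreaCm2(pixelSize(seg))
  mkroi <- function(l) {
    px <- which(lab == l)
    m <- array(FALSE, dim(lab)); m[px] <- TRUE
    bnd <- extractBoundaries(m)
    list(pixels = px, areaCm2 = length(px) * pa,
         boundary = if (length(bnd)) bnd[[1L]] else matrix(numeric(0), 0, 2))
  }
  retained <- lapply(seq_len(k), mkroi)
  exclusions <- as.integer(exclusions)
  exclusions <- exclusions[exclusions >= 1L & exclusions <= k]
  excl <- retained[exclusions]
  if (length(exclusions)) retained <- retained[-exclusions]
  area <- sum(vapply(retained, `[[`, numeric(1L), "areaCm2"))
  new("NecrosisResult", rois = retained, excluded = excl,
      necroticArea = if (length(retained)) area else 0,
      pixelSize = pixelSize(seg), sectionIndex = seg@sectionIndex,
      stepSize = seg@stepSize)
}

#' Reconstruct necrotic volume from serial sections
#'
#' Multiplies each section's necrotic area by the sectioning step size and
#' sums over the series (a Cavalieri-style estimate): with areas in cm^2 and
#' the step in mm, volume in uL is `100 * sum(areas) * step`.
#'
#' @param series list of [NecrosisResult-class] from one animal/specimen
#' @param stepSize step size (mm) override; defaults to the step carried by
#'   the sections, which must be consistent
#' @return A [NecrosisVolume-class]; an empty series has volume 0.
#' @export
necroticVolume <- function(series, stepSize = NULL) {
  if (length(series) == 0L)
    return(new("NecrosisVolume", perSectionAreas = numeric(0),
               stepSize = if (is.null(stepSize)) 1 else stepSize, volume = 0))
  stopifnot(all(vapply(series, is, TRUE, "NecrosisResult")))
  steps <- vapply(series, function(s) s@stepSize, numeric(1L))
  if (is.null(stepSize)) {
    if (length(unique(steps)) != 1L)
      stop("inconsistent step sizes across the series")
    stepSize <- steps[1L]
  }
  ord <- order(vapply(series, function(s) s@sectionIndex, integer(1L)))
  areas <- vapply(series[ord], necroticArea, numeric(1L))
  new("NecrosisVolume", perSectionAreas = areas, stepSize = stepSize,
      volume = cm2mm_to_ul(sum(areas), stepSize))
}

#' Compare automatic to manual necrotic areas
#'
#' Paired comparison of the semi-automated areas against gold-standard manual
#' segmentation: the mean signed difference (auto - manual) and the mean
#' absolute per-pair difference, both in cm^2.
#'
#' @param auto numeric vector of automatic areas (cm^2)
#' @param manual numeric vector of manual areas (cm^2), same length
#' @return A [ManualComparison-class].
#' @export
compareToManual <- function(auto, manual) {
  if (length(auto) != length(manual))
    stop("'auto' and 'manual' must be paired sequences of equal length")
  d <- auto - manual
  new("ManualComparison", meanSignedDifference = mean(d),
      meanAbsoluteDifference = mean(abs(d)))
}
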