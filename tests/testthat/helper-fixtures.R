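# Shared fixtures and independent oracles. Everything here is deliberately
# naive (explicit loops, direct summation) so it cannot share a bug with the
# vectorized implementation it checks.

# Brute-force shape metrics of a voxel mask: plain loops over voxels.
bruteForceMetrics <- function(mask, spacing) {
  idx <- which(mask)
  n <- length(idx)
  d <- dim(mask)
  vol <- n * prod(spacing)
  if (n == 0L) return(list(volume = 0, centroid = rep(NaN, 3),
                           rg = NaN, reff = 0, aspect = NaN))
  cx <- cy <- cz <- 0
  co <- matrix(0, n, 3)
  for (r in seq_len(n)) {
    i <- idx[r] - 1L
    x <- i %% d[1L]
    y <- (i %/% d[1L]) %% d[2L]
    z <- i %/% (d[1L] * d[2L])
    co[r, ] <- (c(x, y, z) + 0.5) * spacing
    cx <- cx + co[r, 1L]; cy <- cy + co[r, 2L]; cz <- cz + co[r, 3L]
  }
  ctr <- c(cx, cy, cz) / n
  s <- 0
  for (r in seq_len(n))
    s <- s + sqrt(sum((co[r, ] - ctr)^2))
  rg <- s / n
  reff <- (3 * vol / (4 * pi))^(1 / 3)
  list(volume = vol, centroid = ctr, rg = rg, reff = reff,
       aspect = rg / reff)
}

# Digitized solid ball mask of radius R voxels, isotropic unit spacing.
ballMask <- function(R, pad = 2L) {
  d <- rep(2L * R + 2L * pad + 1L, 3L)
  ctr <- (d + 1) / 2
  co <- arrayInd(seq_len(prod(d)), d)
  array(rowSums(sweep(co, 2L, ctr)^2) <= R^2, d)
}

# ConcentrationVolume built directly from a grid (bypasses calibration).
concVolume <- function(grid, spacing = c(1, 1, 1)) {
  new("ConcentrationVolume", grid = grid,
      spacing = rep_len(spacing, 3L),
      model = fitTwoPoint(0, -100))
}

# A random blob-ish mask with at most maxVoxels voxels set.
randomMask <- function(dims, density = 0.1) {
  array(stats::runif(prod(dims)) < density, dims)
}

# A tissue segmentation wrapper around a hand-built mask and image, for
# necrosis tests that do not exercise the entropy step.
fakeTissueSeg <- function(maskedImage, mask, pixelSizeUm = 20,
                          sectionIndex = 1L, stepMm = 1) {
  new("TissueSegmentation", mask = mask,
      tissueArea = sum(mask) * (pixelSizeUm * 1e-4)^2,
      boundaries = list(), maskedImage = maskedImage,
      pixelSize = pixelSizeUm, sectionIndex = as.integer(sectionIndex),
      stepSize = stepMm)
}

# RGB image: viable-blue everywhere inside `tissue`, with dark (low-blue)
# blobs painted where `darkMask` is TRUE. No texture.
flatSlideImage <- function(tissue, darkMask,
                           viableBlue = 0.85, darkBlue = 0.3) {
  d <- dim(tissue)
  img <- array(0, c(d, 3L))
  img[, , 1][tissue] <- 0.5
  img[, , 2][tissue] <- 0.5
  img[, , 3][tissue] <- viableBlue
  img[, , 3][darkMask & tissue] <- darkBlue
  img
}

# Paint a filled disc into a logical matrix, returning the matrix.
paintDisc <- function(mask, centerPx, radiusPx, value = TRUE) {
  d <- dim(mask)
  for (i in seq_len(d[1L])) {
    dy2 <- (i - centerPx[1L])^2
    if (dy2 > radiusPx^2) next
    w <- floor(sqrt(radiusPx^2 - dy2))
    j1 <- max(1L, centerPx[2L] - w); j2 <- min(d[2L], centerPx[2L] + w)
    mask[i, j1:j2] <- value
  }
  mask
}
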