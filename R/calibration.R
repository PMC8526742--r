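#' Summarize the radiodensity readings of one region
#'
#' Arithmetic mean, sample standard deviation (n-1 denominator) and a
#' fixed-width histogram of the HU readings of a segmented region.
#'
#' @param sample a [RadiodensitySample-class]
#' @param binWidth histogram bin width in HU (default 5)
#' @return A list with `mean` (HU), `sd` (HU; 0 for a single reading) and
#'   `histogram`, a data.frame of bin `mid` and `count` covering the observed
#'   range.
#' @examples
#' s <- RadiodensitySample(c(-60, -70, -65))
#' summarizeSample(s)$mean
#' @export
summarizeSample <- function(sample, binWidth = 5) {
  stopifnot(is(sample, "RadiodensitySample"))
  v <- huValues(sample)
  if (length(v) == 0L) stop("no readings in sample")
  m <- mean(v)
  s <- if (length(v) > 1L) stats::sd(v) else 0
  lo <- floor(min(v) / binWidth) * binWidth
  hi <- ceiling(max(v) / binWidth) * binWidth
  if (hi <= lo) hi <- lo + binWidth
  breaks <- seq(lo, hi, by = binWidth)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = FALSE)
  list(mean = m, sd = s,
       histogram = data.frame(mid = h$mids, count = h$counts))
}

#' Fit the two-point HU-to-concentration calibration
#'
#' Anchors the affine radiodensity-to-ethanol-fraction map at the measured
#' radiodensities of the 0\% and 100\% ethanol standards. The model
#' reproduces the standards exactly under [estimateConcentration()].
#'
#' @param huZero radiodensity of the 0\% ethanol standard (HU); when
#'   quantifying ethanol in tissue this is the mean pre-ablation tissue HU
#' @param huHundred radiodensity of the 100\% ethanol standard (HU)
#' @return A [CalibrationModel-class].
#' @examples
#' fitTwoPoint(-66.5, -340.3)
#' @export
fitTwoPoint <- function(huZero, huHundred) {
  if (!is.finite(huZero) || !is.finite(huHundred) || huZero == huHundred)
    stop("degenerate calibration: the two standards must differ")
  new("CalibrationModel", huZero = as.numeric(huZero),
      huHundred = as.numeric(huHundred))
}

#' Estimate ethanol concentration from radiodensity
#'
#' Applies the two-point calibration
#' \deqn{c = (HU - HU_{0\%}) / (HU_{100\%} - HU_{0\%})}{c = (hu - huZero) / (huHundred - huZero)}
#' returning the ethanol volume fraction. The estimate is deliberately NOT
#' clipped: values below 0 or above 1 are passed through, and downstream
#' stages decide how to treat them (e.g. the in-vivo > 120\% air-bubble
#' exclusion).
#'
#' @param hu radiodensity value(s) in HU; vectorized, `NA` passes through
#' @param model a [CalibrationModel-class]
#' @return Ethanol fraction(s), unbounded.
#' @examples
#' m <- fitTwoPoint(-66.5, -340.3)
#' estimateConcentration(-203.4, m)  # 0.5
#' @export
estimateConcentration <- function(hu, model) {
  stopifnot(is(model, "CalibrationModel"))
  (hu - model@huZero) / (model@huHundred - model@huZero)
}

#' Diagnostic ordinary least-squares fit of mean HU on concentration
#'
#' Fits mean radiodensity against known ethanol fraction across vials by OLS,
#' as a linearity diagnostic alongside the two-point calibration.
#'
#' @param samples list of [RadiodensitySample-class] with known
#'   `trueConcentration`
#' @return A [LinearFitResult-class] (slope HU/fraction, intercept HU,
#'   r-squared).
#' @export
fitLinear <- function(samples) {
  stopifnot(length(samples) > 0L,
            all(vapply(samples, is, TRUE, "RadiodensitySample")))
  conc <- vapply(samples, trueConcentration, numeric(1L))
  if (anyNA(conc)) stop("every sample must have a known true concentration")
  if (length(unique(conc)) < 2L)
    stop("at least two distinct concentrations are required")
  y <- vapply(samples, function(s) mean(huValues(s)), numeric(1L))
  fit <- stats::lm(y ~ conc)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss < .Machine$double.eps) 1
        else 1 - sum(stats::residuals(fit)^2) / tss
  new("LinearFitResult", slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      rSquared = min(max(r2, 0), 1))
}

#' Systematic (non-linearity) calibration error
#'
#' For each intermediate-concentration sample, the absolute difference between
#' the concentration predicted by the two-point calibration from its mean HU
#' and its true concentration, in percentage points; summarized as mean and
#' standard deviation over samples.
#'
#' @param model a [CalibrationModel-class]
#' @param intermediates list of [RadiodensitySample-class] with known true
#'   concentration strictly inside (0, 1)
#' @return list(mean, sd) in concentration percentage points (`sd` is `NA`
#'   for a single sample).
#' @export
nonlinearityError <- function(model, intermediates) {
  stopifnot(is(model, "CalibrationModel"), length(intermediates) > 0L)
  conc <- vapply(intermediates, trueConcentration, numeric(1L))
  if (anyNA(conc) || any(conc <= 0) || any(conc >= 1))
    stop("intermediates must have known true concentration strictly in (0,1)")
  pred <- vapply(intermediates,
                 function(s) estimateConcentration(mean(huValues(s)), model),
                 numeric(1L))
  err <- abs(pred - conc) * 100
  list(mean = mean(err),
       sd = if (length(err) > 1L) stats::sd(err) else NA_real_)
}

#' Random (measurement-variance) calibration error
#'
#' The variance in radiodensity of homogeneous-concentration samples: the mean
#' (and sd) of the per-sample HU standard deviations, and the mean expressed
#' as a percent of the calibration range |huZero - huHundred|.
#'
#' @param samples list of [RadiodensitySample-class] of homogeneous vials
#' @param model a [CalibrationModel-class]
#' @return list(varianceHuMean, varianceHuSd, variancePctOfRange).
#' @export
measurementVariance <- function(samples, model) {
  stopifnot(length(samples) > 0L, is(model, "CalibrationModel"))
  sds <- vapply(samples, function(s) {
    v <- huValues(s)
    if (length(v) > 1L) stats::sd(v) else 0
  }, numeric(1L))
  m <- mean(sds)
  list(varianceHuMean = m,
       varianceHuSd = if (length(sds) > 1L) stats::sd(sds) else 0,
       variancePctOfRange = m / huRange(model) * 100)
}

#' Combined calibration error report
#'
#' Convenience wrapper assembling [nonlinearityError()] on the intermediate
#' standards and [measurementVariance()] on the homogeneous vials into one
#' [CalibrationErrorReport-class].
#'
#' @param model a [CalibrationModel-class]
#' @param intermediates samples at known concentrations strictly in (0,1)
#' @param vials homogeneous-vial samples for the variance component (defaults
#'   to `intermediates`)
#' @return A [CalibrationErrorReport-class].
#' @export
calibrationErrorReport <- function(model, intermediates, vials = intermediates) {
  nl <- nonlinearityError(model, intermediates)
  mv <- measurementVariance(vials, model)
  new("CalibrationErrorReport",
      nonlinearityErrorMean = nl$mean,
      nonlinearityErrorSd = if (is.na(nl$sd)) 0 else nl$sd,
      varianceHuMean = mv$varianceHuMean,
      varianceHuSd = mv$varianceHuSd,
      variancePctOfRange = mv$variancePctOfRange)
}
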