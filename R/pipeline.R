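#' Fold change between two groups
#'
#' Ratio of group means, reported with both group labels.
#'
#' @param groupA numeric vector (or scalar mean) for the numerator group
#' @param groupB numeric vector (or scalar mean) for the denominator group
#' @param labels character(2) group labels
#' @return list(foldChange, groupA, groupB, meanA, meanB).
#' @examples
#' foldChange(137.7, 17.1)$foldChange  # ex vivo distribution volumes
#' @export
foldChange <- function(groupA, groupB, labels = c("A", "B")) {
  ma <- mean(groupA); mb <- mean(groupB)
  if (!is.finite(mb) || mb <= 0)
    stop("fold change undefined: denominator group mean must be positive")
  list(foldChange = ma / mb, groupA = labels[1L], groupB = labels[2L],
       meanA = ma, meanB = mb)
}

# Run one stage with a stage-tagged error.
stageTry <- function(stage, sample, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage ", stage, "] sample '", sample, "': ",
         conditionMessage(e), call. = FALSE))
}

quantifyCtSample <- function(s, cfg) {
  if (isTRUE(s$simulate)) {
    spArgs <- s$phantom %||% list()
    spArgs$seed <- spArgs$seed %||% (cfg$seed + (s$seedOffset %||% 0L))
    ph <- makeInjectionPhantom(do.call(injectionPhantomSpec, spArgs))
    ct <- ph$ct; tissue <- ph$tissue
    huZero <- truthRecord(ph$truth)$huZero
    huHundred <- truthRecord(ph$truth)$huHundred
    truth <- ph$truth
  } else {
    ct <- readCtVolume(s$ct)
    tissue <- if (!is.null(s$tissueMask)) readTissueMask(s$tissueMask) else NULL
    huHundred <- s$ethanolStandard %||% cfg$ethanolStandard
    huZero <- if (!is.null(s$tissueStandard)) s$tissueStandard
      else if (!is.null(s$pre)) {
        pre <- readCtVolume(s$pre)
        mean(if (is.null(tissue)) gridArray(pre) else gridArray(pre)[tissue])
      } else 0
    truth <- NULL
  }
  model <- fitTwoPoint(huZero, huHundred)
  conc <- toConcentration(ct, model, tissue)
  dist <- segmentDistribution(conc, lower = cfg$lower, upper = cfg$upper)
  list(model = model, conc = conc, dist = dist,
       curve = cumulativeVolumeCurve(conc), truth = truth)
}

quantifyHistologySample <- function(s, cfg) {
  tthr <- s$tissueThreshold %||% cfg$tissueThreshold %||% 0.3
  nthr <- s$necrosisThreshold %||% cfg$necrosisThreshold %||% 0.72
  if (isTRUE(s$simulate)) {
    slArgs <- s$slides %||% list()
    slArgs$seed <- slArgs$seed %||% (cfg$seed + 1000L + (s$seedOffset %||% 0L))
    ss <- makeSlideSeries(do.call(slideSeriesSpec, slArgs))
    sections <- ss$sections
    truth <- ss$truth
  } else {
    if (is.null(s$slideDir)) return(NULL)
    paths <- sort(list.files(s$slideDir, pattern = "\\.(png|tif|tiff)$",
                             full.names = TRUE, ignore.case = TRUE))
    sections <- lapply(seq_along(paths), function(i)
      readSection(paths[i], pixelSize = s$pixelSize %||% cfg$pixelSize,
                  sectionIndex = i, stepSize = s$stepMm %||% cfg$stepMm %||% 1))
    truth <- NULL
  }
  series <- lapply(sections, function(sec) {
    seg <- segmentTissue(sec, threshold = tthr)
    segmentNecrosis(seg, threshold = nthr,
                    exclusions = s$exclusions %||% integer(0))
  })
  list(volume = necroticVolume(series), series = series, truth = truth)
}

#' Run the calibrate / quantify-ct / quantify-histology / correlate pipeline
#'
#' Executes the stages in order for every configured sample and assembles the
#' radiologic-pathologic correlation report. Samples either point to files
#' (NIfTI volumes, slide images) or set `simulate: true` to run on generated
#' phantom + slide-series fixtures with recorded ground truth. Outputs
#' (report.csv, report.json, provenance.json, per-sample projections) are
#' written under `config$outputDir` when it is set; re-running an identical
#' config reproduces byte-identical CSV/JSON.
#'
#' @param config a config list, or path to a YAML/JSON config (see
#'   [readRunConfig()] and the vignette)
#' @return A [CorrelationReport-class], invisibly when writing artifacts.
#' @export
runPipeline <- function(config) {
  cfg <- if (is.character(config)) readRunConfig(config)
         else validateRunConfig(config)
  if (!length(cfg$samples)) {
    warning("empty sample list: nothing to do")
    return(new("CorrelationReport",
               perSample = data.frame(), groupStats = data.frame(),
               foldChanges = data.frame()))
  }

  rows <- list(); prov <- list(); artifacts <- list()
  for (i in seq_along(cfg$samples)) {
    s <- cfg$samples[[i]]
    s$seedOffset <- s$seedOffset %||% (i - 1L)
    ctRes <- stageTry("quantify-ct", s$name, quantifyCtSample(s, cfg))
    hiRes <- stageTry("quantify-histology", s$name,
                      quantifyHistologySample(s, cfg))
    necVol <- if (is.null(hiRes)) NA_real_ else volumeUl(hiRes$volume)
    distVol <- volumeUl(ctRes$dist)
    ratio <- if (!is.na(necVol) && distVol > 0)
      necrosisToDistributionRatio(necVol, distVol) else NA_real_
    ctr <- centroid(ctRes$dist)
    rows[[i]] <- data.frame(
      sample = s$name, group = s$group %||% "all",
      distributionVolumeUl = distVol, necroticVolumeUl = necVol,
      ratio = ratio, aspectRatio = aspectRatio(ctRes$dist),
      nComponents = nComponents(ctRes$dist),
      centroidX = ctr[1L], centroidY = ctr[2L], centroidZ = ctr[3L])
    prov[[s$name]] <- list(
      parameters = s[setdiff(names(s), "name")],
      lower = cfg$lower, upper = cfg$upper, seed = cfg$seed,
      huZero = huZero(ctRes$model), huHundred = huHundred(ctRes$model),
      inputHashes = if (!isTRUE(s$simulate)) {
        f <- unlist(s[c("ct", "pre", "tissueMask")])
        f <- f[!is.na(f) & file.exists(f)]
        as.list(tools::md5sum(f))
      })
    artifacts[[s$name]] <- ctRes
  }
  perSample <- do.call(rbind, rows)

  agg <- function(v) c(mean = mean(v, na.rm = TRUE),
                       sd = stats::sd(v, na.rm = TRUE))
  groups <- split(perSample, perSample$group)
  groupStats <- do.call(rbind, lapply(names(groups), function(g) {
    d <- groups[[g]]
    data.frame(group = g, n = nrow(d),
               distributionVolumeMeanUl = agg(d$distributionVolumeUl)[1L],
               distributionVolumeSdUl = agg(d$distributionVolumeUl)[2L],
               necroticVolumeMeanUl = agg(d$necroticVolumeUl)[1L],
               necroticVolumeSdUl = agg(d$necroticVolumeUl)[2L],
               ratioMean = agg(d$ratio)[1L], ratioSd = agg(d$ratio)[2L])
  }))
  rownames(groupStats) <- NULL

  fc <- list()
  gn <- names(groups)
  if (length(gn) > 1L) {
    for (a in gn) for (b in setdiff(gn, a)) {
      for (metric in c("distributionVolumeUl", "necroticVolumeUl")) {
        mb <- mean(groups[[b]][[metric]], na.rm = TRUE)
        if (is.finite(mb) && mb > 0) {
          f <- foldChange(groups[[a]][[metric]][
                 !is.na(groups[[a]][[metric]])],
               groups[[b]][[metric]][!is.na(groups[[b]][[metric]])],
               labels = c(a, b))
          fc[[length(fc) + 1L]] <- data.frame(
            metric = metric, groupA = a, groupB = b,
            foldChange = f$foldChange)
        }
      }
    }
  }
  foldChanges <- if (length(fc)) do.call(rbind, fc) else data.frame()

  report <- new("CorrelationReport", perSample = perSample,
                groupStats = groupStats, foldChanges = foldChanges)

  if (!is.null(cfg$outputDir) && !identical(cfg$outputDir, FALSE) &&
      nzchar(cfg$outputDir)) {
    dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(perSample, file.path(cfg$outputDir, "report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(perSample = perSample, groupStats = groupStats,
           foldChanges = foldChanges),
      file.path(cfg$outputDir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
    jsonlite::write_json(prov, file.path(cfg$outputDir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (isTRUE(cfg$writeProjections)) {
      for (nm in names(artifacts)) {
        proj <- maxConcentrationProjection(artifacts[[nm]]$conc, axis = 1L)
        writeProjectionPng(proj, file.path(cfg$outputDir,
                                           paste0(nm, "_projection.png")))
      }
    }
  }
  report
}
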