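#' Configure the per-sample analysis pipeline
#'
#' Defaults follow the conventions of the AFM nanotexture workflow this
#' package implements: zero-referencing (minimum height shifted to 0) is on
#' for the roughness stage so mean heights are interpretable, tip
#' reconstruction (when a tip is supplied) is applied before the fractal
#' stage only, and all six fractal estimators run without B-spline
#' resampling.
#'
#' @param zeroReference shift heights so min = 0 before roughness.
#' @param tip optional [TipModel-class]; enables erosion-based surface
#'   reconstruction for the stages in `tipStages`.
#' @param tipStages which stages use the reconstructed map.
#' @param bins histogram bins for the height PDF / mode.
#' @param fractalMethods estimators to run.
#' @param bsplineFactor resampling factor before fractal estimation.
#' @param fitRange `"auto"` or `c(i0, i1)`.
#' @param nThresholds Minkowski threshold count.
#' @param seed seed for any stochastic stage.
#' @return an [AnalysisConfig-class].
#' @seealso [analyzeSample()]
#' @export
analysisConfig <- function(zeroReference = TRUE, tip = NULL,
                           tipStages = "fractal", bins = 256L,
                           fractalMethods = c("variance", "cube_counting",
                                              "triangulation",
                                              "power_spectrum",
                                              "structure_function",
                                              "variation"),
                           bsplineFactor = 1L, fitRange = "auto",
                           nThresholds = 256L, seed = 1L) {
  new("AnalysisConfig", zeroReference = zeroReference, tip = tip,
      tipStages = tipStages, bins = as.integer(bins),
      fractalMethods = fractalMethods,
      bsplineFactor = as.integer(bsplineFactor), fitRange = fitRange,
      nThresholds = as.integer(nThresholds), seed = as.integer(seed))
}

#' Run the full per-sample analysis
#'
#' Stage order: optional zero-referencing, optional tip reconstruction,
#' roughness statistics and height PDF, the fractal estimator suite (on the
#' reconstructed map when a tip is configured), and Minkowski curves with
#' landmark extraction. A stage failure is recorded in the report's
#' `skipped` slot with its reason and the remaining stages still run. Given
#' the same map and config the report is deterministic.
#'
#' @param map a [HeightMap-class].
#' @param config an [AnalysisConfig-class].
#' @return a [SampleReport-class].
#' @seealso [compareSamples()], [writeSampleReport()]
#' @export
#' @examples
#' hm <- generateFbmSurface(sceneSpec(sizePx = 128, seed = 3))
#' rep <- analyzeSample(hm, analysisConfig(fractalMethods = "variance"))
analyzeSample <- function(map, config = analysisConfig()) {
  stopifnot(is(map, "HeightMap"), is(config, "AnalysisConfig"))
  validObject(map)
  validObject(config)
  skipped <- character()
  zr <- map
  if (config@zeroReference)
    zr@heights <- zr@heights - min(zr@heights)
  rec <- NULL
  if (!is.null(config@tip)) {
    rec <- tryCatch(reconstructSurface(zr, config@tip)$surface,
                    error = function(e) {
                      skipped["tip_correction"] <<- conditionMessage(e)
                      NULL
                    })
  }
  pick <- function(stage) {
    if (!is.null(rec) && stage %in% config@tipStages) rec else zr
  }
  roughness <- tryCatch(roughnessReport(pick("roughness"), config@bins),
                        error = function(e) {
                          skipped["roughness"] <<- conditionMessage(e)
                          NULL
                        })
  pdf <- tryCatch(heightPDF(pick("roughness"), config@bins),
                  error = function(e) {
                    skipped["height_pdf"] <<- conditionMessage(e)
                    NULL
                  })
  fractal <- list()
  for (m in config@fractalMethods) {
    est <- tryCatch(
      fractalDimension(pick("fractal"), m, fitRange = config@fitRange,
                       bsplineFactor = config@bsplineFactor),
      error = function(e) {
        skipped[paste0("fractal_", m)] <<- conditionMessage(e)
        NULL
      })
    if (!is.null(est)) fractal[[m]] <- est
  }
  minkowski <- tryCatch(minkowskiCurves(pick("minkowski"), config@nThresholds),
                        error = function(e) {
                          skipped["minkowski"] <<- conditionMessage(e)
                          NULL
                        })
  landmarks <- if (!is.null(minkowski)) {
    lm <- connectivityLandmarks(minkowski)
    lm$volumeSymmetry <- volumeSymmetryScore(minkowski)
    lm
  } else list()
  provenance <- list(
    inputDigest = .heightMapDigest(map),
    dim = dim(map@heights),
    pixelSize = unname(pixelSize(map)),
    config = .configAsList(config),
    package = as.character(utils::packageVersion("afmtexture"))
  )
  new("SampleReport", label = map@label, roughness = roughness, pdf = pdf,
      fractal = fractal, minkowski = minkowski, landmarks = landmarks,
      skipped = skipped, provenance = provenance)
}

# cheap content digest (sum-based, stable across platforms at fixed precision)
.heightMapDigest <- function(map) {
  z <- map@heights
  sprintf("%dx%d:%.10e:%.10e:%.10e", nrow(z), ncol(z), sum(z), sum(z^2),
          sum(z * seq_along(z)))
}

.configAsList <- function(config) {
  list(
    zeroReference = config@zeroReference,
    tip = if (is.null(config@tip)) NULL else list(
      shape = config@tip@shape, apexRadius = config@tip@apexRadius,
      rotationDeg = config@tip@rotationDeg,
      halfAngleDeg = config@tip@halfAngleDeg,
      pixelSize = config@tip@pixelSize),
    tipStages = config@tipStages, bins = config@bins,
    fractalMethods = config@fractalMethods,
    bsplineFactor = config@bsplineFactor,
    fitRange = config@fitRange, nThresholds = config@nThresholds,
    seed = config@seed
  )
}

#' Serialize a SampleReport to JSON
#'
#' Numbers are written at fixed precision (10 significant digits), so the
#' same map and config always produce byte-identical reports. The run's
#' config is embedded verbatim.
#'
#' @param report a [SampleReport-class].
#' @param path output file, or NULL to return the JSON string.
#' @return the path (or JSON string), invisibly.
#' @export
writeSampleReport <- function(report, path = NULL) {
  stopifnot(is(report, "SampleReport"))
  obj <- list(
    label = report@label,
    provenance = report@provenance,
    roughness = if (is.null(report@roughness)) NULL else
      c(as.list(report@roughness@values),
        list(n = report@roughness@nPoints,
             undefined = report@roughness@undefined)),
    fractal = lapply(report@fractal, function(e) list(
      method = e@method, Df = e@Df, slope = e@slope,
      intercept = e@intercept, rSquared = e@rSquared, warn = e@warn)),
    minkowskiLandmarks = if (length(report@landmarks)) {
      lm <- report@landmarks
      lm$plateaus <- NULL
      lm
    } else NULL,
    skipped = as.list(report@skipped)
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(10),
                           null = "null", pretty = TRUE)
  if (is.null(path)) return(invisible(as.character(json)))
  writeLines(as.character(json), path)
  invisible(path)
}

#' Compare sample reports
#'
#' Builds a long-format table of (sample, metric, value) over the roughness
#' statistics, per-method fractal dimensions and Minkowski landmarks of two
#' or more reports, plus all pairwise differences and a sign-of-difference
#' summary per metric. Descriptive only: no hypothesis testing is
#' performed, since each report summarizes a single scan.
#'
#' @param reports list of [SampleReport-class] objects (>= 2).
#' @return list with data.frames `long`, `differences`, `signs`.
#' @export
compareSamples <- function(reports) {
  stopifnot(is.list(reports), length(reports) >= 2L)
  metricsOf <- function(r) {
    out <- c()
    if (!is.null(r@roughness)) out <- c(out, r@roughness@values)
    if (length(r@fractal)) {
      df <- vapply(r@fractal, function(e) e@Df, numeric(1))
      names(df) <- paste0("Df_", names(df))
      out <- c(out, df)
    }
    if (length(r@landmarks)) {
      lm <- r@landmarks
      keep <- c(vHalf = lm$vHalf, chiMin = lm$chiMin, chiMax = lm$chiMax,
                sMax = lm$sMax, volumeSymmetry = lm$volumeSymmetry)
      out <- c(out, keep)
    }
    out
  }
  labels <- vapply(reports, function(r) r@label, character(1))
  ms <- lapply(reports, metricsOf)
  .compareMetricSets(ms, labels)
}

#' Compare serialized sample reports
#'
#' Reads JSON reports written by [writeSampleReport()] and builds the same
#' comparison tables as [compareSamples()].
#'
#' @param paths character vector of report files (>= 2).
#' @return list with data.frames `long`, `differences`, `signs`.
#' @export
compareReportFiles <- function(paths) {
  stopifnot(length(paths) >= 2L)
  reports <- lapply(paths, jsonlite::read_json, simplifyVector = TRUE)
  ms <- lapply(reports, function(r) {
    out <- c()
    if (!is.null(r$roughness)) {
      v <- unlist(r$roughness[setdiff(names(r$roughness),
                                      c("n", "undefined"))])
      num <- suppressWarnings(as.numeric(v))
      names(num) <- names(v)
      out <- c(out, num[is.finite(num)])
    }
    if (length(r$fractal)) {
      df <- vapply(r$fractal, function(e) as.numeric(e$Df), numeric(1))
      names(df) <- paste0("Df_", names(r$fractal))
      out <- c(out, df)
    }
    lm <- r$minkowskiLandmarks
    if (length(lm)) {
      keep <- c(vHalf = lm$vHalf, chiMin = lm$chiMin, chiMax = lm$chiMax,
                sMax = lm$sMax, volumeSymmetry = lm$volumeSymmetry)
      out <- c(out, unlist(keep))
    }
    storage.mode(out) <- "numeric"
    out
  })
  labels <- vapply(reports, function(r)
    if (is.null(r$label)) "" else r$label, character(1))
  .compareMetricSets(ms, labels)
}

.compareMetricSets <- function(ms, labels) {
  if (anyDuplicated(labels))
    labels <- make.unique(labels, sep = "_")
  allMetrics <- unique(unlist(lapply(ms, names)))
  missing <- vapply(ms, function(m) length(setdiff(allMetrics, names(m))) > 0,
                    logical(1))
  if (any(missing))
    warning("some reports are missing metrics; comparison table is partial")
  long <- do.call(rbind, lapply(seq_along(ms), function(i) {
    data.frame(sample = labels[i], metric = allMetrics,
               value = unname(ms[[i]][allMetrics]),
               stringsAsFactors = FALSE)
  }))
  pairs <- utils::combn(seq_along(ms), 2L)
  differences <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1L, j]
    i2 <- pairs[2L, j]
    data.frame(sampleA = labels[i1], sampleB = labels[i2],
               metric = allMetrics,
               difference = unname(ms[[i1]][allMetrics] - ms[[i2]][allMetrics]),
               stringsAsFactors = FALSE)
  }))
  signs <- do.call(rbind, lapply(allMetrics, function(m) {
    d <- differences$difference[differences$metric == m]
    data.frame(metric = m, nPositive = sum(d > 0, na.rm = TRUE),
               nNegative = sum(d < 0, na.rm = TRUE),
               nZero = sum(d == 0, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  list(long = long, differences = differences, signs = signs)
}
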