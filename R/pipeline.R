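## End-to-end orchestration: manifest in, analysis report out.

#' Construct a pipeline configuration
#'
#' @param centreFraction centre-disc radius as a fraction of the capsule's
#'   equivalent radius.
#' @param backgroundErosion halo-exclusion margin, pixels.
#' @param absenceTolerance micrometres; predictions at or below it are
#'   classified shell-absent.
#' @param calibrationMinConc millimolar; direct thickness measurement (and
#'   hence calibration eligibility) starts at this soaking concentration.
#' @param columnMap named list mapping canonical measurement columns onto
#'   external CSV headers.
#' @param seed integer seed recorded with the run.
#' @return a [PipelineConfig-class].
#' @export
pipelineConfig <- function(centreFraction = 0.1, backgroundErosion = 5,
                           absenceTolerance = 0, calibrationMinConc = 5,
                           columnMap = list(sample_id = "sample_id",
                                            conc_mM = "conc_mM",
                                            R_c_um = "R_c_um",
                                            h_um = "h_um"),
                           seed = 1L) {
  new("PipelineConfig", centreFraction = centreFraction,
      backgroundErosion = backgroundErosion,
      absenceTolerance = absenceTolerance,
      calibrationMinConc = calibrationMinConc,
      columnMap = columnMap, seed = as.integer(seed))
}

#' Load an external measurements table
#'
#' Reads a CSV of direct microscope measurements and maps its columns onto
#' the canonical schema (sample_id, conc_mM, R_c_um, h_um) via a declared
#' column map, optionally rescaling units. Rows with a missing thickness are
#' retained and flagged \code{measurable = FALSE} rather than dropped: those
#' are exactly the thin-shell samples whose thickness the colour calibration
#' must later predict.
#'
#' @param path CSV path.
#' @param columnMap named list; names are the canonical columns, values the
#'   headers found in the file.
#' @param scales named numeric multipliers applied after mapping, for unit
#'   coercion to micrometres/millimolar (e.g. \code{c(h_um = 1000)} for a
#'   file reporting millimetres).
#' @return data.frame with columns sample_id, conc_mM, R_c_um, h_um,
#'   measurable.
#' @section Errors: \code{coreshell_schema} listing the headers actually
#'   found when a mapped column is absent.
#' @export
loadExternalMeasurements <- function(path,
                                     columnMap = list(
                                       sample_id = "sample_id",
                                       conc_mM = "conc_mM",
                                       R_c_um = "R_c_um",
                                       h_um = "h_um"),
                                     scales = NULL) {
  if (!file.exists(path))
    csStop(sprintf("measurements file not found: %s", path), "coreshell_io")
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  need <- c("sample_id", "conc_mM", "R_c_um", "h_um")
  missingMap <- setdiff(need, names(columnMap))
  if (length(missingMap))
    csStop(paste("column map must name:", paste(missingMap, collapse = ", ")),
           "coreshell_schema")
  absent <- !vapply(columnMap[need], function(nm) nm %in% names(raw),
                    logical(1))
  if (any(absent))
    csStop(sprintf(
      "mapped column(s) %s not found; file has columns: %s",
      paste(unlist(columnMap[need][absent]), collapse = ", "),
      paste(names(raw), collapse = ", ")), "coreshell_schema")
  num <- function(v) suppressWarnings(as.numeric(v))
  out <- data.frame(
    sample_id = as.character(raw[[columnMap$sample_id]]),
    conc_mM = num(raw[[columnMap$conc_mM]]),
    R_c_um = num(raw[[columnMap$R_c_um]]),
    h_um = num(raw[[columnMap$h_um]]),
    stringsAsFactors = FALSE)
  for (nm in names(scales))
    out[[nm]] <- out[[nm]] * scales[[nm]]
  out$measurable <- is.finite(out$h_um)
  out
}

#' Run the full shell-thickness analysis pipeline
#'
#' Segments every image in the manifest, extracts colour metrics, fits the
#' gelation constant alpha on the directly measured thicknesses (through
#' origin, linearized scale), fits the linear colour-to-thickness calibration
#' on the calibration-eligible samples (soaking concentration at or above
#' \code{calibrationMinConc} and a positive measured thickness), predicts
#' thickness and shell status for every imaged sample, aggregates per
#' concentration and infers the formation threshold.
#'
#' Per-image failures (unreadable files, no capsule found) are logged as
#' skipped rows and do not abort the run; the run fails only when no image is
#' usable or the measurements do not support the fits.
#'
#' @param manifest path to a manifest CSV (image_path, sample_id, conc_mM,
#'   scale_um_per_px) or an equivalent data.frame; relative image paths are
#'   resolved against the manifest's directory.
#' @param measurements path to a measurements CSV (read through
#'   [loadExternalMeasurements()] with the config's column map) or an
#'   equivalent data.frame with canonical columns. Required: the calibration
#'   cannot be fitted without direct measurements.
#' @param config a [PipelineConfig-class].
#' @return an [AnalysisReport-class].
#' @export
runPipeline <- function(manifest, measurements,
                        config = pipelineConfig()) {
  stopifnot(is(config, "PipelineConfig"))
  baseDir <- "."
  if (is.character(manifest)) {
    baseDir <- dirname(manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  need <- c("image_path", "sample_id", "conc_mM", "scale_um_per_px")
  if (!all(need %in% names(manifest)))
    csStop(paste("manifest must contain columns:",
                 paste(need, collapse = ", ")), "coreshell_schema")
  if (missing(measurements) || is.null(measurements))
    csStop("direct measurements are required: cannot calibrate without them",
           "coreshell_degenerate")
  if (is.character(measurements))
    measurements <- loadExternalMeasurements(measurements,
                                             columnMap = config@columnMap)
  if (!"measurable" %in% names(measurements))
    measurements$measurable <- is.finite(measurements$h_um)

  rows <- vector("list", nrow(manifest))
  skipped <- list()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$sample_id[i]
    res <- tryCatch({
      p <- manifest$image_path[i]
      if (!file.exists(p)) p <- file.path(baseDir, manifest$image_path[i])
      img <- readCapsuleImage(p, sampleId = sid,
                              conc = manifest$conc_mM[i],
                              scale = manifest$scale_um_per_px[i])
      seg <- segmentCapsule(img)
      ctr <- centreRegion(seg, fraction = config@centreFraction)
      cs <- extractColourStats(img, ctr, seg,
                               backgroundErosion = config@backgroundErosion)
      cbind(data.frame(sample_id = sid, conc_mM = manifest$conc_mM[i],
                       R_outer_um = measureRadius(seg,
                         manifest$scale_um_per_px[i])),
            as.data.frame(cs))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(sample_id = sid, reason = conditionMessage(res),
                   stringsAsFactors = FALSE)
      res <- data.frame(sample_id = sid, conc_mM = manifest$conc_mM[i],
                        R_outer_um = NA_real_, R_mean = NA_real_,
                        G_mean = NA_real_, B_mean = NA_real_,
                        R_bg = NA_real_, G_bg = NA_real_, B_bg = NA_real_,
                        metric_R = NA_real_, metric_R_minus_bg = NA_real_,
                        R_minus_B = NA_real_)
    }
    rows[[i]] <- res
  }
  perSample <- do.call(rbind, rows)
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(sample_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  if (all(is.na(perSample$R_minus_B)))
    csStop("no usable images in the manifest", "coreshell_no_capsule")
  if (nrow(skipped))
    warning(sprintf("%d image(s) skipped: %s", nrow(skipped),
                    paste(skipped$sample_id, collapse = ", ")),
            call. = FALSE)

  ## alpha: through-origin fit on directly measured (positive) thicknesses
  fitRows <- measurements[measurements$measurable &
                            measurements$h_um > 0, , drop = FALSE]
  alphaModel <- fitAlpha(fitRows)

  ## calibration: eligible samples imaged successfully
  merged <- merge(perSample[, c("sample_id", "conc_mM", "R_minus_B")],
                  measurements[, c("sample_id", "h_um", "measurable")],
                  by = "sample_id")
  elig <- merged$measurable & merged$h_um > 0 &
    merged$conc_mM >= config@calibrationMinConc &
    is.finite(merged$R_minus_B)
  calibration <- fitColourCalibration(merged$R_minus_B[elig],
                                      merged$h_um[elig])

  pred <- predictThicknessFromColour(calibration, perSample$R_minus_B,
                                     tolerance = config@absenceTolerance)
  perSample$h_pred_um <- pred$h_pred_um
  perSample$status <- pred$status

  ok <- is.finite(perSample$R_minus_B)
  aggRB <- aggregateByConcentration(perSample$conc_mM[ok],
                                    perSample$R_minus_B[ok])
  aggH <- aggregateByConcentration(perSample$conc_mM[ok],
                                   perSample$h_pred_um[ok])
  aggregates <- data.frame(conc_mM = aggRB$conc_mM, n = aggRB$n,
                           R_minus_B_mean = aggRB$mean,
                           R_minus_B_sd = aggRB$sd,
                           h_pred_mean = aggH$mean, h_pred_sd = aggH$sd)

  thr <- detectFormationThreshold(perSample$conc_mM[ok],
                                  perSample$status[ok])

  new("AnalysisReport", alphaModel = alphaModel, calibration = calibration,
      perSample = perSample, aggregates = aggregates,
      formationThreshold = thr, measurements = measurements,
      skipped = skipped, config = config)
}

#' @rdname AnalysisReport-class
#' @export
setMethod("perSampleTable", "AnalysisReport",
          function(object) object@perSample)

#' @rdname AnalysisReport-class
#' @export
setMethod("formationThreshold", "AnalysisReport",
          function(object) object@formationThreshold)

#' @rdname AnalysisReport-class
#' @export
setMethod("alphaCoef", "AnalysisReport",
          function(object) object@alphaModel@alpha)

setMethod("show", "AnalysisReport", function(object) {
  cat("AnalysisReport\n")
  cat(sprintf("  alpha-hat: %.3f mM^-1 (n = %d measured)\n",
              object@alphaModel@alpha, object@alphaModel@n))
  cat(sprintf("  calibration: slope %.3f um/unit, intercept %.2f um, r2 %.3f\n",
              object@calibration@slope, object@calibration@intercept,
              object@calibration@rSquared))
  cat(sprintf("  samples: %d analysed, %d skipped\n",
              sum(is.finite(object@perSample$R_minus_B)),
              nrow(object@skipped)))
  if (is.na(object@formationThreshold)) {
    cat("  no formation threshold detected\n")
  } else {
    cat(sprintf("  formation threshold: %g mM (all replicates shell-absent)\n",
                object@formationThreshold))
  }
  invisible(NULL)
})

#' Write the analysis report to disk
#'
#' Writes \code{per_sample.csv}, \code{aggregates.csv},
#' \code{calibration.json}, a plain-text \code{summary.txt}, and two
#' diagnostic figures: the linearized thickness against concentration with
#' the through-origin fit, and measured thickness against R-B with the
#' calibration line (predictions for non-measured samples marked).
#'
#' @param report an [AnalysisReport-class].
#' @param outDir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeReport <- function(report, outDir) {
  stopifnot(is(report, "AnalysisReport"))
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    csStop(sprintf("cannot create output directory '%s'", outDir),
           "coreshell_io")
  paths <- file.path(outDir, c("per_sample.csv", "aggregates.csv",
                               "calibration.json", "summary.txt",
                               "fig_linearized_fit.png",
                               "fig_calibration.png"))
  utils::write.csv(report@perSample, paths[1], row.names = FALSE)
  utils::write.csv(report@aggregates, paths[2], row.names = FALSE)
  cal <- report@calibration
  jsonlite::write_json(list(schema_version = "1.0",
                            slope_um_per_intensity = cal@slope,
                            intercept_um = cal@intercept,
                            r_squared = cal@rSquared, n = cal@n),
                       paths[3], auto_unbox = TRUE, digits = NA)

  thrLine <- if (is.na(report@formationThreshold))
    "no formation threshold detected" else
    sprintf("formation threshold: %g mM (all replicates shell-absent)",
            report@formationThreshold)
  writeLines(c(
    "coreshell analysis summary",
    sprintf("alpha = %.3f mM^-1 (through-origin fit, n = %d)",
            report@alphaModel@alpha, report@alphaModel@n),
    sprintf("calibration: h = %.3f * (R-B) + %.2f um, r2 = %.3f, n = %d",
            cal@slope, cal@intercept, cal@rSquared, cal@n),
    sprintf("samples analysed: %d, skipped: %d",
            sum(is.finite(report@perSample$R_minus_B)),
            nrow(report@skipped)),
    thrLine), paths[4])

  ## figure: linearized thickness vs concentration with through-origin fit
  meas <- report@measurements
  meas <- meas[meas$measurable & meas$h_um > 0, , drop = FALSE]
  grDevices::png(paths[5], width = 600, height = 450)
  y <- linearizedResponse(meas$h_um, meas$R_c_um)
  graphics::plot(meas$conc_mM, y, pch = 16, col = "steelblue",
                 xlab = "[CaCl2] (mM)",
                 ylab = "(h/Rc + 1)^3 - 1",
                 main = "Linearized shell thickness")
  graphics::abline(0, report@alphaModel@alpha, col = "darkorange", lwd = 2)
  grDevices::dev.off()

  ## figure: thickness vs R-B with calibration line
  ps <- report@perSample
  grDevices::png(paths[6], width = 600, height = 450)
  mrg <- merge(ps[, c("sample_id", "R_minus_B")],
               report@measurements[, c("sample_id", "h_um")],
               by = "sample_id")
  graphics::plot(mrg$R_minus_B, mrg$h_um, pch = 16, col = "steelblue",
                 xlab = "R - B (intensity)", ylab = "shell thickness (um)",
                 main = "Colour-to-thickness calibration",
                 xlim = range(ps$R_minus_B, na.rm = TRUE))
  graphics::abline(cal@intercept, cal@slope, col = "darkorange", lwd = 2)
  nm <- is.na(mrg$h_um)
  graphics::points(ps$R_minus_B, ps$h_pred_um, pch = 4, col = "grey40")
  graphics::abline(h = 0, lty = 3)
  grDevices::dev.off()
  invisible(paths)
}
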