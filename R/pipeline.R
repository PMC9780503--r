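#' Run the full ROI enrichment pipeline over a fixture tree
#'
#' Reads every section referenced by a fixture `manifest.csv` (as written
#' by [makeStudyFixture()], or hand-built for real data with the same
#' columns `section_id`, `role`, `image_file`, `labels_file`,
#' `annotations_file`), computes per-ROI isotope statistics, fits the
#' control model on the sections with `role == "control"`, calls
#' enrichment on the labeled sections and writes the four result tables
#' (`roi_stats.csv`, `calls.csv`, `summary.csv`, `tally.csv`) to `outDir`.
#'
#' @param fixtureDir directory holding `manifest.csv` and section files.
#' @param outDir output directory, created if needed.
#' @param minPerComponent minimum control ROIs per component before the
#'   pooled fallback (default 5).
#' @param bound control bound: `"percentile"` or `"ci-of-mean"`.
#' @return invisibly, a list with `stats`, `controls`, `calls`, `summary`,
#'   `tally`.
#' @export
runEnrichmentPipeline <- function(fixtureDir, outDir,
                                  minPerComponent = 5,
                                  bound = c("percentile", "ci-of-mean")) {
  bound <- match.arg(bound)
  manPath <- file.path(fixtureDir, "manifest.csv")
  if (!file.exists(manPath))
    stop("no manifest.csv in ", fixtureDir, call. = FALSE)
  man <- utils::read.csv(manPath)
  secs <- unique(man[c("section_id", "role", "image_file", "labels_file",
                       "annotations_file")])
  if (!any(secs$role == "control"))
    stop("no control sections in manifest: enrichment calling requires unlabeled controls",
         call. = FALSE)
  if (!any(secs$role == "labeled"))
    stop("no labeled sections in manifest", call. = FALSE)
  statsBySec <- lapply(seq_len(nrow(secs)), function(i) {
    img <- readIonImage(file.path(fixtureDir, secs$image_file[i]))
    rois <- readRoiMasks(file.path(fixtureDir, secs$labels_file[i]),
                         file.path(fixtureDir, secs$annotations_file[i]))
    roiStats(img, rois)
  })
  allStats <- do.call(rbind, statsBySec)
  ctrlStats <- do.call(rbind, statsBySec[secs$role == "control"])
  labStats <- do.call(rbind, statsBySec[secs$role == "labeled"])
  controls <- fitControls(ctrlStats, minPerComponent = minPerComponent,
                          bound = bound)
  calls <- callEnrichment(labStats, controls)
  summary <- summarizeComponents(calls)
  tally <- tallyEnrichment(calls, by = c("component", "segment", "site"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeRoiStats(allStats, file.path(outDir, "roi_stats.csv"))
  writeEnrichmentCalls(calls, file.path(outDir, "calls.csv"))
  writeComponentSummary(summary, file.path(outDir, "summary.csv"))
  utils::write.csv(tally, file.path(outDir, "tally.csv"), row.names = FALSE)
  invisible(list(stats = allStats, controls = controls, calls = calls,
                 summary = summary, tally = tally))
}

#' Render greyscale and HSI rasters (and an optional line scan) for one
#' section
#'
#' @param imagePath two-plane ion-count TIFF (see [readIonImage()]).
#' @param outPrefix output path prefix; writes `<prefix>_grey.png`,
#'   `<prefix>_hsi.png` and, when `line` is given, `<prefix>_linescan.csv`.
#' @param ratioMin,ratioMax HSI scale endpoints (defaults 0.0037–0.01).
#' @param smoothWindow odd HSI smoothing window (default 3).
#' @param line optional polyline (`row`, `col` matrix) for a line scan.
#' @param lineWidth odd perpendicular width for the line scan.
#' @return invisibly, the vector of files written.
#' @export
renderSection <- function(imagePath, outPrefix, ratioMin = 0.0037,
                          ratioMax = 0.01, smoothWindow = 3, line = NULL,
                          lineWidth = 3) {
  img <- readIonImage(imagePath)
  files <- c(paste0(outPrefix, "_grey.png"), paste0(outPrefix, "_hsi.png"))
  writeRaster(renderGrey(img), files[1])
  writeRaster(renderHsi(img, ratioMin, ratioMax, smoothWindow), files[2])
  if (!is.null(line)) {
    scanFile <- paste0(outPrefix, "_linescan.csv")
    writeLineScan(extractLineScan(img, line, lineWidth), scanFile)
    files <- c(files, scanFile)
  }
  invisible(files)
}
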