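#' Per-ROI isotope statistics
#'
#' Aggregates ion counts over each ROI mask and converts the summed counts
#' to isotope statistics. Aggregation is ratio-of-summed-counts (the SIMS
#' accumulation convention), never a mean of per-pixel ratios: per-pixel
#' ratios are undefined at zero-count pixels and biased at low counts.
#'
#' ROIs whose summed major count is zero cannot yield a ratio; they are
#' returned with `evaluable = FALSE` (and a message) rather than dropped
#' silently, so downstream exclusions stay auditable. ROIs with zero minor
#' counts carry the conservative sigma bound from [poissonSigma()] and
#' `zero_minor_flag = TRUE`.
#'
#' @param image an [IonCountImage-class].
#' @param rois a [RoiSet-class] over the same raster.
#' @return data.frame, one row per ROI: `roi_id`, `component`, `section_id`,
#'   `segment`, `site`, `n_pixels`, `sum_minor`, `sum_major`, `ratio`,
#'   `atom_percent`, `sigma_atom_percent`, `zero_minor_flag`, `evaluable`.
#' @export
roiStats <- function(image, rois) {
  stopifnot(methods::is(image, "IonCountImage"), methods::is(rois, "RoiSet"))
  if (!identical(dim(image@minor), dim(rois@labels)))
    stop("ROI label image shape does not match the ion image", call. = FALSE)
  ann <- rois@annotations
  lab <- rois@labels
  idx <- lab > 0
  f <- factor(lab[idx], levels = ann$label)
  sumMinor <- as.integer(tapply(image@minor[idx], f, sum, default = 0L))
  sumMajor <- as.integer(tapply(image@major[idx], f, sum, default = 0L))
  nPix <- as.integer(table(f))
  evaluable <- sumMajor > 0
  out <- data.frame(roi_id = ann$roi_id, component = ann$component,
                    section_id = ann$section_id, segment = ann$segment,
                    site = ann$site, n_pixels = nPix,
                    sum_minor = sumMinor, sum_major = sumMajor,
                    ratio = NA_real_, atom_percent = NA_real_,
                    sigma_atom_percent = NA_real_,
                    zero_minor_flag = FALSE, evaluable = evaluable)
  if (any(evaluable)) {
    cs <- countStatistics(sumMinor[evaluable], sumMajor[evaluable])
    out$ratio[evaluable] <- cs$ratio
    out$atom_percent[evaluable] <- cs$atom_percent
    out$sigma_atom_percent[evaluable] <- cs$sigma_atom_percent
    out$zero_minor_flag[evaluable] <- cs$zero_minor_flag
  }
  if (any(!evaluable))
    message("ROI(s) non-evaluable (zero major counts), excluded downstream: ",
            paste(out$roi_id[!evaluable], collapse = ", "))
  out
}

#' Write a per-ROI statistics table
#'
#' Atom % columns are reported to two decimals, the ratio to six significant
#' digits; internal computation is full precision.
#'
#' @param stats data.frame from [roiStats()].
#' @param path output CSV path.
#' @export
writeRoiStats <- function(stats, path) {
  out <- stats
  out$ratio <- signif(out$ratio, 6)
  out$atom_percent <- round(out$atom_percent, 2)
  out$sigma_atom_percent <- signif(out$sigma_atom_percent, 4)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
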