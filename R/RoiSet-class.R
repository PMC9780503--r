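# Closed component vocabulary for bryosphere features
.COMPONENTS <- c("cyanobacterium", "moss_cell_wall", "moss_cytoplasm",
                 "bacterium", "fungal_hypha", "micro_alga", "eps",
                 "unidentified")

.SEGMENTS <- c("green", "brown")

#' RoiSet: labelled regions of interest over one raster section
#'
#' An ROI is a discrete group of pixels delineating one biological feature
#' (a cyanobacterial cell, a moss cell wall, a bacterium, ...). ROIs of a
#' section are stored as an integer label image (0 = background; label k =
#' pixels of ROI k), which structurally guarantees that ROIs never overlap,
#' plus an annotation table mapping each label to its identity.
#'
#' @slot labels integer matrix, same shape as the section's ion image.
#' @slot annotations data.frame with columns `label`, `roi_id`, `component`,
#'   `section_id`, `segment`, `site`; one row per nonzero label.
#' @export
setClass("RoiSet",
         representation(labels = "matrix", annotations = "data.frame"))

setValidity("RoiSet", function(object) {
  msg <- character()
  lab <- object@labels
  if (!is.numeric(lab) || any(lab < 0) || any(abs(lab - round(lab)) > 1e-9))
    msg <- c(msg, "label image must hold non-negative integers")
  need <- c("label", "roi_id", "component", "section_id", "segment", "site")
  if (!all(need %in% names(object@annotations)))
    msg <- c(msg, paste("annotations must have columns:",
                        paste(need, collapse = ", ")))
  else {
    ann <- object@annotations
    present <- sort(unique(lab[lab > 0]))
    unann <- setdiff(present, ann$label)
    if (length(unann))
      msg <- c(msg, paste("label(s) present in mask but not annotated:",
                          paste(unann, collapse = ", ")))
    if (anyDuplicated(ann$label))
      msg <- c(msg, "duplicated labels in annotation table")
    if (anyDuplicated(ann$roi_id))
      msg <- c(msg, "duplicated roi_id in annotation table")
    if (!all(ann$component %in% .COMPONENTS))
      msg <- c(msg, "unknown component name(s) in annotations")
    if (nrow(ann) == 0 || !any(lab > 0))
      msg <- c(msg, "RoiSet must contain at least one ROI pixel")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a RoiSet
#'
#' Annotated labels absent from the label image are dropped with a warning;
#' unannotated labels present in the image are an error. Component strings
#' outside the closed vocabulary map to `"unidentified"` with a warning.
#'
#' @param labels integer label matrix (0 = background).
#' @param annotations data.frame with columns `label`, `roi_id`,
#'   `component`, `section_id`, `segment`, `site`.
#' @return a [RoiSet-class].
#' @export
RoiSet <- function(labels, annotations) {
  mode(labels) <- "integer"
  annotations <- as.data.frame(annotations)
  bad <- !annotations$component %in% .COMPONENTS
  if (any(bad)) {
    warning("unknown component(s) mapped to 'unidentified': ",
            paste(unique(annotations$component[bad]), collapse = ", "),
            call. = FALSE)
    annotations$component[bad] <- "unidentified"
  }
  present <- unique(labels[labels > 0])
  orphan <- !annotations$label %in% present
  if (any(orphan)) {
    warning("annotated label(s) absent from label image, dropped: ",
            paste(annotations$label[orphan], collapse = ", "), call. = FALSE)
    annotations <- annotations[!orphan, , drop = FALSE]
  }
  methods::new("RoiSet", labels = labels, annotations = annotations)
}

#' @describeIn RoiSet-class number of ROIs
#' @param x a RoiSet
#' @export
nRoi <- function(x) nrow(x@annotations)

#' @describeIn RoiSet-class the annotation table
#' @export
roiAnnotations <- function(x) x@annotations

#' @describeIn RoiSet-class the integer label matrix
#' @export
roiLabels <- function(x) x@labels

#' @describeIn RoiSet-class logical pixel mask of one ROI
#' @param roiId a single `roi_id`
#' @export
roiMask <- function(x, roiId) {
  i <- match(roiId, x@annotations$roi_id)
  if (is.na(i)) stop("no such roi_id: ", roiId, call. = FALSE)
  x@labels == x@annotations$label[i]
}

#' @rdname RoiSet-class
#' @param object a RoiSet
#' @export
setMethod("show", "RoiSet", function(object) {
  ann <- object@annotations
  cat(sprintf("RoiSet: %d ROIs over a %d x %d label image\n",
              nrow(ann), nrow(object@labels), ncol(object@labels)))
  print(table(component = ann$component))
})

#' Write ROI masks and annotations
#'
#' Label image as a single-plane 16-bit TIFF (0 = background) plus the
#' annotation CSV with header `label,roi_id,component,section_id,segment,site`.
#'
#' @param rois a [RoiSet-class].
#' @param labelPath output label TIFF path.
#' @param annotationPath output annotation CSV path.
#' @return `labelPath`, invisibly.
#' @export
writeRoiMasks <- function(rois, labelPath, annotationPath) {
  stopifnot(methods::is(rois, "RoiSet"))
  if (max(rois@labels) > .TIFF_MAX)
    stop("label values exceed 16-bit TIFF range", call. = FALSE)
  tiff::writeTIFF(rois@labels / .TIFF_MAX, labelPath,
                  bits.per.sample = 16L, compression = "none")
  cols <- c("label", "roi_id", "component", "section_id", "segment", "site")
  utils::write.csv(rois@annotations[, cols], annotationPath,
                   row.names = FALSE)
  invisible(labelPath)
}

#' Read ROI masks from a label TIFF and annotation CSV
#'
#' @param labelPath single-plane integer label TIFF (0 = background).
#' @param annotationPath CSV with header
#'   `label,roi_id,component,section_id,segment,site`.
#' @return a [RoiSet-class]; unannotated labels in the image are an error,
#'   annotated labels missing from the image a warning.
#' @export
readRoiMasks <- function(labelPath, annotationPath) {
  for (p in c(labelPath, annotationPath))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  lab <- tiff::readTIFF(labelPath, as.is = TRUE)
  if (length(dim(lab)) != 2)
    stop("label image must be a single-plane raster: ", labelPath,
         call. = FALSE)
  if (any(abs(lab - round(lab)) > 1e-9))
    stop("label image holds non-integer values: ", labelPath, call. = FALSE)
  ann <- utils::read.csv(annotationPath,
                         colClasses = c(label = "integer",
                                        roi_id = "character",
                                        component = "character",
                                        section_id = "character",
                                        segment = "character",
                                        site = "character"))
  RoiSet(matrix(as.integer(round(lab)), nrow(lab), ncol(lab)), ann)
}
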