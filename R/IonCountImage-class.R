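#' IonCountImage: co-registered dual ion-count planes
#'
#' Holds the two co-registered integer count planes of a NanoSIMS raster —
#' the major species \eqn{^{12}C^{14}N^-} carrying structural contrast and
#' the minor species \eqn{^{12}C^{15}N^-} carrying the isotope signal —
#' plus free-form acquisition metadata (section id, site, segment, ...).
#'
#' @slot minor integer matrix of \eqn{^{12}C^{15}N^-} counts (rows x cols).
#' @slot major integer matrix of \eqn{^{12}C^{14}N^-} counts, same shape.
#' @slot metadata named list of free-form key-value metadata.
#' @export
setClass("IonCountImage",
         representation(minor = "matrix", major = "matrix",
                        metadata = "list"))

setValidity("IonCountImage", function(object) {
  msg <- character()
  if (!identical(dim(object@minor), dim(object@major)))
    msg <- c(msg, "minor and major planes must share the same shape")
  for (nm in c("minor", "major")) {
    pl <- slot(object, nm)
    if (!is.numeric(pl))
      msg <- c(msg, sprintf("%s plane must be numeric", nm))
    else {
      if (any(pl < 0)) msg <- c(msg, sprintf("%s plane has negative counts", nm))
      if (any(abs(pl - round(pl)) > 1e-9))
        msg <- c(msg, sprintf("%s plane has non-integer counts", nm))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an IonCountImage
#'
#' @param minor,major integer matrices of equal shape: minor
#'   (\eqn{^{12}C^{15}N^-}) and major (\eqn{^{12}C^{14}N^-}) counts.
#' @param metadata named list of acquisition metadata.
#' @return an [IonCountImage-class] object.
#' @examples
#' img <- IonCountImage(matrix(1L, 4, 4), matrix(269L, 4, 4))
#' @export
IonCountImage <- function(minor, major, metadata = list()) {
  mode(minor) <- "integer"; mode(major) <- "integer"
  methods::new("IonCountImage", minor = minor, major = major,
               metadata = metadata)
}

#' @describeIn IonCountImage-class minor-plane (\eqn{^{12}C^{15}N^-}) counts
#' @param x an IonCountImage
#' @export
minorCounts <- function(x) x@minor

#' @describeIn IonCountImage-class major-plane (\eqn{^{12}C^{14}N^-}) counts
#' @export
majorCounts <- function(x) x@major

#' @describeIn IonCountImage-class acquisition metadata list
#' @export
imageMetadata <- function(x) x@metadata

#' @rdname IonCountImage-class
#' @param object an IonCountImage
#' @export
setMethod("show", "IonCountImage", function(object) {
  d <- dim(object@minor)
  cat(sprintf("IonCountImage %d x %d px\n", d[1], d[2]))
  cat(sprintf("  12C14N (major): total %.4g counts\n", sum(object@major)))
  cat(sprintf("  12C15N (minor): total %.4g counts\n", sum(object@minor)))
  r <- sum(object@minor) / max(1, sum(object@major))
  cat(sprintf("  whole-image 15N/14N = %.5f (%.2f atom %%)\n",
              r, atomPercentFromRatio(r)))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata),
                             unlist(object@metadata, use.names = FALSE),
                             sep = "=", collapse = ", "), "\n")
})

#' @export
setMethod("dim", "IonCountImage", function(x) dim(x@minor))

# 16-bit storage ceiling for accumulated per-pixel counts in TIFF output
.TIFF_MAX <- 65535L

#' Write an ion-count image as a multi-plane TIFF
#'
#' Planes are written as 16-bit unsigned integers in a fixed, documented
#' order: plane 1 = major (\eqn{^{12}C^{14}N^-}), plane 2 = minor
#' (\eqn{^{12}C^{15}N^-}). A sidecar `<path>.meta.csv` records the plane
#' order and any metadata so the file round-trips losslessly.
#'
#' @param image an [IonCountImage-class].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
writeIonImage <- function(image, path) {
  stopifnot(methods::is(image, "IonCountImage"))
  if (max(image@minor, image@major) > .TIFF_MAX)
    stop("per-pixel counts exceed the 16-bit TIFF storage ceiling (65535)",
         call. = FALSE)
  tiff::writeTIFF(list(image@major / .TIFF_MAX, image@minor / .TIFF_MAX),
                  path, bits.per.sample = 16L, compression = "none")
  meta <- c(list(plane1 = "12C14N", plane2 = "12C15N"), image@metadata)
  utils::write.csv(data.frame(key = names(meta),
                              value = as.character(unlist(meta))),
                   paste0(path, ".meta.csv"), row.names = FALSE)
  invisible(path)
}

#' Read an ion-count image from a multi-plane TIFF
#'
#' Expects the two-plane layout written by [writeIonImage()]: plane 1 =
#' major \eqn{^{12}C^{14}N^-}, plane 2 = minor \eqn{^{12}C^{15}N^-}
#' (override with `planeOrder`). Pixel data must be integer counts;
#' float-typed TIFFs are rejected.
#'
#' @param path TIFF path.
#' @param planeOrder named integer vector giving the 1-based plane index of
#'   each species, e.g. `c(major = 1, minor = 2)`.
#' @return an [IonCountImage-class].
#' @export
readIonImage <- function(path, planeOrder = c(major = 1L, minor = 2L)) {
  if (!file.exists(path))
    stop("ion image not found: ", path, call. = FALSE)
  stopifnot(all(c("major", "minor") %in% names(planeOrder)))
  planes <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  need <- max(planeOrder)
  if (length(planes) < need)
    stop(sprintf("ion image %s has %d plane(s); plane %d (%s) missing",
                 path, length(planes), need,
                 names(planeOrder)[which.max(planeOrder)]), call. = FALSE)
  grab <- function(which) {
    pl <- planes[[planeOrder[[which]]]]
    bps <- attr(pl, "bits.per.sample")
    if (!is.null(bps) && bps > 16)
      stop(sprintf("plane %s of %s holds non-integer (float-typed) pixel data",
                   which, path), call. = FALSE)
    if (length(dim(pl)) != 2)
      stop(sprintf("plane %s of %s is not a single-channel raster",
                   which, path), call. = FALSE)
    if (any(abs(pl - round(pl)) > 1e-9))
      stop(sprintf("plane %s of %s holds non-integer pixel data",
                   which, path), call. = FALSE)
    if (any(pl < 0))
      stop(sprintf("plane %s of %s holds negative counts", which, path),
           call. = FALSE)
    matrix(as.integer(round(pl)), nrow(pl), ncol(pl))
  }
  major <- grab("major")
  minor <- grab("minor")
  if (!identical(dim(major), dim(minor)))
    stop("plane shape mismatch in ", path, call. = FALSE)
  meta <- list()
  metaPath <- paste0(path, ".meta.csv")
  if (file.exists(metaPath)) {
    tab <- utils::read.csv(metaPath, colClasses = "character")
    keep <- !tab$key %in% c("plane1", "plane2")
    meta <- as.list(stats::setNames(tab$value[keep], tab$key[keep]))
  }
  IonCountImage(minor, major, meta)
}
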