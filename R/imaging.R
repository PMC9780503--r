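# Summed-area-table box filter; window clipped at image borders so both
# count planes truncate identically and ratios stay unbiased at the edge.
.boxSum <- function(m, window) {
  if (window == 1) return(m)
  h <- (window - 1) %/% 2
  nr <- nrow(m); nc <- ncol(m)
  sat <- apply(apply(m, 2, cumsum), 1, cumsum)   # transposed SAT
  sat <- t(sat)
  pad <- matrix(0, nr + 1, nc + 1)
  pad[-1, -1] <- sat
  r1 <- pmax(seq_len(nr) - h, 1); r2 <- pmin(seq_len(nr) + h, nr)
  c1 <- pmax(seq_len(nc) - h, 1); c2 <- pmin(seq_len(nc) + h, nc)
  out <- pad[r2 + 1, c2 + 1, drop = FALSE] -
    pad[r1, c2 + 1, drop = FALSE] -
    pad[r2 + 1, c1, drop = FALSE] +
    pad[r1, c1, drop = FALSE]
  out
}

#' Greyscale structure image from the major ion plane
#'
#' The \eqn{^{12}C^{14}N^-} plane carries cellular structure contrast.
#' Counts are stretched between their 1st and 99th percentiles and mapped
#' linearly to the 0–255 grey range, clipping outside; a constant plane
#' renders uniform mid-grey.
#'
#' @param image an [IonCountImage-class].
#' @return integer matrix in 0–255, same shape as the image.
#' @export
renderGrey <- function(image) {
  stopifnot(methods::is(image, "IonCountImage"))
  m <- image@major
  q <- stats::quantile(m, c(0.01, 0.99), type = 7, names = FALSE)
  if (q[2] <= q[1]) {
    message("constant major plane: rendering uniform mid-grey")
    return(matrix(128L, nrow(m), ncol(m)))
  }
  g <- (m - q[1]) / (q[2] - q[1])
  matrix(as.integer(round(255 * pmin(1, pmax(0, g)))), nrow(m), ncol(m))
}

#' HSI ratio image
#'
#' Renders the per-pixel \eqn{^{15}N/^{14}N} ratio as hue between fixed
#' scale endpoints: ratios at or below `ratioMin` (default 0.0037, natural
#' abundance) render at the blue end (hue 240°), ratios at or above
#' `ratioMax` (default 0.01) at the red end (hue 0°), linearly in between,
#' at full saturation and value. To avoid zero-count speckle, counts are
#' summed over a `smoothWindow` x `smoothWindow` box (default 3; 1 disables
#' smoothing) before the ratio is formed. Pixels whose window-summed major
#' count is zero are non-evaluable and render black.
#'
#' The mapping depends on counts only through per-pixel ratios, so any
#' count rescaling that preserves ratios leaves the rendering unchanged.
#'
#' @param image an [IonCountImage-class].
#' @param ratioMin,ratioMax scale endpoints (require `ratioMin < ratioMax`).
#' @param smoothWindow odd window size >= 1, smaller than the image.
#' @return numeric array `nrow x ncol x 3` of RGB in `[0, 1]`.
#' @export
renderHsi <- function(image, ratioMin = 0.0037, ratioMax = 0.01,
                      smoothWindow = 3) {
  stopifnot(methods::is(image, "IonCountImage"),
            ratioMin < ratioMax,
            smoothWindow >= 1, smoothWindow %% 2 == 1)
  if (smoothWindow > min(dim(image@minor)))
    stop("smoothing window larger than the image", call. = FALSE)
  minorS <- .boxSum(image@minor, smoothWindow)
  majorS <- .boxSum(image@major, smoothWindow)
  ok <- majorS > 0
  t <- matrix(0, nrow(minorS), ncol(minorS))
  t[ok] <- (minorS[ok] / majorS[ok] - ratioMin) / (ratioMax - ratioMin)
  t <- pmin(1, pmax(0, t))
  hue <- (240 / 360) * (1 - t)            # blue 240 deg -> red 0 deg
  col <- grDevices::hsv(h = hue, s = 1, v = 1)
  rgb <- grDevices::col2rgb(col) / 255
  out <- array(0, c(nrow(minorS), ncol(minorS), 3))
  for (k in 1:3) {
    plane <- matrix(rgb[k, ], nrow(minorS), ncol(minorS))
    plane[!ok] <- 0                        # non-evaluable pixels: black
    out[, , k] <- plane
  }
  out
}

#' Write a rendered raster as PNG
#'
#' @param raster a 0–255 integer matrix from [renderGrey()] (written as
#'   8-bit grey) or an RGB array from [renderHsi()] (24-bit colour).
#' @param path output PNG path.
#' @export
writeRaster <- function(raster, path) {
  if (is.matrix(raster)) raster <- raster / 255
  png::writePNG(raster, path)
  invisible(path)
}

#' Extract a line scan of isotope enrichment
#'
#' Resamples a polyline path at unit-pixel arc-length steps; at each step
#' counts are summed over `width` pixels perpendicular to the local path
#' direction, then converted to ratio and atom % \eqn{^{15}N}. Samples
#' whose summed major count is zero are marked non-evaluable (`NA` ratio).
#'
#' Coordinates are 0-based `(row, col)` pixel centres. Perpendicular
#' offsets falling outside the image are dropped, not clamped, so no pixel
#' is counted twice.
#'
#' @param image an [IonCountImage-class].
#' @param path numeric matrix or data.frame of polyline vertices with
#'   columns `row`, `col` (0-based); at least two distinct vertices.
#' @param width odd perpendicular width in pixels, >= 1.
#' @return data.frame: `position_px` (arc length), `row`, `col` (sample
#'   centre), `sum_minor`, `sum_major`, `ratio`, `atom_percent`,
#'   `evaluable`.
#' @export
extractLineScan <- function(image, path, width = 1) {
  stopifnot(methods::is(image, "IonCountImage"),
            width >= 1, width %% 2 == 1)
  path <- as.matrix(path)
  if (!is.null(colnames(path)) && all(c("row", "col") %in% colnames(path)))
    path <- path[, c("row", "col"), drop = FALSE]
  stopifnot(ncol(path) == 2)
  if (nrow(path) < 2 || all(duplicated(path)[-1]))
    stop("line-scan path must contain at least two distinct vertices",
         call. = FALSE)
  nr <- nrow(image@minor); nc <- ncol(image@minor)
  if (any(path[, 1] < 0 | path[, 1] > nr - 1 |
          path[, 2] < 0 | path[, 2] > nc - 1))
    stop("line-scan path leaves the image", call. = FALSE)
  seg <- diff(path)
  segLen <- sqrt(rowSums(seg^2))
  keep <- segLen > 0
  seg <- seg[keep, , drop = FALSE]; segLen <- segLen[keep]
  starts <- path[-nrow(path), , drop = FALSE][keep, , drop = FALSE]
  cumLen <- c(0, cumsum(segLen))
  total <- sum(segLen)
  s <- seq(0, total, by = 1)
  half <- (width - 1) %/% 2
  offs <- seq(-half, half)
  rows <- lapply(s, function(si) {
    i <- max(which(cumLen <= si + 1e-12))
    i <- min(i, length(segLen))
    frac <- (si - cumLen[i]) / segLen[i]
    pt <- starts[i, ] + frac * seg[i, ]
    tang <- seg[i, ] / segLen[i]
    perp <- c(-tang[2], tang[1])
    px <- round(pt[1] + offs * perp[1])
    py <- round(pt[2] + offs * perp[2])
    inb <- px >= 0 & px <= nr - 1 & py >= 0 & py <= nc - 1
    coord <- unique(cbind(px[inb], py[inb]))
    idx <- coord[, 1] + 1 + (coord[, 2]) * nr
    data.frame(position_px = si, row = pt[1], col = pt[2],
               sum_minor = sum(image@minor[idx]),
               sum_major = sum(image@major[idx]))
  })
  out <- do.call(rbind, rows)
  out$evaluable <- out$sum_major > 0
  out$ratio <- ifelse(out$evaluable, out$sum_minor / out$sum_major, NA_real_)
  out$atom_percent <- NA_real_
  out$atom_percent[out$evaluable] <-
    atomPercentFromRatio(out$ratio[out$evaluable])
  out[c("position_px", "row", "col", "sum_minor", "sum_major",
        "ratio", "atom_percent", "evaluable")]
}

#' Write a line scan table
#'
#' @param scan data.frame from [extractLineScan()].
#' @param path output CSV path.
#' @export
writeLineScan <- function(scan, path) {
  out <- scan[c("position_px", "ratio", "atom_percent", "evaluable")]
  out$ratio <- signif(out$ratio, 6)
  out$atom_percent <- round(out$atom_percent, 4)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
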