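#' Isotope ratio from an ion-count pair
#'
#' Computes the minor/major isotope ratio (here \eqn{^{15}N/^{14}N}, measured
#' as the \eqn{^{12}C^{15}N^-} over \eqn{^{12}C^{14}N^-} secondary-ion count
#' ratio) from raw accumulated detector counts.
#'
#' @param nMinor non-negative integer vector of minor-species counts
#'   (\eqn{^{12}C^{15}N^-}).
#' @param nMajor positive integer vector of major-species counts
#'   (\eqn{^{12}C^{14}N^-}).
#' @return numeric vector, `nMinor / nMajor`.
#' @examples
#' ratioFromCounts(37, 10000)   # natural abundance, 0.0037
#' @export
ratioFromCounts <- function(nMinor, nMajor) {
  .checkCounts(nMinor, nMajor)
  if (any(nMajor == 0))
    stop("isotope ratio undefined: major-species count is zero", call. = FALSE)
  nMinor / nMajor
}

#' Convert an isotope ratio to atom percent
#'
#' Atom % \eqn{^{15}N = 100 R / (1 + R)} for ratio \eqn{R = ^{15}N/^{14}N}:
#' the percentage of nitrogen atoms that are \eqn{^{15}N}. The natural
#' abundance ratio 0.0037 corresponds to 0.37 atom %.
#'
#' @param ratio non-negative numeric vector of isotope ratios.
#' @return atom percent in `[0, 100)`.
#' @examples
#' atomPercentFromRatio(0.0037)  # ~0.37, natural abundance
#' atomPercentFromRatio(1)       # 50
#' @export
atomPercentFromRatio <- function(ratio) {
  stopifnot(is.numeric(ratio))
  if (any(ratio < 0, na.rm = TRUE))
    stop("isotope ratio must be non-negative", call. = FALSE)
  100 * ratio / (1 + ratio)
}

#' Convert atom percent to an isotope ratio
#'
#' Exact inverse of [atomPercentFromRatio()]:
#' \eqn{R = (p/100) / (1 - p/100)}.
#'
#' @param atomPercent numeric vector in `[0, 100)`.
#' @return non-negative isotope ratio.
#' @examples
#' ratioFromAtomPercent(50)    # 1
#' ratioFromAtomPercent(0.37)  # ~0.003714
#' @export
ratioFromAtomPercent <- function(atomPercent) {
  stopifnot(is.numeric(atomPercent))
  if (any(atomPercent < 0 | atomPercent >= 100, na.rm = TRUE))
    stop("atom percent must lie in [0, 100)", call. = FALSE)
  p <- atomPercent / 100
  p / (1 - p)
}

#' Poisson counting error of an isotope ratio
#'
#' First-order (delta-method) standard deviation of the count ratio under
#' independent Poisson counting in both species:
#' \deqn{\sigma_R = R \sqrt{1/N_{minor} + 1/N_{major}}}
#' propagated to atom percent as
#' \eqn{\sigma_{at\%} = 100\,\sigma_R / (1+R)^2}.
#'
#' When the minor count is zero the ratio (hence the formula) collapses to
#' zero, which would understate the uncertainty; in that case the sigma is
#' computed as if one minor count had been observed — a conservative upper
#' bound — and flagged in `zeroMinorFlag`.
#'
#' @param nMinor non-negative integer vector of minor-species counts.
#' @param nMajor positive integer vector of major-species counts.
#' @return a data.frame with columns `sigma_ratio`, `sigma_atom_percent`,
#'   `zero_minor_flag`.
#' @examples
#' poissonSigma(100, 10000)  # sigma_ratio ~1.005e-3
#' poissonSigma(0, 10000)    # conservative bound, flagged
#' @export
poissonSigma <- function(nMinor, nMajor) {
  .checkCounts(nMinor, nMajor)
  if (any(nMajor == 0))
    stop("counting error undefined: major-species count is zero",
         call. = FALSE)
  zero <- nMinor == 0
  nEff <- ifelse(zero, 1, nMinor)
  r <- nMinor / nMajor
  rEff <- nEff / nMajor
  sigmaRatio <- rEff * sqrt(1 / nEff + 1 / nMajor)
  sigmaAtom <- 100 * sigmaRatio / (1 + r)^2
  data.frame(sigma_ratio = sigmaRatio, sigma_atom_percent = sigmaAtom,
             zero_minor_flag = zero)
}

#' Full isotope statistics for count pairs
#'
#' Vectorised convenience combining [ratioFromCounts()],
#' [atomPercentFromRatio()] and [poissonSigma()] into the per-measurement
#' record used throughout the ROI pipeline.
#'
#' @inheritParams poissonSigma
#' @return data.frame with columns `ratio`, `atom_percent`, `sigma_ratio`,
#'   `sigma_atom_percent`, `total_counts`, `zero_minor_flag`.
#' @export
countStatistics <- function(nMinor, nMajor) {
  r <- ratioFromCounts(nMinor, nMajor)
  s <- poissonSigma(nMinor, nMajor)
  data.frame(ratio = r,
             atom_percent = atomPercentFromRatio(r),
             sigma_ratio = s$sigma_ratio,
             sigma_atom_percent = s$sigma_atom_percent,
             total_counts = nMinor + nMajor,
             zero_minor_flag = s$zero_minor_flag)
}

.checkCounts <- function(nMinor, nMajor) {
  stopifnot(is.numeric(nMinor), is.numeric(nMajor))
  if (length(nMinor) != length(nMajor))
    stop("count vectors must have equal length", call. = FALSE)
  if (any(nMinor < 0) || any(nMajor < 0))
    stop("ion counts must be non-negative", call. = FALSE)
  bad <- abs(nMinor - round(nMinor)) > 1e-9 | abs(nMajor - round(nMajor)) > 1e-9
  if (any(bad))
    stop("ion counts must be integer-valued", call. = FALSE)
  invisible(TRUE)
}

#' Natural abundance 15N/14N reference
#'
#' The unlabeled baseline used throughout: ratio 0.0037, i.e. ~0.37 atom %.
#' @format A named list with elements `ratio` and `atom_percent`.
#' @export
naturalAbundance <- list(ratio = 0.0037,
                         atom_percent = 100 * 0.0037 / 1.0037)
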