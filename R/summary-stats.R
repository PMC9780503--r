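#' Per-component distribution summaries of atom % 15N
#'
#' Reproduces the box-and-whisker statistics used to present single-cell
#' \eqn{^{15}N} accumulation: per component (within segment and site), the
#' median and 25–75 % box and 5–95 % whisker quantiles of atom %
#' \eqn{^{15}N}, over the significantly enriched ROIs only by default —
#' matching how the study presents "active" cells. Set
#' `enrichedOnly = FALSE` for diagnostic all-ROI summaries.
#'
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile` type 7); ties are kept. Groups with no enriched ROI
#' get `n_enriched = 0` and `NA` quantiles.
#'
#' @param calls data.frame from [callEnrichment()].
#' @param enrichedOnly summarise only enriched ROIs (default `TRUE`).
#' @param by grouping columns (default component within segment and site).
#' @return data.frame: grouping columns, `n_rois`, `n_enriched`,
#'   `percent_enriched`, `median`, `q25`, `q75`, `p5`, `p95`, `min`, `max`,
#'   `control_reference` (natural-abundance atom %).
#' @export
summarizeComponents <- function(calls, enrichedOnly = TRUE,
                                by = c("component", "segment", "site")) {
  stopifnot(nrow(calls) > 0, all(by %in% names(calls)))
  key <- interaction(calls[by], drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(calls, key), function(g) {
    sel <- if (enrichedOnly) g$atom_percent[g$enriched] else g$atom_percent
    q <- if (length(sel))
      stats::quantile(sel, c(0.05, 0.25, 0.5, 0.75, 0.95), type = 7,
                      names = FALSE)
    else rep(NA_real_, 5)
    cbind(g[1, by, drop = FALSE],
          data.frame(n_rois = nrow(g), n_enriched = sum(g$enriched),
                     percent_enriched = round(100 * mean(g$enriched)),
                     median = q[3], q25 = q[2], q75 = q[4],
                     p5 = q[1], p95 = q[5],
                     min = if (length(sel)) min(sel) else NA_real_,
                     max = if (length(sel)) max(sel) else NA_real_,
                     control_reference = naturalAbundance$atom_percent))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a component summary table
#'
#' Medians and quantiles to two decimals, tallies to integer percent.
#'
#' @param summary data.frame from [summarizeComponents()].
#' @param path output CSV path.
#' @export
writeComponentSummary <- function(summary, path) {
  out <- summary
  for (cl in c("median", "q25", "q75", "p5", "p95", "min", "max",
               "control_reference"))
    out[[cl]] <- round(out[[cl]], 2)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Relative abundance shares from read counts
#'
#' Converts a count table (e.g. amplicon reads per taxon or cluster) to
#' percent shares of the total, at the mixed 1–2 decimal precision used in
#' printed proportion statements.
#'
#' @param counts non-negative numeric vector of counts (optionally named).
#' @param total denominator; defaults to `sum(counts)`. Must be positive.
#' @param digits rounding of the share, 1 or 2 decimals.
#' @return data.frame with `label`, `count`, `share_percent`.
#' @examples
#' relativeAbundance(c(alpha = 18), total = 17768, digits = 1)  # 0.1 %
#' @export
relativeAbundance <- function(counts, total = sum(counts), digits = 2) {
  stopifnot(is.numeric(counts), all(counts >= 0), digits %in% 1:2)
  if (total <= 0) stop("total count must be positive", call. = FALSE)
  data.frame(label = if (is.null(names(counts)))
    as.character(seq_along(counts)) else names(counts),
    count = as.numeric(counts),
    share_percent = round(100 * counts / total, digits),
    row.names = NULL)
}

#' Complement of printed percentage shares
#'
#' Given a total share and the shares of explicitly listed parts, returns
#' the remainder attributed to the unlisted part — the arithmetic behind
#' statements such as a dominant cluster holding whatever share the minor
#' clusters leave of the group total.
#'
#' @param totalShare total percent share of the group.
#' @param parts numeric vector of the listed parts' percent shares.
#' @return `totalShare - sum(parts)`; negative remainders are an error.
#' @examples
#' complementShare(99.90, c(0.60, 0.15))  # 99.15
#' @export
complementShare <- function(totalShare, parts = numeric()) {
  rem <- totalShare - sum(parts)
  if (rem < -1e-9)
    stop("parts exceed the total share", call. = FALSE)
  rem
}
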