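#' ControlModel: per-component unlabeled-control distributions
#'
#' Holds the atom % \eqn{^{15}N} distribution of unlabeled control ROIs for
#' each bryosphere component, and the per-component upper reference bound
#' that labeled ROIs must exceed to be called enriched. Components with too
#' few control ROIs fall back to the pooled all-component distribution
#' (flagged), so no bound is ever computed from a handful of values.
#'
#' @slot summary data.frame: `component`, `n`, `mean_atom_percent`,
#'   `upper95`, `pooled_flag`.
#' @slot values named list of the control atom % vectors per component
#'   (plus `.pooled`).
#' @slot bound `"percentile"` (95th percentile of control ROI values,
#'   default) or `"ci-of-mean"` (mean + 1.645 SD/sqrt(n)).
#' @slot minPerComponent minimum control ROIs for a component-specific bound.
#' @export
setClass("ControlModel",
         representation(summary = "data.frame", values = "list",
                        bound = "character", minPerComponent = "numeric"))

setValidity("ControlModel", function(object) {
  msg <- character()
  s <- object@summary
  if (!all(c("component", "n", "mean_atom_percent", "upper95",
             "pooled_flag") %in% names(s)))
    msg <- c(msg, "malformed control summary table")
  if (!object@bound %in% c("percentile", "ci-of-mean"))
    msg <- c(msg, "bound must be 'percentile' or 'ci-of-mean'")
  if (!".pooled" %in% names(object@values))
    msg <- c(msg, "pooled control distribution missing")
  if (length(msg)) msg else TRUE
})

#' @rdname ControlModel-class
#' @param object a ControlModel
#' @export
setMethod("show", "ControlModel", function(object) {
  cat(sprintf("ControlModel (%s bound, min %d controls/component)\n",
              object@bound, as.integer(object@minPerComponent)))
  print(object@summary, row.names = FALSE)
})

.controlBound <- function(values, bound) {
  if (bound == "percentile")
    unname(stats::quantile(values, 0.95, type = 7, names = FALSE))
  else
    mean(values) + 1.645 * stats::sd(values) / sqrt(length(values))
}

#' Fit per-component control distributions from unlabeled ROIs
#'
#' Builds the unlabeled reference for enrichment calling. For each
#' component with at least `minPerComponent` evaluable control ROIs, the
#' reference is that component's own atom % distribution; components below
#' the threshold receive the pooled all-component distribution with
#' `pooled_flag = TRUE`. The upper bound is the 95th percentile of control
#' values computed by linear interpolation between order statistics
#' (`bound = "percentile"`, default) or the normal-theory
#' mean + 1.645 SD/sqrt(n) (`bound = "ci-of-mean"`).
#'
#' @param controlStats data.frame from [roiStats()] on unlabeled sections.
#' @param minPerComponent minimum evaluable control ROIs per component
#'   before the pooled fallback applies (default 5).
#' @param bound `"percentile"` or `"ci-of-mean"`.
#' @return a [ControlModel-class]. Calling without any evaluable control is
#'   an error: enrichment may never be called without controls.
#' @export
fitControls <- function(controlStats, minPerComponent = 5,
                        bound = c("percentile", "ci-of-mean")) {
  bound <- match.arg(bound)
  ok <- controlStats[controlStats$evaluable, , drop = FALSE]
  if (nrow(ok) == 0)
    stop("no evaluable control ROIs: cannot fit control distributions",
         call. = FALSE)
  pooled <- ok$atom_percent
  vals <- split(ok$atom_percent, ok$component)
  comps <- names(vals)
  rows <- lapply(comps, function(cp) {
    v <- vals[[cp]]
    if (length(v) >= minPerComponent)
      data.frame(component = cp, n = length(v), mean_atom_percent = mean(v),
                 upper95 = .controlBound(v, bound), pooled_flag = FALSE)
    else
      data.frame(component = cp, n = length(pooled),
                 mean_atom_percent = mean(pooled),
                 upper95 = .controlBound(pooled, bound), pooled_flag = TRUE)
  })
  summary <- do.call(rbind, rows)
  pooledRow <- any(summary$pooled_flag)
  if (pooledRow)
    message("pooled control fallback used for: ",
            paste(summary$component[summary$pooled_flag], collapse = ", "))
  vals$.pooled <- pooled
  methods::new("ControlModel", summary = summary, values = vals,
               bound = bound, minPerComponent = minPerComponent)
}

#' @describeIn ControlModel-class reference row for one component; unseen
#'   components get the pooled distribution (flagged).
#' @param x a ControlModel
#' @param component component name
#' @export
controlReference <- function(x, component) {
  i <- match(component, x@summary$component)
  if (!is.na(i)) return(x@summary[i, , drop = FALSE])
  pooled <- x@values$.pooled
  data.frame(component = component, n = length(pooled),
             mean_atom_percent = mean(pooled),
             upper95 = .controlBound(pooled, x@bound), pooled_flag = TRUE)
}

#' Call 15N enrichment per ROI against the control model
#'
#' Applies the dual significance criterion: an ROI is significantly
#' enriched when (a) its atom % \eqn{^{15}N} exceeds the 95th-percentile
#' bound of the unlabeled control ROIs of its component, and (b) its
#' Poisson measurement error at 2 sigma is smaller than the difference
#' between its atom % and the control mean. Both criteria use strict
#' inequalities and are stored separately; `enriched` is their conjunction.
#' No multiple-testing correction is applied across ROIs — the criterion is
#' per-ROI by design.
#'
#' Non-evaluable ROIs (zero major counts) are excluded with a message.
#' Zero-minor ROIs are evaluated with their conservative sigma bound.
#'
#' @param labeledStats data.frame from [roiStats()] on labeled sections.
#' @param controls a [ControlModel-class] from [fitControls()].
#' @return data.frame, one row per evaluable ROI: identity columns plus
#'   `atom_percent`, `two_sigma`, `control_mean`, `control_upper95`,
#'   `delta`, `criterion_a`, `criterion_b`, `enriched`, `pooled_controls`.
#' @export
callEnrichment <- function(labeledStats, controls) {
  stopifnot(methods::is(controls, "ControlModel"))
  drop <- !labeledStats$evaluable
  if (any(drop))
    message("excluding non-evaluable ROI(s) from enrichment calling: ",
            paste(labeledStats$roi_id[drop], collapse = ", "))
  st <- labeledStats[!drop, , drop = FALSE]
  if (nrow(st) == 0)
    stop("no evaluable labeled ROIs to call", call. = FALSE)
  ref <- do.call(rbind, lapply(st$component,
                               function(cp) controlReference(controls, cp)))
  twoSigma <- 2 * st$sigma_atom_percent
  delta <- st$atom_percent - ref$mean_atom_percent
  critA <- st$atom_percent > ref$upper95
  critB <- twoSigma < delta
  data.frame(roi_id = st$roi_id, component = st$component,
             section_id = st$section_id, segment = st$segment,
             site = st$site, atom_percent = st$atom_percent,
             two_sigma = twoSigma, control_mean = ref$mean_atom_percent,
             control_upper95 = ref$upper95, delta = delta,
             criterion_a = critA, criterion_b = critB,
             enriched = critA & critB, pooled_controls = ref$pooled_flag)
}

#' Tally enriched ROIs by group
#'
#' Counts enriched ROIs within each group (component, segment, site, or any
#' combination), reporting the share to the nearest integer percent — the
#' precision of the study-level "% of ROIs enriched" figures.
#'
#' @param calls data.frame from [callEnrichment()].
#' @param by character vector of grouping columns (default `"component"`).
#' @return data.frame: grouping columns, `n_total`, `n_enriched`,
#'   `percent_enriched` (integer percent).
#' @export
tallyEnrichment <- function(calls, by = "component") {
  stopifnot(nrow(calls) > 0, all(by %in% names(calls)))
  key <- interaction(calls[by], drop = TRUE, lex.order = TRUE)
  groups <- split(calls, key)
  rows <- lapply(groups, function(g) {
    cbind(g[1, by, drop = FALSE],
          data.frame(n_total = nrow(g), n_enriched = sum(g$enriched),
                     percent_enriched = round(100 * mean(g$enriched))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an enrichment calls table
#'
#' @param calls data.frame from [callEnrichment()].
#' @param path output CSV path.
#' @export
writeEnrichmentCalls <- function(calls, path) {
  out <- calls
  for (cl in c("atom_percent", "control_mean", "control_upper95"))
    out[[cl]] <- round(out[[cl]], 2)
  out$two_sigma <- signif(out$two_sigma, 4)
  out$delta <- NULL
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
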