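---
title: "Quantifying single-cell 15N enrichment from NanoSIMS ion counts"
author: "nanosip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single-cell 15N enrichment from NanoSIMS ion counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanosip)
```

## The measurement model

NanoSIMS counts two secondary ion species per raster pixel:
¹²C¹⁴N⁻ (the major species, tracking total nitrogen and hence cellular
structure) and ¹²C¹⁵N⁻ (the minor species, tracking the ¹⁵N tracer). Both
are discrete detection processes, and the package models them as
independent Poisson counts per pixel per species. Everything downstream
follows from three identities:

* ratio: $R = N_{15}/N_{14}$, the ¹⁵N/¹⁴N isotope ratio;
* atom percent: $p = 100R/(1+R)$, the share of N atoms that are ¹⁵N,
  bounded in $[0, 100)$ and strictly increasing in $R$;
* counting error: $\sigma_R = R\sqrt{1/N_{15} + 1/N_{14}}$, the
  first-order standard deviation of a ratio of independent Poisson
  variables, propagated to atom % by the delta method,
  $\sigma_p = 100\,\sigma_R/(1+R)^2$.

The unlabeled baseline is the natural abundance ratio 0.0037
(≈ 0.37 atom %); enrichment is always judged relative to it.

ROI statistics aggregate by **ratio of summed counts** over the pixel
mask. The alternative — averaging per-pixel ratios — is undefined wherever
a pixel has zero major counts and biased at low counts, while summed
counts are the sufficient statistic under the Poisson model and standard
SIMS practice. A test asserts the equivalent identity that the ratio of
sums is the major-count-weighted mean of per-pixel ratios.

**Zero minor counts.** When an ROI accumulates no minor counts at all,
$R = 0$ and the error formula collapses to $\sigma = 0$, which would
absurdly make an undetectable ROI maximally precise. The package instead
computes the error as if one minor count had been observed
($\sigma_R = (1/N_{14})\sqrt{1 + 1/N_{14}}$), flags the result
(`zero_minor_flag`), and lets the caller treat it as a conservative upper
bound. ROIs with zero *major* counts yield no ratio at all; they are
marked non-evaluable and excluded downstream with a logged reason.

The analysis operates on total accumulated counts per ROI; no
detector-level corrections (dead time, QSA, drift) are modelled, so input
counts are assumed to be whatever the acquisition software exported.

## The enrichment call

An ROI from a labeled sample is called significantly enriched when both:

* **(a)** its atom % ¹⁵N lies above the 95th-percentile bound of the
  unlabeled control ROIs of its own biological component, and
* **(b)** its measurement error at $2\sigma$ is smaller than the
  difference between its atom % and the mean of those controls.

Both criteria use strict inequalities and are stored separately in the
calls table, so the conjunction is auditable. Criterion (a) guards
against the between-ROI biological spread of the unlabeled population;
criterion (b) guards against calling an ROI whose excess over the control
mean is within its own counting noise. The error in (b) is the labeled
ROI's own $\sigma$; control uncertainty is not folded in, which keeps the
criterion interpretable per ROI and matches the conventional reading of
the rule. No multiple-testing correction is applied across ROIs — the
output is a per-ROI decision record, and study-level shares ("x % of
bacteria enriched") are descriptive tallies of those records.

**The control bound.** "The 95th percent confidence interval of unlabeled
control ROIs" admits two readings. The default implements the 95th
percentile of the control ROI atom % distribution per component — the
phrase attaches to the ROI population, not to its mean, and the per-ROI
biological spread is the relevant null. The normal-theory alternative,
mean $+ 1.645\,\mathrm{SD}/\sqrt{n}$, is implemented as
`bound = "ci-of-mean"` for users who prefer the other reading; it yields
a much tighter bound and correspondingly more liberal calls.

Percentiles use linear interpolation between closest order statistics
(`stats::quantile` type 7), fixed so results are bit-reproducible, and
verified in the tests against a hand-written sort-and-interpolate oracle.

**Pooled fallback.** A component with fewer than `minPerComponent`
(default 5) evaluable control ROIs takes the pooled all-component control
distribution, with `pooled_flag = TRUE` recorded in the model and
propagated into every call that used it. The default of 5 is the smallest
n at which a 95th percentile is more than the sample maximum plus
interpolation; users with generous control sets should raise it.

**Display threshold vs statistical call.** Rendering and reporting use a
separate, global highlight cut at > 0.37 atom % ¹⁵N (the natural-abundance
level at two decimals). This display convention is deliberately kept apart
from the statistical call above.

## Summaries

Per-component box-plot statistics (median, 25–75 % box, 5–95 % whiskers)
are computed **over enriched ROIs only** by default, mirroring how active
cells are conventionally presented; `enrichedOnly = FALSE` exposes all-ROI
summaries for diagnostics, and both min–max and quantiles are reported so
"range" statements can be checked under either convention. Tabular
precision follows field convention: atom % to two decimals, tallies to
integer percent, abundance shares to a configurable 1–2 decimals.
`relativeAbundance()` and `complementShare()` cover the printed-proportion
arithmetic of read-count tables (shares of a total; the complement left to
a dominant group by its listed minor parts).

## Imaging

* Greyscale structure images stretch the major plane between its 1st and
  99th count percentiles; a constant plane renders mid-grey.
* HSI ratio images map the per-pixel ratio linearly to hue between fixed
  endpoints — 0.0037 (blue, 240°) to 0.01 (red, 0°), full saturation and
  value, clipping outside. Counts are box-summed over a 3×3 window
  (configurable; 1 disables) *before* ratio formation, to avoid
  zero-count speckle; per-pixel ratios at window scale remain unbiased
  because both planes are summed identically, and the window truncates at
  image borders rather than padding. Pixels with zero window-summed major
  counts render black. Only monotonicity and the endpoint anchoring are
  treated as normative; the exact colour interpolation between them is a
  display choice.
* Line scans resample a polyline at unit arc-length steps; at each step
  counts are summed over an odd `width` of pixels perpendicular to the
  path (out-of-bounds offsets dropped, never clamped, so no pixel is
  double-counted) and converted to ratio and atom %. At
  `width = image height` over a full-width horizontal path, the samples
  partition the image exactly and their aggregate reproduces the
  whole-image ratio of sums — a test asserts this identity.

## The synthetic scene generator

Real NanoSIMS rasters from the motivating experiments are not
redistributable at desk scale, so validation runs on synthetic scenes
with known ground truth. A scene is a natural-abundance background plus
discrete structures mimicking the bryosphere's components: constant-width
polyline filaments (cyanobacterial trichomes, fungal hyphae), annuli
(moss cell walls), disks (bacteria, micro-algae) and radially perturbed
blobs (irregular cytoplasm). Each structure carries a true atom % $p$ and
a mean total ion yield $\lambda$ per pixel; expected species counts are
$\lambda p/100$ and $\lambda(1-p/100)$, so enrichment shifts the isotope
balance without changing total brightness, and realized counts are
independent Poisson draws. A single mandatory seed makes scenes
byte-reproducible.

What the generator emulates: Poisson counting statistics, structure-level
count-rate contrast, component geometry at the right scale, and
labeled-versus-control designs. What it does not emulate: detector
artefacts (dead time, QSA, drift), charging and topography, correlated
noise between species, sub-pixel geometry, and the biological
within-component variance beyond what the preset truth values encode.
Passing tests therefore demonstrate the *statistical chain* is correct
under the stated noise model, not that any instrument-specific correction
is unnecessary on real data.

**Study presets.** `makeStudyFixture()` emits complete fixture trees for
two boreal-forest-site presets plus a minimal smoke fixture. Sections are
256×256 px (a deliberate reduction from full 512 px rasters; all
statistics scale with total counts, not raster size). True atom % values
per component are fixed sets whose medians equal the printed site and
segment medians of the motivating study (green-segment cyanobacteria 0.47
and 0.53, brown 0.85; moss 0.43/0.41/0.39; and so on), and the bacterial
truth fractions match the ~24 % and ~53 % enriched shares of the two
sites. Ion yields (80 counts/px background, 250–400 counts/px in
structures) are typical accumulated NanoSIMS count rates chosen once so
that most ROIs collect ≥ 6×10⁴ total counts; control sections replicate
the same geometry at natural abundance, three per site so each component
has at least five control ROIs.

Calibration scenes for the caller's error rates use
`diskGridConfig()` (identical disks on a regular grid, ~1e5 counts each)
and `simulateRoiCounts()`, which draws ROI-level summed counts directly —
valid because a sum of independent Poisson pixels is Poisson in the
summed mean — and is used where hundreds of ROIs are needed cheaply.

## Numerical and interface choices

* Coordinates are 0-based, row-major `(row, col)` pixel centres; masks
  are explicit label images, which structurally forbids overlapping ROIs
  within a section (the enrichment tally assumes each feature counted
  once). Overlapping *simulated* structures are an error unless
  compositing is explicitly allowed.
* Ion images are two-plane 16-bit TIFFs in a fixed documented plane order
  (major first), with a sidecar CSV carrying metadata; 16 bits bound
  per-pixel accumulated counts at 65535, enforced at write time. The
  component vocabulary is a closed enum; unknown strings map to
  `unidentified` with a warning.
* Problem sizes in the test and acceptance suites — 10⁵ Monte-Carlo draws
  per σ setting, 200-ROI control/null arms, 40 ROIs per enrichment level
  in recovery scenes — were chosen as the smallest sizes at which the
  binomial/Monte-Carlo tolerances in use are comfortably resolvable.
* Determinism: fixed seed and config give byte-identical images, masks,
  CSVs and PNGs across runs; tests assert this at the file level.

## Known limitations

Per-ROI calling with no familywise control means study-level enriched
fractions carry the per-ROI false-positive rate (~5 % under the
percentile bound). The conservative zero-minor σ bound is deliberately
pessimistic at very low count totals. The caller treats control
distributions as fixed references, ignoring their sampling error in
criterion (b). The generator's truth values are constants per structure,
so within-ROI heterogeneity (e.g. intracellular hotspots) is only
represented between, not within, structures.
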