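# Brute-force sort-and-interpolate quantile: h = (n-1)p + 1, linear
# interpolation between the flanking order statistics. Independent of
# stats::quantile.
quantileOracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }, numeric(1))
}

# Monte-Carlo SD of the count ratio (and atom %) under independent Poisson
# counting at the given means; draws with zero major count are dropped.
mcRatioSd <- function(lambdaMinor, lambdaMajor, nDraws = 1e5) {
  minor <- rpois(nDraws, lambdaMinor)
  major <- rpois(nDraws, lambdaMajor)
  keep <- major > 0
  r <- minor[keep] / major[keep]
  list(sd_ratio = sd(r), sd_atom = sd(100 * r / (1 + r)))
}

# Minimal labeled-stats row for exercising the enrichment caller directly.
statsRow <- function(atomPercent, sigmaAtom, component = "bacterium",
                     roiId = "r1", evaluable = TRUE) {
  data.frame(roi_id = roiId, component = component, section_id = "s1",
             segment = "green", site = "test", n_pixels = 100L,
             sum_minor = 100L, sum_major = 26900L,
             ratio = ratioFromAtomPercent(atomPercent),
             atom_percent = atomPercent, sigma_atom_percent = sigmaAtom,
             zero_minor_flag = FALSE, evaluable = evaluable)
}

# ControlModel with exactly specified reference values, for rule tests.
fixedControls <- function(component = "bacterium", mean = 0.37,
                          upper95 = 0.40, n = 20) {
  methods::new("ControlModel",
               summary = data.frame(component = component, n = n,
                                    mean_atom_percent = mean,
                                    upper95 = upper95, pooled_flag = FALSE),
               values = list(.pooled = rep(mean, n)),
               bound = "percentile", minPerComponent = 5)
}
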