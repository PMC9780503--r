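test_that("control distributions use order-statistic interpolation", {
  mk <- function(vals) {
    n <- length(vals)
    data.frame(roi_id = sprintf("c%03d", seq_len(n)),
               component = "bacterium", section_id = "cs",
               segment = "green", site = "x", n_pixels = 100L,
               sum_minor = 100L, sum_major = 26900L,
               ratio = ratioFromAtomPercent(vals), atom_percent = vals,
               sigma_atom_percent = 0.02, zero_minor_flag = FALSE,
               evaluable = TRUE)
  }
  cm <- fitControls(mk(rep(0.37, 20)))
  s <- cm@summary
  expect_equal(s$mean_atom_percent, 0.37)
  expect_equal(s$upper95, 0.37)
  expect_false(s$pooled_flag)

  cm2 <- fitControls(mk(seq(0.30, 0.49, by = 0.01)))
  expect_equal(cm2@summary$upper95, 0.4805)
  expect_equal(cm2@summary$upper95,
               quantileOracle(seq(0.30, 0.49, by = 0.01), 0.95))

  # below the per-component minimum: pooled fallback, flagged
  two <- mk(c(0.36, 0.38)); two$component <- "fungal_hypha"
  pool <- rbind(mk(seq(0.35, 0.40, length.out = 10)), two)
  expect_message(cm3 <- fitControls(pool, minPerComponent = 5), "pooled")
  s3 <- cm3@summary
  expect_true(s3$pooled_flag[s3$component == "fungal_hypha"])
  expect_false(s3$pooled_flag[s3$component == "bacterium"])
  expect_equal(s3$n[s3$component == "fungal_hypha"], 12L)
  expect_gte(s3$n[s3$component == "fungal_hypha"], 5L)

  # the normal-theory alternative bound
  v <- seq(0.35, 0.40, length.out = 10)
  cm4 <- fitControls(mk(v), bound = "ci-of-mean")
  expect_equal(cm4@summary$upper95,
               mean(v) + 1.645 * sd(v) / sqrt(10))

  none <- mk(0.37); none$evaluable <- FALSE
  expect_error(fitControls(none), "no evaluable control")
})

test_that("the dual criterion is evaluated with strict inequalities", {
  ctl <- fixedControls(mean = 0.37, upper95 = 0.40)
  # at the control level: no enrichment
  c0 <- callEnrichment(statsRow(0.37, 0.01), ctl)
  expect_equal(c0$delta, 0)
  expect_false(c0$enriched)

  # clearly above the bound with small error: enriched
  c1 <- callEnrichment(statsRow(0.53, 0.02), ctl)  # two_sigma = 0.04
  expect_true(c1$criterion_a)   # 0.53 > 0.40
  expect_true(c1$criterion_b)   # 0.04 < 0.16
  expect_true(c1$enriched)

  # above the bound but error too large: not enriched
  c2 <- callEnrichment(statsRow(0.41, 0.05), ctl)  # two_sigma = 0.10
  expect_true(c2$criterion_a)   # 0.41 > 0.40
  expect_false(c2$criterion_b)  # 0.10 > 0.04
  expect_false(c2$enriched)

  # strictness at exact equality (binary-exact values): both criteria fail
  ctlEq <- fixedControls(mean = 0.25, upper95 = 0.5)
  c3 <- callEnrichment(statsRow(0.5, 0.125), ctlEq)  # two_sigma = delta = 0.25
  expect_false(c3$criterion_a)   # 0.5 > 0.5 is false
  expect_false(c3$criterion_b)   # 0.25 < 0.25 is false

  # non-evaluable ROIs are excluded with a message, not silently false
  st <- rbind(statsRow(0.53, 0.02, roiId = "ok"),
              statsRow(0.53, 0.02, roiId = "bad", evaluable = FALSE))
  expect_message(cc <- callEnrichment(st, ctl), "bad")
  expect_equal(cc$roi_id, "ok")
  expect_error(
    suppressMessages(callEnrichment(statsRow(0.5, 0.02, evaluable = FALSE),
                                    ctl)),
    "no evaluable")
})

test_that("enrichment tallies report integer percent per group", {
  calls <- do.call(rbind, lapply(1:100, function(i)
    callEnrichment(statsRow(if (i <= 24) 0.53 else 0.37, 0.02,
                            roiId = paste0("r", i)),
                   fixedControls())))
  t1 <- tallyEnrichment(calls)
  expect_equal(t1$n_total, 100L)
  expect_equal(t1$n_enriched, 24L)
  expect_equal(t1$percent_enriched, 24)

  none <- callEnrichment(statsRow(0.37, 0.02), fixedControls())
  expect_equal(tallyEnrichment(none)$percent_enriched, 0)
})

test_that("caller type-I error stays within the binomial envelope", {
  set.seed(101)
  na <- naturalAbundance$atom_percent
  ctrl <- simulateRoiCounts(200, na, 2e4, sectionId = "ctl")
  null <- simulateRoiCounts(200, na, 2e4, sectionId = "nul")
  cm <- fitControls(ctrl)
  calls <- callEnrichment(null, cm)
  frac <- mean(calls$enriched)
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("power is monotone in true atom % and in total counts", {
  set.seed(202)
  cm <- fitControls(simulateRoiCounts(200, naturalAbundance$atom_percent,
                                      1e5, sectionId = "ctl"))
  fracAt <- function(p, counts) {
    mean(callEnrichment(simulateRoiCounts(150, p, counts), cm)$enriched)
  }
  byP <- vapply(c(0.37, 0.42, 0.47, 0.60, 0.85), fracAt, 0, counts = 1e5)
  expect_true(all(diff(byP) >= -0.02))  # non-decreasing up to binomial noise
  expect_gt(byP[5], 0.95)
  byN <- vapply(c(5e3, 2e4, 1e5), function(n) fracAt(0.45, n), 0)
  expect_true(all(diff(byN) >= -0.02))
})

test_that("components unseen in controls fall back to the pooled bound", {
  set.seed(7)
  ctrl <- simulateRoiCounts(50, naturalAbundance$atom_percent, 5e4,
                            component = "bacterium")
  cm <- fitControls(ctrl)
  ref <- controlReference(cm, "micro_alga")
  expect_true(ref$pooled_flag)
  expect_equal(ref$n, 50L)
  lab <- simulateRoiCounts(5, 0.85, 5e4, component = "micro_alga")
  calls <- callEnrichment(lab, cm)
  expect_true(all(calls$pooled_controls))
  expect_true(all(calls$enriched))
})
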