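test_that("identical seeds give byte-identical scenes", {
  cfg <- sceneConfig(list(sceneDisk(30, 30, 8, "bacterium", 0.85, 300),
                          sceneBlob(70, 70, 12, "moss_cytoplasm", 0.47,
                                    250)),
                     dim = c(100, 100), seed = 99)
  a <- simulateScene(cfg)
  b <- simulateScene(cfg)
  expect_identical(minorCounts(a$image), minorCounts(b$image))
  expect_identical(majorCounts(a$image), majorCounts(b$image))
  expect_identical(a$truth$labels, b$truth$labels)
  c3 <- simulateScene(sceneConfig(cfg@structures, dim = c(100, 100),
                                  seed = 100))
  expect_false(identical(minorCounts(a$image), minorCounts(c3$image)))
})

test_that("a background-only scene converges to natural abundance", {
  cfg <- sceneConfig(dim = c(256, 256), backgroundLambda = 270, seed = 4)
  scn <- simulateScene(cfg)
  wholeAtom <- atomPercentFromRatio(sum(minorCounts(scn$image)) /
                                      sum(majorCounts(scn$image)))
  # ~1.8e7 total counts: whole-image sigma from counting statistics
  sig <- poissonSigma(sum(minorCounts(scn$image)),
                      sum(majorCounts(scn$image)))$sigma_atom_percent
  expect_lt(abs(wholeAtom - naturalAbundance$atom_percent), 4 * sig)
})

test_that("structure means are calibrated to their lambda specification", {
  cfg <- sceneConfig(list(sceneDisk(60, 60, 20, "micro_alga", 0.85, 320)),
                     dim = c(128, 128), backgroundLambda = 80, seed = 21)
  scn <- simulateScene(cfg)
  inside <- scn$truth$labels == 1
  tot <- minorCounts(scn$image) + majorCounts(scn$image)
  nPix <- sum(inside)
  expect_lt(abs(mean(tot[inside]) - 320), 3 * sqrt(320 / nPix))
  expect_lt(abs(mean(tot[!inside]) - 80), 3 * sqrt(80 / sum(!inside)))
  # enrichment shifts isotope balance, not total brightness
  expect_equal(mean(tot[inside]) / 320, 1, tolerance = 0.02)
})

test_that("ROI stats over a simulated disk recover the true atom %", {
  cfg <- sceneConfig(list(sceneDisk(40, 40, 14, "cyanobacterium", 0.85,
                                    330)),
                     dim = c(80, 80), seed = 13)
  scn <- simulateScene(cfg)
  st <- roiStats(scn$image, truthRoiSet(scn$truth, "s1"))
  expect_lt(abs(st$atom_percent - 0.85), 2 * st$sigma_atom_percent)
  # empirical ratio-of-sums approaches p/(100-p)
  expect_equal(st$ratio, 0.85 / 99.15, tolerance = 3 * st$sigma_atom_percent)
})

test_that("conflicting structure overlaps are rejected unless allowed", {
  cfg <- sceneConfig(list(sceneDisk(30, 30, 10, "bacterium", 0.5, 300),
                          sceneDisk(34, 34, 10, "fungal_hypha", 0.6, 300)),
                     dim = c(64, 64), seed = 2)
  expect_error(simulateScene(cfg), "overlap")
  scn <- simulateScene(cfg, allowOverwrite = TRUE)
  expect_setequal(unique(as.vector(scn$truth$labels)), c(0L, 1L, 2L))
})

test_that("minimal study fixture emits a consistent, readable tree", {
  d <- withr::local_tempdir()
  man <- makeStudyFixture(d, "minimal", seed = 5)
  expect_true(file.exists(file.path(d, "manifest.csv")))
  expect_gte(length(unique(man$component)), 4L)
  expect_false(anyDuplicated(man$roi_id) > 0)
  # every referenced file exists and round-trips
  for (i in seq_len(nrow(man))) {
    expect_true(file.exists(file.path(d, man$image_file[i])))
    expect_true(file.exists(file.path(d, man$labels_file[i])))
  }
  sec <- man[man$role == "labeled", ][1, ]
  rois <- readRoiMasks(file.path(d, sec$labels_file),
                       file.path(d, sec$annotations_file))
  ann <- roiAnnotations(rois)
  secMan <- man[man$section_id == sec$section_id, ]
  expect_equal(nrow(ann), nrow(secMan))
  # component labels preserved through the mask/annotation round trip
  expect_equal(ann$component[match(secMan$roi_id, ann$roi_id)],
               secMan$component)
  # refuses to clobber unless forced
  expect_error(makeStudyFixture(d, "minimal", seed = 5), "not empty")
  expect_silent(suppressMessages(makeStudyFixture(d, "minimal", seed = 5,
                                                  force = TRUE)))
})

test_that("direct ROI-count simulation matches its specification", {
  set.seed(61)
  st <- simulateRoiCounts(400, 0.53, 5e4)
  expect_true(all(st$evaluable))
  expect_equal(mean(st$atom_percent), 0.53, tolerance = 0.01)
  expect_equal(mean(st$sum_minor + st$sum_major), 5e4, tolerance = 0.01)
  # analytic sigma agrees with the empirical spread across ROIs
  expect_equal(sd(st$atom_percent), median(st$sigma_atom_percent),
               tolerance = 0.15)
})
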