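test_that("ion images round-trip losslessly through multi-plane TIFF", {
  set.seed(5)
  img <- IonCountImage(matrix(rpois(400, 3L), 20, 20),
                       matrix(rpois(400, 300L), 20, 20),
                       metadata = list(section_id = "s1", site = "reivo"))
  f <- withr::local_tempfile(fileext = ".tif")
  writeIonImage(img, f)
  back <- readIonImage(f)
  expect_identical(minorCounts(back), minorCounts(img))
  expect_identical(majorCounts(back), majorCounts(img))
  expect_equal(imageMetadata(back)$site, "reivo")
  expect_equal(dim(back), c(20L, 20L))
  # write-read-write is idempotent
  f2 <- withr::local_tempfile(fileext = ".tif")
  writeIonImage(back, f2)
  expect_identical(readBin(f, "raw", file.size(f)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("malformed ion images are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0.5, 8, 8), f, bits.per.sample = 16L)
  expect_error(readIonImage(f), "plane 2 .*missing|missing")

  # float-typed pixel data is not integer counts
  f3 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(list(matrix(0.31, 8, 8), matrix(0.25, 8, 8)), f3,
                  bits.per.sample = 32L)
  expect_error(readIonImage(f3), "non-integer")

  expect_error(IonCountImage(matrix(1L, 4, 4), matrix(1L, 5, 5)),
               "same shape")
  expect_error(IonCountImage(matrix(-1L, 4, 4), matrix(1L, 4, 4)),
               "negative")
  expect_error(writeIonImage(IonCountImage(matrix(70000L, 2, 2),
                                           matrix(1L, 2, 2)),
                             tempfile()), "65535")
})

test_that("ROI masks load from label TIFF plus annotation CSV", {
  lab <- matrix(0L, 10, 10)
  lab[2:4, 2:4] <- 1L
  lab[7:9, 7:9] <- 2L
  ann <- data.frame(label = 1:2, roi_id = c("a", "b"),
                    component = c("bacterium", "cyanobacterium"),
                    section_id = "s1", segment = "green", site = "x")
  labF <- withr::local_tempfile(fileext = ".tif")
  annF <- withr::local_tempfile(fileext = ".csv")
  writeRoiMasks(RoiSet(lab, ann), labF, annF)
  rs <- readRoiMasks(labF, annF)
  expect_equal(nRoi(rs), 2L)
  expect_identical(roiLabels(rs), lab)
  expect_setequal(roiAnnotations(rs)$component,
                  c("bacterium", "cyanobacterium"))
  expect_equal(sum(roiMask(rs, "a")), 9)

  # unannotated label present in the image is an error naming the label
  lab3 <- lab; lab3[1, 1] <- 3L
  expect_error(RoiSet(lab3, ann), "3")
  # annotated label absent from the image is a warning, row dropped
  ann3 <- rbind(ann, data.frame(label = 9, roi_id = "ghost",
                                component = "eps", section_id = "s1",
                                segment = "green", site = "x"))
  expect_warning(rs2 <- RoiSet(lab, ann3), "absent")
  expect_equal(nRoi(rs2), 2L)
  # unknown component maps to unidentified with a warning
  annU <- ann; annU$component[1] <- "mystery"
  expect_warning(rsU <- RoiSet(lab, annU), "unidentified")
  expect_equal(roiAnnotations(rsU)$component[1], "unidentified")
})

test_that("roiStats aggregates by ratio-of-summed-counts", {
  minor <- matrix(1L, 30, 30)
  major <- matrix(269L, 30, 30)
  lab <- matrix(0L, 30, 30)
  lab[1:10, 1:10] <- 1L       # 100-px mask
  lab[15, 15] <- 2L           # single pixel
  ann <- data.frame(label = 1:2, roi_id = c("m100", "px1"),
                    component = "bacterium", section_id = "s",
                    segment = "green", site = "x")
  st <- roiStats(IonCountImage(minor, major), RoiSet(lab, ann))
  expect_equal(st$n_pixels, c(100L, 1L))
  expect_equal(st$sum_minor, c(100L, 1L))
  expect_equal(st$sum_major, c(26900L, 269L))
  # 100 minor of 27000 total N counts -> 0.3704 atom %
  expect_equal(st$atom_percent[1], 100 * 100 / 27000, tolerance = 1e-12)
  expect_equal(round(st$atom_percent[1], 4), 0.3704)
  expect_equal(st$atom_percent[2], st$atom_percent[1])
  expect_true(all(st$evaluable))
})

test_that("zero-count regions are non-evaluable, zero minor flagged", {
  minor <- matrix(0L, 10, 10); major <- matrix(0L, 10, 10)
  major[6:10, ] <- 200L
  lab <- matrix(0L, 10, 10)
  lab[1:2, 1:2] <- 1L   # dead region
  lab[7:8, 1:2] <- 2L   # major counts only
  ann <- data.frame(label = 1:2, roi_id = c("dead", "zmin"),
                    component = "eps", section_id = "s",
                    segment = "brown", site = "x")
  expect_message(st <- roiStats(IonCountImage(minor, major),
                                RoiSet(lab, ann)), "non-evaluable")
  expect_false(st$evaluable[1])
  expect_true(is.na(st$atom_percent[1]))
  expect_true(st$evaluable[2])
  expect_true(st$zero_minor_flag[2])
  expect_gt(st$sigma_atom_percent[2], 0)
})

test_that("count sums are additive over mask partitions", {
  set.seed(41)
  minor <- matrix(rpois(900, 2L), 30, 30)
  major <- matrix(rpois(900, 250L), 30, 30)
  whole <- matrix(0L, 30, 30); whole[5:20, 5:20] <- 1L
  partA <- partB <- matrix(0L, 30, 30)
  partA[5:12, 5:20] <- 1L; partB[13:20, 5:20] <- 2L
  ann1 <- data.frame(label = 1, roi_id = "w", component = "bacterium",
                     section_id = "s", segment = "green", site = "x")
  ann2 <- data.frame(label = 1:2, roi_id = c("a", "b"),
                     component = "bacterium", section_id = "s",
                     segment = "green", site = "x")
  img <- IonCountImage(minor, major)
  stW <- roiStats(img, RoiSet(whole, ann1))
  stP <- roiStats(img, RoiSet(partA + partB, ann2))
  expect_identical(sum(stP$sum_minor), stW$sum_minor)
  expect_identical(sum(stP$sum_major), stW$sum_major)
  expect_identical(sum(stP$n_pixels), stW$n_pixels)
})

test_that("ratio-of-sums equals the count-weighted mean of pixel ratios", {
  set.seed(42)
  minor <- matrix(rpois(400, 5L), 20, 20)
  major <- matrix(rpois(400, 300L) + 1L, 20, 20)  # all majors > 0
  lab <- matrix(1L, 20, 20)
  ann <- data.frame(label = 1, roi_id = "all", component = "bacterium",
                    section_id = "s", segment = "green", site = "x")
  st <- roiStats(IonCountImage(minor, major), RoiSet(lab, ann))
  weighted <- sum(major * (minor / major)) / sum(major)
  expect_equal(st$ratio, weighted, tolerance = 1e-12)
})
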