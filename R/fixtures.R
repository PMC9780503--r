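# Per-component ion yields (mean total counts per pixel) used by the study
# presets; chosen as typical accumulated NanoSIMS count rates so that most
# ROIs collect >= ~6e4 total counts.
.LAMBDA <- c(cyanobacterium = 400, moss_cell_wall = 300,
             moss_cytoplasm = 250, bacterium = 400, fungal_hypha = 300,
             micro_alga = 350)

# Fixed 256 x 256 section layout: disjoint bands per component so preset
# structures never overlap. Capacities: 3 cyano filaments, 2 moss cells
# (wall annulus + cytoplasm blob), 39 bacterium disks, 2 hyphae, 9 algae.
.sectionStructures <- function(components) {
  sts <- list()
  add <- function(s) sts[[length(sts) + 1]] <<- s
  p <- components$cyanobacterium
  if (length(p) > 3) stop("layout holds at most 3 cyanobacteria per section")
  rows <- c(12, 24, 36)
  for (i in seq_along(p))
    add(sceneFilament(rbind(c(rows[i], 8), c(rows[i] + 3, 128),
                            c(rows[i], 248)),
                      halfWidth = 3, "cyanobacterium", p[i],
                      .LAMBDA[["cyanobacterium"]]))
  pw <- components$moss_cell_wall
  pc <- components$moss_cytoplasm
  if (length(pw) > 2 || length(pc) > 2)
    stop("layout holds at most 2 moss cells per section")
  centers <- list(c(80, 64), c(80, 176))
  for (i in seq_along(pw))
    add(sceneAnnulus(centers[[i]][1], centers[[i]][2], rInner = 23,
                     rOuter = 28, "moss_cell_wall", pw[i],
                     .LAMBDA[["moss_cell_wall"]]))
  for (i in seq_along(pc))
    add(sceneBlob(centers[[i]][1], centers[[i]][2], radius = 16,
                  "moss_cytoplasm", pc[i], .LAMBDA[["moss_cytoplasm"]]))
  p <- components$bacterium
  if (length(p) > 39) stop("layout holds at most 39 bacteria per section")
  slots <- expand.grid(col = seq(16, 232, by = 18),
                       row = c(130, 148, 166))
  for (i in seq_along(p))
    add(sceneDisk(slots$row[i], slots$col[i], radius = 7, "bacterium",
                  p[i], .LAMBDA[["bacterium"]]))
  p <- components$fungal_hypha
  if (length(p) > 2) stop("layout holds at most 2 hyphae per section")
  rows <- c(190, 205)
  for (i in seq_along(p))
    add(sceneFilament(rbind(c(rows[i], 10), c(rows[i] - 2, 120),
                            c(rows[i] + 1, 246)),
                      halfWidth = 2, "fungal_hypha", p[i],
                      .LAMBDA[["fungal_hypha"]]))
  p <- components$micro_alga
  if (length(p) > 9) stop("layout holds at most 9 micro-algae per section")
  cols <- seq(14, 222, by = 26)
  for (i in seq_along(p))
    add(sceneDisk(236, cols[i], radius = 9, "micro_alga", p[i],
                  .LAMBDA[["micro_alga"]]))
  sts
}

.naturalSection <- function(counts) {
  na <- naturalAbundance$atom_percent
  lapply(counts, function(k) rep(na, k))
}

# Study presets at reduced raster scale (256 px sections). True atom %
# values per component are fixed sets whose medians equal the printed
# site/segment medians; bacterial enriched fractions match the study-level
# 24 % (Njallatjirelg) and ~53 % (Reivo) shares.
.presets <- function(preset) {
  na <- naturalAbundance$atom_percent
  ctrlGreen <- .naturalSection(list(cyanobacterium = 3, moss_cell_wall = 2,
                                    moss_cytoplasm = 2, bacterium = 12,
                                    fungal_hypha = 2, micro_alga = 4))
  switch(preset,
    minimal = list(
      list(id = "ctrl1", role = "control", segment = "green",
           comps = .naturalSection(list(cyanobacterium = 1,
                                        moss_cell_wall = 1,
                                        moss_cytoplasm = 1, bacterium = 3,
                                        fungal_hypha = 1, micro_alga = 1))),
      list(id = "lab1", role = "labeled", segment = "green",
           comps = list(cyanobacterium = 0.53, moss_cell_wall = 0.41,
                        moss_cytoplasm = 0.41,
                        bacterium = c(0.47, 0.47, na),
                        fungal_hypha = 0.44, micro_alga = 0.59))),
    njallatjirelg = list(
      list(id = "njg_ctrl1", role = "control", segment = "green",
           comps = ctrlGreen),
      list(id = "njg_ctrl2", role = "control", segment = "green",
           comps = ctrlGreen),
      list(id = "njg_ctrl3", role = "control", segment = "green",
           comps = ctrlGreen),
      list(id = "njg_lab1", role = "labeled", segment = "green",
           comps = list(cyanobacterium = c(0.42, 0.47, 0.50),
                        moss_cell_wall = c(0.41, 0.43),
                        moss_cytoplasm = c(0.40, 0.43),
                        bacterium = c(0.43, 0.45, 0.47, rep(na, 10)),
                        fungal_hypha = c(0.38, 0.50),
                        micro_alga = c(0.38, 0.38, 0.40))),
      list(id = "njg_lab2", role = "labeled", segment = "green",
           comps = list(cyanobacterium = c(0.45, 0.47, 0.53),
                        moss_cell_wall = c(0.43, 0.44),
                        moss_cytoplasm = c(0.43, 0.44),
                        bacterium = c(0.44, 0.46, 0.47, rep(na, 9)),
                        fungal_hypha = c(0.38, 0.38),
                        micro_alga = c(0.38, 0.39, 0.39)))),
    reivo = list(
      list(id = "rvo_ctrl1", role = "control", segment = "green",
           comps = ctrlGreen),
      list(id = "rvo_ctrl2", role = "control", segment = "green",
           comps = ctrlGreen),
      list(id = "rvo_ctrl3", role = "control", segment = "green",
           comps = ctrlGreen),
      list(id = "rvo_lab1", role = "labeled", segment = "green",
           comps = list(cyanobacterium = c(0.48, 0.53, 0.58),
                        moss_cell_wall = c(0.40, 0.41),
                        moss_cytoplasm = c(0.40, 0.41),
                        bacterium = c(0.43, 0.53, 0.64, 0.85, 1.06,
                                      rep(na, 4)),
                        fungal_hypha = c(0.43, 0.44),
                        micro_alga = c(0.57, 0.59))),
      list(id = "rvo_lab2", role = "labeled", segment = "green",
           comps = list(cyanobacterium = c(0.51, 0.53, 0.62),
                        moss_cell_wall = c(0.41, 0.42),
                        moss_cytoplasm = c(0.41, 0.42),
                        bacterium = c(0.47, 0.58, 0.72, 0.95, rep(na, 4)),
                        fungal_hypha = c(0.44, 0.44),
                        micro_alga = c(0.59, 0.61))),
      list(id = "rvo_lab3", role = "labeled", segment = "brown",
           comps = list(cyanobacterium = c(0.80, 0.85, 0.90),
                        moss_cell_wall = c(na, na),
                        moss_cytoplasm = c(0.39, 0.39),
                        bacterium = c(0.47, 0.55, 0.60, 0.80, 1.00, 1.15,
                                      1.30, rep(na, 6)),
                        fungal_hypha = c(0.44, 0.59),
                        micro_alga = c(0.59, 0.61)))),
    stop("unknown preset: ", preset, call. = FALSE))
}

#' Generate a complete study fixture on disk
#'
#' Emits a self-describing file tree of simulated NanoSIMS sections —
#' unlabeled control sections at natural abundance plus labeled sections
#' whose structures carry component-specific true atom % \eqn{^{15}N} —
#' in exactly the formats the ROI pipeline reads: per section a two-plane
#' ion-count TIFF, a label-mask TIFF and an annotation CSV, plus a
#' `manifest.csv` recording every ROI's ground truth.
#'
#' Presets (256 x 256 px sections, reduced from full 512 px rasters):
#' `"minimal"` — one control and one labeled section, a smoke fixture;
#' `"njallatjirelg"` and `"reivo"` — three control and two to three labeled
#' sections per site, with component medians and bacterial enriched
#' fractions mirroring the two boreal forest sites.
#'
#' @param outDir output directory; must be empty unless `force = TRUE`.
#' @param preset `"minimal"`, `"njallatjirelg"` or `"reivo"`.
#' @param seed integer; per-section scene seeds are derived from it.
#' @param force overwrite a non-empty directory.
#' @return invisibly, the manifest data.frame.
#' @export
makeStudyFixture <- function(outDir,
                             preset = c("minimal", "njallatjirelg", "reivo"),
                             seed = 1, force = FALSE) {
  preset <- match.arg(preset)
  if (dir.exists(outDir) && length(dir(outDir)) > 0 && !force)
    stop("output directory not empty (use force = TRUE): ", outDir,
         call. = FALSE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  site <- if (preset == "minimal") "sim" else preset
  sections <- .presets(preset)
  manifest <- list()
  for (i in seq_along(sections)) {
    sec <- sections[[i]]
    cfg <- sceneConfig(.sectionStructures(sec$comps), dim = c(256, 256),
                       seed = as.integer(seed) * 1000L + i)
    scn <- simulateScene(cfg)
    scn$image@metadata <- list(section_id = sec$id, site = site,
                               segment = sec$segment, role = sec$role)
    rois <- truthRoiSet(scn$truth, sec$id, segment = sec$segment,
                        site = site)
    imgFile <- file.path(outDir, paste0(sec$id, ".tif"))
    labFile <- file.path(outDir, paste0(sec$id, "_labels.tif"))
    annFile <- file.path(outDir, paste0(sec$id, "_rois.csv"))
    writeIonImage(scn$image, imgFile)
    writeRoiMasks(rois, labFile, annFile)
    tab <- scn$truth$table
    manifest[[i]] <- data.frame(
      section_id = sec$id, role = sec$role, site = site,
      segment = sec$segment, label = tab$label,
      roi_id = sprintf("%s_r%02d", sec$id, tab$label),
      component = tab$component, shape = tab$shape,
      true_atom_percent = tab$true_atom_percent,
      true_ratio = tab$true_ratio, lambda_total = tab$lambda_total,
      n_pixels = tab$n_pixels, scene_seed = scn$truth$seed,
      image_file = basename(imgFile), labels_file = basename(labFile),
      annotations_file = basename(annFile))
  }
  manifest <- do.call(rbind, manifest)
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
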