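#' SceneConfig: declarative ground truth for a synthetic NanoSIMS scene
#'
#' A scene is a background at natural-abundance \eqn{^{15}N} plus discrete
#' biological structures (filamentous cyanobacteria, moss cell walls and
#' cytoplasm, epiphytic bacteria, hyphae, micro-algae), each with a true
#' atom % \eqn{^{15}N} and a mean total secondary-ion yield per pixel.
#' Detection is independent Poisson per pixel per ion species: with local
#' true atom % \eqn{p} and total yield \eqn{\lambda}, expected counts are
#' \eqn{\lambda p/100} (minor) and \eqn{\lambda(1-p/100)} (major) — so
#' enrichment shifts the isotope balance without changing total brightness.
#'
#' @slot dim image size in pixels, rows x cols (default 512 x 512).
#' @slot backgroundAtomPercent true background atom % (natural abundance).
#' @slot backgroundLambda mean total counts per background pixel.
#' @slot structures list of structure descriptors from [sceneDisk()],
#'   [sceneAnnulus()], [sceneFilament()], [sceneBlob()].
#' @slot seed mandatory integer seed; identical seed, identical scene.
#' @export
setClass("SceneConfig",
         representation(dim = "numeric", backgroundAtomPercent = "numeric",
                        backgroundLambda = "numeric", structures = "list",
                        seed = "numeric"))

setValidity("SceneConfig", function(object) {
  msg <- character()
  if (length(object@dim) != 2 || any(object@dim < 8))
    msg <- c(msg, "dim must be two pixel sizes >= 8")
  p <- c(object@backgroundAtomPercent,
         vapply(object@structures, `[[`, 0, "atomPercent"))
  if (any(p < 0 | p >= 100))
    msg <- c(msg, "true atom % must lie in [0, 100)")
  lam <- c(object@backgroundLambda,
           vapply(object@structures, `[[`, 0, "lambdaTotal"))
  if (any(lam <= 0)) msg <- c(msg, "mean counts must be positive")
  if (length(object@seed) != 1 || is.na(object@seed))
    msg <- c(msg, "a scene seed is mandatory")
  comp <- vapply(object@structures, `[[`, "", "component")
  if (length(comp) && !all(comp %in% .COMPONENTS))
    msg <- c(msg, "unknown component in structure list")
  if (length(msg)) msg else TRUE
})

#' @rdname SceneConfig-class
#' @param structures list of structure descriptors.
#' @param dim image size `c(rows, cols)`.
#' @param backgroundAtomPercent true background atom % (default natural
#'   abundance, 0.3686).
#' @param backgroundLambda mean total counts per background pixel.
#' @param seed integer scene seed (mandatory).
#' @export
sceneConfig <- function(structures = list(), dim = c(512, 512),
                        backgroundAtomPercent = naturalAbundance$atom_percent,
                        backgroundLambda = 80, seed) {
  if (missing(seed)) stop("a scene seed is mandatory", call. = FALSE)
  methods::new("SceneConfig", dim = dim,
               backgroundAtomPercent = backgroundAtomPercent,
               backgroundLambda = backgroundLambda,
               structures = structures, seed = seed)
}

#' @rdname SceneConfig-class
#' @param object a SceneConfig
#' @export
setMethod("show", "SceneConfig", function(object) {
  cat(sprintf("SceneConfig %d x %d px, seed %d\n",
              object@dim[1], object@dim[2], as.integer(object@seed)))
  cat(sprintf("  background: %.4f atom %%, lambda %g counts/px\n",
              object@backgroundAtomPercent, object@backgroundLambda))
  cat(sprintf("  %d structure(s)\n", length(object@structures)))
})

.structure <- function(shape, component, atomPercent, lambdaTotal, geom) {
  stopifnot(component %in% .COMPONENTS,
            atomPercent >= 0, atomPercent < 100, lambdaTotal > 0)
  c(list(shape = shape, component = component, atomPercent = atomPercent,
         lambdaTotal = lambdaTotal), geom)
}

#' Scene structure descriptors
#'
#' Geometry primitives composited into a [SceneConfig-class]: disks (small
#' round cells such as bacteria and micro-algae), annuli (moss cell walls),
#' constant-width polyline filaments (cyanobacterial trichomes, fungal
#' hyphae), and radially perturbed blobs (irregular cytoplasm regions).
#' Coordinates are 0-based `(row, col)` pixel centres.
#'
#' @param row,col centre position.
#' @param radius disk/blob base radius in pixels.
#' @param component one of the closed component vocabulary
#'   (cyanobacterium, moss_cell_wall, moss_cytoplasm, bacterium,
#'   fungal_hypha, micro_alga, eps, unidentified).
#' @param atomPercent true atom % 15N of the structure.
#' @param lambdaTotal mean total ion counts per pixel.
#' @return a structure descriptor list for [sceneConfig()].
#' @name sceneStructures
NULL

#' @rdname sceneStructures
#' @export
sceneDisk <- function(row, col, radius, component, atomPercent, lambdaTotal)
  .structure("disk", component, atomPercent, lambdaTotal,
             list(row = row, col = col, radius = radius))

#' @rdname sceneStructures
#' @param rInner,rOuter annulus radii, `rInner < rOuter`.
#' @export
sceneAnnulus <- function(row, col, rInner, rOuter, component, atomPercent,
                         lambdaTotal) {
  stopifnot(rInner < rOuter)
  .structure("annulus", component, atomPercent, lambdaTotal,
             list(row = row, col = col, rInner = rInner, rOuter = rOuter))
}

#' @rdname sceneStructures
#' @param vertices matrix/data.frame of polyline vertices (`row`, `col`).
#' @param halfWidth half the filament width in pixels.
#' @export
sceneFilament <- function(vertices, halfWidth, component, atomPercent,
                          lambdaTotal) {
  v <- as.matrix(vertices)
  if (!is.null(colnames(v)) && all(c("row", "col") %in% colnames(v)))
    v <- v[, c("row", "col"), drop = FALSE]
  stopifnot(ncol(v) == 2, nrow(v) >= 2)
  dimnames(v) <- list(NULL, c("row", "col"))
  .structure("filament", component, atomPercent, lambdaTotal,
             list(vertices = v, halfWidth = halfWidth))
}

#' @rdname sceneStructures
#' @param amplitude relative radial perturbation amplitude (default 0.25).
#' @export
sceneBlob <- function(row, col, radius, component, atomPercent, lambdaTotal,
                      amplitude = 0.25)
  .structure("blob", component, atomPercent, lambdaTotal,
             list(row = row, col = col, radius = radius,
                  amplitude = amplitude))

.pixelGrid <- function(dim) {
  list(r = matrix(seq_len(dim[1]) - 1, dim[1], dim[2]),
       c = matrix(rep(seq_len(dim[2]) - 1, each = dim[1]), dim[1], dim[2]))
}

.rasterize <- function(st, grid) {
  dr <- grid$r - if (st$shape == "filament") 0 else st$row
  dc <- grid$c - if (st$shape == "filament") 0 else st$col
  switch(st$shape,
    disk = dr^2 + dc^2 <= st$radius^2,
    annulus = {
      d2 <- dr^2 + dc^2
      d2 > st$rInner^2 & d2 <= st$rOuter^2
    },
    blob = {
      # radial harmonics drawn from the scene RNG stream
      a <- stats::runif(3, 0.3, 1)
      ph <- stats::runif(3, 0, 2 * pi)
      a <- st$amplitude * a / sum(a)
      th <- atan2(dc, dr)
      rad <- st$radius * (1 + a[1] * sin(th + ph[1]) +
                            a[2] * sin(2 * th + ph[2]) +
                            a[3] * sin(3 * th + ph[3]))
      sqrt(dr^2 + dc^2) <= rad
    },
    filament = {
      v <- st$vertices
      d2 <- matrix(Inf, nrow(grid$r), ncol(grid$r))
      for (i in seq_len(nrow(v) - 1)) {
        a <- v[i, ]; b <- v[i + 1, ]
        ab <- b - a
        len2 <- sum(ab^2)
        if (len2 == 0) next
        t <- ((grid$r - a[1]) * ab[1] + (grid$c - a[2]) * ab[2]) / len2
        t <- pmin(1, pmax(0, t))
        d2 <- pmin(d2, (grid$r - (a[1] + t * ab[1]))^2 +
                       (grid$c - (a[2] + t * ab[2]))^2)
      }
      d2 <= st$halfWidth^2
    },
    stop("unknown structure shape: ", st$shape))
}

#' Simulate a synthetic dual ion-count scene
#'
#' Composites the configured structures over the background (later
#' structures overwrite earlier ones only when `allowOverwrite = TRUE`;
#' conflicting overlaps are otherwise an error), then draws independent
#' Poisson counts per pixel for each ion species around the local expected
#' counts. The scene seed fully determines the output.
#'
#' @param config a [SceneConfig-class].
#' @param allowOverwrite let later structures overwrite earlier ones where
#'   they overlap (default `FALSE`).
#' @return list with `image` (an [IonCountImage-class]) and `truth`: the
#'   structure label matrix, a per-structure table (`label`, `component`,
#'   `true_atom_percent`, `true_ratio`, `lambda_total`, `n_pixels`) and the
#'   scene seed.
#' @export
simulateScene <- function(config, allowOverwrite = FALSE) {
  stopifnot(methods::is(config, "SceneConfig"))
  set.seed(as.integer(config@seed))
  dim <- as.integer(config@dim)
  grid <- .pixelGrid(dim)
  pMap <- matrix(config@backgroundAtomPercent, dim[1], dim[2])
  lamMap <- matrix(config@backgroundLambda, dim[1], dim[2])
  labels <- matrix(0L, dim[1], dim[2])
  sts <- config@structures
  for (i in seq_along(sts)) {
    mask <- .rasterize(sts[[i]], grid)
    if (!any(mask))
      stop("structure ", i, " rasterises to zero pixels", call. = FALSE)
    clash <- mask & labels > 0
    if (any(clash) && !allowOverwrite)
      stop(sprintf("structure %d overlaps structure %d; set allowOverwrite to composite",
                   i, labels[which(clash)[1]]), call. = FALSE)
    labels[mask] <- i
    pMap[mask] <- sts[[i]]$atomPercent
    lamMap[mask] <- sts[[i]]$lambdaTotal
  }
  lamMinor <- lamMap * pMap / 100
  lamMajor <- lamMap * (1 - pMap / 100)
  n <- prod(dim)
  minor <- matrix(stats::rpois(n, lamMinor), dim[1], dim[2])
  major <- matrix(stats::rpois(n, lamMajor), dim[1], dim[2])
  truthTab <- if (length(sts)) data.frame(
    label = seq_along(sts),
    component = vapply(sts, `[[`, "", "component"),
    shape = vapply(sts, `[[`, "", "shape"),
    true_atom_percent = vapply(sts, `[[`, 0, "atomPercent"),
    true_ratio = vapply(sts, function(s)
      ratioFromAtomPercent(s$atomPercent), 0),
    lambda_total = vapply(sts, `[[`, 0, "lambdaTotal"),
    n_pixels = as.integer(tabulate(labels[labels > 0], length(sts))))
  else data.frame(label = integer(), component = character(),
                  shape = character(), true_atom_percent = numeric(),
                  true_ratio = numeric(), lambda_total = numeric(),
                  n_pixels = integer())
  list(image = IonCountImage(minor, major),
       truth = list(labels = labels, table = truthTab,
                    seed = as.integer(config@seed)))
}

#' RoiSet from simulated ground truth
#'
#' Wraps a simulated scene's structure label matrix and truth table into
#' the [RoiSet-class] the ROI pipeline consumes; ROI ids are
#' `<sectionId>_r<label>`.
#'
#' @param truth the `truth` element returned by [simulateScene()].
#' @param sectionId,segment,site annotation fields for every ROI.
#' @return a [RoiSet-class].
#' @export
truthRoiSet <- function(truth, sectionId, segment = "green", site = "sim") {
  tab <- truth$table
  RoiSet(truth$labels,
         data.frame(label = tab$label,
                    roi_id = sprintf("%s_r%02d", sectionId, tab$label),
                    component = tab$component, section_id = sectionId,
                    segment = segment, site = site))
}

#' Regular disk-grid calibration scene
#'
#' A scene of identical disks on a regular grid, one per requested true
#' atom % value — the workhorse for caller calibration (type-I error,
#' power, parameter recovery), where each disk is one ROI with a known
#' truth and ~`lambdaTotal * disk area` total counts.
#'
#' @param atomPercents vector of true atom % values, one disk each (recycle
#'   with `rep()` for replicates).
#' @param component component label given to every disk.
#' @param radius disk radius px (default 10, ~314 px area).
#' @param lambdaTotal mean total counts per pixel (default 330; with the
#'   default radius about 1e5 counts per ROI).
#' @param dim image size; must fit all disks.
#' @param seed scene seed.
#' @inheritParams sceneConfig
#' @return a [SceneConfig-class].
#' @export
diskGridConfig <- function(atomPercents, component = "bacterium",
                           radius = 10, lambdaTotal = 330,
                           dim = c(512, 512), seed,
                           backgroundLambda = 80) {
  spacing <- 2 * radius + 6
  centers <- seq(radius + 3, min(dim) - radius - 3, by = spacing)
  slots <- expand.grid(row = centers, col = centers)
  if (length(atomPercents) > nrow(slots))
    stop("too many disks for the image size", call. = FALSE)
  sts <- lapply(seq_along(atomPercents), function(i)
    sceneDisk(slots$row[i], slots$col[i], radius, component,
              atomPercents[i], lambdaTotal))
  sceneConfig(sts, dim = dim, backgroundLambda = backgroundLambda,
              seed = seed)
}

#' Simulate per-ROI count pairs directly
#'
#' Draws ROI-level summed counts without rasterising a scene: the sum of
#' independent per-pixel Poisson counts over an ROI is itself Poisson with
#' the summed mean, so ROI-level draws are distributionally identical to
#' aggregating a simulated image — and much faster for calibration runs
#' with hundreds of ROIs.
#'
#' @param n number of ROIs.
#' @param atomPercent true atom % 15N (scalar or length-`n`).
#' @param totalCounts expected total counts per ROI (lambda x area).
#' @param component,sectionId,segment,site annotation fields.
#' @return data.frame in the [roiStats()] schema.
#' @export
simulateRoiCounts <- function(n, atomPercent, totalCounts,
                              component = "bacterium", sectionId = "sim",
                              segment = "green", site = "sim") {
  p <- rep_len(atomPercent, n) / 100
  lam <- rep_len(totalCounts, n)
  sumMinor <- stats::rpois(n, lam * p)
  sumMajor <- stats::rpois(n, lam * (1 - p))
  evaluable <- sumMajor > 0
  out <- data.frame(roi_id = sprintf("%s_r%04d", sectionId, seq_len(n)),
                    component = component, section_id = sectionId,
                    segment = segment, site = site,
                    n_pixels = NA_integer_,
                    sum_minor = sumMinor, sum_major = sumMajor,
                    ratio = NA_real_, atom_percent = NA_real_,
                    sigma_atom_percent = NA_real_,
                    zero_minor_flag = FALSE, evaluable = evaluable)
  if (any(evaluable)) {
    cs <- countStatistics(sumMinor[evaluable], sumMajor[evaluable])
    out$ratio[evaluable] <- cs$ratio
    out$atom_percent[evaluable] <- cs$atom_percent
    out$sigma_atom_percent[evaluable] <- cs$sigma_atom_percent
    out$zero_minor_flag[evaluable] <- cs$zero_minor_flag
  }
  out
}
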