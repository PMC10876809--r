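# Seeded synthetic longitudinal brain phantoms: paired prior/current volumes
# with enhancing ellipsoidal lesions, a known rigid inter-scan transform,
# Gaussian noise, and scripted change scenarios (existing with growth or
# shrinkage, new, disappeared). The scene is analytic (ellipsoids evaluated at
# world coordinates), so the prior volume is rendered directly at transformed
# coordinates and the pair is misaligned by exactly the configured offset.

#' Phantom study configuration
#'
#' @param grid_shape voxels per axis, each >= 32.
#' @param spacing_mm voxel spacing per axis (mm), all > 0.
#' @param n_existing,n_new,n_disappeared lesion counts (>= 0): lesions present
#'   at both timepoints, only in the current scan, and only in the prior scan.
#' @param diameter_range_mm range of sphere-equivalent lesion diameters; the
#'   minimum must be at least twice the largest voxel dimension so every
#'   lesion spans multiple voxels.
#' @param growth_factor_range range of current/prior volume ratios drawn for
#'   existing lesions (> 0; values < 1 are shrinkage).
#' @param lesion_contrast lesion-minus-tissue intensity, in units of
#'   \code{noise_sigma} (> 0).
#' @param noise_sigma additive Gaussian noise standard deviation (a.u., > 0).
#' @param rigid_offset numeric(6): rotations (radians, about x/y/z) then
#'   translations (mm) of the true prior-to-current rigid transform. Defaults
#'   stay within rigid-registration capture range (<= 5 degrees, <= 10 mm),
#'   as expected for same-patient head scans.
#' @param seed integer; identical config + seed reproduces the study
#'   bit-identically.
#' @return A validated configuration list of class "phantomConfig".
#' @export
phantomConfig <- function(grid_shape = c(64, 64, 64),
                          spacing_mm = c(1, 1, 1),
                          n_existing = 3L, n_new = 1L, n_disappeared = 1L,
                          diameter_range_mm = c(6, 14),
                          growth_factor_range = c(0.5, 2),
                          lesion_contrast = 6,
                          noise_sigma = 10,
                          rigid_offset = c(0.03, -0.02, 0.025, 4, -3, 2),
                          seed = 1L) {
  stopifnot(length(grid_shape) == 3, length(spacing_mm) == 3,
            length(diameter_range_mm) == 2, length(growth_factor_range) == 2,
            length(rigid_offset) == 6)
  if (any(grid_shape < 32)) stop("grid_shape must be >= 32 voxels per axis")
  if (any(spacing_mm <= 0)) stop("spacing_mm must be positive")
  if (n_existing < 0 || n_new < 0 || n_disappeared < 0)
    stop("lesion counts must be >= 0")
  if (diameter_range_mm[1] > diameter_range_mm[2] ||
      diameter_range_mm[1] < 2 * max(spacing_mm))
    stop("diameter_range_mm minimum must be >= 2 * max(spacing_mm)")
  if (any(growth_factor_range <= 0) ||
      growth_factor_range[1] > growth_factor_range[2])
    stop("growth_factor_range must be positive and ordered")
  if (lesion_contrast <= 0) stop("lesion_contrast must be > 0")
  if (noise_sigma <= 0) stop("noise_sigma must be > 0")
  structure(list(
    grid_shape = as.integer(grid_shape), spacing_mm = as.numeric(spacing_mm),
    n_existing = as.integer(n_existing), n_new = as.integer(n_new),
    n_disappeared = as.integer(n_disappeared),
    diameter_range_mm = as.numeric(diameter_range_mm),
    growth_factor_range = as.numeric(growth_factor_range),
    lesion_contrast = as.numeric(lesion_contrast),
    noise_sigma = as.numeric(noise_sigma),
    rigid_offset = as.numeric(rigid_offset), seed = as.integer(seed)
  ), class = "phantomConfig")
}

TISSUE_BASE <- 100      # mean tissue intensity, a.u.
TISSUE_RIPPLE <- 0.15   # relative amplitude of the low-frequency field
# brain semi-axes as fractions of the grid extent; deliberately unequal so
# the phantom head, like a real one, has no rotational symmetry
BRAIN_FRACTION <- c(0.45, 0.40, 0.34)
LESION_SEP_MM <- 3      # minimum clearance between lesion surfaces
BLUR_FWHM_VOX <- 1      # one-voxel FWHM smoothing of the rendered scene

# smooth low-frequency tissue non-uniformity: sum of 3 fixed 3D cosines
tissueField <- function(pts) {
  TISSUE_BASE * (1 + TISSUE_RIPPLE * (
    cos(2 * pi * (pts[, 1] / 29 + pts[, 2] / 47) + 0.7) +
    cos(2 * pi * (pts[, 2] / 37 - pts[, 3] / 31) + 2.1) +
    cos(2 * pi * (pts[, 3] / 43 + pts[, 1] / 41) + 4.0)))
}

insideEllipsoid <- function(pts, center, semi) {
  ((pts[, 1] - center[1]) / semi[1])^2 +
    ((pts[, 2] - center[2]) / semi[2])^2 +
    ((pts[, 3] - center[3]) / semi[3])^2 <= 1
}

# render intensities (pre-blur, pre-noise) and the label mask at world points
renderScene <- function(pts, brainSemi, lesions, contrast_au) {
  brain <- insideEllipsoid(pts, c(0, 0, 0), brainSemi)
  intensity <- numeric(nrow(pts))
  intensity[brain] <- tissueField(pts[brain, , drop = FALSE])
  labels <- numeric(nrow(pts))
  for (les in lesions) {
    inside <- insideEllipsoid(pts, les$center, les$semi)
    intensity[inside] <- tissueField(pts[inside, , drop = FALSE]) + contrast_au
    labels[inside] <- les$label
  }
  list(intensity = intensity, labels = labels)
}

#' Generate one synthetic longitudinal phantom study
#'
#' Builds a smooth ellipsoidal "brain" on a dark background, places
#' non-overlapping hyperintense ellipsoidal lesions (axis ratios in
#' [0.7, 1.3]) by rejection sampling, renders the current scan on its grid and
#' the prior scan through the true rigid transform (so the pair is misaligned
#' by exactly \code{rigid_offset}), smooths the rendered scene with a
#' one-voxel-FWHM Gaussian, and adds voxelwise Gaussian noise. Existing
#' lesions reappear at the transformed location with volume scaled by a draw
#' from \code{growth_factor_range}; disappeared lesions are absent from the
#' current scan and new lesions from the prior scan.
#'
#' @param config a configuration from \code{\link{phantomConfig}}.
#' @return A \linkS4class{PhantomStudy} with ground-truth label masks,
#'   transform, matching edges and change classes.
#' @export
generateStudy <- function(config) {
  stopifnot(inherits(config, "phantomConfig"))
  set.seed(config$seed)
  extent <- config$grid_shape * config$spacing_mm
  brainSemi <- BRAIN_FRACTION * extent
  nTot <- config$n_existing + config$n_new + config$n_disappeared
  types <- rep(c("existing", "disappeared", "new"),
               c(config$n_existing, config$n_disappeared, config$n_new))

  lesions <- list()
  for (k in seq_len(nTot)) {
    placed <- FALSE
    for (attempt in seq_len(1000)) {
      d <- runif(1, config$diameter_range_mm[1], config$diameter_range_mm[2])
      ax <- runif(3, 0.7, 1.3)
      ax <- ax / prod(ax)^(1 / 3)           # volume-preserving axis ratios
      g <- runif(1, config$growth_factor_range[1],
                 config$growth_factor_range[2])
      growOrShrink <- if (types[k] == "existing") max(1, g^(1 / 3)) else 1
      semiPrior <- d / 2 * ax
      maxR <- max(semiPrior) * growOrShrink
      # uniform in the brain ellipsoid shrunk by the lesion radius + margin
      u <- runif(3, -1, 1)
      if (sum(u^2) > 1) next
      margin <- (maxR + max(config$spacing_mm)) / brainSemi
      if (any(margin >= 1)) stop(
        "lesion placement impossible: diameter_range_mm too large for grid_shape")
      center <- u * brainSemi * (1 - margin)
      ok <- TRUE
      for (other in lesions) {
        minDist <- maxR + other$maxR + LESION_SEP_MM
        if (sqrt(sum((center - other$center)^2)) < minDist) { ok <- FALSE; break }
      }
      if (!ok) next
      lesions[[k]] <- list(center = center, semiPrior = semiPrior,
                           growth = g, type = types[k], maxR = maxR,
                           diameter = d)
      placed <- TRUE
      break
    }
    if (!placed) stop(
      "failed to place lesion ", k, " after 1000 attempts; relax ",
      "diameter_range_mm, reduce the lesion counts, or enlarge grid_shape")
  }

  t6 <- config$rigid_offset
  gtT <- rigidTransform(t6[1:3], t6[4:6], center = c(0, 0, 0))

  priorSet <- Filter(function(l) l$type %in% c("existing", "disappeared"),
                     lesions)
  currentSet <- Filter(function(l) l$type %in% c("existing", "new"), lesions)
  currentSet <- lapply(currentSet, function(l) {
    if (l$type == "existing") l$semi <- l$semiPrior * l$growth^(1 / 3)
    else l$semi <- l$semiPrior
    l
  })
  priorSet <- lapply(priorSet, function(l) { l$semi <- l$semiPrior; l })

  # deterministic labels: descending volume, ties by lexicographic centroid
  assignLabels <- function(set) {
    if (!length(set)) return(set)
    vol <- vapply(set, function(l) prod(l$semi), numeric(1))
    cx <- vapply(set, function(l) l$center[1], numeric(1))
    cy <- vapply(set, function(l) l$center[2], numeric(1))
    cz <- vapply(set, function(l) l$center[3], numeric(1))
    ord <- order(-vol, cx, cy, cz)
    for (i in seq_along(ord)) set[[ord[i]]]$label <- as.numeric(i)
    set
  }
  priorSet <- assignLabels(priorSet)
  currentSet <- assignLabels(currentSet)

  contrast_au <- config$lesion_contrast * config$noise_sigma
  geom <- volumeImage(array(0, config$grid_shape), spacing = config$spacing_mm)
  ptsCur <- gridWorldCoords(geom)
  sceneCur <- renderScene(ptsCur, brainSemi, currentSet, contrast_au)
  ptsPri <- transformPoints(gtT, ptsCur)  # prior grid shares current's shape
  scenePri <- renderScene(ptsPri, brainSemi, priorSet, contrast_au)

  sigmaVox <- rep(BLUR_FWHM_VOX / (2 * sqrt(2 * log(2))), 3)
  toVol <- function(intensity) {
    v <- array(intensity, config$grid_shape)
    v <- .gaussian_blur3d(v, sigmaVox)
    v + array(rnorm(length(v), 0, config$noise_sigma), config$grid_shape)
  }
  curVol <- volumeImage(toVol(sceneCur$intensity), spacing = config$spacing_mm)
  priVol <- volumeImage(toVol(scenePri$intensity), spacing = config$spacing_mm)
  curMask <- labelMask(array(sceneCur$labels, config$grid_shape), geom)
  priMask <- labelMask(array(scenePri$labels, config$grid_shape), geom)

  findLabel <- function(set, les)
    vapply(set, function(l) isTRUE(all.equal(l$center, les$center)),
           logical(1))
  edges <- data.frame(prior = integer(0), current = integer(0))
  for (l in priorSet) {
    if (l$type != "existing") next
    j <- which(findLabel(currentSet, l))
    edges <- rbind(edges, data.frame(prior = l$label,
                                     current = currentSet[[j]]$label))
  }
  classes <- rbind(
    if (length(priorSet)) data.frame(
      timepoint = "prior",
      label = vapply(priorSet, `[[`, numeric(1), "label"),
      class = vapply(priorSet, function(l)
        if (l$type == "existing") "existing" else "disappeared", character(1)))
    else NULL,
    if (length(currentSet)) data.frame(
      timepoint = "current",
      label = vapply(currentSet, `[[`, numeric(1), "label"),
      class = vapply(currentSet, function(l)
        if (l$type == "existing") "existing" else "new", character(1)))
    else NULL)
  if (is.null(classes))
    classes <- data.frame(timepoint = character(0), label = numeric(0),
                          class = character(0))

  new("PhantomStudy", priorVolume = priVol, currentVolume = curVol,
      priorMask = priMask, currentMask = curMask, gtTransform = gtT,
      gtEdges = edges, gtClasses = classes, config = unclass(config))
}

#' Write a phantom study to disk
#'
#' Writes the two volumes and label masks as NIfTI (.nii.gz) plus a JSON
#' sidecar with the true edges, change classes, rigid transform (6 numbers)
#' and a config echo.
#'
#' @param study A \linkS4class{PhantomStudy}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeVolume(study@priorVolume, file.path(dir, "prior.nii.gz"))
  writeVolume(study@currentVolume, file.path(dir, "current.nii.gz"))
  writeVolume(study@priorMask, file.path(dir, "prior_mask.nii.gz"))
  writeVolume(study@currentMask, file.path(dir, "current_mask.nii.gz"))
  jsonlite::write_json(list(
    gt_transform = c(study@gtTransform@angles, study@gtTransform@translation),
    gt_edges = study@gtEdges, gt_classes = study@gtClasses,
    config = study@config
  ), file.path(dir, "ground_truth.json"), digits = NA, auto_unbox = FALSE)
  invisible(dir)
}
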