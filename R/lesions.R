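# From probability maps to discrete lesions: thresholding, 26-connected
# component extraction with brain-ROI and minimum-size filtering, and the
# sphere-equivalent diameter convention used for size stratification.

#' Threshold a probability map
#'
#' @param probMap \linkS4class{VolumeImage} with values in [0, 1].
#' @param threshold value strictly inside (0, 1); voxels with probability
#'   \code{>= threshold} (ties included) become foreground.
#' @return A \linkS4class{BinaryMask}.
#' @export
binarize <- function(probMap, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be strictly inside (0, 1)")
  v <- probMap@voxels
  if (min(v) < 0 || max(v) > 1) stop("probability map values must be in [0, 1]")
  binaryMask((v >= threshold) * 1, probMap)
}

#' Sphere-equivalent diameter from a volume in cc
#'
#' The diameter of the sphere with the same volume:
#' d = (6 V / pi)^(1/3) with V in mm^3 (1 cc = 1000 mm^3).
#'
#' @param volume_cc lesion volume in cc (>= 0).
#' @return diameter in mm.
#' @export
equivDiameter <- function(volume_cc) {
  if (any(volume_cc < 0)) stop("volume must be non-negative")
  (6000 * volume_cc / pi)^(1 / 3)
}

#' Volume (cc) of a sphere of the given diameter
#' @param diameter_mm sphere diameter in mm (>= 0).
#' @return volume in cc: (pi/6) d^3 / 1000.
#' @export
diameterVolume <- function(diameter_mm) {
  if (any(diameter_mm < 0)) stop("diameter must be non-negative")
  pi / 6 * diameter_mm^3 / 1000
}

#' Extract discrete lesions from a binary mask
#'
#' Labels 26-connected components, removes components whose centroid lies
#' outside the brain ROI and components smaller than \code{minVoxels}, and
#' relabels the survivors 1..n in descending volume order (ties broken by
#' lexicographic world centroid).
#'
#' @param mask A \linkS4class{BinaryMask}.
#' @param roi brain \linkS4class{BinaryMask} on the same grid (NULL disables
#'   the ROI filter).
#' @param timepoint "prior" or "current" tag carried by the result.
#' @param minVoxels minimum component size in voxels (default 2 suppresses
#'   single-voxel noise).
#' @param connectivity 26 (default; compact metastases) or 6.
#' @return A \linkS4class{LesionSet}; empty masks give an empty set.
#' @export
extractLesions <- function(mask, roi = NULL, timepoint = "current",
                           minVoxels = 2L, connectivity = 26L) {
  stopifnot(is(mask, "BinaryMask"))
  lab <- .label_components(mask@voxels, as.integer(connectivity))
  d <- dim(mask@voxels)
  voxVol <- prod(mask@spacing)  # mm^3
  n <- max(lab)
  rows <- list()
  keptVoxels <- list()
  for (k in seq_len(n)) {
    idx <- which(lab == k)
    if (length(idx) < minVoxels) next
    ijk <- arrayInd(idx, d) - 1  # 0-based
    centroidWorld <- colMeans(voxelToWorld(mask, ijk))
    if (!is.null(roi)) {
      cv <- round(worldToVoxel(roi, matrix(centroidWorld, 1))) + 1
      inside <- all(cv >= 1) && all(cv <= dim(roi@voxels)) &&
        roi@voxels[cv[1], cv[2], cv[3]] == 1
      if (!inside) next
    }
    vol_cc <- length(idx) * voxVol / 1000
    rows[[length(rows) + 1]] <- data.frame(
      n_voxels = length(idx), volume_cc = vol_cc,
      diameter_mm = equivDiameter(vol_cc),
      centroid_x = centroidWorld[1], centroid_y = centroidWorld[2],
      centroid_z = centroidWorld[3])
    keptVoxels[[length(keptVoxels) + 1]] <- idx
  }
  labOut <- array(0, d)
  if (length(rows)) {
    tab <- do.call(rbind, rows)
    ord <- order(-tab$volume_cc, tab$centroid_x, tab$centroid_y,
                 tab$centroid_z)
    tab <- tab[ord, , drop = FALSE]
    keptVoxels <- keptVoxels[ord]
    tab$id <- seq_len(nrow(tab))
    tab$timepoint <- timepoint
    rownames(tab) <- NULL
    for (i in seq_along(keptVoxels)) labOut[keptVoxels[[i]]] <- i
    tab <- tab[, c("id", "timepoint", "n_voxels", "volume_cc", "diameter_mm",
                   "centroid_x", "centroid_y", "centroid_z")]
  } else {
    tab <- data.frame(id = integer(0), timepoint = character(0),
                      n_voxels = integer(0), volume_cc = numeric(0),
                      diameter_mm = numeric(0), centroid_x = numeric(0),
                      centroid_y = numeric(0), centroid_z = numeric(0))
  }
  new("LesionSet", labels = labelMask(labOut, mask), table = tab,
      timepoint = timepoint)
}

#' Convert a ground-truth label mask to a LesionSet
#'
#' @param labels A \linkS4class{LabelMask} (e.g. from a phantom study).
#' @param timepoint "prior" or "current".
#' @return A \linkS4class{LesionSet}; existing label identities are replaced
#'   by the canonical descending-volume labelling.
#' @export
lesionSetFromLabels <- function(labels, timepoint) {
  extractLesions(binaryMask((labels@voxels > 0) * 1, labels), roi = NULL,
                 timepoint = timepoint, minVoxels = 1L)
}

#' Stratify lesions into the standard size classes
#'
#' Produces the four overlapping diameter classes used throughout the
#' evaluation: "> 10 mm", "> 5 mm", "< 10 mm" and "All". Membership is by
#' strict inequality on the sphere-equivalent diameter, so a lesion of
#' exactly 10 mm falls in neither "> 10 mm" nor "< 10 mm".
#'
#' @param lesions a \linkS4class{LesionSet} or its lesion table.
#' @param thresholds ascending diameter thresholds in mm (default c(5, 10)).
#' @return named list of lesion tables, one per class.
#' @export
stratifyLesions <- function(lesions, thresholds = c(5, 10)) {
  if (is(lesions, "LesionSet")) lesions <- lesions@table
  if (is.unsorted(thresholds)) stop("thresholds must be ascending")
  lo <- thresholds[1]
  hi <- thresholds[2]
  d <- lesions$diameter_mm
  list(
    ">10mm" = lesions[d > hi, , drop = FALSE],
    ">5mm" = lesions[d > lo, , drop = FALSE],
    "<10mm" = lesions[d < hi, , drop = FALSE],
    "All" = lesions
  )
}

#' Write a lesion table as CSV
#' @param lesions A \linkS4class{LesionSet}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeLesionTable <- function(lesions, path) {
  write.csv(lesions@table, path, row.names = FALSE)
  invisible(path)
}
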