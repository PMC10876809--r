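# Volume I/O (NIfTI-1), intensity normalisation, and the brain
# region-of-interest used to filter false-positive lesions outside the brain.

#' Read a 3D NIfTI volume
#'
#' @param path path to a .nii or .nii.gz file.
#' @return A \linkS4class{VolumeImage}. The affine is taken from the image
#'   xform (RAS mm, 0-based voxel indices); spacing is derived from the affine
#'   column norms so the two are exactly consistent.
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI file: ", path,
                                           " (", conditionMessage(e), ")"))
  vox <- array(as.double(img), dim = dim(img))
  if (length(dim(vox)) == 4L && dim(vox)[4] == 1L) {
    dim(vox) <- dim(vox)[1:3]
  } else if (length(dim(vox)) != 3L) {
    stop("expected a 3D scalar volume, got dimensionality ", length(dim(vox)))
  }
  if (anyNA(vox)) stop("volume contains NaN voxels")
  aff <- structure(RNifti::xform(img), code = NULL)
  sp <- sqrt(colSums(aff[1:3, 1:3]^2))
  new("VolumeImage", voxels = vox, spacing = sp, affine = unclass(aff)[1:4, 1:4])
}

#' Write a volume or mask as NIfTI-1
#'
#' @param vol A \linkS4class{VolumeImage} (or mask subclass).
#' @param path output path (.nii or .nii.gz).
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(vol, path) {
  img <- RNifti::asNifti(vol@voxels)
  # pixdim must be set before the qform: the quaternion form stores rotation
  # separately from the voxel scales
  RNifti::pixdim(img) <- vol@spacing
  RNifti::qform(img) <- structure(vol@affine, code = 1L)
  RNifti::sform(img) <- structure(vol@affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Z-score intensity normalisation within a region of interest
#'
#' Maps intensities so the region of interest has mean 0 and unit variance;
#' voxels outside the region are transformed with the same affine map. This is
#' the conditioning applied to every scan before network inference.
#'
#' @param vol A \linkS4class{VolumeImage}.
#' @param roi A \linkS4class{BinaryMask} with at least 100 voxels set.
#' @return A normalised \linkS4class{VolumeImage}.
#' @export
normalizeIntensity <- function(vol, roi) {
  stopifnot(is(roi, "BinaryMask"))
  inside <- vol@voxels[roi@voxels == 1]
  if (length(inside) < 100) stop("roi must contain at least 100 voxels")
  s <- sd(inside)
  if (s < .Machine$double.eps * max(1, abs(mean(inside))) * 10 || s == 0)
    stop("zero intensity variance inside roi")
  new("VolumeImage", voxels = (vol@voxels - mean(inside)) / s,
      spacing = vol@spacing, affine = vol@affine)
}

otsuThreshold <- function(values, nbins = 256L) {
  rng <- range(values)
  if (diff(rng) == 0) stop("cannot threshold a constant volume")
  h <- tabulate(pmin(nbins, 1L + floor((values - rng[1]) / diff(rng) * nbins)),
                nbins)
  p <- h / sum(h)
  centers <- rng[1] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  muT <- mu[nbins]
  between <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  centers[which.max(between)]
}

#' Brain region of interest
#'
#' A coarse brain mask is sufficient to filter out false-positive lesions
#' outside the brain; accurate brain segmentation is not needed. The mask is
#' obtained by Otsu thresholding, keeping the largest 26-connected foreground
#' component, morphological closing with a 3-voxel ball scaled by the voxel
#' spacing, and hole filling. An externally computed mask (e.g. from a
#' dedicated skull-stripping tool) can be supplied instead via \code{mask}.
#'
#' @param vol A \linkS4class{VolumeImage} with a bright contiguous foreground
#'   on a darker background.
#' @param mask optional precomputed \linkS4class{BinaryMask} returned as-is
#'   (after geometry validation).
#' @return A \linkS4class{BinaryMask}, a single connected component without
#'   internal cavities.
#' @export
brainROI <- function(vol, mask = NULL) {
  if (!is.null(mask)) {
    stopifnot(is(mask, "BinaryMask"),
              all(dim(mask@voxels) == dim(vol@voxels)))
    return(mask)
  }
  thr <- otsuThreshold(as.vector(vol@voxels))
  fg <- (vol@voxels > thr) * 1
  if (sum(fg) == 0) stop("empty foreground after thresholding")
  lab <- .label_components(fg, 26L)
  counts <- tabulate(lab[lab > 0])
  keep <- (lab == which.max(counts)) * 1
  storage.mode(keep) <- "double"
  dim(keep) <- dim(vol@voxels)
  r <- 3 * min(vol@spacing)
  closed <- .morph_ball(.morph_ball(keep, r, vol@spacing, TRUE),
                        r, vol@spacing, FALSE)
  filled <- .fill_holes(closed)
  # closing can in principle reconnect debris; keep the largest component
  lab2 <- .label_components(filled, 26L)
  counts2 <- tabulate(lab2[lab2 > 0])
  out <- (lab2 == which.max(counts2)) * 1
  storage.mode(out) <- "double"
  dim(out) <- dim(vol@voxels)
  binaryMask(out, vol)
}
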