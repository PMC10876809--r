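#' @useDynLib longimets, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject is slot setValidity
#' @importFrom stats rnorm runif sd var quantile median t.test optim setNames
#' @importFrom utils write.csv read.csv
NULL

#' VolumeImage: a 3D scalar grid with geometry
#'
#' The basic unit every pipeline stage consumes: a 3D array of intensities
#' (arbitrary units), per-axis voxel spacing in millimetres, and a 4x4 affine
#' mapping 0-based voxel indices (x,y,z order, x fastest) to world RAS
#' coordinates in millimetres.
#'
#' @slot voxels 3D numeric array of intensities.
#' @slot spacing numeric(3), voxel spacing in mm, all positive.
#' @slot affine 4x4 voxel-index-to-world matrix (RAS mm, 0-based indices).
#' @export
setClass("VolumeImage",
  representation(voxels = "array", spacing = "numeric", affine = "matrix"))

setValidity("VolumeImage", function(object) {
  d <- dim(object@voxels)
  if (length(d) != 3L) return("voxels must be a 3D array")
  if (any(d < 1L)) return("all grid dimensions must be >= 1")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be 3 positive values (mm)")
  if (!all(dim(object@affine) == c(4L, 4L)))
    return("affine must be a 4x4 matrix")
  if (abs(det(object@affine)) < 1e-12) return("affine must be invertible")
  cn <- sqrt(colSums(object@affine[1:3, 1:3]^2))
  if (any(abs(cn - object@spacing) > 1e-6))
    return("spacing inconsistent with affine column norms")
  if (anyNA(object@voxels)) return("voxels contain NA/NaN")
  TRUE
})

#' BinaryMask: a strictly 0/1 mask sharing a VolumeImage geometry
#' @export
setClass("BinaryMask", contains = "VolumeImage")

setValidity("BinaryMask", function(object) {
  v <- object@voxels
  if (!all(v %in% c(0, 1))) return("mask values must be strictly 0/1")
  TRUE
})

#' LabelMask: an integer-labelled mask (0 = background, k = lesion k)
#' @export
setClass("LabelMask", contains = "VolumeImage")

setValidity("LabelMask", function(object) {
  v <- object@voxels
  if (any(v < 0) || any(v != round(v)))
    return("label values must be non-negative integers")
  TRUE
})

#' RigidTransform: rotation + translation in world millimetres
#'
#' Parameterised by three Euler angles (radians) applied in x-then-y-then-z
#' order about a fixed rotation centre, plus a world-frame translation:
#' T(x) = R (x - c) + c + t with R = Rz Ry Rx.
#'
#' @slot angles numeric(3), rotations about x, y, z in radians.
#' @slot translation numeric(3), mm.
#' @slot center numeric(3), rotation centre in world mm.
#' @export
setClass("RigidTransform",
  representation(angles = "numeric", translation = "numeric",
                 center = "numeric"))

setValidity("RigidTransform", function(object) {
  if (length(object@angles) != 3L) return("angles must have length 3")
  if (length(object@translation) != 3L) return("translation must have length 3")
  if (length(object@center) != 3L) return("center must have length 3")
  R <- eulerToMatrix(object@angles)
  if (max(abs(crossprod(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9)
    return("implied rotation matrix is not a proper rotation")
  TRUE
})

#' PhantomStudy: one simulated longitudinal scan pair with full ground truth
#'
#' @slot priorVolume,currentVolume VolumeImage scans at the two timepoints.
#' @slot priorMask,currentMask LabelMask ground-truth lesion masks.
#' @slot gtTransform RigidTransform mapping prior world to current world.
#' @slot gtEdges data.frame(prior, current): true lesion correspondences.
#' @slot gtClasses data.frame(timepoint, label, class): per-lesion change class.
#' @slot config list echo of the generating configuration.
#' @export
setClass("PhantomStudy",
  representation(priorVolume = "VolumeImage", currentVolume = "VolumeImage",
                 priorMask = "LabelMask", currentMask = "LabelMask",
                 gtTransform = "RigidTransform", gtEdges = "data.frame",
                 gtClasses = "data.frame", config = "list"))

setValidity("PhantomStudy", function(object) {
  pl <- setdiff(unique(as.vector(object@priorMask@voxels)), 0)
  cl <- setdiff(unique(as.vector(object@currentMask@voxels)), 0)
  if (nrow(object@gtEdges) &&
      (!all(object@gtEdges$prior %in% pl) || !all(object@gtEdges$current %in% cl)))
    return("gtEdges refer to labels absent from the masks")
  gc <- object@gtClasses
  pc <- gc[gc$timepoint == "prior", ]
  cc <- gc[gc$timepoint == "current", ]
  if (!setequal(pc$label, pl) || !setequal(cc$label, cl))
    return("gtClasses must partition the mask labels")
  if (sum(pc$class == "existing") + sum(pc$class == "disappeared") != length(pl))
    return("prior label count must equal existing + disappeared")
  if (sum(cc$class == "existing") + sum(cc$class == "new") != length(cl))
    return("current label count must equal existing + new")
  TRUE
})

#' SegModel: a multi-channel 3D U-Net segmentation model
#'
#' Encoder-decoder with skip connections; two 3x3x3 convolutions + ReLU per
#' level, 2x max-pool downsampling, nearest-neighbour upsampling, and a final
#' 1x1x1 convolution with per-voxel sigmoid. The first convolution accepts
#' \code{inChannels} registered input channels (the multi-channel input layer
#' is the only difference between the 1-, 2- and 3-channel variants).
#'
#' @slot inChannels integer in {1,2,3}.
#' @slot outChannels integer in {1,2} (current-scan, or prior+current, output).
#' @slot levels integer, resolution levels.
#' @slot baseFilters integer, filters at the top level (doubling per level).
#' @slot weights named list of layer weights.
#' @slot seed integer used for weight initialisation.
#' @export
setClass("SegModel",
  representation(inChannels = "integer", outChannels = "integer",
                 levels = "integer", baseFilters = "integer",
                 weights = "list", seed = "integer"))

setValidity("SegModel", function(object) {
  if (!object@inChannels %in% 1:3) return("inChannels must be 1, 2 or 3")
  if (!object@outChannels %in% 1:2) return("outChannels must be 1 or 2")
  if (object@levels < 1L) return("levels must be >= 1")
  if (object@baseFilters < 1L) return("baseFilters must be >= 1")
  w1 <- object@weights$enc[[1]]$conv1$W
  if (dim(w1)[4] != object@inChannels)
    return("first layer channel count does not match inChannels")
  TRUE
})

#' LesionSet: discrete lesions extracted from one scan
#'
#' @slot labels LabelMask with one integer label per lesion (descending volume).
#' @slot table data.frame with one row per lesion: id, timepoint, n_voxels,
#'   volume_cc, diameter_mm, centroid_x/y/z (world mm).
#' @slot timepoint "prior" or "current".
#' @export
setClass("LesionSet",
  representation(labels = "LabelMask", table = "data.frame",
                 timepoint = "character"))

setValidity("LesionSet", function(object) {
  if (!object@timepoint %in% c("prior", "current"))
    return("timepoint must be 'prior' or 'current'")
  need <- c("id", "timepoint", "n_voxels", "volume_cc", "diameter_mm",
            "centroid_x", "centroid_y", "centroid_z")
  if (!all(need %in% names(object@table)))
    return("lesion table missing required columns")
  lab <- setdiff(unique(as.vector(object@labels@voxels)), 0)
  if (!setequal(lab, object@table$id))
    return("table ids do not match mask labels")
  TRUE
})

#' MatchingGraph: bipartite lesion correspondence graph
#'
#' Nodes are lesion ids at the two timepoints; an edge records a spatial
#' correspondence after registration. Edges found by voxel overlap carry
#' \code{overlap >= 1}; centroid-distance rescue edges carry \code{overlap = 0}
#' and \code{rescued = TRUE}. A node may have 0..k edges (splits and merges
#' are allowed).
#'
#' @slot priorNodes,currentNodes integer lesion ids.
#' @slot edges data.frame(prior, current, overlap, rescued).
#' @export
setClass("MatchingGraph",
  representation(priorNodes = "integer", currentNodes = "integer",
                 edges = "data.frame"))

setValidity("MatchingGraph", function(object) {
  e <- object@edges
  if (nrow(e)) {
    if (!all(e$prior %in% object@priorNodes) ||
        !all(e$current %in% object@currentNodes))
      return("edge endpoints must be graph nodes")
    if (any(!e$rescued & e$overlap < 1))
      return("non-rescued edges must have overlap >= 1 voxel")
  }
  TRUE
})

#' ChangeReport: per-lesion change classes and volumetric change summary
#'
#' @slot classes data.frame(timepoint, id, class) with class in
#'   existing/new/disappeared.
#' @slot groups data.frame of matched groups (connected components of the
#'   matching graph) with prior_cc, current_cc, delta_cc, delta_pct, kind.
#' @slot counts named list of scan-level counts.
#' @slot totals named list of per-scan total volumes (cc).
#' @export
setClass("ChangeReport",
  representation(classes = "data.frame", groups = "data.frame",
                 counts = "list", totals = "list"))

setValidity("ChangeReport", function(object) {
  cl <- object@classes
  pc <- cl[cl$timepoint == "prior", "class"]
  cc <- cl[cl$timepoint == "current", "class"]
  if (length(pc) && !all(pc %in% c("existing", "disappeared")))
    return("prior lesion classes must be existing/disappeared")
  if (length(cc) && !all(cc %in% c("existing", "new")))
    return("current lesion classes must be existing/new")
  n <- object@counts
  if (length(n)) {
    if (n$prior_total != n$existing_prior + n$disappeared)
      return("prior count identity violated")
    if (n$current_total != n$existing_current + n$new)
      return("current count identity violated")
  }
  TRUE
})
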