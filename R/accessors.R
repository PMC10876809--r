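# Accessors and show methods.

#' @rdname accessors
#' @param object,x a longimets S4 object.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' Accessors for longimets objects
#'
#' \code{voxels}, \code{spacing} and \code{affine} expose the grid of a
#' \linkS4class{VolumeImage}; \code{lesionTable} the per-lesion table of a
#' \linkS4class{LesionSet}; \code{graphEdges} the edge table of a
#' \linkS4class{MatchingGraph}; \code{changeClasses}, \code{changeGroups} and
#' \code{changeCounts} the components of a \linkS4class{ChangeReport};
#' \code{gtTransform}, \code{gtEdges} and \code{gtClasses} the ground truth of
#' a \linkS4class{PhantomStudy}.
#'
#' @name accessors
#' @rdname accessors
#' @export
setMethod("voxels", "VolumeImage", function(x) x@voxels)

#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname accessors
#' @export
setMethod("spacing", "VolumeImage", function(x) x@spacing)

#' @rdname accessors
#' @export
setGeneric("affine", function(x) standardGeneric("affine"))

#' @rdname accessors
#' @export
setMethod("affine", "VolumeImage", function(x) x@affine)

#' @rdname accessors
#' @export
setGeneric("lesionTable", function(x) standardGeneric("lesionTable"))

#' @rdname accessors
#' @export
setMethod("lesionTable", "LesionSet", function(x) x@table)

#' @rdname accessors
#' @export
setGeneric("lesionLabels", function(x) standardGeneric("lesionLabels"))

#' @rdname accessors
#' @export
setMethod("lesionLabels", "LesionSet", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @rdname accessors
#' @export
setMethod("graphEdges", "MatchingGraph", function(x) x@edges)

#' @rdname accessors
#' @export
setGeneric("changeClasses", function(x) standardGeneric("changeClasses"))

#' @rdname accessors
#' @export
setMethod("changeClasses", "ChangeReport", function(x) x@classes)

#' @rdname accessors
#' @export
setGeneric("changeGroups", function(x) standardGeneric("changeGroups"))

#' @rdname accessors
#' @export
setMethod("changeGroups", "ChangeReport", function(x) x@groups)

#' @rdname accessors
#' @export
setGeneric("changeCounts", function(x) standardGeneric("changeCounts"))

#' @rdname accessors
#' @export
setMethod("changeCounts", "ChangeReport", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("gtTransform", function(x) standardGeneric("gtTransform"))

#' @rdname accessors
#' @export
setMethod("gtTransform", "PhantomStudy", function(x) x@gtTransform)

#' @rdname accessors
#' @export
setGeneric("gtEdges", function(x) standardGeneric("gtEdges"))

#' @rdname accessors
#' @export
setMethod("gtEdges", "PhantomStudy", function(x) x@gtEdges)

#' @rdname accessors
#' @export
setGeneric("gtClasses", function(x) standardGeneric("gtClasses"))

#' @rdname accessors
#' @export
setMethod("gtClasses", "PhantomStudy", function(x) x@gtClasses)

setMethod("show", "VolumeImage", function(object) {
  d <- dim(object@voxels)
  cat(class(object), sprintf("%d x %d x %d voxels,", d[1], d[2], d[3]),
      sprintf("spacing %.3g x %.3g x %.3g mm\n", object@spacing[1],
              object@spacing[2], object@spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform\n")
  cat(sprintf("  angles (deg): %.3f %.3f %.3f\n",
              object@angles[1] * 180 / pi, object@angles[2] * 180 / pi,
              object@angles[3] * 180 / pi))
  cat(sprintf("  translation (mm): %.3f %.3f %.3f\n",
              object@translation[1], object@translation[2],
              object@translation[3]))
  cat(sprintf("  centre (mm): %.2f %.2f %.2f\n", object@center[1],
              object@center[2], object@center[3]))
})

setMethod("show", "PhantomStudy", function(object) {
  np <- length(setdiff(unique(as.vector(object@priorMask@voxels)), 0))
  nc <- length(setdiff(unique(as.vector(object@currentMask@voxels)), 0))
  cat("PhantomStudy:", np, "prior lesions,", nc, "current lesions,",
      nrow(object@gtEdges), "true matchings\n")
})

setMethod("show", "SegModel", function(object) {
  cat(sprintf("SegModel: %d-channel 3D U-Net, %d levels, %d base filters, %d output channel(s)\n",
              object@inChannels, object@levels, object@baseFilters,
              object@outChannels))
  cat(sprintf("  %d trainable parameters, init seed %d\n",
              modelParameterCount(object), object@seed))
})

setMethod("show", "LesionSet", function(object) {
  cat(sprintf("LesionSet (%s): %d lesion(s), total %.3f cc\n",
              object@timepoint, nrow(object@table),
              sum(object@table$volume_cc)))
})

setMethod("show", "MatchingGraph", function(object) {
  cat(sprintf("MatchingGraph: %d prior node(s), %d current node(s), %d edge(s)\n",
              length(object@priorNodes), length(object@currentNodes),
              nrow(object@edges)))
})

setMethod("show", "ChangeReport", function(object) {
  n <- object@counts
  cat("ChangeReport\n")
  if (length(n)) {
    cat(sprintf("  prior scan: %d lesion(s) (%d existing, %d disappeared)\n",
                n$prior_total, n$existing_prior, n$disappeared))
    cat(sprintf("  current scan: %d lesion(s) (%d existing, %d new)\n",
                n$current_total, n$existing_current, n$new))
  }
  if (length(object@totals))
    cat(sprintf("  total volume: %.3f cc -> %.3f cc\n",
                object@totals$prior_cc, object@totals$current_cc))
})
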