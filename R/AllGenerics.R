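#' @name accessors
#' @title Accessors for volume and skeleton objects
#' @param object a `BinaryVolume`, `IntensityVolume` or `Skeleton`.
#' @description Slot accessors; user code should use these rather than `@`.
NULL

#' @rdname accessors
#' @export
setGeneric("occupancy", function(object) standardGeneric("occupancy"))
#' @rdname accessors
#' @export
setMethod("occupancy", "BinaryVolume", function(object) object@occupancy)

#' @rdname accessors
#' @export
setGeneric("pitch", function(object) standardGeneric("pitch"))
#' @rdname accessors
#' @export
setMethod("pitch", "BinaryVolume", function(object) object@pitch)
#' @rdname accessors
#' @export
setMethod("pitch", "Skeleton", function(object) object@pitch)

#' @rdname accessors
#' @export
setGeneric("voxelValues", function(object) standardGeneric("voxelValues"))
#' @rdname accessors
#' @export
setMethod("voxelValues", "IntensityVolume", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "IntensityVolume", function(object) object@spacing)

#' @rdname accessors
#' @export
setGeneric("nodeCoords", function(object) standardGeneric("nodeCoords"))
#' @rdname accessors
#' @export
setMethod("nodeCoords", "Skeleton", function(object) object@coords)

#' @rdname accessors
#' @export
setGeneric("skeletonEdges", function(object) standardGeneric("skeletonEdges"))
#' @rdname accessors
#' @export
setMethod("skeletonEdges", "Skeleton", function(object) object@edges)

#' @rdname accessors
#' @export
setGeneric("nNodes", function(object) standardGeneric("nNodes"))
#' @rdname accessors
#' @export
setMethod("nNodes", "Skeleton", function(object) nrow(object@coords))

#' Per-node degree of a skeleton
#' @param object a `Skeleton`.
#' @return integer vector, number of incident edges per node.
#' @export
setGeneric("nodeDegree", function(object) standardGeneric("nodeDegree"))
#' @rdname nodeDegree
#' @export
setMethod("nodeDegree", "Skeleton", function(object) {
  tabulate(c(object@edges), nbins = nrow(object@coords))
})

#' Endpoint (degree-one) nodes of a skeleton
#' @param object a `Skeleton`.
#' @return integer vector of node indices with degree one (a single isolated
#'   node counts as an endpoint).
#' @export
setGeneric("endNodes", function(object) standardGeneric("endNodes"))
#' @rdname endNodes
#' @export
setMethod("endNodes", "Skeleton", function(object) {
  deg <- nodeDegree(object)
  if (nrow(object@coords) == 1L) return(1L)
  which(deg == 1L)
})

setMethod("dim", "BinaryVolume", function(x) dim(x@occupancy))
setMethod("dim", "IntensityVolume", function(x) dim(x@values))

setMethod("show", "BinaryVolume", function(object) {
  d <- dim(object@occupancy)
  cat(sprintf("BinaryVolume %d x %d x %d @ %g nm/voxel, %d occupied voxels\n",
              d[1], d[2], d[3], object@pitch, sum(object@occupancy)))
})

setMethod("show", "IntensityVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("IntensityVolume %d x %d x %d, spacing (%g, %g, %g) nm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
})

setMethod("show", "Skeleton", function(object) {
  deg <- nodeDegree(object)
  cat(sprintf(
    "Skeleton: %d nodes, %d edges, %d endpoints, %d junction nodes%s\n",
    nrow(object@coords), nrow(object@edges), sum(deg == 1L), sum(deg >= 3L),
    if (object@lowConfidence) " [low confidence]" else ""))
})

setMethod("show", "SimParams", function(object) {
  cat("SimParams:\n")
  cat(sprintf("  pActivate=%g pAttach=%g pGrow=%g nBarrier=%d\n",
              object@pActivate, object@pAttach, object@pGrow, object@nBarrier))
  cat(sprintf("  pDegrade=%g pDetach=%g punctumLen=%d maxIter=%d\n",
              object@pDegrade, object@pDetach, object@punctumLen,
              object@maxIter))
  cat(sprintf("  growthLaw=%s targetChoice=%s\n", object@growthLaw,
              object@targetChoice))
})

setMethod("show", "NullEnsemble", function(object) {
  cat(sprintf(
    "NullEnsemble: %d/%d trials, mean contacts %.2f, 95%% CI of mean [%.2f, %.2f], trial interval [%g, %g]\n",
    nrow(object@trials), object@nTrials, object@mean, object@ciMean[1],
    object@ciMean[2], object@ciTrials[1], object@ciTrials[2]))
})
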