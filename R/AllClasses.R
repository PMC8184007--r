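#' Binary voxel volume
#'
#' A 3D boolean occupancy grid on an isotropic lattice, the carrier for
#' segmented channels and cell masks. The physical pitch is stored in nm per
#' voxel; the default of 25 nm reflects the resampled super-resolution grids
#' the package is designed around (6 voxels = 150 nm, the optical
#' resolution).
#'
#' @slot occupancy logical 3D array.
#' @slot pitch single positive numeric, nm per voxel (isotropic).
#' @export
setClass("BinaryVolume",
  representation(occupancy = "array", pitch = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@occupancy)) != 3L)
      msg <- c(msg, "occupancy must be a 3D array")
    if (!is.logical(object@occupancy))
      msg <- c(msg, "occupancy must be logical")
    if (length(object@pitch) != 1L || !is.finite(object@pitch) ||
        object@pitch <= 0)
      msg <- c(msg, "pitch must be a single positive number (nm)")
    if (length(msg)) msg else TRUE
  })

#' @param occupancy logical 3D array.
#' @param pitch voxel pitch in nm.
#' @rdname BinaryVolume-class
#' @export
BinaryVolume <- function(occupancy, pitch = 25) {
  storage.mode(occupancy) <- "logical"
  new("BinaryVolume", occupancy = occupancy, pitch = as.numeric(pitch))
}

#' Intensity volume
#'
#' A nonnegative scalar field on a (possibly anisotropic) 3D grid, e.g. a
#' deconvolved fluorescence z-stack. `spacing` is (dz, dy, dx) in nm; stacks
#' are typically collected with 200 nm z spacing and finer xy pitch, and are
#' resampled to an isotropic grid before segmentation.
#'
#' @slot values numeric 3D array (finite, nonnegative).
#' @slot spacing numeric length-3, voxel size (dx, dy, dz) in nm.
#' @export
setClass("IntensityVolume",
  representation(values = "array", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@values)) != 3L)
      msg <- c(msg, "values must be a 3D array")
    if (any(!is.finite(object@values)))
      msg <- c(msg, "values must be finite")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive numbers (nm)")
    if (length(msg)) msg else TRUE
  })

#' @param values numeric 3D array.
#' @param spacing numeric length-3 voxel size in nm (dx, dy, dz).
#' @rdname IntensityVolume-class
#' @export
IntensityVolume <- function(values, spacing) {
  storage.mode(values) <- "double"
  new("IntensityVolume", values = values, spacing = as.numeric(spacing))
}

#' Voxel skeleton graph
#'
#' The medial axis of a binary structure as an undirected spatial graph:
#' nodes are voxel centers (1-based integer grid coordinates), edges join
#' 26-adjacent skeleton voxels. Geodesic distance-from-end labels
#' (`endDistance`, in voxel hops to the nearest degree-one node) are filled
#' in by [endDistances()]; `NA` means not yet computed, `Inf` marks nodes on
#' endpoint-free cycles.
#'
#' @slot coords integer n x 3 matrix of node voxel coordinates (x, y, z).
#' @slot edges integer m x 2 matrix of node indices (each pair 26-adjacent).
#' @slot pitch voxel pitch in nm.
#' @slot endDistance numeric per-node geodesic hop distance to the nearest
#'   endpoint.
#' @slot lowConfidence logical flag set when a junction was untangled from
#'   branches shorter than the nominal 5-node fitting segment.
#' @export
setClass("Skeleton",
  representation(coords = "matrix", edges = "matrix", pitch = "numeric",
                 endDistance = "numeric", lowConfidence = "logical"),
  prototype(endDistance = numeric(), lowConfidence = FALSE),
  validity = function(object) {
    msg <- character()
    if (ncol(object@coords) != 3L) msg <- c(msg, "coords must be n x 3")
    if (nrow(object@edges) > 0) {
      if (ncol(object@edges) != 2L) msg <- c(msg, "edges must be m x 2")
      else {
        a <- object@coords[object@edges[, 1], , drop = FALSE]
        b <- object@coords[object@edges[, 2], , drop = FALSE]
        if (any(abs(a - b) > 1L))
          msg <- c(msg, "edges must join 26-adjacent voxels")
      }
    }
    if (length(object@endDistance) &&
        length(object@endDistance) != nrow(object@coords))
      msg <- c(msg, "endDistance length must match node count")
    if (length(msg)) msg else TRUE
  })

Skeleton <- function(coords, edges, pitch = 25, lowConfidence = FALSE) {
  coords <- matrix(as.integer(coords), ncol = 3,
                   dimnames = list(NULL, c("x", "y", "z")))
  edges <- matrix(as.integer(edges), ncol = 2)
  new("Skeleton", coords = coords, edges = edges, pitch = as.numeric(pitch),
      endDistance = numeric(), lowConfidence = lowConfidence)
}

#' Simulator probability constants
#'
#' Fixed and tunable probabilities of the Monte Carlo engine. Collision
#' constants and `nBarrier`, `pGrow`, `pDetach` carry the canonical defaults;
#' `pActivate`, `pAttach` and `pDegrade` are the biologically variable knobs.
#'
#' `growthLaw` selects how the per-site monomer collision constant
#' `pCollideBcl10` is scheduled against the free monomer pool:
#' \describe{
#'   \item{per_monomer}{each active site receives `Binomial(free, 0.01)`
#'     collisions per iteration, each attaching with the phase probability
#'     (default; see the methods vignette).}
#'   \item{mass_action}{at most one attachment per site per iteration with
#'     probability `min(1, 0.01 * free) * p_phase`.}
#'   \item{per_site}{flat `0.01 * p_phase`, one attachment max.}
#'   \item{hybrid}{mass_action below the nucleation barrier, per_monomer
#'     above it.}
#' }
#'
#' @slot pActivate Carma1 activation probability given a synapse collision.
#' @slot pAttach pre-barrier attachment probability.
#' @slot pGrow post-barrier attachment probability (default 0.4).
#' @slot nBarrier nucleation-barrier size in monomers (default 50).
#' @slot pCollideCarma membrane collision probability of Carma1 (0.1).
#' @slot pCollideBcl10 per-site Bcl10 collision constant (0.01).
#' @slot pCollideAuto autophagosome-filament collision probability (0.1).
#' @slot pAttachAuto autophagosome attachment probability (0.1).
#' @slot pDegrade degradation probability per iteration (variable).
#' @slot pDetach detachment probability when no degradation occurs (0.1).
#' @slot punctumLen structures shorter than this many monomers count as
#'   punctate (default 50 = `nBarrier`, a sub-resolution proxy).
#' @slot maxIter iteration cap (default 10000).
#' @slot growthLaw one of "per_monomer", "mass_action", "per_site",
#'   "hybrid".
#' @slot targetChoice autophagosome target selection, "length" (weighted by
#'   filament length) or "uniform".
#' @export
setClass("SimParams",
  representation(pActivate = "numeric", pAttach = "numeric", pGrow = "numeric",
                 nBarrier = "integer", pCollideCarma = "numeric",
                 pCollideBcl10 = "numeric", pCollideAuto = "numeric",
                 pAttachAuto = "numeric", pDegrade = "numeric",
                 pDetach = "numeric", punctumLen = "integer",
                 maxIter = "integer", growthLaw = "character",
                 targetChoice = "character"),
  prototype(pActivate = 0.5, pAttach = 0.1, pGrow = 0.4, nBarrier = 50L,
            pCollideCarma = 0.1, pCollideBcl10 = 0.01, pCollideAuto = 0.1,
            pAttachAuto = 0.1, pDegrade = 0, pDetach = 0.1, punctumLen = 50L,
            maxIter = 10000L, growthLaw = "per_monomer",
            targetChoice = "length"),
  validity = function(object) {
    ps <- c(object@pActivate, object@pAttach, object@pGrow,
            object@pCollideCarma, object@pCollideBcl10, object@pCollideAuto,
            object@pAttachAuto, object@pDegrade, object@pDetach)
    msg <- character()
    if (any(!is.finite(ps)) || any(ps < 0) || any(ps > 1))
      msg <- c(msg, "all probabilities must lie in [0, 1]")
    if (object@nBarrier < 1L) msg <- c(msg, "nBarrier must be >= 1")
    if (!object@growthLaw %in% c("per_monomer", "mass_action", "per_site", "hybrid"))
      msg <- c(msg, "unknown growthLaw")
    if (!object@targetChoice %in% c("length", "uniform"))
      msg <- c(msg, "targetChoice must be 'length' or 'uniform'")
    if (length(msg)) msg else TRUE
  })

#' @param ... slot values overriding the defaults, e.g.
#'   `SimParams(pActivate = 0.5, pAttach = 0.1, pDegrade = 0.05)`.
#' @rdname SimParams-class
#' @export
SimParams <- function(...) {
  args <- list(...)
  for (nm in c("nBarrier", "punctumLen", "maxIter"))
    if (nm %in% names(args)) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list("SimParams"), args))
}

#' Initial-condition distributions for simulated cells
#'
#' Empirical distributions from which heterogeneous simulated T cells are
#' drawn: Carma1 nucleation sites ~ Gamma(shape 1.59, scale 15.92), synapse
#' fraction ~ Normal(0.40, 0.025), autophagosomes ~ Gamma(shape 4.30, scale
#' 7.90), and the Bcl10 monomer pool ~ Normal(108000, 3600) at endogenous
#' (wild-type) expression. Draws are truncated at zero and counts rounded to
#' integers.
#'
#' @slot siteShape,siteScale gamma parameters of the nucleation-site count.
#' @slot synapseMean,synapseSd normal parameters of the synapse fraction.
#' @slot autoShape,autoScale gamma parameters of the autophagosome count.
#' @slot monomerMean,monomerSd normal parameters of the wild-type monomer
#'   pool.
#' @slot overexprMean,overexprSd normal parameters of the overexpressing
#'   pool (540000 +/- 100000), used when `wildType = FALSE` in
#'   [sampleInitialConditions()].
#' @export
setClass("InitDistributions",
  representation(siteShape = "numeric", siteScale = "numeric",
                 synapseMean = "numeric", synapseSd = "numeric",
                 autoShape = "numeric", autoScale = "numeric",
                 monomerMean = "numeric", monomerSd = "numeric",
                 overexprMean = "numeric", overexprSd = "numeric"),
  prototype(siteShape = 1.59, siteScale = 15.92, synapseMean = 0.40,
            synapseSd = 0.025, autoShape = 4.30, autoScale = 7.90,
            monomerMean = 108000, monomerSd = 3600,
            overexprMean = 540000, overexprSd = 100000),
  validity = function(object) {
    pos <- c(object@siteShape, object@siteScale, object@autoShape,
             object@autoScale, object@synapseSd, object@monomerSd)
    if (any(pos <= 0)) "shape/scale/sd parameters must be positive" else TRUE
  })

#' @param ... slot values overriding the defaults.
#' @rdname InitDistributions-class
#' @export
InitDistributions <- function(...) do.call(new, c(list("InitDistributions"), list(...)))

#' Resampling-null ensemble
#'
#' Per-cell collection of statistics from repeated random rearrangement of
#' segmented autophagosomes inside the cell boundary. Stores per-trial
#' contact counts, puncta-contact counts and pooled end-distance samples,
#' together with the t-based confidence interval of the mean count and the
#' 2.5-97.5 percentile interval of the trial counts (the interval a single
#' observed cell is compared against).
#'
#' @slot trials data.frame with one row per successful trial
#'   (`n_contacts`, `n_puncta_contacts`).
#' @slot endDistances list of per-trial end-distance vectors (voxel hops).
#' @slot nTrials number of requested trials.
#' @slot mean mean null contact count.
#' @slot ciMean t-interval of the mean, `c(lo, hi)`.
#' @slot ciTrials 95 percent percentile interval of per-trial counts.
#' @export
setClass("NullEnsemble",
  representation(trials = "data.frame", endDistances = "list",
                 nTrials = "integer", mean = "numeric", ciMean = "numeric",
                 ciTrials = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@nTrials < 1L) msg <- c(msg, "nTrials must be >= 1")
    if (length(object@ciMean) == 2 && length(object@mean) == 1 &&
        !(object@ciMean[1] <= object@mean && object@mean <= object@ciMean[2]))
      msg <- c(msg, "ciMean must bracket the mean")
    if (length(msg)) msg else TRUE
  })
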