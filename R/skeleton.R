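#' Medial-axis skeleton of a binary structure
#'
#' 3D medial-axis thinning: voxels are removed in order of increasing
#' distance to the background while they remain topologically simple points
#' and are not curve endpoints, until a fixpoint. The result preserves the
#' homotopy type of the structure (a solid torus keeps exactly one cycle)
#' and reduces tubes to one-voxel-wide 26-connected paths.
#'
#' @param structure a [BinaryVolume-class] holding one connected structure.
#' @return a [Skeleton-class].
#' @export
skeletonize <- function(structure) {
  occ <- occupancy(structure)
  if (!any(occ)) stop("cannot skeletonize an empty structure")
  sk <- thin3d_cpp(as.vector(occ), dim(occ))
  sk <- array(sk, dim(occ))
  skeletonFromVoxels(sk, pitch(structure))
}

#' Build a skeleton graph from a voxel set
#'
#' Nodes are the occupied voxels; edges join every 26-adjacent pair.
#'
#' @param voxels logical 3D array (already one voxel wide, e.g. thinning
#'   output) or an n x 3 coordinate matrix.
#' @param pitch voxel pitch in nm.
#' @return a [Skeleton-class].
#' @export
skeletonFromVoxels <- function(voxels, pitch = 25) {
  if (is.matrix(voxels) && ncol(voxels) == 3) {
    coords <- voxels
  } else {
    coords <- which(voxels, arr.ind = TRUE)
    colnames(coords) <- c("x", "y", "z")
  }
  n <- nrow(coords)
  if (n == 0) stop("no skeleton voxels")
  d <- apply(coords, 2, max) + 1L
  key <- function(m) (m[, 1] - 1) + d[1] * ((m[, 2] - 1) + d[2] * (m[, 3] - 1))
  idx <- new.env(hash = TRUE, size = n)
  ks <- key(coords)
  map <- setNames(seq_len(n), as.character(ks))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  half <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & (offs[, 2] > 0 |
           (offs[, 2] == 0 & offs[, 1] > 0))), , drop = FALSE]
  e1 <- integer(); e2 <- integer()
  for (k in seq_len(nrow(half))) {
    nb <- sweep(coords, 2, half[k, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 2] >= 1 & nb[, 3] >= 1
    j <- map[as.character(key(nb[ok, , drop = FALSE]))]
    hit <- !is.na(j)
    e1 <- c(e1, which(ok)[hit])
    e2 <- c(e2, unname(j[hit]))
  }
  Skeleton(coords, cbind(e1, e2), pitch)
}

.skelGraph <- function(skel) {
  g <- igraph::make_empty_graph(nNodes(skel), directed = FALSE)
  if (nrow(skel@edges) > 0)
    g <- igraph::add_edges(g, t(skel@edges))
  g
}

.subSkeleton <- function(skel, keep) {
  keep <- sort(keep)
  newid <- integer(nNodes(skel))
  newid[keep] <- seq_along(keep)
  ed <- skel@edges
  ed <- ed[ed[, 1] %in% keep & ed[, 2] %in% keep, , drop = FALSE]
  Skeleton(skel@coords[keep, , drop = FALSE],
           cbind(newid[ed[, 1]], newid[ed[, 2]]), skel@pitch,
           skel@lowConfidence)
}

## adjacency list (list of integer vectors)
.adjList <- function(skel) {
  n <- nNodes(skel)
  adj <- vector("list", n)
  ed <- skel@edges
  for (i in seq_len(nrow(ed))) {
    a <- ed[i, 1]; b <- ed[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

#' Iteratively prune short terminal spurs
#'
#' Removes terminal branches (degree-one tip up to, and excluding, the first
#' node of degree >= 3) shorter than `min_spur` voxels, repeating until no
#' such spur remains. Spurs arise from surface noise during thinning; the
#' 6-voxel default corresponds to the 150 nm optical resolution at 25 nm
#' pitch. A spur-free simple path is returned unchanged, and pruning never
#' disconnects a skeleton.
#'
#' @param skel a [Skeleton-class].
#' @param min_spur minimum surviving branch length in voxels (default 6).
#' @return a pruned [Skeleton-class].
#' @export
pruneSpurs <- function(skel, min_spur = 6L) {
  repeat {
    deg <- nodeDegree(skel)
    if (!any(deg >= 3L)) return(skel)
    adj <- .adjList(skel)
    leaves <- which(deg == 1L)
    drop <- integer()
    ## are the given nodes 26-connected among themselves?
    connectedSet <- function(v) {
      if (length(v) <= 1) return(TRUE)
      cc <- skel@coords[v, , drop = FALSE]
      dd <- as.matrix(dist(cc, method = "maximum"))
      seen <- c(1L); front <- 1L
      while (length(front)) {
        nb <- which(apply(dd[front, , drop = FALSE] <= 1, 2, any))
        front <- setdiff(nb, seen)
        seen <- union(seen, front)
      }
      length(seen) == length(v)
    }
    for (leaf in leaves) {
      branch <- leaf
      prev <- 0L
      cur <- leaf
      repeat {
        nxt <- setdiff(adj[[cur]], prev)
        if (length(nxt) != 1L) break          # dead end or ambiguity
        prev <- cur
        cur <- nxt
        if (deg[cur] >= 3L) {
          ## `cur` is the spur base. Its external neighbors decide whether
          ## it belongs to the spur (a bump whose neighbors all sit on one
          ## continuous main-body stretch) or is a genuine junction joining
          ## separate arms. The end-to-end spur length counts the base.
          if (length(branch) + 1L < min_spur) {
            drop <- union(drop, branch)
            rest <- setdiff(adj[[cur]], c(branch, cur))
            if (connectedSet(rest)) drop <- union(drop, cur)
          }
          break
        }
        if (deg[cur] == 1L) break             # pure path: not a spur
        branch <- c(branch, cur)
        if (length(branch) >= min_spur) break # long enough: keep
      }
    }
    if (length(drop) == 0) return(skel)
    skel <- .subSkeleton(skel, setdiff(seq_len(nNodes(skel)), drop))
  }
}

#' End-to-end skeleton length in voxels (node count)
#'
#' The number of nodes along the longest geodesic between two endpoints;
#' the voxel-count length used for punctate classification.
#' @param skel a connected [Skeleton-class].
#' @return integer node count (a single voxel counts 1; cycles return the
#'   node count of the whole skeleton).
#' @export
skeletonSpan <- function(skel) {
  n <- nNodes(skel)
  if (n == 1L) return(1L)
  ends <- endNodes(skel)
  if (length(ends) == 0) return(n)
  g <- .skelGraph(skel)
  dm <- igraph::distances(g, v = ends, to = ends)
  dm[!is.finite(dm)] <- -1
  as.integer(max(dm) + 1)
}

#' Classify a skeleton as punctate or filamentous
#'
#' Structurally isolated skeletons shorter than `min_len` voxels (150 nm at
#' the default pitch, the approximate optical resolution) are punctate
#' ("P"); the cutoff is strict (`length < min_len`).
#'
#' @param skel a connected [Skeleton-class].
#' @param min_len punctate cutoff in voxels (default 6).
#' @return `"P"` or `"filament"`.
#' @export
classifyPunctate <- function(skel, min_len = 6L) {
  if (skeletonSpan(skel) < min_len) "P" else "filament"
}

#' Geodesic distance to the nearest skeleton endpoint
#'
#' Per-node minimal hop count (unit edge weight) to any degree-one node,
#' computed by multi-source unweighted shortest paths restricted to the end
#' nodes. On endpoint-free cycles all distances are `Inf` (the "no-end"
#' sentinel, excluded from end-distance statistics).
#'
#' @param skel a [Skeleton-class].
#' @return numeric vector, one distance per node (0 exactly at endpoints).
#' @export
endDistances <- function(skel) {
  n <- nNodes(skel)
  ends <- endNodes(skel)
  if (length(ends) == 0) return(rep(Inf, n))
  if (n == 1L) return(0)
  g <- .skelGraph(skel)
  dm <- igraph::distances(g, v = ends)
  apply(dm, 2, min)
}

## ordered node indices of a simple-path skeleton
.pathOrder <- function(skel) {
  n <- nNodes(skel)
  if (n == 1L) return(1L)
  deg <- nodeDegree(skel)
  if (any(deg > 2L)) stop("skeleton is not a simple path (junction present)")
  ends <- which(deg == 1L)
  if (length(ends) != 2L) stop("skeleton is not a simple path")
  adj <- .adjList(skel)
  ord <- integer(n)
  ord[1] <- min(ends)
  prev <- 0L
  for (i in 2:n) {
    nxt <- setdiff(adj[[ord[i - 1]]], prev)
    prev <- ord[i - 1]
    ord[i] <- nxt[1]
  }
  if (anyNA(ord) || length(unique(ord)) != n)
    stop("skeleton is not a simple path")
  ord
}

#' Length of a simple-path skeleton
#'
#' Two metrics are provided. `"nodes"` counts geodesic hops (node count
#' minus one), the voxel-count convention used for spur pruning and
#' punctate cutoffs; it underestimates obliquely oriented paths. The
#' default `"euclidean"` sums inter-node Euclidean distances after light
#' boxcar smoothing of the node coordinates (window 5), which corrects both
#' the digitization staircase and thinning jitter and tracks the true arc
#' length of curved tubes to within a few percent.
#'
#' @param skel a simple-path [Skeleton-class].
#' @param metric `"euclidean"` or `"nodes"`.
#' @param smooth_window odd boxcar width for the euclidean metric (1 =
#'   no smoothing).
#' @return list with `voxels` (length in voxel units) and `nm`.
#' @export
filamentLength <- function(skel, metric = c("euclidean", "nodes"),
                           smooth_window = 5L) {
  metric <- match.arg(metric)
  n <- nNodes(skel)
  if (n == 1L) return(list(voxels = 0, nm = 0))
  ord <- .pathOrder(skel)
  if (metric == "nodes") {
    L <- n - 1
  } else {
    xyz <- skel@coords[ord, , drop = FALSE]
    if (smooth_window > 1L && n > 2L) {
      h <- (smooth_window - 1L) %/% 2L
      sm <- sapply(1:3, function(cc) {
        sapply(seq_len(n), function(i) {
          w <- max(1, i - h):min(n, i + h)
          mean(skel@coords[ord[w], cc])
        })
      })
      ## pin the endpoints: truncated windows would otherwise pull the tips
      ## inward and shorten every measurement by ~h voxels per end
      sm[1, ] <- xyz[1, ]
      sm[n, ] <- xyz[n, ]
      xyz <- sm
    }
    L <- sum(sqrt(rowSums(diff(xyz)^2)))
  }
  list(voxels = L, nm = L * skel@pitch)
}

#' Skeletonize every labeled structure of a segmented channel
#'
#' Runs [skeletonize()], [pruneSpurs()] and [classifyPunctate()] per
#' 26-connected structure, then [untangleJunctions()] on skeletons that
#' retain junctions after pruning.
#'
#' @param labels integer label array from [labelComponents()].
#' @param pitch voxel pitch in nm.
#' @param min_spur,punctate_len voxel cutoffs (defaults 6).
#' @param untangle logical; untangle remaining junctions into simple paths.
#' @return list with one element per output skeleton:
#'   `list(skeleton, structure, class)` where `structure` is the input
#'   label and `class` is `"P"` or `"filament"`.
#' @export
skeletonizeStructures <- function(labels, pitch = 25, min_spur = 6L,
                                  punctate_len = 6L, untangle = TRUE) {
  nl <- attr(labels, "n_labels")
  out <- list()
  d <- dim(labels)
  for (s in seq_len(nl)) {
    vox <- array(labels == s, d)
    skel <- pruneSpurs(skeletonize(BinaryVolume(vox, pitch)), min_spur)
    parts <- if (untangle && any(nodeDegree(skel) >= 3L))
      untangleJunctions(skel) else list(skel)
    for (p in parts)
      out[[length(out) + 1]] <- list(skeleton = p, structure = s,
                                     class = classifyPunctate(p, punctate_len),
                                     end_distance = endDistances(p))
  }
  out
}
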