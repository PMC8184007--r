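#' Least-squares bending radius through a point sequence
#'
#' Fits the point sequence to a spherical surface and returns the radius of
#' the bent region. Spheres through a (near-)planar curve segment form a
#' one-parameter family whose center slides along the plane normal; the
#' physically meaningful bending radius is the minimal-radius member, whose
#' center lies in the plane of the points. The fit therefore rotates the
#' points into their principal plane and runs a Taubin algebraic circle fit
#' there (near-unbiased for shallow arcs, where the naive Kasa fit
#' collapses to spuriously small radii under digitization noise).
#' Collinear inputs (a straight elastic beam) return `Inf`, for which the
#' bending energy `1/R^2` is exactly 0.
#'
#' @param points numeric matrix (>= 4 rows) of ordered coordinates.
#' @return radius in voxel units, possibly `Inf`.
#' @export
fitSphereRadius <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 4) stop("sphere fit requires at least 4 points")
  ctr <- sweep(points, 2, colMeans(points))
  sv <- svd(ctr)
  if (sv$d[1] < 1e-9 || sv$d[2] / sv$d[1] < 1e-7) return(Inf)  # collinear
  q <- ctr %*% sv$v[, 1:2, drop = FALSE]      # principal-plane coordinates
  R <- .taubinCircleRadius(q[, 1], q[, 2])
  if (!is.finite(R) || R <= 0) Inf else R
}

## Taubin algebraic circle fit (Chernov's formulation); inputs centered.
.taubinCircleRadius <- function(X, Y) {
  Xi <- X - mean(X); Yi <- Y - mean(Y)
  Zi <- Xi^2 + Yi^2
  Mxx <- mean(Xi^2); Myy <- mean(Yi^2); Mxy <- mean(Xi * Yi)
  Mxz <- mean(Xi * Zi); Myz <- mean(Yi * Zi); Mzz <- mean(Zi^2)
  Mz <- Mxx + Myy
  Cov_xy <- Mxx * Myy - Mxy^2
  A3 <- 4 * Mz
  A2 <- -3 * Mz^2 - Mzz
  A1 <- Mzz * Mz + 4 * Cov_xy * Mz - Mxz^2 - Myz^2 - Mz^3
  A0 <- Mxz^2 * Myy + Myz^2 * Mxx - Mzz * Cov_xy -
    2 * Mxz * Myz * Mxy + Mz^2 * Cov_xy
  xnew <- 0; ynew <- 1e20
  for (it in 1:99) {
    yold <- ynew
    ynew <- A0 + xnew * (A1 + xnew * (A2 + xnew * A3))
    if (abs(ynew) > abs(yold)) { xnew <- 0; break }
    Dy <- A1 + xnew * (2 * A2 + xnew * 3 * A3)
    if (Dy == 0) break
    xold <- xnew
    xnew <- xold - ynew / Dy
    if (!is.finite(xnew)) { xnew <- 0; break }
    if (abs((xnew - xold) / (abs(xnew) + 1e-300)) < 1e-12) break
    if (xnew < 0) xnew <- 0
  }
  DET <- xnew^2 - xnew * Mz + Cov_xy
  if (abs(DET) < 1e-12) return(Inf)
  a <- (Mxz * (Myy - xnew) - Myz * Mxy) / DET / 2
  b <- (Myz * (Mxx - xnew) - Mxz * Mxy) / DET / 2
  sqrt(a^2 + b^2 + Mz)
}

## bending energy of joining two branches through a junction point:
## 11-point segment = 5 nodes into each branch + the junction, scored 1/R^2.
.pairEnergy <- function(ptsA, junction, ptsB) {
  seg <- rbind(ptsA[rev(seq_len(nrow(ptsA))), , drop = FALSE],
               junction, ptsB)
  if (nrow(seg) < 4) return(0)   # too short to bend: treat as straight
  R <- fitSphereRadius(seg)
  if (!is.finite(R)) 0 else 1 / R^2
}

## maximal matchings of index vector: all branches paired, except exactly
## one left out when the count is odd.
.maximalMatchings <- function(idx) {
  n <- length(idx)
  if (n == 0) return(list(list()))
  if (n == 1) return(list(list()))
  out <- list()
  if (n %% 2 == 1) {
    for (s in .maximalMatchings(idx[-1])) out[[length(out) + 1]] <- s
    for (k in 2:n) {
      for (s in .maximalMatchings(idx[-c(1, k)]))
        out[[length(out) + 1]] <- c(list(c(idx[1], idx[k])), s)
    }
  } else {
    for (k in 2:n) {
      for (s in .maximalMatchings(idx[-c(1, k)]))
        out[[length(out) + 1]] <- c(list(c(idx[1], idx[k])), s)
    }
  }
  out
}

#' Untangle high-degree junctions into simple filament paths
#'
#' Bcl10 filaments have two ends and no branch points; junctions in measured
#' skeletons are imaging artifacts where filaments overlap within the
#' optical resolution. At each junction (a connected cluster of nodes of
#' degree >= 3) the incident branches are paired by exhaustive search over
#' maximal pairings (capped at degree 8, greedy best-pair-first beyond):
#' each candidate pair is scored by fitting an 11-point segment -- 5 nodes
#' into each branch, in geodesic order, plus the junction -- to a sphere and
#' taking the elastic bending energy `1/R^2`; the pairing with minimal total
#' energy is applied. With an odd branch count one branch terminates at the
#' junction. Equal-energy ties resolve to the lexicographically lowest
#' branch pairing, so outputs are deterministic.
#'
#' At oblique crossing angles medial-axis thinning resolves one physical
#' crossing into two Y-junctions joined by a short bridge along the angle
#' bisector; junction nodes whose connecting chain is shorter than
#' `junction_merge` voxels are therefore merged into a single junction
#' cluster before pairing (the bridge length of a radius-r crossing grows
#' as `2r / tan(angle/2)`, so 16 voxels covers crossings down to ~30
#' degrees for the typical 2-voxel tube radius).
#'
#' @param skel a connected [Skeleton-class].
#' @param junction_merge chains of fewer than this many voxels between
#'   junctions are absorbed into one junction cluster (default 16).
#' @return list of simple-path [Skeleton-class] objects (every node degree
#'   <= 2). Skeletons built from branches shorter than 5 nodes are flagged
#'   low-confidence.
#' @export
untangleJunctions <- function(skel, junction_merge = 16L) {
  deg <- nodeDegree(skel)
  if (!any(deg >= 3L)) return(list(skel))
  n <- nNodes(skel)
  jn <- which(deg >= 3L)
  g <- .skelGraph(skel)
  adj0 <- .adjList(skel)

  ## absorb short junction-junction bridges into the junction set
  repeat {
    rest <- setdiff(seq_len(n), jn)
    gs <- igraph::induced_subgraph(g, rest)
    sm <- igraph::components(gs)$membership
    segnodes <- split(rest, sm)
    grew <- FALSE
    for (v in segnodes) {
      if (length(v) >= junction_merge) next
      sub <- .subSkeleton(skel, v)
      vs <- sort(v)
      tips <- if (length(v) == 1) vs else {
        dsub <- nodeDegree(sub)
        vs[dsub <= 1L]
      }
      touch <- vapply(tips, function(tp)
        length(intersect(adj0[[tp]], jn)) > 0, TRUE)
      nclust <- length(unique(unlist(lapply(tips, function(tp)
        intersect(adj0[[tp]], jn)))))
      if (length(tips) >= 1 && all(touch) && nclust >= 2 &&
          (length(v) == 1 || length(tips) == 2)) {
        jn <- sort(union(jn, v))
        grew <- TRUE
      }
    }
    if (!grew) break
  }

  ## junction clusters: components of the subgraph induced by junction nodes
  gj <- igraph::induced_subgraph(g, jn)
  cl <- igraph::components(gj)$membership
  clusters <- split(jn, cl)

  ## segments: chains of degree <= 2 after junction removal
  rest <- setdiff(seq_len(n), jn)
  gs <- igraph::induced_subgraph(g, rest)
  sm <- igraph::components(gs)$membership
  segnodes <- split(rest, sm)
  ## order each segment as a path
  segs <- lapply(segnodes, function(v) {
    if (length(v) == 1) return(v)
    sub <- .subSkeleton(skel, v)
    sort(v)[.pathOrder(sub)]
  })
  nseg <- length(segs)

  adj <- .adjList(skel)
  lowconf <- FALSE

  ## branch records per cluster: (segment, end, entry junction node)
  links <- vector("list", nseg)      # per segment: list(end1 = , end2 = )
  for (ci in seq_along(clusters)) {
    cn <- clusters[[ci]]
    branches <- list()
    for (si in seq_len(nseg)) {
      sv <- segs[[si]]
      for (endid in unique(c(1L, 2L))) {
        tip <- if (endid == 1L) sv[1] else sv[length(sv)]
        if (length(sv) == 1 && endid == 2L) next
        ents <- intersect(adj[[tip]], cn)
        if (length(ents) == 0) next
        branches[[length(branches) + 1]] <- list(seg = si, end = endid,
                                                 entry = min(ents))
      }
    }
    d <- length(branches)
    if (d < 2) next
    ## energies for all candidate pairs
    jpt <- colMeans(skel@coords[cn, , drop = FALSE])
    bpts <- lapply(branches, function(b) {
      sv <- segs[[b$seg]]
      if (b$end == 2L) sv <- rev(sv)
      take <- head(sv, 5)
      if (length(take) < 5) lowconf <<- TRUE
      skel@coords[take, , drop = FALSE]   # ordered near-junction first
    })
    E <- matrix(0, d, d)
    for (i in seq_len(d - 1)) for (j in (i + 1):d)
      E[i, j] <- E[j, i] <- .pairEnergy(bpts[[i]], jpt, bpts[[j]])

    chosen <- NULL
    if (d <= 8) {
      best <- Inf
      for (m in .maximalMatchings(seq_len(d))) {
        tot <- sum(vapply(m, function(p) E[p[1], p[2]], 0))
        if (tot < best - 1e-12) { best <- tot; chosen <- m }
      }
    } else {
      pairs <- which(upper.tri(E), arr.ind = TRUE)
      pairs <- pairs[order(E[upper.tri(E)]), , drop = FALSE]
      used <- logical(d)
      chosen <- list()
      for (r in seq_len(nrow(pairs))) {
        i <- pairs[r, 1]; j <- pairs[r, 2]
        if (used[i] || used[j]) next
        used[i] <- used[j] <- TRUE
        chosen[[length(chosen) + 1]] <- c(i, j)
      }
    }

    ## connector path through the cluster for each chosen pair
    for (p in chosen) {
      bi <- branches[[p[1]]]; bj <- branches[[p[2]]]
      if (bi$seg == bj$seg) next   # would close a loop on one segment
      conn <- if (bi$entry == bj$entry) bi$entry else {
        sp <- igraph::shortest_paths(gj, from = match(bi$entry, jn),
                                     to = match(bj$entry, jn))$vpath[[1]]
        jn[as.integer(sp)]
      }
      ename <- paste0("end", bi$end)
      links[[bi$seg]][[ename]] <- list(seg = bj$seg, end = bj$end,
                                       connector = conn)
      ename <- paste0("end", bj$end)
      links[[bj$seg]][[ename]] <- list(seg = bi$seg, end = bi$end,
                                       connector = rev(conn))
    }
  }

  ## guard against cycles created by independent clusters: break one link
  ## of any segment chain that closes on itself during assembly
  used <- logical(nseg)
  out <- list()
  for (start in seq_len(nseg)) {
    if (used[start]) next
    ## rewind to a free end if one exists
    si <- start; endid <- 1L
    seen <- c(start)
    repeat {
      lk <- links[[si]][[paste0("end", endid)]]
      if (is.null(lk) || lk$seg %in% seen) break
      seen <- c(seen, lk$seg)
      endid <- if (lk$end == 1L) 2L else 1L
      si <- lk$seg
    }
    ## walk forward from (si, entering at endid)
    seqn <- integer()
    cur <- si; ent <- endid
    repeat {
      used[cur] <- TRUE
      sv <- segs[[cur]]
      if (ent == 2L) sv <- rev(sv)
      seqn <- c(seqn, sv)
      outend <- if (ent == 1L) 2L else 1L
      lk <- links[[cur]][[paste0("end", outend)]]
      if (is.null(lk) || used[lk$seg]) break
      seqn <- c(seqn, lk$connector)
      cur <- lk$seg; ent <- lk$end
    }
    coords <- skel@coords[seqn, , drop = FALSE]
    m <- nrow(coords)
    ed <- if (m > 1) cbind(seq_len(m - 1), 2:m) else
      matrix(integer(), ncol = 2)
    out[[length(out) + 1]] <- Skeleton(coords, ed, skel@pitch, lowconf)
  }
  out
}
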