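#' Configuration for synthetic 3D cell volumes
#'
#' Builds the parameter record consumed by [makeCellMask()],
#' [synthFilaments()] and [synthVesicles()]. Geometry is expressed in voxels
#' at an isotropic pitch (default 25 nm, so 6 voxels = 150 nm). Defaults
#' emulate the scale of activated T cells imaged at super-resolution:
#' an ellipsoidal cell several microns across containing a handful of stiff
#' tubular filaments (radius ~2 voxels, lengths up to ~5 um) and small
#' quasi-spherical vesicles smaller than (0.2 um)^3.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param voxel_pitch_nm isotropic voxel pitch in nm.
#' @param cell_semi_axes numeric length-3 ellipsoid semi-axes in voxels.
#' @param n_filaments number of filaments to draw.
#' @param filament_length_dist list `list(min =, max =)`; centerline lengths
#'   are drawn uniformly in voxels (steps).
#' @param filament_radius tube radius in voxels (>= 1).
#' @param curvature_bound maximum direction change per unit step, degrees;
#'   0 forces straight centerlines.
#' @param n_puncta number of punctate structures (spheres of radius <= 2
#'   voxels recorded in the ground truth) added to the filament channel.
#' @param n_vesicles number of vesicles.
#' @param vesicle_radius_dist list `list(min =, max =)` of radii in voxels.
#' @param placement_mode one of `"uniform"`, `"end_biased"`,
#'   `"puncta_biased"`.
#' @param q for the biased modes, the expected fraction of vesicles placed
#'   touching a filament end (or punctum); in `[0, 1]`.
#' @param allow_crossing logical, permit filaments to overlap each other
#'   (used to synthesize X-crossing test cases).
#' @param seed optional integer seed applied by [synthCell()].
#' @return a list of class `SynthConfig`.
#' @export
synthConfig <- function(grid_shape = c(44L, 44L, 40L), voxel_pitch_nm = 25,
                        cell_semi_axes = c(18, 18, 16), n_filaments = 4L,
                        filament_length_dist = list(min = 15, max = 28),
                        filament_radius = 2, curvature_bound = 10,
                        n_puncta = 0L, n_vesicles = 9L,
                        vesicle_radius_dist = list(min = 2, max = 3),
                        placement_mode = c("uniform", "end_biased",
                                           "puncta_biased"),
                        q = 0, allow_crossing = FALSE, seed = NULL) {
  placement_mode <- match.arg(placement_mode)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1),
            voxel_pitch_nm > 0, length(cell_semi_axes) == 3,
            all(cell_semi_axes >= 0), n_filaments >= 0, n_puncta >= 0,
            n_vesicles >= 0, filament_radius >= 1,
            curvature_bound >= 0, q >= 0, q <= 1)
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_pitch_nm = voxel_pitch_nm,
                 cell_semi_axes = cell_semi_axes,
                 n_filaments = as.integer(n_filaments),
                 filament_length_dist = filament_length_dist,
                 filament_radius = filament_radius,
                 curvature_bound = curvature_bound,
                 n_puncta = as.integer(n_puncta),
                 n_vesicles = as.integer(n_vesicles),
                 vesicle_radius_dist = vesicle_radius_dist,
                 placement_mode = placement_mode, q = q,
                 allow_crossing = allow_crossing, seed = seed),
            class = "SynthConfig")
}

#' Filled ellipsoidal cell mask
#'
#' @param config a `SynthConfig`.
#' @return a [BinaryVolume-class] with a filled ellipsoid centered in the
#'   grid. Degenerate semi-axes (0, 0, 0) give a single center voxel.
#' @export
makeCellMask <- function(config) {
  d <- config$grid_shape
  a <- config$cell_semi_axes
  ctr <- (d + 1) / 2
  for (ax in 1:3)
    if (a[ax] > (d[ax] - 1) / 2)
      stop(sprintf("cell semi-axis %d (%.1f voxels) exceeds grid axis %d (%d voxels)",
                   ax, a[ax], ax, d[ax]))
  a <- pmax(a, 1e-9)
  x <- ((seq_len(d[1]) - ctr[1]) / a[1])^2
  y <- ((seq_len(d[2]) - ctr[2]) / a[2])^2
  z <- ((seq_len(d[3]) - ctr[3]) / a[3])^2
  occ <- outer(outer(x, y, `+`), z, `+`) <= 1
  BinaryVolume(occ, config$voxel_pitch_nm)
}

## ball of voxel offsets with Euclidean radius r (0-based offsets)
.ballOffsets <- function(r) {
  s <- seq(-ceiling(r), ceiling(r))
  g <- as.matrix(expand.grid(x = s, y = s, z = s))
  g[rowSums(g^2) <= r^2 + 1e-9, , drop = FALSE]
}

.stamp <- function(occ, centers, offsets) {
  d <- dim(occ)
  for (i in seq_len(nrow(centers))) {
    v <- sweep(offsets, 2, round(centers[i, ]), `+`)
    ok <- v[, 1] >= 1 & v[, 1] <= d[1] & v[, 2] >= 1 & v[, 2] <= d[2] &
      v[, 3] >= 1 & v[, 3] <= d[3]
    occ[v[ok, , drop = FALSE]] <- TRUE
  }
  occ
}

## all voxels of ball(p, r) inside mask?
.ballInside <- function(mask, p, offsets) {
  d <- dim(mask)
  v <- sweep(offsets, 2, round(p), `+`)
  if (any(v < 1) || any(v[, 1] > d[1]) || any(v[, 2] > d[2]) ||
      any(v[, 3] > d[3])) return(FALSE)
  all(mask[v])
}

## random unit vector
.runitvec <- function() {
  repeat {
    v <- rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

## rotate `v` by angle `ang` (radians) toward a random perpendicular direction
.perturbDir <- function(v, ang) {
  if (ang <= 0) return(v)
  p <- .runitvec()
  p <- p - sum(p * v) * v
  n <- sqrt(sum(p^2))
  if (n < 1e-8) return(v)
  p <- p / n
  cos(ang) * v + sin(ang) * p
}

## rotate `v` toward `target` by at most `ang` radians
.steerDir <- function(v, target, ang) {
  n <- sqrt(sum(target^2))
  if (n < 1e-8) return(v)
  target <- target / n
  cosg <- max(-1, min(1, sum(v * target)))
  gap <- acos(cosg)
  if (gap <= ang) return(target)
  p <- target - cosg * v
  np <- sqrt(sum(p^2))
  if (np < 1e-8) return(v)
  cos(ang) * v + sin(ang) * p / np
}

## binary erosion with the 6-neighborhood, k passes (cheap start-point core)
.erode6 <- function(occ, k) {
  d <- dim(occ)
  for (i in seq_len(k)) {
    er <- occ
    er[-1, , ] <- er[-1, , ] & occ[-d[1], , ]
    er[-d[1], , ] <- er[-d[1], , ] & occ[-1, , ]
    er[, -1, ] <- er[, -1, ] & occ[, -d[2], ]
    er[, -d[2], ] <- er[, -d[2], ] & occ[, -1, ]
    er[, , -1] <- er[, , -1] & occ[, , -d[3]]
    er[, , -d[3]] <- er[, , -d[3]] & occ[, , -1]
    er[1, , ] <- FALSE; er[d[1], , ] <- FALSE
    er[, 1, ] <- FALSE; er[, d[2], ] <- FALSE
    er[, , 1] <- FALSE; er[, , d[3]] <- FALSE
    occ <- er
  }
  occ
}

#' Synthesize tubular filaments inside a cell mask
#'
#' Centerlines are fixed-step (1 voxel) random walks whose direction change
#' per step is uniform within the curvature bound; tubes are the dilation of
#' the centerline by the filament radius, kept wholly inside the mask.
#' Filaments avoid mutual overlap unless `allow_crossing` is set. Optional
#' punctate structures (small spheres) are added to the same channel.
#'
#' @param mask a [BinaryVolume-class] cell mask.
#' @param config a `SynthConfig`.
#' @param max_retries placement retries per filament before giving up.
#' @return `list(volume = BinaryVolume, truth = list(filaments, puncta))`
#'   where each filament record carries its exact centerline (matrix of
#'   points, 1-based voxel coordinates) and arc length in voxels.
#' @export
synthFilaments <- function(mask, config, max_retries = 200) {
  occ <- occupancy(mask)
  if (!any(occ)) stop("mask is empty")
  d <- dim(occ)
  r <- config$filament_radius
  ball <- .ballOffsets(r)
  fil <- array(FALSE, d)
  truth <- list()
  failures <- 0L
  interior <- which(occ)
  core <- which(.erode6(occ, ceiling(r) + 1L))
  if (length(core) == 0) core <- interior
  center <- (d + 1) / 2
  full_tries <- min(20L, ceiling(max_retries / 4))

  for (f in seq_len(config$n_filaments)) {
    L <- round(runif(1, config$filament_length_dist$min,
                     config$filament_length_dist$max))
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      start <- .idx2xyz(core[sample.int(length(core), 1)], d)
      if (!.ballInside(occ, start, ball)) next
      ## head toward the farthest of a few random interior points so that
      ## long filaments find feasible chords
      cand <- t(vapply(interior[sample.int(length(interior),
                                           min(15, length(interior)))],
                       .idx2xyz, numeric(3), d = d))
      far <- cand[which.max(rowSums(sweep(cand, 2, start)^2)), ]
      dirv <- far - start + rnorm(3, 0, 0.5)
      nv <- sqrt(sum(dirv^2))
      dirv <- if (nv > 1e-6) dirv / nv else .runitvec()
      pts <- matrix(NA_real_, L + 1, 3)
      pts[1, ] <- start
      done <- 0L
      for (s in seq_len(L)) {
        ang <- runif(1, 0, config$curvature_bound) * pi / 180
        moved <- FALSE
        for (att in 1:10) {
          ## random turns first; when hemmed in near the boundary, steer
          ## toward the cell center (still within the curvature bound)
          cand_dir <- if (att <= 5) .perturbDir(dirv, ang) else
            .steerDir(dirv, center - pts[s, ],
                      config$curvature_bound * pi / 180)
          cand <- pts[s, ] + cand_dir
          if (.ballInside(occ, cand, ball)) {
            dirv <- cand_dir; pts[s + 1, ] <- cand; moved <- TRUE; break
          }
          if (config$curvature_bound <= 0) break   # straight walk cannot turn
          ang <- runif(1, 0, config$curvature_bound) * pi / 180
        }
        if (!moved) break
        done <- s
      }
      ## prefer the full requested length; after a few attempts accept a
      ## boundary-clipped walk covering most of it (the truth records the
      ## realized arc length)
      if (done < L && try <= full_tries) next
      if (done < max(4L, ceiling(0.6 * L))) next
      pts <- pts[seq_len(done + 1L), , drop = FALSE]
      tube <- array(FALSE, d)
      tube <- .stamp(tube, pts, ball)
      tube <- tube & occ
      if (!config$allow_crossing && any(tube & fil)) next
      fil <- fil | tube
      truth[[length(truth) + 1]] <- list(
        id = length(truth) + 1L, centerline = pts,
        length_voxels = sum(sqrt(rowSums(diff(pts)^2))))
      placed <- TRUE
      break
    }
    if (!placed) failures <- failures + 1L
  }
  if (failures > 0)
    stop(sprintf("failed to place %d of %d filaments after %d retries each",
                 failures, config$n_filaments, max_retries))

  puncta <- list()
  if (config$n_puncta > 0) {
    pball <- .ballOffsets(min(2, r))
    for (p in seq_len(config$n_puncta)) {
      for (try in seq_len(max_retries)) {
        ctr <- .idx2xyz(interior[sample.int(length(interior), 1)], d)
        if (!.ballInside(occ, ctr, pball)) next
        blob <- array(FALSE, d)
        blob <- .stamp(blob, matrix(ctr, 1), pball)
        if (any(blob & fil)) next
        fil <- fil | blob
        puncta[[length(puncta) + 1]] <- list(center = ctr,
                                             radius = min(2, r))
        break
      }
    }
    if (length(puncta) < config$n_puncta)
      stop("failed to place requested puncta")
  }

  list(volume = BinaryVolume(fil, config$voxel_pitch_nm),
       truth = list(filaments = truth, puncta = puncta))
}

.idx2xyz <- function(idx, d) {
  idx <- idx - 1L
  c(idx %% d[1], (idx %/% d[1]) %% d[2], idx %/% (d[1] * d[2])) + 1
}

#' Synthesize vesicles with controllable placement bias
#'
#' Vesicles are voxelized spheres placed wholly inside the mask and pairwise
#' disjoint (overlap with filaments is allowed and is what produces
#' contacts). Under `end_biased` each vesicle is, with probability `q`,
#' centered within one vesicle radius of a randomly chosen filament
#' endpoint; under `puncta_biased` anchors are punctum centers; remaining
#' vesicles are placed uniformly.
#'
#' @param mask a [BinaryVolume-class] cell mask.
#' @param truth ground-truth list from [synthFilaments()].
#' @param config a `SynthConfig`.
#' @param max_tries rejection-sampling budget per vesicle.
#' @return `list(volume = BinaryVolume, truth = data.frame)` with one row
#'   per vesicle (center, radius, placement label).
#' @export
synthVesicles <- function(mask, truth, config, max_tries = 5000) {
  occ <- occupancy(mask)
  d <- dim(occ)
  mode <- config$placement_mode
  if (mode == "end_biased" && length(truth$filaments) == 0)
    stop("end-biased placement requires at least one filament")
  if (mode == "puncta_biased" && length(truth$puncta) == 0)
    stop("puncta-biased placement requires at least one punctum")
  anchors <- switch(mode,
    uniform = NULL,
    end_biased = do.call(rbind, lapply(truth$filaments, function(f)
      rbind(f$centerline[1, ], f$centerline[nrow(f$centerline), ]))),
    puncta_biased = do.call(rbind, lapply(truth$puncta, function(p) p$center)))

  ves <- array(FALSE, d)
  maskIdx <- which(occ) - 1L
  rec <- vector("list", config$n_vesicles)
  for (i in seq_len(config$n_vesicles)) {
    ri <- runif(1, config$vesicle_radius_dist$min,
                config$vesicle_radius_dist$max)
    ball <- .ballOffsets(ri)
    biased <- mode != "uniform" && runif(1) < config$q
    center <- NULL
    if (biased) {
      for (try in seq_len(max_tries)) {
        e <- anchors[sample(nrow(anchors), 1), ]
        off <- .runitvec() * runif(1, 0, ri)
        cand <- round(e + off)
        if (!.ballInside(occ, cand, ball)) next
        v <- sweep(ball, 2, cand, `+`)
        if (any(ves[v])) next
        center <- cand
        break
      }
      if (is.null(center))
        stop(sprintf("vesicle %d: biased placement saturated after %d tries",
                     i, max_tries))
    } else {
      a <- try_place_cpp(occ, ves, d, ball, maskIdx, max_tries)
      if (a < 0)
        stop(sprintf("vesicle %d: uniform placement saturated after %d tries",
                     i, max_tries))
      center <- .idx2xyz(a + 1L, d)
    }
    v <- sweep(ball, 2, round(center), `+`)
    ves[v] <- TRUE
    rec[[i]] <- data.frame(x = center[1], y = center[2], z = center[3],
                           radius = ri, n_voxels = nrow(ball),
                           placement = if (biased) {
                             if (mode == "end_biased") "end" else "punctum"
                           } else "free")
  }
  truth_df <- if (config$n_vesicles > 0) do.call(rbind, rec) else
    data.frame(x = numeric(), y = numeric(), z = numeric(),
               radius = numeric(), n_voxels = integer(),
               placement = character())
  list(volume = BinaryVolume(ves, config$voxel_pitch_nm), truth = truth_df)
}

#' Generate one complete synthetic cell
#'
#' Convenience wrapper running [makeCellMask()], [synthFilaments()] and
#' [synthVesicles()] under a single seeded generator.
#'
#' @param config a `SynthConfig`; its `seed` (if non-NULL) is applied first.
#' @return list with elements `mask`, `filaments`, `vesicles` (all
#'   [BinaryVolume-class]) and `truth`.
#' @export
synthCell <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  mask <- makeCellMask(config)
  fil <- synthFilaments(mask, config)
  ves <- synthVesicles(mask, fil$truth, config)
  list(mask = mask, filaments = fil$volume, vesicles = ves$volume,
       truth = c(fil$truth, list(vesicles = ves$truth)), config = config)
}
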