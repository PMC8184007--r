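## Shared fixture builders. Everything is generated in code; geometry is in
## voxels on small grids so the suite stays fast.

## solid axis-aligned tube (cuboid cross-section tube uses balls): returns
## BinaryVolume with a straight tube of given length/radius centered in grid
straightTube <- function(len = 30, r = 2, axis = 1, pitch = 25) {
  d <- c(len + 4 * r + 4, 4 * r + 9, 4 * r + 9)
  d <- c(d[1], d[2], d[3])
  if (axis == 2) d <- d[c(2, 1, 3)]
  if (axis == 3) d <- d[c(2, 3, 1)]
  occ <- array(FALSE, d)
  ctr <- (d + 1) / 2
  ball <- polkadots:::.ballOffsets(r)
  t0 <- ctr
  t0[axis] <- 2 * r + 2
  pts <- t(sapply(0:len, function(s) { p <- t0; p[axis] <- p[axis] + s; p }))
  occ <- polkadots:::.stamp(occ, pts, ball)
  BinaryVolume(occ, pitch)
}

## voxelized solid torus in the xy-plane
torusVolume <- function(R = 12, r = 3, pitch = 25) {
  d <- c(2 * (R + r) + 7, 2 * (R + r) + 7, 2 * r + 7)
  occ <- array(FALSE, d)
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2; cz <- (d[3] + 1) / 2
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) {
    rad <- sqrt((x - cx)^2 + (y - cy)^2)
    for (z in seq_len(d[3]))
      if ((rad - R)^2 + (z - cz)^2 <= r^2) occ[x, y, z] <- TRUE
  }
  BinaryVolume(occ, pitch)
}

## two straight tubes crossing at `ang_deg` in the xy-plane
crossingTubes <- function(ang_deg, L = 48, r = 2, d = c(70, 70, 30)) {
  ang <- ang_deg * pi / 180
  ctr <- c(35, 35, 15)
  u1 <- c(cos(ang / 2), sin(ang / 2), 0)
  u2 <- c(cos(-ang / 2), sin(-ang / 2), 0)
  t <- seq(-L / 2, L / 2, by = 1)
  c1 <- t(sapply(t, function(s) ctr + s * u1))
  c2 <- t(sapply(t, function(s) ctr + s * u2))
  ball <- polkadots:::.ballOffsets(r)
  occ <- array(FALSE, d)
  occ <- polkadots:::.stamp(occ, c1, ball)
  occ <- polkadots:::.stamp(occ, c2, ball)
  list(volume = BinaryVolume(occ, 25),
       tips = rbind(c1[1, ], c1[nrow(c1), ], c2[1, ], c2[nrow(c2), ]))
}

## straight digitized path skeleton plus optional side spur
pathSkeleton <- function(n = 30, spurs = list()) {
  vox <- cbind(seq_len(n), 10L, 10L)
  for (sp in spurs) vox <- rbind(vox, cbind(sp$x, 10L + seq_len(sp$len), 10L))
  skeletonFromVoxels(vox)
}

## small synthetic cell for contact/null tests
nullStudyConfig <- function(seed, q = 0, n_filaments = 3, n_vesicles = 7,
                            r_max = 3) {
  synthConfig(grid_shape = c(44, 44, 40), cell_semi_axes = c(18, 18, 16),
              n_filaments = n_filaments,
              filament_length_dist = list(min = 15, max = 30),
              n_vesicles = n_vesicles,
              vesicle_radius_dist = list(min = 2, max = r_max),
              placement_mode = if (q > 0) "end_biased" else "uniform",
              q = q, seed = seed)
}

## hand-written multi-source BFS (independent oracle for end distances)
bfsEndDistances <- function(skel) {
  n <- nNodes(skel)
  adj <- polkadots:::.adjList(skel)
  deg <- nodeDegree(skel)
  ends <- if (n == 1) 1L else which(deg == 1L)
  if (length(ends) == 0) return(rep(Inf, n))
  dist <- rep(Inf, n)
  dist[ends] <- 0
  queue <- ends
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (dist[w] > dist[v] + 1) {
      dist[w] <- dist[v] + 1
      queue <- c(queue, w)
    }
  }
  dist
}
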