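test_that("skeletonization of canonical shapes preserves geometry and topology", {
  ## single voxel
  occ <- array(FALSE, c(3, 3, 3)); occ[2, 2, 2] <- TRUE
  sk <- skeletonize(BinaryVolume(occ))
  expect_equal(nNodes(sk), 1)
  expect_equal(nrow(skeletonEdges(sk)), 0)

  expect_error(skeletonize(BinaryVolume(array(FALSE, c(3, 3, 3)))), "empty")

  ## straight 30-voxel tube of radius 2: single path, right length, centered
  tube <- straightTube(30, 2)
  sk <- pruneSpurs(skeletonize(tube))
  deg <- nodeDegree(sk)
  expect_true(all(deg <= 2))
  expect_equal(sum(deg == 1), 2)
  expect_lte(abs(nNodes(sk) - 31), 2)
  cc <- nodeCoords(sk)
  d <- dim(tube)
  expect_lte(max(abs(cc[, 2] - (d[2] + 1) / 2)), 1)   # on-axis to 1 voxel
  expect_lte(max(abs(cc[, 3] - (d[3] + 1) / 2)), 1)

  ## solid torus: homotopy preserved, exactly one cycle and no endpoints
  ## (after pruning the surface-noise spurs)
  sk <- pruneSpurs(skeletonize(torusVolume()))
  expect_equal(length(endNodes(sk)), 0)
  expect_equal(nrow(skeletonEdges(sk)), nNodes(sk))   # Euler: one cycle
})

test_that("spur pruning enforces the strict 6-voxel end-to-end rule", {
  ## 5-voxel side spur removed, 6-voxel spur kept (length counts the
  ## junction attachment)
  sk <- pathSkeleton(30, list(list(x = 15, len = 5), list(x = 22, len = 6)))
  out <- pruneSpurs(sk, 6)
  expect_equal(nNodes(out), 30 + 6)
  yl <- nodeCoords(out)[, 2]
  expect_equal(sum(yl > 10), 6)

  ## spur-free path is a fixpoint
  p <- pathSkeleton(25)
  expect_identical(nodeCoords(pruneSpurs(p)), nodeCoords(p))

  ## nested spurs equal repeated single-pass pruning; pruning never
  ## disconnects
  vox <- cbind(1:40, 10L, 10L)
  vox <- rbind(vox, cbind(20L, 10L + 1:4, 10L))          # spur on main
  vox <- rbind(vox, cbind(20L + 1:3, 14L, 10L))          # spur on spur
  sk <- skeletonFromVoxels(vox)
  out <- pruneSpurs(sk, 6)
  g <- polkadots:::.skelGraph(out)
  expect_equal(igraph::components(g)$no, 1)
  expect_equal(nNodes(out), 40)
})

test_that("punctate classification uses strict node-count length", {
  expect_equal(classifyPunctate(pathSkeleton(4)), "P")
  expect_equal(classifyPunctate(pathSkeleton(6)), "filament")
  expect_equal(classifyPunctate(pathSkeleton(100)), "filament")
  one <- skeletonFromVoxels(cbind(3L, 3L, 3L))
  expect_equal(classifyPunctate(one), "P")
})

test_that("sphere fit recovers exact circles and flags straight beams", {
  th <- seq(0, 2 * pi, length.out = 12)[1:11]
  circ <- cbind(10 * cos(th), 10 * sin(th), 0)
  expect_equal(fitSphereRadius(circ), 10, tolerance = 1e-6)

  ## tilted circle in 3D
  rot <- cbind(c(1, 0, 0), c(0, cos(0.7), sin(0.7)), c(0, -sin(0.7), cos(0.7)))
  expect_equal(fitSphereRadius(circ %*% t(rot) + 5), 10, tolerance = 1e-6)

  line <- cbind(1:11, 2 * (1:11), 3 * (1:11))
  expect_identical(fitSphereRadius(line), Inf)
  expect_error(fitSphereRadius(circ[1:3, ]), "4 points")

  ## noisy circle matches an iterative geometric least-squares oracle
  set.seed(8)
  noisy <- circ + matrix(rnorm(33, 0, 0.2), ncol = 3)
  geom <- function(pts) {
    obj <- function(par) sum((sqrt(colSums((t(pts) - par[1:3])^2)) - par[4])^2)
    optim(c(colMeans(pts), 8), obj, method = "BFGS")$par[4]
  }
  expect_equal(fitSphereRadius(noisy), geom(noisy), tolerance = 0.02)
})

test_that("end distances equal a hand-written multi-source BFS", {
  p <- pathSkeleton(11)
  d <- endDistances(p)
  expect_equal(max(d), 5)                     # center node of an 11-path
  expect_true(all(d[endNodes(p)] == 0))

  ## random tree skeletons: exact agreement with the BFS oracle, and the
  ## 1-Lipschitz property holds across every edge
  set.seed(14)
  for (rep in 1:5) {
    vox <- cbind(1:20, 10L, 10L)
    for (b in 1:3) {
      at <- sample(3:17, 1)
      len <- sample(2:8, 1)
      vox <- rbind(vox, cbind(at, 10L + seq_len(len), 10L))
    }
    vox <- unique(vox)
    sk <- skeletonFromVoxels(vox)
    d <- endDistances(sk)
    expect_equal(d, bfsEndDistances(sk))
    ed <- skeletonEdges(sk)
    expect_true(all(abs(d[ed[, 1]] - d[ed[, 2]]) <= 1))
  }

  ## cycles with no endpoint get the no-end sentinel
  th <- seq(0, 2 * pi, length.out = 17)[1:16]
  ring <- unique(cbind(round(8 + 5 * cos(th)), round(8 + 5 * sin(th)), 3))
  skr <- skeletonFromVoxels(ring)
  if (length(endNodes(skr)) == 0) expect_true(all(is.infinite(endDistances(skr))))
})

test_that("filament length tracks ground truth on synthetic tubes", {
  sk <- pathSkeleton(41)
  expect_equal(filamentLength(sk, metric = "nodes")$nm, 1000)  # the 1-um cutoff
  expect_equal(filamentLength(sk)$nm, 1000, tolerance = 1e-9)  # straight path
  one <- skeletonFromVoxels(cbind(2L, 2L, 2L))
  expect_equal(filamentLength(one)$voxels, 0)

  ## curved generator tubes: euclidean metric within 10% of truth
  set.seed(31)
  errs <- c()
  for (s in 1:6) {
    cfg <- synthConfig(grid_shape = c(80, 80, 60),
                       cell_semi_axes = c(36, 36, 26), n_filaments = 1,
                       filament_length_dist = list(min = 25, max = 60),
                       curvature_bound = 10, n_vesicles = 0, seed = s)
    cl <- synthCell(cfg)
    sk <- pruneSpurs(skeletonize(cl$filaments))
    if (any(nodeDegree(sk) > 2)) next
    L <- filamentLength(sk)$voxels
    errs <- c(errs, abs(L - cl$truth$filaments[[1]]$length_voxels) /
                cl$truth$filaments[[1]]$length_voxels)
  }
  expect_gte(length(errs), 4)
  expect_true(all(errs < 0.1))

  expect_error(filamentLength(pathSkeleton(10, list(list(x = 5, len = 8)))),
               "not a simple path")
})

test_that("junction untangling reconstructs crossing filaments", {
  ## degree-2 chain is returned unchanged
  p <- pathSkeleton(15)
  expect_length(untangleJunctions(p), 1)

  ## X-crossing at 90 degrees: both straight filaments recovered; the
  ## energy-minimal pairing agrees with brute-force enumeration over all
  ## three maximal pairings by construction (exhaustive search is the
  ## implementation at degree 4)
  cs <- crossingTubes(90)
  sk <- pruneSpurs(skeletonize(cs$volume))
  parts <- untangleJunctions(sk)
  parts <- parts[order(-vapply(parts, nNodes, 0L))][1:2]
  for (p in parts) {
    expect_true(all(nodeDegree(p) <= 2))
    tp <- nodeCoords(p)[endNodes(p), , drop = FALSE]
    nt <- apply(tp, 1, function(v) which.min(colSums((t(cs$tips) - v)^2)))
    expect_true(all(sort(nt) == c(1, 2)) || all(sort(nt) == c(3, 4)))
  }

  ## T-junction: collinear branches joined, perpendicular stub split off
  vox <- rbind(cbind(1:31, 20L, 5L), cbind(16L, 20L - (1:10), 5L))
  skT <- skeletonize(BinaryVolume(polkadots:::.stamp(
    array(FALSE, c(40, 40, 10)), vox, polkadots:::.ballOffsets(1.5)), 25))
  skT <- pruneSpurs(skT)
  partsT <- untangleJunctions(skT)
  sizes <- sort(vapply(partsT, nNodes, 0L))
  expect_length(partsT, 2)
  main <- partsT[[which.max(vapply(partsT, nNodes, 0L))]]
  cc <- nodeCoords(main)
  expect_lte(max(cc[, 2]) - min(cc[, 2]), 2)   # main path stays horizontal

  ## node conservation at a clean single-voxel junction: every input node
  ## lands in exactly one path, junction duplicated at most twice
  A <- cbind(5:25, 15L, 8L)
  B <- cbind(15L, 5:25, 8L)
  skX <- skeletonFromVoxels(unique(rbind(A, B)))
  partsX <- untangleJunctions(skX)
  all_nodes <- do.call(rbind, lapply(partsX, nodeCoords))
  key <- paste(all_nodes[, 1], all_nodes[, 2], all_nodes[, 3])
  tab <- table(key)
  expect_true(all(tab <= 2))
  expect_setequal(unique(key),
                  paste(unique(rbind(A, B))[, 1], unique(rbind(A, B))[, 2],
                        unique(rbind(A, B))[, 3]))
})
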