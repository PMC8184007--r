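test_that("isotropic resampling reproduces analytic fields", {
  ## constant field: exact
  v <- IntensityVolume(array(3.5, c(8, 8, 5)), c(25, 25, 200))
  out <- resampleIsotropic(v, 25)
  expect_equal(voxelSpacing(out), c(25, 25, 25))
  expect_true(all(abs(voxelValues(out) - 3.5) < 1e-9))

  ## already isotropic at target pitch: identity
  vi <- IntensityVolume(array(runif(6 * 7 * 8), c(6, 7, 8)), c(25, 25, 25))
  expect_lt(max(abs(voxelValues(resampleIsotropic(vi, 25)) - voxelValues(vi))),
            1e-9)

  ## linear ramp in z resampled 200 -> 25 nm matches the closed form
  nz <- 6
  ramp <- array(rep(seq_len(nz), each = 25), c(5, 5, nz))
  vr <- IntensityVolume(ramp, c(25, 25, 200))
  out <- resampleIsotropic(vr, 25)
  zpos <- (seq_len(dim(out)[3]) - 1) * 25
  expected <- 1 + zpos / 200
  expect_lt(max(abs(sweep(voxelValues(out), 3, expected))), 1e-6)

  expect_error(resampleIsotropic(vr, 1e6), "extent")
})

test_that("binarization thresholds at >= and counts exceedances exactly", {
  z <- IntensityVolume(array(0, c(4, 4, 4)), c(25, 25, 25))
  expect_equal(sum(occupancy(binarizeChannel(z, 0.5))), 0)
  expect_equal(sum(occupancy(binarizeChannel(z, 0))), 64)  # threshold = min

  set.seed(4)
  vals <- array(runif(20^3), c(20, 20, 20))
  v <- IntensityVolume(vals, c(25, 25, 25))
  b <- binarizeChannel(v, 0.3)
  expect_equal(sum(occupancy(b)), sum(vals >= 0.3))
})

test_that("neighborhood filter implements the 8-of-27 kernel rule", {
  ## occupied voxel with exactly 7 occupied neighbors+self is removed,
  ## with exactly 8 it is retained
  mk <- function(nnb) {
    occ <- array(FALSE, c(5, 5, 5))
    occ[3, 3, 3] <- TRUE
    nb <- as.matrix(expand.grid(x = 2:4, y = 2:4, z = 2:4))
    nb <- nb[!(nb[, 1] == 3 & nb[, 2] == 3 & nb[, 3] == 3), ]
    occ[nb[seq_len(nnb), , drop = FALSE]] <- TRUE
    occ
  }
  b7 <- neighborFilter(BinaryVolume(mk(7)))    # count incl. center = 8
  expect_true(occupancy(b7)[3, 3, 3])
  b6 <- neighborFilter(BinaryVolume(mk(6)))    # count incl. center = 7
  expect_false(occupancy(b6)[3, 3, 3])

  ## the exclude-center reading shifts the boundary by one
  expect_false(occupancy(neighborFilter(BinaryVolume(mk(7)),
                                        include_center = FALSE))[3, 3, 3])
  expect_true(occupancy(neighborFilter(BinaryVolume(mk(8)),
                                       include_center = FALSE))[3, 3, 3])

  ## interior of a solid cube is unchanged
  solid <- array(FALSE, c(7, 7, 7)); solid[2:6, 2:6, 2:6] <- TRUE
  out <- occupancy(neighborFilter(BinaryVolume(solid)))
  expect_true(all(out[3:5, 3:5, 3:5]))

  ## random volume equals the brute-force per-voxel count filter
  set.seed(9)
  occ <- array(runif(20^3) < 0.4, c(20, 20, 20))
  got <- occupancy(neighborFilter(BinaryVolume(occ)))
  brute <- array(FALSE, c(20, 20, 20))
  for (x in 1:20) for (y in 1:20) for (z in 1:20) {
    if (!occ[x, y, z]) next
    cnt <- 0
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      xx <- x + dx; yy <- y + dy; zz <- z + dz
      if (xx >= 1 && xx <= 20 && yy >= 1 && yy <= 20 && zz >= 1 && zz <= 20 &&
          occ[xx, yy, zz]) cnt <- cnt + 1
    }
    brute[x, y, z] <- cnt >= 8
  }
  expect_identical(got, brute)

  ## idempotent on solid convex shapes
  once <- neighborFilter(BinaryVolume(solid))
  twice <- neighborFilter(once)
  expect_identical(occupancy(once), occupancy(twice))
})

test_that("small-noise removal respects the exact size boundary", {
  occ <- array(FALSE, c(12, 12, 6))
  occ[2, 2, 2] <- TRUE                       # singleton: removed
  occ[5, 5:6, 2] <- TRUE                     # size 2: kept at min_voxels = 2
  out <- occupancy(removeSmallNoise(BinaryVolume(occ), 2))
  expect_false(out[2, 2, 2])
  expect_true(all(out[5, 5:6, 2]))

  ## survivors equal a brute-force component-size filter
  set.seed(12)
  occ <- array(runif(18^3) < 0.2, c(18, 18, 18))
  lab <- labelComponents(BinaryVolume(occ))
  sizes <- tabulate(lab[lab > 0])
  expect_identical(occupancy(removeSmallNoise(BinaryVolume(occ), 5)),
                   array(lab %in% which(sizes >= 5), dim(occ)))
})

test_that("component labeling is 26-connected with dense labels", {
  occ <- array(FALSE, c(10, 10, 10))
  occ[2:3, 2:3, 2:3] <- TRUE
  occ[7:8, 7:8, 7:8] <- TRUE
  lab <- labelComponents(BinaryVolume(occ))
  expect_equal(attr(lab, "n_labels"), 2)
  expect_setequal(unique(as.vector(lab[lab > 0])), 1:2)

  empty <- labelComponents(BinaryVolume(array(FALSE, c(4, 4, 4))))
  expect_equal(attr(empty, "n_labels"), 0)

  ## diagonal touch joins components (26- vs 6-connectivity)
  occ <- array(FALSE, c(4, 4, 4))
  occ[1, 1, 1] <- TRUE; occ[2, 2, 2] <- TRUE
  expect_equal(attr(labelComponents(BinaryVolume(occ)), "n_labels"), 1)

  ## random volume: label count equals an igraph union-find oracle
  set.seed(5)
  occ <- array(runif(15^3) < 0.15, c(15, 15, 15))
  lab <- labelComponents(BinaryVolume(occ))
  idx <- which(occ)
  co <- cbind((idx - 1) %% 15, ((idx - 1) %/% 15) %% 15,
              (idx - 1) %/% 225) + 1
  n <- nrow(co)
  edges <- c()
  if (n > 1) {
    dd <- as.matrix(dist(co, method = "maximum"))
    pair <- which(dd == 1 & upper.tri(dd), arr.ind = TRUE)
    g <- igraph::make_empty_graph(n, directed = FALSE)
    g <- igraph::add_edges(g, t(pair))
    expect_equal(attr(lab, "n_labels"), igraph::components(g)$no)
  }
})

test_that("pipeline output occupancy is a subset of the binarized channel", {
  set.seed(20)
  vals <- array(runif(24^3)^2, c(24, 24, 24))
  vol <- IntensityVolume(vals, c(25, 25, 25))
  res <- preprocessChannel(vol, threshold = 0.5, target_pitch = 25,
                           min_voxels = 4)
  bin0 <- occupancy(binarizeChannel(vol, 0.5))
  expect_true(all(bin0[occupancy(res$binary)]))
})
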