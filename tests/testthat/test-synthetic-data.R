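test_that("cell mask matches the analytic ellipsoid volume and symmetries", {
  cfg <- synthConfig(grid_shape = c(61, 61, 61), cell_semi_axes = c(25, 22, 20))
  m <- makeCellMask(cfg)
  expect_s4_class(m, "BinaryVolume")
  analytic <- 4 / 3 * pi * 25 * 22 * 20
  expect_lt(abs(sum(occupancy(m)) - analytic) / analytic, 0.05)

  ## degenerate semi-axes collapse to the single center voxel
  cfg0 <- synthConfig(grid_shape = c(9, 9, 9), cell_semi_axes = c(0, 0, 0))
  m0 <- makeCellMask(cfg0)
  expect_equal(sum(occupancy(m0)), 1)
  expect_true(occupancy(m0)[5, 5, 5])

  ## spherical masks are invariant under axis permutation
  cfgS <- synthConfig(grid_shape = c(41, 41, 41), cell_semi_axes = c(15, 15, 15))
  occ <- occupancy(makeCellMask(cfgS))
  expect_identical(occ, aperm(occ, c(2, 3, 1)))

  ## oversize semi-axis errors and names the axis
  bad <- synthConfig(grid_shape = c(21, 41, 41), cell_semi_axes = c(15, 15, 15))
  expect_error(makeCellMask(bad), "axis 1")
})

test_that("synthetic filaments are tubes matching cylinder volume, stay in the mask", {
  cfg <- synthConfig(grid_shape = c(100, 40, 40), cell_semi_axes = c(48, 18, 18),
                     n_filaments = 1, filament_length_dist = list(min = 80, max = 80),
                     curvature_bound = 0, filament_radius = 2, n_vesicles = 0)
  set.seed(101)
  mask <- makeCellMask(cfg)
  f <- synthFilaments(mask, cfg)
  L <- f$truth$filaments[[1]]$length_voxels
  expect_equal(L, 80)
  ## voxel count vs analytic cylinder with hemispherical end caps
  analytic <- pi * 2^2 * L + 4 / 3 * pi * 2^3
  expect_lt(abs(sum(occupancy(f$volume)) - analytic) / analytic, 0.15)
  ## contained in the mask
  expect_true(all(occupancy(mask)[occupancy(f$volume)]))
  ## zero curvature bound forces exact collinearity
  cl <- f$truth$filaments[[1]]$centerline
  dirs <- diff(cl)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  expect_lt(max(abs(sweep(dirs, 2, dirs[1, ]))), 1e-9)

  cfg0 <- synthConfig(n_filaments = 0, n_vesicles = 0)
  set.seed(1)
  f0 <- synthFilaments(makeCellMask(cfg0), cfg0)
  expect_equal(sum(occupancy(f0$volume)), 0)
  expect_length(f0$truth$filaments, 0)
})

test_that("centerline ground truth is inside the tube and lengths are arc lengths", {
  cfg <- synthConfig(seed = 7, n_filaments = 3,
                     filament_length_dist = list(min = 15, max = 30))
  cl <- synthCell(cfg)
  for (f in cl$truth$filaments) {
    pts <- round(f$centerline)
    expect_true(all(occupancy(cl$filaments)[pts]))
    expect_equal(f$length_voxels, sum(sqrt(rowSums(diff(f$centerline)^2))),
                 tolerance = 1e-12)
  }
})

test_that("vesicle placement modes behave as configured", {
  ## q = 1 with enough ends: every vesicle touches a filament-end neighborhood
  cfg <- synthConfig(seed = 21, n_filaments = 4, n_vesicles = 5,
                     filament_length_dist = list(min = 15, max = 25),
                     vesicle_radius_dist = list(min = 2, max = 2),
                     placement_mode = "end_biased", q = 1)
  cl <- synthCell(cfg)
  ends <- do.call(rbind, lapply(cl$truth$filaments, function(f)
    rbind(f$centerline[1, ], f$centerline[nrow(f$centerline), ])))
  vt <- cl$truth$vesicles
  expect_true(all(vt$placement == "end"))
  for (i in seq_len(nrow(vt))) {
    dmin <- min(sqrt(colSums((t(ends) - as.numeric(vt[i, c("x", "y", "z")]))^2)))
    expect_lte(dmin, vt$radius[i] + 1)
  }

  ## all structures stay inside the mask; vesicles pairwise disjoint by count
  expect_true(all(occupancy(cl$mask)[occupancy(cl$vesicles)]))
  lab <- labelComponents(cl$vesicles)
  expect_gte(attr(lab, "n_labels"), 1)

  ## fixed seed => identical volumes
  cl2 <- synthCell(cfg)
  expect_identical(occupancy(cl$vesicles), occupancy(cl2$vesicles))
  expect_identical(occupancy(cl$filaments), occupancy(cl2$filaments))
})

test_that("q = 0 vesicle-end distances look uniform (KS against uniform-placement null)", {
  ## compare end-distance samples between two independent uniform cohorts;
  ## a biased cohort is the positive control
  set.seed(33)
  endDist <- function(cl) {
    ends <- do.call(rbind, lapply(cl$truth$filaments, function(f)
      rbind(f$centerline[1, ], f$centerline[nrow(f$centerline), ])))
    vt <- cl$truth$vesicles
    sapply(seq_len(nrow(vt)), function(i)
      min(sqrt(colSums((t(ends) - as.numeric(vt[i, c("x", "y", "z")]))^2))))
  }
  du1 <- unlist(lapply(1:12, function(s) endDist(synthCell(nullStudyConfig(s)))))
  du2 <- unlist(lapply(13:24, function(s) endDist(synthCell(nullStudyConfig(s)))))
  db <- unlist(lapply(25:36, function(s)
    endDist(synthCell(nullStudyConfig(s, q = 0.8, n_filaments = 4, r_max = 2)))))
  expect_gt(stats::ks.test(du1, du2)$p.value, 0.01)   # uniform vs uniform
  expect_lt(stats::ks.test(du1, db)$p.value, 0.01)    # uniform vs end-biased
})
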