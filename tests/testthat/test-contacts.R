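test_that("contact detection is per structure-vesicle pair on shared voxels", {
  d <- c(20, 20, 10)
  b <- array(0L, d); l <- array(0L, d)
  ## disjoint channels
  b[2:5, 2, 2] <- 1L; l[10:12, 10, 5] <- 1L
  attr(b, "n_labels") <- 1L; attr(l, "n_labels") <- 1L
  expect_equal(nrow(findContacts(b, l)), 0)

  ## one vesicle overlapping one filament in exactly 12 voxels
  b <- array(0L, d); l <- array(0L, d)
  b[3:14, 5:6, 3] <- 1L
  l[3:8, 6:7, 3] <- 1L                        # overlap rows 3:8 x col 6 x 2?
  ov <- sum(b > 0 & l > 0)
  cts <- findContacts(b, l)
  expect_equal(nrow(cts), 1)
  expect_equal(cts$n_overlap, ov)
  expect_equal(length(cts$voxels[[1]]), ov)

  ## one vesicle spanning two structures gives two events
  b <- array(0L, d); l <- array(0L, d)
  b[2:6, 5, 3] <- 1L; b[8:12, 5, 3] <- 2L
  l[5:9, 5, 3] <- 1L
  cts <- findContacts(b, l)
  expect_equal(nrow(cts), 2)
  expect_setequal(cts$structure, 1:2)

  expect_error(findContacts(b, array(0L, c(5, 5, 5))), "grids")
})

test_that("contact localization assigns skeleton end distances", {
  ## straight 41-node filament: tip contact -> 0, midpoint -> 20, rescaled 1
  d <- c(50, 20, 10)
  b <- array(0L, d)
  b[5:45, 10, 5] <- 1L
  attr(b, "n_labels") <- 1L
  skels <- list(list(
    skeleton = skeletonFromVoxels(cbind(5:45, 10L, 5L)),
    structure = 1L, class = "filament"))

  l <- array(0L, d); l[5, 10, 5] <- 1L       # vesicle on the tip
  cts <- locateContacts(findContacts(b, l), skels, d)
  expect_equal(cts$end_distance, 0)
  expect_equal(cts$rescaled, 0)

  l <- array(0L, d); l[25, 10, 5] <- 1L      # vesicle at the midpoint
  cts <- locateContacts(findContacts(b, l), skels, d)
  expect_equal(cts$end_distance, 20)
  expect_equal(cts$rescaled, 1)
  expect_equal(cts$end_distance_nm, 500)

  ## punctate structures are classed "P" with no distance
  skels[[1]]$class <- "P"
  cts <- locateContacts(findContacts(b, l), skels, d)
  expect_equal(cts$class, "P")
  expect_true(is.na(cts$end_distance))
})

test_that("cell summaries compute fractions, cutoffs and correlation inputs", {
  mkskel <- function(n) list(skeleton = skeletonFromVoxels(cbind(seq_len(n), 1L, 1L)),
                             structure = 1L,
                             class = if (n < 6) "P" else "filament")
  sk <- c(lapply(c(2, 3, 4), mkskel), list(mkskel(30)))
  s <- summarizeCell(sk, NULL, pitch = 25)
  expect_equal(s$n_structures, 4)
  expect_equal(s$puncta_fraction, 0.75)
  expect_equal(s$mean_filament_length_nm, 29 * 25)

  ## all filaments 41+ nodes: fraction over 1 um is 1
  sk2 <- lapply(c(41, 45, 60), mkskel)
  s2 <- summarizeCell(sk2, NULL, pitch = 25)
  expect_equal(s2$fraction_over_1um, 1)

  ## histogram including the P bin sums to n_structures
  h <- lengthHistogram(s, breaks_nm = seq(0, 2000, 250))
  expect_equal(h$P + sum(h$counts), s$n_structures)

  ## zero structures: sentinel fractions
  s0 <- summarizeCell(list(), NULL)
  expect_equal(s0$n_structures, 0)
  expect_true(is.na(s0$puncta_fraction))
})

test_that("summaries agree with brute-force recomputation on a generated cohort", {
  set.seed(52)
  for (s in 1:3) {
    cfg <- nullStudyConfig(s + 400)
    cl <- synthCell(cfg)
    res <- analyzeCell(cl$filaments, cl$vesicles)
    summ <- res$summary
    ## brute force from the label arrays
    bl <- res$bcl10_labels; ll <- res$lc3_labels
    pairs <- unique(cbind(bl[bl > 0 & ll > 0], ll[bl > 0 & ll > 0]))
    expect_equal(summ$n_contacts, nrow(pairs))
    expect_equal(summ$n_structures, length(res$skeletons))
    ## rescaled distances stay in [0, 1]
    rs <- res$contacts$rescaled
    rs <- rs[is.finite(rs)]
    if (length(rs)) expect_true(all(rs >= 0 & rs <= 1 + 1e-9))
  }
})

test_that("end-biased cohorts shift contact distances toward filament tips", {
  set.seed(61)
  pool <- function(seeds, q, nf, rmax) {
    unlist(lapply(seeds, function(s) {
      cl <- synthCell(nullStudyConfig(s, q = q, n_filaments = nf, r_max = rmax))
      res <- analyzeCell(cl$filaments, cl$vesicles)
      res$summary$contact_end_distances
    }))
  }
  d0 <- pool(501:512, 0, 3, 3)
  d8 <- pool(601:612, 0.8, 4, 2)
  expect_gte(length(d0), 10)
  expect_gte(length(d8), 10)
  ## one-sided KS: the biased sample is stochastically closer to the ends
  ks <- suppressWarnings(stats::ks.test(d8, d0, alternative = "greater"))
  expect_lt(ks$p.value, 0.01)
})
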