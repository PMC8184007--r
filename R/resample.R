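#' Randomly rearrange segmented autophagosomes inside the cell boundary
#'
#' The image-based resampling null: each segmented vesicle is rotated by
#' three independent angles drawn uniformly from [0, 360) degrees about the
#' x-, y- and z-axes (voxel centers rotated about the object centroid,
#' rounded back to the grid, single-voxel holes closed), then placed one at
#' a time at a uniformly drawn anchor voxel within the cell boundary. A
#' placement is rejected and redrawn if any voxel falls outside the
#' boundary or overlaps a previously placed vesicle; overlap with Bcl10 is
#' allowed -- that is precisely what creates null contacts. Bcl10 and the
#' mask stay fixed.
#'
#' @param cell_mask [BinaryVolume-class] cell boundary.
#' @param lc3_labels integer label array of segmented autophagosomes.
#' @param rotate logical; set `FALSE` to re-place without rotation.
#' @param redraw_rotation logical; if `TRUE` a new rotation is drawn along
#'   with each new location on rejection (default redraws the location
#'   only).
#' @param max_tries rejection budget per vesicle (default 10000).
#' @return integer label array of rearranged vesicles (labels preserved).
#' @export
rearrangeAutophagosomes <- function(cell_mask, lc3_labels, rotate = TRUE,
                                    redraw_rotation = FALSE,
                                    max_tries = 10000L) {
  mask <- occupancy(cell_mask)
  d <- dim(mask)
  if (!identical(d, dim(lc3_labels)))
    stop("mask and label volumes are on different grids")
  nl <- attr(lc3_labels, "n_labels")
  if (is.null(nl)) nl <- max(0L, max(lc3_labels))
  out <- array(0L, d)
  occ <- array(FALSE, d)
  anchors <- which(mask) - 1L
  pos <- which(lc3_labels > 0)
  byves <- split(pos, lc3_labels[pos])
  for (v in seq_len(nl)) {
    vox <- byves[[as.character(v)]]
    if (is.null(vox) || length(vox) == 0) next
    coords <- cbind((vox - 1) %% d[1],
                    ((vox - 1) %/% d[1]) %% d[2],
                    (vox - 1) %/% (d[1] * d[2]))
    ctr <- colMeans(coords)
    offs <- NULL
    placed <- FALSE
    tries_left <- max_tries
    repeat {
      if (is.null(offs)) {
        offs <- if (rotate) .rotateOffsets(coords, ctr) else
          sweep(coords, 2, round(ctr))
        storage.mode(offs) <- "integer"
      }
      budget <- if (redraw_rotation) 1L else tries_left
      a <- try_place_cpp(mask, occ, d, offs, anchors, budget)
      tries_left <- tries_left - budget
      if (a >= 0) {
        axyz <- c(a %% d[1], (a %/% d[1]) %% d[2], a %/% (d[1] * d[2]))
        vv <- sweep(offs, 2, axyz + 1L, `+`)
        lin <- vv[, 1] + d[1] * ((vv[, 2] - 1) + d[2] * (vv[, 3] - 1))
        occ[lin] <- TRUE
        out[lin] <- v
        placed <- TRUE
        break
      }
      if (tries_left <= 0) break
      if (redraw_rotation) offs <- NULL
    }
    if (!placed)
      stop(sprintf("vesicle %d could not be placed after %d tries",
                   v, max_tries))
  }
  attr(out, "n_labels") <- nl
  out
}

## rotate voxel offsets about the centroid by random Euler angles and
## re-voxelize; single-voxel holes are closed to keep the shape solid
.rotateOffsets <- function(coords, ctr) {
  th <- runif(3, 0, 2 * pi)
  cx <- cos(th[1]); sx <- sin(th[1])
  cy <- cos(th[2]); sy <- sin(th[2])
  cz <- cos(th[3]); sz <- sin(th[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  R <- Rz %*% Ry %*% Rx
  off <- sweep(coords, 2, ctr) %*% t(R)
  off <- unique(round(off))
  ## close single-voxel holes: add empty voxels with >= 5 of 6 face
  ## neighbors occupied (vectorized in a small bounding box)
  lo <- apply(off, 2, min) - 1L
  dd <- apply(off, 2, max) - lo + 2L
  box <- array(FALSE, dd)
  box[sweep(off, 2, lo - 1L)] <- TRUE
  cnt <- array(0L, dd)
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    shifted <- array(FALSE, dd)
    src <- lapply(dd, seq_len)
    dst <- src
    if (s == 1L) { dst[[ax]] <- 2:dd[ax]; src[[ax]] <- 1:(dd[ax] - 1L) }
    else { dst[[ax]] <- 1:(dd[ax] - 1L); src[[ax]] <- 2:dd[ax] }
    shifted[dst[[1]], dst[[2]], dst[[3]]] <- box[src[[1]], src[[2]], src[[3]]]
    cnt <- cnt + shifted
  }
  fill <- which(!box & cnt >= 5L, arr.ind = TRUE)
  if (nrow(fill) > 0) off <- rbind(off, sweep(fill, 2, lo - 1L, `+`))
  off
}

#' Build the per-cell resampling null ensemble
#'
#' Repeats rearrangement + contact detection + localization `n_trials`
#' times and aggregates contact counts, punctate-contact counts and
#' end-distance distributions. The mean count carries a t-based 95% CI
#' (`mean +/- t(0.975, n-1) SE`); the percentile interval of the trial
#' counts (2.5-97.5%) is stored for single-observation comparison. Trials
#' whose placement saturates are logged and skipped; the ensemble requires
#' at least 90% successful trials.
#'
#' @param cell_mask [BinaryVolume-class].
#' @param bcl10_labels integer label array (fixed).
#' @param skeletons list from [skeletonizeStructures()].
#' @param lc3_labels integer label array of observed autophagosomes.
#' @param n_trials number of rearrangements (default 100).
#' @param ... passed to [rearrangeAutophagosomes()].
#' @return a [NullEnsemble-class].
#' @export
buildNull <- function(cell_mask, bcl10_labels, skeletons, lc3_labels,
                      n_trials = 100L, ...) {
  stopifnot(n_trials >= 1)
  d <- dim(bcl10_labels)
  counts <- integer(); pcounts <- integer(); ends <- list()
  failed <- 0L
  for (t in seq_len(n_trials)) {
    rl <- tryCatch(rearrangeAutophagosomes(cell_mask, lc3_labels, ...),
                   error = function(e) e)
    if (inherits(rl, "error")) {
      failed <- failed + 1L
      warning(sprintf("trial %d failed: %s", t, conditionMessage(rl)))
      next
    }
    cts <- findContacts(bcl10_labels, rl)
    cts <- locateContacts(cts, skeletons, d)
    counts <- c(counts, nrow(cts))
    pcounts <- c(pcounts, sum(cts$class == "P", na.rm = TRUE))
    ends[[length(ends) + 1]] <-
      cts$end_distance[cts$class == "filament" & is.finite(cts$end_distance)]
  }
  if (length(counts) < 0.9 * n_trials)
    stop(sprintf("only %d/%d rearrangement trials succeeded",
                 length(counts), n_trials))
  m <- mean(counts)
  ci <- if (length(counts) >= 2 && sd(counts) > 0)
    m + qt(0.975, length(counts) - 1) * sd(counts) / sqrt(length(counts)) *
      c(-1, 1) else c(m, m)
  new("NullEnsemble",
      trials = data.frame(n_contacts = counts, n_puncta_contacts = pcounts),
      endDistances = ends, nTrials = as.integer(n_trials),
      mean = m, ciMean = ci,
      ciTrials = unname(quantile(counts, c(0.025, 0.975), type = 1)))
}

#' Compare an observed cell to its resampling null
#'
#' Reports the excess contact count (observed minus null mean), whether the
#' observation falls outside the null 95% interval of trial counts, a
#' two-sample KS comparison of end-distance distributions against the
#' pooled null, and the punctate-contact comparison.
#'
#' @param observed a `CellSummary` for the true cell.
#' @param null a [NullEnsemble-class] for the same cell.
#' @return list (`verdict` record): `observed`, `null_mean`, `excess`,
#'   `ci`, `significant` (observed above the interval), `outside`
#'   (either side), `ks` (statistic, p) on end distances or NULL if either
#'   sample is empty, `puncta_observed`, `puncta_null_mean`.
#' @export
compareToNull <- function(observed, null) {
  obs <- observed$n_contacts
  ci <- null@ciTrials
  ks <- NULL
  pooled <- unlist(null@endDistances)
  if (length(observed$contact_end_distances) >= 1 && length(pooled) >= 1) {
    kt <- suppressWarnings(ks.test(observed$contact_end_distances, pooled))
    ks <- list(statistic = unname(kt$statistic), p.value = kt$p.value)
  }
  list(observed = obs,
       null_mean = null@mean,
       excess = obs - null@mean,
       ci = ci,
       significant = obs > ci[2],
       outside = obs > ci[2] || obs < ci[1],
       ks = ks,
       puncta_observed = observed$n_puncta_contacts,
       puncta_null_mean = mean(null@trials$n_puncta_contacts))
}
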