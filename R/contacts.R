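#' Detect Bcl10-autophagosome contacts by voxel overlap
#'
#' One contact event per (Bcl10 structure, autophagosome) pair sharing at
#' least one voxel in the two label volumes; the per-cell contact count is
#' the number of such pairs.
#'
#' @param bcl10_labels,lc3_labels integer label arrays
#'   (see [labelComponents()]) on the same grid.
#' @return data.frame with one row per event: `structure`, `vesicle`,
#'   `n_overlap`, and a list column `voxels` of linear voxel indices.
#' @export
findContacts <- function(bcl10_labels, lc3_labels) {
  if (!identical(dim(bcl10_labels), dim(lc3_labels)))
    stop("label volumes are on different grids")
  ov <- which(bcl10_labels > 0 & lc3_labels > 0)
  if (length(ov) == 0)
    return(data.frame(structure = integer(), vesicle = integer(),
                      n_overlap = integer(),
                      voxels = I(list())))
  key <- paste(bcl10_labels[ov], lc3_labels[ov])
  grp <- split(ov, key)
  ids <- do.call(rbind, strsplit(names(grp), " "))
  out <- data.frame(structure = as.integer(ids[, 1]),
                    vesicle = as.integer(ids[, 2]),
                    n_overlap = lengths(grp),
                    voxels = I(unname(grp)))
  out <- out[order(out$structure, out$vesicle), ]
  rownames(out) <- NULL
  out
}

#' Localize contacts along filament skeletons
#'
#' Each overlap voxel inherits the end-distance of its Euclidean-nearest
#' skeleton node (ties to the lowest node index); the event's end distance
#' is the minimum over its overlap voxels, i.e. the shortest distance
#' between the autophagosome and a skeleton endpoint. Contacts with
#' punctate structures are classed `"P"` and carry no distance. The
#' rescaled distance divides by half the skeleton hop length, mapping a tip
#' contact to 0 and a midpoint contact to 1.
#'
#' @param contacts data.frame from [findContacts()].
#' @param skeletons list from [skeletonizeStructures()] (skeleton, structure
#'   id, class per entry).
#' @param dims grid dimensions of the label arrays.
#' @return the contacts data.frame with columns `class`, `end_distance`
#'   (voxel hops), `end_distance_nm` and `rescaled` added.
#' @export
locateContacts <- function(contacts, skeletons, dims) {
  n <- nrow(contacts)
  contacts$class <- rep(NA_character_, n)
  contacts$end_distance <- rep(NA_real_, n)
  contacts$end_distance_nm <- rep(NA_real_, n)
  contacts$rescaled <- rep(NA_real_, n)
  if (n == 0) return(contacts)

  ## group package skeletons by originating structure
  bystruct <- split(seq_along(skeletons),
                    vapply(skeletons, function(s) s$structure, 0L))
  for (i in seq_len(n)) {
    sid <- as.character(contacts$structure[i])
    ks <- bystruct[[sid]]
    if (is.null(ks)) next
    classes <- vapply(ks, function(k) skeletons[[k]]$class, "")
    if (all(classes == "P")) {
      contacts$class[i] <- "P"
      next
    }
    vox <- contacts$voxels[[i]]
    vz <- (vox - 1) %/% (dims[1] * dims[2])
    vy <- ((vox - 1) %/% dims[1]) %% dims[2]
    vx <- (vox - 1) %% dims[1]
    P <- cbind(vx + 1, vy + 1, vz + 1)
    best <- Inf; bestres <- NA_real_; pit <- NA_real_
    for (k in ks) {
      if (skeletons[[k]]$class == "P") next
      skel <- skeletons[[k]]$skeleton
      ed <- skeletons[[k]]$end_distance
      if (is.null(ed)) ed <- endDistances(skel)
      cc <- skel@coords
      for (r in seq_len(nrow(P))) {
        d2 <- (cc[, 1] - P[r, 1])^2 + (cc[, 2] - P[r, 2])^2 +
          (cc[, 3] - P[r, 3])^2
        j <- which(d2 == min(d2))[1]      # ties: lowest node index
        if (ed[j] < best) {
          best <- ed[j]
          half <- (nNodes(skel) - 1) / 2
          bestres <- if (half > 0) ed[j] / half else 0
          pit <- skel@pitch
        }
      }
    }
    if (is.finite(best)) {
      contacts$class[i] <- "filament"
      contacts$end_distance[i] <- best
      contacts$end_distance_nm[i] <- best * pit
      contacts$rescaled[i] <- bestres
    } else {
      contacts$class[i] <- "filament"
    }
  }
  contacts
}

#' Per-cell structural and contact summary
#'
#' Collects the per-cell quantities behind the population statistics:
#' puncta fraction, the fraction of filaments at least 1 um long, the
#' length distribution with a separate "P" bin, contact counts and
#' end-distance lists, and the two correlation inputs (puncta count and
#' mean filament length over non-punctate structures). Lengths use the
#' voxel-count metric.
#'
#' @param skeletons list from [skeletonizeStructures()].
#' @param contacts located contacts data.frame (or `NULL`).
#' @param pitch voxel pitch in nm.
#' @param length_cutoff_nm cutoff for the "long filament" fraction
#'   (default 1000 nm).
#' @return list of class `CellSummary`.
#' @export
summarizeCell <- function(skeletons, contacts = NULL, pitch = 25,
                          length_cutoff_nm = 1000) {
  n <- length(skeletons)
  classes <- vapply(skeletons, function(s) s$class, "")
  lens_vox <- vapply(skeletons, function(s)
    filamentLength(s$skeleton, metric = "nodes")$voxels, 0)
  lens_nm <- lens_vox * pitch
  is_p <- classes == "P"
  nfil <- sum(!is_p)
  res <- list(
    n_structures = n,
    n_puncta = sum(is_p),
    puncta_fraction = if (n > 0) sum(is_p) / n else NA_real_,
    n_filaments_over_1um = sum(!is_p & lens_nm >= length_cutoff_nm),
    fraction_over_1um = if (nfil > 0)
      sum(!is_p & lens_nm >= length_cutoff_nm) / nfil else NA_real_,
    length_nm = lens_nm,
    class = classes,
    mean_filament_length_nm = if (nfil > 0) mean(lens_nm[!is_p]) else
      NA_real_,
    n_contacts = if (is.null(contacts)) 0L else nrow(contacts),
    contact_end_distances = if (is.null(contacts)) numeric() else
      contacts$end_distance[contacts$class == "filament" &
                              is.finite(contacts$end_distance)],
    n_puncta_contacts = if (is.null(contacts)) 0L else
      sum(contacts$class == "P", na.rm = TRUE))
  class(res) <- "CellSummary"
  res
}

#' @export
print.CellSummary <- function(x, ...) {
  cat(sprintf(
    "CellSummary: %d structures (%d puncta), %d contacts (%d punctate)\n",
    x$n_structures, x$n_puncta, x$n_contacts, x$n_puncta_contacts))
  invisible(x)
}

#' Histogram of structure lengths with a punctate bin
#'
#' @param summary a `CellSummary`.
#' @param breaks_nm histogram breaks in nm for the filamentous structures.
#' @return list with `P` (punctate count) and `counts`/`breaks` of the
#'   filament length histogram; counts (including "P") sum to
#'   `n_structures`.
#' @export
lengthHistogram <- function(summary, breaks_nm = seq(0, 5000, by = 250)) {
  fil <- summary$length_nm[summary$class != "P"]
  fil <- pmin(fil, max(breaks_nm))
  h <- hist(fil, breaks = breaks_nm, plot = FALSE)
  list(P = summary$n_puncta, counts = h$counts, breaks = breaks_nm)
}
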