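#' Read a multi-page TIFF stack as a volume
#'
#' Pages become z-planes. Intensities are returned as stored (the `tiff`
#' package scales integer data to [0, 1]).
#'
#' @param path TIFF file, one channel per file.
#' @param spacing voxel size (dx, dy, dz) in nm.
#' @return an [IntensityVolume-class].
#' @export
readVolumeTIFF <- function(path, spacing = c(25, 25, 200)) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  v <- array(0, c(d[1], d[2], length(pages)))
  for (i in seq_along(pages)) v[, , i] <- pages[[i]]
  IntensityVolume(v, spacing)
}

#' Write a volume as a multi-page TIFF stack
#'
#' @param vol [BinaryVolume-class], [IntensityVolume-class], or a 3D array;
#'   values are rescaled to [0, 1] for storage.
#' @param path output file.
#' @export
writeVolumeTIFF <- function(vol, path) {
  v <- if (is(vol, "BinaryVolume")) occupancy(vol) * 1 else
    if (is(vol, "IntensityVolume")) voxelValues(vol) else vol
  mx <- max(v)
  if (mx > 0) v <- v / mx
  pages <- lapply(seq_len(dim(v)[3]), function(z) v[, , z])
  tiff::writeTIFF(pages, path)
  invisible(path)
}

#' Export skeletons as a node table
#'
#' One row per node with coordinates, degree, end distance, structure id
#' and punctate flag -- the flat-file form of the skeleton measurements.
#'
#' @param skeletons list from [skeletonizeStructures()].
#' @param path optional CSV path; when `NULL` the data.frame is returned
#'   without writing.
#' @return the node data.frame, invisibly when written.
#' @export
writeSkeletonCSV <- function(skeletons, path = NULL) {
  rows <- lapply(seq_along(skeletons), function(i) {
    s <- skeletons[[i]]
    cc <- nodeCoords(s$skeleton)
    data.frame(skeleton = i, structure = s$structure,
               node = seq_len(nrow(cc)),
               x = cc[, 1], y = cc[, 2], z = cc[, 3],
               degree = nodeDegree(s$skeleton),
               end_distance = endDistances(s$skeleton),
               punctate = s$class == "P")
  })
  df <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Ground truth as JSON
#'
#' @param truth ground-truth list from [synthCell()].
#' @param path output JSON path.
#' @export
writeGroundTruthJSON <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
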