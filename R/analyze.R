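#' End-to-end single-cell contact analysis
#'
#' Orchestrates the full pipeline on segmented (binary) channels: component
#' labeling, per-structure skeletonization (with pruning, punctate
#' classification and junction untangling), voxel-overlap contact
#' detection, contact localization, and the per-cell summary. Optionally
#' attaches a resampling null ensemble and its verdict.
#'
#' @param bcl10 [BinaryVolume-class], segmented Bcl10 channel.
#' @param lc3 [BinaryVolume-class], segmented autophagosome channel.
#' @param mask [BinaryVolume-class], cell boundary (required for the null).
#' @param n_null_trials 0 to skip the resampling null, otherwise the trial
#'   count (the canonical choice is 100).
#' @param min_spur,punctate_len voxel cutoffs passed to the skeleton stage.
#' @return list: `bcl10_labels`, `lc3_labels`, `skeletons`, `contacts`,
#'   `summary`, and when requested `null` ([NullEnsemble-class]) and
#'   `verdict` (see [compareToNull()]).
#' @export
analyzeCell <- function(bcl10, lc3, mask = NULL, n_null_trials = 0L,
                        min_spur = 6L, punctate_len = 6L) {
  stopifnot(identical(dim(bcl10), dim(lc3)))
  bl <- labelComponents(bcl10)
  ll <- labelComponents(lc3)
  sk <- skeletonizeStructures(bl, pitch(bcl10), min_spur, punctate_len)
  cts <- locateContacts(findContacts(bl, ll), sk, dim(bl))
  summ <- summarizeCell(sk, cts, pitch(bcl10))
  out <- list(bcl10_labels = bl, lc3_labels = ll, skeletons = sk,
              contacts = cts, summary = summ)
  if (n_null_trials > 0) {
    if (is.null(mask)) stop("the resampling null requires a cell mask")
    out$null <- buildNull(mask, bl, sk, ll, n_trials = n_null_trials)
    out$verdict <- compareToNull(summ, out$null)
  }
  out
}
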