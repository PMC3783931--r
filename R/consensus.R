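#' Expert-consensus lesion mask
#'
#' Combines independent rater masks by voxelwise vote: ratings (1 = lesion,
#' 0 = normal) are summed across raters and a voxel enters the consensus
#' iff its summative score is at least `cutoff`. With four raters and the
#' default cutoff of 3, at least three raters must agree. The comparison is
#' `>=`: a "cutoff of 3" admits a voxel rated by exactly 3 raters.
#' `cutoff = 1` gives the union of the masks, `cutoff = n_raters` their
#' intersection, and the consensus volume is monotone non-increasing in the
#' cutoff.
#'
#' @param masks list of mask `volume_image`s on a common grid (at least 1).
#' @param cutoff minimum summative score (1 to `length(masks)`).
#' @return A `lesion_mask` (modality taken from the first input when it is
#'   a `lesion_mask`, otherwise `"other"`).
#' @export
consensus_mask <- function(masks, cutoff = 3L) {
  if (!is.list(masks) || length(masks) < 1L)
    stop("'masks' must be a non-empty list of mask volumes")
  for (m in masks) {
    if (!inherits(m, "volume_image")) stop("all elements must be volume_image")
    if (!is_mask_volume(m)) stop("all rater volumes must be binary masks")
    .stop_grid(masks[[1]], m, "rater masks")
  }
  n <- length(masks)
  cutoff <- as.integer(cutoff)
  if (is.na(cutoff) || cutoff < 1L || cutoff > n)
    stop("'cutoff' must be between 1 and the number of raters (", n, ")")
  score <- Reduce(`+`, lapply(masks, function(m) (m$data > 0) + 0L))
  modality <- if (inherits(masks[[1]], "lesion_mask")) masks[[1]]$modality
              else "other"
  lesion_mask(score >= cutoff, masks[[1]], modality)
}
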