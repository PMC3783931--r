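#' Mirrored contralateral reference statistics
#'
#' Healthy-tissue reference for lesion thresholding: each voxel is paired
#' with its mirror across the brain midline along the left-right axis, and
#' the reference mean and SD are computed over a cubic neighborhood (default
#' 5x5x5 voxels) centered on the mirrored position, restricted to brain
#' voxels with defined map values. Voxels whose mirrored position falls
#' outside the brain get an undefined (`NaN`) reference.
#'
#' @param map `volume_image` to reference (b1000 signal or TTP map).
#' @param brain brain mask.
#' @param laterality a `laterality` object (supplies the midline geometry).
#' @param window cubic neighborhood edge in voxels (odd, default 5).
#' @return A list with 3D arrays `mean`, `sd`, `n` (neighborhood voxel
#'   counts), aligned to the input grid.
#' @export
mirror_reference <- function(map, brain, laterality, window = 5L) {
  stopifnot(inherits(map, "volume_image"), inherits(brain, "volume_image"),
            inherits(laterality, "laterality"))
  .stop_grid(map, brain, "map and brain mask")
  if (laterality$status == "undetermined")
    stop("laterality is undetermined; cannot compute a contralateral reference")
  valid <- brain$data > 0 & is.finite(map$data)
  st <- .box_stats(map$data, valid, window)
  ax <- laterality$axis; lo <- laterality$lo; hi <- laterality$hi
  ref_mean <- .mirror_arr(st$mean, ax, lo, hi, fill = NA_real_)
  ref_sd <- .mirror_arr(st$sd, ax, lo, hi, fill = NA_real_)
  ref_n <- .mirror_arr(st$n, ax, lo, hi, fill = 0)
  mir_brain <- .mirror_arr(brain$data > 0, ax, lo, hi, fill = FALSE)
  ref_mean[!mir_brain] <- NaN
  ref_sd[!mir_brain] <- NaN
  ref_n[!mir_brain] <- 0
  list(mean = ref_mean, sd = ref_sd, n = ref_n, window = window)
}

# shared morphological cleanup: opening, minimum cluster size, hole filling,
# in that order
.cleanup_mask <- function(mask, voxel_mL, open_radius, min_cluster_mL) {
  mask <- .open3d(mask, open_radius)
  min_vox <- ceiling(min_cluster_mL / voxel_mL - 1e-9)
  mask <- .filter_small(mask, min_vox)
  .fill_holes(mask)
}

# restrict a candidate mask to brain and (optionally) the affected hemisphere
.clip_candidate <- function(mask, brain, laterality, allow_midline) {
  mask <- mask & brain
  if (!allow_midline) {
    hemi <- .hemisphere_index(dim(mask), laterality$axis, laterality$mid)
    want <- if (laterality$hemisphere == "high") hemi > 0 else hemi < 0
    mask <- mask & want
  }
  mask
}

#' Segment the DWI ischemic core
#'
#' A voxel joins the core iff its diffusion-weighted signal exceeds the
#' mirrored contralateral reference by `k` reference SDs (hyperintensity)
#' AND its ADC is below `adc_max` (true diffusion restriction). The dual
#' criterion guards against T2 shine-through, which elevates the b1000
#' signal without lowering ADC. Candidates are clipped to the affected
#' hemisphere (unless `allow_midline`), then cleaned up by 3D opening,
#' removal of clusters below `min_cluster_mL`, and hole filling.
#'
#' @param b1000 diffusion-weighted signal volume.
#' @param adc ADC map (mm^2/s).
#' @param brain brain mask.
#' @param laterality determined (or manual) `laterality`; an undetermined
#'   state is an error.
#' @param k hyperintensity threshold in reference SDs (default 2).
#' @param adc_max upper ADC bound in mm^2/s (default 620e-6, a common
#'   clinical cutoff for acute infarction).
#' @param ref_window mirrored-reference neighborhood edge (default 5).
#' @param open_radius opening radius in voxels (default 0: the dual intensity
#'   criterion and the minimum-cluster filter already suppress noise, and on
#'   anisotropic grids a radius-1 ball erodes a full slice from thin lesions).
#' @param min_cluster_mL minimum cluster volume retained (default 0.2 mL).
#' @param allow_midline keep voxels on/over the midline (default FALSE).
#' @return A `lesion_mask` with `modality = "DWI"`.
#' @export
segment_dwi_lesion <- function(b1000, adc, brain, laterality, k = 2,
                               adc_max = 620e-6, ref_window = 5L,
                               open_radius = 0, min_cluster_mL = 0.2,
                               allow_midline = FALSE) {
  stopifnot(inherits(b1000, "volume_image"), inherits(adc, "volume_image"))
  .stop_grid(b1000, brain, "b1000 and brain mask")
  .stop_grid(adc, brain, "ADC and brain mask")
  if (laterality$status == "undetermined")
    stop("laterality is undetermined; supply an explicit side")
  ref <- mirror_reference(b1000, brain, laterality, ref_window)
  cand <- !is.na(ref$mean) & !is.na(ref$sd) &
    b1000$data > ref$mean + k * ref$sd &
    is.finite(adc$data) & adc$data < adc_max
  cand <- .clip_candidate(cand, brain$data > 0, laterality, allow_midline)
  cand <- .cleanup_mask(cand, voxel_volume_mL(b1000), open_radius,
                        min_cluster_mL)
  lesion_mask(cand, b1000, "DWI")
}

#' Segment the TTP hypoperfusion lesion
#'
#' A voxel joins the hypoperfused lesion iff its time-to-peak exceeds the
#' mirrored contralateral reference mean by more than `delay_threshold`
#' seconds. Cleanup and hemisphere clipping are identical to the DWI
#' segmentation (same operator order: threshold, opening, minimum cluster,
#' hole filling).
#'
#' @param ttp TTP map (s).
#' @inheritParams segment_dwi_lesion
#' @param delay_threshold minimum ipsilateral-minus-reference delay in s
#'   (default 4).
#' @return A `lesion_mask` with `modality = "TTP"`.
#' @export
segment_ttp_lesion <- function(ttp, brain, laterality, delay_threshold = 4,
                               ref_window = 5L, open_radius = 0,
                               min_cluster_mL = 0.2, allow_midline = FALSE) {
  stopifnot(inherits(ttp, "volume_image"))
  .stop_grid(ttp, brain, "TTP and brain mask")
  if (laterality$status == "undetermined")
    stop("laterality is undetermined; supply an explicit side")
  ref <- mirror_reference(ttp, brain, laterality, ref_window)
  cand <- !is.na(ref$mean) & is.finite(ttp$data) &
    (ttp$data - ref$mean) > delay_threshold
  cand <- .clip_candidate(cand, brain$data > 0, laterality, allow_midline)
  cand <- .cleanup_mask(cand, voxel_volume_mL(ttp), open_radius,
                        min_cluster_mL)
  lesion_mask(cand, ttp, "TTP")
}
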