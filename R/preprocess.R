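#' Compute a whole-brain mask
#'
#' Excludes non-brain structures (background, detached blobs such as eyes)
#' from the b = 0 diffusion image: Otsu intensity threshold, 3D morphological
#' closing, retention of the largest 6-connected component, and interior
#' hole filling. The result is a single connected component covering at
#' least one voxel.
#'
#' @param b0 `volume_image` of b = 0 signal; must not be constant.
#' @param close_radius closing radius in voxels (default 2).
#' @param threshold optional manual threshold overriding Otsu's.
#' @return A mask `volume_image` with extra field `n_voxels`.
#' @export
compute_brain_mask <- function(b0, close_radius = 2, threshold = NULL) {
  stopifnot(inherits(b0, "volume_image"))
  thr <- if (is.null(threshold)) .otsu_threshold(b0$data) else threshold
  bin <- is.finite(b0$data) & b0$data > thr
  if (!any(bin)) stop("brain mask is empty at threshold ", format(thr))
  bin <- .close3d(bin, close_radius)
  bin <- .largest_component(bin)
  bin <- .fill_holes(bin)
  out <- as_mask(bin, b0)
  out$n_voxels <- sum(bin)
  out$threshold <- thr
  out
}

#' Detect lesion laterality from ADC and TTP maps
#'
#' A stroke lesion delays TTP and lowers ADC on the affected side. Each
#' brain voxel is paired with its mirror across the midline (the mid-plane
#' of the brain-mask bounding box along the left-right axis). For each map
#' the ipsilateral-minus-mirror difference is converted to a robust z-score
#' (scaled by IQR/1.349 across the brain), and the fraction of voxels per
#' hemisphere with a lesion-signed z above `z_cut` is computed. The
#' asymmetry score is the left/right contrast of these tail fractions,
#' normalized by their total (floored at `f_floor` so that symmetric noise
#' cannot saturate the contrast), averaged over the TTP-delay and ADC-drop
#' channels. It ranges over \[-1, 1\] in magnitude; scores below
#' `min_score` give an explicit `"undetermined"` state, never a silent
#' default side.
#'
#' @param adc ADC map (`volume_image`, mm^2/s).
#' @param ttp TTP map (`volume_image`, s).
#' @param brain brain mask from [compute_brain_mask()].
#' @param min_score minimum |score| needed to declare a side (default 0.1).
#' @param z_cut robust z-score cut for a voxel to count as asymmetric
#'   (default 2: a mirrored difference beyond twice the robust noise scale).
#' @param f_floor floor on the combined tail fraction used as the contrast
#'   denominator (default 0.01, i.e. 1% of hemisphere voxels).
#' @return An object of class `laterality`: side (`"left"`/`"right"` or
#'   `NA`), hemisphere (`"low"`/`"high"` index side), `asymmetry_score`,
#'   `status` (`"determined"`/`"undetermined"`), and the midline geometry
#'   (`axis`, `lo`, `hi`).
#' @export
detect_laterality <- function(adc, ttp, brain, min_score = 0.1,
                              z_cut = 2, f_floor = 0.01) {
  stopifnot(inherits(adc, "volume_image"), inherits(ttp, "volume_image"),
            inherits(brain, "volume_image"))
  .stop_grid(adc, brain, "maps and brain mask")
  .stop_grid(ttp, brain, "maps and brain mask")
  axis <- adc$lr_axis
  if (is.na(axis)) axis <- ttp$lr_axis
  if (is.na(axis))
    stop("left-right axis unknown; read images with orientation metadata ",
         "or supply lr_axis")
  geom <- .midline_geometry(brain$data > 0, axis)
  hemi <- .hemisphere_index(dim(brain$data), axis, geom$mid)

  score_ttp <- .tail_fraction_contrast(ttp$data, brain$data > 0, axis, geom,
                                       hemi, sign = +1, z_cut = z_cut,
                                       f_floor = f_floor)
  score_adc <- .tail_fraction_contrast(adc$data, brain$data > 0, axis, geom,
                                       hemi, sign = -1, z_cut = z_cut,
                                       f_floor = f_floor)
  score_high <- mean(c(score_ttp, score_adc)) # >0: lesion on high-index side

  hemisphere <- if (score_high > 0) "high" else "low"
  status <- if (abs(score_high) >= min_score) "determined" else "undetermined"
  side <- NA_character_
  lr_dir <- adc$lr_dir
  if (is.na(lr_dir)) lr_dir <- ttp$lr_dir
  if (status == "determined" && !is.na(lr_dir)) {
    # lr_dir = +1: patient left lies at high indices
    side <- if ((hemisphere == "high") == (lr_dir == 1L)) "left" else "right"
  }
  structure(
    list(side = side, hemisphere = if (status == "determined") hemisphere
                                   else NA_character_,
         asymmetry_score = abs(score_high), status = status,
         axis = axis, lo = geom$lo, hi = geom$hi, mid = geom$mid,
         lr_dir = lr_dir,
         channel_scores = c(ttp_delay = score_ttp, adc_drop = score_adc)),
    class = "laterality"
  )
}

#' @export
print.laterality <- function(x, ...) {
  if (x$status == "determined")
    cat(sprintf("<laterality> %s (hemisphere: %s-index side), score %.3f\n",
                if (is.na(x$side)) "side unknown (no LR direction)" else x$side,
                x$hemisphere, x$asymmetry_score))
  else
    cat(sprintf("<laterality> undetermined (score %.3f)\n",
                x$asymmetry_score))
  invisible(x)
}

#' Construct a laterality object from an explicit side
#'
#' Used when automatic detection reports `"undetermined"` and the operator
#' supplies the affected side.
#'
#' @param side `"left"`, `"right"`, or the index-space labels
#'   `"low"`/`"high"`.
#' @param brain brain mask (supplies the midline geometry).
#' @param reference a `volume_image` carrying `lr_axis`/`lr_dir` (defaults
#'   to `brain`).
#' @return A `laterality` object with `status = "manual"`.
#' @export
manual_laterality <- function(side, brain, reference = brain) {
  side <- match.arg(side, c("left", "right", "low", "high"))
  axis <- reference$lr_axis
  lr_dir <- reference$lr_dir
  if (is.na(axis)) stop("reference volume has no left-right axis")
  geom <- .midline_geometry(brain$data > 0, axis)
  if (side %in% c("left", "right")) {
    if (is.na(lr_dir))
      stop("cannot map a patient side without a left-right direction; ",
           "use side = 'low' or 'high'")
    hemisphere <- if ((side == "left") == (lr_dir == 1L)) "high" else "low"
    patient_side <- side
  } else {
    hemisphere <- side
    patient_side <- if (is.na(lr_dir)) NA_character_
      else if ((hemisphere == "high") == (lr_dir == 1L)) "left" else "right"
  }
  structure(
    list(side = patient_side, hemisphere = hemisphere,
         asymmetry_score = NA_real_, status = "manual",
         axis = axis, lo = geom$lo, hi = geom$hi, mid = geom$mid,
         lr_dir = lr_dir, channel_scores = NULL),
    class = "laterality"
  )
}

# midline geometry: bounding interval of the brain along `axis` and its
# mid-plane
.midline_geometry <- function(brain, axis) {
  any_on <- apply(brain, axis, any)
  if (!any(any_on)) stop("brain mask covers no voxels")
  lo <- which(any_on)[1]
  hi <- utils::tail(which(any_on), 1)
  list(lo = lo, hi = hi, mid = (lo + hi) / 2)
}

# per-voxel index along `axis`, classified into hemispheres: -1 low side,
# +1 high side, 0 on the midline plane
.hemisphere_index <- function(d, axis, mid) {
  idx <- slice.index(array(0L, d), axis)
  sign(idx - mid)
}

# tail-fraction contrast for one map: fraction of voxels per hemisphere
# whose lesion-signed mirror difference exceeds z_cut robust SDs, contrasted
# high-minus-low and normalized by the (floored) total. `sign` = +1 when the
# lesion raises the map (TTP delay), -1 when it lowers it (ADC drop).
.tail_fraction_contrast <- function(map, brain, axis, geom, hemi, sign,
                                    z_cut, f_floor) {
  mir <- .mirror_arr(map, axis, geom$lo, geom$hi, fill = NA_real_)
  mir_brain <- .mirror_arr(brain, axis, geom$lo, geom$hi, fill = FALSE)
  d <- sign * (map - mir)
  ok <- brain & mir_brain & is.finite(d)
  dv <- d[ok]
  if (!length(dv)) return(0)
  s <- stats::IQR(dv) / 1.349
  if (!is.finite(s) || s <= 0) s <- stats::sd(dv)
  if (!is.finite(s) || s <= 0) {
    # constant differences: no dispersion to score against
    return(0)
  }
  z <- dv / s
  h <- hemi[ok]
  f_high <- mean(z[h > 0] > z_cut)
  f_low <- mean(z[h < 0] > z_cut)
  if (is.nan(f_high)) f_high <- 0
  if (is.nan(f_low)) f_low <- 0
  (f_high - f_low) / max(f_high + f_low, f_floor)
}
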