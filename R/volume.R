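#' 3D volume image
#'
#' Lightweight carrier for 3D scalar grids: diffusion-weighted signal, ADC
#' maps (mm^2/s), TTP maps (s), or binary masks. Carries voxel spacing in mm
#' and, when known, which array axis runs left-right in the patient.
#'
#' @param data 3D numeric array.
#' @param spacing numeric length-3, voxel spacing (dx, dy, dz) in mm; all
#'   components must be positive and finite.
#' @param lr_axis which array axis (1, 2 or 3) maps to patient left-right;
#'   `NA` when unknown.
#' @param lr_dir `+1` if increasing index along `lr_axis` moves toward
#'   patient left, `-1` if toward patient right, `NA` when unknown.
#'
#' @return An object of class `volume_image`: a list with elements `data`,
#'   `spacing`, `lr_axis`, `lr_dir`.
#' @export
volume_image <- function(data, spacing, lr_axis = NA_integer_,
                         lr_dir = NA_integer_) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3-dimensional array, got ",
         length(dim(data)), " dimension(s)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive finite values (mm)")
  if (!is.na(lr_axis) && !(lr_axis %in% 1:3))
    stop("'lr_axis' must be 1, 2 or 3")
  structure(
    list(data = data, spacing = spacing,
         lr_axis = as.integer(lr_axis), lr_dir = as.integer(lr_dir)),
    class = "volume_image"
  )
}

#' @export
dim.volume_image <- function(x) dim(x$data)

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %s voxels, spacing %s mm%s\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              if (!is.na(x$lr_axis))
                sprintf(", LR axis %d (%s)", x$lr_axis,
                        if (isTRUE(x$lr_dir == 1L)) "left at high index"
                        else "left at low index")
              else ""))
  invisible(x)
}

#' Voxel volume in millilitres
#'
#' `dx * dy * dz / 1000`: the product of the spacing components converted
#' from mm^3 to mL.
#'
#' @param vol a `volume_image`.
#' @return Scalar voxel volume in mL.
#' @export
voxel_volume_mL <- function(vol) {
  stopifnot(inherits(vol, "volume_image"))
  prod(vol$spacing) / 1000
}

#' Volume of a binary mask in millilitres
#'
#' @param vol a mask-valued `volume_image` (values in \{0, 1\}).
#' @return Mask volume in mL (voxel count times voxel volume).
#' @export
mask_volume_mL <- function(vol) {
  stopifnot(inherits(vol, "volume_image"))
  if (!is_mask_volume(vol)) stop("volume is not a binary mask")
  sum(vol$data != 0) * voxel_volume_mL(vol)
}

#' Test whether a volume holds a binary mask
#'
#' @param vol a `volume_image`.
#' @return `TRUE` iff every value is 0 or 1 (logical arrays qualify).
#' @export
is_mask_volume <- function(vol) {
  v <- vol$data
  if (is.logical(v)) return(!anyNA(v))
  !anyNA(v) && all(v == 0 | v == 1)
}

#' Construct a mask volume on the grid of an existing volume
#'
#' @param mask logical or 0/1 array matching `like` in shape.
#' @param like a `volume_image` providing geometry metadata.
#' @return A mask-valued `volume_image`.
#' @export
as_mask <- function(mask, like) {
  stopifnot(inherits(like, "volume_image"))
  if (!identical(dim(mask), dim(like$data)))
    stop("mask shape does not match the reference grid")
  storage.mode(mask) <- "logical"
  if (anyNA(mask)) stop("mask contains missing values")
  volume_image(mask, like$spacing, like$lr_axis, like$lr_dir)
}

#' Flip a volume along its left-right axis
#'
#' Reverses the array along `lr_axis` and flips the recorded left-right
#' direction so patient sides stay correctly labelled.
#'
#' @param vol a `volume_image` with `lr_axis` set.
#' @return The mirrored `volume_image`.
#' @export
flip_lr <- function(vol) {
  stopifnot(inherits(vol, "volume_image"))
  if (is.na(vol$lr_axis)) stop("volume has no left-right axis recorded")
  volume_image(.flip_axis(vol$data, vol$lr_axis), vol$spacing,
               vol$lr_axis, -vol$lr_dir)
}

# same spatial grid: equal shape and spacing (tolerance on spacing)
.same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data)[1:3], dim(b$data)[1:3]) &&
    all(abs(a$spacing - b$spacing) < tol)
}

.stop_grid <- function(a, b, what = "volumes") {
  if (!.same_grid(a, b))
    stop(what, " are not on the same grid (shape/spacing mismatch); ",
         "inputs must be co-registered")
  invisible(TRUE)
}

#' 4D dynamic susceptibility contrast series
#'
#' Raw perfusion time series: a 4D signal array (time on the last axis) with
#' repetition time TR, echo time TE (both in seconds) and the number of
#' pre-bolus baseline time points.
#'
#' @param data 4D numeric array, time last.
#' @param spacing voxel spacing (mm), length 3.
#' @param tr repetition time in s (> 0).
#' @param te echo time in s (> 0).
#' @param n_baseline number of pre-bolus time points (>= 1 and fewer than
#'   the number of time points).
#' @param lr_axis,lr_dir left-right axis metadata as in [volume_image()].
#' @return An object of class `dsc_series`.
#' @export
dsc_series <- function(data, spacing, tr, te, n_baseline,
                       lr_axis = NA_integer_, lr_dir = NA_integer_) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("'data' must be a 4-dimensional array (time last), got ",
         length(dim(data)), " dimension(s)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive finite values (mm)")
  if (!is.finite(tr) || tr <= 0) stop("TR must be > 0 (seconds)")
  if (!is.finite(te) || te <= 0) stop("TE must be > 0 (seconds)")
  nt <- dim(data)[4]
  n_baseline <- as.integer(n_baseline)
  if (is.na(n_baseline) || n_baseline < 1L || n_baseline >= nt)
    stop("'n_baseline' must be >= 1 and smaller than the number of time ",
         "points (", nt, ")")
  structure(
    list(data = data, spacing = spacing, tr = tr, te = te,
         n_baseline = n_baseline,
         lr_axis = as.integer(lr_axis), lr_dir = as.integer(lr_dir)),
    class = "dsc_series"
  )
}

#' @export
print.dsc_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<dsc_series> %s voxels x %d time points, TR %.3g s, TE %.3g s, %d baseline\n",
    paste(d[1:3], collapse = "x"), d[4], x$tr, x$te, x$n_baseline))
  invisible(x)
}

#' Lesion mask
#'
#' A binary mask on a volume grid, tagged with the modality it was outlined
#' on (`"DWI"` or `"TTP"`) and its volume in mL.
#'
#' @param mask logical or 0/1 array.
#' @param like `volume_image` supplying the grid geometry.
#' @param modality `"DWI"` or `"TTP"` (or another short label, e.g.
#'   `"FLAIR"` for follow-up infarct masks).
#' @return An object of class `c("lesion_mask", "volume_image")` with extra
#'   fields `modality` and `volume_mL`.
#' @export
lesion_mask <- function(mask, like, modality = c("DWI", "TTP", "FLAIR",
                                                 "mismatch", "other")) {
  modality <- match.arg(modality)
  v <- as_mask(mask, like)
  v$modality <- modality
  v$volume_mL <- sum(v$data) * voxel_volume_mL(v)
  class(v) <- c("lesion_mask", class(v))
  v
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %s, %.2f mL (%d voxels)\n",
              x$modality, x$volume_mL, sum(x$data)))
  invisible(x)
}
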