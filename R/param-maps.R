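#' Compute an apparent diffusion coefficient map
#'
#' The ADC is recovered per voxel from the monoexponential diffusion signal
#' model `S_b = S_0 exp(-b ADC)`:
#' `ADC = ln(S_b0 / S_b1000) / b`, in mm^2/s. Voxels where either signal is
#' non-positive (background, noise floor) are undefined and set to `NaN`,
#' never clipped to +/-Inf.
#'
#' @param b0 `volume_image`, signal at b = 0 s/mm^2.
#' @param b1000 `volume_image`, signal at the diffusion-weighted b-value.
#' @param b the diffusion weighting of `b1000` in s/mm^2 (default 1000).
#' @return A `volume_image` of ADC values (mm^2/s) with attribute `b_pair`.
#' @export
compute_adc <- function(b0, b1000, b = 1000) {
  stopifnot(inherits(b0, "volume_image"), inherits(b1000, "volume_image"))
  .stop_grid(b0, b1000, "b0/b1000 volumes")
  if (!is.finite(b) || b <= 0) stop("'b' must be > 0 (s/mm^2)")
  s0 <- b0$data
  s1 <- b1000$data
  ok <- is.finite(s0) & is.finite(s1) & s0 > 0 & s1 > 0
  adc <- array(NaN, dim(s0))
  adc[ok] <- log(s0[ok] / s1[ok]) / b
  out <- volume_image(adc, b0$spacing, b0$lr_axis, b0$lr_dir)
  attr(out, "b_pair") <- c(0, b)
  out
}

#' Convert a DSC signal series to contrast concentration
#'
#' Standard dynamic susceptibility contrast relation: the change in
#' transverse relaxation rate is taken as the concentration surrogate,
#' `C(t) = -ln(S(t)/S0) / TE` (1/s), with `S0` the per-voxel mean of the
#' first `n_baseline` (pre-bolus) samples. Samples with `S(t) <= 0` or
#' voxels with `S0 <= 0` are undefined (`NaN`).
#'
#' @param dsc a [dsc_series()].
#' @return A `concentration_series`: same structure as the input with
#'   `data` holding C(t) in 1/s.
#' @export
signal_to_concentration <- function(dsc) {
  stopifnot(inherits(dsc, "dsc_series"))
  d <- dim(dsc$data)
  nt <- d[4]
  sig <- matrix(dsc$data, ncol = nt)
  s0 <- rowMeans(sig[, seq_len(dsc$n_baseline), drop = FALSE])
  conc <- matrix(NaN, nrow(sig), nt)
  ok0 <- is.finite(s0) & s0 > 0
  oks <- is.finite(sig) & sig > 0
  idx <- which(oks & ok0)
  conc[idx] <- -log(sig[idx] / s0[(idx - 1) %% nrow(sig) + 1]) / dsc$te
  out <- dsc
  out$data <- array(conc, d)
  class(out) <- c("concentration_series", "dsc_series")
  out
}

#' Compute a time-to-peak map
#'
#' Per voxel, TTP is the time (in seconds since the start of the series) of
#' the maximum of the tissue concentration curve: `argmax_t C(t) * TR`.
#' Plateau ties resolve to the earliest sample (deterministic, shortest
#' delay). Voxels whose curve is entirely undefined yield `NaN`. An optional
#' centered moving-average window can smooth curves before the peak search
#' (off by default).
#'
#' @param conc a `concentration_series` (from [signal_to_concentration()]),
#'   or any `dsc_series`-like object holding curves to peak-search.
#' @param tr repetition time in s; defaults to the series' own TR.
#' @param smooth_window odd moving-average width in samples; `0` or `1`
#'   disables smoothing.
#' @return A `volume_image` of TTP values in s.
#' @export
compute_ttp <- function(conc, tr = conc$tr, smooth_window = 0L) {
  stopifnot(inherits(conc, "dsc_series"))
  d <- dim(conc$data)
  nt <- d[4]
  if (nt < 2L) stop("need at least 2 time points")
  cm <- matrix(conc$data, ncol = nt)
  if (smooth_window > 1L) {
    if (smooth_window %% 2 == 0) stop("'smooth_window' must be odd")
    h <- (smooth_window - 1L) / 2L
    sm <- matrix(0, nrow(cm), nt)
    cnt <- matrix(0, nrow(cm), nt)
    for (k in -h:h) {
      cols <- pmin(pmax(seq_len(nt) + k, 1L), nt)
      valid <- seq_len(nt) + k >= 1L & seq_len(nt) + k <= nt
      v <- cm[, cols[valid], drop = FALSE]
      fin <- is.finite(v)
      v[!fin] <- 0
      sm[, valid] <- sm[, valid] + v
      cnt[, valid] <- cnt[, valid] + fin
    }
    cm <- ifelse(cnt > 0, sm / cnt, NaN)
  }
  any_finite <- rowSums(is.finite(cm)) > 0
  cm[!is.finite(cm)] <- -Inf
  peak <- max.col(cm, ties.method = "first")
  ttp <- (peak - 1) * tr
  ttp[!any_finite] <- NaN
  volume_image(array(ttp, d[1:3]), conc$spacing, conc$lr_axis, conc$lr_dir)
}
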