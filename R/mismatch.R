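#' Compute the PWI-DWI mismatch
#'
#' The mismatch is the part of the hypoperfused (TTP) lesion not contained
#' in the co-registered DWI lesion: `mismatch = TTP AND NOT DWI`. Volumes
#' are voxel counts times the voxel volume, so the conservation identity
#' `volume(mismatch) + volume(TTP AND DWI) = volume(TTP)` holds exactly.
#'
#' Two ratio conventions are supported and the choice is always recorded:
#' `"pwi_over_dwi"` (hypoperfused volume / core volume; the convention of
#' the trials behind the 1.2 eligibility threshold) and
#' `"mismatch_over_core"` (mismatch volume / core volume). A zero core with
#' a nonzero numerator yields `Inf` (serialized as the string `"inf"`); a
#' zero core with zero numerator yields `NA`.
#'
#' @param ttp_lesion `lesion_mask` of the hypoperfused lesion.
#' @param dwi_lesion `lesion_mask` of the DWI core.
#' @param convention ratio convention (see above).
#' @param side optional `laterality` to record in the result.
#' @return An object of class `mismatch_result`: volumes (mL), ratio,
#'   convention, side, and the mismatch mask.
#' @export
compute_mismatch <- function(ttp_lesion, dwi_lesion,
                             convention = c("pwi_over_dwi",
                                            "mismatch_over_core"),
                             side = NULL) {
  convention <- match.arg(convention)
  stopifnot(inherits(ttp_lesion, "volume_image"),
            inherits(dwi_lesion, "volume_image"))
  .stop_grid(ttp_lesion, dwi_lesion, "lesion masks")
  vv <- voxel_volume_mL(ttp_lesion)
  t_mask <- ttp_lesion$data > 0
  d_mask <- dwi_lesion$data > 0
  mm_mask <- t_mask & !d_mask
  ttp_vol <- sum(t_mask) * vv
  dwi_vol <- sum(d_mask) * vv
  mm_vol <- sum(mm_mask) * vv
  num <- if (convention == "pwi_over_dwi") ttp_vol else mm_vol
  ratio <- if (dwi_vol > 0) num / dwi_vol
           else if (num > 0) Inf
           else NA_real_
  structure(
    list(dwi_volume_mL = dwi_vol, ttp_volume_mL = ttp_vol,
         mismatch_volume_mL = mm_vol, mismatch_ratio = ratio,
         ratio_convention = convention,
         side = if (inherits(side, "laterality")) side$side else side,
         mask = lesion_mask(mm_mask, ttp_lesion, "mismatch")),
    class = "mismatch_result"
  )
}

#' @export
print.mismatch_result <- function(x, ...) {
  cat(sprintf(
    "<mismatch_result> DWI core %.1f mL, TTP lesion %.1f mL, mismatch %.1f mL\n",
    x$dwi_volume_mL, x$ttp_volume_mL, x$mismatch_volume_mL))
  cat(sprintf("  ratio (%s): %s%s\n", x$ratio_convention,
              if (is.na(x$mismatch_ratio)) "undefined"
              else if (is.infinite(x$mismatch_ratio)) "inf"
              else sprintf("%.2f", x$mismatch_ratio),
              if (!is.null(x$side) && !is.na(x$side))
                sprintf("; side: %s", x$side) else ""))
  invisible(x)
}

#' Imaging-based thrombolysis eligibility
#'
#' A patient is an imaging candidate for thrombolysis iff the mismatch
#' volume strictly exceeds `volume_threshold` (default 10 mL) AND the
#' mismatch ratio strictly exceeds `ratio_threshold` (default 1.2). Both
#' inequalities are strict. The decision concerns imaging only; clinical
#' contraindications (see [check_contraindications()]) are reported
#' separately and never fused into a single verdict.
#'
#' @param m a `mismatch_result`.
#' @param volume_threshold mismatch volume threshold in mL (default 10).
#' @param ratio_threshold mismatch ratio threshold (default 1.2).
#' @return An object of class `eligibility_decision`.
#' @export
imaging_eligibility <- function(m, volume_threshold = 10,
                                ratio_threshold = 1.2) {
  stopifnot(inherits(m, "mismatch_result"))
  ratio_ok <- !is.na(m$mismatch_ratio) && m$mismatch_ratio > ratio_threshold
  eligible <- (m$mismatch_volume_mL > volume_threshold) && ratio_ok
  structure(
    list(eligible = eligible,
         mismatch_volume_mL = m$mismatch_volume_mL,
         mismatch_ratio = m$mismatch_ratio,
         ratio_convention = m$ratio_convention,
         volume_threshold = volume_threshold,
         ratio_threshold = ratio_threshold),
    class = "eligibility_decision"
  )
}

#' @export
print.eligibility_decision <- function(x, ...) {
  cat(sprintf(
    "<eligibility_decision> %s (mismatch %.1f mL > %g? ratio %s > %g?)\n",
    if (x$eligible) "ELIGIBLE (imaging criteria)" else "not eligible",
    x$mismatch_volume_mL, x$volume_threshold,
    if (is.na(x$mismatch_ratio)) "NA"
    else if (is.infinite(x$mismatch_ratio)) "inf"
    else sprintf("%.2f", x$mismatch_ratio),
    x$ratio_threshold))
  invisible(x)
}

#' Screen for thrombolysis contraindications
#'
#' Applies the AHA-guideline contraindication list: systolic blood pressure
#' > 185 mmHg, diastolic blood pressure > 110 mmHg, evidence of
#' intracranial hemorrhage, use of anticoagulants, INR > 1.7, and symptom
#' onset-to-treatment time beyond the window (default 4.5 h). All
#' inequalities are strict. An unknown (`NA`) field yields an explicit
#' `"unassessable:<field>"` flag, never a silent pass.
#'
#' @param record a single patient record: a one-row data frame or named
#'   list with fields `sbp`, `dbp`, `hemorrhage`, `anticoagulant`, `inr`,
#'   `onset_to_treatment`.
#' @param window_h treatment window in hours (default 4.5).
#' @return Character vector of violated-criterion flags (empty when all six
#'   criteria pass).
#' @export
check_contraindications <- function(record, window_h = 4.5) {
  if (is.data.frame(record)) {
    if (nrow(record) != 1L)
      stop("'record' must be a single patient (one row)")
    record <- as.list(record)
  }
  g <- function(f) if (is.null(record[[f]])) NA else record[[f]]
  flags <- character(0)
  add <- function(flags, value, test, flag, field) {
    if (is.na(value)) c(flags, paste0("unassessable:", field))
    else if (test(value)) c(flags, flag)
    else flags
  }
  flags <- add(flags, g("sbp"), function(v) v > 185,
               "hypertension_systolic", "sbp")
  flags <- add(flags, g("dbp"), function(v) v > 110,
               "hypertension_diastolic", "dbp")
  flags <- add(flags, g("hemorrhage"), isTRUE,
               "intracranial_hemorrhage", "hemorrhage")
  flags <- add(flags, g("anticoagulant"), isTRUE,
               "anticoagulant_use", "anticoagulant")
  flags <- add(flags, g("inr"), function(v) v > 1.7,
               "inr_elevated", "inr")
  flags <- add(flags, g("onset_to_treatment"), function(v) v > window_h,
               "beyond_window", "onset_to_treatment")
  flags
}
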