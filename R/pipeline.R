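#' Default pipeline configuration
#'
#' Every tunable threshold of the pipeline in one flat list: diffusion
#' b-value (s/mm^2), brain-mask closing radius (voxels), laterality score
#' minimum, mirrored-reference window (voxels), DWI hyperintensity factor
#' `k` (reference SDs), ADC ceiling (mm^2/s), TTP delay threshold (s),
#' opening radius (voxels), minimum cluster volume (mL), consensus cutoff,
#' eligibility thresholds (mL, ratio), ratio convention, treatment window
#' (h), and the optional TTP smoothing window (samples, 0 = off).
#'
#' @return Named list of parameters.
#' @export
default_config <- function() {
  list(
    b_value = 1000,
    brain_close_radius = 2,
    laterality_min_score = 0.1,
    laterality_z_cut = 2,
    laterality_f_floor = 0.01,
    ref_window = 5L,
    dwi_k = 2,
    adc_max = 620e-6,
    ttp_delay_threshold = 4,
    open_radius = 0,
    min_cluster_mL = 0.2,
    allow_midline = FALSE,
    consensus_cutoff = 3L,
    volume_threshold_mL = 10,
    ratio_threshold = 1.2,
    ratio_convention = "pwi_over_dwi",
    window_h = 4.5,
    ttp_smooth = 0L
  )
}

#' Read a flat key = value configuration file
#'
#' INI-style: one `key = value` per line, `#` comments, blank lines
#' ignored. Values are coerced to the type of the corresponding
#' [default_config()] entry; unknown keys are an error. Command-line or
#' call-site overrides should be applied on top of the returned list.
#'
#' @param path configuration file.
#' @param base configuration to override (default [default_config()]).
#' @return A full configuration list.
#' @export
read_config <- function(path, base = default_config()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed config line (expected key = value): '", ln, "'")
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% names(base)) stop("unknown config key: '", key, "'")
    proto <- base[[key]]
    base[[key]] <- if (is.character(proto)) val
      else if (is.logical(proto)) as.logical(val)
      else if (is.integer(proto)) as.integer(val)
      else as.numeric(val)
    if (is.na(base[[key]]) && !is.na(proto))
      stop("cannot parse value for '", key, "': '", val, "'")
  }
  base
}

#' Hash of a resolved configuration
#'
#' MD5 of the canonical (name-sorted) JSON serialization; embedded in run
#' reports so that results are traceable to the exact parameter set.
#'
#' @param config configuration list.
#' @return Character MD5 digest.
#' @export
config_hash <- function(config) {
  config <- config[order(names(config))]
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                           digits = NA)), tf)
  unname(tools::md5sum(tf))
}

#' Run the full mismatch assessment pipeline
#'
#' Maps, brain mask, laterality, lesion segmentation, mismatch and decision
#' in one call: computes ADC from the diffusion pair and TTP from the DSC
#' series, masks the brain, determines (or accepts) the lesion side,
#' outlines the DWI core and the TTP hypoperfusion lesion against the
#' mirrored contralateral reference, derives mismatch volume and ratio, and
#' renders the imaging eligibility plus the contraindication screen.
#'
#' @param b0,b1000 diffusion pair (`volume_image`, co-registered).
#' @param dsc the DSC perfusion series ([dsc_series()], same grid).
#' @param record optional one-row clinical record for the contraindication
#'   screen; when absent the screen is reported as unassessable.
#' @param config pipeline configuration ([default_config()]).
#' @param side optional explicit lesion side (`"left"`, `"right"`,
#'   `"low"`, `"high"`) used instead of automatic detection — required when
#'   detection reports an undetermined laterality, in which case this
#'   function signals an error of class `laterality_undetermined`.
#' @return An object of class `stroke_assessment`: maps, masks,
#'   `laterality`, `mismatch` (a `mismatch_result`), `eligibility`,
#'   `contraindications`, the resolved `config` and its hash.
#' @export
assess_mismatch <- function(b0, b1000, dsc, record = NULL,
                            config = default_config(), side = NULL) {
  stopifnot(inherits(b0, "volume_image"), inherits(b1000, "volume_image"),
            inherits(dsc, "dsc_series"))
  .stop_grid(b0, b1000, "diffusion volumes")
  if (!identical(dim(b0$data), dim(dsc$data)[1:3]))
    stop("DSC series is not on the diffusion grid; inputs must be ",
         "co-registered")
  adc <- compute_adc(b0, b1000, b = config$b_value)
  conc <- signal_to_concentration(dsc)
  ttp <- compute_ttp(conc, smooth_window = config$ttp_smooth)
  brain <- compute_brain_mask(b0, close_radius = config$brain_close_radius)
  lat <- if (is.null(side)) {
    detect_laterality(adc, ttp, brain,
                      min_score = config$laterality_min_score,
                      z_cut = config$laterality_z_cut,
                      f_floor = config$laterality_f_floor)
  } else {
    manual_laterality(side, brain, reference = b0)
  }
  if (lat$status == "undetermined")
    stop(structure(
      class = c("laterality_undetermined", "error", "condition"),
      list(message = sprintf(
        "lesion laterality undetermined (asymmetry score %.3f < %.3f); pass an explicit side",
        lat$asymmetry_score, config$laterality_min_score),
        call = sys.call(-1))))
  dwi_lesion <- segment_dwi_lesion(
    b1000, adc, brain, lat, k = config$dwi_k, adc_max = config$adc_max,
    ref_window = config$ref_window, open_radius = config$open_radius,
    min_cluster_mL = config$min_cluster_mL,
    allow_midline = config$allow_midline)
  ttp_lesion <- segment_ttp_lesion(
    ttp, brain, lat, delay_threshold = config$ttp_delay_threshold,
    ref_window = config$ref_window, open_radius = config$open_radius,
    min_cluster_mL = config$min_cluster_mL,
    allow_midline = config$allow_midline)
  mm <- compute_mismatch(ttp_lesion, dwi_lesion,
                         convention = config$ratio_convention, side = lat)
  elig <- imaging_eligibility(mm,
                              volume_threshold = config$volume_threshold_mL,
                              ratio_threshold = config$ratio_threshold)
  contra <- if (is.null(record)) "unassessable:no_clinical_record"
            else check_contraindications(record, window_h = config$window_h)
  structure(
    list(adc = adc, ttp = ttp, brain = brain, laterality = lat,
         dwi_lesion = dwi_lesion, ttp_lesion = ttp_lesion,
         mismatch = mm, eligibility = elig, contraindications = contra,
         record = record, config = config,
         config_hash = config_hash(config)),
    class = "stroke_assessment"
  )
}

#' @export
print.stroke_assessment <- function(x, ...) {
  cat("<stroke_assessment>\n")
  print(x$laterality)
  print(x$mismatch)
  print(x$eligibility)
  cat(sprintf("  contraindications: %s\n",
              if (length(x$contraindications)) paste(x$contraindications,
                                                     collapse = ", ")
              else "none"))
  invisible(x)
}

# represent a ratio for JSON: Inf serializes as the string "inf"
.json_ratio <- function(r) {
  if (is.na(r)) NA else if (is.infinite(r)) "inf" else r
}

#' Write an assessment report and its masks
#'
#' Emits `report.json` (volumes, ratio and its convention, thresholds,
#' eligibility, contraindication flags, laterality, software version,
#' resolved configuration and its hash) plus the brain, DWI lesion, TTP
#' lesion and mismatch masks as NIfTI. The report contains no timestamps,
#' so a re-run with the same inputs and configuration is byte-identical.
#'
#' @param assessment a `stroke_assessment`.
#' @param dir output directory.
#' @return Path to `report.json`, invisibly.
#' @export
write_report <- function(assessment, dir) {
  stopifnot(inherits(assessment, "stroke_assessment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(assessment$brain, file.path(dir, "brain_mask.nii.gz"))
  write_volume(assessment$dwi_lesion, file.path(dir, "dwi_lesion.nii.gz"))
  write_volume(assessment$ttp_lesion, file.path(dir, "ttp_lesion.nii.gz"))
  write_volume(assessment$mismatch$mask, file.path(dir, "mismatch.nii.gz"))
  m <- assessment$mismatch
  report <- list(
    patient_id = if (!is.null(assessment$record))
      assessment$record$id else NA,
    laterality = list(side = assessment$laterality$side,
                      hemisphere = assessment$laterality$hemisphere,
                      asymmetry_score = assessment$laterality$asymmetry_score,
                      status = assessment$laterality$status),
    volumes_mL = list(dwi_core = m$dwi_volume_mL,
                      ttp_lesion = m$ttp_volume_mL,
                      mismatch = m$mismatch_volume_mL),
    mismatch_ratio = .json_ratio(m$mismatch_ratio),
    ratio_convention = m$ratio_convention,
    eligibility = list(
      eligible = assessment$eligibility$eligible,
      volume_threshold_mL = assessment$eligibility$volume_threshold,
      ratio_threshold = assessment$eligibility$ratio_threshold),
    contraindications = as.list(assessment$contraindications),
    software_version = as.character(utils::packageVersion("strokemismatch")),
    config = assessment$config,
    config_hash = assessment$config_hash
  )
  path <- file.path(dir, "report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Evaluate a cohort table
#'
#' Reproduces the validation machinery on a cohort data frame (for example
#' from [generate_cohort()] or a cohort CSV): imaging eligibility per
#' patient, the confusion matrix against the actual treatment decision,
#' classification metrics, per-cell summaries of decision and outcome
#' variables, rank-sum comparisons of the TP group against the other cells,
#' volumetric agreement between automated and manual mismatch volumes
#' (when a `manual_mismatch_mL` column is present), and a Gini
#' classification tree over the presentation variables (contraindication
#' count, imaging eligibility, mismatch volume, NIHSS).
#'
#' @param cohort cohort data frame; required columns:
#'   `mismatch_volume_mL`, `mismatch_ratio`, `treated`, `sbp`, `dbp`,
#'   `inr`, `anticoagulant`, `hemorrhage`, `onset_to_treatment`,
#'   `nihss_acute`, `nihss_24h`.
#' @param config pipeline configuration (thresholds, treatment window).
#' @return List with `confusion`, `metrics`, `group_summary`, `rank_sum`,
#'   `agreement` (or `NULL`), `cart`, and the per-patient `cells`.
#' @export
evaluate_cohort <- function(cohort, config = default_config()) {
  required <- c("mismatch_volume_mL", "mismatch_ratio", "treated", "sbp",
                "dbp", "inr", "anticoagulant", "hemorrhage",
                "onset_to_treatment", "nihss_acute", "nihss_24h")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols))
    stop("cohort is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!nrow(cohort)) stop("empty cohort")
  eligible <- cohort$mismatch_volume_mL > config$volume_threshold_mL &
    !is.na(cohort$mismatch_ratio) &
    cohort$mismatch_ratio > config$ratio_threshold
  cm <- build_confusion(eligible, cohort$treated)
  cohort$cell <- confusion_cells(eligible, cohort$treated)
  n_contra <- vapply(seq_len(nrow(cohort)), function(i) {
    fl <- check_contraindications(cohort[i, ], window_h = config$window_h)
    sum(!startsWith(fl, "unassessable"))
  }, numeric(1))
  gs <- group_summary(cohort)
  rank_tests <- list()
  tp_mm <- cohort$mismatch_volume_mL[cohort$cell == "TP"]
  for (g in c("TN", "FP", "FN")) {
    other <- cohort$mismatch_volume_mL[cohort$cell == g]
    if (length(tp_mm) && length(other))
      rank_tests[[paste0("mismatch_TP_vs_", g)]] <-
        rank_sum_test(tp_mm, other)
  }
  agreement <- if ("manual_mismatch_mL" %in% names(cohort) &&
                   nrow(cohort) >= 3)
    volumetric_agreement(cohort$manual_mismatch_mL,
                         cohort$mismatch_volume_mL)
  features <- data.frame(
    contraindication_count = n_contra,
    mismatch_eligible = as.numeric(eligible),
    mismatch_volume = cohort$mismatch_volume_mL,
    nihss = cohort$nihss_acute
  )
  tree <- if (nrow(cohort) >= 10 && length(unique(cohort$treated)) == 2)
    fit_cart(features,
             ifelse(cohort$treated, "thrombolysis", "supportive"))
  list(confusion = cm, metrics = classification_metrics(cm),
       group_summary = gs, rank_sum = rank_tests, agreement = agreement,
       cart = tree, cells = cohort$cell, eligible = eligible,
       contraindication_count = n_contra)
}
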