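# evaluate `expr` under a fixed seed, restoring the caller's RNG state
.local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Stroke phantom configuration
#'
#' Defines the synthetic acquisition: an ellipsoidal two-hemisphere brain
#' with an ischemic core (reduced ADC, DWI hyperintensity) nested in a
#' larger hypoperfused region whose contrast bolus arrives late. Defaults
#' emulate a routine acute stroke protocol: 24 cm field of view on a 64x64
#' matrix (3.75 mm in-plane), 5 mm slices, DSC with TR 1.5 s and TE 50 ms,
#' diffusion pair at b = 0 and 1000 s/mm^2, normal ADC 0.9e-3 mm^2/s and
#' core ADC 0.5e-3 mm^2/s.
#'
#' @param grid_shape array shape (default 64 x 64 x 20).
#' @param spacing voxel spacing in mm (default 3.75, 3.75, 5).
#' @param side lesion side: `"left"`, `"right"` or `"none"` (symmetric,
#'   lesion-free phantom).
#' @param core_volume_mL,hypo_volume_mL target volumes of the ischemic core
#'   and the hypoperfused region (core nested inside; core <= hypo).
#' @param ttp_delay_s bolus arrival delay inside the hypoperfused region, s.
#' @param adc_normal,adc_core ADC of normal and core tissue, mm^2/s.
#' @param dwi_hyper_factor T2 signal elevation factor of the core (applied
#'   to the baseline signal of both diffusion images, so the injected ADC
#'   is unchanged).
#' @param noise_sd Gaussian noise SD relative to the tissue baseline signal
#'   (default 0.05; 0 disables noise).
#' @param tr,te DSC repetition and echo time, s.
#' @param n_timepoints,n_baseline DSC samples and pre-bolus baseline count.
#' @param bolus_arrival_s normal-tissue bolus arrival time, s.
#' @param bolus_alpha,bolus_beta gamma-variate shape (default alpha 3,
#'   beta 1.5 s).
#' @param peak_concentration peak tissue concentration surrogate, 1/s.
#' @param b_value diffusion weighting of the second image, s/mm^2.
#' @param baseline_b0,baseline_dsc tissue baseline signal levels (a.u.).
#' @param eye_blobs add two small non-brain blobs (for brain-mask tests).
#' @param seed RNG seed; fully determines all generated data.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(grid_shape = c(64, 64, 20),
                           spacing = c(3.75, 3.75, 5),
                           side = c("right", "left", "none"),
                           core_volume_mL = 20, hypo_volume_mL = 100,
                           ttp_delay_s = 6,
                           adc_normal = 0.9e-3, adc_core = 0.5e-3,
                           dwi_hyper_factor = 1.6, noise_sd = 0.05,
                           tr = 1.5, te = 0.05,
                           n_timepoints = 40, n_baseline = 8,
                           bolus_arrival_s = 14,
                           bolus_alpha = 3, bolus_beta = 1.5,
                           peak_concentration = 10,
                           b_value = 1000,
                           baseline_b0 = 1000, baseline_dsc = 800,
                           eye_blobs = FALSE, seed = 1L) {
  side <- match.arg(side)
  if (side != "none" && core_volume_mL > hypo_volume_mL)
    stop("nested mode requires core_volume_mL <= hypo_volume_mL")
  cfg <- list(grid_shape = as.integer(grid_shape), spacing = spacing,
              side = side, core_volume_mL = core_volume_mL,
              hypo_volume_mL = hypo_volume_mL, ttp_delay_s = ttp_delay_s,
              adc_normal = adc_normal, adc_core = adc_core,
              dwi_hyper_factor = dwi_hyper_factor, noise_sd = noise_sd,
              tr = tr, te = te, n_timepoints = as.integer(n_timepoints),
              n_baseline = as.integer(n_baseline),
              bolus_arrival_s = bolus_arrival_s,
              bolus_alpha = bolus_alpha, bolus_beta = bolus_beta,
              peak_concentration = peak_concentration, b_value = b_value,
              baseline_b0 = baseline_b0, baseline_dsc = baseline_dsc,
              eye_blobs = eye_blobs, seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  cfg
}

#' Generate a synthetic acute stroke MRI study
#'
#' Builds the diffusion pair, the DSC perfusion series and the ground-truth
#' masks from a [phantom_config()]. The brain is an ellipsoid; the
#' hypoperfused region and nested core are ellipsoidal, sized by selecting
#' the requested number of voxels nearest (in an anisotropic metric) to an
#' off-lattice lesion center, so the constructed truth volume matches the
#' requested volume to within one voxel. The DSC curve is a gamma-variate
#' bolus, shifted by `ttp_delay_s` inside the hypoperfused region; the only
#' hypoperfusion effect is the arrival delay. Noise is additive Gaussian on
#' the signal (a deliberate simplification of Rician MR noise, adequate at
#' phantom SNR). Truth masks are returned noise-free. The array convention
#' is axis 1 = left-right with patient left at high indices.
#'
#' @param cfg a [phantom_config()].
#' @return List with elements `b0`, `b1000` (`volume_image`), `dsc`
#'   (`dsc_series`), `truth` (brain/core/hypoperfusion masks, true volumes,
#'   side) and `record` (a one-row clinical data frame).
#' @export
generate_stroke_phantom <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "phantom_config"))
  .local_seed(cfg$seed, .generate_phantom_impl(cfg))
}

.generate_phantom_impl <- function(cfg) {
  d <- cfg$grid_shape
  sp <- cfg$spacing
  vox_mL <- prod(sp) / 1000
  # voxel center coordinates (mm) relative to the grid center
  cx <- (slice.index(array(0L, d), 1) - (d[1] + 1) / 2) * sp[1]
  cy <- (slice.index(array(0L, d), 2) - (d[2] + 1) / 2) * sp[2]
  cz <- (slice.index(array(0L, d), 3) - (d[3] + 1) / 2) * sp[3]
  semi <- c(0.44 * d[1] * sp[1], 0.33 * d[2] * sp[2], 0.45 * d[3] * sp[3])
  brain <- (cx / semi[1])^2 + (cy / semi[2])^2 + (cz / semi[3])^2 <= 1

  core <- array(FALSE, d)
  hypo <- array(FALSE, d)
  if (cfg$side != "none") {
    # lesion center: halfway out in the affected hemisphere, off-lattice
    # offsets break distance ties so voxel counts can be hit exactly
    xsgn <- if (cfg$side == "left") 1 else -1 # patient left = high index
    center <- c(xsgn * 0.5 * semi[1] + 0.37 * sp[1],
                0.23 * sp[2], 0.41 * sp[3])
    rho2 <- (cx - center[1])^2 + (1.15 * (cy - center[2]))^2 +
      (1.25 * (cz - center[3]))^2
    ord <- order(rho2)
    k_hypo <- max(1L, round(cfg$hypo_volume_mL / vox_mL))
    k_core <- max(1L, round(cfg$core_volume_mL / vox_mL))
    if (k_core > k_hypo) stop("core cannot exceed the hypoperfused region")
    sel <- ord[seq_len(k_hypo)]
    same_side <- xsgn * cx[sel] > 0
    if (!all(brain[sel] & same_side))
      stop("requested lesion volume exceeds the capacity of the affected ",
           "hemisphere")
    hypo[sel] <- TRUE
    core[ord[seq_len(k_core)]] <- TRUE
  }

  # diffusion pair
  base <- ifelse(brain, cfg$baseline_b0, 0)
  base[core] <- base[core] * cfg$dwi_hyper_factor
  adc_true <- ifelse(brain, cfg$adc_normal, 0)
  adc_true[core] <- cfg$adc_core
  b0 <- base
  b1000 <- base * exp(-cfg$b_value * adc_true)
  if (cfg$noise_sd > 0) {
    s <- cfg$noise_sd * cfg$baseline_b0
    b0 <- b0 + array(stats::rnorm(length(b0), 0, s), d)
    b1000 <- b1000 + array(stats::rnorm(length(b1000), 0, s), d)
  }

  # DSC series: gamma-variate bolus, arrival delayed inside the lesion
  nt <- cfg$n_timepoints
  tgrid <- (seq_len(nt) - 1) * cfg$tr
  curve <- function(t0) {
    dt <- tgrid - t0
    out <- numeric(nt)
    pos <- dt > 0
    ab <- cfg$bolus_alpha * cfg$bolus_beta
    out[pos] <- cfg$peak_concentration * (dt[pos] / ab)^cfg$bolus_alpha *
      exp(cfg$bolus_alpha - dt[pos] / cfg$bolus_beta)
    out
  }
  conc_normal <- curve(cfg$bolus_arrival_s)
  conc_delayed <- curve(cfg$bolus_arrival_s + cfg$ttp_delay_s)
  nvox <- prod(d)
  sig <- matrix(0, nvox, nt)
  bi <- which(brain & !hypo)
  hi <- which(hypo)
  if (length(bi))
    sig[bi, ] <- cfg$baseline_dsc *
      exp(-cfg$te * matrix(conc_normal, length(bi), nt, byrow = TRUE))
  if (length(hi))
    sig[hi, ] <- cfg$baseline_dsc *
      exp(-cfg$te * matrix(conc_delayed, length(hi), nt, byrow = TRUE))
  if (cfg$noise_sd > 0)
    sig <- sig + stats::rnorm(length(sig), 0, cfg$noise_sd * cfg$baseline_dsc)

  if (cfg$eye_blobs) {
    eye_r <- 8
    for (ex in c(-30, 30)) {
      eye <- ((cx - ex)^2 + (cy + semi[2] + 15)^2 + cz^2) <= eye_r^2
      b0[eye] <- b0[eye] + 0.8 * cfg$baseline_b0
      b1000[eye] <- b1000[eye] + 0.5 * cfg$baseline_b0
    }
  }

  geom <- list(lr_axis = 1L, lr_dir = 1L)
  b0_v <- volume_image(b0, sp, geom$lr_axis, geom$lr_dir)
  b1000_v <- volume_image(b1000, sp, geom$lr_axis, geom$lr_dir)
  dsc <- dsc_series(array(sig, c(d, nt)), sp, cfg$tr, cfg$te,
                    cfg$n_baseline, geom$lr_axis, geom$lr_dir)
  truth <- list(
    brain = as_mask(brain, b0_v),
    core = as_mask(core, b0_v),
    hypoperfusion = as_mask(hypo, b0_v),
    core_volume_mL = sum(core) * vox_mL,
    hypo_volume_mL = sum(hypo) * vox_mL,
    mismatch_volume_mL = sum(hypo & !core) * vox_mL,
    side = if (cfg$side == "none") NA_character_ else cfg$side
  )
  record <- data.frame(
    id = sprintf("PHANTOM-%d", cfg$seed),
    nihss_acute = min(42, round(4 + 0.08 * truth$hypo_volume_mL)),
    nihss_24h = min(42, round(2 + 0.05 * truth$hypo_volume_mL)),
    sbp = 140, dbp = 80, inr = 1.0,
    anticoagulant = FALSE, hemorrhage = FALSE,
    onset_to_treatment = 2.0, treated = TRUE,
    mrs_3m = NA_real_, nihss_3m = NA_real_,
    stringsAsFactors = FALSE
  )
  list(b0 = b0_v, b1000 = b1000_v, dsc = dsc, truth = truth,
       record = record, config = cfg)
}

#' Write a generated phantom study to disk
#'
#' Writes `b0.nii.gz`, `b1000.nii.gz`, `pwi.nii.gz`, the truth masks, a
#' clinical JSON record and the acquisition metadata into a directory.
#'
#' @param ph output of [generate_stroke_phantom()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(ph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(ph$b0, file.path(dir, "b0.nii.gz"))
  write_volume(ph$b1000, file.path(dir, "b1000.nii.gz"))
  write_dsc(ph$dsc, file.path(dir, "pwi.nii.gz"))
  write_volume(ph$truth$brain, file.path(dir, "truth_brain.nii.gz"))
  write_volume(ph$truth$core, file.path(dir, "truth_core.nii.gz"))
  write_volume(ph$truth$hypoperfusion,
               file.path(dir, "truth_hypoperfusion.nii.gz"))
  jsonlite::write_json(ph$record, file.path(dir, "clinical.json"),
                       auto_unbox = FALSE, digits = NA, na = "null")
  meta <- list(tr = ph$dsc$tr, te = ph$dsc$te,
               n_baseline = ph$dsc$n_baseline,
               b_value = ph$config$b_value, side = ph$truth$side,
               core_volume_mL = ph$truth$core_volume_mL,
               hypo_volume_mL = ph$truth$hypo_volume_mL,
               seed = ph$config$seed)
  jsonlite::write_json(meta, file.path(dir, "acquisition.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# cell-specific cohort generation parameters: contraindication prevalence
# and location/scale of the decision variables, loosely shaped like a
# thrombolysis cohort (TP/FN treated; TP/FP imaging-eligible)
.cohort_cells <- c("TP", "TN", "FP", "FN")

#' Generate a synthetic evaluation cohort
#'
#' Produces per-patient clinical records and mismatch statistics consistent
#' with the requested confusion-matrix cells: TP and FP rows satisfy the
#' imaging criteria (mismatch volume > `volume_threshold` and ratio >
#' `ratio_threshold`), TN and FN rows fail at least one criterion, and the
#' treated flag follows the cell definition (TP/FN treated). The DWI and
#' TTP volumes are constructed with the core nested in the hypoperfused
#' lesion, so `mismatch = ttp - dwi`. Contraindication prevalence per cell
#' defaults to TP 24%, TN 83%, FP 73%, FN 23%. A synthetic manual
#' (expert-consensus) mismatch volume is included for volumetric-agreement
#' exercises.
#'
#' @param n cohort size; must equal `sum(group_sizes)`.
#' @param group_sizes named or positional counts `(tp, tn, fp, fn)`.
#' @param seed RNG seed.
#' @param contra_prev per-cell contraindication prevalence (tp, tn, fp, fn).
#' @param volume_threshold,ratio_threshold imaging eligibility thresholds.
#' @param ratio_convention ratio convention for the generated ratios.
#' @return Data frame, one row per patient, with clinical fields, volumes,
#'   `cell`, `treated`, `eligible` and `salvage_mL`.
#' @export
generate_cohort <- function(n = 228, group_sizes = c(112, 12, 30, 74),
                            seed = 1L,
                            contra_prev = c(tp = 0.24, tn = 0.83,
                                            fp = 0.73, fn = 0.23),
                            volume_threshold = 10, ratio_threshold = 1.2,
                            ratio_convention = c("pwi_over_dwi",
                                                 "mismatch_over_core")) {
  ratio_convention <- match.arg(ratio_convention)
  if (length(group_sizes) != 4L) stop("group_sizes must have 4 entries")
  if (is.null(names(contra_prev)))
    names(contra_prev) <- c("tp", "tn", "fp", "fn")
  if (sum(group_sizes) != n)
    stop("group sizes must sum to n (", sum(group_sizes), " != ", n, ")")
  .local_seed(seed, {
    cells <- rep(.cohort_cells, group_sizes)
    rows <- lapply(seq_along(cells), function(i)
      .cohort_row(i, cells[i], contra_prev, volume_threshold,
                  ratio_threshold, ratio_convention))
    df <- do.call(rbind, rows)
    rownames(df) <- NULL
    df
  })
}

.cohort_row <- function(i, cell, contra_prev, vol_thr, ratio_thr,
                        convention) {
  eligible <- cell %in% c("TP", "FP")
  treated <- cell %in% c("TP", "FN")
  med_mm <- c(TP = 96, FP = 73.4)

  if (eligible) {
    mm <- vol_thr + stats::rlnorm(1, log(med_mm[[cell]] - vol_thr), 0.7)
    ratio <- ratio_thr + 0.05 + stats::rexp(1, rate = 2 / 3)
    dwi <- if (convention == "pwi_over_dwi") mm / (ratio - 1) else mm / ratio
  } else {
    p0 <- if (cell == "TN") 0.5 else 0.6
    p_small <- 0.3
    u <- stats::runif(1)
    if (u < p0) {
      mm <- 0
      dwi <- stats::rlnorm(1, log(15), 0.8)
    } else if (u < p0 + p_small) {
      mm <- if (cell == "TN") stats::runif(1, 0.5, 10)
            else stats::runif(1, 0.2, 3)
      dwi <- stats::rlnorm(1, log(8), 0.8)
    } else {
      mm <- if (cell == "TN") stats::runif(1, vol_thr + 0.1, 30)
            else stats::runif(1, vol_thr + 0.1, 20)
      ratio <- if (convention == "pwi_over_dwi")
        1 + (ratio_thr - 1) * stats::runif(1, 0.5, 0.999)
      else ratio_thr * stats::runif(1, 0.5, 0.999)
      dwi <- if (convention == "pwi_over_dwi") mm / (ratio - 1)
             else mm / ratio
    }
  }
  ttp <- if (mm == 0) dwi * stats::runif(1, 0.3, 1) else dwi + mm
  ratio_out <- if (dwi > 0) {
    if (convention == "pwi_over_dwi") ttp / dwi else mm / dwi
  } else if ((if (convention == "pwi_over_dwi") ttp else mm) > 0) Inf
    else NA_real_

  has_contra <- stats::runif(1) < contra_prev[[tolower(cell)]]
  which_contra <- if (has_contra) sample(6L, 1L) else 0L
  sbp <- if (which_contra == 1L) stats::runif(1, 186, 230)
         else stats::runif(1, 110, 180)
  dbp <- if (which_contra == 2L) stats::runif(1, 111, 130)
         else stats::runif(1, 60, 105)
  hemorrhage <- which_contra == 3L
  anticoagulant <- which_contra == 4L
  inr <- if (which_contra == 5L) stats::runif(1, 1.8, 3.5)
         else stats::runif(1, 0.9, 1.3)
  onset <- if (which_contra == 6L) stats::runif(1, 4.6, 9)
           else stats::runif(1, 0.5, 4.4)

  med_nihss <- c(TP = 11, TN = 6, FP = 8, FN = 5)
  med_delta <- c(TP = 5, TN = 3, FP = 2, FN = 1)
  med_mrs <- c(TP = 2, TN = 2, FP = 2, FN = 1)
  nihss_acute <- max(0, min(42, round(stats::rlnorm(
    1, log(med_nihss[[cell]]), 0.45))))
  delta <- round(stats::rnorm(1, med_delta[[cell]], 2))
  nihss_24h <- max(0, min(42, nihss_acute - delta))
  nihss_3m <- max(0, min(42, round(nihss_24h * stats::runif(1, 0.2, 0.8))))
  mrs_3m <- max(0, min(6, round(stats::rnorm(1, med_mrs[[cell]], 1))))
  salvage <- if (mm > 0) mm * stats::runif(
    1, if (eligible) 0.7 else 0.2, if (eligible) 0.98 else 0.8) else 0
  manual_mm <- max(0, mm + stats::rnorm(1, 8, 20))

  data.frame(
    id = sprintf("SYN-%04d", i), cell = cell,
    treated = treated, eligible = eligible,
    dwi_volume_mL = dwi, ttp_volume_mL = ttp, mismatch_volume_mL = mm,
    mismatch_ratio = ratio_out, ratio_convention = convention,
    salvage_mL = salvage, manual_mismatch_mL = manual_mm,
    nihss_acute = nihss_acute, nihss_24h = nihss_24h,
    nihss_3m = nihss_3m, mrs_3m = mrs_3m,
    sbp = sbp, dbp = dbp, inr = inr,
    anticoagulant = anticoagulant, hemorrhage = hemorrhage,
    onset_to_treatment = onset,
    stringsAsFactors = FALSE
  )
}
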