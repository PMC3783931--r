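# grid with 0.02 mL voxels: volumes below are exact multiples
ref_grid <- function() tiny_volume(dims = c(40, 20, 10), spacing = c(2, 2, 5))

test_that("mismatch volumes and ratios follow set arithmetic", {
  g <- ref_grid()
  # nested: TTP 100 mL (5000 vox) containing DWI 20 mL (1000 vox)
  ttp <- lesion_mask(box_mask(g, 1:25, 1:20, 1:10)$data, g, "TTP")
  dwi <- lesion_mask(box_mask(g, 1:10, 1:10, 1:10)$data, g, "DWI")
  m <- compute_mismatch(ttp, dwi, convention = "mismatch_over_core")
  expect_equal(m$ttp_volume_mL, 100)
  expect_equal(m$dwi_volume_mL, 20)
  expect_equal(m$mismatch_volume_mL, 80)
  expect_equal(m$mismatch_ratio, 4.0)
  m2 <- compute_mismatch(ttp, dwi, convention = "pwi_over_dwi")
  expect_equal(m2$mismatch_ratio, 5.0)

  # disjoint: TTP 30 mL, DWI 10 mL -> mismatch 30 mL
  ttp_d <- lesion_mask(box_mask(g, 1:15, 1:10, 1:10)$data, g, "TTP")
  dwi_d <- lesion_mask(box_mask(g, 30:34, 1:10, 1:10)$data, g, "DWI")
  expect_equal(compute_mismatch(ttp_d, dwi_d)$mismatch_volume_mL, 30)

  # empty core: infinity ratio sentinel
  none <- lesion_mask(array(FALSE, dim(g$data)), g, "DWI")
  ttp15 <- lesion_mask(box_mask(g, 1:15, 1:10, 1:5)$data, g, "TTP")
  m3 <- compute_mismatch(ttp15, none)
  expect_equal(m3$mismatch_volume_mL, 15)
  expect_identical(m3$mismatch_ratio, Inf)

  expect_error(compute_mismatch(ttp, lesion_mask(
    array(FALSE, c(4, 4, 4)), tiny_volume(0, dims = c(4, 4, 4)), "DWI")),
    "grid")
})

test_that("mismatch volume conservation holds exactly on random masks", {
  g <- ref_grid()
  set.seed(41)
  for (rep in 1:10) {
    t_arr <- array(runif(prod(dim(g$data))) < 0.3, dim(g$data))
    d_arr <- array(runif(prod(dim(g$data))) < 0.2, dim(g$data))
    ttp <- lesion_mask(t_arr, g, "TTP")
    dwi <- lesion_mask(d_arr, g, "DWI")
    m <- compute_mismatch(ttp, dwi)
    overlap <- sum(t_arr & d_arr) * voxel_volume_mL(g)
    expect_equal(m$mismatch_volume_mL + overlap, m$ttp_volume_mL)
    expect_lte(m$mismatch_volume_mL, m$ttp_volume_mL)
    expect_gte(m$mismatch_volume_mL,
               m$ttp_volume_mL - m$dwi_volume_mL - 1e-12)
  }
})

test_that("eligibility applies strict thresholds on both criteria", {
  g <- ref_grid()
  dwi <- lesion_mask(box_mask(g, 1:10, 1:10, 1:5)$data, g, "DWI") # 10 mL
  # mismatch 96 mL (TP-group-like): eligible
  dwi_far <- lesion_mask(box_mask(g, 30:34, 1:10, 1:10)$data, g, "DWI")
  ttp_big <- lesion_mask(box_mask(g, 1:24, 1:20, 1:10)$data, g, "TTP")
  m_big <- compute_mismatch(ttp_big, dwi_far)
  expect_equal(m_big$mismatch_volume_mL, 96)
  expect_true(imaging_eligibility(m_big)$eligible)

  # mismatch 0 mL (TN/FN-group-like): not eligible
  m_zero <- compute_mismatch(dwi, dwi)
  expect_equal(m_zero$mismatch_volume_mL, 0)
  expect_false(imaging_eligibility(m_zero)$eligible)

  # boundary: mismatch exactly 10 mL with comfortable ratio is NOT eligible
  ttp_b <- lesion_mask(box_mask(g, 1:20, 1:10, 1:5)$data, g, "TTP") # 20 mL
  m_b <- compute_mismatch(ttp_b, dwi) # mismatch exactly 10, ratio 2.0
  expect_equal(m_b$mismatch_volume_mL, 10)
  expect_equal(m_b$mismatch_ratio, 2.0)
  expect_false(imaging_eligibility(m_b)$eligible)
  expect_true(imaging_eligibility(m_b, volume_threshold = 9.99)$eligible)
})

test_that("enlarging the TTP lesion never revokes eligibility", {
  g <- ref_grid()
  dwi <- lesion_mask(box_mask(g, 1:8, 1:8, 1:5)$data, g, "DWI")
  sizes <- seq(10, 40, by = 5)
  elig <- vapply(sizes, function(s) {
    ttp <- lesion_mask(box_mask(g, 1:s, 1:20, 1:10)$data, g, "TTP")
    imaging_eligibility(compute_mismatch(ttp, dwi,
                                         "pwi_over_dwi"))$eligible
  }, logical(1))
  expect_true(all(diff(as.integer(elig)) >= 0))
})

test_that("contraindication screen flags each criterion strictly", {
  base <- list(sbp = 150, dbp = 80, hemorrhage = FALSE,
               anticoagulant = FALSE, inr = 1.0, onset_to_treatment = 3.0)
  expect_identical(check_contraindications(base), character(0))

  hi_sbp <- base; hi_sbp$sbp <- 190
  expect_identical(check_contraindications(hi_sbp), "hypertension_systolic")

  late <- base; late$onset_to_treatment <- 4.6
  expect_identical(check_contraindications(late), "beyond_window")
  at_window <- base; at_window$onset_to_treatment <- 4.5
  expect_identical(check_contraindications(at_window), character(0))

  at_bp <- base; at_bp$sbp <- 185; at_bp$dbp <- 110; at_bp$inr <- 1.7
  expect_identical(check_contraindications(at_bp), character(0))

  multi <- base
  multi$dbp <- 111; multi$anticoagulant <- TRUE; multi$inr <- 1.8
  multi$hemorrhage <- TRUE
  expect_setequal(check_contraindications(multi),
                  c("hypertension_diastolic", "anticoagulant_use",
                    "inr_elevated", "intracranial_hemorrhage"))
})

test_that("unknown fields are unassessable, never a pass", {
  rec <- list(sbp = NA, dbp = 80, hemorrhage = FALSE, anticoagulant = NA,
              inr = 1.2, onset_to_treatment = 2)
  flags <- check_contraindications(rec)
  expect_setequal(flags, c("unassessable:sbp", "unassessable:anticoagulant"))
  rec2 <- list(dbp = 80) # absent fields behave like NA
  expect_true("unassessable:sbp" %in% check_contraindications(rec2))
})
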