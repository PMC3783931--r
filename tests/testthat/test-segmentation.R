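test_that("mirror reference matches brute-force neighborhood statistics", {
  ph <- quick_phantom(side = "right", seed = 10)
  brain <- compute_brain_mask(ph$b0)
  lat <- manual_laterality("right", brain, ph$b0)
  ref <- mirror_reference(ph$b1000, brain, lat, window = 5L)
  valid <- brain$data > 0 & is.finite(ph$b1000$data)
  lo <- lat$lo; hi <- lat$hi
  set.seed(99)
  pts <- which(brain$data > 0)
  for (p in sample(pts, 25)) {
    ijk <- arrayInd(p, dim(brain$data))
    mi <- lo + hi - ijk[1] # mirrored index along the LR axis
    if (mi < 1 || mi > dim(brain$data)[1] || !brain$data[mi, ijk[2], ijk[3]]) {
      expect_true(is.nan(ref$mean[p]))
    } else {
      bb <- brute_box_stats(ph$b1000$data, valid, mi, ijk[2], ijk[3], 5)
      expect_equal(ref$mean[p], bb$mean, tolerance = 1e-9)
      expect_equal(ref$sd[p], bb$sd, tolerance = 1e-9)
      expect_equal(ref$n[p], bb$n)
    }
  }
})

test_that("mirror reference approximates local statistics on symmetry and is
          NaN outside the brain", {
  ph <- quick_phantom(side = "none", seed = 11)
  brain <- compute_brain_mask(ph$b0)
  lat <- manual_laterality("right", brain, ph$b0)
  ref <- mirror_reference(ph$b0, brain, lat)
  inside <- brain$data > 0 & !is.nan(ref$mean)
  # symmetric phantom: reference ~ tissue baseline everywhere in the brain
  expect_lt(max(abs(ref$mean[inside] - 1000)), 100)
  # voxels mirroring outside the brain are undefined
  outside_mirror <- brain$data > 0 & is.nan(ref$mean)
  d1 <- dim(brain$data)[1]
  if (any(outside_mirror)) {
    idx <- which(outside_mirror, arr.ind = TRUE)
    mi <- lat$lo + lat$hi - idx[, 1]
    ok <- mi >= 1 & mi <= d1
    expect_true(all(!brain$data[cbind(pmax(pmin(mi, d1), 1),
                                      idx[, 2], idx[, 3])] | !ok))
  }
})

test_that("DWI core segmentation recovers a 20 mL phantom core", {
  ph <- quick_phantom(side = "right", core_volume_mL = 20,
                      hypo_volume_mL = 100, seed = 12)
  brain <- compute_brain_mask(ph$b0)
  adc <- compute_adc(ph$b0, ph$b1000)
  lat <- manual_laterality("right", brain, ph$b0)
  core <- segment_dwi_lesion(ph$b1000, adc, brain, lat)
  expect_lt(abs(core$volume_mL - ph$truth$core_volume_mL) /
              ph$truth$core_volume_mL, 0.10)
  expect_gte(dice_coef(core, ph$truth$core), 0.8)

  # k -> large: empty mask
  empty <- segment_dwi_lesion(ph$b1000, adc, brain, lat, k = 50)
  expect_equal(empty$volume_mL, 0)
})

test_that("lesion-free symmetric phantoms give empty lesion masks", {
  ph <- quick_phantom(side = "none", seed = 13)
  brain <- compute_brain_mask(ph$b0)
  adc <- compute_adc(ph$b0, ph$b1000)
  ttp <- compute_ttp(signal_to_concentration(ph$dsc))
  lat <- manual_laterality("right", brain, ph$b0)
  core <- segment_dwi_lesion(ph$b1000, adc, brain, lat)
  hypo <- segment_ttp_lesion(ttp, brain, lat)
  expect_lt(core$volume_mL, 1)
  expect_lt(hypo$volume_mL, 1)
})

test_that("TTP lesion segmentation recovers a 100 mL hypoperfused region", {
  ph <- quick_phantom(side = "right", core_volume_mL = 20,
                      hypo_volume_mL = 100, ttp_delay_s = 6, seed = 14)
  brain <- compute_brain_mask(ph$b0)
  ttp <- compute_ttp(signal_to_concentration(ph$dsc))
  lat <- manual_laterality("right", brain, ph$b0)
  lesion <- segment_ttp_lesion(ttp, brain, lat)
  expect_lt(abs(lesion$volume_mL - ph$truth$hypo_volume_mL) /
              ph$truth$hypo_volume_mL, 0.10)
  expect_gte(dice_coef(lesion, ph$truth$hypoperfusion), 0.8)

  # delays entirely below the threshold produce an empty mask
  ph2 <- quick_phantom(side = "right", ttp_delay_s = 2, seed = 15)
  ttp2 <- compute_ttp(signal_to_concentration(ph2$dsc))
  brain2 <- compute_brain_mask(ph2$b0)
  low <- segment_ttp_lesion(ttp2, brain2,
                            manual_laterality("right", brain2, ph2$b0),
                            delay_threshold = 4)
  expect_equal(low$volume_mL, 0)

  # near-zero threshold: mask grows toward the whole delayed region and beyond
  loose <- segment_ttp_lesion(ttp, brain, lat, delay_threshold = 0.1)
  expect_gte(loose$volume_mL, lesion$volume_mL)
})

test_that("segmented volumes are monotone in their thresholds", {
  ph <- quick_phantom(side = "left", seed = 16)
  brain <- compute_brain_mask(ph$b0)
  adc <- compute_adc(ph$b0, ph$b1000)
  ttp <- compute_ttp(signal_to_concentration(ph$dsc))
  lat <- manual_laterality("left", brain, ph$b0)
  dwi_vols <- vapply(c(0.5, 1, 2, 4, 8), function(k)
    segment_dwi_lesion(ph$b1000, adc, brain, lat, k = k)$volume_mL,
    numeric(1))
  expect_true(all(diff(dwi_vols) <= 0))
  adc_vols <- vapply(c(800e-6, 620e-6, 450e-6, 300e-6), function(am)
    segment_dwi_lesion(ph$b1000, adc, brain, lat, adc_max = am)$volume_mL,
    numeric(1))
  expect_true(all(diff(adc_vols) <= 0))
  ttp_vols <- vapply(c(1, 2, 4, 5.5, 8), function(tau)
    segment_ttp_lesion(ttp, brain, lat, delay_threshold = tau)$volume_mL,
    numeric(1))
  expect_true(all(diff(ttp_vols) <= 0))
})

test_that("lesion segmentation is exactly mirror-equivariant", {
  ph <- quick_phantom(side = "right", seed = 17)
  brain <- compute_brain_mask(ph$b0)
  adc <- compute_adc(ph$b0, ph$b1000)
  ttp <- compute_ttp(signal_to_concentration(ph$dsc))
  lat <- manual_laterality("right", brain, ph$b0)
  core <- segment_dwi_lesion(ph$b1000, adc, brain, lat)
  hypo <- segment_ttp_lesion(ttp, brain, lat)

  fb <- flip_lr(brain)
  lat_f <- manual_laterality("right", fb, flip_lr(ph$b0))
  core_f <- segment_dwi_lesion(flip_lr(ph$b1000), flip_lr(adc), fb, lat_f)
  hypo_f <- segment_ttp_lesion(flip_lr(ttp), fb, lat_f)
  expect_identical(core_f$data, flip_lr(core)$data)
  expect_identical(hypo_f$data, flip_lr(hypo)$data)
})

test_that("lesions stay within the affected hemisphere by default", {
  ph <- quick_phantom(side = "right", hypo_volume_mL = 120, seed = 18)
  brain <- compute_brain_mask(ph$b0)
  ttp <- compute_ttp(signal_to_concentration(ph$dsc))
  lat <- manual_laterality("right", brain, ph$b0)
  lesion <- segment_ttp_lesion(ttp, brain, lat)
  idx <- which(lesion$data, arr.ind = TRUE)
  expect_true(all(idx[, 1] < lat$mid)) # right = low-index hemisphere
  expect_error(segment_ttp_lesion(ttp, brain, detect_laterality(
    compute_adc(ph$b0, ph$b0), ttp, brain, min_score = 2)), "undetermined")
})
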