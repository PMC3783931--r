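test_that("phantom truth volumes hit the requested sizes", {
  ph <- quick_phantom(side = "right", core_volume_mL = 20,
                      hypo_volume_mL = 100, seed = 1)
  vv <- voxel_volume_mL(ph$b0)
  expect_lte(abs(ph$truth$core_volume_mL - 20), vv)
  expect_lte(abs(ph$truth$hypo_volume_mL - 100), vv)
  # nesting: core within hypoperfusion within brain
  expect_true(all(!ph$truth$core$data | ph$truth$hypoperfusion$data))
  expect_true(all(!ph$truth$hypoperfusion$data | ph$truth$brain$data))
  expect_error(quick_phantom(core_volume_mL = 50, hypo_volume_mL = 20),
               "core")
  expect_error(quick_phantom(hypo_volume_mL = 900), "exceeds")
})

test_that("the same seed reproduces a phantom bit-identically", {
  a <- quick_phantom(seed = 42)
  b <- quick_phantom(seed = 42)
  expect_identical(a$b0$data, b$b0$data)
  expect_identical(a$b1000$data, b$b1000$data)
  expect_identical(a$dsc$data, b$dsc$data)
  c_ <- quick_phantom(seed = 43)
  expect_false(identical(a$b0$data, c_$b0$data))
})

test_that("phantom generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(quick_phantom(seed = 9))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("a side = none phantom is symmetric and lesion-free", {
  ph <- quick_phantom(side = "none", seed = 2)
  expect_equal(sum(ph$truth$core$data), 0)
  expect_equal(sum(ph$truth$hypoperfusion$data), 0)
  expect_true(is.na(ph$truth$side))
  # noiseless symmetric phantom mirrors exactly about the grid center
  ph0 <- quick_phantom(side = "none", noise_sd = 0, seed = 2)
  d1 <- dim(ph0$b0$data)[1]
  expect_identical(ph0$b0$data, ph0$b0$data[d1:1, , ])
})

test_that("injected signal physics match the configured parameters", {
  ph <- quick_phantom(side = "right", noise_sd = 0, seed = 3)
  adc <- compute_adc(ph$b0, ph$b1000)
  core <- ph$truth$core$data
  normal <- ph$truth$brain$data & !ph$truth$hypoperfusion$data
  expect_equal(unique(round(adc$data[core], 9)), 0.5e-3)
  expect_equal(unique(round(adc$data[normal], 9)), 0.9e-3)
  # core hyperintensity on b1000: factor x exp(-b (ADC_core - ADC_normal))
  expect_equal(mean(ph$b1000$data[core]) / mean(ph$b1000$data[normal]),
               1.6 * exp(-1000 * (0.5e-3 - 0.9e-3)), tolerance = 1e-9)
})

test_that("generated cohorts reproduce the requested confusion layout", {
  cohort <- generate_cohort(228, c(112, 12, 30, 74), seed = 4)
  expect_equal(nrow(cohort), 228)
  expect_equal(as.vector(table(factor(cohort$cell,
                                      c("TP", "TN", "FP", "FN")))),
               c(112, 12, 30, 74))
  cm <- build_confusion(cohort$eligible, cohort$treated)
  expect_equal(c(cm$tp, cm$tn, cm$fp, cm$fn), c(112, 12, 30, 74))
  expect_error(generate_cohort(100, c(50, 30, 10, 5)), "sum to n")
})

test_that("generated eligibility labels agree with the eligibility rule", {
  cohort <- generate_cohort(228, c(112, 12, 30, 74), seed = 5)
  recomputed <- vapply(seq_len(nrow(cohort)), function(i) {
    row <- cohort[i, ]
    # rebuild a mismatch result from the generated volumes
    ratio <- if (row$dwi_volume_mL > 0) {
      if (row$ratio_convention == "pwi_over_dwi")
        row$ttp_volume_mL / row$dwi_volume_mL
      else row$mismatch_volume_mL / row$dwi_volume_mL
    } else Inf
    row$mismatch_volume_mL > 10 && ratio > 1.2
  }, logical(1))
  expect_identical(recomputed, cohort$eligible)
  # salvage respects its definitional bound
  expect_true(all(cohort$salvage_mL <= cohort$mismatch_volume_mL + 1e-12))
  # a degenerate all-TP cohort leaves specificity undefined
  m <- classification_metrics(build_confusion(
    generate_cohort(20, c(20, 0, 0, 0), seed = 6)$eligible,
    generate_cohort(20, c(20, 0, 0, 0), seed = 6)$treated))
  expect_true(is.na(m[["specificity"]]))
})

test_that("cohort contraindication prevalence matches the configuration", {
  big <- generate_cohort(2000, c(500, 500, 500, 500), seed = 7)
  observed <- vapply(c("TP", "TN", "FP", "FN"), function(g) {
    sub <- big[big$cell == g, ]
    mean(vapply(seq_len(nrow(sub)), function(i)
      length(check_contraindications(sub[i, ])) > 0, logical(1)))
  }, numeric(1))
  configured <- c(TP = 0.24, TN = 0.83, FP = 0.73, FN = 0.23)
  expect_true(all(abs(observed - configured) < 0.05))
})
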