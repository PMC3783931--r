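test_that("confusion matrices count agreement cells correctly", {
  cohort <- generate_cohort(228, c(112, 12, 30, 74), seed = 3)
  eligible <- cohort$eligible
  treated <- cohort$treated
  cm <- build_confusion(eligible, treated)
  expect_equal(c(cm$tp, cm$tn, cm$fp, cm$fn), c(112, 12, 30, 74))

  all_pos <- build_confusion(rep(TRUE, 7), rep(TRUE, 7))
  expect_equal(all_pos$tp, 7)
  expect_equal(all_pos$tn + all_pos$fp + all_pos$fn, 0)

  expect_error(build_confusion(logical(0), logical(0)), "empty")
  expect_error(build_confusion(c(TRUE, NA), c(TRUE, FALSE)), "unknown")
  expect_error(build_confusion(TRUE, c(TRUE, FALSE)), "length")
})

test_that("classification metrics match direct formulas and handle zero
          denominators", {
  cm <- confusion_matrix(112, 12, 30, 74)
  m <- classification_metrics(cm)
  expect_equal(round(unname(m)), c(60, 29, 79, 14))
  expect_equal(m[["sensitivity"]], 100 * 112 / 186)

  perfect <- classification_metrics(confusion_matrix(5, 3, 0, 0))
  expect_equal(perfect[["sensitivity"]], 100)
  expect_equal(perfect[["specificity"]], 100)

  degenerate <- classification_metrics(confusion_matrix(0, 0, 0, 0))
  expect_true(all(is.na(degenerate)))
  expect_error(confusion_matrix(-1, 0, 0, 0), "non-negative")
})

test_that("metrics after build_confusion equal direct counting on random
          cohorts", {
  set.seed(61)
  for (rep in 1:10) {
    n <- sample(20:100, 1)
    pred <- runif(n) < 0.5
    act <- runif(n) < 0.7
    m <- classification_metrics(build_confusion(pred, act))
    expect_equal(m[["sensitivity"]],
                 100 * sum(pred & act) / sum(act))
    expect_equal(m[["ppv"]], 100 * sum(pred & act) / sum(pred))
  }
})

test_that("volumetric agreement reports Spearman and Bland-Altman values", {
  a <- c(10, 20, 30, 40, 55)
  ident <- volumetric_agreement(a, a)
  expect_equal(ident$spearman_rho, 1)
  expect_equal(ident$mean_difference, 0)
  expect_equal(ident$sd_difference, 0)

  shifted <- volumetric_agreement(a, a + 8)
  expect_equal(shifted$mean_difference, -8)
  expect_equal(shifted$sd_difference, 0)
  expect_equal(unname(shifted$limits_of_agreement), c(-8, -8))

  set.seed(62)
  x <- runif(10, 0, 150)
  y <- x + rnorm(10, 8, 20)
  ag <- volumetric_agreement(x, y)
  expect_equal(ag$spearman_rho, brute_spearman(x, y), tolerance = 1e-12)
  expect_equal(unname(ag$limits_of_agreement),
               mean(x - y) + c(-2, 2) * sd(x - y))

  expect_true(is.na(volumetric_agreement(rep(5, 4), 1:4)$spearman_rho))
  expect_error(volumetric_agreement(1:2, 1:2), "at least 3")
})

test_that("Spearman rho is invariant under strictly monotone transforms", {
  set.seed(63)
  x <- rlnorm(25, 3, 1)
  y <- x + rnorm(25, 0, 10)
  base <- volumetric_agreement(x, y)$spearman_rho
  expect_equal(volumetric_agreement(exp(x / 50), y)$spearman_rho, base)
  expect_equal(volumetric_agreement(x, log(y - min(y) + 1))$spearman_rho,
               base)
})

test_that("mismatch salvage follows mask set arithmetic exactly", {
  g <- tiny_volume(dims = c(40, 20, 10), spacing = c(2, 2, 5))
  mm <- lesion_mask(box_mask(g, 1:25, 1:10, 1:10)$data, g, "mismatch") # 50
  inf10 <- lesion_mask(box_mask(g, 1:5, 1:10, 1:10)$data, g, "FLAIR")  # 10
  s <- mismatch_salvage(mm, inf10)
  expect_equal(s$salvage_mL, 40)
  expect_equal(s$acute_mismatch_mL, 50)

  all_gone <- mismatch_salvage(mm, mm)
  expect_equal(all_gone$salvage_mL, 0)
  none <- lesion_mask(array(FALSE, dim(g$data)), g, "FLAIR")
  expect_equal(mismatch_salvage(mm, none)$salvage_mL, 50)

  # conservation: salvage + overlap = acute mismatch, exactly
  set.seed(64)
  for (rep in 1:10) {
    m_arr <- array(runif(prod(dim(g$data))) < 0.3, dim(g$data))
    i_arr <- array(runif(prod(dim(g$data))) < 0.4, dim(g$data))
    sr <- mismatch_salvage(lesion_mask(m_arr, g, "mismatch"),
                           lesion_mask(i_arr, g, "FLAIR"))
    overlap <- sum(m_arr & i_arr) * voxel_volume_mL(g)
    expect_equal(sr$salvage_mL + overlap, sr$acute_mismatch_mL)
    expect_gte(sr$salvage_mL, 0)
    expect_lte(sr$salvage_mL, sr$acute_mismatch_mL)
  }
})

test_that("rank-sum test matches exact enumeration on small fixtures", {
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p.value, 0.1) # 2 of the C(6,3)=20 arrangements as extreme

  same <- rank_sum_test(c(2, 5, 9, 9), c(2, 5, 9, 9))
  expect_equal(same$p.value, 1)

  set.seed(65)
  for (rep in 1:5) {
    x <- round(rnorm(8, 10, 3), 1)
    y <- round(rnorm(8, 12, 3), 1)
    r8 <- rank_sum_test(x, y)
    expect_lt(abs(r8$p.value - brute_rank_sum_p(x, y)), 0.011)
  }
  # tied fixture: enumeration path agrees with the brute-force oracle
  x <- c(1, 2, 2, 3, 7)
  y <- c(2, 3, 3, 5, 8)
  expect_equal(rank_sum_test(x, y)$p.value, brute_rank_sum_p(x, y))
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("group summaries use linear-interpolation percentiles", {
  cohort <- data.frame(
    cell = c(rep("TN", 3), "FP", rep("TP", 7)),
    mismatch_volume_mL = c(0, 0, 22, 50, 96, 48, 144, 80, 120, 60, 101),
    salvage_mL = 0, nihss_acute = 10, nihss_24h = 5)
  gs <- group_summary(cohort)
  tn <- gs[gs$cell == "TN" & gs$variable == "mismatch_volume_mL", ]
  expect_equal(tn$median, 0)
  fp <- gs[gs$cell == "FP" & gs$variable == "mismatch_volume_mL", ]
  expect_equal(fp$median, 50)   # singleton group
  expect_equal(fp$q25, 50)      # degenerate IQR
  tp <- gs[gs$cell == "TP" & gs$variable == "mismatch_volume_mL", ]
  x7 <- c(96, 48, 144, 80, 120, 60, 101)
  expect_equal(tp$median, brute_quantile7(x7, 0.5))
  expect_equal(tp$q25, brute_quantile7(x7, 0.25))
  expect_equal(tp$q75, brute_quantile7(x7, 0.75))
  fn <- gs[gs$cell == "FN" & gs$variable == "mismatch_volume_mL", ]
  expect_true(is.na(fn$median)) # empty group -> undefined markers
  # improvement sign convention: acute minus 24 h
  dn <- gs[gs$cell == "TP" & gs$variable == "delta_nihss", ]
  expect_equal(dn$median, 5)
})
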