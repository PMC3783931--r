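#' Confusion matrix from counts
#'
#' Cell semantics follow the decision-support reading: "positive" means the
#' automated assessment favors thrombolysis, the reference is the actual
#' clinical decision (or another reference stated in `reference_label`).
#'
#' @param tp,tn,fp,fn non-negative integer counts.
#' @param reference_label what the reference (column) dimension means.
#' @return An object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, tn, fp, fn,
                             reference_label = "actual treatment") {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  structure(list(tp = as.integer(tp), tn = as.integer(tn),
                 fp = as.integer(fp), fn = as.integer(fn),
                 total = as.integer(tp + tn + fp + fn),
                 reference_label = reference_label),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> (reference: %s)\n", x$reference_label))
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2,
              dimnames = list(predicted = c("positive", "negative"),
                              reference = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Build a confusion matrix from aligned decision vectors
#'
#' @param predicted logical vector: automated eligibility per patient.
#' @param actual logical vector: reference decision per patient (e.g.
#'   thrombolysis actually given).
#' @param reference_label label for the reference dimension.
#' @return A `confusion_matrix`.
#' @export
build_confusion <- function(predicted, actual,
                            reference_label = "actual treatment") {
  if (length(predicted) != length(actual))
    stop("'predicted' and 'actual' must have equal length")
  if (length(predicted) == 0L) stop("empty decision vectors")
  if (anyNA(predicted) || anyNA(actual))
    stop("unknown (NA) decisions are not allowed in a confusion matrix")
  predicted <- as.logical(predicted)
  actual <- as.logical(actual)
  confusion_matrix(tp = sum(predicted & actual),
                   tn = sum(!predicted & !actual),
                   fp = sum(predicted & !actual),
                   fn = sum(!predicted & actual),
                   reference_label = reference_label)
}

#' Classification metrics from a confusion matrix
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive predictive
#' value `tp/(tp+fp)` and negative predictive value `tn/(tn+fn)`, each as a
#' percentage. A zero denominator yields `NA` (an explicit undefined
#' marker), never 0.
#'
#' @param cm a `confusion_matrix`.
#' @return Named numeric vector (percent): `sensitivity`, `specificity`,
#'   `ppv`, `npv`.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  frac <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  c(sensitivity = frac(cm$tp, cm$tp + cm$fn),
    specificity = frac(cm$tn, cm$tn + cm$fp),
    ppv = frac(cm$tp, cm$tp + cm$fp),
    npv = frac(cm$tn, cm$tn + cm$fn))
}

#' Volumetric agreement between two measurement series
#'
#' Spearman rank correlation (average ranks on ties) plus Bland-Altman
#' statistics of the differences `a - b`: mean difference, SD, and limits
#' of agreement at mean +/- 2 SD.
#'
#' @param vols_a,vols_b paired volume measurements (mL), equal length >= 3.
#' @return An object of class `agreement_summary` with fields
#'   `spearman_rho`, `mean_difference`, `sd_difference`,
#'   `limits_of_agreement` (length 2), `n`. `spearman_rho` is `NA` when
#'   either input is constant.
#' @export
volumetric_agreement <- function(vols_a, vols_b) {
  if (length(vols_a) != length(vols_b))
    stop("input vectors must have equal length")
  if (length(vols_a) < 3L) stop("need at least 3 paired measurements")
  if (anyNA(vols_a) || anyNA(vols_b)) stop("missing values not allowed")
  rho <- if (stats::sd(vols_a) == 0 || stats::sd(vols_b) == 0) NA_real_
         else stats::cor(vols_a, vols_b, method = "spearman")
  d <- vols_a - vols_b
  md <- mean(d)
  sdd <- stats::sd(d)
  structure(
    list(spearman_rho = rho, mean_difference = md, sd_difference = sdd,
         limits_of_agreement = c(lower = md - 2 * sdd, upper = md + 2 * sdd),
         n = length(d), differences = d, means = (vols_a + vols_b) / 2),
    class = "agreement_summary"
  )
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf(
    "<agreement_summary> n = %d, Spearman rho = %s\n  mean diff %.2f mL (SD %.2f), limits %.2f to %.2f mL\n",
    x$n, if (is.na(x$spearman_rho)) "undefined"
         else sprintf("%.3f", x$spearman_rho),
    x$mean_difference, x$sd_difference,
    x$limits_of_agreement[1], x$limits_of_agreement[2]))
  invisible(x)
}

#' Mismatch salvage
#'
#' The portion of the acute mismatch that remained functional at follow-up:
#' `salvage = volume(acute mismatch AND NOT follow-up infarct)`. Satisfies
#' `salvage + volume(mismatch AND infarct) = acute mismatch volume` exactly.
#'
#' @param acute_mismatch mismatch mask (`volume_image`/`lesion_mask`).
#' @param followup_infarct follow-up infarct mask on the same grid.
#' @return An object of class `salvage_result` with `salvage_mL` and
#'   `acute_mismatch_mL`.
#' @export
mismatch_salvage <- function(acute_mismatch, followup_infarct) {
  stopifnot(inherits(acute_mismatch, "volume_image"),
            inherits(followup_infarct, "volume_image"))
  .stop_grid(acute_mismatch, followup_infarct,
             "mismatch and follow-up masks")
  vv <- voxel_volume_mL(acute_mismatch)
  mm <- acute_mismatch$data > 0
  inf <- followup_infarct$data > 0
  structure(
    list(salvage_mL = sum(mm & !inf) * vv,
         acute_mismatch_mL = sum(mm) * vv),
    class = "salvage_result"
  )
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sided test for a difference in location between two samples, with
#' average ranks on ties. The exact null distribution is used when both
#' samples have at most 20 observations and there are no ties; with ties,
#' the exact p-value is obtained by full enumeration of group assignments
#' when `choose(n + m, n)` is small enough (<= 2e5), and otherwise the
#' normal approximation with continuity correction is used.
#'
#' @param x,y numeric samples (non-empty).
#' @return A list with `statistic` (the Mann-Whitney U of `x`), `p.value`,
#'   and `method`.
#' @export
rank_sum_test <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  has_ties <- anyDuplicated(pooled) > 0
  if (!has_ties && n <= 20 && m <= 20) {
    wt <- stats::wilcox.test(x, y, exact = TRUE)
    return(list(statistic = unname(wt$statistic), p.value = wt$p.value,
                method = "exact (Wilcoxon distribution)"))
  }
  if (has_ties && choose(n + m, n) <= 2e5) {
    r <- rank(pooled)
    u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
    combos <- utils::combn(n + m, n)
    u_all <- colSums(matrix(r[combos], nrow = n)) - n * (n + 1) / 2
    center <- n * m / 2
    p <- mean(abs(u_all - center) >= abs(u_obs - center) - 1e-9)
    return(list(statistic = u_obs, p.value = min(p, 1),
                method = "exact (enumeration)"))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       method = "normal approximation with continuity correction")
}

#' Per-group summaries of decision and outcome variables
#'
#' Medians and interquartile ranges per confusion-matrix cell, in the style
#' of cohort summary tables. Percentiles use linear interpolation between
#' order statistics (`stats::quantile` type 7). `delta_nihss` (improvement:
#' acute minus 24 h score, positive = improvement) is derived when absent.
#'
#' @param cohort data frame with a `cell` column (values among
#'   `"TP","TN","FP","FN"`) and the variables to summarize.
#' @param variables variables to summarize (default: mismatch volume,
#'   salvage, acute NIHSS, NIHSS improvement).
#' @return Data frame: one row per group x variable with `n`, `median`,
#'   `q25`, `q75` (all `NA` for empty groups).
#' @export
group_summary <- function(cohort,
                          variables = c("mismatch_volume_mL", "salvage_mL",
                                        "nihss_acute", "delta_nihss")) {
  if (!"cell" %in% names(cohort)) stop("cohort needs a 'cell' column")
  if ("delta_nihss" %in% variables && !"delta_nihss" %in% names(cohort) &&
      all(c("nihss_acute", "nihss_24h") %in% names(cohort)))
    cohort$delta_nihss <- cohort$nihss_acute - cohort$nihss_24h
  missing_vars <- setdiff(variables, names(cohort))
  if (length(missing_vars))
    stop("variables not in cohort: ", paste(missing_vars, collapse = ", "))
  groups <- c("TP", "TN", "FP", "FN")
  out <- expand.grid(cell = groups, variable = variables,
                     stringsAsFactors = FALSE)
  stats_for <- function(g, v) {
    x <- cohort[[v]][cohort$cell == g]
    x <- x[!is.na(x)]
    if (!length(x)) return(c(n = 0, median = NA, q25 = NA, q75 = NA))
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    c(n = length(x), median = q[2], q25 = q[1], q75 = q[3])
  }
  res <- t(mapply(stats_for, out$cell, out$variable))
  cbind(out, as.data.frame(res))
}

#' Label cohort rows with their confusion-matrix cell
#'
#' @param predicted,actual logical vectors as in [build_confusion()].
#' @return Character vector of `"TP"/"TN"/"FP"/"FN"` labels.
#' @export
confusion_cells <- function(predicted, actual) {
  if (length(predicted) != length(actual))
    stop("'predicted' and 'actual' must have equal length")
  ifelse(predicted & actual, "TP",
         ifelse(!predicted & !actual, "TN",
                ifelse(predicted & !actual, "FP", "FN")))
}
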