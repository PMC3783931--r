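# Shared fixtures and independent oracles.

# small uniform volume on a 10x10x6 grid
tiny_volume <- function(value = 0, spacing = c(2, 2, 5), dims = c(10, 10, 6),
                        lr_axis = 1L, lr_dir = 1L) {
  volume_image(array(value, dims), spacing, lr_axis, lr_dir)
}

# mask volume from voxel index ranges
box_mask <- function(like, xr, yr, zr) {
  m <- array(FALSE, dim(like$data))
  m[xr, yr, zr] <- TRUE
  as_mask(m, like)
}

# fast low-resolution phantom for unit tests (full default grid is used in
# the acceptance suite)
quick_phantom <- function(...) {
  generate_stroke_phantom(phantom_config(...))
}

# Dice overlap of two masks/logical arrays
dice_coef <- function(a, b) {
  a <- if (inherits(a, "volume_image")) a$data > 0 else a > 0
  b <- if (inherits(b, "volume_image")) b$data > 0 else b > 0
  2 * sum(a & b) / (sum(a) + sum(b))
}

# brute-force neighborhood statistics: mean/sd of map values in the cubic
# window around (i, j, k), restricted to valid voxels
brute_box_stats <- function(map, valid, i, j, k, window) {
  h <- (window - 1) / 2
  d <- dim(map)
  xs <- max(1, i - h):min(d[1], i + h)
  ys <- max(1, j - h):min(d[2], j + h)
  zs <- max(1, k - h):min(d[3], k + h)
  vals <- map[xs, ys, zs][valid[xs, ys, zs]]
  list(mean = if (length(vals)) mean(vals) else NA_real_,
       sd = if (length(vals) > 1) sd(vals) else NA_real_,
       n = length(vals))
}

# brute-force exact two-sided rank-sum p-value by enumeration of all
# C(n+m, n) group assignments (average ranks on ties)
brute_rank_sum_p <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  u_all <- colSums(matrix(r[combos], nrow = n)) - n * (n + 1) / 2
  center <- n * m / 2
  mean(abs(u_all - center) >= abs(u_obs - center) - 1e-9)
}

# brute-force Spearman rho from the rank definition (average ranks)
brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# brute-force type-7 percentile: linear interpolation between order stats
brute_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# exhaustive best CART split: scan every variable and midpoint threshold
brute_best_split <- function(X, y, min_leaf = 1L) {
  n <- length(y)
  parent <- 1 - sum((table(y) / n)^2)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    vals <- sort(unique(X[, j]))
    if (length(vals) < 2) next
    for (t in (vals[-1] + vals[-length(vals)]) / 2) {
      left <- X[, j] < t
      nl <- sum(left); nr <- n - nl
      if (nl < min_leaf || nr < min_leaf) next
      gl <- 1 - sum((table(y[left]) / nl)^2)
      gr <- 1 - sum((table(y[!left]) / nr)^2)
      dec <- parent - (nl * gl + nr * gr) / n
      if (is.null(best) || dec > best$decrease + 1e-12)
        best <- list(variable = colnames(X)[j], threshold = t,
                     decrease = dec)
    }
  }
  best
}

# hierarchical-rule cohort for tree-recovery tests: treatment decided first
# by contraindication, then mismatch volume, then (weakly) NIHSS
rule_cohort <- function(n, flip_rate = 0.02) {
  contraindication_count <- rbinom(n, 2, 0.3)
  mismatch_volume <- round(rlnorm(n, log(40), 0.9), 1)
  nihss <- pmin(42, rpois(n, 9))
  treated <- contraindication_count == 0 |
    (mismatch_volume > 40 & nihss > 5)
  flip <- runif(n) < flip_rate
  treated[flip] <- !treated[flip]
  data.frame(contraindication_count, mismatch_volume, nihss,
             treated = treated)
}
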