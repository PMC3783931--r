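# Internal 3D binary morphology, connected components and box-filter
# statistics. All operations treat voxels outside the array as background.
# Structuring elements live in voxel space (anisotropic spacing is not
# corrected for; radii are in voxels).

# flip an array along one axis
.flip_axis <- function(arr, axis) {
  perm <- c(axis, setdiff(1:3, axis))
  b <- aperm(arr, perm)
  b <- b[dim(b)[1]:1, , , drop = FALSE]
  aperm(b, order(perm))
}

# shift a 3D array by an integer offset, padding with `fill`
.shift_arr <- function(a, off, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  idx_dst <- idx_src <- vector("list", 3L)
  for (ax in 1:3) {
    o <- off[ax]
    if (o >= 0) {
      if (o >= d[ax]) return(out)
      idx_dst[[ax]] <- seq.int(1L + o, d[ax])
      idx_src[[ax]] <- seq.int(1L, d[ax] - o)
    } else {
      if (-o >= d[ax]) return(out)
      idx_dst[[ax]] <- seq.int(1L, d[ax] + o)
      idx_src[[ax]] <- seq.int(1L - o, d[ax])
    }
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# integer offsets within a Euclidean ball of the given radius (voxels),
# excluding the origin
.ball_offsets <- function(radius) {
  r <- max(0L, as.integer(floor(radius)))
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  g <- g[g$dx^2 + g$dy^2 + g$dz^2 <= radius^2 & !(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  as.matrix(g)
}

.offsets6 <- rbind(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
                   c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L))

.dilate <- function(mask, offsets) {
  out <- mask
  for (i in seq_len(nrow(offsets)))
    out <- out | .shift_arr(mask, offsets[i, ], FALSE)
  out
}

.erode <- function(mask, offsets) {
  out <- mask
  for (i in seq_len(nrow(offsets)))
    out <- out & .shift_arr(mask, offsets[i, ], FALSE)
  out
}

.open3d <- function(mask, radius) {
  if (radius <= 0) return(mask)
  off <- .ball_offsets(radius)
  .dilate(.erode(mask, off), off)
}

.close3d <- function(mask, radius) {
  if (radius <= 0) return(mask)
  off <- .ball_offsets(radius)
  .erode(.dilate(mask, off), off)
}

# flood fill `mask` starting from `seed`, 6-connectivity
.flood <- function(mask, seed) {
  seed <- seed & mask
  repeat {
    grown <- seed
    for (i in 1:6) grown <- grown | .shift_arr(seed, .offsets6[i, ], FALSE)
    grown <- grown & mask
    if (!any(grown & !seed)) return(grown)
    seed <- grown
  }
}

# label 6-connected components; returns integer array (0 = background)
.label_components <- function(mask) {
  lab <- array(0L, dim(mask))
  remaining <- mask
  cur <- 0L
  while (any(remaining)) {
    cur <- cur + 1L
    seed <- array(FALSE, dim(mask))
    seed[which(remaining)[1]] <- TRUE
    comp <- .flood(remaining, seed)
    lab[comp] <- cur
    remaining <- remaining & !comp
  }
  lab
}

# keep the largest 6-connected component
.largest_component <- function(mask) {
  lab <- .label_components(mask)
  if (max(lab) <= 1L) return(mask)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

# drop components smaller than min_voxels
.filter_small <- function(mask, min_voxels) {
  if (min_voxels <= 1 || !any(mask)) return(mask)
  lab <- .label_components(mask)
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_voxels)
  array(lab %in% keep, dim(mask))
}

# fill interior cavities: background voxels not 6-connected to the border
.fill_holes <- function(mask) {
  bg <- !mask
  d <- dim(mask)
  seed <- array(FALSE, d)
  seed[c(1, d[1]), , ] <- TRUE
  seed[, c(1, d[2]), ] <- TRUE
  seed[, , c(1, d[3])] <- TRUE
  outside <- .flood(bg, seed & bg)
  mask | (bg & !outside)
}

# Otsu threshold on a numeric array (256-bin histogram, maximizing
# between-class variance); returns the threshold value
.otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) <= 0) stop("cannot threshold a constant volume")
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

# 3D cumulative sum along all axes
.cumsum3 <- function(a) {
  d <- dim(a)
  a <- apply(a, c(2, 3), cumsum)
  dim(a) <- d
  a <- aperm(apply(a, c(1, 3), cumsum), c(2, 1, 3))
  a <- aperm(apply(a, c(1, 2), cumsum), c(2, 3, 1))
  a
}

# moving box sum with half-width h (box edge 2h+1), border-clipped
.box_sum <- function(a, h) {
  d <- dim(a)
  P <- array(0, d + 1L)
  P[-1, -1, -1] <- .cumsum3(a)
  ix <- as.vector(slice.index(a, 1))
  iy <- as.vector(slice.index(a, 2))
  iz <- as.vector(slice.index(a, 3))
  u1 <- pmin(ix + h, d[1]) + 1L; l1 <- pmax(ix - h, 1L)
  u2 <- pmin(iy + h, d[2]) + 1L; l2 <- pmax(iy - h, 1L)
  u3 <- pmin(iz + h, d[3]) + 1L; l3 <- pmax(iz - h, 1L)
  s <- P[cbind(u1, u2, u3)] - P[cbind(l1, u2, u3)] -
       P[cbind(u1, l2, u3)] - P[cbind(u1, u2, l3)] +
       P[cbind(l1, l2, u3)] + P[cbind(l1, u2, l3)] +
       P[cbind(u1, l2, l3)] - P[cbind(l1, l2, l3)]
  array(s, d)
}

# per-voxel mean/SD/count over a cubic neighborhood (edge `window`),
# restricted to voxels where `valid` is TRUE; sample SD (n - 1 denominator)
.box_stats <- function(x, valid, window) {
  stopifnot(window %% 2 == 1, window >= 1)
  h <- (window - 1L) / 2L
  A <- x
  A[!valid] <- 0
  cnt <- .box_sum(valid + 0, h)
  cnt <- round(cnt)
  s <- .box_sum(A, h)
  ss <- .box_sum(A * A, h)
  m <- ifelse(cnt > 0, s / cnt, NA_real_)
  v <- ifelse(cnt > 1, (ss - s^2 / pmax(cnt, 1)) / pmax(cnt - 1, 1), NA_real_)
  list(mean = m, sd = sqrt(pmax(v, 0)), n = cnt)
}

# mirror an array across the midline of the interval [lo, hi] along `axis`;
# positions whose mirror falls outside the array get `fill`
.mirror_arr <- function(arr, axis, lo, hi, fill = NA) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  b <- aperm(arr, perm)
  n <- dim(b)[1]
  j <- seq_len(n)
  jm <- lo + hi - j
  ok <- jm >= 1 & jm <= n
  out <- array(fill, dim(b))
  out[ok, , ] <- b[jm[ok], , , drop = FALSE]
  aperm(out, order(perm))
}
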