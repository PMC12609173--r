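#' Spherical region descriptor
#'
#' Regions are spheres on the voxel grid, described by a centre (1-based
#' voxel indices) and a radius in voxels. World (MNI-like) coordinates are
#' obtained through the image affine.
#'
#' @param center numeric length-3, 1-based voxel indices of the centre.
#' @param radius sphere radius in voxels.
#' @param label optional region label.
#' @return an object of class `cascn_region`.
#' @export
region <- function(center, radius = 2, label = NULL) {
  stopifnot(length(center) == 3, is.finite(center), radius > 0)
  structure(list(center = as.numeric(center), radius = as.numeric(radius),
                 label = label), class = "cascn_region")
}

#' Voxel indices of a spherical region
#'
#' @param reg a [region()].
#' @param dim integer length-3 grid extents.
#' @return integer vector of linear (1-based) voxel indices inside the grid.
#' @export
region_voxels <- function(reg, dim) {
  ctr <- reg$center; r <- reg$radius
  rng <- lapply(1:3, function(k) {
    lo <- max(1L, floor(ctr[k] - r)); hi <- min(dim[k], ceiling(ctr[k] + r))
    if (lo > hi) integer(0) else lo:hi
  })
  if (any(lengths(rng) == 0)) return(integer(0))
  g <- expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]])
  d2 <- (g$i - ctr[1])^2 + (g$j - ctr[2])^2 + (g$k - ctr[3])^2
  g <- g[d2 <= r^2, , drop = FALSE]
  as.integer(g$i + (g$j - 1L) * dim[1] + (g$k - 1L) * dim[1] * dim[2])
}

#' Default affine for the synthetic grid
#'
#' Diagonal affine mapping 1-based voxel indices to an MNI-like frame:
#' world = (ijk - 1) * voxel_size + origin.
#'
#' @param voxel_size isotropic voxel size in mm.
#' @param dim grid extents (used to centre the field of view).
#' @return 4x4 affine matrix.
#' @export
default_affine <- function(voxel_size = 6, dim = c(24L, 24L, 24L)) {
  org <- -voxel_size * dim / 2
  aff <- diag(c(rep(voxel_size, 3), 1))
  aff[1:3, 4] <- org
  aff
}

#' Convert voxel indices to world coordinates
#' @param ijk numeric length-3 or matrix with 3 columns (1-based voxel indices).
#' @param affine 4x4 affine.
#' @return world coordinates, same shape as input.
#' @export
voxel_to_world <- function(ijk, affine) {
  ijk <- rbind(ijk)
  w <- cbind(ijk - 1, 1) %*% t(affine)
  w <- w[, 1:3, drop = FALSE]
  if (nrow(w) == 1) drop(w) else w
}

#' Convert world coordinates to (fractional) voxel indices
#' @param xyz world coordinates (length-3 or 3-column matrix).
#' @param affine 4x4 affine.
#' @return 1-based voxel indices (possibly fractional).
#' @export
world_to_voxel <- function(xyz, affine) {
  xyz <- rbind(xyz)
  v <- cbind(xyz, 1) %*% t(solve(affine))
  v <- v[, 1:3, drop = FALSE] + 1
  if (nrow(v) == 1) drop(v) else v
}

## column z-scores with sample sd; constant columns -> NA columns
zscore_cols <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  mu <- colMeans(m)
  sd <- sqrt(pmax(colSums(m * m) - n * mu^2, 0) / (n - 1))
  out <- sweep(sweep(m, 2, mu), 2, sd, "/")
  out[, sd == 0] <- NA_real_
  out
}

zscore_vec <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant series")
  (x - mean(x)) / s
}

## linear array indices -> i,j,k matrix (1-based)
index_to_ijk <- function(idx, dim) {
  idx0 <- idx - 1L
  i <- idx0 %% dim[1]
  j <- (idx0 %/% dim[1]) %% dim[2]
  k <- idx0 %/% (dim[1] * dim[2])
  cbind(i = i + 1L, j = j + 1L, k = k + 1L)
}

## separable 3D Gaussian smoothing; fwhm in voxels, 0 disables
smooth_gaussian3d <- function(arr, fwhm_vox) {
  if (fwhm_vox <= 0) return(arr)
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(-half:half, sd = sigma)
  kern <- kern / sum(kern)
  d <- dim(arr)
  conv_axis <- function(a, axis) {
    a <- aperm(a, c(axis, setdiff(1:3, axis)))
    da <- dim(a)
    m <- matrix(a, nrow = da[1])
    # reflect-pad then filter
    pad <- rbind(m[half:1, , drop = FALSE], m, m[da[1]:(da[1] - half + 1), , drop = FALSE])
    out <- apply(pad, 2, function(col) stats::filter(col, kern, sides = 2))
    out <- out[(half + 1):(half + da[1]), , drop = FALSE]
    a <- array(out, da)
    aperm(a, order(c(axis, setdiff(1:3, axis))))
  }
  for (ax in 1:3) arr <- conv_axis(arr, ax)
  arr
}
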