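# Separable Gaussian-derivative convolution with reflective boundaries.
# Kernels are sampled analytic Gaussian derivatives; at the sigmas used for
# vesselness (>= half a voxel) sampling error is negligible relative to the
# discretization of the image itself. Truncation at 5 sigma keeps the
# truncated mass below 1e-5 of the kernel norm.

gaussian_kernel <- function(sigma, order = 0L, truncate = 5) {
  stopifnot(sigma > 0, order %in% 0:2)
  r <- max(1L, ceiling(truncate * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
  g <- g / sum(g)                      # unit DC gain for smoothing
  switch(as.character(order),
         "0" = g,
         "1" = g * (-x / sigma^2),     # antisymmetric: zero DC by construction
         "2" = {
           k <- g * ((x^2 - sigma^2) / sigma^4)
           k - sum(k) / length(k)      # annihilate constants exactly
         })
}

# mirror-with-edge-repeat index: ... c b a | a b c ... | c b a ...
reflect_index <- function(i, n) {
  p <- 2L * n
  j <- ((i - 1L) %% p + p) %% p        # 0 .. 2n-1
  ifelse(j < n, j + 1L, p - j)
}

# dense convolution operator along one axis (n is small in this package)
conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (off in -r:r) {
    src <- reflect_index(seq_len(n) + off, n)
    w <- kernel[off + r + 1L]
    K[cbind(seq_len(n), src)] <- K[cbind(seq_len(n), src)] + w
  }
  K
}

conv_axis <- function(arr, kernel, axis) {
  dm <- dim(arr)
  K <- conv_matrix(dm[axis], kernel)
  if (axis == 1L) {
    out <- K %*% matrix(arr, dm[1], dm[2] * dm[3])
    array(out, dm)
  } else {
    perm <- switch(axis, NULL, c(2L, 1L, 3L), c(3L, 2L, 1L))
    a <- aperm(arr, perm)
    da <- dim(a)
    out <- array(K %*% matrix(a, da[1], da[2] * da[3]), da)
    aperm(out, perm)
  }
}

# separable convolution with per-axis derivative orders
gaussian_derivative <- function(arr, sigma_vox, orders) {
  out <- arr
  for (ax in 1:3) out <- conv_axis(out, gaussian_kernel(sigma_vox, orders[ax]), ax)
  out
}

#' Gaussian smoothing of a volume
#'
#' @param vol A `pvs_volume`.
#' @param scale_mm Gaussian standard deviation in mm.
#' @return Smoothed `pvs_volume`.
#' @export
gaussian_smooth <- function(vol, scale_mm) {
  h <- voxel_mm(vol)
  as_volume(gaussian_derivative(vol_data(vol), scale_mm / h, c(0L, 0L, 0L)), h)
}

# All six second-derivative volumes at one scale, in mm units, multiplied by
# scale_mm^2 (second-order scale normalization so responses are comparable
# across scales). Returns a list xx, yy, zz, xy, xz, yz of bare arrays.
scale_normalized_hessian <- function(vol, scale_mm) {
  h <- voxel_mm(vol)
  sigma <- scale_mm / h
  if (sigma < 0.5)
    stop("scale_mm must be at least half the voxel size")
  a <- vol_data(vol)
  if (!all(is.finite(a))) stop("volume contains non-finite voxels")
  # d2/dmm2 = d2/dvox2 / h^2; normalization multiplies by scale_mm^2,
  # so the net factor is sigma^2 in voxel units (mm-true for anisotropy-free
  # isotropic grids, which is all this package renders)
  d <- function(orders) gaussian_derivative(a, sigma, orders) * sigma^2
  list(xx = d(c(2L, 0L, 0L)), yy = d(c(0L, 2L, 0L)), zz = d(c(0L, 0L, 2L)),
       xy = d(c(1L, 1L, 0L)), xz = d(c(1L, 0L, 1L)), yz = d(c(0L, 1L, 1L)))
}
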