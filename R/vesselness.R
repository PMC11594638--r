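#' Frangi filter parameters
#'
#' Constants of the multiscale Hessian vesselness filter. `alpha` controls
#' sensitivity to the plate-vs-line ratio, `beta` to the blobness ratio, and
#' `c` to second-order structureness; `c = "auto"` sets it per scale to half
#' the maximum Hessian Frobenius norm over the volume, the usual default when
#' no value is given. Scales are Gaussian standard deviations in mm and
#' should bracket the expected tube radii (sub-voxel up to the conventional
#' 3 mm PVS diameter).
#'
#' @param scales_mm Strictly positive ascending scales in mm.
#' @param alpha,beta Positive sensitivity constants (default 0.5 each).
#' @param c Positive constant or `"auto"`.
#' @param polarity `"bright"` (tubes brighter than background, e.g. PVS on
#'   T2) or `"dark"` (e.g. PVS on FLAIR), implemented by negating the input.
#' @return A `frangi_params` list.
#' @export
frangi_params <- function(scales_mm = c(0.5, 0.9, 1.4, 2.0),
                          alpha = 0.5, beta = 0.5, c = "auto",
                          polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  if (length(scales_mm) == 0 || any(scales_mm <= 0) || is.unsorted(scales_mm, strictly = TRUE))
    stop("scales_mm must be non-empty, positive, strictly ascending")
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be positive")
  if (!(identical(c, "auto") || (is.numeric(c) && c > 0)))
    stop("c must be positive or \"auto\"")
  structure(list(scales_mm = scales_mm, alpha = alpha, beta = beta, c = c,
                 polarity = polarity), class = "frangi_params")
}

# eigenvalues of many symmetric 3x3 matrices (vectorized trigonometric
# closed form), returned as a 3-column matrix sorted by absolute value
sym3x3_eigenvalues <- function(a11, a22, a33, a12, a13, a23) {
  q <- (a11 + a22 + a33) / 3
  p1 <- a12^2 + a13^2 + a23^2
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(p2 / 6)
  ok <- p > 0
  pn <- ifelse(ok, p, 1)
  b11 <- (a11 - q) / pn; b22 <- (a22 - q) / pn; b33 <- (a33 - q) / pn
  b12 <- a12 / pn; b13 <- a13 / pn; b23 <- a23 / pn
  detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- pmin(1, pmax(-1, detB / 2))
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  e1[!ok] <- q[!ok]; e2[!ok] <- q[!ok]; e3[!ok] <- q[!ok]
  # the trigonometric form loses ~1e-7 relative accuracy near degeneracies;
  # two Newton steps on the characteristic polynomial restore it (guarded
  # against repeated roots where p'(lambda) ~ 0)
  tr <- a11 + a22 + a33
  m2 <- a11 * a22 + a11 * a33 + a22 * a33 - a12^2 - a13^2 - a23^2
  det3 <- a11 * (a22 * a33 - a23^2) - a12 * (a12 * a33 - a23 * a13) +
    a13 * (a12 * a23 - a22 * a13)
  sc <- abs(e1) + abs(e2) + abs(e3) + 1e-300   # spectral scale per voxel
  refine <- function(l) {
    for (it in 1:2) {
      pl <- -l^3 + tr * l^2 - m2 * l + det3
      dpl <- -3 * l^2 + 2 * tr * l - m2
      step <- pl / ifelse(dpl == 0, 1, dpl)
      # near-degenerate roots have p'(lambda) ~ 0 and a wild Newton step;
      # there the trigonometric value is already stable, so only take
      # small corrective steps
      ok <- dpl != 0 & is.finite(step) & abs(step) < 1e-4 * sc
      l <- l - ifelse(ok, step, 0)
    }
    l
  }
  e1 <- refine(e1); e2 <- refine(e2); e3 <- refine(e3)
  m <- cbind(e1, e2, e3)
  am <- abs(m)
  n <- nrow(m)
  i1 <- max.col(-am, ties.method = "first")
  v1 <- m[cbind(seq_len(n), i1)]
  am[cbind(seq_len(n), i1)] <- Inf
  i2 <- max.col(-am, ties.method = "first")
  v2 <- m[cbind(seq_len(n), i2)]
  i3 <- 6L - i1 - i2
  v3 <- m[cbind(seq_len(n), i3)]
  cbind(l1 = v1, l2 = v2, l3 = v3)
}

#' Scale-normalized Hessian eigenvalues of a volume
#'
#' Computes the Gaussian-derivative Hessian at one scale (second derivatives
#' in mm, multiplied by `scale_mm^2`) and its per-voxel eigenvalues sorted by
#' absolute value, `|l1| <= |l2| <= |l3|`.
#'
#' @param vol A `pvs_volume` with at least 5 voxels per axis.
#' @param scale_mm Gaussian scale in mm, at least half the voxel size.
#' @return List of three `pvs_volume`s: `l1`, `l2`, `l3`.
#' @export
hessian_eigenvalues <- function(vol, scale_mm) {
  if (any(dim(vol) < 5)) stop("volume must have at least 5 voxels per axis")
  H <- scale_normalized_hessian(vol, scale_mm)
  ev <- sym3x3_eigenvalues(as.numeric(H$xx), as.numeric(H$yy), as.numeric(H$zz),
                           as.numeric(H$xy), as.numeric(H$xz), as.numeric(H$yz))
  h <- voxel_mm(vol); dm <- dim(vol)
  list(l1 = as_volume(array(ev[, 1], dm), h),
       l2 = as_volume(array(ev[, 2], dm), h),
       l3 = as_volume(array(ev[, 3], dm), h))
}

#' Frangi vesselness from sorted Hessian eigenvalues
#'
#' For bright tubes the response is 0 wherever `l2 > 0` or `l3 > 0`;
#' elsewhere it is
#' `(1 - exp(-Ra^2 / 2 alpha^2)) * exp(-Rb^2 / 2 beta^2) * (1 - exp(-S^2 / 2 c^2))`
#' with `Ra = |l2|/|l3|`, `Rb = |l1|/sqrt(|l2 l3|)` and
#' `S = sqrt(l1^2 + l2^2 + l3^2)`. Structureless voxels (`l3 = 0`) score 0.
#'
#' @param eigs Output of [hessian_eigenvalues()] (or a list of three arrays
#'   sorted by absolute value).
#' @param params A [frangi_params()]; `c = "auto"` resolves to half the
#'   maximum Frobenius norm `S` over this map.
#' @return Array (or `pvs_volume` when inputs are) of vesselness in [0, 1].
#' @export
frangi_vesselness <- function(eigs, params) {
  l1 <- as.numeric(vol_or_num(eigs$l1))
  l2 <- as.numeric(vol_or_num(eigs$l2))
  l3 <- as.numeric(vol_or_num(eigs$l3))
  S <- sqrt(l1^2 + l2^2 + l3^2)
  cc <- params$c
  if (identical(cc, "auto")) {
    cc <- max(S) / 2
    if (cc == 0) cc <- 1  # flat map: response is 0 anyway
  }
  a2 <- 2 * params$alpha^2
  b2 <- 2 * params$beta^2
  c2 <- 2 * cc^2
  # voxels whose entire Hessian is at numerical noise level (e.g. a constant
  # volume) carry no structure; without this floor the scale-free ratios
  # would amplify rounding noise into spurious responses
  bad <- l2 > 0 | l3 > 0 | l3 == 0 | S < 1e-12
  l3s <- ifelse(l3 == 0, 1, l3)
  l2s <- ifelse(l2 == 0 & l3 == 0, 1, l2)
  Ra2 <- (l2 / l3s)^2
  Rb2 <- l1^2 / abs(l2s * l3s)
  Rb2[abs(l2 * l3) == 0] <- 0   # degenerate: treat as perfectly line-like
  v <- (1 - exp(-Ra2 / a2)) * exp(-Rb2 / b2) * (1 - exp(-S^2 / c2))
  v[bad] <- 0
  shape_like(eigs$l1, v)
}

vol_or_num <- function(x) if (inherits(x, "pvs_volume")) vol_data(x) else x

shape_like <- function(template, values) {
  if (inherits(template, "pvs_volume"))
    as_volume(array(values, dim(template)), voxel_mm(template))
  else if (!is.null(dim(template))) array(values, dim(template))
  else values
}

#' Multiscale Frangi vesselness of a volume
#'
#' Per-voxel maximum of the single-scale vesselness over `params$scales_mm`,
#' recording the scale attaining the maximum. Dark polarity negates the
#' input first. Adding a constant to the input does not change the result
#' (the Hessian of a constant is zero).
#'
#' @param vol A `pvs_volume`.
#' @param params A [frangi_params()].
#' @return List: `values` (`pvs_volume` in [0,1]) and `scale_of_max`
#'   (`pvs_volume` of the argmax scale in mm).
#' @export
frangi_filter <- function(vol, params = frangi_params()) {
  work <- if (params$polarity == "dark")
    as_volume(-vol_data(vol), voxel_mm(vol)) else vol
  dm <- dim(vol)
  best <- array(0, dm)
  best_scale <- array(params$scales_mm[1], dm)
  for (s in params$scales_mm) {
    eigs <- hessian_eigenvalues(work, s)
    v <- vol_data(frangi_vesselness(eigs, params))
    better <- v > best
    best[better] <- v[better]
    best_scale[better] <- s
  }
  list(values = as_volume(best, voxel_mm(vol)),
       scale_of_max = as_volume(best_scale, voxel_mm(vol)))
}
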