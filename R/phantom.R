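#' Phantom specification
#'
#' Defines a synthetic head phantom: a region atlas (white matter shell,
#' basal ganglia ellipsoids, brainstem cylinder inside an intracranial mask),
#' bright tubular perivascular spaces (PVS) embedded in those regions, WMH
#' blobs, lacune and stroke cavities, and the T2/FLAIR contrast model used to
#' render them. All sizes are in millimetres; the grid is isotropic.
#'
#' Tissue contrasts default to PVS brighter than white matter on T2 (PVS
#' follow CSF signal), WMH hyperintense on FLAIR, and PVS hypointense on
#' FLAIR (CSF is suppressed), the contrast pattern the segmentation relies
#' on.
#'
#' @param grid_shape Integer vector of 3 voxel counts (default `c(64,64,64)`).
#' @param voxel_size_mm Isotropic voxel spacing in mm (default 0.9).
#' @param pvs_density_per_region Named numeric, expected tube count per
#'   region (`wm`, `bg`, `bs`); actual counts are Poisson draws.
#' @param tube_radius_mm_range,tube_length_mm_range Min/max tube radius and
#'   length in mm. Defaults span thin sub-voxel tubules up to the
#'   conventional 3 mm PVS diameter ceiling.
#' @param wmh_blob_count,wmh_radius_mm_range WMH blob count and radius range.
#' @param lacune_count,lacune_radius_mm_range Lacune cavity count and radius
#'   range (3-15 mm cavities by convention; defaults stay small).
#' @param stroke_count,stroke_radius_mm_range Subacute infarct cavities.
#' @param contrast_levels List with elements `t2` and `flair`, each a named
#'   vector of mean intensities per tissue class
#'   (`background, csf, wm, bg, bs, wmh, pvs, lacune, stroke`).
#' @param noise_sigma Additive noise standard deviation (0 = noiseless).
#' @param rician Logical; if `TRUE` noise is Rician (magnitude of complex
#'   Gaussian), otherwise additive Gaussian.
#' @param seed Integer seed; identical specs give bit-identical phantoms.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         voxel_size_mm = 0.9,
                         pvs_density_per_region = c(wm = 12, bg = 8, bs = 2),
                         tube_radius_mm_range = c(0.5, 1.5),
                         tube_length_mm_range = c(5, 15),
                         wmh_blob_count = 2,
                         wmh_radius_mm_range = c(2, 5),
                         lacune_count = 1,
                         lacune_radius_mm_range = c(2, 4),
                         stroke_count = 1,
                         stroke_radius_mm_range = c(3, 6),
                         contrast_levels = default_contrast_levels(),
                         noise_sigma = 2,
                         rician = FALSE,
                         seed = 1L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1))
  if (voxel_size_mm <= 0) stop("voxel_size_mm must be positive")
  counts <- c(pvs_density_per_region, wmh_blob_count, lacune_count, stroke_count)
  if (any(counts < 0)) stop("counts and densities must be >= 0")
  for (rng in list(tube_radius_mm_range, tube_length_mm_range,
                   wmh_radius_mm_range, lacune_radius_mm_range,
                   stroke_radius_mm_range)) {
    if (length(rng) != 2 || any(rng <= 0) || rng[1] > rng[2])
      stop("radius/length ranges must be positive with min <= max")
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  nm <- names(pvs_density_per_region)
  if (is.null(nm) || !setequal(nm, c("wm", "bg", "bs")))
    stop("pvs_density_per_region must be named wm, bg, bs")
  structure(list(
    grid_shape = as.integer(grid_shape),
    voxel_size_mm = voxel_size_mm,
    pvs_density_per_region = pvs_density_per_region[c("wm", "bg", "bs")],
    tube_radius_mm_range = tube_radius_mm_range,
    tube_length_mm_range = tube_length_mm_range,
    wmh_blob_count = wmh_blob_count,
    wmh_radius_mm_range = wmh_radius_mm_range,
    lacune_count = lacune_count,
    lacune_radius_mm_range = lacune_radius_mm_range,
    stroke_count = stroke_count,
    stroke_radius_mm_range = stroke_radius_mm_range,
    contrast_levels = contrast_levels,
    noise_sigma = noise_sigma,
    rician = rician,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_contrast_levels <- function() {
  list(
    t2 = c(background = 0, csf = 90, wm = 35, bg = 40, bs = 40,
           wmh = 60, pvs = 80, lacune = 85, stroke = 70),
    flair = c(background = 0, csf = 10, wm = 40, bg = 45, bs = 45,
              wmh = 90, pvs = 15, lacune = 12, stroke = 80)
  )
}

# atlas label codes
#' Region label codes used in atlas volumes
#'
#' Background 0, intracranial CSF 1, white matter 2, basal ganglia 3,
#' brainstem 4. The intracranial volume (ICV) mask is `label >= 1`.
#' @return Named integer vector of label codes.
#' @export
region_labels <- function() {
  c(background = 0L, csf = 1L, wm = 2L, bg = 3L, bs = 4L)
}

#' Generate the region atlas of a phantom
#'
#' Deterministic geometry: the intracranial volume (ICV) is a ball; white
#' matter is a thick spherical shell; the basal ganglia are two para-central
#' ellipsoids; the brainstem is an inferior cylinder. Regions are disjoint by
#' construction with precedence brainstem > basal ganglia > white matter.
#'
#' @param spec A [phantom_spec()].
#' @return A `pvs_volume` of integer labels (see [region_labels()]) with
#'   attribute `region_volumes`: voxel counts and mm^3 per region.
#' @export
generate_atlas <- function(spec) {
  dm <- spec$grid_shape
  if (min(dm) < 24)
    stop("grid too small to place WM, BG and BS regions (need >= 24 voxels per axis)")
  g <- index_grids(dm)
  cx <- (dm[1] + 1) / 2; cy <- (dm[2] + 1) / 2; cz <- (dm[3] + 1) / 2
  n <- min(dm)
  r_icv <- 0.46 * n

  d2 <- (g$x - cx)^2 + (g$y - cy)^2 + (g$z - cz)^2
  icv <- d2 <= r_icv^2

  # brainstem: inferior cylinder
  r_bs <- max(3, 0.08 * n)
  bs <- (g$x - cx)^2 + (g$y - cy)^2 <= r_bs^2 &
    g$z >= cz - 0.80 * r_icv & g$z <= cz - 0.15 * r_icv & icv

  # basal ganglia: paired ellipsoids
  ax <- 0.10 * n; ay <- 0.14 * n; az <- 0.12 * n; off <- 0.18 * n
  bg <- (((g$x - (cx - off))^2 / ax^2 + (g$y - cy)^2 / ay^2 +
            (g$z - (cz + 0.05 * n))^2 / az^2) <= 1 |
           ((g$x - (cx + off))^2 / ax^2 + (g$y - cy)^2 / ay^2 +
              (g$z - (cz + 0.05 * n))^2 / az^2) <= 1) & icv & !bs

  # white matter: thick shell, sparing the inferior brainstem corridor
  wm <- d2 >= (0.45 * r_icv)^2 & d2 <= (0.88 * r_icv)^2 &
    g$z > cz - 0.55 * r_icv & icv & !bs & !bg

  lab <- array(0L, dm)
  lab[icv] <- region_labels()[["csf"]]
  lab[wm] <- region_labels()[["wm"]]
  lab[bg] <- region_labels()[["bg"]]
  lab[bs] <- region_labels()[["bs"]]
  if (!any(wm) || !any(bg) || !any(bs))
    stop("grid too small: an atlas region came out empty")

  atlas <- as_volume(lab, spec$voxel_size_mm)
  counts <- c(wm = sum(wm), bg = sum(bg), bs = sum(bs), icv = sum(icv))
  attr(atlas, "region_volumes") <- list(
    voxels = counts, mm3 = counts * spec$voxel_size_mm^3)
  atlas
}

#' Rasterize a capsule (cylinder with hemispherical caps)
#'
#' A voxel belongs to the capsule when its center lies within `radius_mm` of
#' the segment `p0`--`p1` (coordinates in mm, with voxel i centred at
#' `(i - 0.5) * voxel_mm` along each axis).
#'
#' @param p0,p1 Numeric length-3 segment endpoints in mm.
#' @param radius_mm Capsule radius in mm.
#' @param dm Grid dimensions.
#' @param voxel_mm Voxel spacing in mm.
#' @return Logical 3D array.
#' @export
rasterize_capsule <- function(p0, p1, radius_mm, dm, voxel_mm) {
  out <- array(FALSE, dm)
  lo <- pmax(1L, floor((pmin(p0, p1) - radius_mm) / voxel_mm + 0.5))
  hi <- pmin(dm, ceiling((pmax(p0, p1) + radius_mm) / voxel_mm + 0.5))
  if (any(lo > hi)) return(out)
  xs <- (lo[1]:hi[1] - 0.5) * voxel_mm
  ys <- (lo[2]:hi[2] - 0.5) * voxel_mm
  zs <- (lo[3]:hi[3] - 0.5) * voxel_mm
  bx <- expand.grid(x = xs, y = ys, z = zs)
  v <- p1 - p0
  L2 <- sum(v^2)
  w <- cbind(bx$x - p0[1], bx$y - p0[2], bx$z - p0[3])
  t <- if (L2 > 0) pmin(1, pmax(0, as.numeric(w %*% v) / L2)) else 0
  dx <- w[, 1] - t * v[1]; dy <- w[, 2] - t * v[2]; dz <- w[, 3] - t * v[3]
  inside <- dx^2 + dy^2 + dz^2 <= radius_mm^2
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
    array(inside, c(length(xs), length(ys), length(zs)))
  out
}

#' Plant tubular PVS in atlas regions
#'
#' Draws a Poisson number of capsule-shaped tubes per region (expected counts
#' from `spec$pvs_density_per_region`), with uniformly random orientation,
#' radius and length, and keeps only tubes lying wholly inside their assigned
#' region (up to 50 placement attempts each). Returns the exact ground truth.
#'
#' @param spec A [phantom_spec()].
#' @param atlas Output of [generate_atlas()].
#' @return List with `pvs_mask` (logical `pvs_volume`),
#'   `per_region_true_fraction` (% per region, exact),
#'   `tube_records` (data.frame: endpoints in mm, radius, length, region),
#'   and `n_requested` / `n_placed` per region.
#' @export
generate_pvs_tubes <- function(spec, atlas) {
  labs <- region_labels()
  dm <- dim(atlas)
  h <- voxel_mm(atlas)
  if (spec$tube_radius_mm_range[1] < h / 2)
    warning("tube radius below half a voxel; thin tubes may vanish under rasterization")
  mask <- array(FALSE, dm)
  recs <- list()
  n_req <- c(wm = 0L, bg = 0L, bs = 0L)
  n_placed <- c(wm = 0L, bg = 0L, bs = 0L)
  with_seed(spec$seed + 1L, {
    for (rg in c("wm", "bg", "bs")) {
      region <- vol_data(atlas) == labs[[rg]]
      vox <- which(region)
      n_tubes <- stats::rpois(1, spec$pvs_density_per_region[[rg]])
      n_req[rg] <- n_tubes
      if (n_tubes == 0 || length(vox) == 0) next
      for (k in seq_len(n_tubes)) {
        for (attempt in 1:50) {
          ctr_idx <- arrayInd(sample(vox, 1L), dm)
          ctr <- (as.numeric(ctr_idx) - 0.5) * h
          r <- stats::runif(1, spec$tube_radius_mm_range[1], spec$tube_radius_mm_range[2])
          len <- stats::runif(1, spec$tube_length_mm_range[1], spec$tube_length_mm_range[2])
          # uniform direction on the sphere
          u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
          p0 <- ctr - u * len / 2; p1 <- ctr + u * len / 2
          cap <- rasterize_capsule(p0, p1, r, dm, h)
          nv <- sum(cap)
          if (nv > 0 && all(region[cap])) {
            mask <- mask | cap
            n_placed[rg] <- n_placed[rg] + 1L
            recs[[length(recs) + 1L]] <- data.frame(
              x0 = p0[1], y0 = p0[2], z0 = p0[3],
              x1 = p1[1], y1 = p1[2], z1 = p1[3],
              radius_mm = r, length_mm = len, region = rg)
            break
          }
        }
      }
    }
  })
  frac <- vapply(c("wm", "bg", "bs"), function(rg) {
    region <- vol_data(atlas) == labs[[rg]]
    100 * sum(mask & region) / sum(region)
  }, numeric(1))
  list(
    pvs_mask = as_volume(mask, h),
    per_region_true_fraction = frac,
    tube_records = if (length(recs)) do.call(rbind, recs) else
      data.frame(x0 = numeric(), y0 = numeric(), z0 = numeric(),
                 x1 = numeric(), y1 = numeric(), z1 = numeric(),
                 radius_mm = numeric(), length_mm = numeric(),
                 region = character()),
    n_requested = n_req, n_placed = n_placed
  )
}

# spherical lesions clipped to a host mask
place_blobs <- function(n, radius_range, host, dm, h) {
  out <- array(FALSE, dm)
  vox <- which(host)
  if (n == 0 || length(vox) == 0) return(out)
  g <- index_grids(dm)
  for (k in seq_len(n)) {
    ctr_idx <- arrayInd(sample(vox, 1L), dm)
    r_vox <- stats::runif(1, radius_range[1], radius_range[2]) / h
    ball <- (g$x - ctr_idx[1])^2 + (g$y - ctr_idx[2])^2 +
      (g$z - ctr_idx[3])^2 <= r_vox^2
    out <- out | (ball & host)
  }
  out
}

#' Generate WMH, lacune and stroke lesion masks
#'
#' WMH blobs are spheres seeded at white-matter voxels and clipped to white
#' matter (hyperintense on FLAIR). Lacunes and the subacute stroke cavity are
#' spheres seeded in white matter or basal ganglia, clipped to brain tissue.
#'
#' @param spec A [phantom_spec()].
#' @param atlas Output of [generate_atlas()].
#' @return List of logical `pvs_volume` masks: `wmh`, `lacune`, `stroke`.
#' @export
generate_lesions <- function(spec, atlas) {
  labs <- region_labels()
  dm <- dim(atlas); h <- voxel_mm(atlas)
  a <- vol_data(atlas)
  wm <- a == labs[["wm"]]
  deep <- a == labs[["wm"]] | a == labs[["bg"]]
  with_seed(spec$seed + 2L, {
    wmh <- place_blobs(spec$wmh_blob_count, spec$wmh_radius_mm_range, wm, dm, h)
    lac <- place_blobs(spec$lacune_count, spec$lacune_radius_mm_range, deep, dm, h)
    stk <- place_blobs(spec$stroke_count, spec$stroke_radius_mm_range, deep, dm, h)
  })
  list(wmh = as_volume(wmh, h), lacune = as_volume(lac, h),
       stroke = as_volume(stk, h))
}

#' Render T2 and FLAIR volumes from phantom components
#'
#' Each voxel gets the mean intensity of its tissue class for the sequence,
#' plus noise. Overlaps resolve with precedence
#' stroke > lacune > PVS > WMH > tissue label.
#'
#' @param spec A [phantom_spec()].
#' @param atlas,truth Outputs of [generate_atlas()] and [generate_pvs_tubes()].
#' @param wmh_mask,lacune_mask,stroke_mask Logical masks on the atlas grid
#'   (missing lesions may be `NULL`).
#' @return List of `pvs_volume`s `t2` and `flair`.
#' @export
render_sequences <- function(spec, atlas, truth, wmh_mask = NULL,
                             lacune_mask = NULL, stroke_mask = NULL) {
  labs <- region_labels()
  dm <- dim(atlas); h <- voxel_mm(atlas)
  a <- vol_data(atlas)
  empty <- array(FALSE, dm)
  wmh <- if (is.null(wmh_mask)) empty else as.logical(vol_data(wmh_mask))
  lac <- if (is.null(lacune_mask)) empty else as.logical(vol_data(lacune_mask))
  stk <- if (is.null(stroke_mask)) empty else as.logical(vol_data(stroke_mask))
  pvs <- as.logical(vol_data(truth$pvs_mask))
  check_same_grid(atlas, truth$pvs_mask, "atlas and PVS mask")

  cls <- array("background", dm)
  cls[a == labs[["csf"]]] <- "csf"
  cls[a == labs[["wm"]]] <- "wm"
  cls[a == labs[["bg"]]] <- "bg"
  cls[a == labs[["bs"]]] <- "bs"
  cls[wmh] <- "wmh"
  cls[pvs] <- "pvs"
  cls[lac] <- "lacune"
  cls[stk] <- "stroke"

  render_one <- function(levels, noise) {
    img <- array(levels[cls], dm) + noise
    as_volume(img, h)
  }
  nvox <- prod(dm)
  with_seed(spec$seed + 3L, {
    if (spec$noise_sigma > 0) {
      n1 <- array(stats::rnorm(nvox, 0, spec$noise_sigma), dm)
      n2 <- array(stats::rnorm(nvox, 0, spec$noise_sigma), dm)
      n3 <- array(stats::rnorm(nvox, 0, spec$noise_sigma), dm)
      n4 <- array(stats::rnorm(nvox, 0, spec$noise_sigma), dm)
    } else {
      n1 <- n2 <- n3 <- n4 <- array(0, dm)
    }
  })
  if (spec$rician && spec$noise_sigma > 0) {
    t2 <- as_volume(sqrt((array(spec$contrast_levels$t2[cls], dm) + n1)^2 + n2^2), h)
    flair <- as_volume(sqrt((array(spec$contrast_levels$flair[cls], dm) + n3)^2 + n4^2), h)
  } else {
    t2 <- render_one(spec$contrast_levels$t2, n1)
    flair <- render_one(spec$contrast_levels$flair, n3)
  }
  list(t2 = t2, flair = flair)
}

#' Generate a complete phantom subject
#'
#' Convenience wrapper running atlas, tube, lesion and rendering stages.
#'
#' @param spec A [phantom_spec()].
#' @return List: `spec`, `atlas`, `truth`, `wmh`, `lacune`, `stroke`,
#'   `t2`, `flair`.
#' @export
generate_phantom <- function(spec) {
  atlas <- generate_atlas(spec)
  truth <- generate_pvs_tubes(spec, atlas)
  les <- generate_lesions(spec, atlas)
  seqs <- render_sequences(spec, atlas, truth, les$wmh, les$lacune, les$stroke)
  list(spec = spec, atlas = atlas, truth = truth,
       wmh = les$wmh, lacune = les$lacune, stroke = les$stroke,
       t2 = seqs$t2, flair = seqs$flair)
}
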