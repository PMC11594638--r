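#' Fractional PVS volume of a region
#'
#' `100 * |mask & region| / |region|` in percent, the primary quantitative
#' PVS measure.
#'
#' @param mask Logical `pvs_volume` (segmented or ground-truth PVS).
#' @param atlas Region atlas.
#' @param region `"wm"`, `"bg"` or `"bs"`.
#' @return Percent in [0, 100].
#' @export
fractional_volume <- function(mask, atlas, region) {
  check_same_grid(mask, atlas, "mask and atlas")
  lab <- region_labels()[[region]]
  if (is.null(lab)) stop("unknown region: ", region)
  rmask <- vol_data(atlas) == lab
  denom <- sum(rmask)
  if (denom == 0) stop("region '", region, "' is empty in the atlas")
  100 * sum(as.logical(vol_data(mask)) & rmask) / denom
}

#' WM/BG-PVS ratio
#'
#' White-matter fractional PVS volume divided by the basal-ganglia one; the
#' regional-contrast measure. Undefined (NA, with a warning) when the BG
#' fraction is zero.
#'
#' @param frac_wm,frac_bg Fractional volumes in percent.
#' @return Dimensionless ratio, or `NA` when `frac_bg == 0`.
#' @export
wm_bg_ratio <- function(frac_wm, frac_bg) {
  out <- frac_wm / frac_bg
  bad <- !is.na(frac_bg) & frac_bg == 0
  if (any(bad)) {
    warning(sum(bad), " subject(s) with zero BG-PVS fraction; ratio recorded as missing")
    out[bad] <- NA_real_
  }
  out
}

#' WMH volume normalized by intracranial volume
#'
#' @param wmh_mask Logical WMH mask.
#' @param icv_mask Logical intracranial mask; WMH must be contained in it.
#' @return Percent in [0, 100].
#' @export
wmh_icv_ratio <- function(wmh_mask, icv_mask) {
  check_same_grid(wmh_mask, icv_mask, "WMH and ICV masks")
  w <- as.logical(vol_data(wmh_mask))
  i <- as.logical(vol_data(icv_mask))
  if (!any(i)) stop("ICV mask is empty")
  if (any(w & !i)) stop("WMH mask extends outside the ICV mask (registration fault?)")
  100 * sum(w) / sum(i)
}

#' Physical volume of a voxel cluster
#'
#' @param n_voxels Cluster size in voxels.
#' @param voxel_mm Isotropic voxel size in mm.
#' @param digits Decimals for half-up rounding (the convention used when
#'   such cutoffs are reported, e.g. 5 voxels at 0.9 mm -> 3.65 mm^3).
#' @return Volume in mm^3.
#' @export
cluster_volume_mm3 <- function(n_voxels, voxel_mm = 0.9, digits = 2) {
  round_half_up(n_voxels * voxel_mm^3, digits)
}

# majority region of each cluster; ties go to WM
cluster_regions <- function(labels, atlas) {
  labs <- region_labels()
  k <- max(labels)
  if (k == 0) return(character(0))
  a <- vol_data(atlas)
  out <- character(k)
  for (cl in seq_len(k)) {
    vox <- a[labels == cl]
    counts <- c(wm = sum(vox == labs[["wm"]]), bg = sum(vox == labs[["bg"]]),
                bs = sum(vox == labs[["bs"]]))
    mx <- max(counts)
    winners <- names(counts)[counts == mx]
    out[cl] <- if ("wm" %in% winners) "wm" else winners[1]
  }
  out
}

#' Per-subject regional PVS metrics
#'
#' Fractional volumes for WM, BG and BS, the WM/BG ratio, the WMH/ICV
#' percentage and surviving cluster counts per region (clusters assigned to
#' the region holding most of their voxels; ties to WM).
#'
#' @param pvs A `pvs_mask` from [segment_pvs()] / [cluster_filter()], or a
#'   logical `pvs_volume`.
#' @param atlas Region atlas.
#' @param wmh_mask Logical WMH mask or `NULL`.
#' @param subject_id Optional identifier.
#' @return One-row data.frame: `frac_wm`, `frac_bg`, `frac_bs`,
#'   `wm_bg_ratio`, `wmh_icv_pct`, `n_clusters_wm/bg/bs`.
#' @export
compute_metrics <- function(pvs, atlas, wmh_mask = NULL, subject_id = NA_character_) {
  if (inherits(pvs, "pvs_mask")) {
    mask <- pvs$mask
    labels <- pvs$labels
  } else {
    mask <- pvs
    labels <- label_components(mask)$labels
  }
  fw <- fractional_volume(mask, atlas, "wm")
  fb <- fractional_volume(mask, atlas, "bg")
  fs <- fractional_volume(mask, atlas, "bs")
  regs <- cluster_regions(labels, atlas)
  icv <- as_volume(vol_data(atlas) >= 1L, voxel_mm(atlas))
  data.frame(
    subject_id = subject_id,
    frac_wm = fw, frac_bg = fb, frac_bs = fs,
    wm_bg_ratio = if (fb > 0) fw / fb else NA_real_,
    wmh_icv_pct = if (is.null(wmh_mask)) NA_real_ else wmh_icv_ratio(wmh_mask, icv),
    n_clusters_wm = sum(regs == "wm"),
    n_clusters_bg = sum(regs == "bg"),
    n_clusters_bs = sum(regs == "bs")
  )
}

#' Dice overlap between two binary masks
#'
#' @param a,b Logical `pvs_volume`s / arrays on the same grid.
#' @return Dice coefficient in [0, 1]; 1 when both masks are empty.
#' @export
dice_overlap <- function(a, b) {
  x <- as.logical(vol_or_num(a)); y <- as.logical(vol_or_num(b))
  if (length(x) != length(y)) stop("masks differ in size")
  denom <- sum(x) + sum(y)
  if (denom == 0) return(1)
  2 * sum(x & y) / denom
}
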