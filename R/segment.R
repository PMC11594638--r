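#' Segmentation parameters
#'
#' Vesselness thresholds per compartment, the small-cluster cutoff and the
#' clustering neighbourhood. One threshold applies in normal-appearing white
#' matter and brain tissue generally, a separate (usually lower) one inside
#' the WMH mask where the dual-sequence minimum rule already suppresses false
#' positives. Clusters of `min_cluster_voxels` or fewer voxels are removed as
#' noise (5 voxels at 0.9 mm isotropic is 3.65 mm^3).
#'
#' Default thresholds were calibrated on a phantom cohort against the true
#' tube masks and planted visual ratings; see the methods vignette.
#'
#' @param threshold_nawm Vesselness cutoff outside WMHs, in (0, 1).
#' @param threshold_wmh Cutoff inside the WMH mask, in (0, 1).
#' @param min_cluster_voxels Clusters with `<=` this many voxels are removed.
#' @param connectivity 6, 18 or 26 neighbourhood.
#' @param combine_rule How T2 and dark-FLAIR vesselness merge inside WMHs
#'   (only `"min"` — both sequences must agree — is provided).
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(threshold_nawm = 0.05,
                                threshold_wmh = 0.035,
                                min_cluster_voxels = 5L,
                                connectivity = 26L,
                                combine_rule = "min") {
  if (threshold_nawm <= 0 || threshold_nawm >= 1 ||
      threshold_wmh <= 0 || threshold_wmh >= 1)
    stop("thresholds must lie in (0, 1)")
  if (min_cluster_voxels < 0) stop("min_cluster_voxels must be >= 0")
  if (!connectivity %in% c(6L, 18L, 26L)) stop("connectivity must be 6, 18 or 26")
  if (!identical(combine_rule, "min")) stop("only the \"min\" combine rule is implemented")
  structure(list(threshold_nawm = threshold_nawm, threshold_wmh = threshold_wmh,
                 min_cluster_voxels = as.integer(min_cluster_voxels),
                 connectivity = as.integer(connectivity),
                 combine_rule = combine_rule),
            class = "segmentation_params")
}

#' Combine T2 and FLAIR vesselness inside WMHs
#'
#' Outside the WMH mask the T2 vesselness passes through unchanged; inside,
#' the voxelwise minimum of the T2 (bright-tube) and FLAIR (dark-tube)
#' responses is taken, so both sequences must agree before a voxel can
#' become PVS — the false-positive-averse reading of dual-sequence use.
#'
#' @param v_t2,v_flair_dark Vesselness `pvs_volume`s (FLAIR filtered with
#'   dark polarity).
#' @param wmh_mask Logical mask on the same grid.
#' @return Combined vesselness `pvs_volume`.
#' @export
combine_vesselness <- function(v_t2, v_flair_dark, wmh_mask) {
  check_same_grid(v_t2, v_flair_dark, "vesselness maps")
  check_same_grid(v_t2, wmh_mask, "vesselness and WMH mask")
  out <- vol_data(v_t2)
  w <- as.logical(vol_data(wmh_mask))
  vf <- vol_data(v_flair_dark)
  out[w] <- pmin(out[w], vf[w])
  as_volume(out, voxel_mm(v_t2))
}

#' Threshold a combined vesselness map
#'
#' A voxel enters the candidate mask when its vesselness reaches the
#' compartment's threshold (`threshold_wmh` inside the WMH mask,
#' `threshold_nawm` elsewhere) and it lies inside a quantification region
#' (white matter, basal ganglia or brainstem — hence inside the intracranial
#' mask). Free CSF has no PVS threshold: perivascular spaces are defined
#' within brain tissue, and open CSF spaces would otherwise flood the mask
#' with bright tubular-looking false positives.
#'
#' @param v Combined vesselness `pvs_volume`.
#' @param atlas Region atlas (ICV = label >= 1).
#' @param wmh_mask Logical WMH mask (or `NULL`).
#' @param params A [segmentation_params()].
#' @return Logical `pvs_volume` candidate mask.
#' @export
threshold_map <- function(v, atlas, wmh_mask = NULL, params = segmentation_params()) {
  check_same_grid(v, atlas, "vesselness and atlas")
  icv <- vol_data(atlas) >= region_labels()[["wm"]]
  thr <- array(params$threshold_nawm, dim(v))
  if (!is.null(wmh_mask)) {
    check_same_grid(v, wmh_mask, "vesselness and WMH mask")
    thr[as.logical(vol_data(wmh_mask))] <- params$threshold_wmh
  }
  as_volume(vol_data(v) >= thr & icv, voxel_mm(v))
}

# 26/18/6-neighbourhood offsets
connectivity_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(off != 0) > 0, , drop = FALSE]
  d <- rowSums(abs(off))
  switch(as.character(connectivity),
         "6" = off[d == 1, , drop = FALSE],
         "18" = off[d <= 2, , drop = FALSE],
         "26" = off)
}

#' Label connected components of a binary mask
#'
#' Components under a 6/18/26 neighbourhood, computed by building the voxel
#' adjacency graph and taking its connected components.
#'
#' @param mask Logical `pvs_volume` or 3D array.
#' @param connectivity 6, 18 or 26.
#' @return List: `labels` (integer array, 0 = background) and `sizes`
#'   (voxel count per label).
#' @export
label_components <- function(mask, connectivity = 26L) {
  m <- as.logical(vol_or_num(mask))
  dm <- if (inherits(mask, "pvs_volume")) dim(mask) else dim(mask)
  dim(m) <- dm
  idx <- which(m)
  labels <- array(0L, dm)
  if (length(idx) == 0) return(list(labels = labels, sizes = integer(0)))
  pos <- arrayInd(idx, dm)
  lin <- array(0L, dm)
  lin[idx] <- seq_along(idx)           # mask voxel -> vertex id
  offs <- connectivity_offsets(connectivity)
  edges <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(pos, 2, offs[k, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] &
      nb[, 2] >= 1 & nb[, 2] <= dm[2] &
      nb[, 3] >= 1 & nb[, 3] <= dm[3]
    if (!any(ok)) next
    nb_lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * dm[1] +
      (nb[ok, 3] - 1L) * dm[1] * dm[2]
    tgt <- lin[nb_lin]
    src <- seq_along(idx)[ok]
    keep <- tgt > 0L & tgt > src       # each undirected edge once
    if (any(keep)) edges[[k]] <- rbind(src[keep], tgt[keep])
  }
  el <- do.call(cbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(el) && length(el))
    g <- igraph::add_edges(g, as.vector(el))
  comp <- igraph::components(g)
  labels[idx] <- comp$membership
  list(labels = labels, sizes = as.integer(comp$csize))
}

#' Remove small clusters from a candidate mask
#'
#' Connected components with `min_cluster_voxels` or fewer voxels are
#' removed (so a 5-voxel cluster goes and a 6-voxel cluster stays at the
#' default). Idempotent: filtering a filtered mask changes nothing.
#'
#' @param mask Logical `pvs_volume`.
#' @param params A [segmentation_params()].
#' @return List of class `pvs_mask`: `mask` (logical `pvs_volume`), `labels`
#'   (surviving components relabelled 1..k), `cluster_sizes`, `n_removed`.
#' @export
cluster_filter <- function(mask, params = segmentation_params()) {
  comp <- label_components(mask, params$connectivity)
  keep <- which(comp$sizes > params$min_cluster_voxels)
  relab <- integer(length(comp$sizes))
  relab[keep] <- seq_along(keep)
  labels <- array(0L, dim(comp$labels))
  nz <- comp$labels > 0L
  labels[nz] <- relab[comp$labels[nz]]
  h <- voxel_mm(mask)
  structure(list(
    mask = as_volume(labels > 0L, h),
    labels = labels,
    cluster_sizes = comp$sizes[keep],
    n_removed = length(comp$sizes) - length(keep),
    params = params
  ), class = "pvs_mask")
}

#' Remove lacune and stroke areas from a PVS mask
#'
#' @param mask Logical `pvs_volume` (or a `pvs_mask`'s `$mask`).
#' @param lacune_mask,stroke_mask Logical masks on the same grid (`NULL` to
#'   skip).
#' @return Logical `pvs_volume` with zero overlap with either exclusion.
#' @export
apply_exclusions <- function(mask, lacune_mask = NULL, stroke_mask = NULL) {
  out <- as.logical(vol_data(mask))
  dim(out) <- dim(mask)
  for (ex in list(lacune_mask, stroke_mask)) {
    if (is.null(ex)) next
    check_same_grid(mask, ex, "PVS mask and exclusion mask")
    out <- out & !as.logical(vol_data(ex))
  }
  as_volume(out, voxel_mm(mask))
}

#' Full PVS segmentation of one subject
#'
#' Runs the fixed stage order: combine T2/FLAIR vesselness inside WMHs,
#' threshold per compartment, remove lacune/stroke areas, then filter small
#' clusters (exclusion precedes cluster filtering so lesion remnants cannot
#' prop up sub-threshold clusters).
#'
#' @param v_t2 Bright-tube vesselness of the T2 volume.
#' @param v_flair_dark Dark-tube vesselness of the FLAIR volume (`NULL` when
#'   no WMH mask is given).
#' @param atlas Region atlas.
#' @param wmh_mask,lacune_mask,stroke_mask Logical masks or `NULL`.
#' @param params A [segmentation_params()].
#' @return A `pvs_mask` (see [cluster_filter()]) with an extra `provenance`
#'   element: `"wmh"` where the WMH rule applied, `"nawm"` elsewhere within
#'   the mask.
#' @export
segment_pvs <- function(v_t2, v_flair_dark = NULL, atlas,
                        wmh_mask = NULL, lacune_mask = NULL,
                        stroke_mask = NULL, params = segmentation_params()) {
  comb <- if (!is.null(wmh_mask) && !is.null(v_flair_dark))
    combine_vesselness(v_t2, v_flair_dark, wmh_mask) else v_t2
  cand <- threshold_map(comb, atlas, wmh_mask, params)
  cand <- apply_exclusions(cand, lacune_mask, stroke_mask)
  res <- cluster_filter(cand, params)
  prov <- array("nawm", dim(cand))
  if (!is.null(wmh_mask)) prov[as.logical(vol_data(wmh_mask))] <- "wmh"
  prov[!vol_data(res$mask)] <- ""
  res$provenance <- prov
  res
}

#' Calibrate the vesselness threshold against visual ratings
#'
#' Mirrors threshold selection against a visual PVS rating: every candidate
#' threshold is applied to the whole cohort, fractional PVS volumes are
#' computed, and the candidate maximizing the Spearman rank correlation with
#' the visual scores is returned; ties break toward the higher (more
#' conservative) threshold. The chosen threshold is then used cohort-wide.
#'
#' @param subjects List of per-subject lists with elements `vesselness`
#'   (combined map), `atlas`, and optional `wmh`, `lacune`, `stroke`.
#' @param visual_scores Numeric/ordinal score per subject (at least two
#'   distinct grades).
#' @param candidates Numeric vector of candidate thresholds in (0, 1).
#' @param params Base [segmentation_params()]; both compartment thresholds
#'   are set to each candidate during the sweep.
#' @param region Region whose fractional volume is correlated: `"wm"`,
#'   `"bg"`, `"bs"` or `"all"` (all three regions pooled).
#' @return List: `threshold`, `rho` (per candidate), `fractions` (subjects x
#'   candidates matrix).
#' @export
calibrate_threshold <- function(subjects, visual_scores, candidates,
                                params = segmentation_params(),
                                region = "all") {
  if (length(subjects) < 2) stop("need at least 2 subjects to calibrate")
  if (length(visual_scores) != length(subjects))
    stop("one visual score per subject required")
  if (length(unique(visual_scores)) < 2)
    stop("visual scores are constant; correlation undefined")
  candidates <- sort(candidates)
  labs <- region_labels()
  frac <- matrix(NA_real_, length(subjects), length(candidates))
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    a <- vol_data(s$atlas)
    rmask <- if (region == "all") a >= labs[["wm"]] else a == labs[[region]]
    denom <- sum(rmask)
    for (j in seq_along(candidates)) {
      p <- params
      p$threshold_nawm <- candidates[j]
      p$threshold_wmh <- candidates[j]
      cand <- threshold_map(s$vesselness, s$atlas, s$wmh, p)
      cand <- apply_exclusions(cand, s$lacune, s$stroke)
      seg <- cluster_filter(cand, p)
      frac[i, j] <- 100 * sum(vol_data(seg$mask) & rmask) / denom
    }
  }
  rho <- vapply(seq_along(candidates), function(j) {
    if (stats::sd(frac[, j]) == 0) return(NA_real_)
    suppressWarnings(stats::cor(frac[, j], visual_scores, method = "spearman"))
  }, numeric(1))
  if (all(is.na(rho)))
    stop("all candidate thresholds give undefined correlation")
  best <- max(rho, na.rm = TRUE)
  chosen <- max(candidates[!is.na(rho) & rho >= best - 1e-12])
  list(threshold = chosen, rho = stats::setNames(rho, candidates),
       fractions = frac)
}
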