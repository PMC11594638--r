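test_that("dual-sequence combination is a no-op outside WMHs and a minimum inside", {
  dm <- c(8L, 8L, 8L)
  vt2 <- as_volume(array(runif(prod(dm)), dm), 0.9)
  vfl <- as_volume(array(runif(prod(dm)), dm), 0.9)
  none <- as_volume(array(FALSE, dm), 0.9)
  expect_identical(unclass(combine_vesselness(vt2, vfl, none)), unclass(vt2))
  wmh <- as_volume(array(c(TRUE, FALSE), dm), 0.9)
  comb <- unclass(combine_vesselness(vt2, vfl, wmh))
  w <- as.logical(unclass(wmh))
  expect_equal(comb[w], pmin(unclass(vt2)[w], unclass(vfl)[w]))
  expect_true(all(comb[w] <= unclass(vt2)[w]))
  # single-sequence responses die under the min rule
  vt2_hot <- as_volume(array(0.8, dm), 0.9)
  vfl_cold <- as_volume(array(0, dm), 0.9)
  expect_equal(unique(as.numeric(unclass(
    combine_vesselness(vt2_hot, vfl_cold, wmh))[w])), 0)
  bad <- as_volume(array(0.1, c(4, 4, 4)), 0.9)
  expect_error(combine_vesselness(vt2, bad, none), "different grids")
})

test_that("thresholding respects bounds, region membership and monotonicity", {
  v <- noiseless_vesselness()$t2$values
  ph <- noiseless_phantom()
  hi <- threshold_map(v, ph$atlas,
                      params = segmentation_params(threshold_nawm = 0.9999,
                                                   threshold_wmh = 0.9999))
  expect_equal(sum(unclass(hi)), 0)
  lo <- threshold_map(v, ph$atlas,
                      params = segmentation_params(threshold_nawm = 1e-6,
                                                   threshold_wmh = 1e-6))
  tissue <- unclass(ph$atlas) >= region_labels()[["wm"]]
  expect_identical(as.logical(unclass(lo)),
                   as.logical(unclass(v) >= 1e-6 & tissue))
  mid <- threshold_map(v, ph$atlas,
                       params = segmentation_params(threshold_nawm = 0.2,
                                                    threshold_wmh = 0.2))
  # lowering the threshold never removes voxels
  expect_true(all(unclass(mid) <= unclass(lo)))
})

test_that("cluster filter removes <=5-voxel clusters, keeps 6-voxel ones, idempotently", {
  dm <- c(20L, 20L, 20L)
  m <- array(FALSE, dm)
  m[2:6, 2, 2] <- TRUE        # 5 voxels -> removed
  m[10:15, 2, 2] <- TRUE      # 6 voxels -> kept
  m[2:7, 10, 10] <- TRUE      # 6 voxels -> kept
  res <- cluster_filter(as_volume(m, 0.9), segmentation_params())
  expect_equal(sum(unclass(res$mask)), 12)
  expect_equal(res$n_removed, 1)
  expect_equal(sort(res$cluster_sizes), c(6L, 6L))
  expect_false(any(unclass(res$mask)[2:6, 2, 2]))
  # idempotence
  res2 <- cluster_filter(res$mask, segmentation_params())
  expect_identical(unclass(res2$mask), unclass(res$mask))
  # empty input
  e <- cluster_filter(as_volume(array(FALSE, dm), 0.9))
  expect_equal(sum(unclass(e$mask)), 0)
  expect_length(e$cluster_sizes, 0)
})

test_that("component labelling agrees with a flood-fill oracle on random masks", {
  set.seed(99)
  for (conn in c(6L, 18L, 26L)) {
    for (rep in 1:4) {
      m <- array(runif(20^3) < 0.15, c(20L, 20L, 20L))
      got <- label_components(as_volume(m, 0.9), conn)
      want <- floodfill_oracle(m, conn)
      expect_true(same_partition(got$labels, want))
      expect_equal(sort(got$sizes), sort(as.integer(table(want[want > 0]))))
    }
  }
})

test_that("exclusion masks subtract exactly and before cluster filtering", {
  dm <- c(16L, 16L, 16L)
  set.seed(7)
  m <- as_volume(array(runif(prod(dm)) < 0.2, dm), 0.9)
  none <- as_volume(array(FALSE, dm), 0.9)
  expect_identical(unclass(apply_exclusions(m, none, none)), unclass(m))
  all_m <- as_volume(array(TRUE, dm), 0.9)
  expect_equal(sum(unclass(apply_exclusions(m, all_m, NULL))), 0)
  lac <- as_volume(array(runif(prod(dm)) < 0.3, dm), 0.9)
  out <- apply_exclusions(m, lac, none)
  expect_equal(sum(unclass(out) & unclass(lac)), 0)
  expect_lte(sum(unclass(out)), sum(unclass(m)))
  # pipeline order: a 7-voxel cluster cut to 4 by a lacune must not survive
  m2 <- array(FALSE, dm); m2[3:9, 3, 3] <- TRUE
  lac2 <- array(FALSE, dm); lac2[3:5, 3, 3] <- TRUE
  cut <- apply_exclusions(as_volume(m2, 0.9), as_volume(lac2, 0.9), NULL)
  surv <- cluster_filter(cut, segmentation_params())
  expect_equal(sum(unclass(surv$mask)), 0)
})

test_that("segment_pvs output respects exclusions and reproduces bit-identically", {
  ph <- noiseless_phantom()
  vs <- noiseless_vesselness()
  seg1 <- segment_pvs(vs$t2$values, vs$flair$values, ph$atlas,
                      ph$wmh, ph$lacune, ph$stroke)
  seg2 <- segment_pvs(vs$t2$values, vs$flair$values, ph$atlas,
                      ph$wmh, ph$lacune, ph$stroke)
  expect_identical(unclass(seg1$mask), unclass(seg2$mask))
  expect_equal(sum(unclass(seg1$mask) & unclass(ph$lacune)), 0)
  expect_equal(sum(unclass(seg1$mask) & unclass(ph$stroke)), 0)
  expect_true(all(unclass(seg1$mask) <=
                    (unclass(ph$atlas) >= region_labels()[["wm"]])))
  expect_true(all(seg1$cluster_sizes > segmentation_params()$min_cluster_voxels))
})

test_that("threshold calibration recovers burden ordering and breaks ties upward", {
  # small phantom cohort whose visual scores follow true burden; burden
  # levels are well separated (ordering recovery is only well-posed when
  # the gaps exceed segmentation error)
  levels <- c(1, 3, 6)
  subjects <- list(); truth_frac <- numeric(length(levels))
  for (k in seq_along(levels)) {
    i <- levels[k]
    spec <- phantom_spec(grid_shape = c(40L, 40L, 40L), noise_sigma = 0,
                         pvs_density_per_region = c(wm = 2 * i, bg = i, bs = 0),
                         tube_radius_mm_range = c(0.9, 1.3),
                         tube_length_mm_range = c(4, 8),
                         wmh_blob_count = 0, lacune_count = 0, stroke_count = 0,
                         seed = 100 + i)
    ph <- generate_phantom(spec)
    v <- frangi_filter(ph$t2, frangi_params(scales_mm = c(0.9, 1.4)))$values
    subjects[[k]] <- list(vesselness = v, atlas = ph$atlas)
    a <- unclass(ph$atlas)
    tissue <- a >= region_labels()[["wm"]]
    truth_frac[k] <- 100 * sum(unclass(ph$truth$pvs_mask) & tissue) / sum(tissue)
  }
  scores <- rank(truth_frac)  # monotone visual rating of the pooled burden
  cal <- calibrate_threshold(subjects, scores, candidates = c(0.05, 0.1, 0.2))
  expect_true(cal$threshold %in% c(0.05, 0.1, 0.2))
  expect_equal(max(cal$rho, na.rm = TRUE), 1)
  # ties toward the larger threshold
  best <- max(cal$rho, na.rm = TRUE)
  expect_equal(cal$threshold,
               max(as.numeric(names(cal$rho))[!is.na(cal$rho) & cal$rho >= best - 1e-12]))
  # singleton grid returns unchanged
  single <- calibrate_threshold(subjects, scores, candidates = 0.12)
  expect_equal(single$threshold, 0.12)
  expect_error(calibrate_threshold(subjects, rep(1, length(subjects)),
                                   candidates = 0.1),
               "constant")
})
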