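#' Run configuration
#'
#' Binds every stage of the pipeline — phantom simulation (or real co-registered
#' inputs), vesselness filtering, segmentation, quantification, statistics —
#' into one reproducible description. Exactly one of `phantom` or `inputs`
#' must be given.
#'
#' @param phantom List of phantom-cohort settings: `n_subjects`, plus any
#'   [phantom_spec()] arguments to override, and an optional
#'   [effect_config()] under `effects`.
#' @param inputs List describing real data: `covariates` (CSV path with a
#'   `subject_id` column) and `subjects`, a list of per-subject NIfTI paths
#'   (`t2`, `flair`, `atlas`, `wmh`, `lacune`, `stroke`).
#' @param frangi A [frangi_params()].
#' @param segmentation A [segmentation_params()].
#' @param stats_options List: `regressors`, `covariates`, `use_ladder`
#'   (default TRUE; otherwise `transformation` is used as given).
#' @param seed Integer master seed.
#' @param out_dir Output directory.
#' @param write_volumes Write per-subject NIfTI intermediates (default FALSE;
#'   tables and the manifest are always written).
#' @return A `run_config` list.
#' @export
run_config <- function(phantom = NULL, inputs = NULL,
                       frangi = frangi_params(),
                       segmentation = segmentation_params(),
                       stats_options = list(),
                       seed = 1L, out_dir = tempfile("pvsmap_run_"),
                       write_volumes = FALSE) {
  if (is.null(phantom) == is.null(inputs))
    stop("exactly one of 'phantom' or 'inputs' must be given")
  stats_options <- stats_options %||% list()
  if ("regressors" %in% names(stats_options))
    stats_options$regressors <- unlist(stats_options$regressors)
  if ("covariates" %in% names(stats_options))
    stats_options$covariates <- unlist(stats_options$covariates)
  so <- utils::modifyList(list(
    regressors = c("age", "sex_female", "hypertension", "dyslipidemia",
                   "diabetes", "bmi", "smoking", "alcohol", "psqi", "ess",
                   "lacune_count", "microbleed_count", "wmh_icv_pct"),
    covariates = c("age", "sex_female", "hypertension"),
    use_ladder = TRUE, transformation = "logarithmic"), stats_options)
  structure(list(phantom = phantom, inputs = inputs, frangi = frangi,
                 segmentation = segmentation, stats_options = so,
                 seed = as.integer(seed), out_dir = out_dir,
                 write_volumes = isTRUE(write_volumes)),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' Round-trips losslessly: `read_run_config(write_run_config(cfg, f))` gives
#' a configuration equal to `cfg` with all defaults materialized.
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config` returns the path invisibly; `read_run_config`
#'   a `run_config`.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$frangi <- unclass(x$frangi)
  x$segmentation <- unclass(x$segmentation)
  if (!is.null(x$phantom$effects)) x$phantom$effects <- unclass(x$phantom$effects)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  fr <- do.call(frangi_params, x$frangi[c("scales_mm", "alpha", "beta", "c", "polarity")])
  sg <- do.call(segmentation_params,
                x$segmentation[c("threshold_nawm", "threshold_wmh",
                                 "min_cluster_voxels", "connectivity", "combine_rule")])
  ph <- x$phantom
  # YAML maps come back as lists; flatten the numeric phantom fields
  for (f in c("grid_shape", "pvs_density_per_region", "tube_radius_mm_range",
              "tube_length_mm_range", "wmh_radius_mm_range",
              "lacune_radius_mm_range", "stroke_radius_mm_range",
              "base_density"))
    if (!is.null(ph[[f]])) ph[[f]] <- unlist(ph[[f]])
  if (!is.null(ph$contrast_levels))
    ph$contrast_levels <- lapply(ph$contrast_levels, unlist)
  if (!is.null(ph$effects)) {
    ef <- ph$effects
    to_num <- function(v) if (is.list(v)) unlist(v) else v
    ph$effects <- effect_config(
      coef_bg = to_num(ef$coef_bg), coef_wm = to_num(ef$coef_wm),
      coef_bs = to_num(ef$coef_bs), base_log = to_num(ef$base_log),
      sd_shared = ef$sd_shared, sd_indep = ef$sd_indep,
      bs_shared_loading = ef$bs_shared_loading)
  }
  run_config(phantom = ph, inputs = x$inputs, frangi = fr, segmentation = sg,
             stats_options = x$stats_options, seed = x$seed,
             out_dir = x$out_dir, write_volumes = x$write_volumes)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

# per-subject phantom spec derived from the cohort row: expected tube counts
# scale with the subject's latent regional burden
subject_phantom_spec <- function(cfg_phantom, cohort_row, subject_seed) {
  base <- cfg_phantom[setdiff(names(cfg_phantom),
                              c("n_subjects", "effects", "base_density"))]
  base_density <- cfg_phantom$base_density %||% c(wm = 12, bg = 6, bs = 3)
  ref <- c(wm = 1.1, bg = 4.0, bs = 0.6)
  scl <- c(wm = cohort_row$frac_wm, bg = cohort_row$frac_bg,
           bs = cohort_row$frac_bs) / ref
  args <- utils::modifyList(
    list(pvs_density_per_region = base_density[c("wm", "bg", "bs")] * scl,
         seed = subject_seed),
    base)
  args$pvs_density_per_region <- base_density[c("wm", "bg", "bs")] * scl
  args$seed <- subject_seed
  do.call(phantom_spec, args)
}

#' Run the full pipeline
#'
#' Executes simulate (or load) -> vesselness -> segment -> quantify -> stats
#' in a fixed order, writes tables and a JSON manifest with parameter and
#' output checksums to `config$out_dir`, and returns the manifest. Identical
#' configurations (including the seed) produce bit-identical outputs and
#' manifests.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly a list (also written as `manifest.json`):
#'   configuration with all defaults, per-stage outputs, md5 checksums of
#'   every written file.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  is_phantom <- !is.null(config$phantom)

  # ---- simulate / load ----
  subjects <- list()
  cohort <- NULL
  if (is_phantom) {
    run_stage("simulate", {
      ph <- config$phantom
      n <- ph$n_subjects %||% 10L
      effects <- ph$effects %||% effect_config()
      cohort <- generate_cohort_table(n, effects, seed = config$seed)
      for (i in seq_len(n)) {
        spec <- subject_phantom_spec(ph, cohort[i, ], config$seed + i)
        subjects[[i]] <- generate_phantom(spec)
      }
    })
  } else {
    run_stage("load", {
      cohort <- utils::read.csv(config$inputs$covariates)
      subjects <- lapply(config$inputs$subjects, function(s) {
        out <- list(t2 = read_volume(s$t2), atlas = read_volume(s$atlas))
        out$flair <- if (!is.null(s$flair)) read_volume(s$flair)
        for (m in c("wmh", "lacune", "stroke"))
          out[[m]] <- if (!is.null(s[[m]]))
            as_volume(vol_data(read_volume(s[[m]])) > 0, voxel_mm(out$t2))
        out
      })
    })
  }
  n <- length(subjects)

  # ---- vesselness + segment + quantify ----
  metrics <- run_stage("segment", {
    p_bright <- config$frangi
    p_dark <- config$frangi; p_dark$polarity <- "dark"
    do.call(rbind, lapply(seq_len(n), function(i) {
      s <- subjects[[i]]
      v_t2 <- frangi_filter(s$t2, p_bright)$values
      v_fl <- if (!is.null(s$flair)) frangi_filter(s$flair, p_dark)$values
      seg <- segment_pvs(v_t2, v_fl, s$atlas, s$wmh, s$lacune, s$stroke,
                         config$segmentation)
      if (config$write_volumes) {
        sid <- sprintf("S%04d", i)
        write_volume(s$t2, file.path(config$out_dir, paste0(sid, "_t2.nii.gz")))
        write_volume(as_volume(vol_data(seg$mask) * 1L, voxel_mm(seg$mask)),
                     file.path(config$out_dir, paste0(sid, "_pvs.nii.gz")))
      }
      compute_metrics(seg, s$atlas, s$wmh, subject_id = sprintf("S%04d", i))
    }))
  })

  merged <- run_stage("quantify", {
    keep <- setdiff(names(cohort),
                    c("frac_wm", "frac_bg", "frac_bs", "wm_bg_ratio", "wmh_icv_pct"))
    latent <- cohort[, intersect(c("frac_wm", "frac_bg", "frac_bs"), names(cohort)),
                     drop = FALSE]
    names(latent) <- paste0(names(latent), "_latent")
    m <- metrics
    if (!is_phantom && "subject_id" %in% names(cohort))
      m$subject_id <- cohort$subject_id[seq_len(nrow(m))]
    cbind(cohort[, keep, drop = FALSE],
          if (is_phantom) latent,
          m[, setdiff(names(m), "subject_id"), drop = FALSE])
  })

  # ---- stats ----
  stats_out <- run_stage("stats", {
    so <- config$stats_options
    degenerate <- all(merged$frac_bg == 0) || all(merged$frac_wm == 0)
    ladder <- NULL
    transformation <- so$transformation
    vecs <- list(bg = merged$frac_bg, wm = merged$frac_wm, bs = merged$frac_bs)
    if (isTRUE(so$use_ladder) && !degenerate) {
      ladder <- tryCatch(select_transformation(vecs), error = function(e) NULL)
      if (!is.null(ladder)) transformation <- ladder$chosen
    }
    outcomes <- c("frac_bg", "frac_wm", "frac_bs", "wm_bg_ratio")
    outcomes <- outcomes[vapply(outcomes, function(oc) {
      y <- apply_transformation(merged[[oc]], transformation)
      sum(is.finite(y)) > length(so$covariates) + 3
    }, logical(1))]
    if (!"wm_bg_ratio" %in% outcomes)
      warning("WM/BG ratio degenerate in this cohort; ratio models skipped")
    models <- if (length(outcomes))
      regression_table(merged, regressors = so$regressors, outcomes = outcomes,
                       covariates = so$covariates, transformation = transformation)
    list(ladder = ladder, transformation = transformation, models = models)
  })

  # ---- write + manifest ----
  cohort_csv <- file.path(config$out_dir, "cohort.csv")
  metrics_csv <- file.path(config$out_dir, "metrics.csv")
  models_csv <- file.path(config$out_dir, "models.csv")
  utils::write.csv(cohort, cohort_csv, row.names = FALSE)
  utils::write.csv(merged, metrics_csv, row.names = FALSE)
  if (!is.null(stats_out$models))
    utils::write.csv(stats_out$models, models_csv, row.names = FALSE)
  files <- list.files(config$out_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  sums <- tools::md5sum(files)
  cfg_ser <- config
  cfg_ser$out_dir <- NULL  # path does not affect content
  manifest <- list(
    package = "pvsmap",
    version = as.character(utils::packageVersion("pvsmap")),
    seed = config$seed,
    config = rapply(unclass(cfg_ser), unclass, how = "replace"),
    n_subjects = n,
    transformation = stats_out$transformation,
    ladder_scores = if (!is.null(stats_out$ladder))
      as.list(stats_out$ladder$aggregate),
    outputs = stats::setNames(as.list(unname(sums)), basename(files))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(manifest)
}
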