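#' Correlation matrices for regional PVS measures
#'
#' Pearson product-moment correlations (with R^2 = r^2, the linear-fit
#' coefficient of determination for a simple regression between the pair),
#' and Spearman rank correlations for ordinal measures such as visual
#' scores. Pairs with missing values are dropped pairwise.
#'
#' @param data A data.frame or matrix of numeric columns.
#' @return List: `pearson`, `r2` (elementwise square of `pearson`),
#'   `spearman`, and `n` (pairwise complete observations).
#' @export
pvs_correlations <- function(data) {
  m <- as.matrix(data)
  if (!is.numeric(m)) stop("all columns must be numeric")
  if (nrow(m) < 3) stop("need at least 3 observations")
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  if (any(!is.na(sds) & sds == 0))
    warning("zero-variance column(s): ",
            paste(colnames(m)[!is.na(sds) & sds == 0], collapse = ", "),
            "; correlations undefined (NA)")
  pear <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs",
                                      method = "pearson"))
  spear <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs",
                                       method = "spearman"))
  n <- crossprod(!is.na(m))
  list(pearson = pear, r2 = pear^2, spearman = spear, n = n)
}

#' The nine-candidate transformation ladder
#'
#' Power-ladder candidates applied to a positive outcome to approach
#' normality: cubic, square, identity, square root, logarithmic, 1/square
#' root, inverse, 1/square, 1/cubic.
#'
#' @return Character vector of the nine candidate names, in ladder order.
#' @export
ladder_candidates <- function() {
  c("cubic", "square", "identity", "square root", "logarithmic",
    "1/square root", "inverse", "1/square", "1/cubic")
}

#' @rdname ladder_candidates
#' @param x Numeric vector.
#' @param candidate One of [ladder_candidates()].
#' @return Transformed vector (non-finite where the candidate's domain is
#'   violated, e.g. `log` of 0).
#' @export
apply_transformation <- function(x, candidate) {
  switch(candidate,
         "cubic" = x^3,
         "square" = x^2,
         "identity" = x,
         "square root" = suppressWarnings(sqrt(x)),
         "logarithmic" = suppressWarnings(log(x)),
         "1/square root" = suppressWarnings(1 / sqrt(x)),
         "inverse" = 1 / x,
         "1/square" = 1 / x^2,
         "1/cubic" = 1 / x^3,
         stop("unknown transformation: ", candidate))
}

#' Select the normalizing transformation across regions
#'
#' Applies each ladder candidate to each region's outcome vector, scores
#' normality with the Shapiro-Wilk W statistic, aggregates candidates by the
#' minimum W across regions (the worst region governs), and returns the
#' candidate maximizing that aggregate. Candidates producing any non-finite
#' value for any region are disqualified.
#'
#' @param region_vectors Named list of numeric vectors (one per region).
#' @return List of class `transform_ladder`: `chosen`, `scores` (candidate x
#'   region matrix of W), `aggregate` (min-W per candidate).
#' @export
select_transformation <- function(region_vectors) {
  stopifnot(is.list(region_vectors), length(region_vectors) >= 1)
  cands <- ladder_candidates()
  scores <- matrix(NA_real_, length(cands), length(region_vectors),
                   dimnames = list(cands, names(region_vectors)))
  for (ci in seq_along(cands)) {
    ok <- TRUE
    for (ri in seq_along(region_vectors)) {
      y <- apply_transformation(region_vectors[[ri]], cands[ci])
      if (any(!is.finite(y))) { ok <- FALSE; break }
      scores[ci, ri] <- stats::shapiro.test(y)$statistic
    }
    if (!ok) scores[ci, ] <- NA_real_
  }
  agg <- apply(scores, 1, min)
  if (all(is.na(agg))) stop("every transformation candidate was disqualified")
  chosen <- cands[which.max(agg)]
  structure(list(chosen = chosen, scores = scores, aggregate = agg),
            class = "transform_ladder")
}

#' @export
print.transform_ladder <- function(x, ...) {
  cat("Transformation ladder (Shapiro-Wilk W, aggregated by min across regions)\n")
  tab <- cbind(x$scores, `min W` = x$aggregate)
  print(round(tab, 4))
  cat("chosen:", x$chosen, "\n")
  invisible(x)
}

#' Unadjusted and adjusted linear regressions for PVS outcomes
#'
#' One ordinary-least-squares fit per regressor on a (transformed) PVS
#' outcome: unadjusted `outcome ~ regressor`, or adjusted
#' `outcome ~ regressor + covariates`. When the regressor is itself one of
#' the adjustment covariates, its adjusted row is reported from the
#' covariates-only model (the convention used in adjusted-model tables).
#' Reports the slope, its two-sided t-test p-value and the model R^2 in
#' percent. Complete cases per model; collinear designs are flagged
#' degenerate rather than reported.
#'
#' @param cohort Data.frame with outcome and regressor columns.
#' @param outcome Outcome column name (e.g. `frac_bg`).
#' @param regressors Character vector of regressor column names.
#' @param adjust Logical; adjust for `covariates`.
#' @param covariates Adjustment set (default age, sex, hypertension).
#' @param transformation Ladder candidate applied to the outcome before
#'   fitting (default `"logarithmic"`; use `"identity"` for none).
#' @return Data.frame of class `model_results`: one row per regressor with
#'   `outcome`, `regressor`, `beta`, `se`, `p_value`, `r2_pct`, `adjusted`,
#'   `n`, `degenerate`.
#' @export
fit_models <- function(cohort, outcome, regressors, adjust = FALSE,
                       covariates = c("age", "sex_female", "hypertension"),
                       transformation = "logarithmic") {
  stopifnot(outcome %in% names(cohort))
  y <- apply_transformation(cohort[[outcome]], transformation)
  base <- data.frame(.y = y)
  rows <- lapply(regressors, function(rg) {
    if (!rg %in% names(cohort)) stop("regressor not in cohort table: ", rg)
    # adjusted rows for the covariates themselves come from the
    # covariates-only model
    terms <- if (!adjust) rg
    else if (rg %in% covariates) covariates
    else c(rg, covariates)
    dat <- cbind(base, cohort[, terms, drop = FALSE])
    dat <- dat[stats::complete.cases(dat) & is.finite(dat$.y), , drop = FALSE]
    if (nrow(dat) <= length(terms) + 1)
      stop("too few complete cases (", nrow(dat), ") for outcome ", outcome)
    fml <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
    fit <- stats::lm(fml, data = dat)
    co <- stats::coef(fit)
    degenerate <- any(is.na(co)) || is.na(co[rg])
    if (degenerate) {
      warning("degenerate (collinear) design for regressor ", rg)
      return(data.frame(outcome = outcome, regressor = rg, beta = NA_real_,
                        se = NA_real_, p_value = NA_real_, r2_pct = NA_real_,
                        adjusted = adjust, n = nrow(dat), degenerate = TRUE))
    }
    sm <- summary(fit)
    data.frame(outcome = outcome, regressor = rg,
               beta = unname(co[rg]),
               se = sm$coefficients[rg, "Std. Error"],
               p_value = sm$coefficients[rg, "Pr(>|t|)"],
               r2_pct = 100 * sm$r.squared,
               adjusted = adjust, n = nrow(dat), degenerate = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("model_results", class(out))
  out
}

#' Quartile group tests for a PVS measure
#'
#' Bins subjects into quartiles of the measure (type-7 sample quantiles;
#' values on a boundary go to the lower bin) and compares each variable
#' across bins: one-way ANOVA for continuous variables, Kruskal-Wallis for
#' ordinal or skewed ones. Quartile bins emptied by ties are merged with
#' their lower neighbour, with a warning.
#'
#' @param cohort Data.frame.
#' @param measure Column defining the quartiles (e.g. `frac_bg`).
#' @param variables Character vector of columns to test.
#' @param types Named character vector mapping variables to `"anova"` or
#'   `"kruskal"`; unnamed variables default to `"anova"`.
#' @return Data.frame: `variable`, `test`, `statistic`, `p_value`, plus the
#'   `quartile` assignment as an attribute.
#' @export
quartile_tests <- function(cohort, measure, variables,
                           types = character(0)) {
  x <- cohort[[measure]]
  if (length(x) < 8) stop("need n >= 8 for non-degenerate quartiles")
  qs <- stats::quantile(x, probs = c(0.25, 0.5, 0.75), type = 7, na.rm = TRUE)
  brks <- unique(c(-Inf, qs, Inf))
  if (length(brks) < 5)
    warning("tied quartile boundaries; merged ", 5 - length(brks), " bin(s)")
  grp <- cut(x, breaks = brks, labels = FALSE, right = TRUE)
  grp <- factor(grp)
  rows <- lapply(variables, function(v) {
    kind <- if (v %in% names(types)) types[[v]] else "anova"
    y <- cohort[[v]]
    if (kind == "kruskal") {
      kt <- stats::kruskal.test(y ~ grp)
      data.frame(variable = v, test = "kruskal",
                 statistic = unname(kt$statistic), p_value = kt$p.value)
    } else {
      ft <- summary(stats::aov(y ~ grp))[[1]]
      data.frame(variable = v, test = "anova",
                 statistic = ft$`F value`[1], p_value = ft$`Pr(>F)`[1])
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "quartile") <- grp
  out
}

#' Table of unadjusted and adjusted models for all PVS outcomes
#'
#' Convenience wrapper producing the long-format regression table: for each
#' outcome (`frac_bg`, `frac_wm`, `frac_bs`, `wm_bg_ratio`) and each
#' regressor, the unadjusted and adjusted slope, p-value and model R^2.
#'
#' @param cohort Cohort data.frame.
#' @param regressors Regressor columns; defaults to the clinical and
#'   radiological set.
#' @param outcomes Outcome columns.
#' @param transformation Ladder candidate for the outcomes.
#' @inheritParams fit_models
#' @return Long data.frame (one row per outcome x regressor x model).
#' @export
regression_table <- function(cohort,
                             regressors = c("age", "sex_female", "hypertension",
                                            "dyslipidemia", "diabetes", "bmi",
                                            "smoking", "alcohol", "psqi", "ess",
                                            "lacune_count", "microbleed_count",
                                            "wmh_icv_pct"),
                             outcomes = c("frac_bg", "frac_wm", "frac_bs",
                                          "wm_bg_ratio"),
                             covariates = c("age", "sex_female", "hypertension"),
                             transformation = "logarithmic") {
  do.call(rbind, lapply(outcomes, function(oc) {
    rbind(
      fit_models(cohort, oc, regressors, adjust = FALSE,
                 covariates = covariates, transformation = transformation),
      fit_models(cohort, oc, regressors, adjust = TRUE,
                 covariates = covariates, transformation = transformation)
    )
  }))
}
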