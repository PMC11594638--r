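test_that("correlation matrices are self-consistent and match rank oracles", {
  set.seed(31)
  n <- 60
  df <- data.frame(a = rnorm(n))
  df$b <- 0.6 * df$a + rnorm(n)
  df$c <- round(rnorm(n))              # ties for the rank path
  res <- pvs_correlations(df)
  expect_equal(res$pearson["a", "a"], 1)
  expect_equal(res$spearman["a", "a"], 1)
  expect_equal(res$r2, res$pearson^2)
  # Spearman equals rank-then-Pearson with average ranks, ties included
  for (k in 1:20) {
    x <- round(rnorm(25), 1); y <- round(rnorm(25), 1)
    got <- pvs_correlations(data.frame(x = x, y = y))$spearman["x", "y"]
    expect_equal(got, cor(rank(x), rank(y), method = "pearson"),
                 tolerance = 1e-12)
  }
  expect_warning(pvs_correlations(data.frame(u = rep(1, 10), v = rnorm(10))),
                 "zero-variance")
  expect_error(pvs_correlations(data.frame(x = 1:2, y = 2:3)), "at least 3")
})

test_that("the ladder selects log for log-normal data and identity for normal data", {
  set.seed(17)
  mk <- function(gen) replicate(3, gen(), simplify = FALSE)
  lad_log <- select_transformation(mk(function() rlnorm(500, 0, 0.5)))
  expect_equal(lad_log$chosen, "logarithmic")
  lad_id <- select_transformation(mk(function() rnorm(500, 10, 2.5)))
  expect_equal(lad_id$chosen, "identity")
  expect_length(lad_log$aggregate, 9)
  expect_identical(rownames(lad_log$scores), ladder_candidates())
  # a zero disqualifies the log/inverse family but not the power family
  withzero <- list(a = c(0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11))
  lad0 <- select_transformation(withzero)
  bad <- c("logarithmic", "1/square root", "inverse", "1/square", "1/cubic")
  expect_true(all(is.na(lad0$aggregate[bad])))
  expect_true(all(is.finite(lad0$aggregate[c("cubic", "square", "identity")])))
  expect_error(select_transformation(list(a = c(NaN, 1:10))), "disqualified")
})

test_that("ladder choice is deterministic given the data", {
  set.seed(5)
  v <- replicate(3, rlnorm(120, 0, 0.4), simplify = FALSE)
  expect_identical(select_transformation(v)$chosen,
                   select_transformation(v)$chosen)
})

test_that("OLS slopes match the closed-form normal equations and a perfect fit", {
  df <- data.frame(x = 1:30)
  df$y <- 2 * df$x + 1
  fit <- suppressWarnings(fit_models(df, "y", "x", transformation = "identity"))
  expect_equal(fit$beta, 2, tolerance = 1e-12)
  expect_equal(fit$r2_pct, 100, tolerance = 1e-10)
  set.seed(12)
  d <- data.frame(y = rnorm(20), x = rnorm(20), age = rnorm(20),
                  sex_female = rbinom(20, 1, 0.5),
                  hypertension = rbinom(20, 1, 0.5))
  got <- fit_models(d, "y", "x", adjust = TRUE, transformation = "identity")
  X <- cbind(1, d$x, d$age, d$sex_female, d$hypertension)
  beta_hat <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_equal(got$beta, beta_hat[2], tolerance = 1e-8)
  # collinear regressor is flagged degenerate, not silently reported
  d$x2 <- d$age
  expect_warning(deg <- fit_models(d, "y", "x2", adjust = TRUE,
                                   transformation = "identity"),
                 "degenerate")
  expect_true(deg$degenerate)
})

test_that("fitting a log-transformed outcome equals fitting pre-logged data", {
  set.seed(8)
  d <- data.frame(x = rnorm(50))
  d$y <- exp(0.3 * d$x + rnorm(50, 0, 0.2))
  d$ylog <- log(d$y)
  a <- fit_models(d, "y", "x", transformation = "logarithmic")
  b <- fit_models(d, "ylog", "x", transformation = "identity")
  expect_equal(a$beta, b$beta, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
})

test_that("adjusted rows for covariates come from the covariates-only model", {
  df <- generate_cohort_table(120, seed = 44)
  one <- fit_models(df, "frac_bg", c("age", "psqi"), adjust = TRUE)
  ref <- summary(lm(log(frac_bg) ~ age + sex_female + hypertension, df))
  expect_equal(one$beta[one$regressor == "age"],
               ref$coefficients["age", "Estimate"], tolerance = 1e-12)
  expect_equal(one$r2_pct[one$regressor == "age"], 100 * ref$r.squared,
               tolerance = 1e-12)
})

test_that("planted effects are recovered unbiasedly with the right signs", {
  # replicate-averaged recovery: the mean estimate over cohorts must sit
  # within 2 per-cohort SEs of the planted slope (a far stricter bound on
  # the mean than on any single draw)
  ef <- effect_config()
  wm_b <- wm_se <- rt_b <- rt_se <- numeric(10)
  for (r in 1:10) {
    df <- generate_cohort_table(500, ef, seed = 200 + r)
    wm <- fit_models(df, "frac_wm", "lacune_count", adjust = TRUE)
    rt <- fit_models(df, "wm_bg_ratio", "psqi", adjust = TRUE)
    wm_b[r] <- wm$beta; wm_se[r] <- wm$se
    rt_b[r] <- rt$beta; rt_se[r] <- rt$se
  }
  expect_lt(abs(mean(wm_b) - ef$coef_wm[["lacune_count"]]), 2 * mean(wm_se))
  expect_gt(mean(rt_b), 0)   # sleep-quality effect surfaces on the ratio
  expect_lt(abs(mean(rt_b) - ef$coef_wm[["psqi"]]), 2 * mean(rt_se))
})

test_that("the adjusted significance pattern matches the planted star structure", {
  # high-effect-size variant of the default pattern so every planted effect
  # is comfortably detectable at n = 500 (the PSQI slope is raised from its
  # default sub-threshold value; the shared-noise cancellation still makes
  # the ratio the most powerful outcome for it)
  ef <- effect_config(coef_wm = c(age = 0.018, hypertension = 0.256,
                                  lacune_count = 0.117, psqi = 0.02))
  df <- generate_cohort_table(500, ef, seed = 303)
  tab <- regression_table(df)
  adj <- tab[tab$adjusted, ]
  p_of <- function(oc, rg) adj$p_value[adj$outcome == oc & adj$regressor == rg]
  # planted: lacunes/microbleeds/WMH on BG, lacunes on WM, lacunes+PSQI on ratio
  expect_lt(p_of("frac_bg", "lacune_count"), 0.05)
  expect_lt(p_of("frac_bg", "microbleed_count"), 0.05)
  expect_lt(p_of("frac_bg", "wmh_icv_pct"), 0.05)
  expect_lt(p_of("frac_wm", "lacune_count"), 0.05)
  expect_lt(p_of("wm_bg_ratio", "lacune_count"), 0.05)
  expect_lt(p_of("wm_bg_ratio", "psqi"), 0.05)
  # a disjoint null set stays quiet: among seven no-effect regressors at the
  # 5% level, three or more chance crossings would be a calibration failure
  null_p <- vapply(c("dyslipidemia", "diabetes", "bmi", "smoking", "alcohol",
                     "ess", "lacune_count"),
                   function(rg) p_of("frac_bs", rg), numeric(1))
  expect_lte(sum(null_p < 0.05), 2)
})

test_that("quartile tests bin by type-7 quantiles and match hand computations", {
  # equal group means give F = 0, p = 1
  df <- data.frame(x = 1:40, y = rep(c(1, 2, 3, 4, 5), 8))
  qt <- quartile_tests(df, "x", "y")
  expect_equal(qt$statistic, 0, tolerance = 1e-12)
  expect_equal(qt$p_value, 1, tolerance = 1e-12)
  grp <- attr(qt, "quartile")
  expect_equal(as.numeric(table(grp)), c(10, 10, 10, 10))
  # Kruskal-Wallis H against the rank-sum formula on a tie-free 12-obs toy
  toy <- data.frame(x = 1:12,
                    y = c(3.1, 1.2, 5.5, 2.2, 9.9, 4.4, 8.8, 0.5, 7.7, 6.6, 10.1, 11.3))
  kt <- quartile_tests(toy, "x", "y", types = c(y = "kruskal"))
  r <- rank(toy$y)
  g <- attr(kt, "quartile")
  N <- 12
  H <- 12 / (N * (N + 1)) * sum(tapply(r, g, function(v) length(v) * mean(v)^2)) -
    3 * (N + 1)
  expect_equal(unname(kt$statistic), H, tolerance = 1e-10)
  expect_error(quartile_tests(data.frame(x = 1:5, y = 1:5), "x", "y"), "n >= 8")
})
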