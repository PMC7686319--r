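make_measure_data <- function(cfg, group = NULL, seed = NULL) {
  co <- generate_cohort(cfg, seed = seed)
  d <- co$metrics
  if (!is.null(group)) d <- d[d$group == group, ]
  d
}

test_that("noise-free linear data recovers the planted slope exactly", {
  cfg <- noise_free_config(tracts = "FMAJ", metrics = "FA",
                           n_per_group = 15)
  d <- make_measure_data(cfg)
  fit <- fit_mixed(d, 1, include_group = TRUE, include_interaction = FALSE)
  b1 <- cfg$trajectory_spec$b1[1]
  expect_lt(abs(fit$coefficients[["age_c"]] - b1) / abs(b1), 1e-6)
  expect_equal(fit$random_intercept_sd, 0)
  expect_identical(fit$method, "ols")
})

test_that("with no subject-level variance the mixed fit matches OLS", {
  spec <- default_trajectory_spec(tracts = "FMAJ", metrics = "FA")
  spec$random_intercept_sd <- 0
  cfg <- simulation_config(n_per_group = 40, tracts = "FMAJ",
                           metrics = "FA", trajectory_spec = spec,
                           latent_effect = 0, seed = 1)
  d <- make_measure_data(cfg)
  fit <- fit_mixed(d, 1, include_group = TRUE, include_interaction = TRUE)
  # the ML variance estimate sits on the zero boundary here, where the
  # generalized-least-squares solution coincides with ordinary least squares
  expect_lt(fit$random_intercept_sd, 1e-8)
  df <- d
  df$age_c <- df$age - fit$age_center
  df$group <- factor(df$group, c("control", "deletion"))
  df$sex <- factor(df$sex, c("M", "F"))
  df$scanner <- factor(df$scanner, c("A", "B"))
  ols <- coef(lm(value ~ age_c + group + group:age_c + sex + scanner,
                 data = df))
  expect_equal(unname(fit$coefficients[names(ols)]), unname(ols),
               tolerance = 1e-4)
})

test_that("duplicating every observation leaves the mean structure unchanged", {
  # exact for the fixed-effects estimator; under a random-intercept GLS fit
  # duplication re-weights within- vs between-subject information (and
  # duplicated rows make the residual variance degenerate), so the
  # invariance is a property of the mean structure, tested where it is exact
  cfg <- noise_free_config(tracts = "FMAJ", metrics = "FA",
                           n_per_group = 25, seed = 17)
  d <- make_measure_data(cfg)
  f1 <- fit_mixed(d, 1, include_group = TRUE)
  f2 <- fit_mixed(rbind(d, d), 1, include_group = TRUE,
                  age_center = f1$age_center)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
})

test_that("BIC selects the generating polynomial order", {
  for (k in 0:2) {
    d <- make_measure_data(one_measure_config(k, seed = 100 + k))
    fits <- lapply(0:2, function(o)
      fit_mixed(d, o, include_group = TRUE, include_interaction = TRUE))
    expect_identical(select_order(fits)$order, k)
  }
})

test_that("equal-BIC ties resolve to the lower order", {
  mk <- function(order, bic) structure(
    list(order = as.integer(order), bic = bic, converged = TRUE),
    class = "trajectory_fit")
  picked <- select_order(list(mk(2, 10), mk(0, 10), mk(1, 10)))
  expect_identical(picked$order, 0L)
  expect_error(select_order(list()), class = "tractpls_validation_error")
})

test_that("BIC order choice is invariant to recentering age", {
  d <- make_measure_data(one_measure_config(2, n_per_group = 60, seed = 19))
  pick <- function(center) {
    fits <- lapply(0:2, function(o)
      fit_mixed(d, o, include_group = TRUE, include_interaction = TRUE,
                age_center = center))
    f <- select_order(fits)
    c(order = f$order, bic = f$bic)
  }
  a <- pick(mean(d$age))
  b <- pick(mean(d$age) + 7)
  expect_identical(a[["order"]], b[["order"]])
  expect_equal(a[["bic"]], b[["bic"]], tolerance = 1e-4)
})

test_that("likelihood-ratio machinery handles degenerate and nested cases", {
  # noise-free, no group difference: both fits perfect, statistic 0, p = 1
  cfg <- noise_free_config(tracts = "FMAJ", metrics = "FA", n_per_group = 8)
  d <- make_measure_data(cfg)
  tst <- suppressWarnings(test_effects(d, 1))
  expect_equal(tst$stat_group, 0)
  expect_equal(tst$p_group, 1)
  expect_equal(tst$p_interaction, 1)

  # order 0 has no interaction term to drop: df 0, p 1
  d0 <- make_measure_data(one_measure_config(0, n_per_group = 30, seed = 23))
  t0 <- test_effects(d0, 0)
  expect_identical(t0$df_interaction, 0L)
  expect_equal(t0$p_interaction, 1)

  # the full model's likelihood dominates its nested submodels
  d1 <- make_measure_data(one_measure_config(1, n_per_group = 30, seed = 29))
  t1 <- test_effects(d1, 1)
  expect_gte(t1$fits$full$logLik, t1$fits$no_interaction$logLik - 1e-6)
  expect_gte(t1$fits$no_interaction$logLik, t1$fits$no_group$logLik - 1e-6)
  expect_true(t1$p_group >= 0 && t1$p_group <= 1)
})

test_that("a strong planted group offset is detected", {
  cfg <- one_measure_config(1, group_offset = 3 * 0.014, seed = 37)
  d <- make_measure_data(cfg)
  tst <- test_effects(d, 1)
  expect_lt(tst$p_group, 1e-3)
  expect_identical(tst$group_direction, 1)
})

test_that("step-up q-values match the brute-force definition", {
  # printed worked example
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(fdr_adjust(0.5), 0.5)
  expect_error(fdr_adjust(c(0.5, 1.2)), class = "tractpls_validation_error")

  set.seed(97)
  for (rep in 1:100) {
    p <- runif(sample(1:72, 1))
    q <- fdr_adjust(p)
    expect_equal(q, brute_force_stepup(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12) && all(q <= 1))
  }
})

test_that("the trajectory analysis covers every measure and is order-invariant", {
  cfg <- simulation_config(n_per_group = 15, tracts = c("FMAJ", "FMIN"),
                           metrics = c("FA", "MD"), seed = 43)
  co <- generate_cohort(cfg)
  res <- run_trajectory_analysis(co$metrics)
  expect_s3_class(res, "trajectory_results")
  expect_identical(nrow(res), 4L)
  expect_true(all(res$q_group >= res$p_group - 1e-12))
  expect_true(all(res$q_interaction >= res$p_interaction - 1e-12))

  shuffled <- co$metrics[sample(nrow(co$metrics)), ]
  res2 <- run_trajectory_analysis(shuffled)
  expect_equal(res, res2, ignore_attr = TRUE)

  # missing combinations are reported and skipped
  drop <- co$metrics[!(co$metrics$tract == "FMIN" & co$metrics$metric == "MD"), ]
  expect_warning(res3 <- run_trajectory_analysis(drop), "FMIN_MD")
  expect_identical(nrow(res3), 3L)
})

test_that("single-level covariates are dropped with a warning", {
  cfg <- simulation_config(n_per_group = 20, tracts = "FMAJ",
                           metrics = "FA", scanner_prob = 0, seed = 47)
  d <- make_measure_data(cfg)
  expect_warning(fit <- fit_mixed(d, 1, include_group = TRUE), "scanner")
  expect_false("scannerB" %in% names(fit$coefficients))
  expect_identical(fit$dropped_covariates, "scanner")
})
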