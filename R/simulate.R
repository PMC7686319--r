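#' Default per-measure trajectory parameters
#'
#' Builds the table of generating parameters for every (tract, metric)
#' combination: polynomial order of the mean age trend, its coefficients on
#' the raw-age scale, the additive group offset for the deletion group, sex
#' and scanner covariate shifts, and the two variance components.
#'
#' Defaults emulate tract-averaged diffusion values in developmental cohorts:
#' FA rises roughly linearly over ages 5-35 while the diffusivities (in
#' um^2/ms) decline and flatten (quadratic for RD/MD). The deletion group is
#' shifted towards higher FA and lower AD/RD/MD, the direction reported for
#' 22q11.2 deletion carriers. Baseline values vary by a few percent across
#' tracts so tracts are distinguishable.
#'
#' @param tracts,metrics Character vectors of tract and metric labels.
#' @param group_offset,sex_effect,scanner_effect,random_intercept_sd,residual_sd
#'   Named per-metric numeric vectors (or a single number recycled to all
#'   metrics) overriding the defaults, all in metric units.
#' @return A data.frame with one row per (tract, metric).
#' @export
default_trajectory_spec <- function(tracts = tract_names(),
                                    metrics = metric_names(),
                                    group_offset = NULL,
                                    sex_effect = NULL,
                                    scanner_effect = NULL,
                                    random_intercept_sd = NULL,
                                    residual_sd = NULL) {
  base <- list(
    # order, b0, b1, b2 on the raw-age scale (years)
    FA = list(order = 1L, b0 = 0.380, b1 = 2.5e-3, b2 = 0),
    AD = list(order = 1L, b0 = 1.220, b1 = -2.0e-3, b2 = 0),
    # RD/MD decline through childhood and plateau in the mid/late 20s
    RD = list(order = 2L, b0 = 0.670, b1 = -1.06e-2, b2 = 1.9e-4),
    MD = list(order = 2L, b0 = 0.920, b1 = -1.45e-2, b2 = 2.7e-4)
  )
  defaults <- list(
    group_offset = c(FA = 0.012, AD = -0.030, RD = -0.025, MD = -0.025),
    sex_effect = c(FA = 0.004, AD = -0.006, RD = -0.005, MD = -0.005),
    scanner_effect = c(FA = -0.003, AD = 0.008, RD = 0.006, MD = 0.006),
    random_intercept_sd = c(FA = 0.015, AD = 0.025, RD = 0.022, MD = 0.020),
    residual_sd = c(FA = 0.010, AD = 0.018, RD = 0.015, MD = 0.014)
  )
  per_metric <- function(user, name) {
    out <- defaults[[name]][metrics]
    names(out) <- metrics
    out[is.na(out)] <- 0
    if (!is.null(user)) {
      if (is.null(names(user))) {
        if (length(user) == 1L) user <- stats::setNames(rep(user, length(metrics)), metrics)
        else if (length(user) == length(metrics)) names(user) <- metrics
        else stop_config("'", name, "' must be a scalar or a named per-metric vector")
      }
      out[names(user)] <- user
    }
    out
  }
  go <- per_metric(group_offset, "group_offset")
  se <- per_metric(sex_effect, "sex_effect")
  ce <- per_metric(scanner_effect, "scanner_effect")
  ri <- per_metric(random_intercept_sd, "random_intercept_sd")
  rs <- per_metric(residual_sd, "residual_sd")

  # fixed small relative baseline spread across tracts (not randomized)
  rel <- seq(-0.04, 0.04, length.out = max(length(tracts), 2L))[seq_along(tracts)]
  grid <- expand.grid(metric = metrics, tract = tracts,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ti <- match(grid$tract, tracts)
  m <- grid$metric
  b <- base[m]
  unknown <- setdiff(unique(m), names(base))
  if (length(unknown))
    stop_config("no default trajectory for metric(s): ",
                paste(unknown, collapse = ", "))
  data.frame(
    tract = grid$tract,
    metric = m,
    order = vapply(b, `[[`, integer(1), "order"),
    b0 = vapply(b, `[[`, numeric(1), "b0") * (1 + rel[ti]),
    b1 = vapply(b, `[[`, numeric(1), "b1"),
    b2 = vapply(b, `[[`, numeric(1), "b2"),
    group_offset = unname(go[m]),
    sex_effect = unname(se[m]),
    scanner_effect = unname(ce[m]),
    random_intercept_sd = unname(ri[m]),
    residual_sd = unname(rs[m]),
    stringsAsFactors = FALSE
  )[, c("tract", "metric", "order", "b0", "b1", "b2", "group_offset",
        "sex_effect", "scanner_effect", "random_intercept_sd",
        "residual_sd")]
}

#' Configuration of a synthetic longitudinal cohort
#'
#' Describes a two-group cohort (controls vs. 22q11.2 deletion carriers)
#' scanned 1-3 times between ages 5 and 35, with per-(tract, metric)
#' polynomial mean age trends, a per-subject random intercept, observation
#' noise, sex and scanner covariate shifts, five Bernoulli-coded clinical
#' risk factors, and a planted rank-1 latent association linking the risk
#' factors to subject-level deviations of the white-matter measures.
#'
#' The latent component adds
#' `latent_effect * score_i * w_X[k]` to every scan of subject *i* for
#' measure *k*, where `score_i` is the projection of the subject's
#' z-coded risk factors onto `latent_behavior_weights` and `w_X` is the
#' unit-norm `latent_brain_weights` vector. It is a subject-level constant,
#' so averaging age-residualized scans recovers it. With the default brain
#' weights (proportional to each column's random-intercept SD) the default
#' `latent_effect` equals the root-mean-square random-intercept SD, which
#' plants an association of about one subject-SD.
#'
#' @param n_per_group Subjects per group.
#' @param age_range Numeric length-2, minimum and maximum age in years.
#' @param visit_probs Probabilities of a subject contributing 1, 2 or 3
#'   visits (defaults approximate 1.5 scans per subject).
#' @param visit_interval Mean and SD (years) of the between-visit interval;
#'   intervals are truncated below at 0.5 years and visits running past the
#'   age maximum are dropped.
#' @param tracts,metrics Vocabulary of tract and metric labels.
#' @param trajectory_spec Per-(tract, metric) generating parameters; see
#'   [default_trajectory_spec()]. Built from the remaining arguments when
#'   omitted.
#' @param risk_prevalence Named length-5 vector of Bernoulli prevalences of
#'   the risk factors (defaults follow the subgroup sizes of a 39-patient
#'   deletion cohort: 10/39 UHR, 12/39 preterm, 12/36 low baseline IQ,
#'   16/39 cognitive decline, 21/39 baseline anxiety).
#' @param latent_effect Scalar effect size of the planted association
#'   (`NULL` = RMS of the per-column random-intercept SDs, i.e. ~1 SD).
#' @param latent_behavior_weights Unit-norm length-5 vector over
#'   [risk_factor_names()].
#' @param latent_brain_weights Unit-norm length-72 vector over
#'   the (tract, metric) columns; default has positive FA and negative
#'   AD/RD/MD loadings, proportional to each column's random-intercept SD.
#' @param sex_prob,scanner_prob Probability of sex "F" (per subject) and of
#'   scanner "B" (per scan).
#' @param seed Default RNG seed used by [generate_cohort()].
#' @inheritParams default_trajectory_spec
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_per_group = 100,
                              age_range = c(5, 35),
                              visit_probs = c(0.5, 0.45, 0.05),
                              visit_interval = c(mean = 3, sd = 1),
                              tracts = tract_names(),
                              metrics = metric_names(),
                              trajectory_spec = NULL,
                              group_offset = NULL,
                              sex_effect = NULL,
                              scanner_effect = NULL,
                              random_intercept_sd = NULL,
                              residual_sd = NULL,
                              risk_prevalence = c(uhr = 10 / 39,
                                                  preterm = 12 / 39,
                                                  low_baseline_iq = 12 / 36,
                                                  cognitive_decline = 16 / 39,
                                                  baseline_anxiety = 21 / 39),
                              latent_effect = NULL,
                              latent_behavior_weights = NULL,
                              latent_brain_weights = NULL,
                              sex_prob = 0.5,
                              scanner_prob = 0.37,
                              seed = 1L) {
  if (length(n_per_group) != 1L || n_per_group < 1)
    stop_config("n_per_group must be a positive count")
  if (length(age_range) != 2L || age_range[1] >= age_range[2])
    stop_config("age_range must satisfy min < max")
  if (length(visit_probs) != 3L || any(visit_probs < 0) || sum(visit_probs) <= 0)
    stop_config("visit_probs must be 3 non-negative values with positive sum")
  visit_probs <- visit_probs / sum(visit_probs)
  vi <- unname(visit_interval)
  if (length(vi) != 2L || vi[1] <= 0 || vi[2] < 0)
    stop_config("visit_interval must give a positive mean and non-negative sd")
  if (is.null(trajectory_spec))
    trajectory_spec <- default_trajectory_spec(
      tracts, metrics, group_offset, sex_effect, scanner_effect,
      random_intercept_sd, residual_sd)
  needed <- c("tract", "metric", "order", "b0", "b1", "b2", "group_offset",
              "sex_effect", "scanner_effect", "random_intercept_sd",
              "residual_sd")
  missing_cols <- setdiff(needed, names(trajectory_spec))
  if (length(missing_cols))
    stop_config("trajectory_spec lacks column(s): ",
                paste(missing_cols, collapse = ", "))
  if (any(trajectory_spec$random_intercept_sd < 0) ||
      any(trajectory_spec$residual_sd < 0))
    stop_config("standard deviations must be >= 0")
  if (!all(trajectory_spec$order %in% 0:2))
    stop_config("trajectory orders must be 0, 1 or 2")
  keys <- measure_keys(tracts, metrics)
  spec_keys <- paste(trajectory_spec$tract, trajectory_spec$metric, sep = "_")
  if (!setequal(spec_keys, keys) || anyDuplicated(spec_keys))
    stop_config("trajectory_spec must cover each (tract, metric) exactly once")
  trajectory_spec <- trajectory_spec[match(keys, spec_keys), ]
  rownames(trajectory_spec) <- NULL

  rf <- risk_factor_names()
  if (is.null(names(risk_prevalence)) && length(risk_prevalence) == length(rf))
    names(risk_prevalence) <- rf
  if (!setequal(names(risk_prevalence), rf))
    stop_config("risk_prevalence must be named over: ", paste(rf, collapse = ", "))
  risk_prevalence <- risk_prevalence[rf]
  if (any(risk_prevalence <= 0) || any(risk_prevalence >= 1))
    stop_config("risk prevalences must lie strictly inside (0, 1)")

  if (is.null(latent_behavior_weights)) {
    latent_behavior_weights <- c(uhr = 0.75, preterm = -0.57,
                                 low_baseline_iq = -0.32,
                                 cognitive_decline = -0.02,
                                 baseline_anxiety = 0.03)
  }
  if (is.null(names(latent_behavior_weights)) &&
      length(latent_behavior_weights) == length(rf))
    names(latent_behavior_weights) <- rf
  if (!setequal(names(latent_behavior_weights), rf))
    stop_config("latent_behavior_weights must be named over the risk factors")
  latent_behavior_weights <- latent_behavior_weights[rf]
  latent_behavior_weights <-
    latent_behavior_weights / sqrt(sum(latent_behavior_weights^2))

  if (is.null(latent_brain_weights)) {
    sgn <- ifelse(trajectory_spec$metric == "FA", 1, -1)
    w <- sgn * pmax(trajectory_spec$random_intercept_sd, 0)
    if (all(w == 0)) w <- sgn
    latent_brain_weights <- w / sqrt(sum(w^2))
  }
  if (length(latent_brain_weights) != length(keys))
    stop_config("latent_brain_weights must have one entry per (tract, metric)")
  nrm <- sqrt(sum(latent_brain_weights^2))
  if (abs(nrm - 1) > 1e-8)
    latent_brain_weights <- latent_brain_weights / nrm
  names(latent_brain_weights) <- keys

  if (is.null(latent_effect))
    latent_effect <- sqrt(mean(trajectory_spec$random_intercept_sd^2))

  structure(list(
    n_per_group = as.integer(n_per_group),
    age_range = as.numeric(age_range),
    visit_probs = visit_probs,
    visit_interval = c(mean = vi[1], sd = vi[2]),
    tracts = tracts, metrics = metrics,
    measure_keys = keys,
    trajectory_spec = trajectory_spec,
    risk_prevalence = risk_prevalence,
    latent_effect = latent_effect,
    latent_behavior_weights = latent_behavior_weights,
    latent_brain_weights = latent_brain_weights,
    sex_prob = sex_prob, scanner_prob = scanner_prob,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("simulation_config:", 2L * x$n_per_group, "subjects (",
      x$n_per_group, "per group ), ages", x$age_range[1], "-",
      x$age_range[2], "\n")
  cat("  ", length(x$tracts), "tracts x", length(x$metrics),
      "metrics =", length(x$measure_keys), "measures\n")
  cat("   latent_effect:", signif(x$latent_effect, 4),
      "; seed:", x$seed, "\n")
  invisible(x)
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws subjects, visit schedules, tract-metric values and risk factors
#' under a [simulation_config()]. Observed values follow
#' `b0 + b1*age + b2*age^2 + group_offset*[deletion] + sex_effect*[F] +
#' scanner_effect*[B] + b_i + latent + e` with `b_i ~ N(0, ri_sd^2)` per
#' subject and measure and `e ~ N(0, residual_sd^2)` per scan; the planted
#' latent association is described under [simulation_config()].
#'
#' @param config A `simulation_config`.
#' @param seed RNG seed; defaults to `config$seed`. Identical seeds give
#'   byte-identical output.
#' @return A list of class `tract_cohort`:
#'   \describe{
#'     \item{metrics}{Long-format data.frame, one row per
#'       (subject, visit, tract, metric).}
#'     \item{risk}{One row per subject with the five 0/1 risk factors.}
#'     \item{truth}{Planted ground truth: per-subject latent scores,
#'       random intercepts, the trajectory parameter table, latent weights
#'       and the configuration.}
#'   }
#' @export
generate_cohort <- function(config, seed = NULL) {
  if (!inherits(config, "simulation_config"))
    stop_config("config must be a simulation_config")
  seed <- as.integer(seed %||% config$seed)
  set.seed(seed)

  n <- 2L * config$n_per_group
  subject_id <- sprintf("S%04d", seq_len(n))
  group <- rep(c("control", "deletion"), each = config$n_per_group)
  sex <- ifelse(stats::runif(n) < config$sex_prob, "F", "M")

  # visit schedule: first age uniform over the range, later ages add
  # truncated-normal intervals, visits past the maximum age are dropped
  n_visits <- sample.int(3L, n, replace = TRUE, prob = config$visit_probs)
  age1 <- stats::runif(n, config$age_range[1], config$age_range[2])
  gaps <- matrix(pmax(stats::rnorm(2L * n, config$visit_interval["mean"],
                                   config$visit_interval["sd"]), 0.5),
                 nrow = n)
  ages <- cbind(age1, age1 + gaps[, 1], age1 + gaps[, 1] + gaps[, 2])
  keep <- sweep(col(ages), 1, n_visits, `<=`) &
    ages <= config$age_range[2] + 1e-9
  keep[, 1] <- TRUE

  scan_subj <- rep(seq_len(n), times = rowSums(keep))
  scan_age <- as.vector(t(ages))[as.vector(t(keep))]
  scan_visit <- sequence(rowSums(keep))
  n_scans <- length(scan_subj)
  scan_scanner <- ifelse(stats::runif(n_scans) < config$scanner_prob, "B", "A")

  # risk factors and latent subject scores
  p <- config$risk_prevalence
  y <- matrix(as.integer(stats::runif(n * 5L) <
                           rep(p, each = n)), nrow = n,
              dimnames = list(subject_id, names(p)))
  z <- sweep(sweep(y, 2, p, `-`), 2, sqrt(p * (1 - p)), `/`)
  latent_score <- as.vector(z %*% config$latent_behavior_weights)

  spec <- config$trajectory_spec
  n_meas <- nrow(spec)
  b_subj <- matrix(stats::rnorm(n * n_meas), nrow = n) *
    rep(spec$random_intercept_sd, each = n)

  # long table: scans outer, measures inner
  idx_scan <- rep(seq_len(n_scans), each = n_meas)
  idx_meas <- rep(seq_len(n_meas), times = n_scans)
  a <- scan_age[idx_scan]
  subj <- scan_subj[idx_scan]
  value <- spec$b0[idx_meas] + spec$b1[idx_meas] * a +
    spec$b2[idx_meas] * a^2 +
    spec$group_offset[idx_meas] * (group[subj] == "deletion") +
    spec$sex_effect[idx_meas] * (sex[subj] == "F") +
    spec$scanner_effect[idx_meas] * (scan_scanner[idx_scan] == "B") +
    b_subj[cbind(subj, idx_meas)] +
    config$latent_effect * latent_score[subj] *
      config$latent_brain_weights[idx_meas] +
    stats::rnorm(n_scans * n_meas) * spec$residual_sd[idx_meas]

  metrics_tab <- data.frame(
    subject_id = subject_id[subj],
    group = group[subj],
    sex = sex[subj],
    scanner = scan_scanner[idx_scan],
    visit_index = scan_visit[idx_scan],
    age = a,
    tract = spec$tract[idx_meas],
    metric = spec$metric[idx_meas],
    value = unname(value),
    stringsAsFactors = FALSE
  )
  risk_tab <- data.frame(subject_id = subject_id, as.data.frame(y),
                         row.names = NULL, stringsAsFactors = FALSE)
  risk_tab <- risk_tab[, c("subject_id", risk_factor_names())]

  truth <- list(
    seed = seed,
    subjects = data.frame(subject_id = subject_id, group = group, sex = sex,
                          n_visits = rowSums(keep),
                          latent_score = latent_score,
                          stringsAsFactors = FALSE),
    random_intercepts = `dimnames<-`(b_subj,
                                     list(subject_id, config$measure_keys)),
    trajectory_spec = spec,
    latent_effect = config$latent_effect,
    latent_behavior_weights = config$latent_behavior_weights,
    latent_brain_weights = config$latent_brain_weights,
    config = config
  )
  structure(list(metrics = metrics_tab, risk = risk_tab, truth = truth),
            class = "tract_cohort")
}

#' @export
print.tract_cohort <- function(x, ...) {
  cat("tract_cohort:", length(unique(x$metrics$subject_id)), "subjects,",
      nrow(unique(x$metrics[, c("subject_id", "visit_index")])), "scans,",
      nrow(x$metrics), "measure rows\n")
  invisible(x)
}

#' Subject-level deviation configuration
#'
#' A [simulation_config()] variant that emits subject-level deviation
#' scores directly: flat zero trajectories, no group/sex/scanner effects,
#' unit random-intercept SD, zero residual noise and a single visit per
#' subject. The resulting per-subject measure values are exactly
#' `b_i + latent`, the object the residualization stage hands to the PLS
#' — convenient for calibration and recovery studies of the PLS machinery
#' at scale without refitting 72 mixed models per replicate. With unit
#' column SDs, `latent_effect` is directly the planted association
#' strength in subject-SD units.
#'
#' @param n_subjects Number of subjects (all in the deletion group).
#' @param latent_effect Planted association strength (0 = null).
#' @param seed RNG seed.
#' @param ... Further arguments passed to [simulation_config()]
#'   (e.g. `latent_behavior_weights`, `risk_prevalence`).
#' @return A `simulation_config`.
#' @export
deviation_config <- function(n_subjects, latent_effect = 0, seed = 1L, ...) {
  spec <- default_trajectory_spec()
  spec$order <- 0L
  spec$b0 <- 0; spec$b1 <- 0; spec$b2 <- 0
  spec$group_offset <- 0; spec$sex_effect <- 0; spec$scanner_effect <- 0
  spec$random_intercept_sd <- 1
  spec$residual_sd <- 0
  if (n_subjects < 2 || n_subjects %% 2 != 0)
    stop_config("n_subjects must be an even count >= 2")
  simulation_config(n_per_group = n_subjects / 2,
                    visit_probs = c(1, 0, 0),
                    trajectory_spec = spec,
                    latent_effect = latent_effect,
                    seed = seed, ...)
}

#' Per-subject mean value matrix
#'
#' Averages the observed values of each (subject, tract, metric) across
#' scans and pivots them into a subjects-by-measures matrix in canonical
#' column order (the raw, non-residualized counterpart of
#' [subject_deviation_scores()]).
#'
#' @param table Long-format metric table.
#' @return Numeric matrix, rows = sorted subject ids, columns =
#'   `tract_metric` keys.
#' @export
subject_measure_matrix <- function(table) {
  table <- validate_long_table(table)
  tracts <- intersect(tract_names(), unique(table$tract))
  metrics <- intersect(metric_names(), unique(table$metric))
  keys <- measure_keys(tracts, metrics)
  kf <- factor(paste(table$tract, table$metric, sep = "_"), levels = keys)
  sf <- factor(table$subject_id)
  M <- tapply(table$value, list(sf, kf), mean)
  M[, keys, drop = FALSE]
}
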