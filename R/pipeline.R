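#' Configuration of a full pipeline run
#'
#' Bundles the inputs and knobs of [run_pipeline()]: either a
#' [simulation_config()] to generate a synthetic cohort, or paths to a
#' long-format metric TSV and a risk-factor TSV.
#'
#' @param simulation A `simulation_config`, or `NULL` when reading files.
#' @param metrics_path,risk_path Input TSV paths (ignored when
#'   `simulation` is given).
#' @param pls_group Group whose subjects enter residualization and PLS.
#' @param pls_min_visits Minimum number of scans for a subject to enter
#'   the PLS subset (the deviation scores average within-subject scans, so
#'   multi-visit subjects are the intended case).
#' @param alpha FDR significance level for reporting.
#' @param n_perm,n_boot Permutation and bootstrap counts.
#' @param residualization Deviation-score variant, `"per_scan"` or
#'   `"mean_age"` (see [subject_deviation_scores()]).
#' @param seed Master seed; stage seeds are derived from it and recorded.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @return List of class `run_config`.
#' @export
run_config <- function(simulation = NULL, metrics_path = NULL,
                       risk_path = NULL, pls_group = "deletion",
                       pls_min_visits = 2L, alpha = 0.05,
                       n_perm = 1000, n_boot = 500,
                       residualization = c("per_scan", "mean_age"),
                       seed = 1L, out_dir = NULL) {
  residualization <- match.arg(residualization)
  if (is.null(simulation) && (is.null(metrics_path) || is.null(risk_path)))
    stop_config("provide either a simulation config or both input paths")
  if (alpha <= 0 || alpha >= 1) stop_config("alpha must lie in (0, 1)")
  if (n_perm < 100 || n_boot < 100)
    stop_config("n_perm and n_boot must be at least 100")
  structure(list(simulation = simulation, metrics_path = metrics_path,
                 risk_path = risk_path, pls_group = pls_group,
                 pls_min_visits = as.integer(pls_min_visits),
                 alpha = alpha, n_perm = n_perm, n_boot = n_boot,
                 residualization = residualization,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

config_fingerprint <- function(config) {
  # stable content hash of the configuration (file-backed, via serialize)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  x <- config
  x$out_dir <- NULL
  saveRDS(x, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

#' Run the full two-stage analysis
#'
#' Orchestrates simulate/load -> trajectory analysis -> residualization ->
#' PLS correlation, optionally writing every stage product to
#' `config$out_dir`: `metrics.tsv`, `risk_factors.tsv`,
#' `trajectories.tsv`, `trajectories_meta.json`, `brain_matrix.tsv`,
#' `age_models.json`, `pls_components.tsv`, `pls_weights.tsv`,
#' `pls_scores.tsv`, `pls_meta.json` and `report.json` (seeds, config
#' fingerprint, stage counts and output checksums). Rerunning with an
#' identical configuration reproduces identical outputs.
#'
#' @param config A [run_config()].
#' @return List of class `pipeline_result` with elements `table`, `risk`,
#'   `trajectories`, `age_models`, `X`, `Y`, `pls`, `report` (and `truth`
#'   for simulated cohorts).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config"))
    stop_config("config must come from run_config()")
  seed <- config$seed

  truth <- NULL
  if (!is.null(config$simulation)) {
    cohort <- generate_cohort(config$simulation, seed = seed)
    table <- cohort$metrics
    risk <- cohort$risk
    truth <- cohort$truth
  } else {
    table <- read_long_table(config$metrics_path)
    risk <- read_risk_table(config$risk_path)
  }
  table <- validate_long_table(table)

  traj <- run_trajectory_analysis(table, alpha = config$alpha)

  sub <- table[table$group == config$pls_group, ]
  n_vis <- tapply(sub$visit_index, sub$subject_id, function(v)
    length(unique(v)))
  keep <- names(n_vis)[n_vis >= config$pls_min_visits]
  sub <- sub[sub$subject_id %in% keep, ]
  if (!length(keep))
    stop_validation("no subjects in group '", config$pls_group,
                    "' with >= ", config$pls_min_visits, " visits")
  models <- fit_age_models(sub)
  X <- subject_deviation_scores(sub, models,
                                method = config$residualization)
  Y <- behavior_matrix(risk, subjects = rownames(X))
  pls <- pls_correlation(X, Y, n_perm = config$n_perm,
                         n_boot = config$n_boot, seed = seed + 17L)

  n_scans <- sum(!duplicated(table[, c("subject_id", "visit_index")]))
  report <- list(
    seed = seed,
    config_fingerprint = config_fingerprint(config),
    n_subjects = length(unique(table$subject_id)),
    n_scans = n_scans,
    n_trajectory_tests = nrow(traj),
    n_group_significant = sum(traj$q_group < config$alpha, na.rm = TRUE),
    n_interaction_significant =
      sum(traj$q_interaction < config$alpha, na.rm = TRUE),
    n_pls_subjects = nrow(X),
    n_age_models = length(models$fits),
    n_brain_columns = ncol(X),
    n_components = pls$components$n_components,
    n_significant_components = sum(pls$permutation$p < 0.05),
    alpha = config$alpha, n_perm = config$n_perm, n_boot = config$n_boot,
    residualization = config$residualization
  )

  result <- structure(list(table = table, risk = risk, trajectories = traj,
                           age_models = models, X = X, Y = Y, pls = pls,
                           truth = truth, report = report,
                           config = config),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  cfg <- result$config
  write_long_table(result$table, p("metrics.tsv"))
  write_risk_table(result$risk, p("risk_factors.tsv"))

  traj <- as.data.frame(result$trajectories)
  utils::write.table(traj, p("trajectories.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(
    seed = cfg$seed, config_fingerprint = result$report$config_fingerprint,
    age_center = attr(result$trajectories, "age_center"),
    alpha = cfg$alpha,
    fdr_families = attr(result$trajectories, "fdr_families"),
    estimation = "maximum likelihood (not REML)",
    bic = "-2 logLik + n_params * log(n_scans)",
    r_version = as.character(getRversion())
  ), p("trajectories_meta.json"), auto_unbox = TRUE, digits = NA)

  write_matrix_tsv(result$X, p("brain_matrix.tsv"))
  jsonlite::write_json(lapply(result$age_models$fits, function(f) list(
    tract = f$tract, metric = f$metric, order = f$order,
    coefficients = as.list(f$coefficients),
    random_intercept_sd = f$random_intercept_sd,
    residual_sd = f$residual_sd, bic = f$bic, method = f$method,
    dropped_covariates = f$dropped_covariates,
    age_center = f$age_center
  )), p("age_models.json"), auto_unbox = TRUE, digits = NA)

  pls <- result$pls
  utils::write.table(data.frame(
    component = seq_along(pls$components$d),
    singular_value = pls$components$d,
    explained_correlation = pls$components$explained,
    perm_p = pls$permutation$p,
    latent_r = pls$scores$r
  ), p("pls_components.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  weights <- do.call(rbind, lapply(seq_along(pls$bootstrap$behavior),
    function(k) {
      b <- rbind(
        cbind(block = "behavior", pls$bootstrap$behavior[[k]]),
        cbind(block = "brain", pls$bootstrap$brain[[k]]))
      cbind(component = k, b)
    }))
  utils::write.table(weights, p("pls_weights.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  scores <- data.frame(subject_id = rownames(result$X),
                       result$pls$scores$L_X,
                       stats::setNames(as.data.frame(result$pls$scores$L_Y),
                                       paste0("LY", seq_len(ncol(result$pls$scores$L_Y)))),
                       check.names = FALSE)
  names(scores)[2:(1 + ncol(result$pls$scores$L_X))] <-
    paste0("LX", seq_len(ncol(result$pls$scores$L_X)))
  utils::write.table(scores, p("pls_scores.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  jsonlite::write_json(list(
    seed = cfg$seed, pls_seed = cfg$seed + 17L,
    config_fingerprint = result$report$config_fingerprint,
    n_perm = cfg$n_perm, n_boot = cfg$n_boot,
    n_redrawn_bootstrap = pls$bootstrap$n_redrawn,
    sign_convention = "largest-magnitude behavior salience positive",
    correlation_scaling = "R = t(Yz) Xz / (n - 1)",
    permutation_scheme = "Y rows permuted; rank-matched singular values",
    bootstrap_alignment = "sign flip against reference saliences"
  ), p("pls_meta.json"), auto_unbox = TRUE, digits = NA)

  files <- c("metrics.tsv", "risk_factors.tsv", "trajectories.tsv",
             "brain_matrix.tsv", "pls_components.tsv", "pls_weights.tsv",
             "pls_scores.tsv")
  checksums <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(checksums) <- files
  jsonlite::write_json(c(result$report, list(checksums = checksums)),
                       p("report.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat("pipeline_result:", r$n_subjects, "subjects /", r$n_scans, "scans\n")
  cat("  trajectory tests:", r$n_trajectory_tests,
      "| group q <", r$alpha, ":", r$n_group_significant,
      "| interaction q <", r$alpha, ":", r$n_interaction_significant, "\n")
  cat("  PLS:", r$n_pls_subjects, "subjects x", r$n_brain_columns,
      "measures;", r$n_significant_components,
      "significant component(s) at p < 0.05\n")
  invisible(x)
}
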