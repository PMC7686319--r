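#' Fit age-only developmental models in the analysis subset
#'
#' For every (tract, metric), fits a random-intercept model of the measure
#' on a polynomial of age plus sex and scanner covariates — no group terms —
#' in the supplied (single-group) subset, choosing the polynomial order
#' among 0-2 by BIC. These curves define the expected developmental value
#' at a given age against which subject deviations are measured.
#'
#' @param table Long-format metric table restricted to the analysis group
#'   (e.g. the deletion carriers entering the PLS).
#' @param tracts,metrics Measures to fit; defaults to every canonical
#'   measure present in the table.
#' @param age_center Age centering constant; defaults to the subset's mean
#'   scan age.
#' @return List of class `age_model_set`: `fits` (named by
#'   `tract_metric` key, canonical order), `age_center`, `tracts`,
#'   `metrics`.
#' @export
fit_age_models <- function(table, tracts = NULL, metrics = NULL,
                           age_center = NULL) {
  table <- validate_long_table(table)
  if (length(unique(table$group)) > 1L)
    warning("age models are meant for a single-group subset; ",
            "fitting on the pooled data", call. = FALSE)
  tracts <- tracts %||% intersect(tract_names(), unique(table$tract))
  metrics <- metrics %||% intersect(metric_names(), unique(table$metric))
  scans <- !duplicated(table[, c("subject_id", "visit_index")])
  age_center <- age_center %||% mean(table$age[scans])

  keys <- measure_keys(tracts, metrics)
  parts <- split_measure_keys(keys)
  fits <- lapply(seq_along(keys), function(i) {
    d <- table[table$tract == parts$tract[i] &
                 table$metric == parts$metric[i], ]
    if (!nrow(d))
      stop_validation("no observations for measure ", keys[i])
    cand <- lapply(0:2, function(k)
      fit_mixed(d, k, include_group = FALSE, include_interaction = FALSE,
                age_center = age_center,
                tract = parts$tract[i], metric = parts$metric[i]))
    select_order(cand)
  })
  names(fits) <- keys
  structure(list(fits = fits, age_center = age_center,
                 tracts = tracts, metrics = metrics),
            class = "age_model_set")
}

#' @export
print.age_model_set <- function(x, ...) {
  ord <- vapply(x$fits, `[[`, integer(1), "order")
  cat("age_model_set:", length(x$fits), "measures; selected orders:",
      paste(sprintf("%d x order %d", table(ord), as.integer(names(table(ord)))),
            collapse = ", "), "\n")
  invisible(x)
}

#' Age-adjusted per-subject deviation scores (brain matrix)
#'
#' Builds the subjects-by-measures matrix entering the PLS: for every scan
#' the residual from the fixed-effects-only population curve (the
#' subject's random intercept is deliberately excluded — including it would
#' absorb exactly the deviation the matrix is meant to capture), averaged
#' across each subject's scans per measure. A subject lying exactly on the
#' population curve scores 0 everywhere.
#'
#' `method = "per_scan"` (default) residualizes each scan and averages the
#' residuals; `method = "mean_age"` first averages the observed values and
#' ages per subject and takes the residual at the mean age (equal for
#' linear curves, slightly different for quadratic ones; the mean-age
#' variant evaluates sex at the subject's value and scanner at the
#' subject's first-scan level).
#'
#' @param table Long-format metric table for the subjects to score.
#' @param models An [fit_age_models()] result covering all measures.
#' @param method Residualization variant, `"per_scan"` or `"mean_age"`.
#' @return Numeric matrix, rows = subjects (sorted by id), columns = the 72
#'   `tract_metric` keys in canonical order. Subjects missing a measure at
#'   every scan are excluded with a warning.
#' @export
subject_deviation_scores <- function(table, models,
                                     method = c("per_scan", "mean_age")) {
  method <- match.arg(method)
  if (!inherits(models, "age_model_set"))
    stop_validation("models must be an age_model_set")
  table <- validate_long_table(table)
  keys <- names(models$fits)
  table_key <- paste(table$tract, table$metric, sep = "_")
  extra <- setdiff(unique(table_key), keys)
  if (length(extra))
    table <- table[!(table_key %in% extra), ]
  table_key <- paste(table$tract, table$metric, sep = "_")

  subjects <- sort(unique(table$subject_id))
  X <- matrix(NA_real_, nrow = length(subjects), ncol = length(keys),
              dimnames = list(subjects, keys))
  for (k in keys) {
    d <- table[table_key == k, ]
    fit <- models$fits[[k]]
    if (method == "per_scan") {
      res <- d$value - predict_fixed(fit, d)
      avg <- tapply(res, factor(d$subject_id, levels = subjects), mean)
    } else {
      first <- d[order(d$subject_id, d$visit_index), ]
      first <- first[!duplicated(first$subject_id), ]
      sf <- factor(d$subject_id, levels = subjects)
      mval <- tapply(d$value, sf, mean)
      mage <- tapply(d$age, sf, mean)
      nd <- data.frame(subject_id = subjects,
                       age = as.numeric(mage),
                       sex = first$sex[match(subjects, first$subject_id)],
                       scanner = first$scanner[match(subjects,
                                                     first$subject_id)],
                       stringsAsFactors = FALSE)
      avg <- as.numeric(mval) - predict_fixed(fit, nd)
    }
    X[, k] <- as.numeric(avg)
  }
  incomplete <- rowSums(is.na(X)) > 0
  if (any(incomplete)) {
    warning("excluding subject(s) missing a measure at every scan: ",
            paste(subjects[incomplete], collapse = ", "), call. = FALSE)
    X <- X[!incomplete, , drop = FALSE]
  }
  X
}
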