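factor_levels <- list(group = c("control", "deletion"),
                      sex = c("M", "F"),
                      scanner = c("A", "B"))

# Coerce the categorical columns to factors with the package-wide level
# order so coefficient names and contrasts are stable across fits.
prepare_model_frame <- function(data, age_center) {
  data$age_c <- data$age - age_center
  for (v in names(factor_levels)) {
    if (v %in% names(data))
      data[[v]] <- factor(as.character(data[[v]]), levels = factor_levels[[v]])
  }
  data
}

build_fixed_terms <- function(order, include_group, include_interaction,
                              covariates) {
  age_terms <- c("age_c", "I(age_c^2)")[seq_len(order)]
  terms <- age_terms
  if (include_group) {
    terms <- c(terms, "group")
    if (include_interaction && order >= 1)
      terms <- c(terms, paste0("group:", age_terms))
  }
  c(terms, covariates)
}

#' Fit a random-intercept model for one tract and metric
#'
#' Fits `value ~ polynomial(age) [+ group [+ group:age terms]] + sex +
#' scanner + (1 | subject_id)` by maximum likelihood (not REML, so that
#' models differing in fixed effects are comparable by likelihood ratio).
#' Age is centered at `age_center` before fitting; coefficients are
#' reported on the centered scale.
#'
#' Covariates with a single observed level are dropped with a warning.
#' When the fixed-effect structure fits the data (essentially) perfectly —
#' e.g. noise-free synthetic input — the mixed model is degenerate and the
#' fit falls back to ordinary least squares with a zero random-intercept
#' SD; the same fallback applies when every subject contributes a single
#' scan, leaving the intercept variance unidentifiable.
#'
#' @param data Long-table rows for a single (tract, metric): columns
#'   `subject_id`, `group`, `sex`, `scanner`, `age`, `value`.
#' @param order Polynomial order of the age trend, 0, 1 or 2.
#' @param include_group,include_interaction Include the group main effect /
#'   the group-by-age interaction terms (interactions require the group
#'   effect and `order >= 1`).
#' @param age_center Centering constant for age; defaults to the mean age
#'   of `data`.
#' @param tract,metric Optional labels carried into the result.
#' @return Object of class `trajectory_fit` with elements `coefficients`,
#'   `random_intercept_sd`, `residual_sd`, `logLik`, `n_params`, `bic`
#'   (BIC = -2 logLik + n_params * log(number of scans)), `n_obs`,
#'   `converged`, `method` ("lmm" or "ols"), `dropped_covariates`, and the
#'   information needed by [predict_fixed()].
#' @export
fit_mixed <- function(data, order, include_group = FALSE,
                      include_interaction = FALSE, age_center = NULL,
                      tract = NA_character_, metric = NA_character_) {
  if (!order %in% 0:2) stop_config("order must be 0, 1 or 2")
  if (include_interaction && !include_group)
    stop_config("interaction terms require the group effect")
  if (length(unique(data$subject_id)) < 2L)
    stop_validation("need at least 2 subjects")
  age_center <- age_center %||% mean(data$age)
  df <- prepare_model_frame(data, age_center)

  covariates <- c("sex", "scanner")
  dropped <- character(0)
  for (v in c(covariates, if (include_group) "group")) {
    if (length(unique(stats::na.omit(df[[v]]))) < 2L) {
      dropped <- c(dropped, v)
      warning("dropping covariate with a single level: ", v, call. = FALSE)
    }
  }
  if ("group" %in% dropped) {
    include_group <- FALSE
    include_interaction <- FALSE
  }
  covariates <- setdiff(covariates, dropped)

  fixed <- build_fixed_terms(order, include_group, include_interaction,
                             covariates)
  rhs <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
  fixed_formula <- stats::as.formula(paste("value ~", rhs))

  n_obs <- nrow(df)
  ols <- stats::lm(fixed_formula, data = df)
  tol <- max(1e-10 * stats::sd(df$value), 1e-12)
  all_singletons <- !any(duplicated(df$subject_id))
  perfect <- stats::sigma(ols) < tol
  # If fixed effects plus per-subject constants reproduce the data exactly
  # (noise-free input with planted subject offsets), the ML residual
  # variance sits on the zero boundary where lmer degenerates. The sigma->0
  # limit of the random-intercept GLS estimator is OLS on subject means.
  within_degenerate <- FALSE
  if (!perfect && !all_singletons) {
    # within-subject estimator: demean response and design by subject and
    # check whether anything is left for the residual variance to explain
    mm <- stats::model.matrix(fixed_formula, df)
    grp <- factor(df$subject_id)
    demean <- function(x) x - stats::ave(x, grp)
    mmw <- apply(mm, 2, demean)
    fitw <- stats::lm.fit(mmw, demean(df$value))
    within_degenerate <- max(abs(fitw$residuals)) < tol
  }

  converged <- TRUE
  if (within_degenerate) {
    warning("residual variance degenerate (subject-constant residuals): ",
            "fitting the subject-means limit", call. = FALSE)
    mm <- stats::model.matrix(fixed_formula, df)
    grp <- factor(df$subject_id)
    mbar <- rowsum(mm, grp) / as.vector(table(grp))
    ybar <- as.vector(rowsum(df$value, grp) / as.vector(table(grp)))
    fit0 <- stats::lm.fit(mbar, ybar)
    beta <- fit0$coefficients
    ri_sd <- stats::sd(fit0$residuals)
    res_sd <- 0
    ll <- Inf  # the degenerate boundary: dominates any noisy alternative
    method <- "subject_means"
  } else if (perfect || all_singletons) {
    if (all_singletons && stats::sigma(ols) >= tol)
      warning("one scan per subject: random intercept unidentifiable, ",
              "using OLS", call. = FALSE)
    beta <- stats::coef(ols)
    ri_sd <- 0
    res_sd <- stats::sigma(ols)
    ll <- as.numeric(stats::logLik(ols))
    method <- "ols"
  } else {
    full_formula <- stats::as.formula(
      paste("value ~", rhs, "+ (1 | subject_id)"))
    fit <- NULL
    conv_msgs <- character(0)
    fit <- withCallingHandlers(
      tryCatch(lme4::lmer(full_formula, data = df, REML = FALSE),
               error = function(e) e),
      warning = function(w) {
        conv_msgs <<- c(conv_msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) invokeRestart("muffleMessage"))
    if (inherits(fit, "error")) {
      warning("mixed-model fit failed (", conditionMessage(fit),
              "); falling back to OLS", call. = FALSE)
      beta <- stats::coef(ols)
      ri_sd <- 0
      res_sd <- stats::sigma(ols)
      ll <- as.numeric(stats::logLik(ols))
      method <- "ols"
      converged <- FALSE
    } else {
      converged <- !any(grepl("failed to converge", conv_msgs, fixed = TRUE))
      if (!converged)
        warning("mixed-model fit did not converge for ", tract, " ", metric,
                call. = FALSE)
      beta <- lme4::fixef(fit)
      vc <- as.data.frame(lme4::VarCorr(fit))
      ri_sd <- vc$sdcor[vc$grp == "subject_id"][1]
      res_sd <- vc$sdcor[vc$grp == "Residual"][1]
      ll <- as.numeric(stats::logLik(fit))
      method <- "lmm"
    }
  }

  n_params <- length(beta) + 2L  # fixed effects + 2 variance components
  structure(list(
    tract = tract, metric = metric,
    order = as.integer(order),
    include_group = include_group,
    include_interaction = include_interaction,
    coefficients = beta,
    random_intercept_sd = ri_sd,
    residual_sd = res_sd,
    logLik = ll,
    n_params = n_params,
    bic = -2 * ll + n_params * log(n_obs),
    n_obs = n_obs,
    n_subjects = length(unique(df$subject_id)),
    converged = converged,
    method = method,
    perfect = perfect,
    dropped_covariates = dropped,
    age_center = age_center,
    fixed_formula = fixed_formula
  ), class = "trajectory_fit")
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf("trajectory_fit %s %s: order %d, %s, logLik %.3f, BIC %.3f\n",
              x$tract, x$metric, x$order, x$method, x$logLik, x$bic))
  print(signif(x$coefficients, 5))
  invisible(x)
}

#' Fixed-effects-only predictions from a trajectory fit
#'
#' Evaluates the population curve (fixed effects only, random intercept
#' excluded) at the ages/covariates of `newdata`.
#'
#' @param fit A `trajectory_fit`.
#' @param newdata Data.frame with the columns the fit's formula uses.
#' @return Numeric vector of predictions.
#' @export
predict_fixed <- function(fit, newdata) {
  df <- prepare_model_frame(newdata, fit$age_center)
  tt <- stats::delete.response(stats::terms(fit$fixed_formula))
  mm <- stats::model.matrix(tt, df)
  unname(drop(mm[, names(fit$coefficients), drop = FALSE] %*%
                fit$coefficients))
}

#' Select the polynomial order by BIC
#'
#' Returns the converged fit with minimal BIC; exact ties are broken in
#' favor of the lower polynomial order.
#'
#' @param fits List of `trajectory_fit` objects for the same data at
#'   different orders.
#' @return The selected `trajectory_fit`.
#' @export
select_order <- function(fits) {
  if (!length(fits)) stop_validation("no fits to select from")
  fits <- fits[order(vapply(fits, `[[`, integer(1), "order"))]
  ok <- vapply(fits, `[[`, logical(1), "converged")
  if (!any(ok)) stop_validation("no converged fit available")
  fits <- fits[ok]
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  fits[[which.min(bic)]]  # first minimum = lowest order on ties
}

#' Likelihood-ratio tests of group and age-by-group effects
#'
#' At a fixed, previously selected polynomial order, compares by likelihood
#' ratio (ML fits on identical observations):
#' the full model (group + interactions) against the model without
#' interaction terms (chi-squared, df = 1 for a linear trend, 2 for a
#' quadratic one; an order-0 model has no age term, so the interaction
#' statistic is 0 with p = 1); and the no-interaction model against the
#' model without the group effect (df = 1).
#'
#' @param data Rows for a single (tract, metric), as in [fit_mixed()].
#' @param order Selected polynomial order.
#' @param age_center Age centering constant (shared across the family of
#'   fits).
#' @param tract,metric Optional labels.
#' @return List of class `effect_test` with `p_group`, `p_interaction`,
#'   LRT statistics and degrees of freedom, `group_direction` (sign of the
#'   group coefficient in the no-interaction model), `selected_order`, and
#'   the three fits.
#' @export
test_effects <- function(data, order, age_center = NULL,
                         tract = NA_character_, metric = NA_character_) {
  age_center <- age_center %||% mean(data$age)
  full <- fit_mixed(data, order, include_group = TRUE,
                    include_interaction = TRUE, age_center = age_center,
                    tract = tract, metric = metric)
  noint <- fit_mixed(data, order, include_group = TRUE,
                     include_interaction = FALSE, age_center = age_center,
                     tract = tract, metric = metric)
  nogrp <- fit_mixed(data, order, include_group = FALSE,
                     include_interaction = FALSE, age_center = age_center,
                     tract = tract, metric = metric)

  lrt <- function(big, small, df) {
    if (!big$converged || !small$converged)
      return(list(stat = NA_real_, p = NA_real_))
    # perfect fits on both sides (noise-free data): the likelihoods are
    # numerically meaningless (RSS at rounding level) and carry no evidence
    if ((big$perfect %||% FALSE) && (small$perfect %||% FALSE))
      return(list(stat = 0, p = 1))
    if (is.infinite(big$logLik) && is.infinite(small$logLik))
      return(list(stat = 0, p = 1))
    stat <- 2 * (big$logLik - small$logLik)
    if (stat < -1e-6)
      warning("nested model exceeded full-model likelihood (",
              tract, " ", metric, "); statistic clamped to 0",
              call. = FALSE)
    stat <- max(stat, 0)
    p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
    list(stat = stat, p = p)
  }

  df_int <- if (order == 0L || !full$include_interaction) 0L
            else as.integer(order)
  t_int <- lrt(full, noint, df_int)
  t_grp <- lrt(noint, nogrp, 1L)

  gcoef <- noint$coefficients["groupdeletion"]
  structure(list(
    tract = tract, metric = metric,
    selected_order = as.integer(order),
    p_group = t_grp$p, p_interaction = t_int$p,
    stat_group = t_grp$stat, stat_interaction = t_int$stat,
    df_group = 1L, df_interaction = df_int,
    group_coefficient = unname(gcoef),
    group_direction = if (is.na(gcoef)) NA_real_ else sign(unname(gcoef)),
    fits = list(full = full, no_interaction = noint, no_group = nogrp)
  ), class = "effect_test")
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up q-values: `q_i = min over {j : p_j >= p_i} of m * p_j / rank_j`,
#' clipped at 1, with m the number of non-missing p-values.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Vector of q-values, same length and order as `p`.
#' @export
fdr_adjust <- function(p) {
  if (!is.numeric(p)) stop_validation("p-values must be numeric")
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad))
    stop_validation("p-values outside [0, 1] at position(s): ",
                    paste(which(bad), collapse = ", "))
  stats::p.adjust(p, method = "BH", n = sum(!is.na(p)))
}

#' Trajectory analysis across all tracts and metrics
#'
#' For every (tract, metric) present in the table: fits the full model
#' (group, interactions, covariates) at orders 0-2, selects the order by
#' BIC, runs the group and interaction likelihood-ratio tests at the
#' selected order, and FDR-adjusts the two p-value families separately
#' across all measures.
#'
#' @param table Long-format metric table (see [read_long_table()] for the
#'   schema).
#' @param tracts,metrics Measures expected in the table; combinations
#'   absent from the table are reported with a warning and skipped.
#' @param alpha Significance level recorded in the result attributes.
#' @return Data.frame of class `trajectory_results`, one row per measure,
#'   sorted by metric then tract: selected order, coefficient estimates of
#'   the no-interaction model, `p_group`, `p_interaction`, `q_group`,
#'   `q_interaction`, `group_direction`. Attributes record `age_center`,
#'   `alpha` and the FDR family definition.
#' @export
run_trajectory_analysis <- function(table, tracts = NULL, metrics = NULL,
                                    alpha = 0.05) {
  table <- validate_long_table(table)
  tracts <- tracts %||% intersect(tract_names(), unique(table$tract))
  metrics <- metrics %||% intersect(metric_names(), unique(table$metric))
  scans <- !duplicated(table[, c("subject_id", "visit_index")])
  age_center <- mean(table$age[scans])

  combos <- expand.grid(metric = metrics, tract = tracts,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  have <- unique(paste(table$tract, table$metric, sep = "_"))
  want <- paste(combos$tract, combos$metric, sep = "_")
  missing_keys <- setdiff(want, have)
  if (length(missing_keys)) {
    warning("missing (tract, metric) combinations skipped: ",
            paste(missing_keys, collapse = ", "), call. = FALSE)
    combos <- combos[!(want %in% missing_keys), ]
  }

  rows <- lapply(seq_len(nrow(combos)), function(i) {
    tr <- combos$tract[i]; me <- combos$metric[i]
    d <- table[table$tract == tr & table$metric == me, ]
    fits <- lapply(0:2, function(k)
      fit_mixed(d, k, include_group = TRUE, include_interaction = TRUE,
                age_center = age_center, tract = tr, metric = me))
    sel <- select_order(fits)
    tst <- test_effects(d, sel$order, age_center = age_center,
                        tract = tr, metric = me)
    co <- tst$fits$no_interaction$coefficients
    data.frame(
      tract = tr, metric = me, selected_order = sel$order,
      intercept = unname(co["(Intercept)"]),
      age = unname(co["age_c"])[1] %||% NA_real_,
      age2 = unname(co["I(age_c^2)"])[1] %||% NA_real_,
      group = unname(co["groupdeletion"])[1] %||% NA_real_,
      sex = unname(co["sexF"])[1] %||% NA_real_,
      scanner = unname(co["scannerB"])[1] %||% NA_real_,
      p_group = tst$p_group, p_interaction = tst$p_interaction,
      group_direction = tst$group_direction,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  res$q_group <- fdr_adjust(res$p_group)
  res$q_interaction <- fdr_adjust(res$p_interaction)
  res <- res[order(match(res$metric, metric_names()),
                   match(res$tract, tract_names())), ]
  rownames(res) <- NULL
  attr(res, "age_center") <- age_center
  attr(res, "alpha") <- alpha
  attr(res, "fdr_families") <-
    "group and interaction p-values adjusted separately across all measures"
  class(res) <- c("trajectory_results", "data.frame")
  res
}
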