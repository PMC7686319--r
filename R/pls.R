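#' Column-wise z-scoring
#'
#' Standardizes each column to mean 0 and sample SD 1 (n-1 denominator).
#' Dichotomous 0/1 columns are standardized exactly like continuous ones.
#'
#' @param M Numeric matrix or data.frame of numeric columns.
#' @return Matrix of the same shape.
#' @export
zscore_columns <- function(M) {
  M <- as.matrix(M)
  if (!is.numeric(M)) stop_validation("matrix must be numeric")
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0 | is.na(sds))) {
    bad <- colnames(M)[sds == 0 | is.na(sds)] %||%
      which(sds == 0 | is.na(sds))
    stop_validation("constant column(s) cannot be z-scored: ",
                    paste(bad, collapse = ", "))
  }
  scale(M, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Cross-correlation matrix between behavior and brain blocks
#'
#' `R = t(Yz) %*% Xz / (n - 1)`: with column-standardized inputs each entry
#' is the Pearson correlation of one risk factor with one white-matter
#' measure across subjects (5 x 72 under the defaults).
#'
#' @param Xz,Yz Column-standardized matrices with matching row counts
#'   (subjects); rows must be aligned.
#' @return `ncol(Yz)` x `ncol(Xz)` correlation matrix.
#' @export
cross_correlation <- function(Xz, Yz) {
  if (nrow(Xz) != nrow(Yz))
    stop_validation("X and Y must have the same number of rows")
  if (nrow(Xz) < 3L) stop_validation("need at least 3 subjects")
  crossprod(Yz, Xz) / (nrow(Xz) - 1)
}

# Sign convention: flip each component so its largest-magnitude behavior
# salience is positive. Applied once to the reference decomposition;
# bootstrap replicates are instead aligned to the reference.
apply_sign_convention <- function(U, V) {
  for (k in seq_len(ncol(U))) {
    j <- which.max(abs(U[, k]))
    if (U[j, k] < 0) {
      U[, k] <- -U[, k]
      V[k, ] <- -V[k, ]
    }
  }
  list(U = U, V = V)
}

#' Singular value decomposition of the cross-correlation matrix
#'
#' Decomposes `R = U S V` into correlation components: `U`
#' (behaviors x components) holds the behavior saliences in its columns,
#' `V` (components x brain measures) the brain saliences in its rows, and
#' the singular values on the diagonal of `S` measure the correlation
#' explained by each component. With a 5 x 72 matrix exactly five
#' components are extracted. Components are sign-fixed so the
#' largest-magnitude behavior salience of each is positive.
#'
#' @param R Cross-correlation matrix from [cross_correlation()].
#' @return List of class `pls_components`: `d` (singular values,
#'   descending), `U`, `V`, `explained` (`d^2 / sum(d^2)`), `n_components`.
#' @export
svd_components <- function(R) {
  R <- as.matrix(R)
  if (any(!is.finite(R))) stop_validation("R contains non-finite entries")
  s <- svd(R)
  U <- s$u                 # behaviors x components
  V <- t(s$v)              # components x brain measures
  fx <- apply_sign_convention(U, V)
  rownames(fx$U) <- rownames(R)
  colnames(fx$V) <- colnames(R)
  structure(list(d = s$d, U = fx$U, V = fx$V,
                 explained = s$d^2 / sum(s$d^2),
                 n_components = length(s$d)),
            class = "pls_components")
}

#' @export
print.pls_components <- function(x, ...) {
  cat("pls_components:", x$n_components, "components\n")
  print(data.frame(singular_value = signif(x$d, 4),
                   explained_correlation = signif(x$explained, 4)))
  invisible(x)
}

#' Permutation test of the singular values
#'
#' Re-derives the singular-value spectrum under the null of no
#' brain-behavior association by permuting the rows of `Yz` (breaking the
#' subject alignment while preserving both blocks' internal structure).
#' The k-th largest permuted singular value is compared with the k-th
#' observed one (rank matching, no Procrustes rotation), and
#' `p_k = (1 + #permutations with s*_k >= s_k) / (1 + n_perm)`.
#'
#' @param Xz,Yz Column-standardized matrices, rows aligned.
#' @param n_perm Number of permutations (>= 100).
#' @param seed RNG seed for reproducibility.
#' @return List of class `pls_permutation`: `p` (per component),
#'   `observed` singular values, `perm_d` (n_perm x components matrix),
#'   `n_perm`, `seed`.
#' @export
permutation_test <- function(Xz, Yz, n_perm = 1000, seed = NULL) {
  if (n_perm < 100) stop_config("n_perm must be at least 100")
  n <- nrow(Xz)
  if (n <= 3L) stop_validation("too few subjects to permute")
  if (!is.null(seed)) set.seed(as.integer(seed))
  obs <- svd(cross_correlation(Xz, Yz), nu = 0, nv = 0)$d
  perm_d <- matrix(NA_real_, nrow = n_perm, ncol = length(obs))
  for (b in seq_len(n_perm)) {
    Yp <- Yz[sample.int(n), , drop = FALSE]
    perm_d[b, ] <- svd(cross_correlation(Xz, Yp), nu = 0, nv = 0)$d
  }
  exceed <- colSums(sweep(perm_d, 2, obs, `>=`))
  structure(list(p = (1 + exceed) / (1 + n_perm), observed = obs,
                 perm_d = perm_d, n_perm = n_perm, seed = seed),
            class = "pls_permutation")
}

#' Bootstrap stability of the saliences
#'
#' Resamples subjects with replacement, re-standardizes both blocks,
#' recomputes the cross-correlation SVD, and sign-aligns every bootstrap
#' component to the reference decomposition (flipped when the combined dot
#' product of its behavior and brain saliences with the reference is
#' negative; rank matching, no Procrustes rotation). Resamples in which a
#' risk-factor column is constant cannot be standardized and are redrawn
#' (counted in `n_redrawn`).
#'
#' The bootstrap score (bootstrap ratio) of each original weight is the
#' mean of its aligned bootstrap distribution divided by its SD;
#' `|score| > 1.96` flags a weight as robust at the 95% level.
#'
#' @param Xz,Yz Column-standardized matrices, rows aligned.
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed RNG seed.
#' @param reference A [svd_components()] result on the full sample.
#' @return List of class `pls_bootstrap` with per-component data.frames
#'   `behavior` (weight, boot_mean, boot_sd, boot_score, stable) and
#'   `brain`, plus `n_boot`, `n_redrawn`, `seed`.
#' @export
bootstrap_weights <- function(Xz, Yz, n_boot = 500, seed = NULL,
                              reference = NULL) {
  if (n_boot < 100) stop_config("n_boot must be at least 100")
  n <- nrow(Xz)
  if (n < 4L)
    stop_validation("too few subjects to bootstrap")
  if (is.null(reference))
    reference <- svd_components(cross_correlation(Xz, Yz))
  if (!is.null(seed)) set.seed(as.integer(seed))
  K <- reference$n_components
  u_acc <- array(NA_real_, c(n_boot, nrow(reference$U), K))
  v_acc <- array(NA_real_, c(n_boot, K, ncol(reference$V)))
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      Xb <- Xz[idx, , drop = FALSE]
      Yb <- Yz[idx, , drop = FALSE]
      if (all(apply(Yb, 2, stats::sd) > 0) &&
          all(apply(Xb, 2, stats::sd) > 0)) break
      n_redrawn <- n_redrawn + 1L
    }
    s <- svd(cross_correlation(zscore_columns(Xb), zscore_columns(Yb)))
    Ub <- s$u
    Vb <- t(s$v)
    for (k in seq_len(K)) {
      flip <- sum(Ub[, k] * reference$U[, k]) +
        sum(Vb[k, ] * reference$V[k, ])
      if (flip < 0) {
        Ub[, k] <- -Ub[, k]
        Vb[k, ] <- -Vb[k, ]
      }
    }
    u_acc[b, , ] <- Ub
    v_acc[b, , ] <- Vb
  }
  if (n_redrawn > 0)
    message("bootstrap: redrew ", n_redrawn,
            " resample(s) with a constant column")
  summarize <- function(draws, ref_w, names_w) {
    m <- apply(draws, 2, mean)
    s <- apply(draws, 2, stats::sd)
    data.frame(name = names_w, weight = ref_w, boot_mean = m, boot_sd = s,
               boot_score = m / s, stable = abs(m / s) > 1.96,
               stringsAsFactors = FALSE, row.names = NULL)
  }
  behavior <- lapply(seq_len(K), function(k)
    summarize(u_acc[, , k], reference$U[, k],
              rownames(reference$U) %||% paste0("y", seq_len(nrow(reference$U)))))
  brain <- lapply(seq_len(K), function(k)
    summarize(v_acc[, k, ], reference$V[k, ],
              colnames(reference$V) %||% paste0("x", seq_len(ncol(reference$V)))))
  structure(list(behavior = behavior, brain = brain, n_boot = n_boot,
                 n_redrawn = n_redrawn, seed = seed),
            class = "pls_bootstrap")
}

#' Per-subject latent brain and behavior scores
#'
#' Projects each subject onto the saliences: brain scores
#' `L_X = Xz %*% t(V)` and behavior scores `L_Y = Yz %*% U`, plus the
#' Pearson correlation `r_k` between the paired score columns — the
#' strength of the correlation captured by each component. A high brain
#' (behavior) score means the subject expresses the component's brain
#' (behavior) pattern strongly.
#'
#' @param Xz,Yz Column-standardized matrices, rows aligned.
#' @param components A [svd_components()] result on the same matrices.
#' @return List of class `pls_scores`: `L_X` (subjects x components),
#'   `L_Y`, `r` (per-component Pearson correlations).
#' @export
latent_scores <- function(Xz, Yz, components) {
  if (!inherits(components, "pls_components"))
    stop_validation("components must come from svd_components()")
  if (ncol(Xz) != ncol(components$V) || ncol(Yz) != nrow(components$U))
    stop_validation("matrix dimensions do not match the components")
  L_X <- Xz %*% t(components$V)
  L_Y <- Yz %*% components$U
  colnames(L_X) <- colnames(L_Y) <- paste0("LC", seq_len(ncol(L_X)))
  r <- vapply(seq_len(ncol(L_X)), function(k) {
    if (stats::sd(L_X[, k]) == 0 || stats::sd(L_Y[, k]) == 0) NA_real_
    else stats::cor(L_X[, k], L_Y[, k])
  }, numeric(1))
  structure(list(L_X = L_X, L_Y = L_Y, r = r), class = "pls_scores")
}

#' PLS correlation between brain deviations and risk factors
#'
#' End-to-end PLS correlation analysis: z-scores both blocks, computes the
#' cross-correlation matrix, extracts the correlation components by SVD,
#' assesses component significance by permutation, salience stability by
#' bootstrap, and per-subject latent scores. Permutation and bootstrap use
#' independent seeded RNG substreams derived from `seed`.
#'
#' @param X Brain matrix (subjects x measures), e.g. from
#'   [subject_deviation_scores()].
#' @param Y Behavior matrix of 0/1 risk factors (subjects x 5), rows
#'   aligned with `X`; see [behavior_matrix()].
#' @param n_perm,n_boot Permutation and bootstrap sample counts.
#' @param seed Master seed.
#' @return List of class `pls_result`: `components`, `permutation`,
#'   `bootstrap`, `scores`, `R`, `n_subjects`, `seed`, `n_perm`, `n_boot`.
#' @export
pls_correlation <- function(X, Y, n_perm = 1000, n_boot = 500, seed = 1L) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y))
    stop_validation("X and Y must have the same subjects (rows)")
  if (!is.null(rownames(X)) && !is.null(rownames(Y)) &&
      !identical(rownames(X), rownames(Y)))
    stop_validation("X and Y row names disagree; align subjects first")
  Xz <- zscore_columns(X)
  Yz <- zscore_columns(Y)
  R <- cross_correlation(Xz, Yz)
  comps <- svd_components(R)
  seed <- as.integer(seed)
  perm <- permutation_test(Xz, Yz, n_perm = n_perm, seed = seed)
  boot <- bootstrap_weights(Xz, Yz, n_boot = n_boot,
                            seed = seed + 1000003L, reference = comps)
  scores <- latent_scores(Xz, Yz, comps)
  structure(list(components = comps, permutation = perm, bootstrap = boot,
                 scores = scores, R = R, n_subjects = nrow(X),
                 seed = seed, n_perm = n_perm, n_boot = n_boot),
            class = "pls_result")
}

#' @export
print.pls_result <- function(x, ...) {
  cat("PLS correlation:", x$n_subjects, "subjects,",
      ncol(x$R), "brain measures,", nrow(x$R), "risk factors\n")
  df <- data.frame(
    component = seq_along(x$components$d),
    singular_value = signif(x$components$d, 4),
    explained_correlation = signif(x$components$explained, 4),
    perm_p = signif(x$permutation$p, 4),
    latent_r = signif(x$scores$r, 4))
  print(df, row.names = FALSE)
  b1 <- x$bootstrap$behavior[[1]]
  cat("component 1 behavior weights (bootstrap score):\n")
  for (i in seq_len(nrow(b1)))
    cat(sprintf("  %-18s %+.3f (%.2f)%s\n", b1$name[i], b1$weight[i],
                b1$boot_score[i], if (b1$stable[i]) " *" else ""))
  invisible(x)
}

#' Behavior matrix from a risk-factor table
#'
#' Arranges the five 0/1 risk factors into the fixed column order of the
#' behavior block (`uhr`, `preterm`, `low_baseline_iq`,
#' `cognitive_decline`, `baseline_anxiety`), rows sorted by subject id.
#'
#' @param risk Risk-factor table (see [read_risk_table()]).
#' @param subjects Optional subject ids to keep, in the row order of the
#'   brain matrix.
#' @return Integer matrix subjects x 5 with subject ids as row names.
#' @export
behavior_matrix <- function(risk, subjects = NULL) {
  risk <- validate_risk_table(risk)
  subjects <- subjects %||% sort(risk$subject_id)
  idx <- match(subjects, risk$subject_id)
  if (anyNA(idx))
    stop_validation("risk factors missing for subject(s): ",
                    paste(subjects[is.na(idx)], collapse = ", "))
  Y <- as.matrix(risk[idx, risk_factor_names()])
  rownames(Y) <- subjects
  Y
}
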