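# Shared cohort constructors for the test suite. All fixtures are built in
# code at test time; nothing is read from disk.

# Noise-free configuration: deterministic values equal to the planted
# polynomial plus any requested offsets.
noise_free_config <- function(tracts = c("FMAJ", "FMIN"),
                              metrics = c("FA", "MD"),
                              n_per_group = 10, group_offset = 0,
                              sex_effect = 0, scanner_effect = 0,
                              seed = 42, ...) {
  simulation_config(
    n_per_group = n_per_group, tracts = tracts, metrics = metrics,
    group_offset = group_offset, sex_effect = sex_effect,
    scanner_effect = scanner_effect,
    random_intercept_sd = 0, residual_sd = 0, latent_effect = 0,
    seed = seed, ...)
}

# Single-measure configuration with explicit per-order generating
# coefficients (an MD-like curve: plateau in the late 20s when quadratic).
one_measure_config <- function(order, n_per_group = 100, group_offset = 0,
                               seed = 1, ...) {
  spec <- default_trajectory_spec(tracts = "FMAJ", metrics = "MD")
  spec$order <- as.integer(order)
  spec$b1 <- c(0, -1.45e-2, -1.45e-2)[order + 1]
  spec$b2 <- c(0, 0, 2.7e-4)[order + 1]
  spec$group_offset <- group_offset
  simulation_config(n_per_group = n_per_group, tracts = "FMAJ",
                    metrics = "MD", trajectory_spec = spec,
                    latent_effect = 0, seed = seed, ...)
}

# Subject-level deviation cohort pivoted to aligned X and Y blocks, for
# PLS calibration and recovery studies.
deviation_blocks <- function(n_subjects, latent_effect = 0, seed = 1, ...) {
  co <- generate_cohort(deviation_config(n_subjects, latent_effect,
                                         seed = seed, ...))
  X <- subject_measure_matrix(co$metrics)
  Y <- behavior_matrix(co$risk, subjects = rownames(X))
  list(X = X, Y = Y, truth = co$truth)
}

# Expected generating value of the mean curve for a trajectory_spec row.
planted_value <- function(spec_row, age, deletion = FALSE) {
  spec_row$b0 + spec_row$b1 * age + spec_row$b2 * age^2 +
    spec_row$group_offset * deletion
}
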