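#' Canonical tract and metric vocabularies
#'
#' The 18 white-matter tracts are the forceps major and minor of the corpus
#' callosum plus eight bilateral bundles (anterior thalamic radiation,
#' corticospinal tract, parietal and temporal superior longitudinal
#' fasciculus, inferior longitudinal fasciculus, cingulate and angular
#' cingulum bundles, uncinate fasciculus), lateralized with `lh.`/`rh.`
#' prefixes. The four diffusion metrics are fractional anisotropy (FA) and
#' axial, radial and mean diffusivity (AD, RD, MD).
#'
#' @return Character vector of tract or metric labels, in canonical order.
#' @export
#' @examples
#' tract_names()
#' metric_names()
tract_names <- function() {
  bilateral <- c("ATR", "CST", "SLFP", "SLFT", "ILF", "CCG", "CAB", "UNC")
  c("FMAJ", "FMIN",
    paste0("lh.", bilateral),
    paste0("rh.", bilateral))
}

#' @rdname tract_names
#' @export
metric_names <- function() {
  c("FA", "AD", "RD", "MD")
}

#' Fixed column order of the risk-factor (behavior) matrix
#'
#' Ultra-high-risk status first, then preterm birth, low baseline full-scale
#' IQ (cut-off 75), cognitive decline (negative FSIQ change between first and
#' last assessment), and anxiety disorder at baseline.
#'
#' @return Character vector of the five risk-factor column names.
#' @export
risk_factor_names <- function() {
  c("uhr", "preterm", "low_baseline_iq", "cognitive_decline",
    "baseline_anxiety")
}

# Canonical (tract, metric) column keys of the brain matrix: tracts outer,
# metrics inner, both in vocabulary order. 72 keys under the defaults.
measure_keys <- function(tracts = tract_names(), metrics = metric_names()) {
  as.vector(t(outer(tracts, metrics, paste, sep = "_")))
}

# Split "tract_metric" keys back into their parts (metric is the suffix
# after the last underscore; tract labels contain dots, never underscores).
split_measure_keys <- function(keys) {
  metric <- sub("^.*_", "", keys)
  tract <- sub("_[^_]*$", "", keys)
  data.frame(key = keys, tract = tract, metric = metric,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(class = c("tractpls_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_validation <- function(...) {
  stop(structure(class = c("tractpls_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
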