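long_table_columns <- c("subject_id", "group", "sex", "scanner",
                        "visit_index", "age", "tract", "metric", "value")

#' Validate a long-format metric table
#'
#' Checks the schema of the per-scan tract-metric table: required columns,
#' closed tract/metric/group/sex/scanner vocabularies, numeric age and
#' value without missing entries, no duplicate
#' (subject, visit, tract, metric) keys, consistent age per
#' (subject, visit), and ages strictly increasing with visit index within
#' subject. Error messages list the offending rows.
#'
#' @param table Data.frame to validate.
#' @return The validated table (character columns normalized).
#' @export
validate_long_table <- function(table) {
  miss <- setdiff(long_table_columns, names(table))
  if (length(miss))
    stop_validation("missing required column(s): ", paste(miss, collapse = ", "))
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  for (v in c("subject_id", "group", "sex", "scanner", "tract", "metric"))
    table[[v]] <- as.character(table[[v]])
  table$visit_index <- as.integer(table$visit_index)
  table$age <- as.numeric(table$age)
  table$value <- as.numeric(table$value)

  check_levels <- function(col, allowed) {
    bad <- which(!(table[[col]] %in% allowed))
    if (length(bad))
      stop_validation("invalid ", col, " value(s) '",
                      paste(unique(table[[col]][bad]), collapse = "', '"),
                      "' in row(s): ",
                      paste(utils::head(bad, 10), collapse = ", "))
  }
  check_levels("group", factor_levels$group)
  check_levels("sex", factor_levels$sex)
  check_levels("scanner", factor_levels$scanner)
  check_levels("tract", tract_names())
  check_levels("metric", metric_names())

  na_rows <- which(is.na(table$age) | is.na(table$value) |
                     is.na(table$visit_index))
  if (length(na_rows))
    stop_validation("missing age/value/visit_index in row(s): ",
                    paste(utils::head(na_rows, 10), collapse = ", "))

  key <- paste(table$subject_id, table$visit_index, table$tract,
               table$metric, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop_validation("duplicate (subject, visit, tract, metric) key(s) in ",
                    "row(s): ", paste(utils::head(dup, 10), collapse = ", "))

  sv <- paste(table$subject_id, table$visit_index, sep = "\r")
  age_span <- tapply(table$age, sv, function(a) diff(range(a)))
  if (any(age_span > 1e-9))
    stop_validation("inconsistent age within (subject, visit): ",
                    paste(utils::head(names(age_span)[age_span > 1e-9], 5),
                          collapse = ", "))
  scans <- table[!duplicated(sv), c("subject_id", "visit_index", "age")]
  scans <- scans[order(scans$subject_id, scans$visit_index), ]
  bad_subj <- unique(unlist(lapply(
    split(scans, scans$subject_id),
    function(s) if (is.unsorted(s$age, strictly = TRUE)) s$subject_id[1])))
  if (length(bad_subj))
    stop_validation("ages not strictly increasing with visit_index for ",
                    "subject(s): ", paste(bad_subj, collapse = ", "))
  table
}

#' Validate a risk-factor table
#'
#' One row per subject; the five risk factors must be 0/1 with no missing
#' entries.
#'
#' @param risk Data.frame to validate.
#' @return The validated table.
#' @export
validate_risk_table <- function(risk) {
  needed <- c("subject_id", risk_factor_names())
  miss <- setdiff(needed, names(risk))
  if (length(miss))
    stop_validation("missing required column(s): ", paste(miss, collapse = ", "))
  risk <- as.data.frame(risk, stringsAsFactors = FALSE)
  risk$subject_id <- as.character(risk$subject_id)
  if (anyDuplicated(risk$subject_id))
    stop_validation("duplicate subject_id in risk-factor table")
  for (v in risk_factor_names()) {
    risk[[v]] <- as.integer(risk[[v]])
    if (anyNA(risk[[v]]) || !all(risk[[v]] %in% 0:1))
      stop_validation("risk factor '", v, "' must be 0/1 with no missing ",
                      "values")
  }
  risk
}

#' Read and write the long-format metric table
#'
#' Canonical serialization is TSV: tab-separated, header row, UTF-8, "."
#' decimal, no quoting, `NA` forbidden in required columns. Reading
#' validates the schema (see [validate_long_table()]).
#'
#' @param path File path.
#' @param table Table to write.
#' @return `read_long_table()` returns the validated data.frame;
#'   the writers return `path` invisibly.
#' @export
read_long_table <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_long_table(tab)
}

#' @rdname read_long_table
#' @export
write_long_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write the risk-factor table
#'
#' @inheritParams read_long_table
#' @param risk Risk-factor table to write.
#' @return `read_risk_table()` returns the validated data.frame.
#' @export
read_risk_table <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_risk_table(tab)
}

#' @rdname read_risk_table
#' @export
write_risk_table <- function(risk, path) {
  utils::write.table(risk, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

write_matrix_tsv <- function(M, path, rowname_col = "subject_id") {
  df <- data.frame(rownames(M), M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- rowname_col
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
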