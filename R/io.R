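# Dataset readers/writers and configuration files: the operational shell
# around the estimators and the simulation engine.

#' Read a time-to-event dataset from delimited text
#'
#' Reads a CSV (default) or TSV file with a header and validates it into a
#' [tte_data()]. Column roles are configurable; covariate columns default
#' to every remaining numeric column.
#'
#' @param path file path; `.tsv`/`.txt` extensions are read tab-delimited.
#' @param time_col,event_col,group_col column names for follow-up time,
#'   event indicator (0/1) and group (0/1).
#' @param covariate_cols covariate column names, or `NULL` for all other
#'   columns.
#' @return a [tte_data()].
#' @export
read_tte_data <- function(path, time_col = "time", event_col = "status",
                          group_col = "group", covariate_cols = NULL) {
  if (!file.exists(path)) {
    ah_error(sprintf("file not found: %s", path), "ahadjust_parse_error")
  }
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c(time_col, event_col, group_col)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    ah_error(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
             "ahadjust_parse_error")
  }
  if (is.null(covariate_cols)) {
    covariate_cols <- setdiff(names(df), need)
  } else {
    missing_cov <- setdiff(covariate_cols, names(df))
    if (length(missing_cov)) {
      ah_error(sprintf("missing covariate column(s): %s",
                       paste(missing_cov, collapse = ", ")),
               "ahadjust_parse_error")
    }
  }
  tryCatch(
    tte_data(df[[time_col]], df[[event_col]], df[[group_col]],
             if (length(covariate_cols)) df[covariate_cols] else NULL),
    ahadjust_input_error = function(e) {
      ah_error(sprintf("%s: %s", path, conditionMessage(e)), "ahadjust_parse_error")
    }
  )
}

#' Write a time-to-event dataset as delimited text
#'
#' @param ds a [tte_data()].
#' @param path output path; extension selects the delimiter as in
#'   [read_tte_data()].
#' @export
write_tte_data <- function(ds, path) {
  df <- cbind(data.frame(time = ds$time, status = ds$status, group = ds$group),
              ds$x)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an analysis or simulation configuration
#'
#' Parses a YAML (`.yml`/`.yaml`) or JSON configuration file. Recognized
#' keys mirror the function interfaces: `tau`, `method`/`methods`,
#' `outcome_terms`, `treatment_terms`, `censoring`, `censoring_terms`,
#' `bootstrap: {B, seed}`, and `simulation: {scenario, censoring, case, n,
#' reps}`.
#'
#' @param path configuration file path.
#' @return a named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    ah_error(sprintf("config file not found: %s", path), "ahadjust_parse_error")
  }
  if (grepl("\\.(json)$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Build a model_spec from a configuration list
#'
#' @param config list as returned by [read_config()].
#' @return a [model_spec()].
#' @export
config_model_spec <- function(config) {
  model_spec(outcome_terms = unlist(config$outcome_terms),
             treatment_terms = unlist(config$treatment_terms),
             censoring = if (is.null(config$censoring)) "pooled_km" else config$censoring,
             censoring_terms = unlist(config$censoring_terms))
}
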