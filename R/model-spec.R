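#' Working-model specification
#'
#' Term lists for the three nuisance models an adjusted analysis may need:
#' the outcome Cox model, the logistic propensity (treatment) model, and the
#' censoring-survival model used to build inverse probability of censoring
#' weights. Terms are covariate names with an optional `"^2"` suffix
#' denoting squaring (e.g. `"X5^2"`); no other transforms are supported.
#'
#' @param outcome_terms character vector of outcome-model terms (the
#'   treatment indicator is always included and need not be listed).
#' @param treatment_terms character vector of propensity-model terms (an
#'   intercept is always included).
#' @param censoring one of `"pooled_km"` (Kaplan-Meier of the censoring
#'   distribution on the pooled sample) or `"cox"` (Cox model for the
#'   censoring hazard on `censoring_terms`).
#' @param censoring_terms terms for the censoring Cox model; required when
#'   `censoring = "cox"`.
#' @return an object of class `"model_spec"`.
#' @export
#' @examples
#' model_spec(outcome_terms = c("X1", "X2", "X4", "X5^2"),
#'            treatment_terms = c("X2", "X3", "X5", "X6"))
model_spec <- function(outcome_terms = character(0),
                       treatment_terms = character(0),
                       censoring = c("pooled_km", "cox"),
                       censoring_terms = NULL) {
  censoring <- match.arg(censoring)
  check_terms <- function(terms, what) {
    bad <- !grepl("^[A-Za-z.][A-Za-z0-9._]*(\\^2)?$", terms)
    if (any(bad)) {
      ah_error(sprintf("invalid %s term(s): %s (only plain names and a '^2' suffix are supported)",
                       what, paste(terms[bad], collapse = ", ")),
               "ahadjust_input_error")
    }
  }
  check_terms(outcome_terms, "outcome")
  check_terms(treatment_terms, "treatment")
  if (censoring == "cox") {
    if (is.null(censoring_terms) || length(censoring_terms) == 0L) {
      ah_error("censoring = 'cox' requires censoring_terms", "ahadjust_input_error")
    }
    check_terms(censoring_terms, "censoring")
  }
  structure(list(outcome_terms = as.character(outcome_terms),
                 treatment_terms = as.character(treatment_terms),
                 censoring = censoring,
                 censoring_terms = censoring_terms),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  fmt <- function(v) if (length(v)) paste(v, collapse = " + ") else "(none)"
  cat("model_spec\n")
  cat("  outcome:   Z +", fmt(x$outcome_terms), "\n")
  cat("  treatment:", fmt(x$treatment_terms), "\n")
  cat("  censoring:", x$censoring,
      if (x$censoring == "cox") paste0("(", fmt(x$censoring_terms), ")") else "", "\n")
  invisible(x)
}
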