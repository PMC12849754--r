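#' Right-censored time-to-event dataset
#'
#' Container for the per-subject observable data \eqn{(Y_i, \Delta_i, Z_i,
#' X_i)}: follow-up time, event indicator, binary group, and a covariate
#' table. Optional nonnegative case weights default to 1.
#'
#' @param time positive follow-up times \eqn{Y_i}.
#' @param status event indicators \eqn{\Delta_i} (1 = event observed, 0 =
#'   censored).
#' @param group binary group indicators \eqn{Z_i \in \{0, 1\}} (1 is
#'   conventionally the treated group).
#' @param covariates data frame (or coercible) of numeric covariates, one
#'   row per subject; may be `NULL` for unadjusted analyses.
#' @param weights nonnegative case weights, default all 1.
#' @param validate set to `FALSE` to skip input checks (internal fast path
#'   used by the bootstrap).
#' @return an object of class `"tte_data"`: a list with elements `time`,
#'   `status`, `group`, `x` (data frame, possibly zero-column), `weights`
#'   and `n`.
#' @export
#' @examples
#' ds <- tte_data(c(0.2, 0.4, 0.5, 0.8), c(1, 0, 1, 1), c(0, 0, 1, 1))
#' ds$n
tte_data <- function(time, status, group, covariates = NULL, weights = NULL,
                     validate = TRUE) {
  n <- length(time)
  time <- as.numeric(time)
  status <- as.integer(status)
  group <- as.integer(group)
  if (is.null(weights)) weights <- rep(1, n)
  if (is.null(covariates)) {
    covariates <- as.data.frame(matrix(numeric(0), nrow = n, ncol = 0))
  } else {
    covariates <- as.data.frame(covariates)
  }
  if (validate) {
    if (n == 0L) ah_error("dataset is empty", "ahadjust_input_error")
    if (length(status) != n || length(group) != n || length(weights) != n ||
        nrow(covariates) != n) {
      ah_error("time, status, group, weights and covariates must have one entry per subject",
               "ahadjust_input_error")
    }
    if (anyNA(time) || any(time <= 0)) {
      ah_error(sprintf("follow-up times must be positive (offending rows: %s)",
                       paste(utils::head(which(is.na(time) | time <= 0), 5), collapse = ", ")),
               "ahadjust_input_error")
    }
    if (!all(status %in% c(0L, 1L))) {
      ah_error(sprintf("event indicator must be 0/1 (offending rows: %s)",
                       paste(utils::head(which(!status %in% c(0L, 1L)), 5), collapse = ", ")),
               "ahadjust_input_error")
    }
    if (!all(group %in% c(0L, 1L))) {
      ah_error(sprintf("group must be 0/1 (offending rows: %s)",
                       paste(utils::head(which(!group %in% c(0L, 1L)), 5), collapse = ", ")),
               "ahadjust_input_error")
    }
    if (anyNA(weights) || any(weights < 0)) {
      ah_error("case weights must be nonnegative", "ahadjust_input_error")
    }
  }
  structure(list(time = time, status = status, group = group,
                 x = covariates, weights = weights, n = n),
            class = "tte_data")
}

#' @export
print.tte_data <- function(x, ...) {
  cat(sprintf("tte_data: %d subjects (%d events, %d censored), groups 0/1 = %d/%d\n",
              x$n, sum(x$status), sum(1 - x$status),
              sum(x$group == 0L), sum(x$group == 1L)))
  if (ncol(x$x) > 0) {
    cat("covariates:", paste(names(x$x), collapse = ", "), "\n")
  }
  invisible(x)
}

# Row subset, skipping validation (used by the bootstrap and group splits).
ds_subset <- function(ds, idx) {
  tte_data(ds$time[idx], ds$status[idx], ds$group[idx],
           ds$x[idx, , drop = FALSE], ds$weights[idx], validate = FALSE)
}

# Split into group-0 / group-1 datasets; errors if either group is absent.
ds_split <- function(ds) {
  i0 <- ds$group == 0L
  if (!any(i0) || all(i0)) {
    ah_error("both groups must be present for a contrast", "ahadjust_input_error")
  }
  list(ds_subset(ds, which(i0)), ds_subset(ds, which(!i0)))
}
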