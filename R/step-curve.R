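#' Right-continuous step survival curve
#'
#' A survival function represented by its jump times and the survival value
#' attained at (and after) each jump: \eqn{S(t) = 1} for \eqn{t} before the
#' first jump, and \eqn{S(t)} equals the value at the largest jump time
#' \eqn{\le t} otherwise, extended as a constant beyond the last jump.
#'
#' @param time strictly increasing positive jump times.
#' @param surv survival values in \eqn{[0, 1]} aligned to `time`,
#'   non-increasing.
#' @param max_time largest follow-up time supporting the curve; evaluation
#'   beyond it carries the last value forward with a warning from [rmst()].
#'   Defaults to the last jump time (or `Inf` for a jump-free curve).
#' @return an object of class `"step_curve"`.
#' @export
#' @examples
#' s <- step_curve(c(0.2, 0.5), c(0.75, 0.375))
#' surv_at(s, c(0.1, 0.2, 0.7))
step_curve <- function(time, surv, max_time = NULL) {
  time <- as.numeric(time)
  surv <- as.numeric(surv)
  if (length(time) != length(surv)) {
    ah_error("jump times and survival values must align", "ahadjust_input_error")
  }
  if (length(time) > 0) {
    if (any(time <= 0) || is.unsorted(time, strictly = TRUE)) {
      ah_error("jump times must be strictly increasing and positive",
               "ahadjust_input_error")
    }
    if (any(surv < -1e-12) || any(surv > 1 + 1e-12) ||
        any(diff(surv) > 1e-12)) {
      ah_error("survival values must be non-increasing within [0, 1]",
               "ahadjust_input_error")
    }
    surv <- pmin(pmax(surv, 0), 1)
  }
  if (is.null(max_time)) max_time <- if (length(time)) time[length(time)] else Inf
  structure(list(time = time, surv = surv, max_time = max_time),
            class = "step_curve")
}

#' Evaluate a step survival curve
#'
#' `surv_at()` evaluates \eqn{S(t)} (right-continuous); `surv_left()`
#' evaluates the left limit \eqn{S(t^-)}, needed when censoring-survival
#' weights must not be deflated by a jump at the evaluation point itself.
#'
#' @param curve a [step_curve()].
#' @param t vector of nonnegative evaluation times.
#' @return numeric vector of survival probabilities.
#' @export
surv_at <- function(curve, t) {
  if (length(curve$time) == 0L) return(rep(1, length(t)))
  i <- findInterval(t, curve$time)
  ifelse(i == 0L, 1, curve$surv[pmax(i, 1L)])
}

#' @rdname surv_at
#' @export
surv_left <- function(curve, t) {
  if (length(curve$time) == 0L) return(rep(1, length(t)))
  i <- findInterval(t, curve$time, left.open = TRUE)
  ifelse(i == 0L, 1, curve$surv[pmax(i, 1L)])
}

#' @export
print.step_curve <- function(x, ...) {
  cat(sprintf("step_curve: %d jumps", length(x$time)))
  if (length(x$time)) {
    cat(sprintf(", S(%.4g) = %.4f", x$time[length(x$time)],
                x$surv[length(x$surv)]))
  }
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.step_curve <- function(x, ...) {
  data.frame(time = x$time, surv = x$surv)
}

#' Restricted mean survival time
#'
#' Exact area under the step curve over \eqn{[0, \tau]}, by rectangle
#' summation (no quadrature), so that the plug-in identity
#' \eqn{\eta(\tau)\,\mathrm{RMST}(\tau) = 1 - S(\tau)} holds to machine
#' precision. If \eqn{\tau} exceeds the largest follow-up time backing the
#' curve, the last survival value is carried forward and a warning is
#' emitted.
#'
#' @param curve a [step_curve()].
#' @param tau positive truncation time.
#' @return the RMST, a value in \eqn{(0, \tau]}.
#' @export
rmst <- function(curve, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0) {
    ah_error("tau must be a single positive number", "ahadjust_input_error")
  }
  if (tau > curve$max_time) {
    warning(sprintf("tau = %g exceeds the largest supporting time %g; carrying the last survival value forward",
                    tau, curve$max_time))
  }
  keep <- curve$time < tau
  knots <- c(0, curve$time[keep], tau)
  values <- c(1, curve$surv[keep])
  sum(diff(knots) * values)
}

#' Average hazard of a survival curve
#'
#' The average hazard over \eqn{[0, \tau]} is the cumulative incidence at
#' \eqn{\tau} divided by the RMST,
#' \eqn{\eta(\tau) = \{1 - S(\tau)\} / \int_0^\tau S(u)\,du},
#' in units of events per person-time.
#'
#' @inheritParams rmst
#' @return the average hazard \eqn{\eta(\tau) \ge 0}.
#' @export
#' @examples
#' s <- step_curve(c(0.2, 0.5), c(0.75, 0.375))
#' average_hazard(s, 0.7)
average_hazard <- function(curve, tau) {
  r <- rmst(curve, tau)
  if (r <= 0) ah_error("RMST is zero; average hazard undefined", "ahadjust_state_error")
  (1 - surv_at(curve, tau)) / r
}

#' Person-time incidence rate
#'
#' The classical person-time rate: observed events divided by total
#' observation time, \eqn{\sum_i \Delta_i / \sum_i Y_i}. Unlike the average
#' hazard, this quantity depends on the censoring distribution.
#'
#' @param ds a [tte_data()].
#' @return events per person-time.
#' @export
person_time_rate <- function(ds) {
  sum(ds$status) / sum(ds$time)
}

#' Average-hazard contrast between two groups
#'
#' Computes the per-group average hazards at `tau` together with their
#' difference (DAH \eqn{= \eta_1 - \eta_0}) and ratio (RAH
#' \eqn{= \eta_1 / \eta_0}). When \eqn{\eta_0 = 0} the ratio is undefined
#' and returned as `NA` while the difference is still reported.
#'
#' @param curve0,curve1 [step_curve()]s for group 0 and group 1.
#' @param tau positive truncation time.
#' @param method optional method label stored in the result.
#' @return an object of class `"ah_summary"` with elements `tau`, `eta0`,
#'   `eta1`, `dah`, `rah` and `method`.
#' @export
ah_contrast <- function(curve0, curve1, tau, method = NA_character_) {
  eta0 <- average_hazard(curve0, tau)
  eta1 <- average_hazard(curve1, tau)
  structure(list(tau = tau, eta0 = eta0, eta1 = eta1,
                 dah = eta1 - eta0,
                 rah = if (eta0 > 0) eta1 / eta0 else NA_real_,
                 method = method),
            class = "ah_summary")
}

#' @export
print.ah_summary <- function(x, digits = 4, ...) {
  cat(sprintf("Average hazard summary (tau = %g%s)\n", x$tau,
              if (is.na(x$method)) "" else paste0(", method = ", x$method)))
  fmt <- function(v) formatC(v, digits = digits, format = "f")
  line <- function(lab, est, lcl, ucl) {
    cat(sprintf("  %-6s %s", lab, fmt(est)))
    if (!is.null(lcl) && !is.na(lcl)) {
      cat(sprintf("  (95%% CI %s to %s)", fmt(lcl), fmt(ucl)))
    }
    cat("\n")
  }
  line("eta0", x$eta0, x$ci_eta0[1], x$ci_eta0[2])
  line("eta1", x$eta1, x$ci_eta1[1], x$ci_eta1[2])
  line("DAH", x$dah, x$ci_dah[1], x$ci_dah[2])
  line("RAH", x$rah, x$ci_rah[1], x$ci_rah[2])
  if (!is.null(x$n_boot_failed)) {
    cat(sprintf("  bootstrap: %d resamples, %d failed\n", x$B, x$n_boot_failed))
  }
  invisible(x)
}

#' Standardized average hazard across strata
#'
#' Standardizes the group-specific average hazard over a stratification
#' variable: with stratum proportions \eqn{\pi_x} and per-stratum per-group
#' Kaplan-Meier plug-ins \eqn{\hat F_{jx}(\tau)} and \eqn{\hat R_{jx}(\tau)}
#' (cumulative incidence and RMST), the standardized AH for group \eqn{j} is
#' \deqn{AH_j^*(\tau) = \sum_x \pi_x \hat F_{jx}(\tau) \Big/ \sum_x \pi_x \hat R_{jx}(\tau).}
#' This coincides with the marginal AH under no censoring, whereas a
#' \eqn{\pi}-weighted average of stratum-specific AHs generally does not
#' (the AH is not collapsible).
#'
#' @param ds a [tte_data()].
#' @param strata factor (or coercible) of stratum labels, one per subject.
#' @param tau positive truncation time.
#' @return list with per-group standardized AHs `eta0`, `eta1` and their
#'   contrast `dah`, `rah`.
#' @export
standardized_ah <- function(ds, strata, tau) {
  strata <- as.factor(strata)
  if (length(strata) != ds$n) {
    ah_error("strata must have one label per subject", "ahadjust_input_error")
  }
  pi_x <- as.vector(table(strata)) / ds$n
  lev <- levels(strata)
  F_num <- c(0, 0); R_den <- c(0, 0)
  for (k in seq_along(lev)) {
    for (j in 0:1) {
      idx <- which(strata == lev[k] & ds$group == j)
      if (length(idx) == 0L) {
        ah_error(sprintf("stratum '%s' has no subjects in group %d", lev[k], j),
                 "ahadjust_input_error")
      }
      cv <- km_curve(ds_subset(ds, idx))
      F_num[j + 1] <- F_num[j + 1] + pi_x[k] * (1 - surv_at(cv, tau))
      R_den[j + 1] <- R_den[j + 1] + pi_x[k] * rmst(cv, tau)
    }
  }
  eta <- F_num / R_den
  list(eta0 = eta[1], eta1 = eta[2], dah = eta[2] - eta[1],
       rah = if (eta[1] > 0) eta[2] / eta[1] else NA_real_)
}

#' Write a step curve as two-column delimited text
#'
#' @param curve a [step_curve()].
#' @param path output file path.
#' @export
write_step_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
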