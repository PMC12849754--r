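# Point estimation and bootstrap inference for the average-hazard
# estimands under any adjustment method.

#' Bootstrap configuration
#'
#' @param B number of resamples (default 300).
#' @param seed integer master seed; resample `b` draws its indices under a
#'   substream seed derived from `(seed, b)`, so increasing `B` does not
#'   reshuffle earlier resamples.
#' @param min_valid_fraction minimum fraction of resamples that must yield
#'   an estimate; below it, inference aborts with a typed error.
#' @param ci_level confidence level (only 0.95 is used by the simulation
#'   engine, but any level is accepted).
#' @param stratified resample within treatment groups instead of from the
#'   pooled cohort (default `FALSE`, matching a single-cohort sampling
#'   model).
#' @return a list of class `"bootstrap_config"`.
#' @export
bootstrap_config <- function(B = 300L, seed = 1L, min_valid_fraction = 0.8,
                             ci_level = 0.95, stratified = FALSE) {
  if (B < 2L) ah_error("bootstrap needs B >= 2", "ahadjust_input_error")
  structure(list(B = as.integer(B), seed = as.integer(seed),
                 min_valid_fraction = min_valid_fraction,
                 ci_level = ci_level, stratified = stratified),
            class = "bootstrap_config")
}

#' Point estimates of the average-hazard estimands
#'
#' Runs one adjustment method and computes \eqn{\eta_0(\tau)},
#' \eqn{\eta_1(\tau)}, DAH and RAH from the adjusted curve pair.
#'
#' @param ds a [tte_data()].
#' @param method adjustment method name, see [adjusted_curves()].
#' @param spec a [model_spec()] (ignored by `"km"`).
#' @param tau positive truncation time.
#' @return an `"ah_summary"` (no confidence intervals).
#' @export
point_estimates <- function(ds, method, spec = NULL, tau) {
  pair <- adjusted_curves(ds, method, spec)
  ah_contrast(pair$curve0, pair$curve1, tau, method = pair$method)
}

#' Bootstrap standard errors and confidence intervals
#'
#' Nonparametric bootstrap of subjects: each resample re-runs the complete
#' adjustment pipeline (model fitting, weight or match construction,
#' adjusted curves, estimands). Standard errors are the sample standard
#' deviations of the resample estimates, with RAH handled on the log
#' scale; confidence intervals are normal-approximation intervals around
#' the point estimate (symmetric for DAH, log-symmetric for RAH).
#' Resamples on which the pipeline fails (e.g. no events before `tau` in a
#' group, infeasible balancing weights, non-convergent fits) are skipped
#' and counted rather than redrawn.
#'
#' @inheritParams point_estimates
#' @param cfg a [bootstrap_config()].
#' @return an `"ah_summary"` augmented with standard errors (`se_eta0`,
#'   `se_eta1`, `se_dah`, `se_log_rah`), 95% CI bounds (`ci_eta0`, ...,
#'   `ci_rah`), the resample count `B` and `n_boot_failed`.
#' @export
#' @examples
#' set.seed(11)
#' ds <- make_dataset(150, scenario = 2, censoring = "A")
#' bootstrap_inference(ds, "km", tau = 0.7, cfg = bootstrap_config(B = 50, seed = 3))
bootstrap_inference <- function(ds, method, spec = NULL, tau,
                                cfg = bootstrap_config()) {
  pt <- point_estimates(ds, method, spec, tau)
  n <- ds$n
  i0 <- which(ds$group == 0L)
  i1 <- which(ds$group == 1L)
  eta0_b <- eta1_b <- rep(NA_real_, cfg$B)
  failures <- character(0)
  for (b in seq_len(cfg$B)) {
    set.seed(substream_seed(cfg$seed, b))
    idx <- if (cfg$stratified) {
      c(i0[sample.int(length(i0), replace = TRUE)],
        i1[sample.int(length(i1), replace = TRUE)])
    } else {
      sample.int(n, replace = TRUE)
    }
    est <- tryCatch(
      suppressWarnings(point_estimates(ds_subset(ds, idx), method, spec, tau)),
      error = function(e) e
    )
    if (inherits(est, "error")) {
      failures <- c(failures, conditionMessage(est))
    } else {
      eta0_b[b] <- est$eta0
      eta1_b[b] <- est$eta1
    }
  }
  valid <- !is.na(eta0_b)
  if (mean(valid) < cfg$min_valid_fraction) {
    ah_error(sprintf("only %d/%d bootstrap resamples succeeded; reasons: %s",
                     sum(valid), cfg$B,
                     paste(names(sort(table(failures), decreasing = TRUE)),
                           collapse = " | ")),
             "ahadjust_inference_error")
  }
  zq <- stats::qnorm(1 - (1 - cfg$ci_level) / 2)
  dah_b <- eta1_b - eta0_b
  lograh_b <- ifelse(valid & eta0_b > 0 & eta1_b > 0,
                     log(eta1_b) - log(eta0_b), NA_real_)
  pt$se_eta0 <- stats::sd(eta0_b[valid])
  pt$se_eta1 <- stats::sd(eta1_b[valid])
  pt$se_dah <- stats::sd(dah_b[valid])
  pt$se_log_rah <- stats::sd(lograh_b, na.rm = TRUE)
  ci <- function(est, se) c(est - zq * se, est + zq * se)
  pt$ci_eta0 <- ci(pt$eta0, pt$se_eta0)
  pt$ci_eta1 <- ci(pt$eta1, pt$se_eta1)
  pt$ci_dah <- ci(pt$dah, pt$se_dah)
  pt$ci_rah <- if (!is.na(pt$rah) && pt$rah > 0) {
    exp(ci(log(pt$rah), pt$se_log_rah))
  } else {
    c(NA_real_, NA_real_)
  }
  pt$B <- cfg$B
  pt$n_boot_failed <- sum(!valid)
  pt
}

#' Flatten an `ah_summary` to a one-row data frame
#'
#' Serializes estimates, standard errors and CI bounds as a flat record
#' (the shape of a results table row).
#'
#' @param x an `"ah_summary"`.
#' @param ... unused.
#' @return a one-row data frame.
#' @export
as.data.frame.ah_summary <- function(x, ...) {
  grab <- function(name, k) {
    v <- x[[name]]
    if (is.null(v)) NA_real_ else v[k]
  }
  data.frame(method = x$method, tau = x$tau,
             eta0 = x$eta0, se_eta0 = grab("se_eta0", 1),
             eta0_lcl = grab("ci_eta0", 1), eta0_ucl = grab("ci_eta0", 2),
             eta1 = x$eta1, se_eta1 = grab("se_eta1", 1),
             eta1_lcl = grab("ci_eta1", 1), eta1_ucl = grab("ci_eta1", 2),
             dah = x$dah, se_dah = grab("se_dah", 1),
             dah_lcl = grab("ci_dah", 1), dah_ucl = grab("ci_dah", 2),
             rah = x$rah, se_log_rah = grab("se_log_rah", 1),
             rah_lcl = grab("ci_rah", 1), rah_ucl = grab("ci_rah", 2),
             n_boot_failed = if (is.null(x$n_boot_failed)) NA_integer_ else x$n_boot_failed,
             stringsAsFactors = FALSE)
}

#' Estimate the average-hazard contrast by several methods
#'
#' Convenience wrapper producing one results row per requested method:
#' group average hazards, DAH and RAH, with bootstrap confidence intervals
#' when a [bootstrap_config()] is supplied.
#'
#' @param ds a [tte_data()].
#' @param methods character vector of method names, see [adjusted_curves()].
#' @param spec a [model_spec()].
#' @param tau positive truncation time.
#' @param boot a [bootstrap_config()], or `NULL` for point estimates only.
#' @return a data frame with one row per method.
#' @export
ah_estimate <- function(ds, methods = c("km", "ds", "iptw_km", "iptw_ch",
                                        "matching", "el", "aiptw"),
                        spec = NULL, tau, boot = bootstrap_config()) {
  rows <- lapply(methods, function(m) {
    est <- if (is.null(boot)) {
      point_estimates(ds, m, spec, tau)
    } else {
      bootstrap_inference(ds, m, spec, tau, boot)
    }
    as.data.frame(est)
  })
  do.call(rbind, rows)
}
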