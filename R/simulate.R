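# Simulation engine: data-generating processes, working-model cases,
# counterfactual truth oracle, and the performance-study grid.

#' Generate simulation covariates
#'
#' Six covariates mimicking a mixed case-mix: three Bernoulli
#' (`X1 ~ Bern(0.5)`, `X3 ~ Bern(0.5)`, `X2 ~ Bern(0.3 + 0.1 X3)`) and
#' three Gaussian-type (`X4, X6 ~ N(0,1)`, `X5 = 0.3 + 0.1 X6 + N(0,1)`).
#' `X2` is the key confounder: it drives both treatment assignment and the
#' event hazard. Uses the current R random number generator state.
#'
#' @param n number of subjects.
#' @return a data frame with columns `X1`..`X6`.
#' @export
gen_covariates <- function(n) {
  X1 <- stats::rbinom(n, 1, 0.5)
  X3 <- stats::rbinom(n, 1, 0.5)
  X2 <- stats::rbinom(n, 1, 0.3 + 0.1 * X3)
  X4 <- stats::rnorm(n)
  X6 <- stats::rnorm(n)
  X5 <- 0.3 + 0.1 * X6 + stats::rnorm(n)
  data.frame(X1 = X1, X2 = X2, X3 = X3, X4 = X4, X5 = X5, X6 = X6)
}

expit <- function(a) exp(a) / (1 + exp(a))

#' Generate treatment assignment
#'
#' Bernoulli draw with logit
#' \eqn{a = -1.2 + \log(3) X_2 + \log(1.5) X_3 + \log(1.5) X_5 + \log(2) X_6}.
#'
#' @param x covariate data frame from [gen_covariates()].
#' @return integer 0/1 vector.
#' @export
gen_treatment <- function(x) {
  a <- -1.2 + log(3) * x$X2 + log(1.5) * x$X3 + log(1.5) * x$X5 + log(2) * x$X6
  stats::rbinom(nrow(x), 1, expit(a))
}

# Event-time linear predictor shared by both scenarios.
event_lp <- function(x, z) {
  log(1.8) * x$X1 + log(1.8) * x$X2 + log(1.8) * x$X4 +
    log(2.3) * x$X5^2 - 1 * z
}

#' Generate event times
#'
#' Inverse-transform draw
#' \eqn{T = \{-\log U / e^{lp}\}^{p}} with
#' \eqn{lp = \log(1.8)(X_1 + X_2 + X_4) + \log(2.3) X_5^2 - Z} and
#' \eqn{p = 0.5} (Scenario 1, conditionally Weibull) or \eqn{p = 1}
#' (Scenario 2, conditionally exponential). Treatment (\eqn{Z = 1}) is
#' protective: it multiplies the conditional hazard by \eqn{e^{-1}}.
#'
#' @param x covariate data frame.
#' @param z treatment vector (or scalar, recycled).
#' @param scenario 1 or 2.
#' @return vector of positive event times.
#' @export
gen_event_time <- function(x, z, scenario) {
  if (!scenario %in% c(1, 2)) {
    ah_error("scenario must be 1 or 2", "ahadjust_input_error")
  }
  u <- stats::runif(nrow(x))
  base <- -log(u) / exp(event_lp(x, z))
  if (scenario == 1) sqrt(base) else base
}

#' Generate censoring times
#'
#' Exponential censoring capped by administrative end of follow-up at 1.0:
#' `C = min(C*, 1)` with `C* ~ Exp(rate)`, rate 0.1 (pattern `"A"`), 0.2
#' (`"B"`), or `0.01 + 0.4 X2` (`"C"`, covariate-dependent).
#'
#' @param x covariate data frame.
#' @param pattern `"A"`, `"B"` or `"C"`.
#' @return vector of censoring times in `(0, 1]`.
#' @export
gen_censoring <- function(x, pattern = c("A", "B", "C")) {
  pattern <- match.arg(pattern)
  rate <- switch(pattern,
                 A = rep(0.1, nrow(x)),
                 B = rep(0.2, nrow(x)),
                 C = 0.01 + 0.4 * x$X2)
  pmin(stats::rexp(nrow(x), rate), 1.0)
}

#' Generate a complete observational dataset
#'
#' Composes covariates, confounded treatment assignment, event times and
#' censoring into the observable data \eqn{(Y, \Delta, Z, X)} with
#' \eqn{Y = \min(T, C)} and \eqn{\Delta = I(T \le C)}.
#'
#' @param n sample size.
#' @param scenario event-time scenario, 1 or 2.
#' @param censoring censoring pattern, `"A"`, `"B"` or `"C"`.
#' @return a [tte_data()] carrying all six covariates.
#' @export
#' @examples
#' set.seed(5)
#' make_dataset(100, scenario = 1, censoring = "A")
make_dataset <- function(n, scenario = 1, censoring = "A") {
  x <- gen_covariates(n)
  z <- gen_treatment(x)
  t_ev <- gen_event_time(x, z, scenario)
  c_ev <- gen_censoring(x, censoring)
  tte_data(pmin(t_ev, c_ev), as.integer(t_ev <= c_ev), z, x)
}

#' Working-model specification for a misspecification case
#'
#' The five model-specification cases of the performance study:
#' * Case 1 — both models correct: outcome `X1, X2, X4, X5^2`; treatment
#'   `X2, X3, X5, X6`.
#' * Case 2 — both models overfit with extra (inactive) variables: outcome
#'   adds `X3, X6`; treatment adds `X1, X4`.
#' * Case 3 — outcome model drops the confounder `X2`; treatment correct.
#' * Case 4 — outcome correct; treatment model drops `X2`.
#' * Case 5 — both models drop `X2`.
#'
#' Censoring model: pooled Kaplan-Meier for patterns `"A"`/`"B"`
#' (independent censoring), Cox on `X2` for pattern `"C"`
#' (covariate-dependent censoring, correctly including its driver).
#'
#' @param case integer 1-5.
#' @param censoring censoring pattern the analysis is run under.
#' @return a [model_spec()].
#' @export
case_model_spec <- function(case, censoring = "A") {
  if (!case %in% 1:5) ah_error("case must be in 1..5", "ahadjust_input_error")
  outcome <- switch(case,
                    c("X1", "X2", "X4", "X5^2"),
                    c("X1", "X2", "X3", "X4", "X5^2", "X6"),
                    c("X1", "X4", "X5^2"),
                    c("X1", "X2", "X4", "X5^2"),
                    c("X1", "X4", "X5^2"))
  treatment <- switch(case,
                      c("X2", "X3", "X5", "X6"),
                      c("X1", "X2", "X3", "X4", "X5", "X6"),
                      c("X2", "X3", "X5", "X6"),
                      c("X3", "X5", "X6"),
                      c("X3", "X5", "X6"))
  if (censoring == "C") {
    model_spec(outcome, treatment, censoring = "cox", censoring_terms = "X2")
  } else {
    model_spec(outcome, treatment, censoring = "pooled_km")
  }
}

#' Counterfactual Monte Carlo truth oracle
#'
#' True values of \eqn{\eta_1(\tau)}, \eqn{\eta_0(\tau)}, DAH and RAH under
#' a scenario, derived numerically: per repetition, `M` covariate vectors
#' are drawn, counterfactual event times are generated under \eqn{Z = 1}
#' and \eqn{Z = 0} sharing the same covariates (independent uniforms per
#' arm), the two arms are pooled into one uncensored dataset, and the
#' plug-in Kaplan-Meier average hazard is computed per arm. Estimates are
#' averaged over `reps` repetitions; Monte Carlo standard errors of the
#' repetition means are reported.
#'
#' @param scenario 1 or 2.
#' @param tau truncation time (default 0.7).
#' @param M covariate draws per repetition (default 10000).
#' @param reps repetitions (default 100).
#' @return a list of class `"true_values"`: `eta0`, `eta1`, `dah`, `rah`,
#'   and their Monte Carlo standard errors `mcse`.
#' @export
#' @examples
#' set.seed(21)
#' true_values(2, M = 2000, reps = 5)
true_values <- function(scenario, tau = 0.7, M = 10000L, reps = 100L) {
  est <- matrix(NA_real_, reps, 4)
  for (r in seq_len(reps)) {
    x <- gen_covariates(M)
    t1 <- gen_event_time(x, 1, scenario)
    t0 <- gen_event_time(x, 0, scenario)
    pooled <- tte_data(c(t0, t1), rep(1L, 2 * M), rep(c(0L, 1L), each = M),
                       validate = FALSE)
    gs <- ds_split(pooled)
    e0 <- average_hazard(km_curve(gs[[1]]), tau)
    e1 <- average_hazard(km_curve(gs[[2]]), tau)
    est[r, ] <- c(e0, e1, e1 - e0, e1 / e0)
  }
  m <- colMeans(est)
  mcse <- apply(est, 2, stats::sd) / sqrt(reps)
  structure(list(scenario = scenario, tau = tau,
                 eta0 = m[1], eta1 = m[2], dah = m[3], rah = m[4],
                 mcse = stats::setNames(mcse, c("eta0", "eta1", "dah", "rah"))),
            class = "true_values")
}

#' @export
print.true_values <- function(x, digits = 3, ...) {
  cat(sprintf("True values (scenario %d, tau = %g):\n", x$scenario, x$tau))
  cat(sprintf("  eta1 = %.*f  eta0 = %.*f  DAH = %.*f  RAH = %.*f\n",
              digits, x$eta1, digits, x$eta0, digits, x$dah, digits, x$rah))
  cat(sprintf("  max MC SE = %.2g\n", max(x$mcse)))
  invisible(x)
}

#' Simulation cell configuration
#'
#' One cell of the performance-study grid: a (scenario, censoring pattern,
#' model-specification case) combination with its sample size, replicate
#' count, bootstrap size and method list.
#'
#' @param scenario 1 or 2.
#' @param censoring `"A"`, `"B"` or `"C"`.
#' @param case model-specification case, 1-5.
#' @param n per-replicate sample size (default 300).
#' @param reps number of replicates (default 2000).
#' @param B bootstrap resamples per replicate (default 300).
#' @param tau truncation time (default 0.7; must not exceed the
#'   administrative follow-up cap of 1.0).
#' @param methods methods to evaluate.
#' @param seed master seed for the cell.
#' @return a list of class `"scenario_config"`.
#' @export
scenario_config <- function(scenario = 1, censoring = "A", case = 1,
                            n = 300L, reps = 2000L, B = 300L, tau = 0.7,
                            methods = c("km", "ds", "iptw_km", "iptw_ch",
                                        "matching", "el", "aiptw"),
                            seed = 1L) {
  if (tau <= 0 || tau >= 1.0) {
    ah_error("tau must lie in (0, 1), inside the administrative follow-up cap",
             "ahadjust_input_error")
  }
  if (n < 2L || reps < 1L) {
    ah_error("n and reps must be positive", "ahadjust_input_error")
  }
  structure(list(scenario = scenario, censoring = censoring, case = case,
                 n = as.integer(n), reps = as.integer(reps), B = as.integer(B),
                 tau = tau, methods = methods, seed = as.integer(seed)),
            class = "scenario_config")
}

# Deterministic per-cell seed from the master seed and the cell labels, so
# cells can run in any order (or in parallel) without shared RNG state.
cell_seed <- function(cfg) {
  cens_idx <- match(cfg$censoring, c("A", "B", "C"))
  substream_seed(cfg$seed, cfg$scenario * 1000 + cens_idx * 100 + cfg$case)
}

#' Run one simulation cell
#'
#' Generates `cfg$reps` independent datasets, applies every requested
#' method (with bootstrap confidence intervals when `bootstrap = TRUE`),
#' and summarizes performance against the oracle truth: mean relative bias
#' \eqn{(\bar{\hat\theta} - \theta)/\theta}, root mean squared error,
#' coverage of the 95% CI, and median CI length, for each of the four
#' parameters. Replicates on which a method fails are excluded from that
#' method's metrics and counted; a method failing on more than 20% of
#' replicates is flagged.
#'
#' @param cfg a [scenario_config()].
#' @param truth a `"true_values"` object for the cell's scenario and `tau`;
#'   computed on the fly (under a cell-derived seed) when `NULL`.
#' @param bootstrap compute bootstrap CIs (set `FALSE` for bias/rMSE-only
#'   studies, which avoids the dominant cost).
#' @return a data frame of performance rows (one per method x parameter).
#' @export
run_cell <- function(cfg, truth = NULL, bootstrap = TRUE) {
  if (is.null(truth)) {
    set.seed(substream_seed(cell_seed(cfg), 0L))
    truth <- true_values(cfg$scenario, cfg$tau)
  }
  spec <- case_model_spec(cfg$case, cfg$censoring)
  cs <- cell_seed(cfg)
  params <- c("eta0", "eta1", "dah", "rah")
  res <- vector("list", length(cfg$methods))
  names(res) <- cfg$methods
  for (m in cfg$methods) {
    res[[m]] <- list(est = matrix(NA_real_, cfg$reps, 4),
                     lcl = matrix(NA_real_, cfg$reps, 4),
                     ucl = matrix(NA_real_, cfg$reps, 4))
  }
  for (r in seq_len(cfg$reps)) {
    set.seed(substream_seed(cs, 2L * r))
    ds <- make_dataset(cfg$n, cfg$scenario, cfg$censoring)
    for (m in cfg$methods) {
      est <- tryCatch(suppressWarnings(
        if (bootstrap) {
          bootstrap_inference(ds, m, spec, cfg$tau,
                              bootstrap_config(B = cfg$B,
                                               seed = substream_seed(cs, 2L * r + 1L)))
        } else {
          point_estimates(ds, m, spec, cfg$tau)
        }), error = function(e) NULL)
      if (is.null(est)) next
      res[[m]]$est[r, ] <- c(est$eta0, est$eta1, est$dah, est$rah)
      if (bootstrap) {
        res[[m]]$lcl[r, ] <- c(est$ci_eta0[1], est$ci_eta1[1],
                               est$ci_dah[1], est$ci_rah[1])
        res[[m]]$ucl[r, ] <- c(est$ci_eta0[2], est$ci_eta1[2],
                               est$ci_dah[2], est$ci_rah[2])
      }
    }
  }
  th <- c(truth$eta0, truth$eta1, truth$dah, truth$rah)
  out <- list()
  for (m in cfg$methods) {
    for (k in seq_along(params)) {
      est <- res[[m]]$est[, k]
      ok <- !is.na(est)
      n_failed <- sum(!ok)
      flagged <- n_failed > 0.2 * cfg$reps
      lcl <- res[[m]]$lcl[, k]; ucl <- res[[m]]$ucl[, k]
      cov_ok <- ok & !is.na(lcl) & !is.na(ucl)
      out[[length(out) + 1L]] <- data.frame(
        scenario = cfg$scenario, censoring = cfg$censoring, case = cfg$case,
        method = m, parameter = params[k],
        truth = th[k],
        rel_bias = mean((est[ok] - th[k]) / th[k]),
        rmse = sqrt(mean((est[ok] - th[k])^2)),
        coverage = if (bootstrap && any(cov_ok)) {
          mean(lcl[cov_ok] <= th[k] & th[k] <= ucl[cov_ok])
        } else NA_real_,
        median_ci_length = if (bootstrap && any(cov_ok)) {
          stats::median(ucl[cov_ok] - lcl[cov_ok])
        } else NA_real_,
        n_valid = sum(ok), n_failed = n_failed, flagged = flagged,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Run a grid of simulation cells
#'
#' Concatenates [run_cell()] results over a list of configurations. Each
#' cell derives its own RNG substream, so cell order does not affect
#' results.
#'
#' @param cfgs list of [scenario_config()]s.
#' @param truths optional named cache of `"true_values"` keyed by
#'   `"scenario<k>_tau<t>"`; computed per cell when absent.
#' @param bootstrap passed to [run_cell()].
#' @param verbose print per-cell progress.
#' @return row-bound performance data frame.
#' @export
run_grid <- function(cfgs, truths = NULL, bootstrap = TRUE, verbose = FALSE) {
  if (length(cfgs) == 0L) {
    return(data.frame())
  }
  rows <- lapply(cfgs, function(cfg) {
    key <- sprintf("scenario%d_tau%g", cfg$scenario, cfg$tau)
    truth <- if (!is.null(truths) && key %in% names(truths)) truths[[key]] else NULL
    if (verbose) {
      message(sprintf("cell: scenario %d / censoring %s / case %d (%d reps)",
                      cfg$scenario, cfg$censoring, cfg$case, cfg$reps))
    }
    tab <- run_cell(cfg, truth = truth, bootstrap = bootstrap)
    if (verbose) {
      message(sprintf("  failures: %s",
                      paste(sprintf("%s=%d", tab$method[tab$parameter == "dah"],
                                    tab$n_failed[tab$parameter == "dah"]),
                            collapse = " ")))
    }
    tab
  })
  do.call(rbind, rows)
}
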