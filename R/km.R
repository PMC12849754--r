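# Weighted product-limit and Nelson-Aalen survival estimators. These are the
# primitives every adjustment method reduces to: each method differs only in
# the per-subject weights it feeds in. Ties: events and censorings at the
# same time are both in the risk set for that time (events processed first,
# the standard Kaplan-Meier convention).

# Weighted event mass dN^w and at-risk mass Y^w at each distinct event time.
risk_table <- function(y, d, w) {
  o <- order(y)
  y <- y[o]; d <- d[o]; w <- w[o]
  atrisk <- rev(cumsum(rev(w)))
  first <- !duplicated(y)
  ut <- y[first]
  Yw <- atrisk[first]
  dNw <- as.vector(rowsum(w * d, y))
  ev <- dNw > 0
  list(time = ut[ev], dN = dNw[ev], Y = Yw[ev], max_time = y[length(y)])
}

check_curve_input <- function(ds, weights) {
  if (ds$n == 0L) ah_error("dataset is empty", "ahadjust_input_error")
  if (length(weights) != ds$n) {
    ah_error("weights must have one entry per subject", "ahadjust_input_error")
  }
  if (anyNA(weights) || any(weights < 0)) {
    ah_error("weights must be nonnegative", "ahadjust_input_error")
  }
  if (all(weights == 0)) {
    ah_error("weights must not all be zero", "ahadjust_input_error")
  }
}

#' Weighted Kaplan-Meier survival curve
#'
#' Product-limit estimator using weighted event and at-risk counts,
#' \eqn{\hat S(t) = \prod_{t_j \le t} \{1 - dN^w(t_j)/Y^w(t_j)\}}. With unit
#' weights this is the classical Kaplan-Meier estimator; rescaling all
#' weights by a positive constant leaves the curve unchanged.
#'
#' @param ds a [tte_data()].
#' @param weights nonnegative per-subject weights; defaults to the dataset's
#'   case weights.
#' @return a [step_curve()] with a jump at each distinct event time.
#' @export
#' @examples
#' ds <- tte_data(c(0.2, 0.4, 0.5, 0.8), c(1, 0, 1, 1), c(0, 0, 0, 0))
#' km_curve(ds)
km_curve <- function(ds, weights = ds$weights) {
  check_curve_input(ds, weights)
  rt <- risk_table(ds$time, ds$status, weights)
  step_curve(rt$time, cumprod(1 - rt$dN / rt$Y), max_time = rt$max_time)
}

#' Survival via the weighted Nelson-Aalen cumulative hazard
#'
#' Weighted Nelson-Aalen estimate of the cumulative hazard,
#' \eqn{\hat\Lambda(t) = \sum_{t_j \le t} dN^w(t_j)/Y^w(t_j)}, returned as
#' the survival curve \eqn{\exp\{-\hat\Lambda(t)\}}. Equivalent to the
#' Breslow estimator of a weighted Cox model containing no covariates, the
#' building block of the IPTW cumulative-hazard method. Pointwise,
#' \eqn{\exp(-\hat\Lambda) \ge \hat S_{KM}}.
#'
#' @inheritParams km_curve
#' @return a [step_curve()].
#' @export
cumhaz_exp_curve <- function(ds, weights = ds$weights) {
  check_curve_input(ds, weights)
  rt <- risk_table(ds$time, ds$status, weights)
  step_curve(rt$time, exp(-cumsum(rt$dN / rt$Y)), max_time = rt$max_time)
}
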