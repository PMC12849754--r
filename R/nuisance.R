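# Nuisance model fits: logistic propensity, outcome Cox model with Breslow
# baseline hazard, and censoring-survival models for IPCW.

#' Fit a logistic propensity model
#'
#' Unpenalized maximum-likelihood logistic regression of the group indicator
#' on the specification's treatment terms (plus intercept), fitted by IRLS.
#' Fitted scores are floored to `[1e-6, 1 - 1e-6]` for numerical safety; no
#' substantive trimming is applied.
#'
#' @param ds a [tte_data()] with both groups present.
#' @param spec a [model_spec()].
#' @return an object of class `"propensity_fit"` with elements `coef`
#'   (including `(Intercept)`), `fitted` (per-subject \eqn{\hat\pi_i =
#'   P(Z=1|X_i)}) and `converged`.
#' @export
fit_propensity <- function(ds, spec) {
  if (length(unique(ds$group)) < 2L) {
    ah_error("both groups must be present to fit a propensity model",
             "ahadjust_input_error")
  }
  X <- cbind(`(Intercept)` = 1, term_matrix(spec$treatment_terms, ds$x))
  if (qr(X)$rank < ncol(X)) {
    ah_error("propensity design matrix is rank deficient", "ahadjust_input_error")
  }
  fit <- suppressWarnings(
    stats::glm.fit(X, ds$group, weights = ds$weights,
                   family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  )
  if (!fit$converged || anyNA(fit$coefficients)) {
    ah_error(sprintf("propensity model did not converge (terms: %s); check for separation",
                     paste(spec$treatment_terms, collapse = ", ")),
             "ahadjust_fit_error")
  }
  pi_hat <- pmin(pmax(fit$fitted.values, 1e-6), 1 - 1e-6)
  structure(list(coef = fit$coefficients, fitted = pi_hat,
                 converged = fit$converged, terms = spec$treatment_terms),
            class = "propensity_fit")
}

# Breslow cumulative baseline hazard on the uncentered linear-predictor
# scale: Lambda_0(t) = sum_{event times s <= t} dN^w(s) / sum_{Y_j >= s} w_j exp(lp_j).
breslow_cumhaz <- function(y, d, w, explp) {
  o <- order(y)
  wr <- (w * explp)[o]
  wd <- (w * d)[o]
  y <- y[o]
  denom <- rev(cumsum(rev(wr)))
  first <- !duplicated(y)
  ut <- y[first]
  dN <- as.vector(rowsum(wd, y))
  ev <- dN > 0
  list(time = ut[ev], hazard = cumsum(dN[ev] / denom[first][ev]))
}

#' Fit the outcome Cox model
#'
#' Cox proportional-hazards partial-likelihood fit of the follow-up time on
#' the treatment indicator plus the specification's outcome terms, with the
#' Efron correction for ties and the Breslow estimator of the cumulative
#' baseline hazard at event times.
#'
#' @param ds a [tte_data()] with at least one event.
#' @param spec a [model_spec()].
#' @return an object of class `"cox_fit"`: `coef` (named, treatment first),
#'   `basehaz_time` / `basehaz` (Breslow \eqn{\hat\Lambda_0} step function),
#'   `terms`, and `max_time`.
#' @export
fit_outcome_cox <- function(ds, spec) {
  cox_hazard_fit(ds$time, ds$status, ds$weights,
                 cbind(z = as.numeric(ds$group),
                       term_matrix(spec$outcome_terms, ds$x)),
                 spec$outcome_terms)
}

cox_hazard_fit <- function(y, d, w, X, terms) {
  if (sum(d) == 0L) {
    ah_error("no events; cannot fit a Cox model", "ahadjust_fit_error")
  }
  if (ncol(X) == 0L) {
    # null model: Breslow baseline collapses to the Nelson-Aalen estimator
    bh <- breslow_cumhaz(y, d, w, rep(1, length(y)))
    return(structure(list(coef = numeric(0), terms = terms,
                          basehaz_time = bh$time, basehaz = bh$hazard,
                          max_time = max(y)),
                     class = "cox_fit"))
  }
  if (qr(X)$rank < ncol(X)) {
    ah_error("Cox design matrix is rank deficient", "ahadjust_input_error")
  }
  fit <- survival::coxph.fit(X, survival::Surv(y, d), strata = NULL,
                             offset = NULL, init = NULL,
                             control = survival::coxph.control(),
                             weights = w, method = "efron", rownames = NULL)
  beta <- fit$coefficients
  if (anyNA(beta) || any(!is.finite(beta))) {
    ah_error(sprintf("Cox model failed to converge after %s iterations",
                     paste(fit$iter, collapse = "/")),
             "ahadjust_fit_error")
  }
  bh <- breslow_cumhaz(y, d, w, exp(drop(X %*% beta)))
  structure(list(coef = beta, terms = terms,
                 basehaz_time = bh$time, basehaz = bh$hazard,
                 max_time = max(y)),
            class = "cox_fit")
}

# Linear predictor for new covariate rows; z is the treatment value
# (scalar or per-row vector), always the first coefficient.
cox_lp <- function(fit, x, z) {
  tm <- term_matrix(fit$terms, x)
  base <- rep_len(fit$coef[1L] * z, nrow(x))
  if (ncol(tm)) base + drop(tm %*% fit$coef[-1L]) else base
}

#' Predicted survival curve from a Cox fit
#'
#' \eqn{\hat S(t \mid z, x) = \exp\{-\hat\Lambda_0(t) e^{\hat\beta^\top(z,
#' \psi(x))}\}} as a step curve on the event-time grid.
#'
#' @param fit a `"cox_fit"` from [fit_outcome_cox()].
#' @param covariates single-row data frame of covariates.
#' @param z treatment value (0 or 1) to condition on.
#' @return a [step_curve()].
#' @export
predict_cox_survival <- function(fit, covariates, z) {
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != 1L) {
    ah_error("predict_cox_survival expects a single covariate row",
             "ahadjust_input_error")
  }
  lp <- cox_lp(fit, covariates, z)
  step_curve(fit$basehaz_time, exp(-fit$basehaz * exp(lp)),
             max_time = fit$max_time)
}

# n x G matrix of predicted survival for all rows of x at the baseline grid.
cox_surv_matrix <- function(fit, x, z) {
  explp <- exp(cox_lp(fit, x, z))
  exp(-outer(explp, fit$basehaz))
}

# Weighted average over subjects of predicted survival at every grid time,
# computed in grid chunks so that memory stays bounded for large n.
cox_average_surv <- function(fit, x, z, w) {
  explp <- exp(cox_lp(fit, x, z))
  G <- length(fit$basehaz)
  chunk <- max(1L, floor(2e7 / length(explp)))
  out <- numeric(G)
  for (s in seq(1L, G, by = chunk)) {
    e <- min(G, s + chunk - 1L)
    out[s:e] <- colSums(w * exp(-outer(explp, fit$basehaz[s:e])))
  }
  out
}

#' Fit a censoring-survival model for IPCW
#'
#' Estimates \eqn{G(t \mid Z, X) = P(C > t \mid \cdot)} by reversing the
#' roles of event and censoring (indicator \eqn{1 - \Delta}). Mode
#' `"pooled_km"` uses the Kaplan-Meier estimator on the pooled sample
#' (appropriate under completely random censoring); mode `"cox"` fits a Cox
#' model on the specification's censoring terms (covariate-dependent
#' censoring). A dataset with no censored subjects yields \eqn{G \equiv 1}.
#'
#' @param ds a [tte_data()].
#' @param spec a [model_spec()]; its `censoring` field selects the mode.
#' @return an object of class `"censoring_fit"`.
#' @export
fit_censoring <- function(ds, spec) {
  cens <- 1L - ds$status
  if (spec$censoring == "pooled_km") {
    curve <- if (sum(cens) == 0L) {
      step_curve(numeric(0), numeric(0))
    } else {
      km_curve(tte_data(ds$time, cens, ds$group, validate = FALSE))
    }
    structure(list(mode = "pooled_km", curve = curve), class = "censoring_fit")
  } else {
    fit <- cox_hazard_fit(ds$time, cens, ds$weights,
                          term_matrix(spec$censoring_terms, ds$x),
                          spec$censoring_terms)
    structure(list(mode = "cox", fit = fit), class = "censoring_fit")
  }
}

#' Evaluate censoring survival at left limits
#'
#' Per-subject \eqn{\hat G(t_i^- \mid Z_i, X_i)}: the censoring survival just
#' before each evaluation time, so a subject's own censoring jump does not
#' deflate its weight.
#'
#' @param cfit a `"censoring_fit"` from [fit_censoring()].
#' @param t vector of evaluation times (typically the follow-up times).
#' @param ds the [tte_data()] supplying covariates in `"cox"` mode.
#' @return numeric vector of left-limit censoring survival probabilities.
#' @export
censoring_surv_left <- function(cfit, t, ds = NULL) {
  if (cfit$mode == "pooled_km") {
    surv_left(cfit$curve, t)
  } else {
    fit <- cfit$fit
    tm <- term_matrix(fit$terms, ds$x)
    explp <- exp(drop(tm %*% fit$coef))
    i <- findInterval(t, fit$basehaz_time, left.open = TRUE)
    lam <- c(0, fit$basehaz)[i + 1L]
    exp(-lam * explp)
  }
}
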