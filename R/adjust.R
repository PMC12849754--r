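# The seven survival-curve adjustment methods. Each returns an
# "adjusted_curve_pair": the group-0 and group-1 adjusted survival curves
# plus method diagnostics. The average-hazard estimands plug into these.

curve_pair <- function(curve0, curve1, method, diagnostics = list()) {
  structure(list(curve0 = curve0, curve1 = curve1, method = method,
                 diagnostics = diagnostics),
            class = "adjusted_curve_pair")
}

#' @export
print.adjusted_curve_pair <- function(x, ...) {
  cat(sprintf("adjusted_curve_pair (method = %s): %d / %d jumps in groups 0 / 1\n",
              x$method, length(x$curve0$time), length(x$curve1$time)))
  invisible(x)
}

# Effective sample size of a weight vector (Kish).
ess <- function(w) sum(w)^2 / sum(w^2)

#' Unadjusted group-wise Kaplan-Meier curves
#'
#' The reference method: Kaplan-Meier estimates per group with unit (case)
#' weights and no confounding adjustment.
#'
#' @param ds a [tte_data()] with both groups present.
#' @param spec ignored; accepted for a uniform method signature.
#' @return an `"adjusted_curve_pair"`.
#' @export
unadjusted_km <- function(ds, spec = NULL) {
  gs <- ds_split(ds)
  curve_pair(km_curve(gs[[1]]), km_curve(gs[[2]]), "km")
}

#' Direct standardization (G-formula) via a Cox model
#'
#' Fits a Cox model on the treatment indicator plus the outcome terms, then
#' averages the predicted survival curves over all subjects with treatment
#' set to 1 and to 0: \eqn{\hat S_j(t) = n^{-1}\sum_i \hat S(t \mid Z = j,
#' X_i)}. Consistent when the outcome model is correctly specified;
#' tolerates covariate-dependent censoring acting through modeled
#' covariates.
#'
#' @param ds a [tte_data()].
#' @param spec a [model_spec()] supplying `outcome_terms`.
#' @return an `"adjusted_curve_pair"`.
#' @export
direct_standardization <- function(ds, spec) {
  fit <- fit_outcome_cox(ds, spec)
  w <- ds$weights / sum(ds$weights)
  s0 <- cox_average_surv(fit, ds$x, 0, w)
  s1 <- cox_average_surv(fit, ds$x, 1, w)
  curve_pair(step_curve(fit$basehaz_time, s0, max_time = fit$max_time),
             step_curve(fit$basehaz_time, s1, max_time = fit$max_time),
             "ds")
}

# ATE weights from a propensity fit: 1/pi for treated, 1/(1-pi) for controls.
# Unstabilized on purpose: a multiplicative constant cancels inside the
# group-wise product-limit ratios, so stabilization cannot change the curves.
ate_weights <- function(ds, spec) {
  pfit <- fit_propensity(ds, spec)
  w <- ifelse(ds$group == 1L, 1 / pfit$fitted, 1 / (1 - pfit$fitted))
  w <- w * ds$weights
  if (max(w) > 10 * stats::median(w)) {
    warning(sprintf("extreme IPTW weight detected (max %.2f vs median %.2f)",
                    max(w), stats::median(w)))
  }
  list(w = w, pfit = pfit)
}

iptw_diag <- function(w, g) {
  list(weight_range = range(w), ess0 = ess(w[g == 0L]), ess1 = ess(w[g == 1L]))
}

#' IPTW Kaplan-Meier curves
#'
#' Weighted Kaplan-Meier estimator per group with inverse probability of
#' treatment weights \eqn{w_i = Z_i/\hat\pi_i + (1-Z_i)/(1-\hat\pi_i)} from
#' a logistic propensity model. Consistent when the treatment model is
#' correctly specified.
#'
#' @inheritParams direct_standardization
#' @return an `"adjusted_curve_pair"`.
#' @export
iptw_km <- function(ds, spec) {
  aw <- ate_weights(ds, spec)
  i0 <- ds$group == 0L
  curve_pair(km_curve(ds_subset(ds, which(i0)), aw$w[i0]),
             km_curve(ds_subset(ds, which(!i0)), aw$w[!i0]),
             "iptw_km", iptw_diag(aw$w, ds$group))
}

#' IPTW survival via the cumulative hazard
#'
#' Inverse probability of treatment weighting combined with the
#' treatment-stratified weighted Breslow (Nelson-Aalen) cumulative hazard;
#' the adjusted survival curve is \eqn{\exp\{-\hat\Lambda_j(t)\}} per group.
#'
#' @inheritParams direct_standardization
#' @return an `"adjusted_curve_pair"`.
#' @export
iptw_ch <- function(ds, spec) {
  aw <- ate_weights(ds, spec)
  i0 <- ds$group == 0L
  curve_pair(cumhaz_exp_curve(ds_subset(ds, which(i0)), aw$w[i0]),
             cumhaz_exp_curve(ds_subset(ds, which(!i0)), aw$w[!i0]),
             "iptw_ch", iptw_diag(aw$w, ds$group))
}

# Nearest opposite-group neighbour on the propensity-score scale, with
# replacement. Ties in distance are broken toward the candidate with the
# lowest subject index; among candidates sharing a score the lowest index
# wins (deduplication keeps the first, i.e. lowest-index, holder).
nearest_match <- function(query_scores, cand_scores, cand_idx) {
  o <- order(cand_scores, cand_idx)
  cs <- cand_scores[o]; ci <- cand_idx[o]
  keep <- !duplicated(cs)
  cs <- cs[keep]; ci <- ci[keep]
  m <- length(cs)
  pos <- findInterval(query_scores, cs)
  left <- pmax(pos, 1L); right <- pmin(pos + 1L, m)
  dl <- abs(query_scores - cs[left])
  dr <- abs(query_scores - cs[right])
  pick <- ifelse(pos == 0L, right,
          ifelse(pos == m, left,
          ifelse(dl < dr, left,
          ifelse(dr < dl, right,
          ifelse(ci[left] <= ci[right], left, right)))))
  ci[pick]
}

#' Bidirectional propensity-score matching
#'
#' 1:1 nearest-neighbour matching on the probability-scale propensity
#' score, with replacement, in both directions: every treated subject is
#' matched to a control and every control to a treated subject. The matched
#' sample is the original cohort plus all matched counterparts (as
#' frequency weights), so it represents the overall population and the
#' targeted estimand is the average treatment effect. Group-wise weighted
#' Kaplan-Meier curves are computed on the matched sample. Matching is
#' deterministic: distance ties are broken toward the lowest subject index.
#'
#' @inheritParams direct_standardization
#' @return an `"adjusted_curve_pair"`.
#' @export
ps_match_km <- function(ds, spec) {
  pfit <- fit_propensity(ds, spec)
  idx0 <- which(ds$group == 0L)
  idx1 <- which(ds$group == 1L)
  if (length(idx0) == 0L || length(idx1) == 0L) {
    ah_error("both groups must be nonempty for matching", "ahadjust_input_error")
  }
  ps <- pfit$fitted
  m_for_0 <- nearest_match(ps[idx0], ps[idx1], idx1)  # controls -> treated
  m_for_1 <- nearest_match(ps[idx1], ps[idx0], idx0)  # treated -> controls
  mult <- rep(1, ds$n)
  tab <- table(c(m_for_0, m_for_1))
  at <- as.integer(names(tab))
  mult[at] <- mult[at] + as.vector(tab)
  w <- ds$weights * mult
  i0 <- ds$group == 0L
  curve_pair(km_curve(ds_subset(ds, which(i0)), w[i0]),
             km_curve(ds_subset(ds, which(!i0)), w[!i0]),
             "matching",
             list(multiplicity_range = range(mult),
                  matched_n = ds$n + length(m_for_0) + length(m_for_1)))
}

# Empirical-likelihood weights for one group: maximize sum log p_i subject
# to sum p_i = 1 and sum p_i psi_i = target. Solved through the Lagrange
# dual: p_i = 1 / {n_g (1 + lambda' c_i)} with c_i = psi_i - target, lambda
# the root of sum c_i / (1 + lambda' c_i) = 0, found by damped Newton with
# backtracking that keeps every denominator positive.
el_weights <- function(C, tol = 1e-10, maxit = 100L) {
  lam <- rep(0, ncol(C))
  denom <- rep(1, nrow(C))
  for (it in seq_len(maxit)) {
    g <- colSums(C / denom)
    # convergence is judged on the weighted-moment violation sum(p_i c_i),
    # not on the raw gradient, which also vanishes when lambda diverges
    if (max(abs(g)) / sum(1 / denom) < tol * 100) {
      return(list(w = (1 / denom) / sum(1 / denom), iterations = it))
    }
    if (max(abs(lam)) > 1e8) break
    Cd <- C / denom
    H <- crossprod(Cd)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    alpha <- 1
    repeat {
      cand <- lam + alpha * step
      denom_c <- drop(1 + C %*% cand)
      if (all(denom_c > 1e-10)) break
      alpha <- alpha / 2
      if (alpha < 1e-12) break
    }
    if (alpha < 1e-12) break
    lam <- lam + alpha * step
    denom <- drop(1 + C %*% lam)
  }
  NULL
}

#' Empirical-likelihood balanced Kaplan-Meier curves
#'
#' For each group, subject weights are chosen to maximize the empirical
#' likelihood \eqn{\sum_i \log p_i} subject to \eqn{\sum p_i = 1} and the
#' group's weighted first moments of the treatment-model covariates
#' matching the pooled-sample means. Group-wise weighted Kaplan-Meier
#' curves are then computed with these balancing weights. When the groups
#' are already exactly balanced the weights are uniform and the result
#' equals the unadjusted estimator.
#'
#' @inheritParams direct_standardization
#' @return an `"adjusted_curve_pair"`.
#' @export
el_km <- function(ds, spec) {
  psi <- term_matrix(spec$treatment_terms, ds$x)
  if (ncol(psi) == 0L) {
    pair <- unadjusted_km(ds)
    pair$method <- "el"
    return(pair)
  }
  target <- colMeans(psi)
  curves <- vector("list", 2)
  iters <- integer(2)
  for (j in 0:1) {
    idx <- which(ds$group == j)
    sol <- el_weights(sweep(psi[idx, , drop = FALSE], 2, target))
    if (is.null(sol)) {
      ah_error(sprintf("empirical-likelihood weights infeasible for group %d (pooled covariate mean outside the group's convex hull?)", j),
               "ahadjust_el_error")
    }
    curves[[j + 1]] <- km_curve(ds_subset(ds, idx), sol$w * ds$weights[idx])
    iters[j + 1] <- sol$iterations
  }
  curve_pair(curves[[1]], curves[[2]], "el", list(newton_iterations = iters))
}

#' Augmented IPTW adjusted curves
#'
#' Doubly robust estimator of the per-group cumulative incidence combining
#' the outcome Cox model, the logistic propensity model, and inverse
#' probability of censoring weights:
#' \deqn{\hat F_j(t) = n^{-1}\sum_i \Big[\hat F(t \mid j, X_i) +
#'   \frac{I(Z_i = j)}{\hat\pi_j(X_i)}\Big\{\frac{I(Y_i \le t, \Delta_i = 1)}
#'   {\hat G(Y_i^- \mid Z_i, X_i)} - \hat F(t \mid j, X_i)\Big\}\Big],}
#' a one-step IPCW-augmented form (no censoring-martingale efficiency
#' term). \eqn{\hat S_j = 1 - \hat F_j} is clipped to \eqn{[0,1]} and
#' monotonized by a running minimum; the number of repaired grid points is
#' reported in the diagnostics. Consistent if either nuisance model is
#' correct, provided the censoring model is correct.
#'
#' @inheritParams direct_standardization
#' @return an `"adjusted_curve_pair"`.
#' @export
aiptw_curves <- function(ds, spec) {
  pfit <- fit_propensity(ds, spec)
  ofit <- fit_outcome_cox(ds, spec)
  cfit <- fit_censoring(ds, spec)
  grid <- ofit$basehaz_time
  Gy <- censoring_surv_left(cfit, ds$time, ds)
  if (any(ds$status == 1L & Gy <= 0)) {
    ah_error("censoring survival is zero at an observed event time; IPCW degenerate",
             "ahadjust_ipcw_error")
  }
  ipcw <- ds$status / pmax(Gy, 1e-12)
  w <- ds$weights / sum(ds$weights)
  repairs <- integer(2)
  curves <- vector("list", 2)
  n <- ds$n
  G <- length(grid)
  chunk <- max(1L, floor(2e7 / n))
  for (j in 0:1) {
    explp <- exp(cox_lp(ofit, ds$x, j))
    pi_j <- if (j == 1L) pfit$fitted else 1 - pfit$fitted
    ipw <- (ds$group == j) / pi_j
    Fj <- numeric(G)
    for (s in seq(1L, G, by = chunk)) {
      e <- min(G, s + chunk - 1L)
      # model-based cumulative incidence and IPCW event process, n x chunk
      A <- 1 - exp(-outer(explp, ofit$basehaz[s:e]))
      U <- outer(ds$time, grid[s:e], "<=") * ipcw
      Fj[s:e] <- colSums(w * A) + colSums(w * ipw * (U - A))
    }
    S <- pmin(pmax(1 - Fj, 0), 1)
    S_mono <- cummin(S)
    repairs[j + 1] <- sum(S_mono != (1 - Fj))
    curves[[j + 1]] <- step_curve(grid, S_mono, max_time = ofit$max_time)
  }
  curve_pair(curves[[1]], curves[[2]], "aiptw",
             list(monotonicity_repairs = repairs,
                  weight_range = range(1 / pfit$fitted, 1 / (1 - pfit$fitted))))
}

#' Adjusted survival curves by method name
#'
#' Dispatcher over the seven adjustment methods.
#'
#' @param ds a [tte_data()].
#' @param method one of `"km"`, `"ds"`, `"iptw_km"`, `"iptw_ch"`,
#'   `"matching"`, `"el"`, `"aiptw"`.
#' @param spec a [model_spec()]; ignored by `"km"`.
#' @return an `"adjusted_curve_pair"`.
#' @export
#' @examples
#' set.seed(7)
#' ds <- make_dataset(200, scenario = 1, censoring = "A")
#' pair <- adjusted_curves(ds, "iptw_km", case_model_spec(1))
#' ah_contrast(pair$curve0, pair$curve1, tau = 0.7, method = pair$method)
adjusted_curves <- function(ds, method, spec = NULL) {
  method <- match.arg(method, c("km", "ds", "iptw_km", "iptw_ch",
                                "matching", "el", "aiptw"))
  if (method != "km" && is.null(spec)) {
    ah_error(sprintf("method '%s' requires a model_spec", method),
             "ahadjust_input_error")
  }
  switch(method,
         km = unadjusted_km(ds),
         ds = direct_standardization(ds, spec),
         iptw_km = iptw_km(ds, spec),
         iptw_ch = iptw_ch(ds, spec),
         matching = ps_match_km(ds, spec),
         el = el_km(ds, spec),
         aiptw = aiptw_curves(ds, spec))
}
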