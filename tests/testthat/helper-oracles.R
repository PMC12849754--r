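# Independent oracles and fixture builders used across the suite. These are
# deliberately naive (loops over risk sets, grid searches) so they share no
# code path with the implementation they check.

# Brute-force weighted product-limit estimator: loop over distinct event
# times, recompute the risk set from scratch each time.
brute_km <- function(y, d, w = rep(1, length(y))) {
  times <- sort(unique(y[d == 1]))
  surv <- numeric(length(times))
  s <- 1
  for (k in seq_along(times)) {
    at_risk <- sum(w[y >= times[k]])
    events <- sum(w[y == times[k] & d == 1])
    s <- s * (1 - events / at_risk)
    surv[k] <- s
  }
  list(time = times, surv = surv)
}

# Brute-force Nelson-Aalen cumulative hazard.
brute_na <- function(y, d, w = rep(1, length(y))) {
  times <- sort(unique(y[d == 1]))
  haz <- cumsum(vapply(times, function(s) {
    sum(w[y == s & d == 1]) / sum(w[y >= s])
  }, numeric(1)))
  list(time = times, cumhaz = haz)
}

# Cox partial log-likelihood (Breslow form, valid for untied event times),
# for the independent numerical maximizer check.
cox_pll <- function(beta, y, d, X) {
  lp <- drop(X %*% beta)
  sum(vapply(which(d == 1), function(i) {
    lp[i] - log(sum(exp(lp[y >= y[i]])))
  }, numeric(1)))
}

# Bernoulli log-likelihood for the logistic oracle.
logit_ll <- function(beta, z, X) {
  eta <- drop(X %*% beta)
  sum(z * eta - log(1 + exp(eta)))
}

# The four-subject worked example used throughout: (Y, Delta) =
# (0.2,1), (0.4,0), (0.5,1), (0.8,1), all in group 0.
ds_hand <- function() {
  tte_data(c(0.2, 0.4, 0.5, 0.8), c(1, 0, 1, 1), c(0, 0, 0, 0))
}

# Dense step-function discretization of S(t) = exp(-lambda t).
exp_curve <- function(lambda, upto = 1.5, by = 1e-4) {
  tt <- seq(by, upto, by = by)
  step_curve(tt, exp(-lambda * tt), max_time = upto)
}

# Enumerate every dataset with n subjects, times drawn (with repetition,
# sorted) from `grid`, and all event-indicator patterns.
enumerate_small_datasets <- function(n, grid = c(0.25, 0.5, 0.75)) {
  time_sets <- as.matrix(expand.grid(rep(list(grid), n)))
  if (n > 1) time_sets <- t(apply(time_sets, 1, sort))
  time_sets <- unique(time_sets)
  out <- list()
  status_sets <- as.matrix(expand.grid(rep(list(0:1), n)))
  for (i in seq_len(nrow(time_sets))) {
    for (j in seq_len(nrow(status_sets))) {
      out[[length(out) + 1L]] <- list(y = time_sets[i, ],
                                      d = status_sets[j, ])
    }
  }
  out
}

# Thin wrappers over internal helpers used by tests.
ds_subset_public <- function(ds, idx) ahadjust:::ds_subset(ds, idx)
ds_split_public <- function(ds) ahadjust:::ds_split(ds)
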