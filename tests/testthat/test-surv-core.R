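# Step-curve primitives and the average-hazard estimands.

test_that("km_curve reproduces the hand-computed product-limit example", {
  cv <- km_curve(ds_hand())
  expect_equal(surv_at(cv, 0.2), 0.75)
  expect_equal(surv_at(cv, 0.5), 0.375)
  expect_equal(surv_at(cv, 0.7), 0.375)
  # no censoring: product-limit collapses to the empirical survival function
  set.seed(101)
  y <- rexp(40)
  ds <- tte_data(y, rep(1, 40), rep(0, 40))
  cv2 <- km_curve(ds)
  for (t in c(0.1, 0.5, 1.2)) {
    expect_equal(surv_at(cv2, t), mean(y > t))
  }
})

test_that("km and cumhaz curves are invariant to rescaling all weights", {
  set.seed(102)
  ds <- tte_data(rexp(30), rbinom(30, 1, 0.7), rep(0, 30))
  w <- runif(30, 0.5, 2)
  for (f in list(km_curve, cumhaz_exp_curve)) {
    a <- f(ds, w)
    b <- f(ds, w * 7.3)
    expect_equal(a$time, b$time)
    expect_equal(a$surv, b$surv)
  }
})

test_that("cumhaz_exp_curve matches hand Nelson-Aalen computations", {
  one <- tte_data(1, 1, 0)
  expect_equal(surv_at(cumhaz_exp_curve(one), 1), exp(-1))
  expect_equal(surv_at(cumhaz_exp_curve(ds_hand()), 0.7), exp(-(1 / 4 + 1 / 2)))
  no_events <- tte_data(c(1, 2), c(0, 0), c(0, 0))
  expect_equal(surv_at(cumhaz_exp_curve(no_events), c(0.5, 1.5, 3)), rep(1, 3))
})

test_that("km_curve equals the brute-force oracle on all small datasets", {
  for (n in 1:4) {
    for (case in enumerate_small_datasets(n)) {
      if (sum(case$d) == 0) next
      ds <- tte_data(case$y, case$d, rep(0, n))
      cv <- km_curve(ds)
      oracle <- brute_km(case$y, case$d)
      expect_equal(cv$time, oracle$time)
      expect_equal(cv$surv, oracle$surv)
    }
  }
  # weighted spot checks at n = 6 against the same oracle
  set.seed(103)
  for (rep in 1:25) {
    y <- sample(c(0.25, 0.5, 0.75, 1), 6, replace = TRUE)
    d <- rbinom(6, 1, 0.6)
    w <- sample(1:3, 6, replace = TRUE)
    if (sum(d) == 0) next
    cv <- km_curve(tte_data(y, d, rep(0, 6)), w)
    oracle <- brute_km(y, d, w)
    expect_equal(cv$surv, oracle$surv)
    na <- cumhaz_exp_curve(tte_data(y, d, rep(0, 6)), w)
    expect_equal(na$surv, exp(-brute_na(y, d, w)$cumhaz))
  }
})

test_that("rmst computes exact rectangle areas and handles extensions", {
  cv <- km_curve(ds_hand())
  expect_equal(rmst(cv, 0.7), 0.2 * 1 + 0.3 * 0.75 + 0.2 * 0.375)
  flat <- step_curve(numeric(0), numeric(0))
  expect_equal(rmst(flat, 0.4), 0.4)
  expect_equal(rmst(exp_curve(1), 1), 1 - exp(-1), tolerance = 1e-3)
  expect_warning(rmst(cv, 0.9), "carrying the last survival value")
  expect_error(rmst(cv, -1), class = "ahadjust_input_error")
})

test_that("average hazard matches the plug-in identity and hand example", {
  cv <- km_curve(ds_hand())
  expect_equal(average_hazard(cv, 0.7), 0.625 / 0.5)
  # identity AH * RMST = 1 - S(tau) to machine precision on random curves
  set.seed(104)
  for (rep in 1:10) {
    ds <- tte_data(rexp(25), rbinom(25, 1, 0.6), rep(0, 25))
    if (sum(ds$status) == 0) next
    cv <- km_curve(ds)
    tau <- runif(1, 0.1, max(ds$time))
    expect_equal(average_hazard(cv, tau) * rmst(cv, tau),
                 1 - surv_at(cv, tau), tolerance = 1e-15)
  }
  # no events by tau -> zero
  late <- tte_data(c(2, 3), c(1, 1), c(0, 0))
  expect_equal(suppressWarnings(average_hazard(km_curve(late), 1)), 0)
})

test_that("average hazard of an exponential curve recovers its rate", {
  for (lam in c(0.5, 2)) {
    cv <- exp_curve(lam)
    for (tau in c(0.2, 0.7, 1.0)) {
      expect_equal(average_hazard(cv, tau), lam, tolerance = 1e-3)
    }
  }
})

test_that("person_time_rate is events over person-time", {
  expect_equal(person_time_rate(tte_data(c(1, 3), c(1, 0), c(0, 0))), 0.25)
  expect_equal(person_time_rate(tte_data(c(1, 2), c(0, 0), c(0, 0))), 0)
  # converges to the hazard rate for uncensored exponential data
  set.seed(105)
  y <- rexp(1e5, 1.7)
  expect_equal(person_time_rate(tte_data(y, rep(1, 1e5), rep(0, 1e5))),
               1.7, tolerance = 0.02)
})

test_that("ah_contrast has the expected symmetry and degenerate behavior", {
  cv <- km_curve(ds_hand())
  same <- ah_contrast(cv, cv, 0.7)
  expect_equal(same$dah, 0)
  expect_equal(same$rah, 1)
  set.seed(106)
  ds <- make_dataset(200, 2, "A")
  gs <- list(km_curve(ds_subset_public(ds, ds$group == 0)),
             km_curve(ds_subset_public(ds, ds$group == 1)))
  fwd <- ah_contrast(gs[[1]], gs[[2]], 0.7)
  rev <- ah_contrast(gs[[2]], gs[[1]], 0.7)
  expect_equal(fwd$dah, -rev$dah)
  expect_equal(fwd$rah, 1 / rev$rah)
  # eta0 = 0: DAH reported, RAH flagged undefined
  none <- tte_data(c(2, 2), c(1, 1), c(0, 0))
  some <- ds_hand()
  res <- suppressWarnings(
    ah_contrast(km_curve(none), km_curve(some), 0.7))
  expect_true(is.na(res$rah))
  expect_equal(res$dah, res$eta1)
})

test_that("standardized AH over strata equals the marginal AH without censoring", {
  set.seed(107)
  # each group carries the same stratum composition as the pooled sample,
  # which is what makes the standardization identity exact in finite samples
  strata <- c(rep(0, 100), rep(0, 50), rep(1, 200), rep(1, 100))
  g <- c(rep(0, 100), rep(1, 50), rep(0, 200), rep(1, 100))
  n <- length(g)
  y <- rexp(n, 0.8 + strata + 0.5 * g)
  ds <- tte_data(y, rep(1, n), g)
  std <- suppressWarnings(standardized_ah(ds, strata, 0.7))
  gs <- ds_split_public(ds)
  marg0 <- suppressWarnings(average_hazard(km_curve(gs[[1]]), 0.7))
  marg1 <- suppressWarnings(average_hazard(km_curve(gs[[2]]), 0.7))
  expect_equal(std$eta0, marg0, tolerance = 1e-12)
  expect_equal(std$eta1, marg1, tolerance = 1e-12)
  # non-collapsibility: the pi-weighted mean of stratum AHs differs
  pi_x <- table(strata) / n
  strat_ah <- sapply(0:1, function(s) {
    idx <- strata == s & g == 0
    suppressWarnings(
      average_hazard(km_curve(tte_data(y[idx], rep(1, sum(idx)), rep(0, sum(idx)))), 0.7))
  })
  expect_gt(abs(sum(pi_x * strat_ah) - std$eta0), 1e-3)
  # single stratum reduces to the marginal estimate
  one <- suppressWarnings(standardized_ah(ds, rep(1, n), 0.7))
  expect_equal(one$eta0, marg0)
  # empty stratum-group cell is a typed error
  bad_strata <- ifelse(g == 1, "a", "b")
  expect_error(standardized_ah(ds, bad_strata, 0.7),
               class = "ahadjust_input_error")
})

test_that("invalid curve and dataset inputs raise typed errors", {
  expect_error(tte_data(numeric(0), integer(0), integer(0)),
               class = "ahadjust_input_error")
  expect_error(tte_data(c(0, 1), c(1, 1), c(0, 0)),
               class = "ahadjust_input_error")
  expect_error(tte_data(c(1, 2), c(2, 1), c(0, 0)),
               class = "ahadjust_input_error")
  ds <- ds_hand()
  expect_error(km_curve(ds, rep(0, 4)), class = "ahadjust_input_error")
  expect_error(km_curve(ds, rep(1, 3)), class = "ahadjust_input_error")
  expect_error(step_curve(c(0.5, 0.2), c(0.9, 0.8)),
               class = "ahadjust_input_error")
  expect_error(step_curve(c(0.2, 0.5), c(0.5, 0.9)),
               class = "ahadjust_input_error")
})
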