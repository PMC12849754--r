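# Propensity, outcome Cox, and censoring-survival model fits.

make_sim <- function(n, scenario = 1, censoring = "A", seed = 1) {
  set.seed(seed)
  make_dataset(n, scenario, censoring)
}

test_that("propensity fit has the closed-form solutions in degenerate designs", {
  ds <- make_sim(200, seed = 201)
  # intercept-only model: fitted scores are the sample treated fraction
  fit <- fit_propensity(ds, model_spec(treatment_terms = character(0)))
  expect_equal(unique(round(fit$fitted, 12)), round(mean(ds$group), 12))
  # single binary covariate: coefficient is the sample log odds ratio
  spec <- model_spec(treatment_terms = "X1")
  fit2 <- fit_propensity(ds, spec)
  tab <- table(ds$x$X1, ds$group)
  lor <- log(tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1]))
  expect_equal(unname(fit2$coef["X1"]), lor, tolerance = 1e-8)
})

test_that("logistic and Cox fits agree with independent likelihood maximizers", {
  set.seed(202)
  n <- 18
  x <- data.frame(X1 = rnorm(n))
  z <- rbinom(n, 1, 0.5)
  y <- rexp(n, exp(0.5 * x$X1))
  d <- rbinom(n, 1, 0.8)
  if (sum(d) < 2) d[1:2] <- 1
  ds <- tte_data(y, d, z, x)

  pfit <- fit_propensity(ds, model_spec(treatment_terms = "X1"))
  Xp <- cbind(1, x$X1)
  opt <- optim(c(0, 0), function(b) -logit_ll(b, z, Xp), method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(unname(pfit$coef), opt$par, tolerance = 1e-6)

  cfit <- fit_outcome_cox(ds, model_spec(outcome_terms = "X1"))
  Xc <- cbind(z, x$X1)
  optc <- optim(c(0, 0), function(b) -cox_pll(b, y, d, Xc), method = "BFGS",
                control = list(reltol = 1e-14))
  expect_equal(unname(cfit$coef), optc$par, tolerance = 1e-6)
})

test_that("Cox fit matches the survival package on simulated data", {
  ds <- make_sim(500, seed = 203)
  spec <- case_model_spec(1)
  fit <- fit_outcome_cox(ds, spec)
  df <- data.frame(y = ds$time, d = ds$status, z = ds$group, ds$x,
                   X5sq = ds$x$X5^2)
  ref <- survival::coxph(survival::Surv(y, d) ~ z + X1 + X2 + X4 + X5sq,
                         data = df, ties = "efron")
  expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-6)
  bh <- survival::basehaz(ref, centered = FALSE)
  idx <- findInterval(c(0.2, 0.5, 0.7), bh$time)
  idx2 <- findInterval(c(0.2, 0.5, 0.7), fit$basehaz_time)
  expect_equal(fit$basehaz[idx2], bh$hazard[idx], tolerance = 1e-4)
})

test_that("propensity coefficients recover the generating treatment model", {
  ds <- make_sim(1e5, seed = 204)
  fit <- fit_propensity(ds, model_spec(treatment_terms = c("X2", "X3", "X5", "X6")))
  truth <- c(-1.2, log(3), log(1.5), log(1.5), log(2))
  # ~3 standard errors at this sample size
  expect_equal(unname(fit$coef), truth, tolerance = Inf)
  expect_true(all(abs(fit$coef - truth) < 0.06))
})

test_that("Cox coefficients recover the generating outcome model (Scenario 2)", {
  ds <- make_sim(1e5, scenario = 2, seed = 205)
  fit <- fit_outcome_cox(ds, case_model_spec(1))
  truth <- c(-1, log(1.8), log(1.8), log(1.8), log(2.3))
  expect_true(all(abs(fit$coef - truth) < 0.05))
})

test_that("null Cox model baseline equals the Nelson-Aalen estimator", {
  ds <- make_sim(300, seed = 206)
  fit <- ahadjust:::cox_hazard_fit(ds$time, ds$status, ds$weights,
                                   matrix(numeric(0), ds$n, 0), character(0))
  na <- brute_na(ds$time, ds$status)
  expect_equal(fit$basehaz_time, na$time)
  expect_equal(fit$basehaz, na$cumhaz)
})

test_that("predicted Cox survival obeys the proportional-hazards structure", {
  ds <- make_sim(400, seed = 207)
  spec <- model_spec(outcome_terms = c("X1", "X4"))
  fit <- fit_outcome_cox(ds, spec)
  x0 <- data.frame(X1 = 0, X2 = 0, X3 = 0, X4 = 0, X5 = 0, X6 = 0)
  base <- predict_cox_survival(fit, x0, z = 0)
  expect_equal(base$surv, exp(-fit$basehaz))
  # a +log(2) shift in the linear predictor squares the survival pointwise
  xx <- x0; xx$X1 <- log(2) / fit$coef["X1"]
  shifted <- predict_cox_survival(fit, xx, z = 0)
  expect_equal(shifted$surv, base$surv^2, tolerance = 1e-12)
  # larger linear predictor -> pointwise smaller survival, S(0) = 1 region
  expect_true(all(shifted$surv <= base$surv))
  expect_true(all(diff(shifted$surv) <= 1e-12))
  expect_error(predict_cox_survival(fit, data.frame(bad = 1), 0),
               class = "ahadjust_input_error")
})

test_that("censoring fits cover the degenerate and role-reversed cases", {
  # no censoring: G = 1 everywhere, so IPCW weights are exactly 1
  ds <- tte_data(rexp(50, 2), rep(1, 50), rep(0:1, 25))
  cfit <- fit_censoring(ds, model_spec())
  expect_equal(censoring_surv_left(cfit, ds$time, ds), rep(1, 50))
  # all censored: G is the KM of the observed times
  ds2 <- tte_data(c(0.2, 0.4, 0.5), c(0, 0, 0), c(0, 0, 0))
  cfit2 <- fit_censoring(ds2, model_spec())
  expect_equal(cfit2$curve$time, c(0.2, 0.4, 0.5))
  expect_equal(cfit2$curve$surv, c(2 / 3, 1 / 3, 0))
  # left-limit evaluation: a subject's own censoring jump does not count
  expect_equal(surv_left(cfit2$curve, 0.4), 2 / 3)
  expect_equal(surv_at(cfit2$curve, 0.4), 1 / 3)
})

test_that("covariate-dependent censoring is detected by the Cox censoring model", {
  set.seed(209)
  ds <- make_dataset(1e5, 1, "C")
  cfit <- fit_censoring(ds, model_spec(censoring = "cox", censoring_terms = "X2"))
  # X2 raises the censoring rate from 0.01 to 0.41; the administrative cap
  # makes the observed censoring hazard non-proportional, so only the
  # direction (clearly positive) is asserted
  expect_gt(cfit$fit$coef["X2"], 0.3)
})

test_that("model fits raise typed errors for impossible inputs", {
  ds <- make_sim(50, seed = 210)
  allsame <- tte_data(ds$time, ds$status, rep(1, 50), ds$x)
  expect_error(fit_propensity(allsame, model_spec(treatment_terms = "X4")),
               class = "ahadjust_input_error")
  no_events <- tte_data(ds$time, rep(0, 50), ds$group, ds$x)
  expect_error(fit_outcome_cox(no_events, case_model_spec(1)),
               class = "ahadjust_fit_error")
  dup <- ds
  dup$x$X7 <- dup$x$X1
  expect_error(fit_propensity(dup, model_spec(treatment_terms = c("X1", "X7"))),
               class = "ahadjust_input_error")
})
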