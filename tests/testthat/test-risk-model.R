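make_units <- function(n, spacing = 100) {
  data.frame(unit_id = seq_len(n), x_km = (seq_len(n) - 0.5) * spacing,
             y_km = 0)
}

test_that("impact zones expose units within 30 km and not beyond", {
  units <- data.frame(unit_id = 1L, x_km = 0, y_km = 0)
  near <- data.frame(x_km = 25, y_km = 0, year = 2000L, fatalities = 3L)
  far <- data.frame(x_km = 35, y_km = 0, year = 2000L, fatalities = 3L)
  expect_equal(nrow(assign_exposure(units, near, 30)), 1)
  expect_equal(assign_exposure(units, near, 30)$n_events, 1L)
  expect_equal(nrow(assign_exposure(units, far, 30)), 0)
  expect_error(assign_exposure(units, near, -1), "radius_km")
})

test_that("exposure tallies equal the brute-force unit-event double loop", {
  set.seed(11)
  units <- expand.grid(row = 1:20, col = 1:20)
  units <- data.frame(unit_id = seq_len(400),
                      x_km = (units$col - 0.5) * 10,
                      y_km = (units$row - 0.5) * 10)
  events <- data.frame(
    x_km = runif(50, 0, 200), y_km = runif(50, 0, 200),
    year = sample(2000:2005, 50, replace = TRUE),
    fatalities = rpois(50, 4))
  got <- assign_exposure(units, events, 30)
  want <- exposure_oracle(units, events, 30)
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$n_events, want$n_events)
  expect_equal(got$n_fatalities, want$n_fatalities)
  # order of the event list does not matter
  flip <- assign_exposure(units, events[sample.int(50), ], 30)
  expect_equal(flip$n_events, got$n_events)
})

test_that("predictors summarize the calibration window with censoring", {
  units <- make_units(3) # centroids at x = 50, 150, 250
  # unit 1 exposed in years 3 and 7 of a 10-year window; unit 2 never;
  # unit 3 exposed only after the window closes
  events <- data.frame(x_km = c(50, 50, 250), y_km = 0,
                       year = c(2002, 2006, 2012),
                       fatalities = c(2L, 5L, 1L))
  tal <- assign_exposure(units, events, 10)
  pred <- build_predictors(tal, c(2000, 2009))
  expect_equal(pred$n_events[1], 2L)
  expect_equal(pred$n_fatalities[1], 7L)
  expect_equal(pred$years_since_last[1], 3) # 2009 - 2006
  expect_equal(pred$years_since_last[2], 11) # censored: window length + 1
  expect_equal(pred$n_events[2], 0L)
  # events outside the window are invisible
  expect_equal(pred$n_events[3], 0L)
  # custom censor value is honoured
  expect_equal(build_predictors(tal, c(2000, 2009),
                                censor = 99)$years_since_last[2], 99)
})

test_that("predictor rows match a per-unit brute-force scan", {
  set.seed(3)
  units <- make_units(15)
  events <- data.frame(x_km = runif(60, 0, 150), y_km = runif(60, -5, 5),
                       year = sample(2000:2009, 60, replace = TRUE),
                       fatalities = rpois(60, 3))
  tal <- assign_exposure(units, events, 12)
  pred <- build_predictors(tal, c(2000, 2007))
  for (i in seq_len(nrow(units))) {
    d <- sqrt((events$x_km - units$x_km[i])^2 +
                (events$y_km - units$y_km[i])^2)
    hit <- d <= 12 & events$year >= 2000 & events$year <= 2007
    expect_equal(pred$n_events[i], sum(hit))
    expect_equal(pred$n_fatalities[i], sum(events$fatalities[hit]))
    expect_equal(pred$years_since_last[i],
                 if (any(hit)) 2007 - max(events$year[hit]) else 9)
  }
})

test_that("response labels presence in the validation window only", {
  units <- make_units(3)
  events <- data.frame(x_km = c(50, 150), y_km = 0, year = c(2010, 2003),
                       fatalities = 0L)
  tal <- assign_exposure(units, events, 10)
  resp <- label_response(tal, c(2009, 2014), c(1999, 2008))
  expect_equal(resp$response, c(1L, 0L, 0L))
  expect_error(label_response(tal, c(2005, 2010), c(1999, 2008)),
               "must start after")
  none <- assign_exposure(units, events[0, ], 10)
  expect_true(all(label_response(none, c(2009, 2014))$response == 0L))
})

test_that("logistic fit recovers known coefficients and errors on degenerate input", {
  set.seed(42)
  n <- 5000
  pred <- data.frame(unit_id = seq_len(n),
                     n_events = rpois(n, 2),
                     n_fatalities = rpois(n, 6),
                     years_since_last = sample(0:11, n, replace = TRUE))
  beta <- c(-3, 0.4, 0.02, -0.3)
  eta <- beta[1] + beta[2] * pred$n_events + beta[3] * pred$n_fatalities +
    beta[4] * pred$years_since_last
  y <- rbinom(n, 1, plogis(eta))
  fit <- fit_risk_model(pred, y)
  expect_true(all(abs(fit$coefficients - beta) < 3 * fit$se))
  expect_gt(fit$pseudo_r2, 0)
  expect_true(all(fit$z == fit$coefficients / fit$se))
  # log-likelihood of the fitted model can never fall below the null's
  expect_gte(fit$loglik_model, fit$loglik_null)

  expect_error(fit_risk_model(pred, rep(0L, n)), "no variation")
  expect_error(fit_risk_model(pred[1:3, ], y[1:3]), "at least 4")
})

test_that("zero-variance predictors collapse to the null model", {
  set.seed(1)
  pred <- data.frame(unit_id = 1:200, n_events = 1L, n_fatalities = 0L,
                     years_since_last = 11)
  y <- rbinom(200, 1, 0.3)
  fit <- fit_risk_model(pred, y)
  expect_equal(fit$pseudo_r2, 0)
  expect_equal(unname(fit$coefficients[-1]), c(0, 0, 0))
})

test_that("perfect separation is reported with the offending covariate", {
  pred <- data.frame(unit_id = 1:40, n_events = rep(c(0L, 10L), each = 20),
                     n_fatalities = 0L, years_since_last = 5)
  y <- rep(c(0L, 1L), each = 20)
  expect_error(fit_risk_model(pred, y), "n_events")
})

test_that("risk prediction is the inverse-logit of the linear predictor", {
  model <- structure(list(
    coefficients = c(`(Intercept)` = -3, n_events = 0.4,
                     n_fatalities = 0.02, years_since_last = -0.3),
    vcov = matrix(0, 4, 4), log1p_fatalities = FALSE
  ), class = "cp_risk_model")
  pred <- data.frame(unit_id = 1L, n_events = 5, n_fatalities = 10,
                     years_since_last = 2)
  est <- predict_risk(model, pred)
  expect_equal(est$p, plogis(-3 + 0.4 * 5 + 0.02 * 10 - 0.3 * 2)) # -1.4
  # degenerate (zero-variance) coefficients give a zero-width interval
  expect_equal(est$ci_low, est$p)
  expect_equal(est$ci_high, est$p)

  # linear predictor exactly 0 maps to p = 0.5
  p0 <- data.frame(unit_id = 1L, n_events = 7.5, n_fatalities = 0,
                   years_since_last = 0)
  expect_equal(predict_risk(model, p0)$p, 0.5)

  expect_error(predict_risk(model, data.frame(unit_id = 1, n_events = 1)),
               "lack column")
})

test_that("fitted-model predictions keep CI ordering and monotonicity", {
  set.seed(9)
  n <- 800
  pred <- data.frame(unit_id = seq_len(n), n_events = rpois(n, 2),
                     n_fatalities = rpois(n, 5),
                     years_since_last = sample(0:11, n, replace = TRUE))
  eta <- -2 + 0.5 * pred$n_events - 0.2 * pred$years_since_last
  fit <- fit_risk_model(pred, rbinom(n, 1, plogis(eta)))
  est <- predict_risk(fit, pred)
  expect_true(all(est$ci_low <= est$p & est$p <= est$ci_high))
  expect_true(all(est$p >= 0 & est$ci_high <= 1))

  stopifnot(fit$coefficients["n_events"] > 0)
  base <- data.frame(unit_id = 1, n_events = 0:10, n_fatalities = 2,
                     years_since_last = 4)
  expect_true(all(diff(predict_risk(fit, base)$p) > 0))
})
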