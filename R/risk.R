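#' Assign conflict exposure via impact zones
#'
#' The footprint of an armed-conflict incident extends beyond its exact
#' location (movement of conflict actors and refugees), so each incident is
#' surrounded by an impact zone: a planning unit is deemed to have
#' experienced the incident iff the Euclidean distance from its centroid to
#' the event is at most `radius_km` (default 30 km). One event can expose
#' many units.
#'
#' @param units Planning-unit data frame with `unit_id`, `x_km`, `y_km`.
#' @param events Event data frame with `x_km`, `y_km`, `year`, `fatalities`.
#' @param radius_km Impact-zone radius in km (default 30).
#' @return A `cp_exposure` object: data frame of per-unit per-year tallies
#'   (`unit_id`, `year`, `n_events`, `n_fatalities`; only exposed
#'   unit-years appear) with the full unit-id universe kept as an attribute.
#' @export
assign_exposure <- function(units, events, radius_km = 30) {
  check_number(radius_km, "radius_km", 0)
  stopifnot(all(c("unit_id", "x_km", "y_km") %in% names(units)))
  req <- c("x_km", "y_km", "year", "fatalities")
  stopifnot(all(req %in% names(events)))
  if (any(events$fatalities < 0)) stopf("fatalities must be >= 0")

  pairs <- vector("list", nrow(events))
  if (nrow(events) > 0) {
    for (i in seq_len(nrow(events))) {
      d2 <- (units$x_km - events$x_km[i])^2 + (units$y_km - events$y_km[i])^2
      hit <- which(d2 <= radius_km^2)
      if (length(hit) > 0) {
        pairs[[i]] <- data.frame(unit_id = units$unit_id[hit],
                                 year = events$year[i],
                                 fatalities = events$fatalities[i])
      }
    }
  }
  pairs <- pairs[!vapply(pairs, is.null, logical(1))]
  if (length(pairs) == 0) {
    tallies <- data.frame(unit_id = integer(), year = integer(),
                          n_events = integer(), n_fatalities = integer())
  } else {
    pu <- do.call(rbind, pairs)
    key <- interaction(pu$unit_id, pu$year, drop = TRUE)
    tallies <- data.frame(
      unit_id = tapply(pu$unit_id, key, `[`, 1),
      year = tapply(pu$year, key, `[`, 1),
      n_events = as.integer(tapply(rep(1L, nrow(pu)), key, sum)),
      n_fatalities = as.integer(tapply(pu$fatalities, key, sum))
    )
    tallies <- tallies[order(tallies$unit_id, tallies$year), ]
    rownames(tallies) <- NULL
  }
  structure(tallies, unit_ids = units$unit_id, radius_km = radius_km,
            class = c("cp_exposure", "data.frame"))
}

#' Build per-unit conflict-history predictors
#'
#' Restricts exposure tallies to a calibration window and summarizes them
#' into the three predictors of the logistic risk model: number of exposing
#' incidents, summed fatalities of those incidents, and years since the
#' last incident (window end minus last exposure year). Units never exposed
#' in the window receive a censored value, by default window length + 1.
#'
#' @param tallies A `cp_exposure` from [assign_exposure()].
#' @param calibration_window Inclusive year span `c(start, end)`.
#' @param censor Value of `years_since_last` for never-exposed units;
#'   default `NULL` means window length + 1.
#' @return Data frame: `unit_id`, `n_events`, `n_fatalities`,
#'   `years_since_last`, one row per unit in the universe.
#' @export
build_predictors <- function(tallies, calibration_window, censor = NULL) {
  stopifnot(inherits(tallies, "cp_exposure"))
  win <- check_year_span(calibration_window, "calibration_window")
  win_len <- win[2] - win[1] + 1L
  censor <- censor %||% (win_len + 1L)
  check_number(censor, "censor", 0)

  ids <- attr(tallies, "unit_ids")
  out <- data.frame(unit_id = ids, n_events = 0L, n_fatalities = 0L,
                    years_since_last = censor)
  keep <- tallies$year >= win[1] & tallies$year <= win[2]
  tw <- tallies[keep, , drop = FALSE]
  if (nrow(tw) > 0) {
    idx <- match(tw$unit_id, ids)
    ne <- tapply(tw$n_events, idx, sum)
    nf <- tapply(tw$n_fatalities, idx, sum)
    last <- tapply(tw$year, idx, max)
    at <- as.integer(names(ne))
    out$n_events[at] <- as.integer(ne)
    out$n_fatalities[at] <- as.integer(nf)
    out$years_since_last[at] <- win[2] - as.integer(last)
  }
  out
}

#' Label the presence/absence response
#'
#' Binary response for the risk model: 1 iff the unit was exposed to at
#' least one incident during the validation window. When the calibration
#' window is supplied, it must end before the validation window begins.
#'
#' @param tallies A `cp_exposure` from [assign_exposure()].
#' @param validation_window Inclusive year span `c(start, end)`.
#' @param calibration_window Optional span used to check the windows are
#'   disjoint and ordered.
#' @return Data frame: `unit_id`, `response` (0/1).
#' @export
label_response <- function(tallies, validation_window,
                           calibration_window = NULL) {
  stopifnot(inherits(tallies, "cp_exposure"))
  win <- check_year_span(validation_window, "validation_window")
  if (!is.null(calibration_window)) {
    cal <- check_year_span(calibration_window, "calibration_window")
    if (cal[2] >= win[1]) {
      stopf("validation window (%d-%d) must start after the calibration window ends (%d)",
            win[1], win[2], cal[2])
    }
  }
  ids <- attr(tallies, "unit_ids")
  hit <- unique(tallies$unit_id[tallies$year >= win[1] &
                                  tallies$year <= win[2]])
  data.frame(unit_id = ids, response = as.integer(ids %in% hit))
}

#' Fit the logistic conflict-risk model
#'
#' Maximum-likelihood logistic regression of incident presence/absence on
#' the three conflict-history predictors (incident count, fatalities, years
#' since last incident). Fitting uses iteratively reweighted least squares
#' ([stats::glm()]); standard errors come from the observed information,
#' and fit is summarized by McFadden's pseudo-R-squared,
#' `1 - logLik(model) / logLik(null)`.
#'
#' @param predictors Data frame from [build_predictors()].
#' @param response Data frame from [label_response()] (matched on
#'   `unit_id`) or a 0/1 vector in `predictors` row order.
#' @param log1p_fatalities Apply `log1p` to the fatality covariate before
#'   fitting (default `FALSE`: fatalities enter untransformed).
#' @return A `cp_risk_model` with elements `coefficients`, `se`, `z`,
#'   `p_value`, `vcov`, `loglik_model`, `loglik_null`, `pseudo_r2`,
#'   `n`, `converged`, `log1p_fatalities`.
#' @export
fit_risk_model <- function(predictors, response, log1p_fatalities = FALSE) {
  req <- c("unit_id", "n_events", "n_fatalities", "years_since_last")
  stopifnot(all(req %in% names(predictors)))
  if (is.data.frame(response)) {
    response <- response$response[match(predictors$unit_id, response$unit_id)]
  }
  if (anyNA(response) || !all(response %in% c(0, 1))) {
    stopf("response must be 0/1 for every unit in `predictors`")
  }
  if (nrow(predictors) < 4) stopf("need at least 4 observations")
  if (length(unique(response)) < 2) {
    stopf("response has no variation (all %d); cannot fit", response[1])
  }

  d <- data.frame(
    response = response,
    n_events = predictors$n_events,
    n_fatalities = if (log1p_fatalities) log1p(predictors$n_fatalities)
                   else predictors$n_fatalities,
    years_since_last = predictors$years_since_last
  )
  covars <- c("n_events", "n_fatalities", "years_since_last")
  # zero-variance covariates carry no information: they enter with a zero
  # coefficient instead of breaking the fit (intercept-only in the limit)
  active <- covars[vapply(covars, function(v) sd(d[[v]]) > 0, logical(1))]
  form <- if (length(active) == 0) response ~ 1 else {
    stats::reformulate(active, response = "response")
  }
  fit <- suppressWarnings(
    glm(form, data = d, family = binomial(), control = list(maxit = 100,
                                                            epsilon = 1e-8))
  )
  cf_fit <- coef(fit)
  if (anyNA(cf_fit)) {
    bad <- names(cf_fit)[is.na(cf_fit)]
    stopf("covariate `%s` is collinear/degenerate; cannot fit", bad[1])
  }
  fitted_p <- fit$fitted.values
  separated <- length(active) > 0 &&
    all(fitted_p[d$response == 1] > 1 - 1e-6) &&
    all(fitted_p[d$response == 0] < 1e-6)
  if (!fit$converged || separated) {
    infl <- abs(cf_fit[-1]) *
      vapply(active, function(v) sd(d[[v]]), numeric(1))
    stopf("logistic fit failed (separation or non-convergence); offending covariate: `%s`",
          active[which.max(infl)])
  }
  all_terms <- c("(Intercept)", covars)
  cf <- setNames(numeric(4), all_terms)
  se <- setNames(numeric(4), all_terms)
  V <- matrix(0, 4, 4, dimnames = list(all_terms, all_terms))
  cf[names(cf_fit)] <- cf_fit
  se[names(cf_fit)] <- sqrt(diag(vcov(fit)))
  V[names(cf_fit), names(cf_fit)] <- vcov(fit)
  ll <- as.numeric(logLik(fit))
  ll0 <- as.numeric(logLik(glm(response ~ 1, data = d, family = binomial())))
  z <- ifelse(se > 0, cf / se, 0)
  structure(list(
    coefficients = cf, se = se, z = z,
    p_value = 2 * pnorm(-abs(z)), vcov = V,
    loglik_model = ll, loglik_null = ll0,
    pseudo_r2 = 1 - ll / ll0, n = nrow(d),
    converged = fit$converged, log1p_fatalities = log1p_fatalities
  ), class = "cp_risk_model")
}

#' @export
print.cp_risk_model <- function(x, ...) {
  cat("<cp_risk_model> logistic conflict-risk model\n")
  tab <- data.frame(estimate = x$coefficients, se = x$se, z = x$z,
                    p = signif(x$p_value, 3))
  print(round(tab, 4))
  cat(sprintf("n = %d, logLik = %.2f (null %.2f), McFadden pseudo-R2 = %.3f\n",
              x$n, x$loglik_model, x$loglik_null, x$pseudo_r2))
  invisible(x)
}

model_matrix_for <- function(model, predictors) {
  req <- c("n_events", "n_fatalities", "years_since_last")
  missing <- setdiff(req, names(predictors))
  if (length(missing) > 0) {
    stopf("predictors lack column(s) required by the model: %s",
          paste(missing, collapse = ", "))
  }
  fat <- if (model$log1p_fatalities) log1p(predictors$n_fatalities)
         else predictors$n_fatalities
  cbind(1, predictors$n_events, fat, predictors$years_since_last)
}

#' Predict per-unit conflict risk with confidence limits
#'
#' Risk is the probability of at least one incident in the five-year
#' horizon: the inverse logit of the linear predictor. The 95% interval is
#' a normal interval on the link (logit) scale, transformed back, which
#' keeps both limits in `[0, 1]` and ordered around the point estimate.
#'
#' @param model A `cp_risk_model` from [fit_risk_model()].
#' @param predictors Data frame with `unit_id`, `n_events`,
#'   `n_fatalities`, `years_since_last` (typically [build_predictors()] on
#'   the prediction window).
#' @param level Confidence level (default 0.95).
#' @return Data frame: `unit_id`, `p`, `ci_low`, `ci_high`, each in
#'   `[0, 1]` with `ci_low <= p <= ci_high`.
#' @export
predict_risk <- function(model, predictors, level = 0.95) {
  stopifnot(inherits(model, "cp_risk_model"))
  check_number(level, "level", 0, 1)
  X <- model_matrix_for(model, predictors)
  eta <- as.numeric(X %*% model$coefficients)
  se_eta <- sqrt(pmax(rowSums((X %*% model$vcov) * X), 0))
  zq <- qnorm(1 - (1 - level) / 2)
  data.frame(
    unit_id = predictors$unit_id,
    p = plogis(eta),
    ci_low = plogis(eta - zq * se_eta),
    ci_high = plogis(eta + zq * se_eta)
  )
}
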