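#' Aggregate fine-scale risk to the national scale
#'
#' National-scale planning sees only one risk value per nation. Here that
#' value is the within-nation mean of the fine-scale estimates, which
#' preserves the average risk while destroying all within-nation
#' variation — the property that distinguishes the two scales.
#'
#' @param units Planning-unit data frame with `unit_id` and `nation_id`.
#' @param fine_risk Fine-scale risk: data frame (`unit_id`, `p`, optional
#'   `ci_low`/`ci_high`) or vector aligned with `units`.
#' @return Data frame (`unit_id`, `p`, and averaged `ci_low`/`ci_high`
#'   when supplied) with zero within-nation variance.
#' @export
national_risk <- function(units, fine_risk) {
  if (!"nation_id" %in% names(units) || anyNA(units$nation_id)) {
    stopf("every unit must carry a non-missing nation_id")
  }
  if (!is.data.frame(fine_risk)) {
    fine_risk <- data.frame(unit_id = units$unit_id,
                            p = as_risk_vector(fine_risk, units$unit_id))
  }
  idx <- match(units$unit_id, fine_risk$unit_id)
  if (anyNA(idx)) stopf("fine_risk missing for some units")
  out <- data.frame(unit_id = units$unit_id,
                    p = ave(fine_risk$p[idx], units$nation_id))
  for (col in c("ci_low", "ci_high")) {
    if (col %in% names(fine_risk)) {
      out[[col]] <- ave(fine_risk[[col]][idx], units$nation_id)
    }
  }
  out
}

# Default analysis windows over a conflict-history span: hold the last
# few years out for validation, calibrate on everything before, and build
# prediction predictors from the most recent ten years.
derive_windows <- function(years) {
  n <- years[2] - years[1] + 1L
  if (n < 2) stopf("need at least 2 years of history to fit a risk model")
  val_len <- max(1L, min(5L, n %/% 3L))
  list(calibration = c(years[1], years[2] - val_len),
       validation = c(years[2] - val_len + 1L, years[2]),
       prediction = c(max(years[1], years[2] - 9L), years[2]))
}

#' Full-pipeline run configuration
#'
#' @param landscape A [landscape_config()].
#' @param conflict A [conflict_config()]; the default couples hotspot
#'   placement to species richness (`biodiversity_coupling = 2`),
#'   reproducing the biodiversity-risk association that makes conflict
#'   ignorance costly.
#' @param strategies Character vector of strategies to sweep.
#' @param thresholds Sorted risk-threshold grid in `[0, 1]` for the
#'   avoiding/sensitive strategies (default 0 to 1 in 0.05 steps).
#' @param reliability,target_fraction Passed to [strategy_spec()].
#' @param risk_scales Subset of `c("fine", "national")`.
#' @param risk_bounds Subset of `c("point", "ci_low", "ci_high")`:
#'   which risk estimate planning uses (evaluation always uses the
#'   fine-scale point estimate).
#' @param impact_radius_km Impact-zone radius (default 30 km).
#' @param calibration_window,validation_window,prediction_window Year
#'   spans; `NULL` derives them from the conflict config's span
#'   (validation = last years held out, prediction = last 10 years).
#' @param solver A [solver_config()].
#' @param evaluation An [evaluation_config()].
#' @param seed Master seed; all stage seeds derive from it.
#' @return A `cp_run_config` list.
#' @export
run_config <- function(landscape = landscape_config(),
                       conflict = conflict_config(biodiversity_coupling = 2),
                       strategies = c("ignorant", "avoiding", "accounting",
                                      "sensitive"),
                       thresholds = seq(0, 1, by = 0.05),
                       reliability = 0.95, target_fraction = 0.30,
                       risk_scales = c("fine", "national"),
                       risk_bounds = "point",
                       impact_radius_km = 30,
                       calibration_window = NULL, validation_window = NULL,
                       prediction_window = NULL,
                       solver = solver_config(),
                       evaluation = evaluation_config(),
                       seed = 42L) {
  stopifnot(inherits(landscape, "cp_landscape_config"),
            inherits(conflict, "cp_conflict_config"),
            inherits(solver, "cp_solver_config"),
            inherits(evaluation, "cp_evaluation_config"))
  strategies <- match.arg(strategies, c("ignorant", "avoiding", "accounting",
                                        "sensitive"), several.ok = TRUE)
  risk_scales <- match.arg(risk_scales, c("fine", "national"),
                           several.ok = TRUE)
  risk_bounds <- match.arg(risk_bounds, c("point", "ci_low", "ci_high"),
                           several.ok = TRUE)
  if (any(thresholds < 0 | thresholds > 1) || is.unsorted(thresholds)) {
    stopf("thresholds must be a sorted grid within [0, 1]")
  }
  check_number(impact_radius_km, "impact_radius_km", 0)
  check_number(seed, "seed", integer = TRUE)
  w <- derive_windows(conflict$years)
  structure(list(
    landscape = landscape, conflict = conflict, strategies = strategies,
    thresholds = thresholds, reliability = reliability,
    target_fraction = target_fraction, risk_scales = risk_scales,
    risk_bounds = risk_bounds, impact_radius_km = impact_radius_km,
    calibration_window = calibration_window %||% w$calibration,
    validation_window = validation_window %||% w$validation,
    prediction_window = prediction_window %||% w$prediction,
    solver = solver, evaluation = evaluation, seed = as.integer(seed)
  ), class = "cp_run_config")
}

plan_and_evaluate <- function(units, features, plan_risk, eval_risk, spec,
                              solver_cfg, eval_cfg, seed,
                              reliability_solver = NULL) {
  problem <- apply_strategy(units, plan_risk, features, spec)
  rel_converged <- NA
  if (spec$name %in% c("accounting", "sensitive")) {
    problem <- enforce_reliability(problem,
                                   solver_cfg = reliability_solver,
                                   seed = seed)
    rel_converged <- attr(problem, "converged")
  }
  scfg <- solver_cfg
  scfg$seed <- seed
  ens <- run_ensemble(problem, scfg)
  best <- ens$best
  feasible <- !is.null(best)
  if (!feasible) { # best infeasible run: least shortfall, then cost
    short <- vapply(ens$solutions, function(s) {
      sum(pmax(problem$target - s$representation, 0))
    }, numeric(1))
    cost <- vapply(ens$solutions, function(s) s$total_cost_usd, numeric(1))
    best <- ens$solutions[[order(short, cost)[1]]]
  }
  ecfg <- eval_cfg
  ecfg$seed <- seed + 500000L
  report <- evaluate_network(best, problem, ecfg, risks = eval_risk)
  list(problem = problem, ensemble = ens, best = best, report = report,
       feasible = feasible, reliability_converged = rel_converged)
}

#' Sweep strategies, thresholds, risk scales and bounds
#'
#' The end-to-end comparison: generate (or accept) a landscape and
#' conflict history, fit the risk model, and for every requested
#' combination of strategy, threshold, risk scale and risk bound, build
#' the problem, enforce reliability where applicable, solve an ensemble,
#' and evaluate the best network by Monte Carlo — one row per combination.
#' Threshold-independent strategies (ignorant, accounting) are solved once
#' per scale/bound and replicated across the threshold grid. Evaluation
#' always uses the fine-scale point risk estimates, so rows are
#' comparable.
#'
#' @param cfg A [run_config()].
#' @param landscape Optional pre-built `cp_landscape` (otherwise generated
#'   from `cfg$landscape`).
#' @param events Optional pre-built event table (otherwise generated from
#'   `cfg$conflict`).
#' @param quiet Suppress per-stage progress messages.
#' @return A `cp_sweep` data frame: `strategy`, `threshold`, `risk_scale`,
#'   `risk_bound`, `targets_met_median`, `targets_met_lo`,
#'   `targets_met_hi`, `total_cost_usd`, `roi_targets_per_billion`,
#'   `abandoned`, `feasible`, `reliability_converged`. The fitted risk
#'   model and landscape ride along as attributes `risk_model`,
#'   `landscape`, `risk_estimates`.
#' @export
run_sweep <- function(cfg, landscape = NULL, events = NULL, quiet = FALSE) {
  stopifnot(inherits(cfg, "cp_run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))

  say("generating landscape (%dx%d)...", cfg$landscape$n_rows,
      cfg$landscape$n_cols)
  land <- landscape %||% generate_landscape(cfg$landscape)
  ev <- events %||% generate_conflict_history(cfg$conflict, land)
  say("assigning exposure for %d events...", nrow(ev))
  tallies <- assign_exposure(land$units, ev, cfg$impact_radius_km)

  say("fitting risk model (calibration %d-%d, validation %d-%d)...",
      cfg$calibration_window[1], cfg$calibration_window[2],
      cfg$validation_window[1], cfg$validation_window[2])
  pred_cal <- build_predictors(tallies, cfg$calibration_window)
  resp <- label_response(tallies, cfg$validation_window,
                         cfg$calibration_window)
  model <- fit_risk_model(pred_cal, resp)
  pred_now <- build_predictors(tallies, cfg$prediction_window)
  fine <- predict_risk(model, pred_now)

  risk_layers <- list(fine = fine)
  if ("national" %in% cfg$risk_scales) {
    risk_layers$national <- national_risk(land$units, fine)
  }
  eval_risk <- fine[, c("unit_id", "p")]

  rows <- list()
  combo <- 0L
  for (scale in cfg$risk_scales) {
    for (bound in cfg$risk_bounds) {
      layer <- risk_layers[[scale]]
      col <- switch(bound, point = "p", ci_low = "ci_low",
                    ci_high = "ci_high")
      plan_risk <- data.frame(unit_id = layer$unit_id, p = layer[[col]])
      for (strat in cfg$strategies) {
        thetas <- if (strat %in% c("avoiding", "sensitive")) {
          cfg$thresholds
        } else {
          cfg$thresholds[1] # unused by the strategy; computed once
        }
        for (theta in thetas) {
          combo <- combo + 1L
          say("[%s | %s | %s | theta=%.2f]", strat, scale, bound, theta)
          spec <- strategy_spec(strat, threshold = theta,
                                reliability = cfg$reliability,
                                target_fraction = cfg$target_fraction)
          res <- plan_and_evaluate(
            land$units, land$features, plan_risk, eval_risk, spec,
            cfg$solver, cfg$evaluation, seed = cfg$seed + 1000L * combo,
            reliability_solver = NULL)
          r <- res$report
          base <- data.frame(
            strategy = strat, threshold = theta, risk_scale = scale,
            risk_bound = bound,
            targets_met_median = r$median_targets_met,
            targets_met_lo = r$ci[1], targets_met_hi = r$ci[2],
            total_cost_usd = r$total_cost_usd,
            roi_targets_per_billion = r$roi_targets_per_billion,
            abandoned = r$abandoned, feasible = res$feasible,
            reliability_converged = res$reliability_converged,
            stringsAsFactors = FALSE
          )
          if (!strat %in% c("avoiding", "sensitive")) {
            # theta plays no role: replicate the row across the grid
            base <- base[rep(1L, length(cfg$thresholds)), ]
            base$threshold <- cfg$thresholds
          }
          rows[[length(rows) + 1L]] <- base
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "risk_model") <- model
  attr(out, "landscape") <- land
  attr(out, "risk_estimates") <- fine
  class(out) <- c("cp_sweep", "data.frame")
  out
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Convenience hook for correlating per-region biodiversity totals with
#' historical spending totals: mid-ranks are assigned (exact tie
#' handling), the Pearson correlation of the ranks gives `rs`, and the
#' two-sided p-value uses the t approximation
#' `t = rs * sqrt((n - 2) / (1 - rs^2))` on `n - 2` degrees of freedom.
#'
#' @param biodiversity,spending Paired numeric vectors, `n >= 4`.
#' @return List: `estimate` (rs), `p_value`, `n`.
#' @export
spending_correlation <- function(biodiversity, spending) {
  if (length(biodiversity) != length(spending)) {
    stopf("vectors must be paired (equal length)")
  }
  ok <- complete.cases(biodiversity, spending)
  x <- biodiversity[ok]
  y <- spending[ok]
  n <- length(x)
  if (n < 4) stopf("need at least 4 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    stopf("correlation undefined for a constant vector")
  }
  rs <- cor(rank(x), rank(y))
  p <- if (abs(rs) >= 1) 0 else {
    tt <- rs * sqrt((n - 2) / (1 - rs^2))
    2 * pt(-abs(tt), n - 2)
  }
  list(estimate = rs, p_value = p, n = n)
}
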