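# CSV/JSON dialects shared by the modules and the command-line wrapper.
# All readers validate the column contract and fail loudly on mismatch.

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stopf("%s is missing column(s): %s", what, paste(missing, collapse = ", "))
  }
  invisible(df)
}

#' Read and write the planning-table CSV dialects
#'
#' Planning units: `unit_id, row, col, x_km, y_km, area_km2, cost_usd,
#' status, nation_id`. Features (long): `feature_id, feature_class,
#' unit_id, amount_km2`. Events: `event_id, x_km, y_km, year, fatalities`.
#' Risk: `unit_id, p, ci_low, ci_high`.
#'
#' @param path File path.
#' @param x Object to write (matching data frame, or `cp_landscape` for
#'   [write_landscape_csv()]).
#' @param dir Directory for the landscape pair (`units.csv`,
#'   `features.csv`).
#' @return Readers return validated data frames; writers return their
#'   path(s) invisibly.
#' @name planning_io
NULL

#' @rdname planning_io
#' @export
read_units_csv <- function(path) {
  check_columns(read.csv(path), c("unit_id", "x_km", "y_km", "area_km2",
                                  "cost_usd", "status"), "units CSV")
}

#' @rdname planning_io
#' @export
read_features_csv <- function(path) {
  check_columns(read.csv(path), c("feature_id", "unit_id", "amount_km2"),
                "features CSV")
}

#' @rdname planning_io
#' @export
read_events_csv <- function(path) {
  ev <- check_columns(read.csv(path), c("x_km", "y_km", "year", "fatalities"),
                      "events CSV")
  if (any(ev$fatalities < 0)) stopf("events CSV has negative fatalities")
  ev
}

#' @rdname planning_io
#' @export
read_risk_csv <- function(path) {
  check_columns(read.csv(path), c("unit_id", "p"), "risk CSV")
}

#' @rdname planning_io
#' @export
write_landscape_csv <- function(x, dir) {
  stopifnot(inherits(x, "cp_landscape"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("units.csv", "features.csv"))
  write.csv(x$units, paths[1], row.names = FALSE)
  write.csv(x$features, paths[2], row.names = FALSE)
  invisible(paths)
}

#' @rdname planning_io
#' @export
write_events_csv <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname planning_io
#' @export
write_risk_csv <- function(x, path) {
  check_columns(x, c("unit_id", "p"), "risk table")
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Write a fitted risk model summary as JSON
#'
#' @param model A `cp_risk_model`.
#' @param path Output path.
#' @param windows Optional named list of year spans to record alongside
#'   the fit.
#' @return The path, invisibly.
#' @export
write_model_summary_json <- function(model, path, windows = NULL) {
  stopifnot(inherits(model, "cp_risk_model"))
  out <- list(
    coefficients = as.list(model$coefficients),
    se = as.list(model$se), z = as.list(model$z),
    p_value = as.list(model$p_value),
    pseudo_r2 = model$pseudo_r2,
    loglik_model = model$loglik_model, loglik_null = model$loglik_null,
    n = model$n, log1p_fatalities = model$log1p_fatalities
  )
  if (!is.null(windows)) out$windows <- windows
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write solver output tables
#'
#' The ensemble CSV has one row per unit (`unit_id`, `selected` in the
#' best solution, `frequency` across runs); the JSON summary records the
#' best solution's cost, feasibility and per-feature representation.
#'
#' @param ensemble A `cp_ensemble`.
#' @param csv_path,json_path Output paths (`NULL` to skip either).
#' @return The written paths, invisibly.
#' @export
write_ensemble_output <- function(ensemble, csv_path = NULL,
                                  json_path = NULL) {
  stopifnot(inherits(ensemble, "cp_ensemble"))
  best <- ensemble$best %||% ensemble$solutions[[1]]
  if (!is.null(csv_path)) {
    df <- data.frame(
      unit_id = names(ensemble$selection_frequency),
      selected = names(ensemble$selection_frequency) %in%
        as.character(best$selected),
      frequency = as.integer(ensemble$selection_frequency)
    )
    write.csv(df, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      total_cost_usd = best$total_cost_usd,
      feasible = best$feasible,
      n_selected = length(best$selected),
      n_runs = ensemble$n_runs,
      representation = as.list(best$representation)
    ), json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(c(csv_path, json_path))
}

#' Write an evaluation report as JSON (plus optional per-rep CSV)
#'
#' @param report A `cp_evaluation`.
#' @param json_path Summary JSON path.
#' @param reps_csv_path Optional per-replicate CSV (`rep`, `targets_met`).
#' @return The written paths, invisibly.
#' @export
write_report_json <- function(report, json_path, reps_csv_path = NULL) {
  stopifnot(inherits(report, "cp_evaluation"))
  jsonlite::write_json(list(
    median_targets_met = report$median_targets_met,
    targets_met_ci = report$ci,
    total_cost_usd = report$total_cost_usd,
    roi_targets_per_billion = report$roi_targets_per_billion,
    n_features = report$n_features,
    abandoned = report$abandoned,
    n_reps = length(report$targets_met),
    feature_met_freq = as.list(report$feature_met_freq)
  ), json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(reps_csv_path)) {
    write.csv(data.frame(rep = seq_along(report$targets_met),
                         targets_met = report$targets_met),
              reps_csv_path, row.names = FALSE)
  }
  invisible(c(json_path, reps_csv_path))
}
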