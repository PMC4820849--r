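#' Evaluation configuration
#'
#' @param n_reps Monte Carlo replicates (default 1000).
#' @param loss_mode `"continuous"` (unit lost iff `u < p`,
#'   `u ~ Uniform[0,1)`; unbiased, the default) or `"paper_integer"`
#'   (integer `r ~ DiscreteUniform{1..100}`, lost iff `r < 100 p` — the
#'   classic percent-roll rule, whose effective loss probability is
#'   `ceiling(100 p - 1) / 100`, at most 1% below `p`).
#' @param target_fraction Fraction of each feature's original total that
#'   must survive for its target to count as met (default 0.30).
#' @param seed Integer seed.
#' @return A `cp_evaluation_config` list.
#' @export
evaluation_config <- function(n_reps = 1000,
                              loss_mode = c("continuous", "paper_integer"),
                              target_fraction = 0.30, seed = 1L) {
  loss_mode <- match.arg(loss_mode)
  check_number(n_reps, "n_reps", 1, integer = TRUE)
  check_number(target_fraction, "target_fraction", 1e-9, 1)
  check_number(seed, "seed", integer = TRUE)
  structure(list(n_reps = as.integer(n_reps), loss_mode = loss_mode,
                 target_fraction = target_fraction, seed = as.integer(seed)),
            class = "cp_evaluation_config")
}

#' Simulate conflict losses of network units
#'
#' Draws, independently per unit and replicate, whether each unit is lost
#' to conflict during the management horizon. Every network unit —
#' locked-in or newly acquired — is at risk.
#'
#' @param risks Per-unit loss probabilities: named numeric vector or data
#'   frame (`unit_id`, `p`).
#' @param cfg An [evaluation_config()].
#' @return Logical matrix, `n_reps` rows by units (named columns): `TRUE`
#'   where the unit is lost in that replicate.
#' @export
simulate_losses <- function(risks, cfg = evaluation_config()) {
  stopifnot(inherits(cfg, "cp_evaluation_config"))
  if (is.data.frame(risks)) risks <- setNames(risks$p, risks$unit_id)
  if (any(risks < 0 | risks > 1) || anyNA(risks)) {
    stopf("risks must be probabilities in [0, 1]")
  }
  n <- length(risks)
  with_seed(cfg$seed, {
    lost <- if (cfg$loss_mode == "continuous") {
      matrix(runif(cfg$n_reps * n), cfg$n_reps, n) <
        rep(risks, each = cfg$n_reps)
    } else {
      matrix(sample.int(100, cfg$n_reps * n, replace = TRUE),
             cfg$n_reps, n) < rep(100 * risks, each = cfg$n_reps)
    }
    colnames(lost) <- names(risks)
    lost
  })
}

#' Evaluate a protected-area network under conflict losses
#'
#' Monte Carlo performance of a solved network: in each replicate, units
#' are lost according to their risk; a feature's target is met iff the raw
#' (undiscounted) amount surviving in the network reaches
#' `target_fraction` of the feature's original total. Reports the
#' distribution of the number of targets met, the network cost (newly
#' acquired units), and the return on investment — median targets met per
#' billion USD.
#'
#' @param solution A `cp_solution`.
#' @param problem The `cp_problem` it solved (supplies raw amounts and
#'   totals).
#' @param cfg An [evaluation_config()].
#' @param risks Per-unit evaluation risks (data frame `unit_id`, `p`, or
#'   vector over the problem's units). Defaults to the problem's planning
#'   risks; pass the fine-scale point estimates explicitly when planning
#'   used a different layer (national scale, or a confidence bound).
#' @return A `cp_evaluation`: `targets_met` (per-rep counts),
#'   `median_targets_met`, `ci` (2.5/97.5 percentiles), `total_cost_usd`,
#'   `roi_targets_per_billion`, `feature_met_freq`, `n_features`,
#'   `abandoned`.
#' @export
evaluate_network <- function(solution, problem, cfg = evaluation_config(),
                             risks = NULL) {
  stopifnot(inherits(solution, "cp_solution"), inherits(problem, "cp_problem"),
            inherits(cfg, "cp_evaluation_config"))
  if (!all(solution$selected %in% problem$unit_id)) {
    stopf("solution contains units outside the problem's unit universe")
  }
  p_all <- if (is.null(risks)) problem$risk else {
    as_risk_vector(risks, problem$unit_id)
  }
  sel_idx <- match(solution$selected, problem$unit_id)
  p_sel <- setNames(p_all[sel_idx], as.character(solution$selected))

  lost <- simulate_losses(p_sel, cfg)
  A_sel <- problem$amount_raw[, sel_idx, drop = FALSE]
  surviving <- (!lost) %*% t(A_sel) # reps x features
  need <- cfg$target_fraction * problem$total_raw
  met <- surviving >= rep(need, each = nrow(surviving)) - 1e-9
  targets_met <- as.integer(rowSums(met))

  med <- median(targets_met)
  cost <- solution$total_cost_usd
  structure(list(
    targets_met = targets_met,
    median_targets_met = med,
    ci = quantile(targets_met, c(0.025, 0.975), names = FALSE),
    total_cost_usd = cost,
    roi_targets_per_billion = med / (cost / 1e9),
    feature_met_freq = setNames(colMeans(met), rownames(problem$amount_raw)),
    n_features = nrow(problem$amount_raw),
    abandoned = count_abandoned(problem),
    cfg = cfg
  ), class = "cp_evaluation")
}

#' @export
print.cp_evaluation <- function(x, ...) {
  cat(sprintf(
    "<cp_evaluation> %d reps: median %g/%d targets met [%g, %g], cost %.3g USD, ROI %.3g targets/$bn\n",
    length(x$targets_met), x$median_targets_met, x$n_features,
    x$ci[1], x$ci[2], x$total_cost_usd, x$roi_targets_per_billion))
  invisible(x)
}

#' Exact expected number of targets met
#'
#' Analytic counterpart of [evaluate_network()]: the sum over features of
#' the exact probability (via [meeting_probability_hetero()]) that the
#' feature's surviving raw amount in the network reaches its target.
#' Features held in more than 20 selected units fall back to Monte Carlo
#' within the probability computation.
#'
#' @param solution A `cp_solution`.
#' @param problem The `cp_problem` it solved.
#' @param target_fraction Target fraction (default: the evaluation
#'   convention, 0.30).
#' @param risks Optional evaluation risks (as in [evaluate_network()]).
#' @param mc_reps Monte Carlo replicates for the >20-unit fallback.
#' @param seed Seed for the fallback draws.
#' @return Expected number of targets met (numeric).
#' @export
exact_expected_targets <- function(solution, problem, target_fraction = 0.30,
                                   risks = NULL, mc_reps = 20000, seed = 1L) {
  stopifnot(inherits(solution, "cp_solution"), inherits(problem, "cp_problem"))
  p_all <- if (is.null(risks)) problem$risk else {
    as_risk_vector(risks, problem$unit_id)
  }
  sel_idx <- match(solution$selected, problem$unit_id)
  total <- 0
  for (f in seq_len(nrow(problem$amount_raw))) {
    a <- problem$amount_raw[f, sel_idx]
    keep <- a > 0
    total <- total + as.numeric(meeting_probability_hetero(
      p_all[sel_idx][keep], a[keep],
      target_fraction * problem$total_raw[f],
      n_reps = mc_reps, seed = seed + f, warn = FALSE))
  }
  total
}
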