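#' Probability of meeting a target under equal unit-loss risk
#'
#' If `n_selected` units each protect one unit of a feature and each is
#' lost independently with probability `p_loss`, the target (needing
#' `n_required` surviving units) is met when the number of losses is at
#' most `n_selected - n_required`: a binomial tail. For example, a feature
#' needing 3 of its units protected, where each protected unit faces a 25%
#' loss chance, has a 96.2% chance of retaining its target if 6 units are
#' protected.
#'
#' @param n_selected Number of protected units (>= 0).
#' @param n_required Number that must survive (>= 0).
#' @param p_loss Per-unit loss probability in `[0, 1]`.
#' @return `P(losses <= n_selected - n_required)` for
#'   `losses ~ Binomial(n_selected, p_loss)`; 0 when
#'   `n_selected < n_required`.
#' @examples
#' meeting_probability(6, 3, 0.25) # 0.962
#' @export
meeting_probability <- function(n_selected, n_required, p_loss) {
  check_number(n_selected, "n_selected", 0, integer = TRUE)
  check_number(n_required, "n_required", 0, integer = TRUE)
  check_prob(p_loss, "p_loss")
  if (n_selected < n_required) return(0)
  pbinom(n_selected - n_required, n_selected, p_loss)
}

#' Probability of meeting a target under heterogeneous risks
#'
#' Generalizes [meeting_probability()] to units with unequal loss
#' probabilities and fractional amounts (a Poisson-binomial-type
#' computation on amounts): the probability that the summed amount over
#' surviving units reaches `target`. Exact by outcome enumeration for up to
#' `exact_limit` units; Monte Carlo (with a standard-error attribute)
#' beyond that.
#'
#' @param p_vector Per-unit loss probabilities in `[0, 1]`.
#' @param amounts Per-unit feature amounts (>= 0), same length.
#' @param target Required surviving amount.
#' @param exact_limit Largest unit count enumerated exactly (default 20).
#' @param n_reps Monte Carlo replicates above the limit (default 10000).
#' @param seed Optional seed for the Monte Carlo branch.
#' @param warn Warn when the target exceeds the total amount (default
#'   `TRUE`).
#' @return The meeting probability, with attributes `exact` (logical) and,
#'   for Monte Carlo, `se`. Returns 0 with a warning when
#'   `target > sum(amounts)`.
#' @export
meeting_probability_hetero <- function(p_vector, amounts, target,
                                       exact_limit = 20, n_reps = 10000,
                                       seed = NULL, warn = TRUE) {
  if (length(p_vector) != length(amounts)) {
    stopf("`p_vector` and `amounts` must have equal length")
  }
  if (any(p_vector < 0 | p_vector > 1)) stopf("loss probabilities must be in [0, 1]")
  if (any(amounts < 0)) stopf("amounts must be >= 0")
  check_number(target, "target")
  tol <- 1e-9
  if (target > sum(amounts) + tol) {
    if (warn) {
      warning("target exceeds the total amount; meeting probability is 0",
              call. = FALSE)
    }
    return(structure(0, exact = TRUE))
  }
  if (target <= tol) return(structure(1, exact = TRUE))

  n <- length(amounts)
  if (n <= exact_limit) {
    probs <- 1
    sums <- 0
    for (i in seq_len(n)) {
      sums <- c(sums + amounts[i], sums)
      probs <- c(probs * (1 - p_vector[i]), probs * p_vector[i])
    }
    return(structure(sum(probs[sums >= target - tol]), exact = TRUE))
  }
  with_seed(seed, {
    surv <- matrix(runif(n_reps * n), n_reps, n) >= rep(p_vector,
                                                        each = n_reps)
    s <- as.numeric(surv %*% amounts)
    est <- mean(s >= target - tol)
    structure(est, exact = FALSE,
              se = sqrt(est * (1 - est) / n_reps))
  })
}

#' Units needed to meet a target at a given reliability
#'
#' Smallest number of protected units such that, with per-unit loss
#' probability `p_loss`, at least `n_required` survive with probability at
#' least `rho`. Found by incrementing `n` and evaluating the binomial tail.
#'
#' @param n_required Units that must survive.
#' @param p_loss Per-unit loss probability, `< 1`.
#' @param rho Required reliability in `(0, 1)`.
#' @return The smallest sufficient integer `n`.
#' @examples
#' required_units(3, 0.25, 0.95) # 6: five units give ~0.896, six ~0.962
#' @export
required_units <- function(n_required, p_loss, rho) {
  check_number(n_required, "n_required", 0, integer = TRUE)
  check_prob(p_loss, "p_loss")
  if (p_loss >= 1) stopf("p_loss = 1: no number of units can meet the target")
  check_number(rho, "rho", 0, 1)
  if (rho >= 1) stopf("rho must be < 1")
  n <- n_required
  while (meeting_probability(n, n_required, p_loss) < rho) n <- n + 1L
  as.integer(n)
}

#' Strategy specification
#'
#' The four attitudes to conflict risk:
#' * `ignorant` — risk plays no role; plan on biodiversity and cost alone.
#' * `avoiding` — units with risk above `threshold` are unavailable.
#' * `accounting` — all units available, but feature amounts are discounted
#'   to their expected surviving value `a * (1 - p)` and targets are
#'   inflated until each feature's survival reliability reaches `reliability`.
#' * `sensitive` — `avoiding` then `accounting` on the remaining units.
#'
#' @param name One of `"ignorant"`, `"avoiding"`, `"accounting"`,
#'   `"sensitive"`.
#' @param threshold Maximum tolerable risk for avoiding/sensitive, in
#'   `[0, 1]` (default 0.35).
#' @param reliability Required per-feature survival probability for
#'   accounting/sensitive, in `(0, 1)` (default 0.95).
#' @param target_fraction Representation target as a fraction of each
#'   feature's total amount, in `(0, 1]` (default 0.30, the conventional
#'   30% of current extent).
#' @return A `cp_strategy` list.
#' @export
strategy_spec <- function(name = c("ignorant", "avoiding", "accounting",
                                   "sensitive"),
                          threshold = 0.35, reliability = 0.95,
                          target_fraction = 0.30) {
  name <- match.arg(name)
  check_prob(threshold, "threshold")
  check_number(reliability, "reliability", 1e-9, 1 - 1e-9)
  check_number(target_fraction, "target_fraction", 1e-9, 1)
  structure(list(name = name, threshold = threshold,
                 reliability = reliability,
                 target_fraction = target_fraction),
            class = "cp_strategy")
}

# Dense feature-by-unit amount matrix from the long feature table.
feature_matrix <- function(features, unit_ids) {
  fid <- sort(unique(features$feature_id))
  A <- matrix(0, length(fid), length(unit_ids),
              dimnames = list(fid, as.character(unit_ids)))
  A[cbind(match(features$feature_id, fid),
          match(features$unit_id, unit_ids))] <- features$amount_km2
  A
}

as_risk_vector <- function(risks, unit_ids) {
  if (is.data.frame(risks)) {
    p <- risks$p[match(unit_ids, risks$unit_id)]
  } else if (length(risks) == length(unit_ids)) {
    p <- as.numeric(risks)
  } else {
    stopf("risks must be a data frame (unit_id, p) or a vector aligned with units")
  }
  if (anyNA(p)) stopf("risks missing for some units")
  if (any(p < 0 | p > 1)) stopf("risks must be in [0, 1]")
  p
}

#' Transform a selection problem under a risk strategy
#'
#' Builds the minimum-set problem instance a solver consumes: available
#' units, costs, per-feature effective amounts, and representation targets
#' (`target_fraction` times each feature's total raw amount). Under
#' `avoiding`/`sensitive`, units with risk above the threshold become
#' unavailable (locked-in units are always retained); under
#' `accounting`/`sensitive`, effective amounts are risk-discounted to
#' `a * (1 - p)`. Targets that exceed the total available effective amount
#' are capped there and flagged.
#'
#' @param units Planning-unit data frame (`unit_id`, `cost_usd`, `status`).
#' @param risks Per-unit risk: data frame (`unit_id`, `p`) or aligned vector.
#' @param features Long feature table (`feature_id`, `unit_id`,
#'   `amount_km2`).
#' @param spec A [strategy_spec()].
#' @return A `cp_problem`: unit vectors (`unit_id`, `cost`, `risk`,
#'   `locked`, `available`), amount matrices (`amount_raw`, `amount_eff`,
#'   features x units), per-feature `target`, `target_raw`, `total_raw`,
#'   `capped`, and the `spec`.
#' @export
apply_strategy <- function(units, risks, features, spec) {
  stopifnot(inherits(spec, "cp_strategy"))
  p <- as_risk_vector(risks, units$unit_id)
  locked <- units$status == "locked_in"
  A <- feature_matrix(features, units$unit_id)

  available <- rep(TRUE, nrow(units))
  if (spec$name %in% c("avoiding", "sensitive")) {
    available <- p <= spec$threshold
  }
  available <- available | locked

  A_eff <- if (spec$name %in% c("accounting", "sensitive")) {
    A * rep(1 - p, each = nrow(A))
  } else {
    A
  }

  total_raw <- rowSums(A)
  target_raw <- spec$target_fraction * total_raw
  avail_eff <- rowSums(A_eff[, available, drop = FALSE])
  capped <- target_raw > avail_eff + 1e-9
  target <- pmin(target_raw, avail_eff)

  structure(list(
    unit_id = units$unit_id, cost = units$cost_usd, risk = p,
    locked = locked, available = available,
    amount_raw = A, amount_eff = A_eff,
    target = target, target_raw = target_raw, total_raw = total_raw,
    capped = capped, spec = spec
  ), class = "cp_problem")
}

#' @export
print.cp_problem <- function(x, ...) {
  cat(sprintf(
    "<cp_problem> strategy '%s': %d/%d units available (%d locked in), %d features (%d capped targets)\n",
    x$spec$name, sum(x$available), length(x$unit_id), sum(x$locked),
    nrow(x$amount_raw), sum(x$capped)))
  invisible(x)
}

#' Count features abandoned by exclusion
#'
#' A feature is abandoned when its entire distribution lies in excluded
#' (unavailable) units, so no amount of investment can protect any of it.
#'
#' @param problem A `cp_problem` from [apply_strategy()].
#' @return Integer count of abandoned features.
#' @export
count_abandoned <- function(problem) {
  stopifnot(inherits(problem, "cp_problem"))
  avail_raw <- rowSums(problem$amount_raw[, problem$available, drop = FALSE])
  sum(problem$total_raw > 0 & avail_raw <= 1e-12)
}

#' Inflate targets until reliability is met
#'
#' The accounting and sensitive strategies promise each feature a
#' `reliability` chance that its raw target survives conflict losses.
#' Discounted amounts alone only secure the expected value, so this loop
#' solves the problem, computes each feature's survival reliability over
#' the selected units ([meeting_probability_hetero()] of the raw target),
#' and multiplies the working target of every unreliable feature by
#' `inflate` (capped at the available effective amount) before re-solving —
#' up to `max_iter` times.
#'
#' @param problem A `cp_problem` (strategy accounting or sensitive).
#' @param solver_cfg [solver_config()] used for the inner solves (default a
#'   single greedy run; the final inflated problem is typically re-solved
#'   by a full ensemble afterwards).
#' @param inflate Multiplicative target inflation per iteration (default 1.1).
#' @param max_iter Maximum solve-inflate iterations (default 20).
#' @param mc_reps Monte Carlo replicates for reliabilities of features held
#'   in more than 20 selected units.
#' @param seed Seed for inner solves and Monte Carlo reliability checks.
#' @return The problem with inflated targets; attribute `reliability` holds
#'   the per-feature report (`feature_id`, `target_raw`, `working_target`,
#'   `achieved_reliability`, `inflated`, `capped`, `met`) and attribute
#'   `converged` whether all features reached the required reliability.
#' @export
enforce_reliability <- function(problem, solver_cfg = NULL, inflate = 1.1,
                                max_iter = 20, mc_reps = 10000, seed = 1L) {
  stopifnot(inherits(problem, "cp_problem"))
  if (!problem$spec$name %in% c("accounting", "sensitive")) {
    stopf("reliability enforcement applies to the accounting/sensitive strategies")
  }
  check_number(inflate, "inflate", 1)
  solver_cfg <- solver_cfg %||% solver_config(method = "greedy", n_runs = 1)
  rho <- problem$spec$reliability
  avail_eff <- rowSums(problem$amount_eff[, problem$available, drop = FALSE])
  inflated <- rep(FALSE, length(problem$target))
  rel <- rep(NA_real_, length(problem$target))

  for (iter in seq_len(max_iter)) {
    sol <- solve_once(problem, solver_cfg, seed = seed + iter - 1L)
    sel <- problem$unit_id %in% sol$selected
    changed <- FALSE
    for (f in seq_along(problem$target)) {
      a <- problem$amount_raw[f, sel]
      keep <- a > 0
      rel[f] <- as.numeric(meeting_probability_hetero(
        problem$risk[sel][keep], a[keep], problem$target_raw[f],
        n_reps = mc_reps, seed = seed + 1000L + f, warn = FALSE))
      if (rel[f] < rho && !problem$capped[f]) {
        new_t <- min(problem$target[f] * inflate, avail_eff[f])
        if (new_t > problem$target[f] + 1e-12) {
          problem$target[f] <- new_t
          inflated[f] <- TRUE
          changed <- TRUE
        }
        if (new_t >= avail_eff[f] - 1e-12) problem$capped[f] <- TRUE
      }
    }
    if (!changed) break
  }
  report <- data.frame(
    feature_id = rownames(problem$amount_raw),
    target_raw = problem$target_raw,
    working_target = problem$target,
    achieved_reliability = rel,
    inflated = inflated,
    capped = problem$capped,
    met = rel >= rho,
    row.names = NULL
  )
  attr(problem, "reliability") <- report
  attr(problem, "converged") <- all(report$met)
  problem
}
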