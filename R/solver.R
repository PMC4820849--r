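#' Solver configuration
#'
#' @param method `"anneal"` (simulated annealing, the default and the
#'   method behind the run ensembles), `"greedy"` (cost-effectiveness
#'   complementarity heuristic), or `"brute_force"` (exact enumeration,
#'   small instances only).
#' @param n_runs Number of runs in [run_ensemble()] (default 100).
#' @param temp_init Initial annealing temperature; `NULL` scales it to the
#'   mean available-unit cost so early single-unit moves are accepted.
#' @param cooling Geometric cooling factor per iteration, in `(0, 1)`.
#' @param iterations Annealing proposals per run.
#' @param shortfall_penalty_scale Dimensionless multiplier converting
#'   target shortfall into cost-comparable penalty (each feature's
#'   shortfall is normalized by its target and scaled by a cheapest-cover
#'   cost estimate).
#' @param seed Base seed; run `i` of an ensemble uses `seed + i - 1`.
#' @return A `cp_solver_config` list.
#' @export
solver_config <- function(method = c("anneal", "greedy", "brute_force"),
                          n_runs = 100, temp_init = NULL, cooling = 0.999,
                          iterations = 10000,
                          shortfall_penalty_scale = 2, seed = 1L) {
  method <- match.arg(method)
  check_number(n_runs, "n_runs", 1, integer = TRUE)
  if (!is.null(temp_init)) check_number(temp_init, "temp_init", 0)
  check_number(cooling, "cooling", 1e-12, 1 - 1e-12)
  check_number(iterations, "iterations", 1, integer = TRUE)
  check_number(shortfall_penalty_scale, "shortfall_penalty_scale", 1e-12)
  check_number(seed, "seed", integer = TRUE)
  structure(list(method = method, n_runs = as.integer(n_runs),
                 temp_init = temp_init, cooling = cooling,
                 iterations = as.integer(iterations),
                 shortfall_penalty_scale = shortfall_penalty_scale,
                 seed = as.integer(seed)),
            class = "cp_solver_config")
}

# Assemble a cp_solution from a logical selection over problem$unit_id.
# Cost counts newly acquired units only: locked-in (pre-existing) units
# contribute their amounts but not their (sunk) acquisition cost.
make_solution <- function(problem, sel, seed = NA_integer_,
                          method = NA_character_) {
  rep_eff <- as.numeric(problem$amount_eff %*% sel)
  names(rep_eff) <- rownames(problem$amount_eff)
  structure(list(
    selected = problem$unit_id[sel],
    total_cost_usd = sum(problem$cost[sel & !problem$locked]),
    representation = rep_eff,
    feasible = all(rep_eff >= problem$target - 1e-9),
    seed = seed, method = method
  ), class = "cp_solution")
}

#' @export
print.cp_solution <- function(x, ...) {
  cat(sprintf("<cp_solution> %s: %d units, cost %.3g USD, %s\n",
              x$method, length(x$selected), x$total_cost_usd,
              if (x$feasible) "all targets met" else "INFEASIBLE"))
  invisible(x)
}

# Greedy feasibility pass: add best shortfall-reduction-per-cost unit
# until targets are met or nothing helps. `sel` and the return value are
# logicals over problem$unit_id.
greedy_fill <- function(problem, sel, order_rank) {
  A <- problem$amount_eff
  rep_eff <- as.numeric(A %*% sel)
  shortfall <- pmax(problem$target - rep_eff, 0)
  while (any(shortfall > 1e-9)) {
    cand <- which(problem$available & !sel)
    if (length(cand) == 0) break
    gain <- colSums(pmin(A[, cand, drop = FALSE], shortfall))
    if (max(gain) <= 1e-12) break
    score <- gain / problem$cost[cand]
    top <- which(score >= max(score) - 1e-12)
    j <- cand[top[which.min(order_rank[cand[top]])]]
    sel[j] <- TRUE
    rep_eff <- rep_eff + A[, j]
    shortfall <- pmax(problem$target - rep_eff, 0)
  }
  sel
}

# Reverse pass: drop selected non-locked units (most expensive first)
# whose removal keeps every target met.
greedy_trim <- function(problem, sel) {
  rep_eff <- as.numeric(problem$amount_eff %*% sel)
  drop_order <- which(sel & !problem$locked)
  drop_order <- drop_order[order(-problem$cost[drop_order])]
  for (j in drop_order) {
    new_rep <- rep_eff - problem$amount_eff[, j]
    if (all(new_rep >= problem$target - 1e-9)) {
      sel[j] <- FALSE
      rep_eff <- new_rep
    }
  }
  sel
}

#' Greedy minimum-set heuristic
#'
#' Starts from the locked-in set and repeatedly adds the available unit
#' with the largest capped shortfall reduction per unit cost (ties broken
#' by a seed-determined random ranking), until all targets are met or no
#' unit helps; a reverse pass then drops any non-locked unit whose removal
#' keeps all targets met.
#'
#' @param problem A `cp_problem` from [apply_strategy()].
#' @param seed Integer seed (tie-breaking only).
#' @return A `cp_solution`.
#' @export
greedy_solve <- function(problem, seed = 1L) {
  stopifnot(inherits(problem, "cp_problem"))
  n <- length(problem$unit_id)
  order_rank <- with_seed(seed, sample.int(n))
  sel <- problem$locked
  sel <- greedy_fill(problem, sel, order_rank)
  sel <- greedy_trim(problem, sel)
  make_solution(problem, sel, seed, "greedy")
}

#' Simulated-annealing minimum-set solver
#'
#' Minimizes selected cost plus a penalty proportional to each feature's
#' target shortfall, via single-unit add/drop proposals with Metropolis
#' acceptance and geometric cooling (the approach of Marxan-class reserve
#' selection software). Locked-in units are never dropped. After the
#' chain, a greedy repair pass restores feasibility when attainable and a
#' trim pass removes redundant units. Deterministic under a fixed seed.
#'
#' @param problem A `cp_problem`.
#' @param cfg A [solver_config()] (annealing parameters).
#' @param seed Integer seed for the chain.
#' @return A `cp_solution`.
#' @export
anneal_solve <- function(problem, cfg = solver_config(), seed = 1L) {
  stopifnot(inherits(problem, "cp_problem"))
  cand <- which(problem$available & !problem$locked)
  avail <- problem$available
  A_av <- problem$amount_eff[, avail, drop = FALSE]
  cost_av <- problem$cost[avail]

  # penalty weight: shortfall_f / target_f, scaled by an estimated cost of
  # covering feature f from scratch with its cheapest available units
  nf <- nrow(problem$amount_eff)
  w <- numeric(nf)
  for (f in seq_len(nf)) {
    t_f <- problem$target[f]
    if (t_f <= 1e-12) next
    a <- A_av[f, ]
    keep <- a > 0
    if (!any(keep)) next
    o <- order(cost_av[keep] / a[keep])
    cum <- cumsum(a[keep][o])
    need <- which(cum >= t_f - 1e-9)[1]
    if (is.na(need)) need <- sum(keep)
    cover_cost <- sum(cost_av[keep][o][seq_len(need)])
    w[f] <- cfg$shortfall_penalty_scale * cover_cost / t_f
  }

  temp0 <- cfg$temp_init %||%
    (if (length(cand) > 0) mean(problem$cost[cand]) else 1)

  sel <- with_seed(seed, {
    init <- problem$locked
    if (length(cand) > 0) init[cand] <- runif(length(cand)) < 0.5
    .anneal_core(problem$amount_eff, problem$cost, cand - 1L, init,
                 problem$target, w, temp0, cfg$cooling, cfg$iterations)
  })
  order_rank <- with_seed(seed + 1L, sample.int(length(problem$unit_id)))
  sel <- greedy_fill(problem, sel, order_rank)
  sel <- greedy_trim(problem, sel)
  make_solution(problem, sel, seed, "anneal")
}

#' Exact minimum-set solution by enumeration
#'
#' Enumerates every subset of the available non-locked units (at most 20,
#' refused above that) and returns the cheapest feasible one; ties are
#' broken deterministically by enumeration order (lowest bitmask over
#' id-ordered units). Intended as a test oracle for the heuristics.
#'
#' @param problem A `cp_problem` with at most 20 available non-locked units.
#' @return A `cp_solution`; `feasible = FALSE` (with the locked-in set)
#'   when no subset meets every target.
#' @export
brute_force_solve <- function(problem) {
  stopifnot(inherits(problem, "cp_problem"))
  cand <- which(problem$available & !problem$locked)
  m <- length(cand)
  if (m > 20) {
    stopf("brute_force_solve refuses instances with > 20 available units (got %d)", m)
  }
  base_rep <- as.numeric(problem$amount_eff %*% problem$locked)
  A_cand <- problem$amount_eff[, cand, drop = FALSE]
  cost_cand <- problem$cost[cand]

  best_mask <- NA_real_
  best_cost <- Inf
  chunk <- 2^16
  n_masks <- 2^m
  for (start in seq(0, n_masks - 1, by = chunk)) {
    masks <- start:min(start + chunk - 1, n_masks - 1)
    S <- vapply(seq_len(m),
                function(i) (masks %/% 2^(i - 1)) %% 2 == 1,
                logical(length(masks)))
    if (length(masks) == 1) S <- matrix(S, nrow = 1)
    rep_all <- S %*% t(A_cand) # masks x features
    feas <- rep_all + rep(base_rep, each = nrow(S)) >=
      rep(problem$target, each = nrow(S)) - 1e-9
    ok <- rowSums(feas) == length(problem$target)
    if (any(ok)) {
      costs <- as.numeric(S %*% cost_cand)
      costs[!ok] <- Inf
      i <- which.min(costs)
      if (costs[i] < best_cost - 1e-12) {
        best_cost <- costs[i]
        best_mask <- masks[i]
      }
    }
  }
  sel <- problem$locked
  if (!is.na(best_mask)) {
    bits <- (best_mask %/% 2^(seq_len(m) - 1)) %% 2 == 1
    sel[cand[bits]] <- TRUE
  }
  make_solution(problem, sel, NA_integer_, "brute_force")
}

solve_once <- function(problem, cfg, seed) {
  switch(cfg$method,
         greedy = greedy_solve(problem, seed),
         anneal = anneal_solve(problem, cfg, seed),
         brute_force = brute_force_solve(problem))
}

#' Solve a problem many times and tally selection frequencies
#'
#' Runs the configured solver `n_runs` times with seeds `seed + 0 ...
#' seed + n_runs - 1`. Each available unit's selection frequency across
#' runs indicates its relative priority; the best solution is the
#' least-cost feasible run.
#'
#' @param problem A `cp_problem`.
#' @param cfg A [solver_config()].
#' @return A `cp_ensemble`: `solutions` (list), `selection_frequency`
#'   (named count vector, 0..n_runs), `best` (least-cost feasible
#'   `cp_solution`, or `NULL` if no run is feasible), `n_runs`.
#' @export
run_ensemble <- function(problem, cfg = solver_config()) {
  stopifnot(inherits(problem, "cp_problem"), inherits(cfg, "cp_solver_config"))
  sols <- vector("list", cfg$n_runs)
  freq <- setNames(rep(0L, length(problem$unit_id)),
                   as.character(problem$unit_id))
  for (i in seq_len(cfg$n_runs)) {
    sols[[i]] <- solve_once(problem, cfg, seed = cfg$seed + i - 1L)
    freq[as.character(sols[[i]]$selected)] <-
      freq[as.character(sols[[i]]$selected)] + 1L
  }
  feas <- vapply(sols, function(s) s$feasible, logical(1))
  best <- NULL
  if (any(feas)) {
    costs <- vapply(sols, function(s) s$total_cost_usd, numeric(1))
    costs[!feas] <- Inf
    best <- sols[[which.min(costs)]]
  }
  structure(list(solutions = sols, selection_frequency = freq,
                 best = best, n_runs = cfg$n_runs),
            class = "cp_ensemble")
}

#' @export
print.cp_ensemble <- function(x, ...) {
  nf <- sum(vapply(x$solutions, function(s) s$feasible, logical(1)))
  cat(sprintf("<cp_ensemble> %d runs (%d feasible)", x$n_runs, nf))
  if (!is.null(x$best)) {
    cat(sprintf("; best: %d units, cost %.3g USD",
                length(x$best$selected), x$best$total_cost_usd))
  }
  cat("\n")
  invisible(x)
}
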