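test_that("binomial meeting probability matches enumeration and its limits", {
  # independent oracle: enumerate all 2^4 loss outcomes
  expect_equal(hetero_oracle(rep(0.5, 4), rep(1, 4), 2), 11 / 16)
  expect_equal(as.numeric(meeting_probability(4, 2, 0.5)), 11 / 16)

  expect_equal(meeting_probability(3, 5, 0.2), 0) # impossible
  expect_equal(meeting_probability(5, 3, 0), 1) # lossless
  expect_error(meeting_probability(-1, 2, 0.5), "n_selected")
})

test_that("meeting probability is monotone in its arguments", {
  for (p in c(0.1, 0.4, 0.7)) {
    probs <- vapply(3:12, meeting_probability, numeric(1),
                    n_required = 3, p_loss = p)
    expect_true(all(diff(probs) >= 0)) # more units never hurt
  }
  grid_p <- seq(0, 1, by = 0.1)
  probs <- vapply(grid_p, function(p) meeting_probability(8, 4, p),
                  numeric(1))
  expect_true(all(diff(probs) <= 0)) # riskier units never help
  probs <- vapply(1:8, function(k) meeting_probability(8, k, 0.3),
                  numeric(1))
  expect_true(all(diff(probs) <= 0)) # stricter targets never help
})

test_that("heterogeneous meeting probability matches enumeration and the binomial special case", {
  # equal risks and unit amounts reduce to the binomial tail
  expect_equal(as.numeric(meeting_probability_hetero(rep(0.25, 6),
                                                     rep(1, 6), 3)),
               as.numeric(meeting_probability(6, 3, 0.25)))
  expect_equal(as.numeric(meeting_probability_hetero(rep(0, 5),
                                                     rep(1, 5), 4)), 1)
  expect_warning(
    z <- meeting_probability_hetero(c(0.1, 0.1), c(1, 1), 5),
    "exceeds the total")
  expect_equal(as.numeric(z), 0)

  p <- c(0.1, 0.2, 0.3, 0.1, 0.5, 0.05)
  a <- rep(1, 6)
  exact <- as.numeric(meeting_probability_hetero(p, a, 4))
  expect_equal(exact, hetero_oracle(p, a, 4))
  mc <- meeting_probability_hetero(p, a, 4, exact_limit = 3,
                                   n_reps = 100000, seed = 1)
  expect_lt(abs(as.numeric(mc) - exact), 3 * attr(mc, "se"))

  # fractional amounts against the same enumeration oracle
  set.seed(2)
  for (i in 1:5) {
    p <- runif(6)
    a <- runif(6, 0.2, 2)
    t <- runif(1, 0.2, 0.8) * sum(a)
    expect_equal(as.numeric(meeting_probability_hetero(p, a, t)),
                 hetero_oracle(p, a, t))
  }
})

test_that("required_units inverts the binomial tail at the reliability level", {
  expect_identical(required_units(3, 0, 0.9), 3L)
  expect_identical(required_units(1, 0.5, 0.75), 2L) # 1 - 0.5^2 = 0.75
  expect_error(required_units(3, 1, 0.9), "p_loss")

  # non-decreasing in loss probability and in reliability
  by_p <- vapply(c(0, 0.1, 0.25, 0.4, 0.6), required_units, integer(1),
                 n_required = 3, rho = 0.9)
  expect_true(all(diff(by_p) >= 0))
  by_rho <- vapply(c(0.5, 0.8, 0.9, 0.95, 0.99), function(r) {
    required_units(3, 0.25, r)
  }, integer(1))
  expect_true(all(diff(by_rho) >= 0))
})

test_that("apply_strategy implements the four risk attitudes", {
  costs <- rep(1, 4)
  amounts <- rbind(c(10, 10, 0, 0), c(0, 5, 5, 5))
  risks <- c(0.4, 0.0, 0.5, 0.2)

  ig <- toy_problem(costs, amounts, risks, strategy = "ignorant")
  expect_true(all(ig$available))
  expect_equal(ig$amount_eff, ig$amount_raw)
  expect_equal(unname(ig$target), unname(0.3 * rowSums(amounts)))

  av <- toy_problem(costs, amounts, risks, strategy = "avoiding",
                    threshold = 0.35)
  expect_true(all(av$risk[av$available] <= 0.35))
  expect_equal(av$amount_eff, av$amount_raw)

  ac <- toy_problem(c(1, 1), rbind(c(10, 10)), c(0.4, 0.0),
                    strategy = "accounting")
  expect_equal(unname(ac$amount_eff[1, ]), c(6, 10)) # a * (1 - p)
  expect_true(all(ac$available))

  se <- toy_problem(costs, amounts, risks, strategy = "sensitive",
                    threshold = 0.35)
  expect_true(all(se$risk[se$available] <= 0.35))
  expect_equal(unname(se$amount_eff[1, ]), unname(amounts[1, ] * (1 - risks)))

  # locked-in units are retained even above the threshold
  av2 <- toy_problem(costs, amounts, risks, strategy = "avoiding",
                     threshold = 0.35, locked = 1)
  expect_true(av2$available[1])
})

test_that("infeasible targets are capped at the available effective amount", {
  # avoiding excludes the whole feature: target capped to zero
  pr <- toy_problem(rep(1, 3), rbind(c(4, 4, 0), c(0, 0, 6)),
                    risks = c(0.1, 0.1, 0.9), strategy = "avoiding",
                    threshold = 0.5)
  expect_true(pr$capped[2])
  expect_equal(unname(pr$target[2]), 0)
  expect_false(pr$capped[1])
})

test_that("abandoned-feature counts match enumeration and shrink with theta", {
  set.seed(8)
  n <- 30
  amounts <- matrix(0, 6, n)
  for (f in 1:6) amounts[f, sample.int(n, 5)] <- 1
  risks <- runif(n)
  counts <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(theta) {
    pr <- toy_problem(rep(1, n), amounts, risks, strategy = "avoiding",
                      threshold = theta)
    # enumeration oracle: a feature is abandoned iff all its cells excluded
    oracle <- sum(vapply(1:6, function(f) {
      all(risks[amounts[f, ] > 0] > theta)
    }, logical(1)))
    expect_identical(count_abandoned(pr), oracle)
    count_abandoned(pr)
  }, integer(1))
  expect_true(all(diff(counts) <= 0)) # higher tolerance frees features
  expect_identical(
    count_abandoned(toy_problem(rep(1, n), amounts, risks,
                                strategy = "ignorant")), 0L)
})

test_that("exclusion is monotone: lowering theta never adds an available unit", {
  set.seed(12)
  risks <- runif(20)
  amounts <- rbind(runif(20))
  prev <- rep(TRUE, 20)
  for (theta in c(1, 0.75, 0.5, 0.25, 0)) {
    av <- toy_problem(rep(1, 20), amounts, risks, strategy = "avoiding",
                      threshold = theta)$available
    expect_true(all(!av | prev))
    prev <- av
  }
})

test_that("reliability loop leaves zero-risk problems untouched", {
  pr <- toy_problem(rep(1, 8), rbind(rep(1, 8)), rep(0, 8),
                    strategy = "accounting")
  out <- enforce_reliability(pr, seed = 1)
  expect_true(attr(out, "converged"))
  rep_tab <- attr(out, "reliability")
  expect_false(any(rep_tab$inflated))
  expect_equal(out$target, pr$target)
})

test_that("reliability loop reproduces the equal-risk redundancy rule", {
  # 10 unit-amount cells at 25% risk, 3 needed: 6 must be held for 95%
  pr <- toy_problem(rep(1, 10), rbind(rep(1, 10)), rep(0.25, 10),
                    strategy = "accounting", targets_fraction = 0.3)
  out <- enforce_reliability(pr, seed = 1)
  sol <- greedy_solve(out, seed = 1)
  held <- sum(out$amount_raw[1, out$unit_id %in% sol$selected] > 0)
  expect_gte(held, 6)
  expect_true(attr(out, "converged"))
})

test_that("enforced reliability is confirmed by Monte Carlo loss simulation", {
  for (p in c(0.1, 0.3, 0.5)) {
    pr <- toy_problem(rep(1, 14), rbind(rep(1, 14)), rep(p, 14),
                      strategy = "accounting", targets_fraction = 0.3)
    pr$spec$reliability <- 0.9
    out <- enforce_reliability(pr, seed = 2)
    sol <- greedy_solve(out, seed = 2)
    sel <- out$unit_id %in% sol$selected
    lost <- simulate_losses(setNames(rep(p, sum(sel)), which(sel)),
                            evaluation_config(n_reps = 10000, seed = 3))
    surviving <- rowSums(!lost)
    freq <- mean(surviving >= out$target_raw[1] - 1e-9)
    se <- sqrt(freq * (1 - freq) / 10000)
    expect_gte(freq, 0.9 - 3 * se)
  }
})
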