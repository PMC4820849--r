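# Fixtures built in code: tiny landscapes, hand-rolled problems, and
# random solver instances used across the test files.

tiny_landscape <- function(seed = 1, n = 10, n_species = 5,
                           n_ecoregions = 3, locked = 0.1) {
  generate_landscape(landscape_config(
    n_rows = n, n_cols = n, n_species = n_species,
    n_ecoregions = n_ecoregions, species_range_radius_km = 30,
    locked_in_fraction = locked, seed = seed
  ))
}

# A bare problem from explicit vectors: n units of unit cost/amount unless
# overridden, one feature per row of `amounts`.
toy_problem <- function(costs, amounts, risks = NULL, targets_fraction = 0.3,
                        strategy = "ignorant", threshold = 0.35,
                        locked = NULL, area = 1) {
  n <- length(costs)
  amounts <- if (is.matrix(amounts)) amounts else matrix(amounts, nrow = 1)
  units <- data.frame(
    unit_id = seq_len(n), row = 1, col = seq_len(n),
    x_km = seq_len(n), y_km = 0, area_km2 = area, cost_usd = costs,
    status = ifelse(seq_len(n) %in% (locked %||% integer()),
                    "locked_in", "available"),
    nation_id = 1L
  )
  feats <- do.call(rbind, lapply(seq_len(nrow(amounts)), function(f) {
    keep <- amounts[f, ] > 0
    if (!any(keep)) return(NULL)
    data.frame(feature_id = sprintf("f%02d", f), feature_class = "species",
               unit_id = which(keep), amount_km2 = amounts[f, keep])
  }))
  if (is.null(feats)) { # all-zero instance: keep one empty-target feature
    feats <- data.frame(feature_id = "f01", feature_class = "species",
                        unit_id = 1L, amount_km2 = 0)
  }
  spec <- strategy_spec(strategy, threshold = threshold,
                        target_fraction = targets_fraction)
  apply_strategy(units, risks %||% rep(0, n), feats, spec)
}

# Random feasible minimum-set instance for solver comparisons.
random_instance <- function(n_units = 12, n_features = 4, seed = 1,
                            target_fraction = NULL) {
  set.seed(seed)
  costs <- runif(n_units, 1, 10)
  amounts <- matrix(0, n_features, n_units)
  for (f in seq_len(n_features)) {
    k <- sample(2:n_units, 1)
    amounts[f, sample.int(n_units, k)] <- runif(k, 0.5, 2)
  }
  toy_problem(costs, amounts,
              targets_fraction = target_fraction %||% runif(1, 0.2, 0.5))
}

solution_cost <- function(s) s$total_cost_usd

# Brute-force exposure oracle: O(units x events) double loop.
exposure_oracle <- function(units, events, radius_km) {
  rows <- list()
  for (i in seq_len(nrow(units))) {
    for (j in seq_len(nrow(events))) {
      d <- sqrt((units$x_km[i] - events$x_km[j])^2 +
                  (units$y_km[i] - events$y_km[j])^2)
      if (d <= radius_km) {
        rows[[length(rows) + 1L]] <- data.frame(
          unit_id = units$unit_id[i], year = events$year[j],
          fatalities = events$fatalities[j])
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(unit_id = integer(), year = integer(),
                      n_events = integer(), n_fatalities = integer()))
  }
  df <- do.call(rbind, rows)
  agg <- aggregate(cbind(n_events = rep(1L, nrow(df)),
                         n_fatalities = df$fatalities),
                   by = list(unit_id = df$unit_id, year = df$year), FUN = sum)
  agg[order(agg$unit_id, agg$year), ]
}

# Exact meeting probability by explicit enumeration of all loss outcomes.
hetero_oracle <- function(p, amounts, target) {
  n <- length(p)
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), n)) # TRUE = lost
  tot <- 0
  for (r in seq_len(nrow(grid))) {
    lost <- unlist(grid[r, ])
    pr <- prod(ifelse(lost, p, 1 - p))
    if (sum(amounts[!lost]) >= target - 1e-9) tot <- tot + pr
  }
  tot
}
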