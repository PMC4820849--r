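test_that("landscape generation is deterministic under a fixed seed", {
  cfg <- landscape_config(n_rows = 10, n_cols = 10, n_species = 5, seed = 1)
  a <- generate_landscape(cfg)
  b <- generate_landscape(cfg)
  expect_identical(a$units, b$units)
  expect_identical(a$features, b$features)

  ccfg <- conflict_config(seed = 7, biodiversity_coupling = 1)
  expect_identical(generate_conflict_history(ccfg, a),
                   generate_conflict_history(ccfg, a))
})

test_that("ecoregions tessellate the grid and conserve total area", {
  land <- generate_landscape(landscape_config(n_rows = 10, n_cols = 10,
                                              n_species = 2,
                                              n_ecoregions = 4, seed = 3))
  eco <- land$features[land$features$feature_class == "ecoregion", ]
  per_unit <- tapply(eco$amount_km2, eco$unit_id, sum)
  expect_equal(length(per_unit), nrow(land$units)) # every cell covered once
  expect_true(all(per_unit == land$units$area_km2[1]))
  expect_equal(sum(eco$amount_km2), sum(land$units$area_km2))
})

test_that("species range totals match brute-force per-unit summation", {
  land <- generate_landscape(landscape_config(n_rows = 30, n_cols = 30,
                                              n_species = 40, seed = 7))
  sp <- land$features[land$features$feature_class == "species", ]
  for (id in unique(sp$feature_id)) {
    rows <- sp[sp$feature_id == id, ]
    brute <- 0
    for (i in seq_len(nrow(rows))) brute <- brute + rows$amount_km2[i]
    expect_equal(sum(sp$amount_km2[sp$feature_id == id]), brute)
    expect_true(all(rows$unit_id %in% land$units$unit_id))
  }
})

test_that("degenerate landscape configurations are rejected", {
  expect_error(
    generate_landscape(landscape_config(n_rows = 3, n_cols = 3,
                                        species_range_radius_km = 1000)),
    "exceeds the grid extent")
  expect_error(
    generate_landscape(landscape_config(n_rows = 2, n_cols = 2,
                                        n_ecoregions = 5,
                                        species_range_radius_km = 10)),
    "exceeds the number of cells")
  expect_error(landscape_config(locked_in_fraction = 1.2), "must be in")
  expect_error(conflict_config(persistence = -0.1), "must be in")
  expect_error(conflict_config(years = c(2010, 2005)), "year span")
})

test_that("zero-intensity conflict process yields no events", {
  land <- tiny_landscape()
  ev <- generate_conflict_history(conflict_config(hotspot_intensity = 0),
                                  land)
  expect_equal(nrow(ev), 0)
  expect_named(ev, c("event_id", "x_km", "y_km", "year", "fatalities"))
})

test_that("fully persistent single hotspot stays put across years", {
  land <- tiny_landscape(seed = 2, n = 20)
  shifts <- numeric(0)
  for (s in 1:200) {
    ev <- generate_conflict_history(
      conflict_config(n_hotspots = 1, hotspot_intensity = 5,
                      hotspot_dispersion_km = 15, persistence = 1,
                      years = c(2000, 2004), seed = s), land)
    cx <- tapply(ev$x_km, ev$year, mean)
    cy <- tapply(ev$y_km, ev$year, mean)
    if (length(cx) > 1) {
      shifts <- c(shifts, sqrt(diff(cx)^2 + diff(cy)^2))
    }
  }
  expect_lt(mean(shifts), 15) # centroid wander below the dispersion scale
})

test_that("biodiversity coupling raises the richness-event correlation", {
  land <- tiny_landscape(seed = 5, n = 30, n_species = 20)
  rich <- tabulate(
    land$features$unit_id[land$features$feature_class == "species"],
    nbins = nrow(land$units))
  event_counts <- function(coupling, seed) {
    ev <- generate_conflict_history(
      conflict_config(biodiversity_coupling = coupling, n_hotspots = 5,
                      hotspot_intensity = 3, years = c(2000, 2004),
                      seed = seed), land)
    col <- pmin(pmax(ceiling(ev$x_km / 10), 1), 30)
    row <- pmin(pmax(ceiling(ev$y_km / 10), 1), 30)
    tabulate((row - 1) * 30 + col, nbins = nrow(land$units))
  }
  cors <- vapply(1:100, function(s) {
    c(cor(rich, event_counts(2, s), method = "spearman"),
      cor(rich, event_counts(0, s), method = "spearman"))
  }, numeric(2))
  expect_gt(mean(cors[1, ]), mean(cors[2, ]))
})

test_that("event counts scale linearly with hotspot intensity", {
  land <- tiny_landscape(seed = 4)
  mean_count <- function(intensity) {
    mean(vapply(1:100, function(s) {
      nrow(generate_conflict_history(
        conflict_config(hotspot_intensity = intensity, n_hotspots = 3,
                        years = c(2000, 2002), seed = s), land))
    }, numeric(1)))
  }
  m2 <- mean_count(2)
  m4 <- mean_count(4)
  expect_gt(m4 / m2, 1.8)
  expect_lt(m4 / m2, 2.2)
})
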