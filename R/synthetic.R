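#' Landscape generator configuration
#'
#' Parameters for the synthetic gridded landscape: a rectangular grid of
#' square planning units with spatially autocorrelated acquisition costs,
#' disc-shaped species ranges, a Voronoi tessellation of ecoregions,
#' contiguous nation blocks, and a fraction of units locked in as existing
#' protected areas.
#'
#' @param n_rows,n_cols Grid dimensions (cells).
#' @param cell_size_km Cell edge length in km (default 10, giving the
#'   10 km grid resolution typical of continental-scale prioritizations).
#' @param cost_mean_usd Mean acquisition cost per unit in USD.
#' @param cost_autocorrelation_range_km Gaussian smoothing range of the
#'   log-cost field, km; 0 gives independent costs.
#' @param n_species Number of species features (compact range patches).
#' @param species_range_radius_km Mean species range radius, km.
#' @param n_ecoregions Number of ecoregion features (they partition the grid).
#' @param locked_in_fraction Fraction of units pre-protected (status
#'   `"locked_in"`), forcibly included in every solution.
#' @param n_nations Number of contiguous nation blocks.
#' @param seed Integer seed; identical seeds give byte-identical landscapes.
#'
#' @return A `cp_landscape_config` list.
#' @seealso [generate_landscape()]
#' @export
landscape_config <- function(n_rows = 30, n_cols = 30, cell_size_km = 10,
                             cost_mean_usd = 1e6,
                             cost_autocorrelation_range_km = 30,
                             n_species = 40, species_range_radius_km = 40,
                             n_ecoregions = 6, locked_in_fraction = 0.05,
                             n_nations = 4, seed = 1L) {
  check_number(n_rows, "n_rows", 1, integer = TRUE)
  check_number(n_cols, "n_cols", 1, integer = TRUE)
  check_number(cell_size_km, "cell_size_km", lower = 1e-9)
  check_number(cost_mean_usd, "cost_mean_usd", lower = 1e-9)
  check_number(cost_autocorrelation_range_km, "cost_autocorrelation_range_km", 0)
  check_number(n_species, "n_species", 1, integer = TRUE)
  check_number(species_range_radius_km, "species_range_radius_km", lower = 1e-9)
  check_number(n_ecoregions, "n_ecoregions", 1, integer = TRUE)
  check_prob(locked_in_fraction, "locked_in_fraction")
  check_number(n_nations, "n_nations", 1, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    cell_size_km = cell_size_km, cost_mean_usd = cost_mean_usd,
    cost_autocorrelation_range_km = cost_autocorrelation_range_km,
    n_species = as.integer(n_species),
    species_range_radius_km = species_range_radius_km,
    n_ecoregions = as.integer(n_ecoregions),
    locked_in_fraction = locked_in_fraction,
    n_nations = as.integer(n_nations), seed = as.integer(seed)
  ), class = "cp_landscape_config")
}

# Separable Gaussian smoothing of a matrix, edge-normalized so the local
# kernel mass always sums to 1.
smooth_field <- function(m, sd_cells) {
  if (sd_cells <= 0) return(m)
  h <- max(1L, ceiling(3 * sd_cells))
  w <- dnorm(seq(-h, h), sd = sd_cells)
  conv1 <- function(v) {
    n <- length(v)
    out <- numeric(n)
    for (i in seq_len(n)) {
      j <- max(1L, i - h):min(n, i + h)
      k <- w[j - i + h + 1L]
      out[i] <- sum(v[j] * k) / sum(k)
    }
    out
  }
  m <- apply(m, 2L, conv1)
  t(apply(m, 1L, conv1))
}

# Nearest-seed (Voronoi) partition of grid cells; ties go to the lowest
# seed index so the partition is deterministic.
voronoi_labels <- function(x, y, n_blocks) {
  idx <- sample.int(length(x), n_blocks)
  d2 <- outer(x, x[idx], function(a, b) (a - b)^2) +
    outer(y, y[idx], function(a, b) (a - b)^2)
  max.col(-d2, ties.method = "first")
}

#' Generate a synthetic planning landscape
#'
#' Builds the three tables every downstream stage consumes: planning units
#' (with costs, protection status and nation membership), a long-format
#' feature table (species ranges and ecoregions, amounts in km2), and the
#' grid geometry. Costs are log-normal with Gaussian spatial smoothing;
#' species ranges are discs with jittered boundaries; ecoregions and nations
#' are contiguous Voronoi blocks.
#'
#' @param cfg A [landscape_config()].
#' @return A `cp_landscape` list with elements `units` (data frame:
#'   `unit_id`, `row`, `col`, `x_km`, `y_km`, `area_km2`, `cost_usd`,
#'   `status`, `nation_id`), `features` (data frame: `feature_id`,
#'   `feature_class`, `unit_id`, `amount_km2`), and `config`.
#' @examples
#' land <- generate_landscape(landscape_config(n_rows = 10, n_cols = 10,
#'                                             n_species = 5, seed = 1))
#' head(land$units)
#' @export
generate_landscape <- function(cfg) {
  stopifnot(inherits(cfg, "cp_landscape_config"))
  n_cells <- cfg$n_rows * cfg$n_cols
  extent <- c(cfg$n_cols, cfg$n_rows) * cfg$cell_size_km
  if (cfg$species_range_radius_km > max(extent)) {
    stopf("species_range_radius_km (%g) exceeds the grid extent (%g km)",
          cfg$species_range_radius_km, max(extent))
  }
  if (cfg$n_ecoregions > n_cells) {
    stopf("n_ecoregions (%d) exceeds the number of cells (%d)",
          cfg$n_ecoregions, n_cells)
  }
  if (cfg$n_nations > n_cells) {
    stopf("n_nations (%d) exceeds the number of cells (%d)",
          cfg$n_nations, n_cells)
  }

  with_seed(cfg$seed, {
    row <- rep(seq_len(cfg$n_rows), each = cfg$n_cols)
    col <- rep(seq_len(cfg$n_cols), times = cfg$n_rows)
    x <- (col - 0.5) * cfg$cell_size_km
    y <- (row - 0.5) * cfg$cell_size_km
    area <- cfg$cell_size_km^2

    # log-normal cost field: smooth a white-noise field, restandardize,
    # exponentiate (log-sd 0.5), rescale to the requested mean
    z <- matrix(rnorm(n_cells), nrow = cfg$n_rows, ncol = cfg$n_cols)
    z <- smooth_field(z, cfg$cost_autocorrelation_range_km / cfg$cell_size_km)
    z <- (z - mean(z)) / max(sd(z), 1e-12)
    raw <- exp(0.5 * as.numeric(t(z))) # t(): cells ordered row-major
    cost <- raw / mean(raw) * cfg$cost_mean_usd

    n_locked <- round(cfg$locked_in_fraction * n_cells)
    status <- rep("available", n_cells)
    if (n_locked > 0) status[sample.int(n_cells, n_locked)] <- "locked_in"

    nation <- voronoi_labels(x, y, cfg$n_nations)
    eco <- voronoi_labels(x, y, cfg$n_ecoregions)

    units <- data.frame(
      unit_id = seq_len(n_cells), row = row, col = col,
      x_km = x, y_km = y, area_km2 = area, cost_usd = cost,
      status = status, nation_id = nation,
      stringsAsFactors = FALSE
    )

    feat <- list()
    for (s in seq_len(cfg$n_species)) {
      r_s <- cfg$species_range_radius_km * runif(1, 0.6, 1.4)
      ctr <- sample.int(n_cells, 1)
      d <- sqrt((x - x[ctr])^2 + (y - y[ctr])^2)
      jit <- runif(n_cells, -0.5, 0.5) * cfg$cell_size_km
      inside <- d + jit <= r_s
      inside[ctr] <- TRUE
      feat[[length(feat) + 1L]] <- data.frame(
        feature_id = sprintf("sp%03d", s), feature_class = "species",
        unit_id = which(inside), amount_km2 = area,
        stringsAsFactors = FALSE
      )
    }
    for (e in seq_len(cfg$n_ecoregions)) {
      inside <- which(eco == e)
      if (length(inside) == 0) next
      feat[[length(feat) + 1L]] <- data.frame(
        feature_id = sprintf("eco%02d", e), feature_class = "ecoregion",
        unit_id = inside, amount_km2 = area,
        stringsAsFactors = FALSE
      )
    }
    features <- do.call(rbind, feat)
    rownames(features) <- NULL

    structure(list(units = units, features = features, config = cfg),
              class = "cp_landscape")
  })
}

#' @export
print.cp_landscape <- function(x, ...) {
  cat(sprintf(
    "<cp_landscape> %d x %d grid (%g km cells), %d units, %d features (%d species, %d ecoregions), %d locked in\n",
    x$config$n_rows, x$config$n_cols, x$config$cell_size_km,
    nrow(x$units), length(unique(x$features$feature_id)),
    sum(grepl("^sp", unique(x$features$feature_id))),
    sum(grepl("^eco", unique(x$features$feature_id))),
    sum(x$units$status == "locked_in")
  ))
  invisible(x)
}

#' Conflict point-process configuration
#'
#' Parameters of the clustered spatio-temporal conflict process: a set of
#' hotspots that persist between years with probability `persistence` and
#' otherwise relocate, each emitting a Poisson number of incidents per year
#' scattered around it. Hotspot placement can be biased toward species-rich
#' cells (`biodiversity_coupling`), reproducing the positive
#' biodiversity-risk association seen in real conflict data.
#'
#' @param n_hotspots Number of simultaneous conflict hotspots.
#' @param hotspot_intensity Mean incidents per hotspot per year (Poisson).
#' @param hotspot_dispersion_km Gaussian scatter of incidents around a
#'   hotspot, km.
#' @param persistence Year-to-year probability a hotspot stays in place
#'   (history then predicts future risk); in `[0, 1]`.
#' @param fatality_mean Mean fatalities per incident.
#' @param fatality_overdispersion Overdispersion of the fatality count;
#'   0 gives Poisson, larger values negative binomial with
#'   `size = mean / overdispersion`.
#' @param biodiversity_coupling Weighting (>= 0) of hotspot placement toward
#'   species-rich cells: sampling weight `exp(coupling * standardized
#'   richness)`; 0 is uniform.
#' @param years Inclusive year span `c(start, end)`.
#' @param seed Integer seed.
#' @return A `cp_conflict_config` list.
#' @seealso [generate_conflict_history()]
#' @export
conflict_config <- function(n_hotspots = 5, hotspot_intensity = 6,
                            hotspot_dispersion_km = 25, persistence = 0.85,
                            fatality_mean = 5, fatality_overdispersion = 2,
                            biodiversity_coupling = 0,
                            years = c(1999L, 2014L), seed = 1L) {
  check_number(n_hotspots, "n_hotspots", 1, integer = TRUE)
  check_number(hotspot_intensity, "hotspot_intensity", 0)
  check_number(hotspot_dispersion_km, "hotspot_dispersion_km", 0)
  check_prob(persistence, "persistence")
  check_number(fatality_mean, "fatality_mean", 0)
  check_number(fatality_overdispersion, "fatality_overdispersion", 0)
  check_number(biodiversity_coupling, "biodiversity_coupling", 0)
  years <- check_year_span(years, "years")
  check_number(seed, "seed", integer = TRUE)
  structure(list(
    n_hotspots = as.integer(n_hotspots),
    hotspot_intensity = hotspot_intensity,
    hotspot_dispersion_km = hotspot_dispersion_km,
    persistence = persistence, fatality_mean = fatality_mean,
    fatality_overdispersion = fatality_overdispersion,
    biodiversity_coupling = biodiversity_coupling,
    years = years, seed = as.integer(seed)
  ), class = "cp_conflict_config")
}

# Species richness per unit (count of species features present).
unit_richness <- function(landscape) {
  sp <- landscape$features[landscape$features$feature_class == "species", ]
  counts <- table(factor(sp$unit_id, levels = landscape$units$unit_id))
  as.numeric(counts)
}

#' Generate a synthetic conflict-event history
#'
#' Simulates geo-referenced armed-conflict incidents over the configured
#' year span. Hotspots persist between years with probability
#' `persistence`, so cells with a history of conflict have elevated future
#' event probability; with positive `biodiversity_coupling`, expected event
#' density increases with cell species richness.
#'
#' @param cfg A [conflict_config()].
#' @param landscape A `cp_landscape` from [generate_landscape()].
#' @return Data frame of events: `event_id`, `x_km`, `y_km`, `year`,
#'   `fatalities` (non-negative integers). Zero-intensity processes give an
#'   empty (0-row) frame.
#' @export
generate_conflict_history <- function(cfg, landscape) {
  stopifnot(inherits(cfg, "cp_conflict_config"),
            inherits(landscape, "cp_landscape"))
  units <- landscape$units
  lcfg <- landscape$config
  extent_x <- lcfg$n_cols * lcfg$cell_size_km
  extent_y <- lcfg$n_rows * lcfg$cell_size_km
  yrs <- seq(cfg$years[1], cfg$years[2])

  empty <- data.frame(event_id = integer(), x_km = numeric(),
                      y_km = numeric(), year = integer(),
                      fatalities = integer(), stringsAsFactors = FALSE)
  if (cfg$hotspot_intensity == 0) return(empty)

  rich <- unit_richness(landscape)
  w <- if (cfg$biodiversity_coupling > 0 && sd(rich) > 0) {
    exp(cfg$biodiversity_coupling * (rich - mean(rich)) / sd(rich))
  } else {
    rep(1, nrow(units))
  }

  with_seed(cfg$seed, {
    hs <- sample.int(nrow(units), cfg$n_hotspots, replace = TRUE, prob = w)
    out <- vector("list", length(yrs))
    for (i in seq_along(yrs)) {
      if (i > 1) {
        move <- runif(cfg$n_hotspots) > cfg$persistence
        if (any(move)) {
          hs[move] <- sample.int(nrow(units), sum(move),
                                 replace = TRUE, prob = w)
        }
      }
      k <- rpois(cfg$n_hotspots, cfg$hotspot_intensity)
      n <- sum(k)
      if (n == 0) next
      cx <- rep(units$x_km[hs], k)
      cy <- rep(units$y_km[hs], k)
      ex <- pmin(pmax(cx + rnorm(n, 0, cfg$hotspot_dispersion_km), 0), extent_x)
      ey <- pmin(pmax(cy + rnorm(n, 0, cfg$hotspot_dispersion_km), 0), extent_y)
      fat <- if (cfg$fatality_mean == 0) {
        integer(n)
      } else if (cfg$fatality_overdispersion > 0) {
        rnbinom(n, mu = cfg$fatality_mean,
                size = cfg$fatality_mean / cfg$fatality_overdispersion)
      } else {
        rpois(n, cfg$fatality_mean)
      }
      out[[i]] <- data.frame(x_km = ex, y_km = ey, year = yrs[i],
                             fatalities = as.integer(fat),
                             stringsAsFactors = FALSE)
    }
    out <- out[!vapply(out, is.null, logical(1))]
    if (length(out) == 0) return(empty)
    ev <- do.call(rbind, out)
    ev <- cbind(event_id = seq_len(nrow(ev)), ev)
    rownames(ev) <- NULL
    ev
  })
}
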