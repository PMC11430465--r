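# Synthetic-data generator: emulates the structure of the compiled flux
# database (site networks over 4 cryosphere zones x 2 water-body types,
# log-normal diffusive CO2/CH4 fluxes with zone multipliers and a seasonal
# cycle, zero-inflated CH4 ebullition, N2O with a sink fraction, seasonal
# ice-phenology area curves, NEE grids) with closed-form ground truth for
# parameter-recovery tests. It makes no attempt to reproduce the real
# database's values or site map.

#' Configuration of the synthetic world
#'
#' Defaults encode the qualitative structure of the observed system: river
#' CO2 fluxes exceed lake CO2 fluxes, sporadic/isolated-permafrost ebullition
#' is highest, glacial fluxes are near zero with glacial river CO2 slightly
#' negative, 39% of river and 13% of lake ebullition records are zero, 65% of
#' lake and 36% of river N2O records are negative (undersaturation), N2O is
#' unmeasured in the glacial zone, and observations occur only in open-water
#' months, with reduced sampling in the shoulder seasons.
#'
#' @param n_sites Sites per (zone, water body) cell (default 8).
#' @param obs_rate Poisson mean observations per site-month at peak sampling
#'   (default 2).
#' @param month_prob Length-12 relative sampling intensity (default: low in
#'   the shoulder seasons, zero nowhere; frozen months are excluded by the
#'   area curve instead).
#' @param sdlog Log-scale spread of CO2 and diffusive CH4 fluxes (default
#'   0.8); `0` makes every draw equal to its group mean.
#' @param eb_sdlog Log-scale spread of non-zero ebullitive fluxes (default 1).
#' @param eb_zero_prob Zero-ebullition probability, named by water body
#'   (defaults lake 0.13, river 0.39).
#' @param n2o_sd Spread of N2O fluxes (default 0.02 mmol m^-2 day^-1).
#' @param n2o_sink_share Probability of a negative N2O flux, named by water
#'   body (defaults lake 0.65, river 0.36).
#' @param seasonal_amp Amplitude of the seasonal sinusoid on CO2 and CH4
#'   fluxes (default 0.4).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_sites = 8L,
                             obs_rate = 2,
                             month_prob = c(0.15, 0.15, 0.3, 0.55, 0.85, 1,
                                            1, 1, 0.9, 0.6, 0.3, 0.15),
                             sdlog = 0.8,
                             eb_sdlog = 1,
                             eb_zero_prob = c(lake = 0.13, river = 0.39),
                             n2o_sd = 0.02,
                             n2o_sink_share = c(lake = 0.65, river = 0.36),
                             seasonal_amp = 0.4) {
  assert_that(n_sites >= 1, "n_sites must be >= 1")
  assert_that(length(month_prob) == 12 && all(month_prob >= 0 & month_prob <= 1),
              "month_prob must be 12 probabilities")
  assert_that(all(eb_zero_prob >= 0 & eb_zero_prob <= 1) &&
                all(n2o_sink_share >= 0 & n2o_sink_share <= 1),
              "probabilities must be in [0, 1]")
  assert_that(sdlog >= 0 && eb_sdlog >= 0 && n2o_sd >= 0,
              "spread parameters must be >= 0")
  structure(list(
    n_sites = as.integer(n_sites), obs_rate = obs_rate,
    month_prob = month_prob, sdlog = sdlog, eb_sdlog = eb_sdlog,
    eb_zero_prob = eb_zero_prob, n2o_sd = n2o_sd,
    n2o_sink_share = n2o_sink_share, seasonal_amp = seasonal_amp
  ), class = "synthetic_config")
}

# Baseline flux medians (mmol m^-2 day^-1) and zone multipliers expressing
# the qualitative ordering: permafrost >> glacial, river CO2 > lake CO2,
# sporadic/isolated ebullition highest.
flux_model_params <- function() {
  list(
    co2_base = c(lake = 20, river = 60),
    co2_zone = c(continuous = 0.8, discontinuous = 1.3,
                 sporadic_isolated = 1.0, glacial = 0.02),
    ch4_base = c(lake = 1.5, river = 0.8),
    ch4_zone = c(continuous = 1.0, discontinuous = 1.2,
                 sporadic_isolated = 0.9, glacial = 0.02),
    eb_base = c(lake = 2.0, river = 1.0),
    eb_zone = c(continuous = 0.8, discontinuous = 1.4,
                sporadic_isolated = 2.5, glacial = 0.01),
    # glacial rivers: slight net CO2 uptake
    co2_glacial_river_mean = -0.5
  )
}

season_factor <- function(month, amp) 1 + amp * sin(2 * pi * (month - 4) / 12)

#' True group-mean fluxes of the synthetic world
#'
#' Closed-form expected flux for every (gas, pathway, water body, zone, month)
#' cell of the generator model. N2O has no glacial cells (unmeasured stratum).
#'
#' @param cfg A [synthetic_config()].
#' @return Tibble: key columns plus `true_mean` (mmol m^-2 day^-1).
#' @export
true_group_means <- function(cfg) {
  p <- flux_model_params()
  grid <- tidyr::expand_grid(
    water_body = ghg_water_bodies(), zone = ghg_zones(), month = 1:12)
  sf <- season_factor(grid$month, cfg$seasonal_amp)

  co2 <- grid
  co2$gas <- "CO2"; co2$pathway <- "diffusive"
  co2$true_mean <- unname(p$co2_base[co2$water_body] * p$co2_zone[co2$zone] *
                            sf * exp(cfg$sdlog^2 / 2))
  glr <- co2$water_body == "river" & co2$zone == "glacial"
  co2$true_mean[glr] <- p$co2_glacial_river_mean

  ch4 <- grid
  ch4$gas <- "CH4"; ch4$pathway <- "diffusive"
  ch4$true_mean <- unname(p$ch4_base[ch4$water_body] * p$ch4_zone[ch4$zone] *
                            sf * exp(cfg$sdlog^2 / 2))

  eb <- grid
  eb$gas <- "CH4"; eb$pathway <- "ebullitive"
  eb$true_mean <- unname((1 - cfg$eb_zero_prob[eb$water_body]) *
    p$eb_base[eb$water_body] * p$eb_zone[eb$zone] * sf *
    exp(cfg$eb_sdlog^2 / 2))

  n2o <- grid[grid$zone != "glacial", ]
  n2o$gas <- "N2O"; n2o$pathway <- "diffusive"
  n2o$true_mean <- unname(cfg$n2o_sd *
                            qnorm(1 - cfg$n2o_sink_share[n2o$water_body]))

  dplyr::bind_rows(co2, ch4, eb, n2o)[, c(group_key_cols(), "true_mean")]
}

#' Synthetic monthly open-water areas
#'
#' Ice-phenology-shaped monthly curves per zone and water body: lake areas
#' peak in September and never freeze out entirely in the large-lake zones;
#' river areas peak in June and are zero in the coldest months (January
#' included), matching the freeze adjustment convention.
#'
#' @return Tibble `zone`, `water_body`, `month`, `area` (km^2), 96 rows.
#' @export
generate_areas <- function() {
  lake_peak <- c(continuous = 5e5, discontinuous = 1e5,
                 sporadic_isolated = 3e5, glacial = 1e4)
  river_peak <- c(continuous = 1e5, discontinuous = 2e4,
                  sporadic_isolated = 5e4, glacial = 2e3)
  lake_ratio <- c(0.20, 0.18, 0.15, 0.25, 0.45, 0.70,
                  0.85, 0.95, 1.00, 0.90, 0.55, 0.30)
  river_ratio <- c(0, 0, 0.05, 0.35, 0.85, 1.00,
                   0.95, 0.90, 0.80, 0.50, 0.15, 0)
  dplyr::bind_rows(
    tidyr::expand_grid(zone = ghg_zones(), month = 1:12) |>
      dplyr::mutate(water_body = "lake",
                    area = unname(lake_peak[.data$zone]) *
                      lake_ratio[.data$month]),
    tidyr::expand_grid(zone = ghg_zones(), month = 1:12) |>
      dplyr::mutate(water_body = "river",
                    area = unname(river_peak[.data$zone]) *
                      river_ratio[.data$month])
  ) |>
    dplyr::select("zone", "water_body", "month", "area")
}

draw_group <- function(n, gas, pathway, water_body, zone, month, cfg) {
  p <- flux_model_params()
  sf <- season_factor(month, cfg$seasonal_amp)
  if (gas == "CO2") {
    if (water_body == "river" && zone == "glacial") {
      if (cfg$sdlog == 0) return(rep(p$co2_glacial_river_mean, n))
      return(rnorm(n, p$co2_glacial_river_mean, 0.2 * cfg$sdlog))
    }
    mu <- p$co2_base[[water_body]] * p$co2_zone[[zone]] * sf
    if (cfg$sdlog == 0) return(rep(mu, n))
    return(rlnorm(n, log(mu), cfg$sdlog))
  }
  if (gas == "CH4" && pathway == "diffusive") {
    mu <- p$ch4_base[[water_body]] * p$ch4_zone[[zone]] * sf
    if (cfg$sdlog == 0) return(rep(mu, n))
    return(rlnorm(n, log(mu), cfg$sdlog))
  }
  if (gas == "CH4" && pathway == "ebullitive") {
    mu <- p$eb_base[[water_body]] * p$eb_zone[[zone]] * sf
    p0 <- cfg$eb_zero_prob[[water_body]]
    if (cfg$eb_sdlog == 0) return(rep((1 - p0) * mu, n))
    nz <- rbinom(n, 1L, 1 - p0)
    nz * rlnorm(n, log(mu), cfg$eb_sdlog)
  } else {  # N2O
    mu <- cfg$n2o_sd * qnorm(1 - cfg$n2o_sink_share[[water_body]])
    if (cfg$n2o_sd == 0) return(rep(mu, n))
    rnorm(n, mu, cfg$n2o_sd)
  }
}

#' Generate a complete synthetic flux dataset with ground truth
#'
#' Builds a site network of `cfg$n_sites` sites per (zone, water body) cell
#' and draws dated flux observations from the generator model. Observation
#' counts per site-month are Poisson with mean `obs_rate * month_prob[m]`,
#' and months whose zonal open-water area is zero receive no observations.
#' The returned ground truth carries the closed-form group means, the area
#' table, and the implied true annual emissions.
#'
#' @param cfg A [synthetic_config()].
#' @param seed RNG seed.
#' @return List with `dataset` (a [ghg_dataset()]) and `truth` (list:
#'   `group_means`, `areas`, `annual`, `config`).
#' @export
generate_dataset <- function(cfg = synthetic_config(), seed = 1L) {
  set.seed(seed)
  areas <- generate_areas()
  means <- true_group_means(cfg)

  sources <- tibble::tibble(
    source_id = sprintf("SRC%02d", 1:4),
    citation = sprintf("Synthetic compilation %d", 1:4),
    year_published = 2018L + (0:3))

  site_grid <- tidyr::expand_grid(
    zone = ghg_zones(), water_body = ghg_water_bodies(),
    idx = seq_len(cfg$n_sites))
  sites <- site_grid |>
    dplyr::mutate(
      site_id = sprintf("%s_%s_%02d",
                        toupper(substr(.data$water_body, 1, 1)),
                        substr(.data$zone, 1, 4), .data$idx),
      source_id = sample(sources$source_id, dplyr::n(), replace = TRUE),
      latitude = runif(dplyr::n(), 45, 80),
      longitude = runif(dplyr::n(), -170, 170)) |>
    dplyr::select("site_id", "source_id", "water_body", "zone",
                  "latitude", "longitude")

  open <- areas |>
    dplyr::filter(.data$area > 0) |>
    dplyr::distinct(.data$zone, .data$water_body, .data$month)
  strata <- dplyr::distinct(means, .data$gas, .data$pathway)

  # one Poisson draw per site x open month x stratum, then one value draw per
  # populated (gas, pathway, water body, zone, month) cell
  cells <- sites[, c("site_id", "water_body", "zone")] |>
    dplyr::inner_join(open, by = c("water_body", "zone"),
                      relationship = "many-to-many") |>
    tidyr::crossing(strata) |>
    dplyr::filter(!(.data$gas == "N2O" & .data$zone == "glacial")) |>
    dplyr::arrange(.data$gas, .data$pathway, .data$water_body, .data$zone,
                   .data$month, .data$site_id)
  n_draw <- rpois(nrow(cells), cfg$obs_rate * cfg$month_prob[cells$month])
  obs <- cells[rep(seq_len(nrow(cells)), n_draw), ]

  obs$flux <- NA_real_
  keyv <- paste(obs$gas, obs$pathway, obs$water_body, obs$zone, obs$month)
  for (k in unique(keyv)) {
    idx <- which(keyv == k)
    first <- obs[idx[1], ]
    obs$flux[idx] <- draw_group(length(idx), first$gas, first$pathway,
                                first$water_body, first$zone, first$month, cfg)
  }
  day <- 1L + floor(runif(nrow(obs)) * days_in_month()[obs$month])
  obs$date_or_period <- sprintf("%04d-%02d-%02d",
                                sample(2005:2020, nrow(obs), replace = TRUE),
                                obs$month, day)
  fluxes <- obs[, c("site_id", "date_or_period", "gas", "pathway", "flux")]
  # duplicate (site, date, gas, pathway) keys are legitimate sub-daily
  # replicates; averaging them at harmonization is part of the contract

  ds <- ghg_dataset(sources, sites, fluxes)
  truth <- list(
    group_means = means,
    areas = areas,
    annual = true_annual_emissions(means, areas),
    config = cfg)
  list(dataset = ds, truth = truth)
}

#' Closed-form annual emissions implied by true means and areas
#'
#' For each (gas, water body, zone): sum over months of
#' `flux_to_emission(true mean, area, days, gas)`, with CH4 as the sum of its
#' diffusive and ebullitive pathways. Also returns per-gas cryosphere totals
#' (`water_body = zone = "all"`).
#'
#' @param group_means Tibble from [true_group_means()].
#' @param areas Area table as from [generate_areas()].
#' @return Tibble: `gas`, `water_body`, `zone`, `annual` (Tg, or Gg for N2O).
#' @export
true_annual_emissions <- function(group_means, areas) {
  joined <- group_means |>
    dplyr::inner_join(areas, by = c("water_body", "zone", "month")) |>
    dplyr::mutate(days = days_in_month()[.data$month])
  joined$emission <- purrr::pmap_dbl(
    list(joined$true_mean, joined$area, joined$days, joined$gas),
    function(f, a, d, g) flux_to_emission(f, a, d, g))
  by_zone <- joined |>
    dplyr::group_by(.data$gas, .data$water_body, .data$zone) |>
    dplyr::summarise(annual = sum(.data$emission), .groups = "drop")
  total <- by_zone |>
    dplyr::group_by(.data$gas) |>
    dplyr::summarise(annual = sum(.data$annual), .groups = "drop") |>
    dplyr::mutate(water_body = "all", zone = "all")
  dplyr::bind_rows(by_zone, total)[, c("gas", "water_body", "zone", "annual")]
}

#' Draw a synthetic lake-area inventory from a truncated power law
#'
#' Lake areas follow the size-abundance law `N(a) ~ c a^b` on `[a_lo, a_hi]`,
#' i.e. areas are drawn from the density proportional to `a^b` truncated to
#' the range (inverse-CDF sampling). Binning and refitting the inventory
#' recovers `b`.
#'
#' @param n Number of lakes to draw.
#' @param b Power-law exponent (must be < -1 for a realistic size spectrum).
#' @param range Length-2 area range in km^2 (default `c(0.03, 0.1)`).
#' @param seed RNG seed.
#' @return Numeric vector of `n` lake areas.
#' @export
generate_lake_inventory <- function(n, b = -1.49, range = c(0.03, 0.1),
                                    seed = 1L) {
  assert_that(length(range) == 2 && range[1] > 0 && range[1] < range[2],
              "range must be c(lo, hi) with 0 < lo < hi")
  assert_that(b < -1, "b must be < -1")
  set.seed(seed)
  u <- runif(n)
  k <- b + 1
  (range[1]^k + u * (range[2]^k - range[1]^k))^(1 / k)
}

#' Generate a synthetic gridded NEE field with known zonal sums
#'
#' Builds an `nr x nc` field (negative values = land sink) and per-zone
#' coverage-fraction grids: the four zones are contiguous column bands whose
#' boundary cells are split fractionally between neighbours. The true zonal
#' sums are computed directly from the weighted-sum definition.
#'
#' @param nr,nc Grid dimensions (defaults 10 x 10).
#' @param base Mean field value (default -2; a sink).
#' @param gradient Linear east-west trend added across columns (default 1).
#' @param noise Standard deviation of cell noise (default 0.5; `0` gives a
#'   deterministic field).
#' @param cell_area Cell area in km^2 (default 81).
#' @param seed RNG seed.
#' @return List with `field` (matrix), `coverage` (named list of matrices),
#'   `cell_area`, and `true_sums` (tibble `zone`, `nee`).
#' @export
generate_nee_grid <- function(nr = 10L, nc = 10L, base = -2, gradient = 1,
                              noise = 0.5, cell_area = 81, seed = 1L) {
  set.seed(seed)
  grad <- matrix(rep(seq(-gradient, gradient, length.out = nc), each = nr),
                 nrow = nr)
  field <- base + grad +
    (if (noise > 0) matrix(rnorm(nr * nc, 0, noise), nrow = nr) else 0)

  # contiguous column bands with fractional boundaries
  zones <- ghg_zones()
  edges <- seq(0, nc, length.out = length(zones) + 1)
  coverage <- lapply(seq_along(zones), function(z) {
    lo <- edges[z]; hi <- edges[z + 1]
    frac_col <- pmax(0, pmin(seq_len(nc), hi) - pmax(seq_len(nc) - 1, lo))
    matrix(rep(frac_col, each = nr), nrow = nr)
  })
  names(coverage) <- zones

  true_sums <- tibble::tibble(
    zone = zones,
    nee = vapply(coverage, function(fr) sum(field * fr) * cell_area, 0,
                 USE.NAMES = FALSE))
  list(field = field, coverage = coverage, cell_area = cell_area,
       true_sums = true_sums)
}
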