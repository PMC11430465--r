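# CO2-equivalent budgeting: global-warming-potential conversion, combined-GHG
# totals, fractional-coverage zonal NEE aggregation, and the terrestrial-sink
# offset comparison.

#' Global warming potential specification
#'
#' IPCC AR6 mass-based factors: under GWP20 1 kg of CH4 (N2O) has the warming
#' effect of 79.7 (273) kg of CO2; under GWP100, 27.0 (273) kg.
#'
#' @param horizon `"GWP20"` or `"GWP100"`.
#' @return List with `horizon`, `ch4_factor`, `n2o_factor`.
#' @export
#' @examples
#' gwp_spec("GWP20")$ch4_factor
gwp_spec <- function(horizon = c("GWP100", "GWP20")) {
  horizon <- match.arg(horizon)
  list(horizon = horizon,
       ch4_factor = if (horizon == "GWP20") 79.7 else 27.0,
       n2o_factor = 273)
}

# Tg CO2e per native reporting unit of the gas (Tg for CO2/CH4, Gg for N2O;
# the Gg -> Tg conversion happens here so budget sums are uniformly Tg CO2e).
co2e_factor <- function(gas, spec) {
  unname(c(CO2 = 1, CH4 = spec$ch4_factor, N2O = spec$n2o_factor / 1000)[gas])
}

#' Convert emission estimates to CO2 equivalents
#'
#' CO2 passes through; CH4 mass (Tg) is scaled by the CH4 factor; N2O mass
#' (Gg) is converted to Tg and scaled by the N2O factor. Replicates, where
#' present, are converted element-wise so downstream quantiles stay coherent;
#' the conversion is linear, so medians and quartiles scale by the same
#' factor.
#'
#' @param estimates Tibble from [aggregate_emissions()] (columns `gas`,
#'   `median`, `q1`, `q3`, `unit`, optionally `replicates`).
#' @param spec A [gwp_spec()].
#' @return The same tibble with `median`, `q1`, `q3` (and `replicates`) in
#'   Tg CO2e, `unit` set to `"Tg CO2e"`, and a `horizon` column.
#' @export
to_co2e <- function(estimates, spec = gwp_spec()) {
  assert_that(all(estimates$gas %in% ghg_gases()),
              sprintf("unknown gas: %s",
                      paste(setdiff(estimates$gas, ghg_gases()), collapse = ",")))
  f <- co2e_factor(estimates$gas, spec)
  out <- estimates
  out$median <- out$median * f
  out$q1 <- out$q1 * f
  out$q3 <- out$q3 * f
  if ("replicates" %in% names(out)) {
    out$replicates <- purrr::map2(out$replicates, f, function(r, fi) {
      if (is.null(r)) NULL else r * fi
    })
  }
  out$unit <- "Tg CO2e"
  out$horizon <- spec$horizon
  out
}

#' Combine per-gas emissions into a total CO2e GHG budget
#'
#' Converts each gas to CO2 equivalents and sums across gases within every
#' scope cell (water body x zone x month). Where all contributing rows carry
#' replicates the sum is replicate-wise and quantiles come from the summed
#' replicates; otherwise the median is the sum of medians and the quartiles
#' are reported as `NA` (quantiles are never summed).
#'
#' @param estimates Tibble of per-gas estimates sharing scope columns
#'   (`gas`, `water_body`, `zone`, `month`, `median`, `q1`, `q3`, `unit`,
#'   optionally `replicates`).
#' @param spec A [gwp_spec()].
#' @return Tibble with one row per scope cell: `water_body`, `zone`, `month`,
#'   `median`, `q1`, `q3`, `unit = "Tg CO2e"`, `horizon`, `gases` (gases
#'   summed).
#' @export
combine_budget <- function(estimates, spec = gwp_spec()) {
  scope_cols <- intersect(c("water_body", "zone", "month"), names(estimates))
  conv <- to_co2e(estimates, spec)
  has_reps <- "replicates" %in% names(conv) &&
    all(!purrr::map_lgl(conv$replicates, is.null))
  if (has_reps) {
    lens <- unique(purrr::map_int(conv$replicates, length))
    assert_that(length(lens) == 1,
                "replicate vectors must share one length across gases")
  }
  grouped <- conv |>
    dplyr::group_by(dplyr::across(dplyr::all_of(scope_cols)))
  if (has_reps) {
    sums <- grouped |>
      dplyr::summarise(
        reps = list(sum_replicates(.data$replicates)),
        gases = paste(sort(unique(.data$gas)), collapse = "+"),
        .groups = "drop")
    qs <- dplyr::bind_rows(purrr::map(sums$reps, summarise_replicates))
    out <- dplyr::bind_cols(sums[, c(scope_cols, "gases")], qs)
    out$replicates <- sums$reps
  } else {
    out <- grouped |>
      dplyr::summarise(
        median = sum(.data$median),
        gases = paste(sort(unique(.data$gas)), collapse = "+"),
        .groups = "drop")
    out$q1 <- NA_real_
    out$q3 <- NA_real_
  }
  out$unit <- "Tg CO2e"
  out$horizon <- spec$horizon
  out
}

#' Zonal aggregation of a gridded NEE field with fractional coverage
#'
#' Computes, for each cryosphere zone, `sum(cells) value x cell_area x
#' coverage_fraction` — the weighted sum a polygon extraction with exact
#' cell-coverage fractions would produce. Fields are mass per unit area per
#' period; with `cell_area` in km^2 and values in g m^-2 the result can be
#' rescaled by the caller (the function is unit-agnostic and linear).
#'
#' @param field Numeric matrix of per-cell NEE values (negative = land sink).
#' @param coverage Named list of matrices (one per zone, same dimensions as
#'   `field`) of cell coverage fractions in `[0, 1]`.
#' @param cell_area Area of one grid cell (km^2); default 81 (9 x 9 km cells).
#' @return Tibble with columns `zone` and `nee` (field unit x km^2).
#' @export
aggregate_nee <- function(field, coverage, cell_area = 81) {
  assert_that(is.matrix(field), "field must be a matrix")
  assert_that(is.list(coverage) && !is.null(names(coverage)),
              "coverage must be a named list of matrices")
  assert_that(cell_area > 0, "cell_area must be > 0")
  out <- purrr::imap(coverage, function(frac, zone) {
    assert_that(all(dim(frac) == dim(field)),
                sprintf("coverage grid for zone %s has wrong dimensions", zone))
    assert_that(all(frac >= 0 & frac <= 1),
                sprintf("coverage fractions for zone %s outside [0, 1]", zone))
    tibble::tibble(zone = zone, nee = sum(field * frac) * cell_area)
  })
  dplyr::bind_rows(out)
}

#' Summarise a multi-year monthly zonal NEE series
#'
#' Sums monthly zonal NEE to calendar-year totals (years with fewer than 12
#' months are dropped as incomplete edge years) and reports the median and
#' interquartile range across years, per zone and for the whole cryosphere
#' (zone `"all"`, summed across zones within each year).
#'
#' @param nee_monthly Tibble with columns `zone`, `year`, `month`, `nee`
#'   (Tg CO2 per month; negative = sink).
#' @return Tibble: `zone`, `median`, `q1`, `q3`, `n_years` (annual Tg CO2).
#' @export
summarise_nee <- function(nee_monthly) {
  complete <- nee_monthly |>
    dplyr::group_by(.data$zone, .data$year) |>
    dplyr::filter(dplyr::n_distinct(.data$month) == 12) |>
    dplyr::summarise(nee = sum(.data$nee), .groups = "drop")
  assert_that(nrow(complete) > 0, "no complete calendar years in the series")
  total <- complete |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(nee = sum(.data$nee), .groups = "drop") |>
    dplyr::mutate(zone = "all")
  dplyr::bind_rows(complete, total) |>
    dplyr::group_by(.data$zone) |>
    dplyr::summarise(
      median = median(.data$nee),
      q1 = unname(quantile(.data$nee, 0.25)),
      q3 = unname(quantile(.data$nee, 0.75)),
      n_years = dplyr::n(), .groups = "drop")
}

#' Percentage by which aquatic CO2e emissions exceed the terrestrial sink
#'
#' For a terrestrial NEE that is a net sink (negative), returns
#' `(E - |NEE|) / |NEE| * 100`: the percent by which annual inland-water CO2e
#' emissions exceed the magnitude of the land carbon sink.
#'
#' @param co2e_total Annual inland-water emission, Tg CO2e yr^-1.
#' @param nee Annual terrestrial NEE, Tg CO2 yr^-1; must be negative (a sink).
#' @return Percentage (numeric scalar).
#' @export
#' @examples
#' offset_percentage(1533.6, -623)  # ~146
offset_percentage <- function(co2e_total, nee) {
  assert_that(is.finite(nee) && nee != 0, "NEE must be nonzero")
  assert_that(nee < 0,
              "NEE is a net source (positive): there is no sink to offset")
  (co2e_total - abs(nee)) / abs(nee) * 100
}
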