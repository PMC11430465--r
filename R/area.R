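# Monthly open-water surface area assembly: size-binned lake inventories, the
# log-log power-law size-abundance fit, extrapolation of small-lake number and
# area, seasonal scaling of the small-lake series, and the river freeze
# adjustment. Areas are km^2 throughout.

#' Bin a lake-area inventory into fixed-width size classes
#'
#' Bins are half-open intervals `[k w, (k+1) w)` of width `w`; for each
#' non-empty bin the arithmetic mean area of its member lakes and the member
#' count are returned. Empty bins are omitted.
#'
#' @param areas Numeric vector of individual lake areas (km^2, all > 0).
#' @param bin_width Bin width in km^2 (default 0.0001, i.e. 100 m^2).
#' @return Tibble with columns `mean_area` (km^2) and `count`, ordered by
#'   `mean_area`; zero rows for empty input.
#' @export
bin_lake_inventory <- function(areas, bin_width = 1e-4) {
  assert_that(bin_width > 0, "bin_width must be > 0")
  if (length(areas) == 0) {
    return(tibble::tibble(mean_area = double(), count = integer()))
  }
  assert_that(all(is.finite(areas) & areas > 0), "all areas must be finite and > 0")
  k <- floor(areas / bin_width)
  tibble::tibble(
    mean_area = as.numeric(tapply(areas, k, mean)),
    count = as.integer(tapply(areas, k, length))
  ) |>
    dplyr::arrange(.data$mean_area)
}

#' Fit the lake size-abundance power law
#'
#' Ordinary least squares of log10(count) on log10(mean area) over the bins
#' whose mean area falls inside `fit_range` (inclusive). The fitted law is
#' `count = c * area^b` with `c = 10^intercept` (no back-transform bias
#' correction) and `b` the slope.
#'
#' @param bins Tibble from [bin_lake_inventory()] (columns `mean_area`,
#'   `count`).
#' @param fit_range Length-2 numeric: area range (km^2) of bins used in the
#'   fit. Default `c(0.03, 0.1)`, the size class where the inventory is
#'   reliable.
#' @return An object of class `power_law_fit`: list with `c`, `b`, `r2`,
#'   `n_bins`, `fit_range`.
#' @export
fit_size_abundance <- function(bins, fit_range = c(0.03, 0.1)) {
  assert_that(is.numeric(fit_range) && length(fit_range) == 2 &&
                fit_range[1] < fit_range[2], "fit_range must be c(lo, hi), lo < hi")
  use <- bins$mean_area >= fit_range[1] & bins$mean_area <= fit_range[2]
  zero <- use & bins$count <= 0
  if (any(zero)) {
    warning(sprintf("%d zero-count bin(s) inside fit_range excluded", sum(zero)),
            call. = FALSE)
    use <- use & bins$count > 0
  }
  assert_that(sum(use) >= 3,
              sprintf("need >= 3 usable bins inside fit_range, got %d", sum(use)))
  fit <- lm(log10(count) ~ log10(mean_area), data = bins[use, ])
  structure(
    list(c = 10^unname(coef(fit)[1]), b = unname(coef(fit)[2]),
         r2 = summary(fit)$r.squared, n_bins = sum(use), fit_range = fit_range),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "<power_law_fit> count = %.5f * area^%.6f  (R2 = %.4f, %d bins in [%g, %g] km2)\n",
    x$c, x$b, x$r2, x$n_bins, x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' Extrapolate small-lake number and area from a fitted power law
#'
#' Evaluates the fitted abundance `N(a) = c a^b` at bin centers
#' `a = a_min, a_min + step, ..., a_max` (both endpoints included) and returns
#' the summed (unrounded) lake count and the summed area `sum N(a) * a`.
#'
#' @param fit A `power_law_fit`, or a list with elements `c` and `b`.
#' @param a_min,a_max Extrapolation range in km^2 (defaults 0.0001 and 0.03).
#' @param step Bin width in km^2 (default 0.0001).
#' @return List with `total_count` (lakes) and `total_area` (km^2).
#' @export
#' @examples
#' extrapolate_small_lakes(list(c = 23.74398, b = -1.490131))
extrapolate_small_lakes <- function(fit, a_min = 1e-4, a_max = 0.03, step = 1e-4) {
  assert_that(a_min > 0 && a_max >= a_min, "need 0 < a_min <= a_max")
  assert_that(step > 0, "step must be > 0")
  a <- seq(a_min, a_max, by = step)
  n <- fit$c * a^fit$b
  list(total_count = sum(n), total_area = sum(n * a))
}

#' Distribute a yearly-maximum small-lake area over months
#'
#' The extrapolated small-lake area is a yearly maximum assumed to occur in
#' September (as for the 0.1-1 km^2 size class whose monthly dynamics are
#' observed); each month receives `max_area` times that month's
#' area-to-September ratio of the reference class.
#'
#' @param max_area Yearly maximum area (km^2) of the small-lake class.
#' @param reference_ratios Numeric vector of 12 monthly ratios (month area /
#'   September area of the reference size class); all in `[0, 1]`, September
#'   (month 9) equal to 1.
#' @return Numeric vector of 12 monthly areas (km^2).
#' @export
monthly_small_lake_area <- function(max_area, reference_ratios) {
  assert_that(length(reference_ratios) == 12, "need 12 monthly ratios")
  assert_that(all(reference_ratios >= 0 & reference_ratios <= 1),
              "ratios must be in [0, 1] (September is the maximum)")
  assert_that(isTRUE(all.equal(reference_ratios[9], 1)),
              "September ratio must equal 1")
  assert_that(max_area >= 0, "max_area must be >= 0")
  max_area * reference_ratios
}

#' Apply the winter-freeze adjustment to a monthly river-area series
#'
#' Cryosphere rivers are taken to be completely frozen in the coldest month:
#' the January area is subtracted from every month and the result clipped at
#' zero, so January becomes 0 and all months shift down by the residual winter
#' baseline.
#'
#' @param monthly Numeric vector of 12 non-negative monthly areas (km^2),
#'   January first.
#' @return Numeric vector of 12 adjusted areas.
#' @export
adjust_river_area <- function(monthly) {
  assert_that(length(monthly) == 12, "need 12 monthly values")
  assert_that(all(monthly >= 0), "areas must be non-negative")
  pmax(monthly - monthly[1], 0)
}

#' Assemble the monthly area table for upscaling
#'
#' Combines, per cryosphere zone, the large-lake monthly series with the
#' extrapolated small-lake series (allocated across zones proportionally to
#' each zone's large-lake area in that month) and the freeze-adjusted river
#' series, into one row per (zone, water body, month).
#'
#' @param lake_large Tibble: `zone`, `month`, `area` (km^2) for lakes covered
#'   by the monthly area product.
#' @param river Tibble: `zone`, `month`, `area` (km^2) for rivers, already
#'   freeze-adjusted (see [adjust_river_area()]).
#' @param small_lake_monthly Optional numeric vector of 12 cryosphere-wide
#'   small-lake areas (km^2) from [monthly_small_lake_area()]; `NULL` (default)
#'   adds nothing.
#' @return Tibble with columns `zone`, `water_body`, `month`, `area`: one row
#'   per (zone, water body, month), 96 rows in total.
#' @export
assemble_area_table <- function(lake_large, river, small_lake_monthly = NULL) {
  check_series <- function(df, what) {
    need <- tidyr::expand_grid(zone = ghg_zones(), month = 1:12)
    got <- dplyr::anti_join(need, df, by = c("zone", "month"))
    assert_that(nrow(got) == 0,
                sprintf("%s series missing %d (zone, month) cell(s), e.g. %s month %d",
                        what, nrow(got), got$zone[1] %||% "?", got$month[1] %||% 0L))
  }
  check_series(lake_large, "lake")
  check_series(river, "river")

  lake <- lake_large |>
    dplyr::select("zone", "month", "area")
  if (!is.null(small_lake_monthly)) {
    assert_that(length(small_lake_monthly) == 12, "need 12 small-lake areas")
    lake <- lake |>
      dplyr::group_by(.data$month) |>
      dplyr::mutate(
        share = if (sum(.data$area) > 0) .data$area / sum(.data$area) else 1 / dplyr::n(),
        area = .data$area + small_lake_monthly[.data$month[1]] * .data$share) |>
      dplyr::ungroup() |>
      dplyr::select(-"share")
  }

  dplyr::bind_rows(
    dplyr::mutate(lake, water_body = "lake"),
    dplyr::mutate(dplyr::select(river, "zone", "month", "area"),
                  water_body = "river")
  ) |>
    dplyr::select("zone", "water_body", "month", "area") |>
    dplyr::arrange(match(.data$zone, ghg_zones()), .data$water_body, .data$month)
}

#' Read or write a monthly area table
#'
#' Delimited text with columns `zone`, `water_body`, `month`, `area_km2`.
#'
#' @param path File path.
#' @return For `read_area_table()`, a tibble with columns `zone`,
#'   `water_body`, `month`, `area`.
#' @export
read_area_table <- function(path) {
  assert_that(file.exists(path), sprintf("area table not found: %s", path))
  tab <- read_delim_auto(path, readr::cols(
    zone = readr::col_character(), water_body = readr::col_character(),
    month = readr::col_integer(), area_km2 = readr::col_double()))
  dplyr::rename(tab, area = "area_km2")
}

#' @rdname read_area_table
#' @param areas Tibble with columns `zone`, `water_body`, `month`, `area`.
#' @export
write_area_table <- function(areas, path) {
  readr::write_csv(dplyr::rename(areas, area_km2 = "area"), path, progress = FALSE)
  invisible(path)
}
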