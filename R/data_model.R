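# Observation schema: four linked tables (sources, sites, concentrations,
# fluxes) mirroring the compiled cryosphere inland-water GHG database layout.
# Fluxes are areal rates in mmol m^-2 day^-1; concentrations are carried and
# validated but never enter the emission estimates.

#' Construct a GHG flux dataset
#'
#' Bundles the four subtables of the observation schema into a single object.
#' Every flux and concentration row must reference a known `site_id`, and every
#' site a known `source_id`; referential integrity is checked at construction.
#'
#' @param sources Data frame with columns `source_id`, `citation`,
#'   `year_published`.
#' @param sites Data frame with columns `site_id`, `source_id`, `water_body`
#'   (`"lake"` or `"river"`), `zone` (one of `"continuous"`,
#'   `"discontinuous"`, `"sporadic_isolated"`, `"glacial"`), `latitude`,
#'   `longitude`.
#' @param fluxes Data frame with columns `site_id`, `date_or_period`, `gas`
#'   (`"CO2"`, `"CH4"`, `"N2O"`), `pathway` (`"diffusive"`, `"ebullitive"`,
#'   `"total"`; the latter two only for CH4), `flux` (mmol m^-2 day^-1,
#'   signed).
#' @param concentrations Optional data frame with columns `site_id`,
#'   `date_or_period`, `gas`, `concentration`. Schema-validated only.
#' @param check Check referential integrity (default `TRUE`).
#'
#' @return An object of class `ghg_dataset`: a list with elements `sources`,
#'   `sites`, `concentrations`, `fluxes` (tibbles).
#' @export
#' @examples
#' ds <- ghg_dataset(
#'   sources = data.frame(source_id = "S1", citation = "Doe 2020",
#'                        year_published = 2020L),
#'   sites = data.frame(site_id = "L1", source_id = "S1", water_body = "lake",
#'                      zone = "continuous", latitude = 68.1, longitude = 20.5),
#'   fluxes = data.frame(site_id = "L1", date_or_period = "2014-07-19",
#'                       gas = "CO2", pathway = "diffusive", flux = 12.3)
#' )
#' ds
ghg_dataset <- function(sources, sites, fluxes, concentrations = NULL, check = TRUE) {
  sources <- tibble::as_tibble(sources)
  sites <- tibble::as_tibble(sites)
  fluxes <- tibble::as_tibble(fluxes)
  concentrations <- if (is.null(concentrations)) {
    tibble::tibble(site_id = character(), date_or_period = character(),
                   gas = character(), concentration = double())
  } else {
    tibble::as_tibble(concentrations)
  }

  req <- function(df, cols, what) {
    missing <- setdiff(cols, names(df))
    assert_that(length(missing) == 0,
                sprintf("%s table lacks column(s): %s", what,
                        paste(missing, collapse = ", ")))
  }
  req(sources, c("source_id", "citation", "year_published"), "sources")
  req(sites, c("site_id", "source_id", "water_body", "zone",
               "latitude", "longitude"), "sites")
  req(fluxes, c("site_id", "date_or_period", "gas", "pathway", "flux"), "fluxes")
  req(concentrations, c("site_id", "date_or_period", "gas", "concentration"),
      "concentrations")

  ds <- structure(
    list(sources = sources, sites = sites,
         concentrations = concentrations, fluxes = fluxes),
    class = "ghg_dataset"
  )
  if (check) {
    bad_src <- setdiff(sites$source_id, sources$source_id)
    assert_that(length(bad_src) == 0,
                sprintf("sites reference unknown source_id(s): %s",
                        paste(unique(bad_src), collapse = ", ")))
    bad_site <- setdiff(fluxes$site_id, sites$site_id)
    assert_that(length(bad_site) == 0,
                sprintf("fluxes reference unknown site_id(s): %s",
                        paste(unique(bad_site), collapse = ", ")))
    bad_conc <- setdiff(concentrations$site_id, sites$site_id)
    assert_that(length(bad_conc) == 0,
                sprintf("concentrations reference unknown site_id(s): %s",
                        paste(unique(bad_conc), collapse = ", ")))
  }
  ds
}

#' @export
print.ghg_dataset <- function(x, ...) {
  cat("<ghg_dataset>\n")
  cat(sprintf("  sources:        %d\n", nrow(x$sources)))
  cat(sprintf("  sites:          %d (%s)\n", nrow(x$sites),
              paste(sprintf("%d %s", table(x$sites$water_body),
                            names(table(x$sites$water_body))),
                    collapse = ", ")))
  cat(sprintf("  fluxes:         %d\n", nrow(x$fluxes)))
  cat(sprintf("  concentrations: %d\n", nrow(x$concentrations)))
  invisible(x)
}

# canonical on-disk file names
dataset_files <- function() {
  c(sources = "sources.csv", sites = "sites.csv",
    concentrations = "concentrations.csv", fluxes = "fluxes.csv")
}

read_delim_auto <- function(path, col_types) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) {
    readr::read_tsv(path, col_types = col_types, progress = FALSE)
  } else {
    readr::read_csv(path, col_types = col_types, progress = FALSE)
  }
}

#' Read a GHG flux dataset from delimited text
#'
#' Reads the four subtables (comma-delimited canonical; tab-delimited accepted)
#' and assembles a [ghg_dataset()], checking referential integrity. Rows that
#' fail to parse are reported through `readr`'s problem mechanism rather than
#' silently dropped.
#'
#' @param dir Directory holding `sources.csv`, `sites.csv`,
#'   `concentrations.csv` (optional on disk), `fluxes.csv`; ignored when all
#'   four `*_file` paths are given.
#' @param sources_file,sites_file,concentrations_file,fluxes_file Explicit file
#'   paths overriding `dir`.
#' @return A `ghg_dataset`.
#' @seealso [write_ghg_dataset()], [validate_dataset()]
#' @export
read_ghg_dataset <- function(dir = NULL, sources_file = NULL, sites_file = NULL,
                             concentrations_file = NULL, fluxes_file = NULL) {
  files <- dataset_files()
  pick <- function(explicit, name) {
    if (!is.null(explicit)) return(explicit)
    assert_that(!is.null(dir), "either `dir` or explicit file paths are required")
    file.path(dir, files[[name]])
  }
  src_p <- pick(sources_file, "sources")
  site_p <- pick(sites_file, "sites")
  flux_p <- pick(fluxes_file, "fluxes")
  conc_p <- concentrations_file %||%
    (if (!is.null(dir) && file.exists(file.path(dir, files[["concentrations"]])))
       file.path(dir, files[["concentrations"]]) else NULL)

  sources <- read_delim_auto(src_p, readr::cols(
    source_id = readr::col_character(), citation = readr::col_character(),
    year_published = readr::col_integer()))
  sites <- read_delim_auto(site_p, readr::cols(
    site_id = readr::col_character(), source_id = readr::col_character(),
    water_body = readr::col_character(), zone = readr::col_character(),
    latitude = readr::col_double(), longitude = readr::col_double()))
  fluxes <- read_delim_auto(flux_p, readr::cols(
    site_id = readr::col_character(), date_or_period = readr::col_character(),
    gas = readr::col_character(), pathway = readr::col_character(),
    flux = readr::col_double()))
  conc <- if (is.null(conc_p)) NULL else read_delim_auto(conc_p, readr::cols(
    site_id = readr::col_character(), date_or_period = readr::col_character(),
    gas = readr::col_character(), concentration = readr::col_double()))

  for (tab in list(sources, sites, fluxes, conc)) {
    if (!is.null(tab)) {
      probs <- readr::problems(tab)
      if (nrow(probs) > 0) {
        warning(sprintf("%d row(s) failed to parse cleanly; see readr::problems()",
                        nrow(probs)), call. = FALSE)
      }
    }
  }
  ghg_dataset(sources, sites, fluxes, concentrations = conc)
}

#' Write a GHG flux dataset to delimited text
#'
#' Writes the four subtables as UTF-8 comma-delimited files into `dir`.
#' `read_ghg_dataset()` on the result reproduces the dataset field for field.
#'
#' @param ds A `ghg_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ghg_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "ghg_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- dataset_files()
  for (name in names(files)) {
    readr::write_csv(ds[[name]], file.path(dir, files[[name]]), progress = FALSE)
  }
  invisible(dir)
}

#' Resolve an observation date or period label to a calendar month
#'
#' Daily dates (`"2014-07-19"`) map to their calendar month; explicit month
#' labels (`"July"`, `"Jul"`, `"2014-07"`, `"7"`) pass through. Season, annual
#' or free-text period labels cannot be placed in a month without per-study
#' metadata and resolve to `NA` (such records are excluded from monthly
#' upscaling and counted in the coverage log).
#'
#' @param x Character vector of date or period labels.
#' @return Integer vector of months (1-12) with `NA` for unresolved labels.
#' @export
#' @examples
#' resolve_month(c("2014-07-19", "July", "open-water season"))
resolve_month <- function(x) {
  x <- as.character(x)
  out <- rep(NA_integer_, length(x))
  x_trim <- trimws(x)

  is_date <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x_trim)
  if (any(is_date, na.rm = TRUE)) {
    idx <- which(is_date)
    d <- as.Date(x_trim[idx], format = "%Y-%m-%d")
    bad <- is.na(d)
    if (any(bad)) {
      stop(sprintf("malformed date string(s) at position(s): %s",
                   paste(idx[bad], collapse = ", ")), call. = FALSE)
    }
    out[idx] <- as.integer(format(d, "%m"))
  }

  is_ym <- !is_date & grepl("^\\d{4}-\\d{2}$", x_trim)
  out[is_ym] <- as.integer(substr(x_trim[is_ym], 6, 7))

  is_num <- !is_date & !is_ym & grepl("^\\d{1,2}$", x_trim)
  out[is_num] <- as.integer(x_trim[is_num])

  month_lut <- setNames(rep(1:12, 2), c(tolower(month.name), tolower(month.abb)))
  is_name <- is.na(out) & tolower(x_trim) %in% names(month_lut)
  out[is_name] <- month_lut[tolower(x_trim[is_name])]

  out[!is.na(out) & (out < 1L | out > 12L)] <- NA_integer_
  out
}

#' Validate a GHG flux dataset against the schema invariants
#'
#' Checks enum domains (water body, zone, gas, pathway), coordinate ranges,
#' pathway/gas compatibility (only CH4 may be ebullitive or total), the
#' non-negativity of ebullitive fluxes, flux finiteness, and uniqueness of
#' source and site identifiers. This is a reporting operation: it never throws.
#'
#' @param ds A `ghg_dataset`.
#' @return A tibble with columns `table`, `row`, `field`, `message`; zero rows
#'   if and only if the dataset satisfies every invariant.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "ghg_dataset"))
  v <- list()
  add <- function(table, row, field, message) {
    if (length(row) > 0) {
      v[[length(v) + 1]] <<- tibble::tibble(
        table = table, row = as.integer(row), field = field, message = message)
    }
  }

  add("sources", which(duplicated(ds$sources$source_id)), "source_id",
      "duplicated source_id")
  add("sites", which(duplicated(ds$sites$site_id)), "site_id",
      "duplicated site_id")
  add("sites", which(!(ds$sites$water_body %in% ghg_water_bodies())),
      "water_body", "water_body must be 'lake' or 'river'")
  add("sites", which(!(ds$sites$zone %in% ghg_zones())), "zone",
      sprintf("zone must be one of: %s", paste(ghg_zones(), collapse = ", ")))
  add("sites", which(is.na(ds$sites$latitude) | abs(ds$sites$latitude) > 90),
      "latitude", "latitude must be in [-90, 90]")
  add("sites", which(is.na(ds$sites$longitude) | abs(ds$sites$longitude) > 180),
      "longitude", "longitude must be in [-180, 180]")

  fl <- ds$fluxes
  add("fluxes", which(!(fl$gas %in% ghg_gases())), "gas",
      "gas must be CO2, CH4 or N2O")
  add("fluxes", which(!(fl$pathway %in% ghg_pathways())), "pathway",
      "pathway must be diffusive, ebullitive or total")
  add("fluxes", which(fl$gas != "CH4" & fl$pathway %in% c("ebullitive", "total")),
      "pathway", "only CH4 may have an ebullitive or total pathway")
  add("fluxes", which(fl$gas == "CH4" & fl$pathway == "ebullitive" & fl$flux < 0),
      "flux", "ebullition must be >= 0")
  add("fluxes", which(!is.finite(fl$flux)), "flux", "flux must be finite")

  if (length(v) == 0) {
    tibble::tibble(table = character(), row = integer(),
                   field = character(), message = character())
  } else {
    dplyr::bind_rows(v)
  }
}

#' Harmonize a dataset to the monthly analysis grain
#'
#' Prepares flux observations for upscaling: sub-daily replicates are averaged
#' to daily values keyed on (site, date, gas, pathway); date/period labels are
#' resolved to calendar months; site attributes (zone, water body) are joined
#' on. Records whose period cannot be placed in a month (season or annual
#' labels) are excluded and tallied in the coverage log.
#'
#' @param ds A validated `ghg_dataset`.
#' @return A list with elements `fluxes` (tibble: `site_id`, `zone`,
#'   `water_body`, `month`, `gas`, `pathway`, `flux`) and `coverage` (tibble
#'   tallying excluded records by reason).
#' @export
harmonize_dataset <- function(ds) {
  stopifnot(inherits(ds, "ghg_dataset"))
  fl <- ds$fluxes
  # sub-daily (or replicate) averaging at the daily key
  fl <- fl |>
    dplyr::group_by(.data$site_id, .data$date_or_period, .data$gas, .data$pathway) |>
    dplyr::summarise(flux = mean(.data$flux), .groups = "drop")

  fl$month <- resolve_month(fl$date_or_period)
  unresolved <- fl[is.na(fl$month), ]
  resolved <- fl[!is.na(fl$month), ]

  out <- resolved |>
    dplyr::inner_join(
      ds$sites[, c("site_id", "zone", "water_body")], by = "site_id") |>
    dplyr::select("site_id", "zone", "water_body", "month", "gas",
                  "pathway", "flux")

  coverage <- tibble::tibble(
    reason = c("resolved_monthly", "unresolved_period"),
    n = c(nrow(out), nrow(unresolved))
  )
  list(fluxes = out, coverage = coverage)
}
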