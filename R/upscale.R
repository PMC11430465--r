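# The core estimator: stratified two-level bootstrap of monthly group-mean
# fluxes, sparse-month substitution, integration against monthly open-water
# areas, and replicate-level aggregation. Groups are the cells of
# gas x pathway x water body x cryosphere zone x month.

group_key_cols <- function() c("gas", "pathway", "water_body", "zone", "month")

# Deterministic per-group substream seed: results are reproducible and
# independent of the order groups are processed in. Kept below 2^31.
derive_group_seed <- function(base_seed, key) {
  h <- 0
  for (ch in utf8ToInt(paste(key, collapse = "|"))) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer((as.numeric(base_seed) * 7919 + h) %% 2147483647)
}

#' Bootstrap the mean flux of one observation group
#'
#' Two-level resampling: each replicate draws sites with replacement (as many
#' as the group has), then observations with replacement within each chosen
#' site, and takes the mean of the pooled values. This respects the clustering
#' of observations within sites so heavily sampled sites do not dominate.
#' With `multilevel = FALSE` a plain observation-level bootstrap is used
#' instead (comparison mode).
#'
#' @param flux Numeric vector of flux observations (mmol m^-2 day^-1).
#' @param site_id Character or factor vector parallel to `flux`.
#' @param B Number of bootstrap replicates (default 10000).
#' @param multilevel Resample sites then observations (default `TRUE`).
#' @return List with `replicates` (length-B numeric), `median`, `q1`, `q3`,
#'   `n_obs`, `n_sites`.
#' @export
#' @examples
#' set.seed(1)
#' bootstrap_group(c(0, 10), c("a", "a"), B = 1000)$median
bootstrap_group <- function(flux, site_id, B = 10000L, multilevel = TRUE) {
  assert_that(length(flux) >= 1, "empty group: nothing to bootstrap")
  assert_that(length(site_id) == length(flux), "site_id must parallel flux")
  assert_that(all(is.finite(flux)), "flux values must be finite")
  B <- as.integer(B)
  assert_that(B >= 1L, "B must be >= 1")
  site_idx <- as.integer(factor(site_id))
  reps <- if (multilevel) {
    .boot_group_means(as.numeric(flux), site_idx, B)
  } else {
    .boot_obs_means(as.numeric(flux), B)
  }
  q <- unname(quantile(reps, c(0.25, 0.5, 0.75)))
  list(replicates = reps, median = q[2], q1 = q[1], q3 = q[3],
       n_obs = length(flux), n_sites = length(unique(site_idx)))
}

#' Bootstrap all observation groups of a harmonized flux table
#'
#' Splits the table into its (gas, pathway, water body, zone, month) groups
#' and applies [bootstrap_group()] to each, with a per-group RNG substream
#' derived deterministically from the seed and the group key.
#'
#' @param fluxes Harmonized flux tibble (from [harmonize_dataset()]).
#' @param B Bootstrap replicates per group (default 10000).
#' @param seed Base seed for the per-group substreams.
#' @param multilevel Passed to [bootstrap_group()].
#' @return Tibble with the key columns, `n_obs`, `n_sites`, `median`, `q1`,
#'   `q3`, a `replicates` list-column, and substitution bookkeeping columns
#'   (`substituted`, `donor_month`, both unset here).
#' @export
bootstrap_fluxes <- function(fluxes, B = 10000L, seed = 1L, multilevel = TRUE) {
  assert_that(all(group_key_cols() %in% names(fluxes)),
              "fluxes must carry gas, pathway, water_body, zone, month")
  assert_that(nrow(fluxes) > 0, "no flux observations to bootstrap")
  # canonical order: results do not depend on input row order
  fluxes <- dplyr::arrange(fluxes, .data$gas, .data$pathway, .data$water_body,
                           .data$zone, .data$month, .data$site_id, .data$flux)
  keyv <- paste(fluxes$gas, fluxes$pathway, fluxes$water_body, fluxes$zone,
                fluxes$month, sep = "|")
  idx_by_group <- split(seq_len(nrow(fluxes)), factor(keyv, levels = unique(keyv)))
  keys <- fluxes[vapply(idx_by_group, `[`, 0L, 1L), group_key_cols()]

  res <- vector("list", length(idx_by_group))
  for (i in seq_along(idx_by_group)) {
    idx <- idx_by_group[[i]]
    set.seed(derive_group_seed(seed, unlist(keys[i, ])))
    bs <- bootstrap_group(fluxes$flux[idx], fluxes$site_id[idx], B = B,
                          multilevel = multilevel)
    res[[i]] <- tibble::tibble(
      keys[i, ], n_obs = bs$n_obs, n_sites = bs$n_sites,
      median = bs$median, q1 = bs$q1, q3 = bs$q3,
      replicates = list(bs$replicates),
      substituted = FALSE, donor_month = NA_integer_)
  }
  dplyr::bind_rows(res)
}

#' Substitute bootstrap statistics for data-sparse months
#'
#' Within each (gas, pathway, water body, zone) stratum, every month observed
#' with fewer than `min_obs` measurements — including months with none at all —
#' discards its own bootstrap statistics and receives those of the donor
#' month: the month of the same stratum with at least `min_obs` observations
#' whose replicate median has the smallest absolute value (earlier calendar
#' month wins ties). Replicates are copied along with the summary so
#' downstream uncertainty propagation stays coherent. This is a conservative
#' fill: sparse months inherit the weakest defensible monthly signal of their
#' stratum.
#'
#' @param summaries Tibble from [bootstrap_fluxes()].
#' @param min_obs Sparseness threshold (default 3: months with fewer than
#'   three measurements are substituted).
#' @return Completed tibble: 12 months per stratum, with `substituted` and
#'   `donor_month` set on filled rows. Strata with no donor month keep their
#'   sparse rows at zero contribution (`median = q1 = q3 = 0`, zero
#'   replicates) with a warning.
#' @export
substitute_sparse_months <- function(summaries, min_obs = 3L) {
  assert_that(min_obs >= 0, "min_obs must be >= 0")
  strata <- summaries |>
    dplyr::distinct(.data$gas, .data$pathway, .data$water_body, .data$zone)
  out <- vector("list", nrow(strata))
  B <- length(summaries$replicates[[1]])
  for (i in seq_len(nrow(strata))) {
    st <- strata[i, ]
    rows <- dplyr::semi_join(summaries, st,
                             by = c("gas", "pathway", "water_body", "zone"))
    donors <- rows[rows$n_obs >= min_obs, ]
    # complete the stratum to all 12 months
    missing_months <- setdiff(1:12, rows$month)
    if (length(missing_months) > 0) {
      fill <- tibble::tibble(
        st, month = as.integer(missing_months), n_obs = 0L, n_sites = 0L,
        median = NA_real_, q1 = NA_real_, q3 = NA_real_,
        replicates = rep(list(numeric(B)), length(missing_months)),
        substituted = FALSE, donor_month = NA_integer_)
      fill <- fill[, names(rows)]
      rows <- dplyr::bind_rows(rows, fill)
    }
    sparse <- rows$n_obs < min_obs
    if (any(sparse)) {
      if (nrow(donors) == 0) {
        warning(sprintf(
          "stratum %s/%s/%s/%s has no month with >= %d observations; sparse months contribute zero",
          st$gas, st$pathway, st$water_body, st$zone, min_obs), call. = FALSE)
        for (j in which(sparse)) {
          rows$median[j] <- 0; rows$q1[j] <- 0; rows$q3[j] <- 0
          rows$replicates[[j]] <- numeric(B)
          rows$substituted[j] <- TRUE
          rows$donor_month[j] <- NA_integer_
        }
      } else {
        d <- donors[order(abs(donors$median), donors$month), ][1, ]
        for (j in which(sparse)) {
          rows$median[j] <- d$median; rows$q1[j] <- d$q1; rows$q3[j] <- d$q3
          rows$replicates[[j]] <- d$replicates[[1]]
          rows$substituted[j] <- TRUE
          rows$donor_month[j] <- d$month
        }
      }
    }
    out[[i]] <- dplyr::arrange(rows, .data$month)
  }
  dplyr::bind_rows(out)
}

#' Convert an areal flux to a monthly mass emission
#'
#' mass(g) = flux (mmol m^-2 day^-1) x 10^-3 mol/mmol x M (g/mol)
#'           x area (km^2) x 10^6 m^2/km^2 x days.
#' Reported in Tg (10^12 g) for CO2 and CH4 and Gg (10^9 g) for N2O. Signs are
#' preserved, so N2O uptake (negative flux) yields a negative emission.
#'
#' @param flux Numeric flux (scalar or vector, e.g. bootstrap replicates).
#' @param area Open-water area in km^2 (>= 0).
#' @param days Number of days in the month (28-31).
#' @param gas `"CO2"`, `"CH4"` or `"N2O"`.
#' @return Mass emission, Tg per month (CO2, CH4) or Gg per month (N2O).
#' @export
#' @examples
#' flux_to_emission(1, area = 1, days = 30, gas = "CO2")  # 1.3203e-06 Tg
flux_to_emission <- function(flux, area, days, gas) {
  assert_that(length(gas) == 1 && gas %in% ghg_gases(),
              sprintf("unknown gas: %s", paste(gas, collapse = ",")))
  assert_that(all(area >= 0), "area must be >= 0")
  assert_that(all(days >= 28 & days <= 31), "days must be in [28, 31]")
  grams <- flux * 1e-3 * molar_masses()[[gas]] * area * 1e6 * days
  if (gas == "N2O") grams * 1e-9 else grams * 1e-12
}

#' Unit of the reported emission for a gas
#' @param gas Gas code.
#' @return `"Tg"` or `"Gg"`.
#' @export
emission_unit <- function(gas) ifelse(gas == "N2O", "Gg", "Tg")

# CH4 'total'-pathway rule: pathway-specific series take precedence; records
# labeled total enter only for (water body, zone, month) cells lacking both
# diffusive and ebullitive series, and are never added on top of them.
mark_usable_groups <- function(summaries) {
  ch4 <- summaries$gas == "CH4"
  use <- rep(TRUE, nrow(summaries))
  if (any(ch4 & summaries$pathway == "total")) {
    cells <- summaries[ch4, c("water_body", "zone", "month", "pathway")]
    specific <- unique(cells[cells$pathway %in% c("diffusive", "ebullitive"),
                             c("water_body", "zone", "month")])
    tot <- which(ch4 & summaries$pathway == "total")
    covered <- dplyr::semi_join(
      summaries[tot, c("water_body", "zone", "month")], specific,
      by = c("water_body", "zone", "month"))
    if (nrow(covered) > 0) {
      drop <- tot[do.call(paste, summaries[tot, c("water_body", "zone", "month")]) %in%
                    do.call(paste, covered)]
      use[drop] <- FALSE
    }
  }
  summaries$used <- use
  summaries
}

#' Integrate bootstrapped fluxes into per-group monthly emissions
#'
#' Multiplies each group's flux replicates by the matching monthly open-water
#' area and month length. CH4 groups with pathway `"total"` are used only for
#' cells lacking both pathway-specific series (column `used`).
#'
#' @param summaries Completed summaries from [substitute_sparse_months()].
#' @param areas Monthly area table (`zone`, `water_body`, `month`, `area`).
#' @return `summaries` with columns `area`, `days`, `used`, and an
#'   `emission_replicates` list-column (Tg or Gg per month), plus
#'   `emission_median`, `emission_q1`, `emission_q3`.
#' @export
group_emissions <- function(summaries, areas) {
  need <- dplyr::distinct(summaries, .data$zone, .data$water_body, .data$month)
  miss <- dplyr::anti_join(need, areas, by = c("zone", "water_body", "month"))
  assert_that(nrow(miss) == 0,
              sprintf("missing area cell(s), e.g. (%s, %s, month %d)",
                      miss$zone[1] %||% "?", miss$water_body[1] %||% "?",
                      miss$month[1] %||% 0L))
  out <- summaries |>
    mark_usable_groups() |>
    dplyr::left_join(areas, by = c("zone", "water_body", "month")) |>
    dplyr::mutate(days = days_in_month()[.data$month])
  out$emission_replicates <- purrr::pmap(
    list(out$replicates, out$area, out$days, out$gas),
    function(r, a, d, g) flux_to_emission(r, a, d, g))
  em_q <- purrr::map(out$emission_replicates,
                     ~ unname(quantile(.x, c(0.25, 0.5, 0.75))))
  out$emission_q1 <- purrr::map_dbl(em_q, 1)
  out$emission_median <- purrr::map_dbl(em_q, 2)
  out$emission_q3 <- purrr::map_dbl(em_q, 3)
  out
}

# replicate-wise sum of a list of equal-length numeric vectors
sum_replicates <- function(lst) {
  if (length(lst) == 0) return(numeric(0))
  Reduce(`+`, lst)
}

summarise_replicates <- function(reps) {
  q <- unname(quantile(reps, c(0.25, 0.5, 0.75)))
  tibble::tibble(median = q[2], q1 = q[1], q3 = q[3])
}

#' Aggregate group emissions to the reporting levels
#'
#' Sums emission replicates across groups *within each replicate index*, so
#' totals are exactly additive inside every replicate and reported quantiles
#' are quantiles of summed replicates (never sums of quantiles). Produces
#' estimates at the levels gas x water body x zone x month, gas x water body x
#' zone (annual), gas x water body (annual), gas x month, and gas (annual);
#' CH4 totals are diffusive + ebullitive within each replicate. Aggregation is
#' hierarchical — each level is the replicate-wise sum of the level below it
#' in that level's row order — so zone totals sum bitwise to body totals and
#' body totals to the cryosphere total within every replicate.
#'
#' @param group_em Output of [group_emissions()].
#' @param keep_replicates Retain the replicate vectors in the output
#'   (default `TRUE`; needed for CO2-equivalent budgeting).
#' @return Tibble with columns `gas`, `water_body`, `zone`, `month` (`"all"` /
#'   `NA` marking aggregated dimensions), `median`, `q1`, `q3`, `unit`,
#'   `n_groups`, and (optionally) a `replicates` list-column.
#' @export
aggregate_emissions <- function(group_em, keep_replicates = TRUE) {
  used <- group_em[group_em$used, ]
  agg <- function(df, by, reps_col = "reps") {
    df |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::summarise(
        reps = list(sum_replicates(.data[[reps_col]])),
        n_groups = sum(.data$n_groups), .groups = "drop")
  }
  # hierarchical replicate-wise summation: each level is the exact sum of the
  # level below it, so totals are additive bitwise within every replicate
  used$n_groups <- 1L
  cell <- agg(used, c("gas", "water_body", "zone", "month"),
              "emission_replicates")                       # CH4 = diff + eb here
  zone_annual <- agg(cell, c("gas", "water_body", "zone"))
  body_annual <- agg(zone_annual, c("gas", "water_body"))
  gas_month <- agg(cell, c("gas", "month"))
  gas_annual <- agg(body_annual, "gas")
  levels <- list(cell, zone_annual, body_annual, gas_month, gas_annual)
  all <- dplyr::bind_rows(levels)
  if (!("water_body" %in% names(all))) all$water_body <- NA_character_
  all$water_body[is.na(all$water_body)] <- "all"
  if (!("zone" %in% names(all))) all$zone <- NA_character_
  all$zone[is.na(all$zone)] <- "all"
  if (!("month" %in% names(all))) all$month <- NA_integer_

  qs <- dplyr::bind_rows(purrr::map(all$reps, summarise_replicates))
  out <- dplyr::bind_cols(
    all[, c("gas", "water_body", "zone", "month", "n_groups")], qs)
  out$unit <- emission_unit(out$gas)
  if (keep_replicates) out$replicates <- all$reps
  out
}

#' Pairwise Wilcoxon rank-sum comparison of flux rates between zones
#'
#' Two-sided Wilcoxon rank-sum tests between every pair of cryosphere zones
#' for one gas (and optionally one pathway) and water-body type, with
#' significance stars at 0.05 (*), 0.01 (**), 0.001 (***) and 0.0001 (****).
#' Degenerate comparisons where all values of both samples are tied return
#' p = 1 with a warning.
#'
#' @param fluxes Harmonized flux tibble.
#' @param gas Gas code.
#' @param water_body `"lake"` or `"river"`.
#' @param pathway Optional pathway filter (e.g. for CH4).
#' @return Tibble: `zone_a`, `zone_b`, `n_a`, `n_b`, `p_value`, `stars`.
#' @export
compare_zones <- function(fluxes, gas, water_body, pathway = NULL) {
  sub <- fluxes[fluxes$gas == gas & fluxes$water_body == water_body, ]
  if (!is.null(pathway)) sub <- sub[sub$pathway == pathway, ]
  zones <- intersect(ghg_zones(), unique(sub$zone))
  counts <- table(sub$zone)[zones]
  zones <- zones[counts >= 2]
  assert_that(length(zones) >= 2,
              "need at least two zones with >= 2 observations each")
  pairs <- utils::combn(zones, 2)
  res <- vector("list", ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    x <- sub$flux[sub$zone == pairs[1, i]]
    y <- sub$flux[sub$zone == pairs[2, i]]
    p <- if (length(unique(c(x, y))) == 1) {
      warning(sprintf("all values tied for zones %s vs %s; p = 1",
                      pairs[1, i], pairs[2, i]), call. = FALSE)
      1
    } else {
      suppressWarnings(wilcox.test(x, y, alternative = "two.sided")$p.value)
    }
    res[[i]] <- tibble::tibble(
      zone_a = pairs[1, i], zone_b = pairs[2, i],
      n_a = length(x), n_b = length(y), p_value = p)
  }
  out <- dplyr::bind_rows(res)
  out$stars <- as.character(cut(out$p_value,
                                breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
                                labels = c("****", "***", "**", "*", "")))
  out
}
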