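# Small in-code fixtures shared across test files.

toy_dataset <- function() {
  ghg_dataset(
    sources = tibble::tibble(source_id = "S1", citation = "Doe 2020",
                             year_published = 2020L),
    sites = tibble::tibble(site_id = "L1", source_id = "S1",
                           water_body = "lake", zone = "continuous",
                           latitude = 68.1, longitude = 20.5),
    fluxes = tibble::tibble(site_id = "L1", date_or_period = "2014-07-19",
                            gas = "CO2", pathway = "diffusive", flux = 12.3)
  )
}

# a flux table already at the harmonized grain
harmonized_fluxes <- function(zone = "continuous", water_body = "lake",
                              gas = "CO2", pathway = "diffusive",
                              month = 7L, flux, site_id = NULL) {
  n <- length(flux)
  tibble::tibble(
    site_id = site_id %||% sprintf("s%02d", seq_len(n)),
    zone = zone, water_body = water_body, month = as.integer(month),
    gas = gas, pathway = pathway, flux = flux)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent brute-force generalized ESD oracle (straight transcription of
# the recursion, no shared code with the package implementation)
esd_oracle <- function(x, alpha = 0.05, k_max = 10L) {
  n <- length(x)
  keep <- seq_len(n)
  cand <- integer(0)
  R <- lam <- numeric(k_max)
  for (i in seq_len(k_max)) {
    xx <- x[keep]
    R[i] <- max(abs(xx - mean(xx))) / stats::sd(xx)
    worst <- keep[which.max(abs(xx - mean(xx)))]
    cand <- c(cand, worst)
    keep <- setdiff(keep, worst)
    m <- n - i + 1
    tq <- stats::qt(1 - alpha / (2 * m), m - 2)
    lam[i] <- (m - 1) * tq / sqrt((m - 2 + tq^2) * m)
  }
  k <- if (any(R > lam)) max(which(R > lam)) else 0
  sort(cand[seq_len(k)])
}

# constant-replicate bootstrap summaries for deterministic aggregation tests
constant_summaries <- function(cells, value, B = 50L) {
  out <- cells
  out$n_obs <- 10L
  out$n_sites <- 3L
  out$median <- value
  out$q1 <- value
  out$q3 <- value
  out$replicates <- rep(list(rep(value, B)), nrow(cells))
  out$substituted <- FALSE
  out$donor_month <- NA_integer_
  out
}
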