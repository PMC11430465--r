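test_that("degenerate groups bootstrap to their constant value", {
  set.seed(1)
  bs <- bootstrap_group(rep(4.2, 8), rep(c("a", "b"), 4), B = 200)
  expect_equal(bs$median, 4.2)
  expect_equal(bs$q1, 4.2)
  expect_equal(bs$q3, 4.2)
  expect_equal(bs$n_sites, 2L)
})

test_that("one site with values {0, 10} matches the exhaustive enumeration", {
  # level 2 draws 2 of {0, 10} with replacement: mean in {0, 5, 10} with
  # probabilities {1/4, 1/2, 1/4}; the replicate median is 5
  set.seed(99)
  bs <- bootstrap_group(c(0, 10), c("s1", "s1"), B = 1e5)
  expect_equal(bs$median, 5)
  freq <- table(factor(bs$replicates, levels = c(0, 5, 10))) / 1e5
  expect_equal(as.numeric(freq), c(0.25, 0.5, 0.25), tolerance = 0.02)
})

test_that("two balanced sites centre the replicate distribution between site means", {
  set.seed(5)
  flux <- c(rnorm(50, 0, 0.5), rnorm(50, 10, 0.5))
  site <- rep(c("lo", "hi"), each = 50)
  bs <- bootstrap_group(flux, site, B = 1e4)
  expect_equal(bs$median, 5, tolerance = 0.5)
})

test_that("bootstrap summaries are reproducible and order-independent", {
  w <- generate_dataset(synthetic_config(n_sites = 3L), seed = 4)
  h <- harmonize_dataset(w$dataset)
  s1 <- bootstrap_fluxes(h$fluxes, B = 200, seed = 10)
  s2 <- bootstrap_fluxes(h$fluxes[sample(nrow(h$fluxes)), ], B = 200, seed = 10)
  expect_equal(s1, s2)
  s3 <- bootstrap_fluxes(h$fluxes, B = 200, seed = 11)
  expect_false(identical(s1$median, s3$median))
})

test_that("sparse months receive the lowest-|median| donor of their stratum", {
  cells <- tidyr::expand_grid(gas = "CO2", pathway = "diffusive",
                              water_body = "lake", zone = "continuous",
                              month = c(6L, 7L, 8L))
  s <- constant_summaries(cells, 1, B = 10L)
  s$n_obs <- c(50L, 40L, 2L)
  s$median <- c(8, 3, 99); s$q1 <- s$median - 1; s$q3 <- s$median + 1
  s$replicates <- list(rep(8, 10), rep(3, 10), rep(99, 10))
  out <- substitute_sparse_months(s)
  expect_identical(nrow(out), 12L)          # completed to all months
  aug <- out[out$month == 8, ]
  expect_true(aug$substituted)
  expect_identical(aug$donor_month, 7L)
  expect_equal(aug$median, 3)
  expect_equal(aug$replicates[[1]], rep(3, 10))
  jan <- out[out$month == 1, ]              # absent month, also filled
  expect_true(jan$substituted)
  expect_identical(jan$donor_month, 7L)
})

test_that("donor choice uses absolute value and earlier-month tie-breaks", {
  cells <- tidyr::expand_grid(gas = "N2O", pathway = "diffusive",
                              water_body = "river", zone = "discontinuous",
                              month = c(5L, 6L, 7L))
  s <- constant_summaries(cells, 0, B = 4L)
  s$n_obs <- c(30L, 30L, 1L)
  s$median <- c(-2, 5, 0)
  s$replicates <- list(rep(-2, 4), rep(5, 4), rep(0, 4))
  out <- substitute_sparse_months(s)
  expect_identical(out$donor_month[out$month == 7], 5L)  # |-2| < |5|
  expect_equal(out$median[out$month == 7], -2)

  s$median <- c(-2, 2, 0)                                # tie on |median|
  s$replicates <- list(rep(-2, 4), rep(2, 4), rep(0, 4))
  out2 <- substitute_sparse_months(s)
  expect_identical(out2$donor_month[out2$month == 7], 5L)
})

test_that("fully sampled strata pass through substitution unchanged", {
  cells <- tidyr::expand_grid(gas = "CH4", pathway = "diffusive",
                              water_body = "lake", zone = "glacial",
                              month = 1:12)
  s <- constant_summaries(cells, 2, B = 5L)
  out <- substitute_sparse_months(s)
  expect_false(any(out$substituted))
  expect_equal(out$median, rep(2, 12))
})

test_that("strata with no viable donor contribute zero with a warning", {
  cells <- tidyr::expand_grid(gas = "N2O", pathway = "diffusive",
                              water_body = "lake", zone = "glacial",
                              month = 7L)
  s <- constant_summaries(cells, 3, B = 6L)
  s$n_obs <- 2L
  expect_warning(out <- substitute_sparse_months(s), "no month")
  expect_equal(out$median, rep(0, 12))
  expect_equal(out$replicates[[7]], rep(0, 6))
})

test_that("flux-to-mass conversion follows the unit chain and preserves sign", {
  expect_equal(flux_to_emission(1, area = 1, days = 30, gas = "CO2"),
               1e-3 * 44.01 * 1e6 * 30 * 1e-12)
  expect_equal(flux_to_emission(0, 500, 31, "CH4"), 0)
  expect_lt(flux_to_emission(-0.1, 100, 30, "N2O"), 0)
  # N2O reports Gg: three orders of magnitude larger numerically than Tg
  expect_equal(flux_to_emission(1, 1, 30, "N2O") /
                 flux_to_emission(1, 1, 30, "CO2"), 1000)
  expect_error(flux_to_emission(1, 1, 30, "O3"), "unknown gas")
})

test_that("deterministic replicates aggregate to the closed-form annual sum", {
  cells <- tidyr::expand_grid(gas = c("CO2", "N2O"), pathway = "diffusive",
                              water_body = "lake", zone = "continuous",
                              month = 1:12)
  s <- constant_summaries(cells, 2, B = 8L)
  areas <- generate_areas()
  ge <- group_emissions(s, areas)
  est <- aggregate_emissions(ge)
  a <- areas[areas$zone == "continuous" & areas$water_body == "lake", ]
  closed_tg <- sum(2 * 1e-3 * 44.01 * a$area * 1e6 * days_in_month() * 1e-12)
  co2 <- est[est$gas == "CO2" & est$zone == "continuous" &
               est$water_body == "lake" & is.na(est$month), ]
  expect_equal(co2$median, closed_tg, tolerance = 1e-12)
  expect_equal(co2$q1, co2$median)
  expect_equal(co2$q3, co2$median)
  n2o <- est[est$gas == "N2O" & est$zone == "continuous" &
               est$water_body == "lake" & is.na(est$month), ]
  expect_equal(n2o$median, closed_tg * 1000, tolerance = 1e-9)
})

test_that("missing area cells fail loudly by name", {
  cells <- tidyr::expand_grid(gas = "CO2", pathway = "diffusive",
                              water_body = "lake", zone = "continuous",
                              month = 7L)
  s <- constant_summaries(cells, 1, B = 3L)
  areas <- generate_areas()
  areas <- areas[!(areas$zone == "continuous" & areas$water_body == "lake" &
                     areas$month == 7), ]
  expect_error(group_emissions(s, areas), "continuous.*lake.*7")
})

test_that("replicate aggregation is additive bitwise across the hierarchy", {
  w <- generate_dataset(synthetic_config(n_sites = 4L), seed = 21)
  h <- harmonize_dataset(w$dataset)
  s <- substitute_sparse_months(bootstrap_fluxes(h$fluxes, B = 300, seed = 21))
  est <- aggregate_emissions(group_emissions(s, w$truth$areas))
  for (g in c("CO2", "CH4", "N2O")) {
    for (wb in c("lake", "river")) {
      zonal <- est[est$gas == g & est$water_body == wb &
                     est$zone != "all" & is.na(est$month), ]
      body <- est[est$gas == g & est$water_body == wb &
                    est$zone == "all" & is.na(est$month), ]
      if (nrow(zonal) > 0 && nrow(body) == 1) {
        expect_identical(Reduce(`+`, zonal$replicates), body$replicates[[1]])
      }
    }
    bodies <- est[est$gas == g & est$water_body != "all" &
                    est$zone == "all" & is.na(est$month), ]
    total <- est[est$gas == g & est$water_body == "all" &
                   est$zone == "all" & is.na(est$month), ]
    expect_identical(Reduce(`+`, bodies$replicates), total$replicates[[1]])
    # reported median is the median of the summed replicates
    expect_equal(total$median, median(total$replicates[[1]]))
  }
})

test_that("CH4 'total'-pathway records fill only cells without pathway series", {
  cells <- dplyr::bind_rows(
    tibble::tibble(gas = "CH4", pathway = c("diffusive", "ebullitive", "total"),
                   water_body = "lake", zone = "continuous", month = 7L),
    tibble::tibble(gas = "CH4", pathway = "total",
                   water_body = "lake", zone = "glacial", month = 7L))
  s <- constant_summaries(cells, 1, B = 4L)
  areas <- generate_areas()
  ge <- group_emissions(s, areas)
  expect_identical(ge$used, c(TRUE, TRUE, FALSE, TRUE))
})

test_that("zone comparisons reproduce the exact rank-sum p and star conventions", {
  fl <- dplyr::bind_rows(
    harmonized_fluxes(zone = "continuous", flux = c(1, 2, 3)),
    harmonized_fluxes(zone = "glacial", flux = c(10, 11, 12)))
  out <- compare_zones(fl, gas = "CO2", water_body = "lake")
  expect_equal(out$p_value, 0.1, tolerance = 1e-12)  # 2/C(6,3) * ... exact
  expect_identical(out$stars, "")

  fl2 <- dplyr::bind_rows(
    harmonized_fluxes(zone = "continuous", flux = rep(1, 5)),
    harmonized_fluxes(zone = "glacial", flux = rep(1, 5)))
  expect_warning(out2 <- compare_zones(fl2, "CO2", "lake"), "tied")
  expect_equal(out2$p_value, 1)

  set.seed(12)
  fl3 <- dplyr::bind_rows(
    harmonized_fluxes(zone = "continuous", flux = rlnorm(200, 0, 1)),
    harmonized_fluxes(zone = "discontinuous", flux = rlnorm(200, log(2), 1)))
  out3 <- compare_zones(fl3, "CO2", "lake")
  expect_lte(out3$p_value, 1e-4)
  expect_identical(out3$stars, "****")

  expect_error(compare_zones(fl[1:3, ], "CO2", "lake"), "two zones")
})
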