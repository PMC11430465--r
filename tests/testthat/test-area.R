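test_that("binning uses half-open intervals, arithmetic means, and conserves counts", {
  b <- bin_lake_inventory(c(0.00015, 0.00017), bin_width = 1e-4)
  expect_equal(nrow(b), 1L)
  expect_equal(b$mean_area, 0.00016)
  expect_equal(b$count, 2L)

  b2 <- bin_lake_inventory(c(0.00005, 0.00015), bin_width = 1e-4)
  expect_equal(b2$count, c(1L, 1L))

  expect_identical(nrow(bin_lake_inventory(numeric(0))), 0L)

  areas <- generate_lake_inventory(1e4, b = -1.49, range = c(1e-4, 1), seed = 3)
  expect_equal(sum(bin_lake_inventory(areas)$count), 1e4)
})

test_that("the size-abundance fit recovers exact power laws", {
  bins <- tibble::tibble(mean_area = c(0.04, 0.05, 0.08),
                         count = 2 * c(0.04, 0.05, 0.08)^-1)
  fit <- fit_size_abundance(bins)
  expect_equal(fit$c, 2, tolerance = 1e-10)
  expect_equal(fit$b, -1, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)

  # self-consistency at the reference coefficients
  a <- seq(0.031, 0.099, by = 0.002)
  bins2 <- tibble::tibble(mean_area = a, count = 23.74398 * a^-1.490131)
  fit2 <- fit_size_abundance(bins2)
  expect_equal(fit2$c, 23.74398, tolerance = 1e-7)
  expect_equal(fit2$b, -1.490131, tolerance = 1e-7)
})

test_that("the fit tolerates multiplicative noise and rejects unusable input", {
  slopes <- vapply(1:10, function(seed) {
    set.seed(seed)
    a <- seq(0.031, 0.099, by = 0.002)
    bins <- tibble::tibble(mean_area = a,
                           count = 23.74398 * a^-1.490131 *
                             exp(rnorm(length(a), 0, 0.05)))
    fit_size_abundance(bins)$b
  }, 0)
  expect_true(all(abs(slopes - (-1.490131)) < 0.1))

  expect_error(
    fit_size_abundance(tibble::tibble(mean_area = c(0.04, 0.05), count = c(5, 4))),
    ">= 3")
  expect_warning(
    fit_size_abundance(tibble::tibble(mean_area = seq(0.03, 0.1, by = 0.01),
                                      count = c(0, 9, 8, 7, 6, 5, 4, 3))),
    "zero-count")
})

test_that("small-lake extrapolation matches closed forms and a naive loop", {
  # constant law: arithmetic series
  r <- extrapolate_small_lakes(list(c = 1, b = 0))
  expect_equal(r$total_count, 300)
  expect_equal(r$total_area, 4.515, tolerance = 1e-12)

  r2 <- extrapolate_small_lakes(list(c = 2, b = -1), a_min = 0.01,
                                a_max = 0.01, step = 1e-4)
  expect_equal(r2$total_count, 200)
  expect_equal(r2$total_area, 2)

  # brute-force loop oracle at the reference coefficients
  fit <- list(c = 23.74398, b = -1.490131)
  got <- extrapolate_small_lakes(fit)
  cnt <- 0; ar <- 0
  for (a in seq(1e-4, 0.03, by = 1e-4)) {
    n <- fit$c * a^fit$b
    cnt <- cnt + n; ar <- ar + n * a
  }
  expect_equal(got$total_count, cnt, tolerance = 1e-12)
  expect_equal(got$total_area, ar, tolerance = 1e-12)

  expect_error(extrapolate_small_lakes(fit, a_min = -1), "a_min")
})

test_that("extrapolated totals grow with c and with a smaller lower bound", {
  fit <- list(c = 23.74398, b = -1.490131)
  up <- extrapolate_small_lakes(list(c = fit$c * 2, b = fit$b))
  base <- extrapolate_small_lakes(fit)
  expect_gt(up$total_count, base$total_count)
  expect_gt(up$total_area, base$total_area)
  deeper <- extrapolate_small_lakes(fit, a_min = 5e-5, step = 5e-5)
  expect_gt(deeper$total_count, base$total_count)
  expect_gt(deeper$total_area, base$total_area)
})

test_that("monthly scaling anchors the maximum in September", {
  ratios <- c(0.2, 0.2, 0.2, 0.3, 0.5, 0.8, 0.9, 0.95, 1, 0.9, 0.5, 0.3)
  m <- monthly_small_lake_area(141018, ratios)
  expect_equal(m[9], 141018)
  expect_equal(monthly_small_lake_area(141018, replace(ratios, 6, 0.8))[6],
               112814.4)
  expect_equal(monthly_small_lake_area(100, rep(1, 12)), rep(100, 12))
  expect_equal(monthly_small_lake_area(100, replace(ratios, 1, 0))[1], 0)
  expect_error(monthly_small_lake_area(100, replace(ratios, 3, 1.2)), "\\[0, 1\\]")
})

test_that("the river freeze adjustment subtracts January and clips at zero", {
  x <- c(100, 120, 150, 200, 300, 400, 500, 480, 400, 300, 200, 120)
  adj <- adjust_river_area(x)
  expect_equal(adj, pmax(x - 100, 0))
  expect_equal(adj[1], 0)
  expect_equal(adjust_river_area(rep(7, 12)), rep(0, 12))
  x0 <- replace(x, 1, 0)
  expect_equal(adjust_river_area(x0), x0)
})

test_that("area table assembly has full cardinality and conserves input sums", {
  lake <- tidyr::expand_grid(zone = c("continuous", "discontinuous",
                                      "sporadic_isolated", "glacial"),
                             month = 1:12)
  lake$area <- seq_len(nrow(lake)) * 10
  river <- lake
  river$area <- seq_len(nrow(river)) * 2

  tab <- assemble_area_table(lake, river)
  expect_identical(nrow(tab), 96L)
  expect_equal(sum(tab$area), sum(lake$area) + sum(river$area))

  small <- rep(1200, 12)
  tab2 <- assemble_area_table(lake, river, small_lake_monthly = small)
  expect_equal(sum(tab2$area[tab2$water_body == "lake"]),
               sum(lake$area) + sum(small))
  # proportional allocation preserves each month's lake total
  jul <- tab2[tab2$water_body == "lake" & tab2$month == 7, ]
  expect_equal(sum(jul$area), sum(lake$area[lake$month == 7]) + 1200)

  expect_error(assemble_area_table(lake[-1, ], river), "missing")
})

test_that("area tables round-trip through delimited text", {
  tab <- generate_areas()
  path <- withr::local_tempfile(fileext = ".csv")
  write_area_table(tab, path)
  expect_equal(as.data.frame(read_area_table(path)), as.data.frame(tab),
               tolerance = 1e-12)
})
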