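test_that("standard equivalent: packaged constants and the grain formula", {
  expect_equal(standard_equivalent(2020)$Ea, 2181)
  expect_equal(standard_equivalent(1990)$Ea, 2006)
  expect_error(standard_equivalent(1995), "packaged")
  # one seventh of grain output value per hectare
  expect_equal(standard_equivalent(2030, list(price = 1, yield = 7000))$Ea,
               1000)
  # linear in price and yield
  e1 <- standard_equivalent(2030, list(price = 2, yield = 5000))$Ea
  e2 <- standard_equivalent(2030, list(price = 4, yield = 10000))$Ea
  expect_equal(e2, 4 * e1)
  # series form
  gs <- list(grain_price = socio_series("p", 2019:2021, c(1, 2, 3)),
             grain_yield = socio_series("y", 2019:2021, c(7, 7, 7)))
  expect_equal(standard_equivalent(2020, gs)$Ea, 2)
})

test_that("social-stage logistic L behaves per its closed form", {
  expect_equal(engel_L(1 / 3), 0.5)
  expect_equal(engel_L(1), 1 / (1 + exp(2)))
  expect_gt(engel_L(1e-6), 1 - 1e-9)   # limit toward 1 as En -> 0+
  expect_error(engel_L(0), "0, 1")
  expect_error(engel_L(-0.2), "0, 1")
  # strictly decreasing on a fine grid in (0, 1] (start above the region
  # where the logistic saturates to 1 in double precision)
  grid <- seq(0.05, 1, length.out = 100)
  expect_true(all(diff(engel_L(grid)) < 0))
})

test_that("biomass and social correction coefficients", {
  expect_equal(biomass_factor(300, 300, 0.4, 0.4), 1)
  expect_equal(biomass_factor(360, 300, 0.32, 0.4), 1.0)  # (1.2 + 0.8)/2
  expect_equal(biomass_factor(150, 300, 0.2, 0.4), 0.5)
  expect_error(biomass_factor(1, 0, 1, 1), "positive")
  expect_equal(social_coefficient(100, 100, 0.4, 0.4)$PI, 1)
  sc <- social_coefficient(200, 100, 1 / 3, 1 / 3)
  expect_equal(sc$PI, 2)  # A = 2, W = 1
  pi3 <- social_coefficient(80, 100, 0.30, 1 / 3)$PI
  expect_equal(pi3, 0.8 * engel_L(0.30) / 0.5)
})

test_that("corrected coefficients reduce and scale as a valuation should", {
  eq <- equivalent_table("2003")
  vc <- corrected_coefficients(eq, Ea = 2006, Q = 1, PI = 1)
  # identity reduction: plain table sum times Ea
  grass_sum <- sum(eq$equivalent[eq$class == 3])
  expect_equal(unname(vc$vc["3"]), 2006 * grass_sum)
  expect_equal(unname(vc$vc["5"]), 0)   # construction always zero
  # linear in Ea, Q, PI
  vc2 <- corrected_coefficients(eq, Ea = 4012, Q = 1, PI = 1)
  expect_equal(vc2$vc, 2 * vc$vc)
  vc3 <- corrected_coefficients(eq, Ea = 2006, Q = 1.3, PI = 0.7)
  expect_equal(vc3$vc, 1.3 * 0.7 * vc$vc)
  # monotone: any increase in the factors raises every positive coefficient
  pos <- vc$vc > 0
  expect_true(all(corrected_coefficients(eq, 2006, 1.01, 1)$vc[pos] >
                    vc$vc[pos]))
  # the 2015 table carries the two added provisioning/support functions
  eq15 <- equivalent_table("2015")
  expect_true(all(c("water_sup", "nutrient") %in% eq15$fun))
})

test_that("esv_total aggregates linearly and its margins agree", {
  eq <- equivalent_table("2015")
  vc <- corrected_coefficients(eq, Ea = 2181, Q = 1.1, PI = 0.9)
  at <- area_table(c(`1` = 100, `2` = 50, `3` = 500, `4` = 30, `5` = 10,
                     `6` = 300), year = 2020)
  rep1 <- esv_total(at, vc)
  expect_equal(sum(rep1$per_class), rep1$total, tolerance = 1e-9)
  expect_equal(sum(rep1$per_function), rep1$total, tolerance = 1e-9)
  expect_equal(sum(rep1$per_category), rep1$total, tolerance = 1e-9)
  expect_equal(unname(rep1$per_class["5"]), 0)
  # single class on one hectare
  single <- area_table(c(`4` = 1))
  vcy <- corrected_coefficients(eq, Ea = 1, Q = 1, PI = 1)
  expect_equal(esv_total(single, vcy)$total,
               sum(eq$equivalent[eq$class == 4]))
  # scaling all areas scales the total
  at2 <- at; at2$area_hm2 <- at$area_hm2 * 3.5
  expect_equal(esv_total(at2, vc)$total, 3.5 * rep1$total)
  expect_error(esv_total(area_table(c(`1` = 1)),
                         corrected_coefficients(eq, 1)), NA)
})

test_that("raster valuation equals tabular valuation on the same data", {
  cfg <- synthetic_config(40, 40, transition_kernel = demo_kernel(),
                          cell_area = 25, seed = 6)
  g <- generate_lulc_pair(cfg)$end
  eq <- equivalent_table("2015")
  vc <- corrected_coefficients(eq, Ea = 2181, Q = 1.05, PI = 1.2)
  tab_total <- esv_total(class_areas(g), vc)$total
  eg <- esv_grid(g, vc)                      # yuan per hm^2 per cell
  raster_total <- sum(eg, na.rm = TRUE) * g$cell_area
  expect_equal(raster_total, tab_total, tolerance = 1e-9)
})

test_that("derived statistics reproduce endpoint arithmetic", {
  ds <- derived_stats(c(`1990` = 18.62, `2020` = 67.28))
  expect_equal(ds$changes$increment[2], 48.66)
  expect_equal(contribution_share(c(30.64, 14.61), 48.66), 93)
  ds2 <- derived_stats(c(a = 50, b = 50))
  expect_equal(ds2$changes$pct_change[2], 0)
  expect_error(derived_stats(c(a = 0, b = 1)), "zero baseline")
  expect_error(derived_stats(c(a = 1)), "at least two")
})

test_that("jenks breaks agree with exhaustive partition search", {
  set.seed(42)
  for (k in c(2, 3, 4)) {
    x <- round(runif(18, 0, 100), 1)
    got <- jenks_breaks(x, k)
    oracle <- exhaustive_jenks(x, k)
    expect_equal(got, oracle$breaks, tolerance = 1e-9,
                 label = paste("breaks at k =", k))
  }
  # two well-separated clusters: the break falls between them
  x2 <- c(rnorm(10, 0, 0.1), rnorm(10, 10, 0.1))
  br <- jenks_breaks(x2, 2)
  expect_lt(br[1], 5); expect_gt(br[2], 5)
})

test_that("level maps classify every cell with lower-tie breaks", {
  vals <- matrix(c(1, 1, 2, 2, 10, 10, 11, 11, 30, 30, 31, 31), 3, 4)
  lm3 <- jenks_levels(vals, k = 3)
  expect_equal(sort(unique(as.integer(lm3$levels))), 1:3)
  expect_equal(lm3$levels[vals <= 2], rep(1L, 4))
  expect_true(all(diff(lm3$breaks) > 0))
  # value exactly on a break goes to the lower level
  expect_equal(unique(lm3$levels[vals == lm3$breaks[1]]), 1L)
  # k = 1 puts everything in one class; constant raster errors
  expect_equal(unique(as.integer(jenks_levels(vals, 1)$levels)), 1L)
  expect_error(jenks_levels(matrix(5, 4, 4), 5), "distinct")
  # nodata stays unclassified
  vals[2, 2] <- NA
  expect_true(is.na(jenks_levels(vals, 2)$levels[2, 2]))
})

test_that("fvc derivation clamps to the dimidiate-pixel range", {
  nd <- seq(0, 1, length.out = 200)
  fvc <- fvc_from_ndvi(nd)
  expect_true(all(fvc >= 0 & fvc <= 1))
  expect_equal(fvc[1], 0); expect_equal(fvc[200], 1)
  expect_error(fvc_from_ndvi(rep(0.5, 10)), "degenerate")
})
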