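sch <- default_scheme()
F <- 1L; C <- 3L

toy_pair <- function() {
  a <- lc_raster(matrix(c(F, F, F, C), 2, 2, byrow = TRUE), 2000, 1, sch)
  b <- lc_raster(matrix(c(F, F, C, C), 2, 2, byrow = TRUE), 2005, 1, sch)
  list(a = a, b = b)
}

test_that("crosstab reproduces the hand-enumerated 4-pixel toy", {
  p <- toy_pair()
  tm <- crosstab_transitions(p$a, p$b)
  expect_equal(tm$flows["forest", "forest"], 2)
  expect_equal(tm$flows["forest", "cropland"], 1)
  expect_equal(tm$flows["cropland", "cropland"], 1)
  expect_equal(sum(tm$flows), 4)
})

test_that("identical maps give a strictly diagonal matrix", {
  m <- lc_raster(matrix(sample(1:7, 36, TRUE), 6, 6), 2000, 0.09, sch)
  m2 <- lc_raster(m$values, 2005, 0.09, sch)
  tm <- crosstab_transitions(m, m2)
  offdiag <- tm$flows; diag(offdiag) <- 0
  expect_true(all(offdiag == 0))
  expect_equal(diag(tm$flows), class_areas(m), tolerance = 1e-12)
})

test_that("crosstab and change map equal the per-pixel brute-force oracle", {
  for (seed in 1:25) {
    nr <- sample(3:32, 1); nc <- sample(3:32, 1)
    p <- random_map_pair(nr, nc, seed)
    tm <- crosstab_transitions(p$a, p$b)
    expect_equal(tm$flows,
                 oracle_crosstab(p$a$values, p$b$values, sch, 0.09),
                 tolerance = 1e-12)
    cm <- change_map(p$a, p$b)
    expect_equal(unname(change_areas(cm) / 0.09),
                 unname(oracle_change_counts(p$a$values, p$b$values, F)))
    # conservation: total flow area equals jointly valid pixels x cell area
    valid <- sum(!is.na(p$a$values) & !is.na(p$b$values))
    expect_equal(sum(tm$flows), valid * 0.09, tolerance = 1e-9)
  }
})

test_that("change map aggregates agree with the transition matrix", {
  p <- toy_pair()
  cm <- change_map(p$a, p$b)
  areas <- change_areas(cm)
  expect_equal(unname(areas["net deforestation"]), 1)
  expect_equal(unname(areas["stable forest"]), 2)
  expect_equal(unname(areas["stable non-forest"]), 1)
  # swapping epochs swaps deforestation and regrowth
  a2 <- lc_raster(p$b$values, 2000, 1, sch)
  b2 <- lc_raster(p$a$values, 2005, 1, sch)
  rev_areas <- change_areas(change_map(a2, b2))
  expect_equal(unname(rev_areas["net regrowth"]), unname(areas["net deforestation"]))
  expect_equal(unname(rev_areas["net deforestation"]), unname(areas["net regrowth"]))
})

test_that("nodata in either epoch drops the pixel from matrix and map", {
  a <- lc_raster(matrix(c(F, NA, F, C), 2, 2), 2000, 1, sch)
  b <- lc_raster(matrix(c(F, F, NA, C), 2, 2), 2005, 1, sch)
  tm <- crosstab_transitions(a, b)
  expect_equal(sum(tm$flows), 2)
  cm <- change_map(a, b)
  expect_equal(sum(is.na(cm$values)), 2)
})

test_that("chained transition marginals conserve class areas", {
  set.seed(42)
  sc <- landscape_scenario(30, 30, epochs = c(2000, 2005, 2010),
    initial_class_proportions = c(forest = 0.6, shrubland = 0.2, cropland = 0.2),
    kernel = transition_kernel(sch, data.frame(
      from = "forest", to = "cropland", annual_rate = 0.03)),
    seed = 17)
  maps <- simulate_landscape_series(sc)$rasters
  tm01 <- crosstab_transitions(maps[[1]], maps[[2]])
  tm12 <- crosstab_transitions(maps[[2]], maps[[3]])
  expect_equal(rowSums(tm12$flows), colSums(tm01$flows), tolerance = 1e-9)
})

test_that("map pair validation catches mismatches", {
  p <- toy_pair()
  small <- lc_raster(matrix(F, 1, 2), 2005, 1, sch)
  expect_error(crosstab_transitions(p$a, small), "shape")
  late <- lc_raster(p$a$values, 1995, 1, sch)
  expect_error(crosstab_transitions(p$a, late), "precede")
  all_na <- lc_raster(matrix(NA_integer_, 2, 2), 2005, 1, sch)
  expect_error(crosstab_transitions(p$a, all_na), "valid")
})

test_that("forest area series normalizes to its baseline", {
  maps <- list(
    lc_raster(matrix(c(F, F, F, C), 2, 2), 2000, 1, sch),
    lc_raster(matrix(c(F, F, C, C), 2, 2), 2010, 1, sch),
    lc_raster(matrix(c(F, C, C, C), 2, 2), 2022, 1, sch))
  s <- forest_area_series(maps, "toy")
  expect_equal(s$normalized_pct, c(100, 100 * 2 / 3, 100 / 3))
  expect_equal(attr(s, "baseline_epoch"), 2000)
  # direct pass-through from tabulated areas
  s2 <- patch_series("p", c(2000, 2022), c(619, 505))
  expect_equal(s2$normalized_pct[2], 100 * 505 / 619)
  expect_error(patch_series("p", c(2000, 2010), c(0, 5)), "zero")
})

test_that("net change percent follows the loss-positive convention", {
  expect_equal(net_change_percent(619, 505), 100 * 114 / 619)
  expect_equal(net_change_percent(100, 100), 0)
  expect_equal(net_change_percent(100, 110), -10)
  expect_error(net_change_percent(0, 10), "positive")
  expect_equal(reported_net_change(1285.0, 1283.9), 0.09)
  expect_equal(reported_net_change(619, 505), 18.4)
})

test_that("trend fit recovers a closed-form collinear slope", {
  s <- patch_series("p", c(0, 5, 10), c(100, 90, 80))
  tr <- fit_trend(s)
  expect_equal(tr$slope, -2, tolerance = 1e-9)
  expect_false(tr$p_undefined)
  expect_equal(tr$p_value, 0)  # numerically perfect declining fit
  flat <- fit_trend(patch_series("p", c(2010, 2015, 2020, 2022),
                                 c(50, 50, 50, 50)))
  expect_equal(flat$slope, 0)
  expect_true(flat$p_undefined || flat$p_value >= 0.10)
})

test_that("two-point windows flag the p-value as undefined", {
  tr <- fit_trend(patch_series("p", c(2010, 2022), c(1285.0, 1283.9)))
  expect_true(tr$p_undefined)
  expect_true(is.na(tr$p_value))
  expect_equal(tr$net_change_pct, net_change_percent(1285.0, 1283.9))
  expect_error(fit_trend(patch_series("p", c(2010, 2022), c(10, 9)),
                         window = c(2015, 2022)),
               "fewer than 2")
})

test_that("stability rule classifies the documented endpoint cases", {
  thr <- threshold_config()
  stable <- classify_direction(
    patch_series("ngam", c(2010, 2015, 2020, 2022),
                 c(1285.0, 1284.5, 1285.2, 1283.9)), thresholds = thr)
  expect_equal(stable$direction, "stable")
  decline <- classify_direction(
    patch_series("ewe", c(2010, 2022), c(586.9, 505.4)), thresholds = thr)
  expect_equal(decline$direction, "decline")
  constant <- classify_direction(
    patch_series("c", c(2010, 2016, 2022), c(40, 40, 40)), thresholds = thr)
  expect_equal(constant$direction, "stable")
  gain <- classify_direction(
    patch_series("g", c(2010, 2022), c(100, 120)), thresholds = thr)
  expect_equal(gain$direction, "increase")
})

test_that("raising the stable net-change threshold is monotone", {
  set.seed(31)
  for (rep in 1:30) {
    areas <- 100 * exp(cumsum(c(0, rnorm(3, 0, 0.02))))
    s <- patch_series("p", c(2010, 2015, 2020, 2022), areas)
    lo <- classify_direction(s, thresholds = threshold_config(
      stable_max_net_change_pct = 1))
    hi <- classify_direction(s, thresholds = threshold_config(
      stable_max_net_change_pct = 6))
    if (lo$direction == "stable") expect_equal(hi$direction, "stable")
  }
})

test_that("trend fitting supports absolute areas via flag", {
  s <- patch_series("p", c(2000, 2010, 2020), c(600, 550, 500))
  norm <- fit_trend(s)
  abs_fit <- fit_trend(s, use_normalized = FALSE)
  expect_equal(abs_fit$slope, -5, tolerance = 1e-9)
  expect_equal(norm$slope, -5 / 6, tolerance = 1e-9)
})
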