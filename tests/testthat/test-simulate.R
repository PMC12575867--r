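test_that("identity kernel with an all-forest start is absorbing", {
  sch <- default_scheme()
  sc <- landscape_scenario(10, 10, epochs = c(2000, 2005, 2010),
                           initial_class_proportions = c(forest = 1),
                           seed = 3)
  maps <- simulate_landscape_series(sc)$rasters
  for (m in maps) {
    expect_true(all(m$values == forest_code(sch)))
  }
})

test_that("realized forest loss matches the Markov-chain expectation", {
  sch <- default_scheme()
  k <- transition_kernel(sch, data.frame(from = "forest", to = "cropland",
                                         annual_rate = 0.02))
  sc <- landscape_scenario(200, 200, epochs = c(2010, 2022),
                           initial_class_proportions = c(forest = 1),
                           kernel = k, seed = 7)
  maps <- simulate_landscape_series(sc)$rasters
  loss <- 1 - forest_area(maps[[2]]) / forest_area(maps[[1]])
  expected <- 1 - 0.98^12  # per-pixel 12-step survival
  se <- sqrt(expected * (1 - expected) / (200 * 200))
  expect_lt(abs(loss - expected), 3 * se)
})

test_that("epoch class frequencies track P0 %*% K^t across classes", {
  sch <- default_scheme()
  k <- transition_kernel(sch, data.frame(
    from = c("forest", "forest", "shrubland"),
    to = c("shrubland", "cropland", "forest"),
    annual_rate = c(0.01, 0.02, 0.03)))
  p0 <- c(forest = 0.6, shrubland = 0.3, cropland = 0.1)
  sc <- landscape_scenario(120, 120, epochs = c(2000, 2010),
                           initial_class_proportions = p0,
                           clump_size = 1, kernel = k, seed = 21)
  maps <- simulate_landscape_series(sc)$rasters
  n <- 120 * 120
  p_start <- class_areas(maps[[1]]) / (n * sc$cell_area_ha)
  pred <- as.numeric(p_start %*% kernel_power_oracle(k, 10))
  obs <- class_areas(maps[[2]]) / (n * sc$cell_area_ha)
  for (i in seq_along(pred)) {
    if (pred[i] > 0) {
      se <- sqrt(pred[i] * (1 - pred[i]) / n)
      expect_lt(abs(obs[[i]] - pred[i]), 4 * se)
    }
  }
})

test_that("same seed reproduces rasters and reflectance stacks bit for bit", {
  sc <- landscape_scenario(24, 24, epochs = c(2000, 2005),
                           initial_class_proportions = c(forest = 0.5, cropland = 0.5),
                           seed = 99)
  r1 <- simulate_landscape_series(sc, reflectance = TRUE)
  r2 <- simulate_landscape_series(sc, reflectance = TRUE)
  expect_identical(r1$rasters[[2]]$values, r2$rasters[[2]]$values)
  expect_identical(r1$stacks[[1]]$bands, r2$stacks[[1]]$bands)
})

test_that("clumped initialization matches target proportions in expectation", {
  sc <- landscape_scenario(150, 150, epochs = 2000,
                           initial_class_proportions = c(forest = 0.7, cropland = 0.3),
                           clump_size = 10, seed = 5)
  m <- simulate_landscape_series(sc)$rasters[[1]]
  share <- forest_area(m) / sum(class_areas(m))
  # clumping inflates the variance of the realized share well beyond the
  # i.i.d. binomial SE; seeds are ~n/clump_size independent draws
  se <- sqrt(0.7 * 0.3 / (150 * 150 / 10))
  expect_lt(abs(share - 0.7), 4 * se)
})

test_that("simulated reflectances order NDVI by vegetation density", {
  sc <- landscape_scenario(40, 40, epochs = 2000,
                           initial_class_proportions =
                             c(forest = 0.4, shrubland = 0.3, `built-up` = 0.3),
                           seed = 13)
  sim <- simulate_landscape_series(sc, reflectance = TRUE)
  ndvi <- compute_index(sim$stacks[[1]], "NDVI")
  cls <- sim$rasters[[1]]$values
  sch <- default_scheme()
  mean_ndvi <- function(lab) mean(ndvi[cls == sch$codes[match(lab, sch$labels)]])
  expect_gt(mean_ndvi("forest"), mean_ndvi("shrubland"))
  expect_gt(mean_ndvi("shrubland"), mean_ndvi("built-up"))
})

test_that("kernel construction rejects bad configurations", {
  sch <- default_scheme()
  expect_error(transition_kernel(sch, data.frame(from = "forest", to = "moon",
                                                 annual_rate = 0.1)),
               "unknown class")
  expect_error(landscape_scenario(8, 8, 2000, c(forest = 0.9)),
               "sum to 1")
  expect_error(landscape_scenario(8, 8, c(2005, 2000), c(forest = 1)),
               "strictly increasing")
  expect_error(landscape_scenario(8, 8, 2000, c(forest = 1),
                                  kernel = matrix(1, 2, 3)),
               "square")
})

test_that("degenerate survey distribution yields unanimous responses", {
  v <- c(1, 0, 0, 0); names(v) <- response_categories()
  sc <- survey_scenario(50, "p", list(`5y` = v, `10y` = v), seed = 1)
  tab <- simulate_survey(sc)
  expect_true(all(tab$perceived_change_10y == "Decreased"))
  sm <- summarize_responses(tab, "p", "10y")
  expect_equal(sm$consensus_direction, "decline")
  expect_equal(sm$consensus_proportion, 1.0)
})

test_that("survey proportions are consistent estimators as n grows", {
  target <- 0.93
  v <- c(target, 0.03, 0.02, 0.02); names(v) <- response_categories()
  for (n in c(50, 500, 5000)) {
    sc <- survey_scenario(n, "p", list(`5y` = v, `10y` = v), seed = n)
    tab <- simulate_survey(sc)
    obs <- mean(tab$perceived_change_10y == "Decreased")
    expect_lt(abs(obs - target), 3 * sqrt(target * (1 - target) / n) + 1e-9)
  }
})

test_that("demographic effects shift responses in the designed direction", {
  v <- c(0.5, 0.3, 0.1, 0.1); names(v) <- response_categories()
  eff <- list(gender = list(male = c(Decreased = 1.5)))
  sc <- survey_scenario(2000, "p", list(`5y` = v, `10y` = v),
                        demographic_effects = eff, seed = 8)
  tab <- simulate_survey(sc)
  p_male <- mean(tab$perceived_change_10y[tab$gender == "male"] == "Decreased")
  p_female <- mean(tab$perceived_change_10y[tab$gender == "female"] == "Decreased")
  expect_gt(p_male, p_female + 0.1)
})

test_that("fixture suite is byte-identical across reruns and ends as designed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  make_fixture_suite(1, d1)
  make_fixture_suite(1, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_setequal(files, list.files(d2, recursive = TRUE))
  for (f in files) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }
  # designed end-to-end outcomes
  for (nm in c("full", "dissonance", "partial")) {
    patch <- read_fixture_patch(file.path(d1, nm))
    series <- forest_area_series(patch$rasters, nm)
    trend <- classify_direction(series, window = c(2010, 2022))
    lk <- summarize_responses(patch$survey, nm, "10y")
    asm <- classify_convergence(trend, lk)
    expected <- c(full = "full_convergence", dissonance = "dissonance",
                  partial = "partial_convergence")[[nm]]
    expect_equal(asm$category, expected, label = nm)
  }
})
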