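test_that("Pearson r and p match the covariance formula and t distribution", {
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
  res <- pearson_with_test(x, y)
  expect_equal(res$r, 0.8, tolerance = 1e-12)
  tstat <- 0.8 * sqrt(2 / (1 - 0.64))
  expect_equal(res$p, 2 * pt(-tstat, df = 2), tolerance = 1e-12)

  expect_equal(pearson_with_test(x, x)$r, 1)
  expect_equal(pearson_with_test(x, -2 * x + 7)$r, -1)
  expect_error(pearson_with_test(x, rep(1, 4)), "degenerate")
  expect_error(pearson_with_test(1:2, 2:1), "at least 3")

  # covariance-formula oracle on random vectors
  set.seed(4)
  for (i in 1:25) {
    a <- rnorm(10); b <- rnorm(10)
    r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(pearson_with_test(a, b)$r, r_oracle, tolerance = 1e-12)
  }
})

test_that("correlation categories apply the four-way strict rule", {
  expect_equal(as.character(categorize_correlation(0.5, 0.2)), "NSP")
  expect_equal(as.character(categorize_correlation(-0.7, 0.01)), "SN")
  expect_equal(as.character(categorize_correlation(0.7, 0.01)), "SP")
  expect_equal(as.character(categorize_correlation(-0.1, 0.5)), "NSN")
  expect_equal(as.character(categorize_correlation(0, 0.001)), "NSP")  # tie rule
  # partition: every (r, p) pair lands in exactly one class
  set.seed(2)
  cl <- categorize_correlation(runif(500, -1, 1), runif(500))
  expect_false(anyNA(cl))
})

test_that("per-pixel correlation maps label every pixel and sum to 100", {
  scen <- tiny_scen
  agb <- dplyr::rename(scen$truth$agb_true, value = agb)
  drv <- scen$truth$driver_table[, c("year", "row", "col", "PPT")]
  names(drv)[4] <- "value"
  cm <- correlation_map(agb, drv)
  expect_identical(nrow(cm), 36L)
  af <- area_fraction(cm, "category")
  expect_equal(sum(af$percent), 100, tolerance = 1e-9)
  # self-correlation is exactly 1 everywhere
  self <- correlation_map(agb, agb)
  expect_true(all(abs(self$r - 1) < 1e-12))
})

test_that("type-wise correlation reduces to the plain test on one type", {
  scen <- tiny_scen
  agb <- dplyr::rename(scen$truth$agb_true, value = agb)
  drv <- scen$truth$driver_table[, c("year", "row", "col", "PPT")]
  names(drv)[4] <- "value"
  one_type <- scen$inputs$type_map
  one_type$type <- factor("alpine meadow", levels = grassland_types())
  tt <- per_type_correlation(agb, drv, one_type)
  expect_identical(nrow(tt), 1L)
  m_agb <- agb |> dplyr::group_by(year) |> dplyr::summarise(v = mean(value))
  m_drv <- drv |> dplyr::group_by(year) |> dplyr::summarise(v = mean(value))
  ref <- pearson_with_test(m_drv$v, m_agb$v)
  expect_equal(tt$r, ref$r, tolerance = 1e-12)
  expect_equal(tt$p, ref$p, tolerance = 1e-12)
  # identical driver gives r = 1 for every type present
  tt1 <- per_type_correlation(agb, agb, scen$inputs$type_map)
  expect_true(all(abs(tt1$r - 1) < 1e-12))
})

test_that("seasonal type-wise correlation aggregates before correlating", {
  scen <- tiny_scen
  agb_m <- scen$truth$npp_true   # any monthly stack works for the mechanics
  tt <- per_type_correlation(agb_m, agb_m, scen$inputs$type_map,
                             season = "summer")
  expect_true(all(abs(tt$r - 1) < 1e-12))
})

test_that("random-forest importance shares normalise and stay deterministic", {
  set.seed(5)
  n <- 300
  tab <- tibble::tibble(T = rnorm(n), PPT = rnorm(n), VPD = rnorm(n),
                        SR = rnorm(n), RH = rnorm(n), SM = rnorm(n),
                        GI = rnorm(n))
  tab$agb <- 100 + 30 * tab$GI + rnorm(n, sd = 5)
  rf1 <- rf_importance(tab, n_trees = 300, seed = 42)
  rf2 <- rf_importance(tab, n_trees = 300, seed = 42)
  expect_identical(rf1$importance, rf2$importance)
  expect_equal(sum(rf1$importance$share), 100, tolerance = 1e-6)
  expect_true(all(rf1$importance$share >= 0))
  imp <- tidy(rf1)
  expect_equal(imp$driver[1], "GI")
  expect_gt(imp$share[1], 50)
  g <- glance(rf1)
  expect_identical(g$top_driver, "GI")
  expect_identical(g$n_rows, as.integer(n))
})

test_that("a pure-noise response leaves no driver with real importance", {
  set.seed(6)
  n <- 1000
  tab <- tibble::tibble(T = rnorm(n), PPT = rnorm(n), VPD = rnorm(n),
                        SR = rnorm(n), RH = rnorm(n), SM = rnorm(n),
                        GI = rnorm(n), agb = rnorm(n))
  rf <- rf_importance(tab, n_trees = 1000, seed = 7)
  # raw permutation importances hover at zero: none explains a meaningful
  # share of the unit response variance, and the forest has no OOB skill
  expect_lt(max(abs(rf$importance$raw)), 0.05 * var(tab$agb))
  expect_lt(rf$oob_r_squared, 0.05)
  expect_equal(sum(rf$importance$share), 100, tolerance = 1e-6)
})

test_that("all-negative raw importances fall back to uniform shares", {
  set.seed(1)   # seed where every raw permutation importance is negative
  n <- 1000
  tab <- tibble::tibble(T = rnorm(n), PPT = rnorm(n), VPD = rnorm(n),
                        SR = rnorm(n), RH = rnorm(n), SM = rnorm(n),
                        GI = rnorm(n), agb = rnorm(n))
  rf <- rf_importance(tab, n_trees = 1000, seed = 1)
  if (all(rf$importance$raw <= 0)) {
    expect_equal(rf$importance$share, rep(100 / 7, 7), tolerance = 1e-9)
  }
  expect_equal(sum(rf$importance$share), 100, tolerance = 1e-6)
})

test_that("row hygiene: missing cells are dropped and counted", {
  set.seed(9)
  tab <- tibble::tibble(T = rnorm(80), PPT = rnorm(80), VPD = rnorm(80),
                        SR = rnorm(80), RH = rnorm(80), SM = rnorm(80),
                        GI = rnorm(80), agb = rnorm(80))
  tab$PPT[1:10] <- NA
  rf <- rf_importance(tab, n_trees = 100, seed = 1)
  expect_identical(rf$n_rows, 70L)
  expect_identical(rf$n_dropped, 10L)
  expect_error(rf_importance(tab[1:20, ], n_trees = 100), "usable rows")
  expect_error(rf_importance(tab[, -2], n_trees = 100), "missing column")
})

test_that("the driver table collapses to the requested sampling unit", {
  scen <- tiny_scen
  py <- build_driver_table(scen$truth$driver_table, "pixel_year")
  px <- build_driver_table(scen$truth$driver_table, "pixel")
  expect_identical(nrow(py), 4L * 36L)
  expect_identical(nrow(px), 36L)
  m <- scen$truth$driver_table |>
    dplyr::filter(row == 1, col == 1) |>
    dplyr::summarise(GI = mean(GI), agb = mean(agb))
  expect_equal(px$GI[px$row == 1 & px$col == 1], m$GI)
  expect_equal(px$agb[px$row == 1 & px$col == 1], m$agb)
})
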