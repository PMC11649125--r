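test_that("linear gap filling interpolates interiors and extends edges", {
  expect_equal(fill_missing_linear(c(1, NA, 3)), c(1, 2, 3))
  expect_equal(fill_missing_linear(c(NA, 5, 5)), c(5, 5, 5))
  expect_equal(fill_missing_linear(c(0, NA, NA, 6)), c(0, 2, 4, 6))
  expect_equal(fill_missing_linear(c(NA, NA, 7, NA)), c(7, 7, 7, 7))
  expect_error(fill_missing_linear(c(NA_real_, NA_real_)), "unfillable")
})

test_that("IQR screen reproduces hand-computed type-7 fences", {
  x <- c(1:9, 100)
  # type-7 quartiles: Q1 = 3.25, Q3 = 7.75, IQR = 4.5, fences [-3.5, 14.5]
  res <- remove_outliers_iqr(x, k = 1.5)
  expect_equal(unname(res$fences), c(3.25 - 1.5 * 4.5, 7.75 + 1.5 * 4.5))
  expect_identical(which(res$flags), 10L)
  expect_equal(res$values[1:9], as.numeric(1:9))
  expect_true(is.na(res$values[10]))
})

test_that("IQR screen keeps constants and respects huge fences", {
  expect_identical(sum(remove_outliers_iqr(rep(5, 10))$flags), 0L)
  expect_identical(sum(remove_outliers_iqr(c(1, 2, 3, 4), k = 1000)$flags), 0L)
  expect_error(remove_outliers_iqr(1:10, k = 0), class = "grassagb_parameter_error")
  expect_error(remove_outliers_iqr(c(1, 2, 3)), "at least 4")
})

test_that("IQR screen leaves no survivor outside its own fences", {
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(50) + sample(c(0, 10), 50, replace = TRUE, prob = c(0.9, 0.1))
    res <- remove_outliers_iqr(x)
    kept <- res$values[!is.na(res$values)]
    expect_true(all(kept >= res$fences[1] & kept <= res$fences[2]))
  }
})

test_that("Savitzky-Golay reproduces polynomials and matches least squares", {
  t <- 1:20
  quad <- 2 + 0.5 * t - 0.1 * t^2
  expect_equal(sg_filter(quad, 5, 2), quad, tolerance = 1e-9)
  expect_equal(sg_filter(rep(3, 10), 5, 2), rep(3, 10))

  x <- c(0, 1, 0, 1, 0, 1, 0)
  sm <- sg_filter(x, window = 5, order = 2)
  expect_equal(sm[4], sg_oracle(x[2:6], 2, at = 0), tolerance = 1e-10)
  # edges come from the first/last full window's polynomial
  expect_equal(sm[1], sg_oracle(x[1:5], 2, at = -2), tolerance = 1e-10)
  expect_equal(sm[7], sg_oracle(x[3:7], 2, at = 2), tolerance = 1e-10)

  expect_error(sg_filter(1:10, window = 4), class = "grassagb_parameter_error")
  expect_error(sg_filter(1:10, window = 5, order = 5),
               class = "grassagb_parameter_error")
  expect_error(sg_filter(c(1, NA, 3, 4, 5), 5, 2), "missing")
})

test_that("interior Savitzky-Golay output agrees with the signal package", {
  set.seed(7)
  x <- cumsum(rnorm(40))
  mine <- sg_filter(x, 7, 3)
  ref <- signal::sgolayfilt(x, p = 3, n = 7)
  expect_equal(mine[4:37], ref[4:37], tolerance = 1e-10)
})

test_that("monthly composites take the per-month maximum and keep masks", {
  dates <- as.Date(c("2000-01-01", "2000-01-16", "2000-02-01", "2000-02-16",
                     "2000-03-01", "2000-03-16", "2000-03-25"))
  s <- grid_stack(tibble::tibble(date = dates, row = 1, col = 1,
                                 value = c(0.3, 0.5, NA, NA, 0.2, 0.6, 0.4)),
                  units = "unitless")
  m <- tibble::as_tibble(mvc_monthly(s))
  expect_equal(m$value[1], 0.5)
  expect_true(is.na(m$value[2]))
  expect_equal(m$value[3], 0.6)
  # dominance: composite >= every contributing observation
  expect_true(all(m$value[1] >= c(0.3, 0.5)))
})

test_that("soil-moisture layers combine with 7:21 thickness weights", {
  d <- as.Date("2000-01-01")
  mk <- function(v) grid_stack(tibble::tibble(date = d, row = 1:2, col = 1,
                                              value = v), units = "m3/m3")
  out <- tibble::as_tibble(combine_soil_moisture(mk(c(0.2, 0.3)), mk(c(0.4, 0.3))))
  expect_equal(out$value, c(0.25 * 0.2 + 0.75 * 0.4, 0.3))
  # mask propagation
  out2 <- tibble::as_tibble(combine_soil_moisture(mk(c(NA, 0.3)), mk(c(0.4, 0.3))))
  expect_true(is.na(out2$value[1]))
  # misalignment
  other <- grid_stack(tibble::tibble(date = d + 31, row = 1:2, col = 1,
                                     value = c(0.1, 0.1)), units = "m3/m3")
  expect_error(combine_soil_moisture(mk(c(0.2, 0.3)), other),
               class = "grassagb_alignment_error")
})

test_that("VPD follows the Tetens formulation", {
  expect_equal(tetens_es(25), 0.6108 * exp(17.27 * 25 / 262.3), tolerance = 1e-12)
  d <- as.Date("2000-07-01")
  tstk <- grid_stack(tibble::tibble(date = d, row = 1:3, col = 1,
                                    value = c(25, 25, 30)), units = "degC")
  rhstk <- grid_stack(tibble::tibble(date = d, row = 1:3, col = 1,
                                     value = c(50, 100, 50)), units = "%")
  v <- tibble::as_tibble(compute_vpd(tstk, rhstk))$value
  expect_equal(v[1], 1.584, tolerance = 1e-3)
  expect_equal(v[2], 0)
  expect_gt(v[3], v[1])   # es strictly increases with T at fixed RH < 100

  bad <- grid_stack(tibble::tibble(date = d, row = 1:3, col = 1,
                                   value = c(50, 101, 50)), units = "%")
  expect_error(compute_vpd(tstk, bad), class = "grassagb_validation_error")
})

test_that("grid resampling reproduces identity, constants and bilinear weights", {
  g <- grid_geom(nrow = 2, ncol = 2, res = 0.05, lat_origin = 40, lon_origin = 100)
  s <- grid_stack(tibble::tibble(date = as.Date("2000-01-01"),
                                 row = c(1, 2, 1, 2), col = c(1, 1, 2, 2),
                                 value = c(0, 0, 1, 1)),
                  units = "unitless", geom = g)
  idt <- resample_grid(s, g, "nearest")
  expect_equal(dplyr::arrange(tibble::as_tibble(idt), col, row)$value,
               c(0, 0, 1, 1))

  cst <- grid_stack(tibble::tibble(date = as.Date("2000-01-01"),
                                   row = c(1, 2, 1, 2), col = c(1, 1, 2, 2),
                                   value = 7), units = "unitless", geom = g)
  for (m in c("nearest", "bilinear")) {
    expect_true(all(tibble::as_tibble(resample_grid(cst, g, m))$value == 7))
  }

  # one target pixel centred in the middle of the 2x2 block
  mid <- grid_geom(nrow = 1, ncol = 1, res = 0.05,
                   lat_origin = 40 - 0.025, lon_origin = 100 + 0.025)
  expect_equal(tibble::as_tibble(resample_grid(s, mid, "bilinear"))$value, 0.5)

  far <- grid_geom(nrow = 2, ncol = 2, res = 0.05, lat_origin = 10, lon_origin = 10)
  expect_error(resample_grid(s, far), "overlap")
})

test_that("the NDVI cleaning chain is a contraction with no-op fill/screen on clean data", {
  doy <- as.integer(strftime(seq(as.Date("2000-01-01"), by = "month",
                                 length.out = 72), "%j"))
  clean <- 0.15 + 0.5 * ifelse(doy >= 91 & doy <= 304,
                               sin(pi * (doy - 91) / 213)^2, 0)
  s <- series_stack(clean)
  # full-record scope: the noise-free series makes within-period groups
  # degenerate (IQR = 0), which is not a regime real composites ever visit
  p1 <- preprocess_ndvi(s, scope = "full", composite = FALSE)
  # gap filling and outlier screening do nothing on clean data
  expect_identical(p1$report$n_filled, 0L)
  expect_identical(p1$report$n_outliers_removed, 0L)
  # smoothing is polynomial-reproducing but not a projection: a second pass
  # must change strictly less than the first (contraction toward smoothness)
  p2 <- preprocess_ndvi(p1$stack, scope = "full", composite = FALSE)
  expect_identical(p2$report$n_filled, 0L)
  expect_identical(p2$report$n_outliers_removed, 0L)
  d1 <- max(abs(tibble::as_tibble(p1$stack)$value - clean))
  d2 <- max(abs(tibble::as_tibble(p2$stack)$value -
                  tibble::as_tibble(p1$stack)$value))
  expect_lt(d2, d1)
})

test_that("inverse-distance gridding honours nearest stations", {
  st <- tibble::tibble(station_id = 1:2, lat = c(39.9, 39.8),
                       lon = c(100.1, 100.2), date = as.Date("2000-01-01"),
                       T = c(10, 20))
  g <- grid_geom(nrow = 4, ncol = 4)
  out <- tibble::as_tibble(idw_grid(st, "T", g))
  expect_true(all(out$value >= 10 & out$value <= 20))
  # a pixel essentially on top of station 1 takes its value
  near <- out$value[which.min((pixel_lat(out$row, g) - 39.9)^2 +
                                (pixel_lon(out$col, g) - 100.1)^2)]
  expect_lt(abs(near - 10), 2)
})
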