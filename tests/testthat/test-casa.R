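test_that("the FPAR ramp pins its anchors and hand-computed interior", {
  expect_equal(fpar_ramp(0.05), 0.001)
  expect_equal(fpar_ramp(0.75), 0.95)
  expect_equal(fpar_ramp(0.40, 0.05, 0.75, 0.001, 0.95),
               0.001 + (0.35 / 0.70) * 0.949, tolerance = 1e-12)
  expect_equal(fpar_ramp(0.40), 0.4755, tolerance = 1e-9)
  # clipping outside the ramp
  expect_equal(fpar_ramp(-0.1), 0.001)
  expect_equal(fpar_ramp(0.95), 0.95)
})

test_that("compute_fpar maps per-type parameters and rejects bad NDVI", {
  tm <- make_type_map(c(2, 2), c("alpine meadow" = 0.5, "alpine steppe" = 0.5), 1)
  s <- grid_stack(tibble::tibble(date = as.Date("2000-07-01"),
                                 row = c(1, 2, 1, 2), col = c(1, 1, 2, 2),
                                 value = c(0.4, 0.4, 0.4, 0.4)), units = "unitless")
  f <- compute_fpar(s, tm)
  expect_equal(tibble::as_tibble(f)$value, rep(0.4755, 4), tolerance = 1e-9)

  bad <- grid_stack(tibble::tibble(date = as.Date("2000-07-01"),
                                   row = c(1, 2, 1, 2), col = c(1, 1, 2, 2),
                                   value = c(1.5, 0.4, 0.4, 0.4)), units = "unitless")
  expect_error(compute_fpar(bad, tm), class = "grassagb_validation_error")

  # a type present in the map but absent from the parameter table is named
  p <- casa_params()[casa_params()$type != "alpine steppe", ]
  expect_error(compute_fpar(s, tm, p), "alpine steppe")
})

test_that("APAR is half the radiation intercepted by the canopy", {
  d <- as.Date("2000-07-01")
  sol <- grid_stack(tibble::tibble(date = d, row = 1:2, col = 1,
                                   value = c(100, 200)), units = "MJ/m2/month")
  fp <- grid_stack(tibble::tibble(date = d, row = 1:2, col = 1,
                                  value = c(0.5, 0.5)), units = "unitless")
  a <- tibble::as_tibble(compute_apar(sol, fp))$value
  expect_equal(a[1], 25)
  expect_equal(a[2], 2 * a[1])   # linearity in SOL
  zero <- grid_stack(tibble::tibble(date = d, row = 1:2, col = 1, value = 0),
                     units = "unitless")
  expect_equal(tibble::as_tibble(compute_apar(sol, zero))$value, c(0, 0))
  neg <- grid_stack(tibble::tibble(date = d, row = 1:2, col = 1,
                                   value = c(-1, 100)), units = "MJ/m2/month")
  expect_error(compute_apar(neg, fp), class = "grassagb_validation_error")
})

test_that("temperature stress matches its closed forms", {
  expect_equal(t_stress1(20, 15), 0.8 + 0.02 * 20 - 0.0005 * 400, tolerance = 1e-12)
  expect_equal(t_stress1(20, 15), 1.0)
  expect_equal(t_stress1(20, -15), 0)       # freezing cutoff at T <= -10
  expect_equal(t_stress1(20, -10), 0)
  expect_true(t_stress1(60, 15) >= 0)       # floored, never negative

  expect_equal(t_stress2(20, 20),
               1.1814 / ((1 + exp(-2)) * (1 + exp(-3))), tolerance = 1e-12)
  expect_equal(t_stress2(20, 20), 0.9912, tolerance = 1e-4)
  # symmetric decline away from the optimum keeps values in (0, 1.2)
  tt <- seq(-30, 50, by = 0.5)
  expect_true(all(t_stress2(20, tt) > 0 & t_stress2(20, tt) < 1.2))
})

test_that("water stress interpolates between half and full supply", {
  d <- as.Date("2000-07-01")
  mk <- function(v, u = "mm") grid_stack(tibble::tibble(date = d, row = seq_along(v),
                                                        col = 1, value = v), units = u)
  w <- tibble::as_tibble(water_stress(mk(c(60, 0, 30)), mk(c(60, 60, 60))))$value
  expect_equal(w, c(1.0, 0.5, 0.75))
  # soil-moisture mode
  wsm <- tibble::as_tibble(water_stress(sm = mk(c(0.35, 0, 0.175), "m3/m3")))$value
  expect_equal(wsm, c(1.0, 0.5, 0.75))
  expect_error(water_stress(), class = "grassagb_config_error")
})

test_that("NPP is the hand-computed product of its factors", {
  d <- as.Date("2000-07-01")
  tm <- tibble::tibble(row = 1, col = 1,
                       type = factor("alpine meadow", levels = grassland_types()))
  mk <- function(v, u) grid_stack(tibble::tibble(date = d, row = 1, col = 1,
                                                 value = v), units = u)
  te2 <- t_stress2(20, 20)
  out <- compute_npp(mk(25, "MJ/m2/month"), mk(1.0, "unitless"),
                     mk(te2, "unitless"), mk(0.75, "unitless"), tm)
  expect_equal(tibble::as_tibble(out$npp)$value,
               25 * 1.0 * te2 * 0.75 * 0.542, tolerance = 1e-12)
  expect_equal(tibble::as_tibble(out$npp)$value, 10.073, tolerance = 1e-3)
  # multiplicative chain: a zero stress annihilates NPP
  out0 <- compute_npp(mk(25, "MJ/m2/month"), mk(0, "unitless"),
                      mk(te2, "unitless"), mk(0.75, "unitless"), tm)
  expect_equal(tibble::as_tibble(out0$npp)$value, 0)
})

test_that("model bounds hold over a large random input sweep", {
  set.seed(99)
  n <- 1e5
  ndvi <- runif(n, -0.2, 1)
  f <- fpar_ramp(ndvi)
  expect_true(all(f >= 0.001 & f <= 0.95))
  topt <- runif(n, -5, 35); temp <- runif(n, -40, 45)
  e1 <- t_stress1(topt, temp); e2 <- t_stress2(topt, temp)
  expect_true(all(e1 >= 0 & e1 <= 1.2))
  expect_true(all(e2 >= 0 & e2 <= 1.2))
  ppt <- runif(n, 0, 300); pet <- runif(n, 1e-3, 300)
  w <- 0.5 + 0.5 * pmin(ppt, pet) / pet
  expect_true(all(w >= 0.5 & w <= 1))
  npp <- runif(n, 0, 500) * e1 * e2 * w * 0.542
  expect_true(all(npp >= 0))
})

test_that("the thermal optimum comes from the NDVI-peak month", {
  dates <- seq(as.Date("2000-01-01"), by = "month", length.out = 24)
  m <- lubridate::month(dates)
  ndvi <- series_stack(ifelse(m == 7, 0.8, 0.2))
  temp <- series_stack(ifelse(m == 7, c(20, 22)[lubridate::year(dates) - 1999], 5),
                       units = "degC")
  to <- estimate_topt(temp, ndvi)
  expect_equal(to$topt, 21)   # mean of the two July temperatures
})

test_that("Hamon PET is positive and increases with temperature", {
  s10 <- series_stack(rep(10, 3), start = "2000-06-01", units = "degC")
  s20 <- series_stack(rep(20, 3), start = "2000-06-01", units = "degC")
  p10 <- tibble::as_tibble(hamon_pet(s10))$value
  p20 <- tibble::as_tibble(hamon_pet(s20))$value
  expect_true(all(p10 > 0))
  expect_true(all(p20 > p10))
})

test_that("the full chain reproduces the generator's truth NPP within noise", {
  scen <- tiny_scen
  pp <- preprocess_ndvi(scen$inputs$ndvi)
  est <- casa_npp(pp$stack,
                  grassagb:::monthly_mean_stack(scen$inputs$temperature),
                  grassagb:::monthly_sum_stack(scen$inputs$solar_radiation),
                  grassagb:::monthly_sum_stack(scen$inputs$precipitation),
                  scen$inputs$type_map, scen$truth$casa_params)$npp
  j <- dplyr::inner_join(
    dplyr::rename(tibble::as_tibble(est), est = value),
    dplyr::rename(tibble::as_tibble(scen$truth$npp_true), tru = value),
    by = c("date", "row", "col"))
  rmse <- sqrt(mean((j$est - j$tru)^2))
  expect_lt(rmse, 0.25 * sd(j$tru))
})
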