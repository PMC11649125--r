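#' The nine grassland classes of the working classification
#'
#' Byte codes 1-9 in the order returned here. Two classes without published
#' allocation parameters (montane meadow; warm-temperate tussock) borrow the
#' nearest listed class's parameters, flagged in [allocation_params()].
#'
#' @return Character vector of the nine class names.
#' @export
grassland_types <- function() {
  c("alpine meadow", "alpine steppe", "temperate meadow steppe",
    "temperate typical steppe", "temperate desert steppe", "temperate meadow",
    "montane meadow", "warm-temperate tussock", "tropical tussock")
}

#' Add an exact linear ramp to a time series
#'
#' @param series Numeric vector (finite values).
#' @param slope Trend to inject, in units per year.
#' @param time_step Spacing of consecutive observations in years (e.g. `1/12`
#'   for monthly data).
#' @return `series + slope * time_step * (0, 1, 2, ...)`. Reversible:
#'   injecting `-slope` recovers the input exactly.
#' @export
inject_trend <- function(series, slope, time_step = 1) {
  if (!is.numeric(slope) || length(slope) != 1L || !is.finite(slope)) {
    rlang::abort("`slope` must be a single finite number")
  }
  if (!is.finite(time_step) || time_step <= 0) {
    rlang::abort("`time_step` must be a positive number")
  }
  series + slope * time_step * (seq_along(series) - 1)
}

#' Generate a categorical grassland-type map
#'
#' Per-class pixel quotas are fixed by largest-remainder rounding of the
#' requested fractions (realised counts match the fractions to within one
#' pixel per class), then classes grow as spatially contiguous patches from
#' randomly seeded nuclei so per-type summaries are non-degenerate.
#'
#' @param grid_shape Integer `(rows, cols)`.
#' @param type_fractions Named numeric vector over (a subset of)
#'   [grassland_types()], summing to 1.
#' @param seed Integer RNG seed.
#' @return Tibble with columns `row`, `col`, `type` (factor over the nine
#'   classes).
#' @export
make_type_map <- function(grid_shape, type_fractions, seed = 1L) {
  nr <- as.integer(grid_shape[1]); nc <- as.integer(grid_shape[2])
  if (is.na(nr) || is.na(nc) || nr < 1 || nc < 1) {
    rlang::abort("`grid_shape` must give a non-empty grid",
                 class = "grassagb_config_error")
  }
  check_fractions(type_fractions, "type_fractions")
  n <- nr * nc
  k <- length(type_fractions)

  # largest-remainder quotas
  exact <- type_fractions * n
  quota <- floor(exact)
  rem <- n - sum(quota)
  if (rem > 0) {
    top <- order(exact - quota, decreasing = TRUE)[seq_len(rem)]
    quota[top] <- quota[top] + 1
  }

  set.seed(as.integer(seed))
  assigned <- integer(n)            # 0 = unassigned; else class index
  frontier <- vector("list", k)
  neigh <- function(cell) {
    r <- ((cell - 1) %% nr) + 1; cc <- ((cell - 1) %/% nr) + 1
    out <- integer(0)
    if (r > 1) out <- c(out, cell - 1)
    if (r < nr) out <- c(out, cell + 1)
    if (cc > 1) out <- c(out, cell - nr)
    if (cc < nc) out <- c(out, cell + nr)
    out
  }
  remaining <- quota
  while (any(remaining > 0)) {
    for (cl in which(remaining > 0)) {
      cell <- NA_integer_
      while (is.na(cell)) {
        if (length(frontier[[cl]]) == 0) {
          free <- which(assigned == 0L)
          frontier[[cl]] <- free[sample.int(length(free), 1L)]
        }
        cand <- frontier[[cl]][1L]
        frontier[[cl]] <- frontier[[cl]][-1L]
        if (assigned[cand] == 0L) cell <- cand
      }
      assigned[cell] <- cl
      remaining[cl] <- remaining[cl] - 1L
      nb <- neigh(cell)
      frontier[[cl]] <- c(frontier[[cl]], nb[assigned[nb] == 0L])
    }
  }
  tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    type = factor(names(type_fractions)[assigned], levels = grassland_types())
  )
}

check_fractions <- function(fr, field) {
  if (is.null(names(fr)) || any(!nzchar(names(fr)))) {
    rlang::abort(sprintf("`%s` must be a named vector", field),
                 class = "grassagb_config_error")
  }
  unknown <- setdiff(names(fr), grassland_types())
  if (length(unknown) > 0) {
    rlang::abort(sprintf("`%s` has unknown grassland types: %s", field,
                         paste(unknown, collapse = ", ")),
                 class = "grassagb_config_error")
  }
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9) {
    rlang::abort(sprintf("`%s` must be non-negative and sum to 1", field),
                 class = "grassagb_config_error")
  }
  invisible(TRUE)
}

#' Configure a synthetic gridded scenario
#'
#' Collects every knob of the generator: grid and record length, the
#' grassland-type mosaic, the NDVI seasonal cycle with its gap and spike
#' rates, linear trends injected into the meteorological drivers, the
#' driver-effect sizes that shape the ground-truth AGB, observation noise,
#' and the seed. The same configuration (including seed) always produces
#' bit-identical output.
#'
#' Truth AGB is a log-linear function of the panel-standardised annual
#' drivers plus a linear ramp of `agb_trend` g/m2/yr and Gaussian noise of sd
#' `noise_sd["agb"]`, so effect-size and trend recovery are analytically
#' checkable.
#'
#' @param n_years Record length in years (>= 2).
#' @param steps_per_month 1 (monthly) or 2 (biweekly-like composites).
#' @param grid_shape Integer `(rows, cols)`.
#' @param type_fractions Named fractions over the grassland classes.
#' @param ndvi_baseline,ndvi_amplitude Dormant-season NDVI level and
#'   growing-season amplitude (unitless).
#' @param gap_rate,outlier_rate Fractions in `[0, 1]` of NDVI cells turned
#'   into missing values / multiplicative spikes (x2 or x0.2, clipped to
#'   `[-0.2, 1]`).
#' @param met_trends Named slopes (units/yr) injected into `temperature`
#'   (degC), `precipitation` (mm/month), `solar_radiation` (MJ/m2/month),
#'   `relative_humidity` (%), `soil_moisture` (m3/m3).
#' @param agb_baseline Baseline truth AGB, g/m2.
#' @param agb_trend Linear AGB trend injected into the truth, g/m2/yr.
#' @param driver_effects Named log-scale effect sizes of the seven drivers
#'   `GI, SM, PPT, T, VPD, SR, RH` on truth AGB.
#' @param noise_sd Named observation-noise standard deviations, incl. `agb`
#'   (g/m2) for the truth series.
#' @param start_year First calendar year.
#' @param seed Integer RNG seed.
#' @return A list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_years = 35,
                               steps_per_month = 2,
                               grid_shape = c(20, 20),
                               type_fractions = c("alpine meadow" = 0.30,
                                                  "alpine steppe" = 0.25,
                                                  "temperate typical steppe" = 0.25,
                                                  "temperate desert steppe" = 0.20),
                               ndvi_baseline = 0.12,
                               ndvi_amplitude = 0.50,
                               gap_rate = 0.05,
                               outlier_rate = 0.02,
                               met_trends = c(temperature = 0, precipitation = 0,
                                              solar_radiation = 0,
                                              relative_humidity = 0,
                                              soil_moisture = 0),
                               agb_baseline = 200,
                               agb_trend = 0,
                               driver_effects = c(GI = 0.45, SM = 0.25, PPT = 0.15,
                                                  T = 0.05, VPD = 0.04, SR = 0.03,
                                                  RH = 0.02),
                               noise_sd = c(ndvi = 0.02, temperature = 0.8,
                                            precipitation = 8, solar_radiation = 30,
                                            relative_humidity = 3,
                                            soil_moisture = 0.02, agb = 10),
                               start_year = 1981,
                               seed = 1L) {
  cfg <- list(n_years = n_years, steps_per_month = steps_per_month,
              grid_shape = as.integer(grid_shape),
              type_fractions = type_fractions,
              ndvi_baseline = ndvi_baseline, ndvi_amplitude = ndvi_amplitude,
              gap_rate = gap_rate, outlier_rate = outlier_rate,
              met_trends = met_trends, agb_baseline = agb_baseline,
              agb_trend = agb_trend, driver_effects = driver_effects,
              noise_sd = noise_sd, start_year = start_year,
              seed = as.integer(seed))
  validate_scenario(cfg)
  structure(cfg, class = "synthetic_scenario")
}

validate_scenario <- function(cfg) {
  bad <- function(field, why) {
    rlang::abort(sprintf("invalid scenario field `%s`: %s", field, why),
                 class = "grassagb_config_error")
  }
  if (!is.numeric(cfg$n_years) || cfg$n_years < 2) bad("n_years", "must be >= 2")
  if (!cfg$steps_per_month %in% c(1, 2)) bad("steps_per_month", "must be 1 or 2")
  if (length(cfg$grid_shape) != 2 || any(cfg$grid_shape < 1)) {
    bad("grid_shape", "must be two positive integers")
  }
  check_fractions(cfg$type_fractions, "type_fractions")
  for (f in c("gap_rate", "outlier_rate")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) bad(f, "must be in [0, 1]")
  }
  if (any(!is.finite(cfg$met_trends))) bad("met_trends", "must be finite")
  need <- c("GI", "SM", "PPT", "T", "VPD", "SR", "RH")
  if (!all(need %in% names(cfg$driver_effects))) {
    bad("driver_effects", paste("must name all of", paste(need, collapse = ", ")))
  }
  if (any(cfg$noise_sd < 0)) bad("noise_sd", "must be non-negative")
  invisible(TRUE)
}

# smooth unit-variance spatial field on an nr x nc grid
random_field <- function(nr, nc, smooth_passes = 2) {
  m <- matrix(stats::rnorm(nr * nc), nr, nc)
  for (i in seq_len(smooth_passes)) {
    p <- matrix(0, nr + 2, nc + 2)
    p[2:(nr + 1), 2:(nc + 1)] <- m
    p[1, ] <- p[2, ]; p[nr + 2, ] <- p[nr + 1, ]
    p[, 1] <- p[, 2]; p[, nc + 2] <- p[, nc + 1]
    m <- (p[1:nr, 2:(nc + 1)] + p[3:(nr + 2), 2:(nc + 1)] +
          p[2:(nr + 1), 1:nc] + p[2:(nr + 1), 3:(nc + 2)] +
          p[2:(nr + 1), 2:(nc + 1)]) / 5
  }
  m <- m - mean(m)
  s <- stats::sd(as.vector(m))
  if (s > 0) m <- m / s
  m
}

#' Generate a synthetic scenario with stored ground truth
#'
#' Produces the full set of input stacks the pipeline expects (NDVI with
#' gaps and spike outliers, temperature, precipitation, solar radiation,
#' relative humidity, two soil-moisture layers, a type map) together with a
#' `truth` bundle: noise-free monthly NPP obtained by running the
#' light-use-efficiency forward model on the clean fields, an annual truth
#' AGB panel driven by the configured effect sizes and trend, the per-pixel
#' injected slope map, the exact positions of injected gaps and outliers,
#' and the clean annual driver table for attribution tests.
#'
#' @param cfg A [synthetic_scenario()].
#' @param detail `"full"` stores the complete truth bundle; `"trend"` skips
#'   the forward-model NPP truth and the driver panel (for trend-recovery
#'   studies that only consume `agb_true`). The random-number stream is
#'   identical under both levels, so shared components agree bit for bit.
#' @return List with elements `inputs` (named grid stacks + `type_map`),
#'   `truth`, and `cfg`.
#' @export
generate_scenario <- function(cfg, detail = c("full", "trend")) {
  detail <- match.arg(detail)
  if (!inherits(cfg, "synthetic_scenario")) cfg <- do.call(synthetic_scenario, cfg)
  validate_scenario(cfg)
  set.seed(cfg$seed)

  nr <- cfg$grid_shape[1]; nc <- cfg$grid_shape[2]
  npx <- nr * nc
  spm <- cfg$steps_per_month
  steps_per_year <- 12L * spm
  n_steps <- cfg$n_years * steps_per_year
  geom <- grid_geom(nrow = nr, ncol = nc)

  years <- cfg$start_year + seq_len(cfg$n_years) - 1L
  months <- rep(1:12, each = spm)
  days <- if (spm == 2) c(1L, 16L) else 1L
  dates <- as.Date(sprintf("%d-%02d-%02d",
                           rep(years, each = steps_per_year),
                           rep(months, times = cfg$n_years),
                           rep(days, times = 12L * cfg$n_years)))
  t_years <- (seq_len(n_steps) - 0.5) / steps_per_year  # elapsed years at step centre
  doy <- as.integer(strftime(dates, "%j"))
  month_of <- rep(rep(1:12, each = spm), times = cfg$n_years)
  year_idx <- rep(seq_len(cfg$n_years), each = steps_per_year)

  type_map <- make_type_map(cfg$grid_shape, cfg$type_fractions, seed = cfg$seed)

  # spatial fields (unit variance, smooth)
  f <- list(ndvi = random_field(nr, nc), temperature = random_field(nr, nc),
            precipitation = random_field(nr, nc), solar = random_field(nr, nc),
            rh = random_field(nr, nc), sm = random_field(nr, nc),
            gi = random_field(nr, nc))

  # interannual anomalies, one draw per pixel-year and variable
  z_yr <- lapply(stats::setNames(nm = c("temperature", "precipitation", "solar",
                                        "rh", "sm", "gi")),
                 function(v) matrix(stats::rnorm(npx * cfg$n_years), npx, cfg$n_years))

  # seasonal shapes
  grow <- as.numeric(doy >= 91 & doy <= 304)
  sin2 <- ifelse(grow > 0, sin(pi * (doy - 91) / 213)^2, 0)
  t_cycle <- -12 * cos(2 * pi * (month_of - 1) / 12)    # peak in July
  sr_cycle <- 450 + 250 * sin2
  ppt_cycle <- 30 + 25 * sin2
  rh_cycle <- 55 + 8 * sin2

  px <- seq_len(npx)
  long <- tidyr::expand_grid(step = seq_len(n_steps), pixel = px)
  # pixel index <-> (row, col); column-major like make_type_map
  row_of <- ((px - 1) %% nr) + 1
  col_of <- ((px - 1) %/% nr) + 1

  sdv <- function(v) unname(cfg$noise_sd[v] %||% 0)
  trend_of <- function(v) unname(cfg$met_trends[v] %||% 0)
  noise <- function(v) stats::rnorm(n_steps * npx, sd = sdv(v))
  sp <- function(field) rep(as.vector(field), times = 1)[long$pixel]
  yr_anom <- function(v) z_yr[[v]][cbind(long$pixel, year_idx[long$step])]

  clean <- list()
  clean$ndvi <- pmin(1, pmax(-0.2,
    cfg$ndvi_baseline * (1 + 0.10 * sp(f$ndvi)) +
      cfg$ndvi_amplitude * (1 + 0.10 * sp(f$ndvi)) * sin2[long$step]))
  clean$temperature <- 2 + 1.0 * sp(f$temperature) + t_cycle[long$step] +
    0.5 * yr_anom("temperature") + trend_of("temperature") * t_years[long$step]
  clean$precipitation <- pmax(0,
    ppt_cycle[long$step] * (1 + 0.20 * sp(f$precipitation)) *
      (1 + 0.12 * yr_anom("precipitation")) +
      trend_of("precipitation") * t_years[long$step])
  clean$solar_radiation <- pmax(0,
    sr_cycle[long$step] * (1 + 0.05 * sp(f$solar)) *
      (1 + 0.04 * yr_anom("solar")) +
      trend_of("solar_radiation") * t_years[long$step])
  clean$relative_humidity <- pmin(98, pmax(5,
    rh_cycle[long$step] + 4 * sp(f$rh) + 2 * yr_anom("rh") +
      trend_of("relative_humidity") * t_years[long$step]))
  sm_base <- 0.03 * sp(f$sm) + 0.015 * yr_anom("sm") +
    trend_of("soil_moisture") * t_years[long$step]
  clean$sm_top <- pmin(0.5, pmax(0.02, 0.18 + 0.06 * sin2[long$step] + sm_base))
  clean$sm_mid <- pmin(0.5, pmax(0.02, 0.22 + 0.04 * sin2[long$step] + sm_base))

  mk_stack <- function(values, units) {
    grid_stack(tibble::tibble(date = dates[long$step],
                              row = row_of[long$pixel], col = col_of[long$pixel],
                              value = values),
               units = units, geom = geom)
  }
  units_of <- c(ndvi = "unitless", temperature = "degC",
                precipitation = "mm/month", solar_radiation = "MJ/m2/month",
                relative_humidity = "%", sm_top = "m3/m3", sm_mid = "m3/m3")

  observed <- clean
  for (v in names(observed)) {
    nv <- switch(v, ndvi = "ndvi", temperature = "temperature",
                 precipitation = "precipitation", solar_radiation = "solar_radiation",
                 relative_humidity = "relative_humidity",
                 sm_top = "soil_moisture", sm_mid = "soil_moisture")
    observed[[v]] <- observed[[v]] + noise(nv)
  }
  observed$ndvi <- pmin(1, pmax(-0.2, observed$ndvi))
  observed$precipitation <- pmax(0, observed$precipitation)
  observed$solar_radiation <- pmax(0, observed$solar_radiation)
  observed$relative_humidity <- pmin(100, pmax(0, observed$relative_humidity))
  observed$sm_top <- pmin(0.6, pmax(0.01, observed$sm_top))
  observed$sm_mid <- pmin(0.6, pmax(0.01, observed$sm_mid))

  # NDVI gaps and multiplicative spikes, with exact bookkeeping
  ncells <- n_steps * npx
  n_gap <- round(cfg$gap_rate * ncells)
  gap_idx <- if (n_gap > 0) sample.int(ncells, n_gap) else integer(0)
  rest <- setdiff(seq_len(ncells), gap_idx)
  n_out <- round(cfg$outlier_rate * ncells)
  out_idx <- if (n_out > 0) rest[sample.int(length(rest), n_out)] else integer(0)
  factors <- if (n_out > 0) sample(c(2, 0.2), n_out, replace = TRUE) else numeric(0)

  ndvi_obs <- observed$ndvi
  # a spike replaces the observation outright (sensor artifact), keeping the
  # injected target unambiguous rather than riding on the observation noise
  spiked <- pmin(1, pmax(-0.2, clean$ndvi[out_idx] * factors))
  ndvi_obs[out_idx] <- spiked
  ndvi_obs[gap_idx] <- NA_real_

  cell_tbl <- function(idx, ...) {
    tibble::tibble(date = dates[long$step[idx]], row = row_of[long$pixel[idx]],
                   col = col_of[long$pixel[idx]], ...)
  }
  gaps <- cell_tbl(gap_idx, clean_value = clean$ndvi[gap_idx])
  outliers <- cell_tbl(out_idx, factor = factors,
                       clean_value = clean$ndvi[out_idx], spiked_value = spiked)

  inputs <- list(
    ndvi = mk_stack(ndvi_obs, units_of[["ndvi"]]),
    temperature = mk_stack(observed$temperature, units_of[["temperature"]]),
    precipitation = mk_stack(observed$precipitation, units_of[["precipitation"]]),
    solar_radiation = mk_stack(observed$solar_radiation, units_of[["solar_radiation"]]),
    relative_humidity = mk_stack(observed$relative_humidity, units_of[["relative_humidity"]]),
    sm_top = mk_stack(observed$sm_top, units_of[["sm_top"]]),
    sm_mid = mk_stack(observed$sm_mid, units_of[["sm_mid"]]),
    type_map = type_map
  )

  # --- truth ------------------------------------------------------------
  # nothing below draws random numbers before the final AGB noise, so the
  # stream is identical whichever detail level is requested
  eff <- cfg$driver_effects
  params <- casa_params()
  need_panel <- detail == "full" || any(eff != 0)
  npp_true <- NULL
  panel <- NULL

  if (need_panel || detail == "full") {
    clean_stacks <- lapply(stats::setNames(nm = names(clean)), function(v) {
      mk_stack(clean[[v]], units_of[[v]])
    })
    met_monthly <- list(
      temperature = monthly_mean_stack(clean_stacks$temperature),
      precipitation = monthly_sum_stack(clean_stacks$precipitation),
      solar_radiation = monthly_sum_stack(clean_stacks$solar_radiation),
      relative_humidity = monthly_mean_stack(clean_stacks$relative_humidity))
    if (detail == "full") {
      ndvi_monthly <- mvc_monthly(clean_stacks$ndvi)
      npp_true <- casa_npp(ndvi = ndvi_monthly,
                           temperature = met_monthly$temperature,
                           solar_radiation = met_monthly$solar_radiation,
                           precipitation = met_monthly$precipitation,
                           type_map = type_map, params = params)$npp
    }
    # annual clean driver panel
    vpd_monthly <- compute_vpd(met_monthly$temperature, met_monthly$relative_humidity)
    sm_comb <- combine_soil_moisture(monthly_mean_stack(clean_stacks$sm_top),
                                     monthly_mean_stack(clean_stacks$sm_mid))
    ann <- function(stk, reducer) aggregate_period(stk, "annual", reducer)
    drv <- list(T = ann(met_monthly$temperature, "mean"),
                PPT = ann(met_monthly$precipitation, "sum"),
                VPD = ann(vpd_monthly, "mean"),
                SR = ann(met_monthly$solar_radiation, "sum"),
                RH = ann(met_monthly$relative_humidity, "mean"),
                SM = ann(sm_comb, "mean"))
    panel <- drv$T[, c("year", "row", "col")]
    for (v in names(drv)) panel[[v]] <- drv[[v]]$value
  } else {
    # same (year, row, col) ordering that the grouped aggregation produces
    panel <- tidyr::expand_grid(year = years, row = seq_len(nr), col = seq_len(nc))
  }
  pix <- (panel$col - 1) * nr + panel$row
  panel$GI <- pmax(0, 1.5 + 0.8 * as.vector(f$gi)[pix] +
                     0.4 * z_yr$gi[cbind(pix, panel$year - cfg$start_year + 1L)])

  zsc <- function(x) (x - mean(x)) / stats::sd(x)
  log_agb <- log(cfg$agb_baseline)
  for (v in names(eff)) if (eff[[v]] != 0) log_agb <- log_agb + eff[[v]] * zsc(panel[[v]])
  agb_det <- exp(log_agb)
  panel$agb <- pmax(0, agb_det + cfg$agb_trend * (panel$year - cfg$start_year) +
                      stats::rnorm(nrow(panel), sd = sdv("agb")))

  truth <- list(
    npp_true = npp_true,
    agb_true = panel[, c("year", "row", "col", "agb")],
    driver_table = if (need_panel) panel else NULL,
    injected_slopes = tibble::tibble(row = row_of, col = col_of,
                                     slope = cfg$agb_trend),
    gaps = gaps,
    outliers = outliers,
    casa_params = params,
    noise_sd = cfg$noise_sd
  )

  list(inputs = inputs, truth = truth, cfg = cfg)
}

monthly_mean_stack <- function(stack) {
  df <- tibble::as_tibble(stack)
  keys <- tibble::tibble(date = lubridate::floor_date(df$date, "month"),
                         row = df$row, col = df$col)
  out <- dplyr::arrange(fast_agg(keys, df$value, "mean"),
                        .data$date, .data$row, .data$col)
  grid_stack(out, units = stack_units(stack), geom = stack_geom(stack))
}

monthly_sum_stack <- function(stack) {
  df <- tibble::as_tibble(stack)
  spm <- length(unique(lubridate::day(df$date)))
  keys <- tibble::tibble(date = lubridate::floor_date(df$date, "month"),
                         row = df$row, col = df$col)
  out <- dplyr::arrange(fast_agg(keys, df$value, "sum"),
                        .data$date, .data$row, .data$col)
  # sub-monthly composites sample the monthly rate; average, don't double-count
  if (spm > 1) out$value <- out$value / spm
  grid_stack(out, units = stack_units(stack), geom = stack_geom(stack))
}
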