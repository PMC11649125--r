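#' Fill gaps in a series by linear interpolation
#'
#' Interior gaps are filled linearly between the nearest observed neighbours;
#' leading/trailing gaps take the nearest observed value (no extrapolation at
#' the record ends).
#'
#' @param series Numeric vector; `NA` marks missing.
#' @return Numeric vector with every gap filled.
#' @export
fill_missing_linear <- function(series) {
  obs <- which(!is.na(series))
  if (length(obs) == 0) {
    rlang::abort("unfillable series: no observed values")
  }
  if (length(obs) == length(series)) return(series)
  if (length(obs) == 1L) return(rep(series[obs], length(series)))
  stats::approx(x = obs, y = series[obs], xout = seq_along(series),
                method = "linear", rule = 2)$y
}

#' Screen a series for outliers with interquartile-range fences
#'
#' Values outside `[Q1 - k*IQR, Q3 + k*IQR]` are masked (`NA`). Quartiles use
#' the linear-interpolation quantile rule (type 7). Applied to the full
#' record; for seasonal series see the `scope` argument of
#' [preprocess_ndvi()], which screens within composite periods across years.
#'
#' @param series Numeric vector, >= 4 observed values.
#' @param k Fence multiplier, > 0 (default 1.5).
#' @return List with `values` (series with outliers set `NA`) and `flags`
#'   (logical, `TRUE` where masked).
#' @export
remove_outliers_iqr <- function(series, k = 1.5) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0) {
    rlang::abort("`k` must be a single positive number",
                 class = "grassagb_parameter_error")
  }
  if (sum(!is.na(series)) < 4) {
    rlang::abort("outlier screening needs at least 4 observed values")
  }
  q <- stats::quantile(series, c(0.25, 0.75), na.rm = TRUE, type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - k * iqr
  hi <- q[2] + k * iqr
  flags <- !is.na(series) & (series < lo | series > hi)
  series[flags] <- NA_real_
  list(values = series, flags = flags, fences = c(lower = lo, upper = hi))
}

# Savitzky-Golay convolution weights: value of the local least-squares
# polynomial of degree `order` over positions -h..h, evaluated at `at`.
sg_weights <- function(window, order, at = 0) {
  h <- (window - 1) / 2
  v <- outer(-h:h, 0:order, `^`)
  # row of the hat matrix evaluating the fit at position `at`
  as.vector((at^(0:order)) %*% solve(crossprod(v), t(v)))
}

#' Savitzky-Golay smoothing
#'
#' Each interior point is replaced by the centre value of the local
#' least-squares polynomial of degree `order` over the moving window. The
#' first and last `(window-1)/2` points are taken from the polynomial fitted
#' to the first/last full window, evaluated at their positions.
#'
#' @param series Numeric vector without missing values (run after gap
#'   filling), length >= `window`.
#' @param window Odd window length (default 5).
#' @param order Polynomial degree, `< window` (default 2).
#' @return Smoothed numeric vector of the same length.
#' @export
sg_filter <- function(series, window = 5, order = 2) {
  if (window %% 2 != 1 || window < 3) {
    rlang::abort("`window` must be an odd integer >= 3",
                 class = "grassagb_parameter_error")
  }
  if (order >= window || order < 0) {
    rlang::abort("`order` must be non-negative and smaller than `window`",
                 class = "grassagb_parameter_error")
  }
  if (anyNA(series)) rlang::abort("series must have no missing values; gap-fill first")
  n <- length(series)
  if (n < window) rlang::abort("series shorter than the smoothing window")
  h <- (window - 1) / 2
  centre <- sg_weights(window, order, at = 0)
  out <- stats::filter(series, rev(centre), sides = 2)
  out <- as.numeric(out)
  for (i in seq_len(h)) {
    out[i] <- sum(sg_weights(window, order, at = i - 1 - h) * series[1:window])
    out[n - i + 1] <- sum(sg_weights(window, order, at = h - i + 1) *
                            series[(n - window + 1):n])
  }
  out
}

#' Maximum-value composite to monthly cadence
#'
#' Per pixel and calendar month, the composite is the maximum over that
#' month's unmasked observations; months where every observation is masked
#' stay masked.
#'
#' @param stack Grid stack at (sub-)monthly cadence.
#' @return Monthly grid stack (dates on the first of each month).
#' @export
mvc_monthly <- function(stack) {
  df <- tibble::as_tibble(stack)
  if (nrow(df) == 0) rlang::abort("empty stack")
  keys <- tibble::tibble(date = lubridate::floor_date(df$date, "month"),
                         row = df$row, col = df$col)
  out <- dplyr::arrange(fast_agg(keys, df$value, "max"),
                        .data$date, .data$row, .data$col)
  grid_stack(out, units = stack_units(stack), geom = stack_geom(stack))
}

#' Combine two soil-moisture layers by thickness weighting
#'
#' The 0-7 cm and 7-28 cm layers are averaged with their thicknesses as
#' weights: `(7 * top + 21 * mid) / 28`, i.e. weights 0.25 and 0.75. The
#' result is masked wherever either layer is masked.
#'
#' @param sm_top 0-7 cm volumetric soil moisture stack.
#' @param sm_mid 7-28 cm volumetric soil moisture stack.
#' @return 0-28 cm grid stack.
#' @export
combine_soil_moisture <- function(sm_top, sm_mid) {
  j <- join_stacks(sm_top, sm_mid, c("sm_top", "sm_mid"))
  j$value <- (7 * j$a + 21 * j$b) / 28
  grid_stack(j[, c("date", "row", "col", "value")],
             units = stack_units(sm_top), geom = stack_geom(sm_top))
}

#' Saturation vapour pressure (Tetens)
#'
#' `es(T) = 0.6108 * exp(17.27 * T / (T + 237.3))` kPa, T in degrees C.
#'
#' @param temp_c Air temperature, degC.
#' @return Saturation vapour pressure, kPa.
#' @export
tetens_es <- function(temp_c) {
  0.6108 * exp(17.27 * temp_c / (temp_c + 237.3))
}

#' Vapour pressure deficit from temperature and relative humidity
#'
#' `VPD = es(T) * (1 - RH/100)` with the Tetens saturation curve; always
#' non-negative, zero at saturation.
#'
#' @param temperature Air-temperature stack, degC.
#' @param relative_humidity Relative-humidity stack, percent in `[0, 100]`.
#' @return VPD grid stack, kPa.
#' @export
compute_vpd <- function(temperature, relative_humidity) {
  j <- join_stacks(temperature, relative_humidity, c("temperature", "relative_humidity"))
  rh <- j$b[!is.na(j$b)]
  if (any(rh < 0 | rh > 100)) {
    rlang::abort("relative humidity outside [0, 100]",
                 class = "grassagb_validation_error")
  }
  j$value <- tetens_es(j$a) * (1 - j$b / 100)
  grid_stack(j[, c("date", "row", "col", "value")], units = "kPa",
             geom = stack_geom(temperature))
}

#' Resample a stack onto a target grid
#'
#' Nearest-neighbour (for categorical fields) or bilinear (for continuous
#' fields) resampling between two pixel-centre-registered geographic grids.
#' Bilinear output is masked wherever any contributing source cell is masked.
#'
#' @param stack Source grid stack.
#' @param target_geom Target [grid_geom()] with `nrow`/`ncol` set.
#' @param method `"nearest"` or `"bilinear"`.
#' @return Grid stack on the target lattice.
#' @export
resample_grid <- function(stack, target_geom, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  sg <- stack_geom(stack)
  if (is.null(target_geom$nrow) || is.null(target_geom$ncol)) {
    rlang::abort("`target_geom` must carry nrow and ncol")
  }
  df <- tibble::as_tibble(stack)
  nr_s <- max(df$row); nc_s <- max(df$col)
  tg <- tidyr::expand_grid(row = seq_len(target_geom$nrow),
                           col = seq_len(target_geom$ncol))
  # fractional source indices of the target pixel centres
  fr <- (sg$lat_origin - pixel_lat(tg$row, target_geom)) / sg$res + 0.5
  fc <- (pixel_lon(tg$col, target_geom) - sg$lon_origin) / sg$res + 0.5
  if (all(fr < 0.5 | fr > nr_s + 0.5) || all(fc < 0.5 | fc > nc_s + 0.5)) {
    rlang::abort("target grid does not overlap the source extent")
  }
  dates <- sort(unique(df$date))
  per_date <- split(df, df$date)
  out <- purrr::map(dates, function(d) {
    m <- matrix(NA_real_, nr_s, nc_s)
    sl <- per_date[[as.character(d)]]
    m[cbind(sl$row, sl$col)] <- sl$value
    val <- if (method == "nearest") {
      ri <- pmin(nr_s, pmax(1L, as.integer(round(fr))))
      ci <- pmin(nc_s, pmax(1L, as.integer(round(fc))))
      m[cbind(ri, ci)]
    } else {
      r0 <- pmin(nr_s - 1L, pmax(1L, floor(fr))); r1 <- r0 + 1L
      c0 <- pmin(nc_s - 1L, pmax(1L, floor(fc))); c1 <- c0 + 1L
      wr <- pmin(1, pmax(0, fr - r0)); wc <- pmin(1, pmax(0, fc - c0))
      (1 - wr) * (1 - wc) * m[cbind(r0, c0)] + (1 - wr) * wc * m[cbind(r0, c1)] +
        wr * (1 - wc) * m[cbind(r1, c0)] + wr * wc * m[cbind(r1, c1)]
    }
    tibble::tibble(date = d, row = tg$row, col = tg$col, value = val)
  })
  grid_stack(dplyr::bind_rows(out), units = stack_units(stack), geom = target_geom)
}

#' Clean an NDVI stack and composite it to monthly cadence
#'
#' Applies, per pixel: linear gap filling, interquartile-range outlier
#' screening (masked cells re-filled by interpolation), Savitzky-Golay
#' smoothing, then maximum-value compositing to monthly values. Outliers must
#' not anchor the interpolation, hence fill -> screen -> re-fill -> smooth ->
#' composite.
#'
#' @param stack NDVI grid stack at (sub-)monthly cadence.
#' @param k IQR fence multiplier (default 1.5).
#' @param scope `"seasonal"` screens each composite period-of-year across
#'   years (robust for strongly seasonal series, the default); `"full"`
#'   screens each pixel's full record at once.
#' @param sg_window,sg_order Savitzky-Golay window (odd) and polynomial
#'   degree.
#' @param composite If `FALSE`, skip the monthly composite and return the
#'   cleaned series at input cadence.
#' @return List with `stack` (cleaned, monthly unless `composite = FALSE`)
#'   and `report` (counts of filled/removed cells, parameters, and the
#'   per-cell outlier flags).
#' @export
preprocess_ndvi <- function(stack, k = 1.5, scope = c("seasonal", "full"),
                            sg_window = 5, sg_order = 2, composite = TRUE) {
  scope <- match.arg(scope)
  df <- tibble::as_tibble(stack) |>
    dplyr::arrange(.data$row, .data$col, .data$date)
  df$period <- strftime(df$date, "%m-%d")
  n_gaps <- sum(is.na(df$value))

  cleaned <- df |>
    dplyr::group_by(.data$row, .data$col) |>
    dplyr::group_modify(function(g, key) {
      filled <- fill_missing_linear(g$value)
      if (scope == "full") {
        scr <- remove_outliers_iqr(filled, k = k)
        vals <- scr$values; flags <- scr$flags
      } else {
        vals <- filled; flags <- logical(length(filled))
        for (p in unique(g$period)) {
          idx <- which(g$period == p)
          if (length(idx) < 4) next  # too few years for within-period fences
          scr <- remove_outliers_iqr(filled[idx], k = k)
          vals[idx] <- scr$values
          flags[idx] <- scr$flags
        }
      }
      refilled <- fill_missing_linear(vals)
      g$value <- sg_filter(refilled, window = sg_window, order = sg_order)
      g$outlier <- flags
      g
    }) |>
    dplyr::ungroup()

  n_out <- sum(cleaned$outlier)
  flags <- cleaned[cleaned$outlier, c("date", "row", "col")]
  clean_stack <- grid_stack(cleaned[, c("date", "row", "col", "value")],
                            units = stack_units(stack), geom = stack_geom(stack))
  if (composite) clean_stack <- mvc_monthly(clean_stack)
  list(stack = clean_stack,
       report = list(n_filled = n_gaps, n_outliers_removed = n_out,
                     sg_window = sg_window, sg_order = sg_order,
                     iqr_k = k, iqr_scope = scope, outlier_cells = flags))
}

#' Inverse-distance-weighted gridding of station records
#'
#' Optional ingestion path for station CSVs (columns `station_id, lat, lon,
#' date, <variable>`): each grid pixel takes the inverse-squared-distance
#' weighted mean of the `n_nearest` stations.
#'
#' @param stations Data frame with `lat`, `lon`, `date` and the value column.
#' @param variable Name of the value column to grid.
#' @param geom Target [grid_geom()] with `nrow`/`ncol`.
#' @param n_nearest Number of nearest stations to average (default 8).
#' @param power Inverse-distance power (default 2).
#' @param units Unit string for the output stack.
#' @return Grid stack on `geom`.
#' @export
idw_grid <- function(stations, variable, geom, n_nearest = 8, power = 2,
                     units = "unknown") {
  px <- tidyr::expand_grid(row = seq_len(geom$nrow), col = seq_len(geom$ncol))
  px$lat <- pixel_lat(px$row, geom); px$lon <- pixel_lon(px$col, geom)
  st <- dplyr::distinct(stations, .data$lat, .data$lon)
  d <- outer(px$lat, st$lat, `-`)^2 + outer(px$lon, st$lon, `-`)^2
  k <- min(n_nearest, nrow(st))
  dates <- sort(unique(stations$date))
  out <- purrr::map(dates, function(dt) {
    sl <- stations[stations$date == dt, ]
    sl <- dplyr::left_join(st, sl, by = c("lat", "lon"))
    vals <- vapply(seq_len(nrow(px)), function(i) {
      ord <- order(d[i, ])[seq_len(k)]
      w <- 1 / pmax(d[i, ord]^(power / 2), 1e-12)
      v <- sl[[variable]][ord]
      ok <- !is.na(v)
      if (!any(ok)) return(NA_real_)
      sum(w[ok] * v[ok]) / sum(w[ok])
    }, numeric(1))
    tibble::tibble(date = dt, row = px$row, col = px$col, value = vals)
  })
  grid_stack(dplyr::bind_rows(out), units = units, geom = geom)
}
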