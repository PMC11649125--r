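#' Theil-Sen slope of a series
#'
#' The median of all pairwise slopes `(x_j - x_i) / (t_j - t_i)`, `i < j`;
#' for an even pair count the median is the mean of the two central order
#' statistics. Robust to outliers and non-normal noise.
#'
#' @param series Numeric values, n >= 3 (NA allowed, dropped with its time).
#' @param t Observation times (default `1, 2, ...`), same length.
#' @return The slope in units per unit of `t`.
#' @export
theil_sen <- function(series, t = seq_along(series)) {
  ok <- !is.na(series) & !is.na(t)
  x <- series[ok]; tt <- t[ok]
  n <- length(x)
  if (n < 3) rlang::abort("Theil-Sen needs at least 3 observed points")
  ij <- utils::combn(n, 2)
  stats::median((x[ij[2, ]] - x[ij[1, ]]) / (tt[ij[2, ]] - tt[ij[1, ]]))
}

#' Mann-Kendall trend test
#'
#' `S = sum over i < j of sign(x_j - x_i)`; the variance uses the
#' tie-corrected formula, and `Z` applies the continuity correction
#' (`(S - 1)/sd` for positive S, `(S + 1)/sd` for negative, 0 when `S = 0`).
#' Two-sided p from the standard normal approximation, appropriate for the
#' multi-decade series this package targets.
#'
#' @param series Numeric values, n >= 4 after NA removal.
#' @return List with `S`, `var_S`, `Z`, `p`, `n`.
#' @export
mann_kendall <- function(series) {
  x <- series[!is.na(series)]
  n <- length(x)
  if (n < 4) rlang::abort("Mann-Kendall needs at least 4 observed points")
  s <- 0L
  d <- outer(x, x, `-`)
  s <- sum(sign(d[lower.tri(d)]))   # d[j, i] = x_j - x_i for j > i
  ties <- table(x)
  ties <- ties[ties > 1]
  var_s <- (n * (n - 1) * (2 * n + 5) - sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  z <- if (s > 0) (s - 1) / sqrt(var_s) else if (s < 0) (s + 1) / sqrt(var_s) else 0
  if (!is.finite(z)) z <- 0           # all values tied
  p <- if (s == 0) 1 else 2 * stats::pnorm(-abs(z))
  list(S = s, var_S = var_s, Z = z, p = min(1, p), n = n)
}

#' Five-class trend category from slope and significance
#'
#' `|slope| < slope_threshold` is stable; beyond the threshold, the
#' Mann-Kendall p-value splits slight from significant improvement
#' (positive slopes) or degradation (negative slopes).
#'
#' @param slope Trend slope(s), units/yr.
#' @param p Mann-Kendall p-value(s).
#' @param slope_threshold Half-width of the stable band, >= 0 (default 0.5
#'   g/m2/yr).
#' @param alpha Significance level (default 0.05).
#' @return Factor with levels `significant degradation`, `slight
#'   degradation`, `stable`, `slight improvement`, `significant
#'   improvement`.
#' @export
classify_trend <- function(slope, p, slope_threshold = 0.5, alpha = 0.05) {
  if (!is.numeric(slope_threshold) || slope_threshold < 0) {
    rlang::abort("`slope_threshold` must be non-negative",
                 class = "grassagb_parameter_error")
  }
  lev <- trend_levels()
  out <- ifelse(abs(slope) < slope_threshold, "stable",
         ifelse(slope >= slope_threshold,
                ifelse(p < alpha, "significant improvement", "slight improvement"),
                ifelse(p < alpha, "significant degradation", "slight degradation")))
  factor(out, levels = lev)
}

trend_levels <- function() {
  c("significant degradation", "slight degradation", "stable",
    "slight improvement", "significant improvement")
}

cv_levels <- function() {
  c("low", "relatively low", "medium", "relatively high", "high")
}

#' Coefficient of variation
#'
#' Sample standard deviation divided by the mean; undefined for zero-mean
#' series.
#'
#' @param series Numeric values, n >= 2 after NA removal.
#' @return The CV (unitless).
#' @export
coefficient_of_variation <- function(series) {
  x <- series[!is.na(series)]
  if (length(x) < 2) rlang::abort("CV needs at least 2 observed values")
  m <- mean(x)
  if (m == 0) rlang::abort("undefined CV: zero mean")
  stats::sd(x) / m
}

#' Five-level stability classification of a CV field
#'
#' Fixed mode cuts at four ascending breaks; quantile mode (default) uses
#' the 20/40/60/80th percentiles of the valid pixels so each level holds a
#' fifth of the map.
#'
#' @param cv Numeric CV values (NA allowed).
#' @param breaks `"quantile"` or four ascending thresholds.
#' @return Factor with levels `low` ... `high`.
#' @export
classify_cv <- function(cv, breaks = "quantile") {
  valid <- cv[!is.na(cv)]
  if (identical(breaks, "quantile")) {
    if (length(valid) < 5) rlang::abort("quantile mode needs >= 5 valid pixels")
    br <- stats::quantile(valid, c(0.2, 0.4, 0.6, 0.8), type = 7, names = FALSE)
  } else {
    if (length(breaks) != 4 || any(diff(breaks) <= 0)) {
      rlang::abort("`breaks` must be four ascending thresholds",
                   class = "grassagb_parameter_error")
    }
    br <- breaks
  }
  cut(cv, breaks = c(-Inf, br, Inf), labels = cv_levels(), right = TRUE)
}

#' Per-category area percentages
#'
#' Percentages over the valid (non-NA) pixels, by simple pixel count or
#' weighted by `cos(latitude)` to account for meridian convergence.
#'
#' @param df Data frame with a category column and, for the weighted mode, a
#'   `row` column (or `lat` column) to derive latitude.
#' @param category Name of the category column.
#' @param mode `"count"` or `"latitude"`.
#' @param geom [grid_geom()] used to derive latitudes from `row` when no
#'   `lat` column is present.
#' @return Tibble `(category, percent)`; percentages sum to 100.
#' @export
area_fraction <- function(df, category = "category", mode = c("count", "latitude"),
                          geom = grid_geom()) {
  mode <- match.arg(mode)
  keep <- !is.na(df[[category]])
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0) rlang::abort("no valid pixels")
  w <- if (mode == "count") rep(1, nrow(df))
       else cos(pi / 180 * (if ("lat" %in% names(df)) df$lat
                            else pixel_lat(df$row, geom)))
  out <- tibble::tibble(category = df[[category]], w = w) |>
    dplyr::group_by(.data$category, .drop = FALSE) |>
    dplyr::summarise(percent = 100 * sum(.data$w), .groups = "drop")
  out$percent <- out$percent / sum(out$percent) * 100
  out
}

#' Per-pixel trend analysis of an annual stack
#'
#' Theil-Sen slope, Mann-Kendall test and the five-class category for every
#' pixel of an annual series.
#'
#' @param annual Tibble `(year, row, col, value)` from [aggregate_period()].
#' @param slope_threshold,alpha Passed to [classify_trend()].
#' @return Tibble of class `agb_trend`: `(row, col, slope, S, Z, p,
#'   category)`.
#' @export
trend_analysis <- function(annual, slope_threshold = 0.5, alpha = 0.05) {
  out <- tibble::as_tibble(annual) |>
    dplyr::group_by(.data$row, .data$col) |>
    dplyr::summarise(slope = theil_sen(.data$value, .data$year),
                     mk = list(mann_kendall(.data$value)), .groups = "drop") |>
    dplyr::mutate(S = purrr::map_dbl(.data$mk, "S"),
                  Z = purrr::map_dbl(.data$mk, "Z"),
                  p = purrr::map_dbl(.data$mk, "p")) |>
    dplyr::select(-"mk")
  out$category <- classify_trend(out$slope, out$p, slope_threshold, alpha)
  class(out) <- c("agb_trend", class(out))
  out
}

#' Per-pixel stability analysis of an annual stack
#'
#' Coefficient of variation and its five-level classification for every
#' pixel.
#'
#' @param annual Tibble `(year, row, col, value)`.
#' @param breaks Passed to [classify_cv()].
#' @return Tibble of class `agb_stability`: `(row, col, cv, level)`.
#' @export
stability_analysis <- function(annual, breaks = "quantile") {
  out <- tibble::as_tibble(annual) |>
    dplyr::group_by(.data$row, .data$col) |>
    dplyr::summarise(cv = coefficient_of_variation(.data$value), .groups = "drop")
  out$level <- classify_cv(out$cv, breaks)
  class(out) <- c("agb_stability", class(out))
  out
}
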