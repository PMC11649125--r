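#' Pearson correlation with its t test
#'
#' Standard Pearson r with the two-sided p-value of
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, non-degenerate.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_with_test <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) rlang::abort("correlation needs at least 3 paired points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::abort("degenerate series: zero variance")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Four-way correlation category
#'
#' `SN` (r < 0, p < alpha), `NSN` (r < 0, p >= alpha), `NSP` (r > 0,
#' p >= alpha), `SP` (r > 0, p < alpha). An exact zero r, unassigned by the
#' strict inequalities, is placed in `NSP`.
#'
#' @param r Correlation coefficient(s).
#' @param p P-value(s).
#' @param alpha Significance level (default 0.05).
#' @return Factor with levels `SN`, `NSN`, `NSP`, `SP`.
#' @export
categorize_correlation <- function(r, p, alpha = 0.05) {
  out <- ifelse(r < 0, ifelse(p < alpha, "SN", "NSN"),
                ifelse(r > 0 & p < alpha, "SP", "NSP"))
  factor(out, levels = c("SN", "NSN", "NSP", "SP"))
}

#' Per-pixel correlation map between AGB and a driver
#'
#' Correlates the annual AGB and driver series of every pixel and attaches
#' the four-way category. Pixels with a degenerate series are returned with
#' `NA`.
#'
#' @param agb_annual,driver_annual Tibbles `(year, row, col, value)` on the
#'   same pixels and years.
#' @param alpha Significance level.
#' @return Tibble `(row, col, r, p, category)`.
#' @export
correlation_map <- function(agb_annual, driver_annual, alpha = 0.05) {
  j <- dplyr::inner_join(
    stats::setNames(tibble::as_tibble(agb_annual)[, c("year", "row", "col", "value")],
                    c("year", "row", "col", "agb")),
    stats::setNames(tibble::as_tibble(driver_annual)[, c("year", "row", "col", "value")],
                    c("year", "row", "col", "driver")),
    by = c("year", "row", "col"))
  out <- j |>
    dplyr::group_by(.data$row, .data$col) |>
    dplyr::summarise(res = list(tryCatch(pearson_with_test(.data$driver, .data$agb),
                                         error = function(e) list(r = NA_real_,
                                                                  p = NA_real_))),
                     .groups = "drop") |>
    dplyr::mutate(r = purrr::map_dbl(.data$res, "r"),
                  p = purrr::map_dbl(.data$res, "p")) |>
    dplyr::select(-"res")
  out$category <- categorize_correlation(out$r, out$p, alpha)
  out
}

#' Type-wise correlation between AGB and a driver
#'
#' For each grassland type, the type's pixels are spatially averaged into
#' one AGB and one driver series, which are then correlated through time
#' (the `"spatial_mean"` unit). Alternatively all pixel-years of the type
#' are pooled (`"pooled"`). A seasonal variant first aggregates monthly
#' stacks to the requested season via [aggregate_period()].
#'
#' @param agb,driver Annual tibbles `(year, row, col, value)`, or monthly
#'   grid stacks when `season` is given.
#' @param type_map Type map.
#' @param season Optional `"spring"`, `"summer"`, `"autumn"`, `"winter"`;
#'   requires monthly inputs.
#' @param unit `"spatial_mean"` (default) or `"pooled"`.
#' @param reducer Seasonal reducer for the inputs (`"mean"` for drivers,
#'   `"sum"` for fluxes), used only with `season`.
#' @return Tibble `(type, r, p, n)`; types with too few pixels or years are
#'   skipped with a warning.
#' @export
per_type_correlation <- function(agb, driver, type_map, season = NULL,
                                 unit = c("spatial_mean", "pooled"),
                                 reducer = "mean") {
  unit <- match.arg(unit)
  if (!is.null(season)) {
    agb <- aggregate_period(agb, season, reducer)
    driver <- aggregate_period(driver, season, reducer)
  }
  j <- dplyr::inner_join(
    stats::setNames(tibble::as_tibble(agb)[, c("year", "row", "col", "value")],
                    c("year", "row", "col", "agb")),
    stats::setNames(tibble::as_tibble(driver)[, c("year", "row", "col", "value")],
                    c("year", "row", "col", "driver")),
    by = c("year", "row", "col")) |>
    dplyr::inner_join(type_map, by = c("row", "col"))
  rows <- lapply(split(j, droplevels(j$type)), function(g) {
    res <- tryCatch({
      if (unit == "spatial_mean") {
        s <- g |>
          dplyr::group_by(.data$year) |>
          dplyr::summarise(agb = mean(.data$agb), driver = mean(.data$driver))
        pearson_with_test(s$driver, s$agb)
      } else {
        pearson_with_test(g$driver, g$agb)
      }
    }, error = function(e) {
      rlang::warn(sprintf("type '%s' skipped: %s", g$type[1], conditionMessage(e)))
      NULL
    })
    if (is.null(res)) return(NULL)
    tibble::tibble(type = as.character(g$type[1]), r = res$r, p = res$p, n = res$n)
  })
  dplyr::bind_rows(rows)
}

#' Random-forest relative importance of the seven drivers
#'
#' Fits a random-forest regression of AGB on the drivers (via `ranger`, the
#' reference implementation) and reports permutation importance on
#' out-of-bag samples, with negative raw importances floored at 0 and the
#' rest normalised to percentage shares. Deterministic for a given seed
#' (single-threaded).
#'
#' @param table Data frame with the response column and one column per
#'   driver; rows are pixels (temporal means) or pixel-years. Rows with
#'   missing cells are dropped and counted.
#' @param response Name of the response column (default `"agb"`).
#' @param drivers Driver column names (default the seven standard drivers).
#' @param n_trees Number of trees (default 1000).
#' @param seed Integer seed.
#' @param min_rows Minimum usable rows (default 50).
#' @return Object of class `rf_importance`: importance shares (%), raw
#'   importances, `n_trees`, `seed`, row counts and OOB R-squared.
#' @export
rf_importance <- function(table, response = "agb",
                          drivers = c("T", "PPT", "VPD", "SR", "RH", "SM", "GI"),
                          n_trees = 1000, seed = 1L, min_rows = 50) {
  cols <- c(response, drivers)
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("table is missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  df <- as.data.frame(table)[, cols]
  complete <- stats::complete.cases(df)
  n_dropped <- sum(!complete)
  df <- df[complete, , drop = FALSE]
  if (nrow(df) < min_rows) {
    rlang::abort(sprintf("only %d usable rows (< %d)", nrow(df), min_rows))
  }
  fit <- ranger::ranger(
    dependent.variable.name = response, data = df,
    num.trees = n_trees, importance = "permutation",
    seed = as.integer(seed), num.threads = 1
  )
  raw <- fit$variable.importance[drivers]
  floored <- pmax(0, raw)
  share <- if (sum(floored) > 0) 100 * floored / sum(floored)
           else stats::setNames(rep(100 / length(drivers), length(drivers)), drivers)
  structure(list(importance = tibble::tibble(driver = drivers,
                                             share = unname(share),
                                             raw = unname(raw)),
                 n_trees = n_trees, seed = as.integer(seed),
                 n_rows = nrow(df), n_dropped = n_dropped,
                 oob_r_squared = fit$r.squared),
            class = "rf_importance")
}

#' @export
print.rf_importance <- function(x, ...) {
  cat(sprintf("Random-forest driver importance (%d trees, %d rows, OOB R2 = %.3f)\n",
              x$n_trees, x$n_rows, x$oob_r_squared))
  imp <- dplyr::arrange(x$importance, dplyr::desc(.data$share))
  for (i in seq_len(nrow(imp))) {
    cat(sprintf("  %-4s %6.2f %%\n", imp$driver[i], imp$share[i]))
  }
  invisible(x)
}

#' Tidy a random-forest importance fit
#' @param x An `rf_importance` object.
#' @param ... Unused.
#' @return Tibble `(driver, share, raw)` sorted by share.
#' @export
tidy.rf_importance <- function(x, ...) {
  dplyr::arrange(x$importance, dplyr::desc(.data$share))
}

#' One-row summary of a random-forest importance fit
#' @param x An `rf_importance` object.
#' @param ... Unused.
#' @return One-row tibble with fit metadata.
#' @export
glance.rf_importance <- function(x, ...) {
  tibble::tibble(n_rows = x$n_rows, n_dropped = x$n_dropped,
                 n_trees = x$n_trees, seed = x$seed,
                 oob_r_squared = x$oob_r_squared,
                 top_driver = x$importance$driver[which.max(x$importance$share)])
}

#' Build the driver design table from a scenario's truth panel
#'
#' Collapses the pixel-year driver panel to the requested sampling unit:
#' one row per pixel (temporal means over the study period, the default) or
#' one row per pixel-year.
#'
#' @param driver_table Tibble with `year`, `row`, `col`, the seven driver
#'   columns and `agb` (e.g. `truth$driver_table` from
#'   [generate_scenario()]).
#' @param unit `"pixel"` or `"pixel_year"`.
#' @return Tibble ready for [rf_importance()].
#' @export
build_driver_table <- function(driver_table, unit = c("pixel", "pixel_year")) {
  unit <- match.arg(unit)
  if (unit == "pixel_year") return(tibble::as_tibble(driver_table))
  tibble::as_tibble(driver_table) |>
    dplyr::group_by(.data$row, .data$col) |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric) & !dplyr::any_of("year"),
                                   mean), .groups = "drop")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
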