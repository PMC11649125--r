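#' Build a gridded time-series stack
#'
#' A grid stack is the package's universal currency: one variable observed on
#' a regular raster through time, stored as a long tibble with columns `date`
#' (class `Date`, strictly increasing time axis), `row`, `col` (1-based pixel
#' indices) and `value` (the observation; `NA` marks a missing/masked cell).
#' Units and the affine georeference travel as attributes `units` and `geom`.
#'
#' @param df Data frame with columns `date`, `row`, `col`, `value`.
#' @param units Non-empty unit string (e.g. `"g C/m2/month"`).
#' @param geom Grid georeference from [grid_geom()]; defaults to a 0.05-degree
#'   WGS84 lattice anchored at 40N, 100E.
#' @return A tibble of class `grid_stack`.
#' @export
#' @examples
#' df <- expand.grid(row = 1:2, col = 1:2)
#' df$date <- as.Date("2000-01-01")
#' df$value <- runif(4)
#' grid_stack(df, units = "unitless")
grid_stack <- function(df, units, geom = grid_geom()) {
  needed <- c("date", "row", "col", "value")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("grid stack is missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (!is.character(units) || length(units) != 1L || !nzchar(units)) {
    rlang::abort("`units` must be a non-empty string")
  }
  df <- tibble::as_tibble(df)[, needed]
  df$date <- as.Date(df$date)
  ax <- sort(unique(df$date))
  if (vctrs::vec_duplicate_any(df[, c("date", "row", "col")])) {
    rlang::abort("grid stack has duplicated (date, row, col) cells")
  }
  attr(df, "units") <- units
  attr(df, "geom") <- geom
  class(df) <- c("grid_stack", class(df))
  df
}

#' Affine georeference of the working grid
#'
#' Pixel-centre registration on a geographic lattice: pixel (1, 1) has its
#' centre at `lat_origin - res/2`, `lon_origin + res/2`; rows run north to
#' south, columns west to east.
#'
#' @param nrow,ncol Grid dimensions in pixels.
#' @param res Pixel size in degrees (default 0.05, the working resolution).
#' @param lat_origin,lon_origin North-west corner of the grid, degrees.
#' @return A list of class `grid_geom`.
#' @export
grid_geom <- function(nrow = NULL, ncol = NULL, res = 0.05,
                      lat_origin = 40, lon_origin = 100) {
  structure(list(nrow = nrow, ncol = ncol, res = res,
                 lat_origin = lat_origin, lon_origin = lon_origin),
            class = "grid_geom")
}

#' @export
format.grid_geom <- function(x, ...) {
  sprintf("<grid_geom %sx%s @ %g deg, NW corner (%g, %g)>",
          x$nrow %||% "?", x$ncol %||% "?", x$res, x$lat_origin, x$lon_origin)
}

#' @export
print.grid_geom <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Pixel-centre latitude for grid rows
#'
#' @param row Integer row index (1 = northernmost).
#' @param geom A [grid_geom()].
#' @return Latitude in degrees.
#' @export
pixel_lat <- function(row, geom = grid_geom()) {
  geom$lat_origin - (row - 0.5) * geom$res
}

#' Pixel-centre longitude for grid columns
#' @param col Integer column index (1 = westernmost).
#' @param geom A [grid_geom()].
#' @return Longitude in degrees.
#' @export
pixel_lon <- function(col, geom = grid_geom()) {
  geom$lon_origin + (col - 0.5) * geom$res
}

stack_units <- function(x) attr(x, "units") %||% "unknown"

stack_geom <- function(x) attr(x, "geom") %||% grid_geom()

#' Check that two stacks share a time axis and pixel set
#' @noRd
check_aligned <- function(a, b, what = c("a", "b")) {
  key <- function(x) {
    x <- tibble::as_tibble(x)
    x <- dplyr::arrange(x[, c("date", "row", "col")], date, row, col)
    data.frame(date = as.Date(x$date), row = as.numeric(x$row),
               col = as.numeric(x$col))
  }
  if (!identical(key(a), key(b))) {
    rlang::abort(sprintf("stacks `%s` and `%s` are not aligned (different time axis or pixel set)",
                         what[1], what[2]), class = "grassagb_alignment_error")
  }
  invisible(TRUE)
}

#' Join two aligned stacks into one tibble with value columns `a` and `b`
#' @noRd
join_stacks <- function(a, b, what = c("a", "b")) {
  check_aligned(a, b, what)
  out <- dplyr::inner_join(
    dplyr::rename(tibble::as_tibble(a)[, c("date", "row", "col", "value")], a = "value"),
    dplyr::rename(tibble::as_tibble(b)[, c("date", "row", "col", "value")], b = "value"),
    by = c("date", "row", "col")
  )
  out
}

# grouped reduction on long tables; rowsum-based so large stacks stay fast.
# NA semantics: sum/mean propagate NA; max drops NA and yields NA only for
# all-missing groups
fast_agg <- function(keys, x, op = c("sum", "mean", "max")) {
  op <- match.arg(op)
  g <- vctrs::vec_group_id(keys)
  out <- keys[!duplicated(g), , drop = FALSE]   # first-appearance = id order
  if (op %in% c("sum", "mean")) {
    s <- rowsum(x, g, reorder = TRUE)[, 1]
    if (op == "mean") s <- s / tabulate(g)
    out$value <- unname(s)
  } else {
    loc <- vctrs::vec_group_loc(keys)$loc
    out$value <- vapply(loc, function(i) {
      v <- x[i]
      v <- v[!is.na(v)]
      if (length(v) == 0) NA_real_ else max(v)
    }, numeric(1))
  }
  tibble::as_tibble(out)
}

season_of <- function(month) {
  dplyr::case_when(
    month %in% 3:5 ~ "spring",
    month %in% 6:8 ~ "summer",
    month %in% 9:11 ~ "autumn",
    TRUE ~ "winter"
  )
}

#' Aggregate a monthly stack to annual or seasonal values
#'
#' Seasons follow the meteorological convention: spring March-May, summer
#' June-August, autumn September-November, winter December-February, with
#' winter assigned to the year of its January/February (December of year
#' y - 1 opens the winter of year y). Annual aggregation is the calendar-year
#' reduction; `sum` is appropriate for fluxes such as NPP, `mean` for state
#' drivers.
#'
#' Incomplete periods at the record boundaries (e.g. the first winter of a
#' January-start record, which lacks its December) are dropped. A month
#' missing from the interior of the record is an error listing the missing
#' months.
#'
#' @param stack Monthly grid stack.
#' @param period One of `"annual"`, `"spring"`, `"summer"`, `"autumn"`,
#'   `"winter"`.
#' @param reducer `"sum"` or `"mean"`.
#' @return Tibble with columns `year`, `row`, `col`, `value`.
#' @export
aggregate_period <- function(stack,
                             period = c("annual", "spring", "summer", "autumn", "winter"),
                             reducer = c("sum", "mean")) {
  period <- match.arg(period)
  reducer <- match.arg(reducer)
  df <- tibble::as_tibble(stack)
  df$month <- lubridate::month(df$date)
  df$year <- lubridate::year(df$date)
  if (period == "annual") {
    need <- 1:12
    df$agg_year <- df$year
  } else if (period == "winter") {
    df <- df[df$month %in% c(12, 1, 2), , drop = FALSE]
    need <- c(12, 1, 2)
    df$agg_year <- df$year + (df$month == 12)
  } else {
    mm <- switch(period, spring = 3:5, summer = 6:8, autumn = 9:11)
    df <- df[df$month %in% mm, , drop = FALSE]
    need <- mm
    df$agg_year <- df$year
  }
  if (nrow(df) == 0) rlang::abort("no observations fall in the requested period")

  # completeness on the time axis, not per pixel
  ax <- dplyr::distinct(df, .data$agg_year, .data$month)
  have <- split(ax$month, ax$agg_year)
  complete <- vapply(have, function(m) all(need %in% m), logical(1))
  yrs <- as.integer(names(have))
  boundary <- yrs %in% c(min(yrs), max(yrs))
  if (any(!complete & !boundary)) {
    bad <- yrs[!complete & !boundary]
    miss <- unlist(lapply(bad, function(y) {
      sprintf("%d-%02d", y, setdiff(need, have[[as.character(y)]]))
    }))
    rlang::abort(paste0("missing months in interior periods: ",
                        paste(miss, collapse = ", ")))
  }
  keep <- yrs[complete]
  df <- df[df$agg_year %in% keep, , drop = FALSE]
  keys <- tibble::tibble(year = df$agg_year, row = df$row, col = df$col)
  out <- fast_agg(keys, df$value, reducer)
  dplyr::arrange(out, .data$year, .data$row, .data$col)
}

#' Write / read a grid stack as long CSV
#'
#' Plain-text interchange: columns `date,row,col,value` plus a `# units:`
#' header comment.
#'
#' @param stack Grid stack.
#' @param path File path.
#' @return `read_stack_csv()` returns a grid stack; `write_stack_csv()` the
#'   path, invisibly.
#' @export
write_stack_csv <- function(stack, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# units: %s", stack_units(stack)), con)
  utils::write.csv(tibble::as_tibble(stack)[, c("date", "row", "col", "value")],
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stack_csv
#' @export
read_stack_csv <- function(path) {
  first <- readLines(path, n = 1L)
  units <- if (startsWith(first, "# units:")) trimws(sub("^# units:", "", first)) else "unknown"
  df <- utils::read.csv(path, comment.char = "#")
  df$date <- as.Date(df$date)
  grid_stack(df, units = units)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
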