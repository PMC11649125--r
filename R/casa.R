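#' Light-use-efficiency model constants per grassland type
#'
#' The productivity model needs, per grassland class: the maximum light-use
#' efficiency `eps_max` (g C/MJ) and the NDVI/FPAR ramp anchors. Published
#' regional configurations vary; the packaged defaults (grassland
#' `eps_max = 0.542` g C/MJ, NDVI ramp 0.05-0.75 onto FPAR 0.001-0.95) are
#' documented assumptions from the classic CASA grassland literature and are
#' fully overridable.
#'
#' @param eps_max,ndvi_min,ndvi_max,fpar_min,fpar_max Scalar defaults applied
#'   to every class; pass a data frame to `params` arguments downstream for
#'   per-class values.
#' @return Tibble with one row per grassland class.
#' @export
casa_params <- function(eps_max = 0.542, ndvi_min = 0.05, ndvi_max = 0.75,
                        fpar_min = 0.001, fpar_max = 0.95) {
  stopifnot(ndvi_min < ndvi_max, fpar_min >= 0, fpar_min < fpar_max,
            fpar_max <= 0.95, eps_max > 0)
  tibble::tibble(type = grassland_types(), eps_max = eps_max,
                 ndvi_min = ndvi_min, ndvi_max = ndvi_max,
                 fpar_min = fpar_min, fpar_max = fpar_max)
}

join_type_params <- function(df, type_map, params, cols) {
  df <- dplyr::left_join(df, type_map, by = c("row", "col"))
  missing_type <- unique(df$row[is.na(df$type)])
  if (anyNA(df$type)) {
    rlang::abort("pixels without a grassland type in `type_map`")
  }
  present <- unique(as.character(df$type))
  absent <- setdiff(present, params$type)
  if (length(absent) > 0) {
    rlang::abort(paste0("no parameters for grassland type(s): ",
                        paste(absent, collapse = ", ")))
  }
  dplyr::left_join(df, params[, c("type", cols)], by = "type")
}

#' FPAR from NDVI by the linear ramp
#'
#' `FPAR = fpar_min + (NDVI - ndvi_min) / (ndvi_max - ndvi_min) *
#' (fpar_max - fpar_min)`, clipped to `[fpar_min, fpar_max]`.
#'
#' @param ndvi NDVI values in `[-0.2, 1]`.
#' @param ndvi_min,ndvi_max,fpar_min,fpar_max Ramp anchors.
#' @return FPAR values (unitless).
#' @export
fpar_ramp <- function(ndvi, ndvi_min = 0.05, ndvi_max = 0.75,
                      fpar_min = 0.001, fpar_max = 0.95) {
  f <- fpar_min + (ndvi - ndvi_min) / (ndvi_max - ndvi_min) * (fpar_max - fpar_min)
  pmin(fpar_max, pmax(fpar_min, f))
}

#' Per-pixel FPAR stack from an NDVI stack
#'
#' @param ndvi Monthly NDVI grid stack.
#' @param type_map Type map from [make_type_map()].
#' @param params [casa_params()] table.
#' @return FPAR grid stack (unitless).
#' @export
compute_fpar <- function(ndvi, type_map, params = casa_params()) {
  df <- tibble::as_tibble(ndvi)
  if (any(df$value < -0.2 | df$value > 1, na.rm = TRUE)) {
    rlang::abort("NDVI outside [-0.2, 1]", class = "grassagb_validation_error")
  }
  df <- join_type_params(df, type_map, params,
                         c("ndvi_min", "ndvi_max", "fpar_min", "fpar_max"))
  df$value <- fpar_ramp(df$value, df$ndvi_min, df$ndvi_max, df$fpar_min, df$fpar_max)
  grid_stack(df[, c("date", "row", "col", "value")], units = "unitless",
             geom = stack_geom(ndvi))
}

#' Absorbed photosynthetically active radiation
#'
#' `APAR = SOL x FPAR x 0.5`; the factor 0.5 is the photosynthetically
#' active fraction of total shortwave radiation.
#'
#' @param solar_radiation Total solar radiation stack, MJ/m2/month, >= 0.
#' @param fpar FPAR stack (unitless).
#' @param par_fraction PAR fraction of total radiation (default 0.5).
#' @return APAR grid stack, MJ/m2/month.
#' @export
compute_apar <- function(solar_radiation, fpar, par_fraction = 0.5) {
  if (any(tibble::as_tibble(solar_radiation)$value < 0, na.rm = TRUE)) {
    rlang::abort("negative solar radiation", class = "grassagb_validation_error")
  }
  j <- join_stacks(solar_radiation, fpar, c("solar_radiation", "fpar"))
  j$value <- j$a * j$b * par_fraction
  grid_stack(j[, c("date", "row", "col", "value")], units = "MJ/m2/month",
             geom = stack_geom(solar_radiation))
}

#' Temperature stress factors of the light-use-efficiency model
#'
#' `t_stress1` expresses the fixed penalty of a pixel's thermal optimum:
#' `0.8 + 0.02 * Topt - 0.0005 * Topt^2`, floored at 0, and set to 0 in
#' months with mean temperature at or below -10 degC. `t_stress2` penalises
#' departure of the month's temperature from the optimum:
#' `1.1814 / ((1 + exp(0.2 * (Topt - 10 - T))) * (1 + exp(0.3 * (-Topt - 10 + T))))`.
#'
#' @param topt Optimum temperature(s), degC.
#' @param temp Monthly mean temperature(s), degC.
#' @return Numeric stress values.
#' @export
t_stress1 <- function(topt, temp) {
  e1 <- pmax(0, 0.8 + 0.02 * topt - 0.0005 * topt^2)
  ifelse(temp <= -10, 0, e1)
}

#' @rdname t_stress1
#' @export
t_stress2 <- function(topt, temp) {
  1.1814 / ((1 + exp(0.2 * (topt - 10 - temp))) * (1 + exp(0.3 * (-topt - 10 + temp))))
}

#' Temperature stress stacks
#'
#' @param temperature Monthly temperature stack, degC.
#' @param topt Per-pixel optimum temperature: tibble `(row, col, topt)` from
#'   [estimate_topt()], or a single number applied everywhere.
#' @return List of grid stacks `te1` and `te2`.
#' @export
temperature_stress <- function(temperature, topt) {
  df <- tibble::as_tibble(temperature)
  if (is.numeric(topt) && length(topt) == 1L) {
    df$topt <- topt
  } else {
    df <- dplyr::left_join(df, topt, by = c("row", "col"))
    if (anyNA(df$topt)) rlang::abort("missing `topt` for some pixels")
  }
  g <- stack_geom(temperature)
  mk <- function(v) grid_stack(tibble::tibble(date = df$date, row = df$row,
                                              col = df$col, value = v),
                               units = "unitless", geom = g)
  list(te1 = mk(t_stress1(df$topt, df$value)),
       te2 = mk(t_stress2(df$topt, df$value)))
}

#' Per-pixel optimum temperature from the month of peak NDVI
#'
#' The thermal optimum of each pixel is taken as its mean temperature in the
#' calendar month where the NDVI climatology peaks.
#'
#' @param temperature Monthly temperature stack, degC.
#' @param ndvi Monthly NDVI stack.
#' @return Tibble `(row, col, topt)`.
#' @export
estimate_topt <- function(temperature, ndvi) {
  nd <- tibble::as_tibble(ndvi)
  nd$month <- lubridate::month(nd$date)
  peak <- nd |>
    dplyr::group_by(.data$row, .data$col, .data$month) |>
    dplyr::summarise(ndvi = mean(.data$value, na.rm = TRUE), .groups = "drop_last") |>
    dplyr::slice_max(.data$ndvi, n = 1, with_ties = FALSE) |>
    dplyr::select("row", "col", peak_month = "month")
  tt <- tibble::as_tibble(temperature)
  tt$month <- lubridate::month(tt$date)
  dplyr::inner_join(tt, peak, by = c("row", "col")) |>
    dplyr::filter(.data$month == .data$peak_month) |>
    dplyr::group_by(.data$row, .data$col) |>
    dplyr::summarise(topt = mean(.data$value, na.rm = TRUE), .groups = "drop")
}

#' Water stress factor
#'
#' Default mode scales the estimated ratio of actual to potential
#' evapotranspiration into `[0.5, 1]`: `W = 0.5 + 0.5 * E/Ep`, with
#' `E = min(PPT, PET)` and `Ep = PET`. The alternative mode uses relative
#' soil moisture: `W = 0.5 + 0.5 * SM/SM_fc` (clipped), for records where
#' soil moisture is the better-observed water term.
#'
#' @param precipitation Monthly precipitation stack, mm.
#' @param pet Monthly potential evapotranspiration stack, mm, > 0; see
#'   [hamon_pet()].
#' @param sm Optional volumetric soil-moisture stack (activates the
#'   soil-moisture mode).
#' @param sm_fc Field capacity for the soil-moisture mode, m3/m3.
#' @return Water-stress grid stack in `[0.5, 1]`.
#' @export
water_stress <- function(precipitation = NULL, pet = NULL, sm = NULL, sm_fc = 0.35) {
  if (!is.null(sm)) {
    df <- tibble::as_tibble(sm)
    df$value <- 0.5 + 0.5 * pmin(1, pmax(0, df$value / sm_fc))
    return(grid_stack(df[, c("date", "row", "col", "value")], units = "unitless",
                      geom = stack_geom(sm)))
  }
  if (is.null(precipitation) || is.null(pet)) {
    rlang::abort("supply either `precipitation` + `pet` or `sm`",
                 class = "grassagb_config_error")
  }
  j <- join_stacks(precipitation, pet, c("precipitation", "pet"))
  if (any(j$b <= 0, na.rm = TRUE)) rlang::abort("PET must be positive")
  j$value <- 0.5 + 0.5 * pmin(j$a, j$b) / j$b
  grid_stack(j[, c("date", "row", "col", "value")], units = "unitless",
             geom = stack_geom(precipitation))
}

#' Hamon potential evapotranspiration
#'
#' `PET (mm/day) = 29.8 * D * es(T) / (T + 273.2)` with day length `D` in
#' hours (from pixel latitude and the mid-month day of year) and Tetens
#' `es` in kPa, scaled by the number of days in the month. Needs only inputs
#' the pipeline already carries.
#'
#' @param temperature Monthly temperature stack, degC.
#' @param geom Grid georeference for pixel latitudes (defaults to the
#'   stack's own).
#' @return Monthly PET grid stack, mm/month (floored at 0.1 mm so the water
#'   stress ratio stays defined in polar-night months).
#' @export
hamon_pet <- function(temperature, geom = NULL) {
  geom <- geom %||% stack_geom(temperature)
  df <- tibble::as_tibble(temperature)
  mid <- lubridate::`day<-`(df$date, 15L)
  doy <- as.integer(strftime(mid, "%j"))
  dl <- geosphere::daylength(pixel_lat(df$row, geom), doy)
  ndays <- lubridate::days_in_month(df$date)
  pet <- 29.8 * dl * tetens_es(df$value) / (df$value + 273.2) * as.numeric(ndays)
  df$value <- pmax(0.1, pet)
  grid_stack(df[, c("date", "row", "col", "value")], units = "mm/month",
             geom = geom)
}

#' Monthly NPP from APAR and the stress-scaled light-use efficiency
#'
#' `LUE = te1 * te2 * w * eps_max` and `NPP = APAR * LUE`, per pixel and
#' month; `eps_max` comes from the per-type parameter table.
#'
#' @param apar APAR stack, MJ/m2/month.
#' @param te1,te2 Temperature stress stacks from [temperature_stress()].
#' @param w Water stress stack from [water_stress()].
#' @param type_map Type map.
#' @param params [casa_params()] table.
#' @return List of class `npp_field`: stacks `npp` (g C/m2/month), `apar`,
#'   `lue`, `te1`, `te2`, `w`.
#' @export
compute_npp <- function(apar, te1, te2, w, type_map, params = casa_params()) {
  check_aligned(apar, te1, c("apar", "te1"))
  check_aligned(apar, te2, c("apar", "te2"))
  check_aligned(apar, w, c("apar", "w"))
  grab <- function(s, nm) stats::setNames(
    tibble::as_tibble(s)[, c("date", "row", "col", "value")],
    c("date", "row", "col", nm))
  j <- grab(apar, "apar") |>
    dplyr::inner_join(grab(te1, "te1"), by = c("date", "row", "col")) |>
    dplyr::inner_join(grab(te2, "te2"), by = c("date", "row", "col")) |>
    dplyr::inner_join(grab(w, "w"), by = c("date", "row", "col"))
  j <- join_type_params(j, type_map, params, "eps_max")
  j$lue <- j$te1 * j$te2 * j$w * j$eps_max
  j$npp <- pmax(0, j$apar * j$lue)
  g <- stack_geom(apar)
  mk <- function(v, units) grid_stack(tibble::tibble(date = j$date, row = j$row,
                                                     col = j$col, value = v),
                                      units = units, geom = g)
  structure(list(npp = mk(j$npp, "g C/m2/month"),
                 apar = mk(j$apar, "MJ/m2/month"),
                 lue = mk(j$lue, "g C/MJ"),
                 te1 = mk(j$te1, "unitless"), te2 = mk(j$te2, "unitless"),
                 w = mk(j$w, "unitless")),
            class = "npp_field")
}

#' Run the full light-use-efficiency NPP chain
#'
#' Convenience orchestrator: FPAR from NDVI, APAR from solar radiation,
#' per-pixel thermal optimum from the NDVI-peak month, Hamon PET, water
#' stress from precipitation/PET (or soil moisture when supplied), and the
#' final NPP product.
#'
#' @param ndvi,temperature,solar_radiation,precipitation Monthly input
#'   stacks.
#' @param type_map Type map.
#' @param params [casa_params()] table.
#' @param topt Optional fixed thermal optimum (degC) or `(row, col, topt)`
#'   tibble; default estimates it from the NDVI-peak month.
#' @param sm Optional soil-moisture stack for the alternative water-stress
#'   mode.
#' @param par_fraction PAR fraction of solar radiation.
#' @return An `npp_field` (see [compute_npp()]) with `fpar` added.
#' @export
casa_npp <- function(ndvi, temperature, solar_radiation, precipitation,
                     type_map, params = casa_params(), topt = NULL, sm = NULL,
                     par_fraction = 0.5) {
  fpar <- compute_fpar(ndvi, type_map, params)
  apar <- compute_apar(solar_radiation, fpar, par_fraction)
  if (is.null(topt)) topt <- estimate_topt(temperature, ndvi)
  ts <- temperature_stress(temperature, topt)
  w <- if (!is.null(sm)) water_stress(sm = sm)
       else water_stress(precipitation, hamon_pet(temperature))
  out <- compute_npp(apar, ts$te1, ts$te2, w, type_map, params)
  out$fpar <- fpar
  out
}
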