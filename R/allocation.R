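#' Root:shoot allocation and carbon-fraction parameters per grassland type
#'
#' Per class: the root-to-shoot biomass ratio `rs_ratio` and the carbon
#' fractions of aboveground (`c_a`) and belowground (`c_b`) biomass. Seven
#' classes carry published values; montane meadow and warm-temperate tussock
#' have no published row and borrow the nearest listed class (temperate
#' meadow and tropical tussock respectively), marked by `proxy`.
#'
#' @return Tibble with columns `type`, `rs_ratio`, `c_a`, `c_b`, `proxy`.
#' @export
allocation_params <- function() {
  tbl <- tibble::tribble(
    ~type,                        ~rs_ratio, ~c_a, ~c_b, ~proxy,
    "temperate meadow steppe",    5.3, 0.43, 0.37, NA_character_,
    "temperate typical steppe",   5.3, 0.43, 0.37, NA_character_,
    "temperate desert steppe",    6.7, 0.43, 0.37, NA_character_,
    "alpine steppe",              5.2, 0.43, 0.37, NA_character_,
    "tropical tussock",           1.6, 0.43, 0.37, NA_character_,
    "temperate meadow",           6.3, 0.43, 0.37, NA_character_,
    "alpine meadow",              6.8, 0.43, 0.37, NA_character_,
    "montane meadow",             6.3, 0.43, 0.37, "temperate meadow",
    "warm-temperate tussock",     1.6, 0.43, 0.37, "tropical tussock"
  )
  stopifnot(all(tbl$rs_ratio > 0), all(tbl$c_a > 0 & tbl$c_a < 1),
            all(tbl$c_b > 0 & tbl$c_b < 1))
  tbl[match(grassland_types(), tbl$type), ]
}

#' Convert NPP to aboveground biomass
#'
#' Two documented readings of the production-to-biomass conversion sit
#' behind a strategy switch:
#'
#' * `carbon_partition` (default): total production carbon splits between
#'   layers by the root:shoot biomass ratio with layer-specific carbon
#'   fractions, so `AGB = NPP / (Ca + (R/S) * Cb)` and `ANPP = Ca * AGB`.
#'   This is the only reading that closes the carbon budget exactly:
#'   `Ca * AGB + Cb * (R/S) * AGB = NPP`.
#' * `literal_eq2`: `ANPP = NPP / (1 + R/S)` and
#'   `AGB = ANPP / ((R/S) * (Ca + Cb))`.
#'
#' @param npp NPP grid stack, g C/m2.
#' @param type_map Type map.
#' @param params [allocation_params()] table.
#' @param strategy `"carbon_partition"` or `"literal_eq2"`.
#' @return List of class `agb_field`: stacks `agb` (g dry matter/m2), `anpp`
#'   (g C/m2), `agb_carbon` (g C/m2, `0.45 * agb`), and the `strategy`
#'   label.
#' @export
npp_to_agb <- function(npp, type_map, params = allocation_params(),
                       strategy = c("carbon_partition", "literal_eq2")) {
  strategy <- match.arg(strategy)
  df <- join_type_params(tibble::as_tibble(npp), type_map, params,
                         c("rs_ratio", "c_a", "c_b"))
  if (strategy == "carbon_partition") {
    agb <- df$value / (df$c_a + df$rs_ratio * df$c_b)
    anpp <- df$c_a * agb
  } else {
    anpp <- df$value / (1 + df$rs_ratio)
    agb <- anpp / (df$rs_ratio * (df$c_a + df$c_b))
  }
  g <- stack_geom(npp)
  mk <- function(v, units) grid_stack(tibble::tibble(date = df$date, row = df$row,
                                                     col = df$col, value = v),
                                      units = units, geom = g)
  structure(list(agb = mk(agb, "g/m2"), anpp = mk(anpp, "g C/m2"),
                 agb_carbon = mk(0.45 * agb, "g C/m2"), strategy = strategy),
            class = "agb_field")
}

#' Carbon density of aboveground biomass
#'
#' Dry mass converts to carbon with the conventional coefficient 0.45.
#'
#' @param agb AGB grid stack (g/m2) or numeric vector, >= 0.
#' @return Same shape, 0.45 times the input, in g C/m2.
#' @export
agb_to_carbon <- function(agb) {
  if (is.numeric(agb)) return(0.45 * agb)
  df <- tibble::as_tibble(agb)
  df$value <- 0.45 * df$value
  grid_stack(df[, c("date", "row", "col", "value")], units = "g C/m2",
             geom = stack_geom(agb))
}

#' Grazing intensity from the production / standing-crop balance
#'
#' `GI = (ANPP_t - AGB_t) / (P * T)`: the biomass produced but not found
#' standing, divided by one livestock unit's intake over the grazing period.
#' Negative differences (standing crop above production) have no livestock
#' interpretation and are floored at 0 with a flag.
#'
#' @param anpp_t Aboveground production over the period, g/m2 (grid stack or
#'   tibble with `value`).
#' @param agb_t Standing aboveground biomass, g/m2, aligned with `anpp_t`.
#' @param daily_intake_p Daily dry-matter intake per standard livestock
#'   unit, g/day (default 1800, a standard sheep unit).
#' @param grazing_days_t Number of grazing days (default 365).
#' @return Tibble with per-cell `gi` (livestock units/m2), `gi_per_ha`
#'   (`gi * 1e4`), and `negative` flag.
#' @export
compute_gi <- function(anpp_t, agb_t, daily_intake_p = 1800, grazing_days_t = 365) {
  if (!is.numeric(daily_intake_p) || !is.numeric(grazing_days_t) ||
      daily_intake_p <= 0 || grazing_days_t <= 0) {
    rlang::abort("`daily_intake_p` and `grazing_days_t` must be positive",
                 class = "grassagb_parameter_error")
  }
  a <- tibble::as_tibble(anpp_t); b <- tibble::as_tibble(agb_t)
  keys <- intersect(c("date", "year", "row", "col"), names(a))
  j <- dplyr::inner_join(stats::setNames(a[, c(keys, "value")], c(keys, "anpp")),
                         stats::setNames(b[, c(keys, "value")], c(keys, "agb")),
                         by = keys)
  if (nrow(j) != nrow(a)) {
    rlang::abort("`anpp_t` and `agb_t` are not aligned",
                 class = "grassagb_alignment_error")
  }
  raw <- (j$anpp - j$agb) / (daily_intake_p * grazing_days_t)
  j$negative <- !is.na(raw) & raw < 0
  j$gi <- pmax(0, raw)
  j$gi_per_ha <- j$gi * 1e4
  j[, c(keys, "gi", "gi_per_ha", "negative")]
}
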