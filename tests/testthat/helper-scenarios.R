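# one small scenario shared across test files (built once per run)
tiny_scen <- generate_scenario(
  synthetic_scenario(n_years = 4, grid_shape = c(6, 6), seed = 3)
)

# single-pixel monthly grid stack from a vector of values
series_stack <- function(values, start = "2000-01-01", units = "unitless",
                         row = 1, col = 1) {
  grid_stack(tibble::tibble(
    date = seq(as.Date(start), by = "month", length.out = length(values)),
    row = row, col = col, value = values
  ), units = units)
}

# multi-pixel stack from a (time x pixel) value matrix on a given date axis
panel_stack <- function(m, dates, units = "unitless") {
  px <- tidyr::expand_grid(t = seq_along(dates), p = seq_len(ncol(m)))
  grid_stack(tibble::tibble(date = dates[px$t], row = px$p, col = 1,
                            value = m[cbind(px$t, px$p)]), units = units)
}

# brute-force Theil-Sen oracle: explicit double loop over all pairs
theil_sen_oracle <- function(x, t = seq_along(x)) {
  sl <- c()
  n <- length(x)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sl <- c(sl, (x[j] - x[i]) / (t[j] - t[i]))
  }
  median(sl)
}

# brute-force Mann-Kendall S oracle
mk_s_oracle <- function(x) {
  s <- 0
  n <- length(x)
  for (i in 1:(n - 1)) for (j in (i + 1):n) s <- s + sign(x[j] - x[i])
  s
}

# all permutations of 1..n as a matrix (row per ordering)
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- combinat_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# least-squares polynomial fit oracle for the Savitzky-Golay filter:
# value at position `at` (relative to window centre) of the polynomial of
# degree `order` fitted to `window_vals` at positions -h..h
sg_oracle <- function(window_vals, order, at = 0) {
  h <- (length(window_vals) - 1) / 2
  t <- -h:h
  fit <- lm(window_vals ~ poly(t, order, raw = TRUE))
  unname(predict(fit, newdata = data.frame(t = at)))
}
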