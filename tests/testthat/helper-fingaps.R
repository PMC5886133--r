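# Shared fixtures and independent oracles, all built in code at test time.

# Small deterministic hand-built panel: 3 countries x 2000-2015 observed,
# 2016-2030 forecast covariates. Values are smooth and well inside every
# validity bound.
tiny_panel <- function(n_countries = 3L, year_end_forecast = 2030L) {
  ids <- c("AFG", "COD", "CMR")[seq_len(n_countries)]
  years <- 2000:year_end_forecast
  grid <- expand.grid(country_id = ids, year = years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  i <- match(grid$country_id, ids)
  t <- grid$year - 2000L
  gdp_pc <- c(600, 800, 1400)[i] * 1.02^t
  pop <- c(25e6, 70e6, 20e6)[i] * 1.01^t
  df <- data.frame(
    country_id = grid$country_id,
    year = grid$year,
    gdp = gdp_pc * pop,
    gdp_pc = gdp_pc,
    maternal_education = c(2, 3, 5)[i] + 0.1 * t,
    dah_pc = c(8, 6, 4)[i],
    ghe_s_pc = c(5, 7, 15)[i] * 1.01^t,
    population = pop,
    live_births = 0.04 * pop,
    u5mr = c(110, 100, 80)[i] * 0.98^t,
    income_group = c("low", "low", "lower-middle")[i],
    is_observed = grid$year <= 2015L,
    stringsAsFactors = FALSE
  )
  as_country_panel(df)
}

# Independent concave-envelope oracle for the single-input single-output
# output-oriented VRS program: enumerate every point and every pairwise
# convex combination meeting the input constraint. Deliberately brute force
# and solver-free.
envelope_oracle <- function(xr, yr, x0) {
  xe <- min(x0, max(xr))
  best <- max(yr[xr <= xe + 1e-12])
  n <- length(xr)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (xr[i] == xr[j]) next
      t <- (xe - xr[j]) / (xr[i] - xr[j])
      if (t >= -1e-12 && t <= 1 + 1e-12) {
        v <- t * yr[i] + (1 - t) * yr[j]
        if (v > best) best <- v
      }
    }
  }
  best
}

# Year-by-year "spreadsheet" oracle for lives to save.
lives_oracle <- function(expected, required, births) {
  vapply(seq_along(expected), function(k) {
    gap <- expected[k] - required[k]
    if (gap < 0) gap <- 0
    gap / 1000 * births[k]
  }, numeric(1))
}

default_config <- function(...) run_config(alpha = 0.05, beta = 0, ...)

# Hand-built share model with known coefficients, for arithmetic checks
# that should not depend on a fitted object.
fake_fraction_model <- function(coefs, link = "identity") {
  structure(list(coefficients = coefs, residual_sd = 0,
                 n_obs = NA_integer_, link = link, fit = NULL),
            class = "child_fraction_model")
}
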