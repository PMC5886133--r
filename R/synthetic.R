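#' Specification of a synthetic country panel
#'
#' Describes the generating process for a synthetic country-year panel whose
#' statistical structure matches what the pipeline assumes: under-five
#' mortality follows a log-linear model in the panel covariates with known
#' coefficients; government health spending per capita sits below a concave,
#' increasing power-law frontier of GDP per capita, scaled by a per-country
#' efficiency; the child-health share of government health spending is linear
#' in log spending and log income; and covariates evolve smoothly (geometric
#' GDP growth, linear education growth). Because every generating parameter
#' is recorded, each downstream estimator can be tested by recovery.
#'
#' The coefficient vector is ordered (intercept, ln GDP, ln GDP per capita,
#' maternal education in years, ln(1 + DAH per capita),
#' ln(1 + GHE-S per capita), year centred at the last observed year) — the
#' same transforms and centring [fit_mortality_model()] applies, so at zero
#' noise the fit recovers the truth exactly.
#'
#' @param n_countries number of countries (>= 3; the DEA frontier needs at
#'   least three reference points).
#' @param year_start first observed year.
#' @param year_end_observed last observed year (the base year).
#' @param year_end_forecast last forecast year.
#' @param true_mortality_coefficients named 7-vector on the log-mortality
#'   scale, in the order above.
#' @param mortality_noise_sd sd of log-scale mortality residuals.
#' @param frontier_params `c(a, b)` of the spending frontier
#'   `a * gdp_pc^b`, with `0 < b < 1` (concave, increasing).
#' @param efficiency_range interval in (0, 1] from which per-country
#'   spending efficiencies are drawn uniformly.
#' @param child_fraction_coefficients 3-vector (intercept, ln GHE-S pc,
#'   ln GDP pc) of the true child-health share.
#' @param fraction_noise_sd sd of the child-health share residuals.
#' @param gdp_growth `c(mean, sd)` of per-country annual log GDP-per-capita
#'   growth.
#' @param seed integer seed; identical specs generate identical panels.
#' @return a list with class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_countries = 50L,
                           year_start = 2000L,
                           year_end_observed = 2015L,
                           year_end_forecast = 2030L,
                           true_mortality_coefficients = c(
                             intercept = 9.9,
                             log_gdp = -0.05,
                             log_gdp_pc = -0.55,
                             maternal_education = -0.04,
                             log1p_dah_pc = -0.02,
                             log1p_ghe_s_pc = -0.05,
                             year_c = -0.02),
                           mortality_noise_sd = 0.05,
                           frontier_params = c(a = 0.015, b = 0.95),
                           efficiency_range = c(0.4, 1),
                           child_fraction_coefficients = c(
                             intercept = 0.30,
                             log_ghe_s_pc = 0.01,
                             log_gdp_pc = -0.03),
                           fraction_noise_sd = 0.01,
                           gdp_growth = c(mean = 0.03, sd = 0.01),
                           seed = 1L) {
  if (n_countries < 3L) {
    stop("synthetic spec error: n_countries must be >= 3 (DEA needs at ",
         "least three reference points)", call. = FALSE)
  }
  stopifnot(year_start < year_end_observed,
            year_end_observed < year_end_forecast)
  if (length(true_mortality_coefficients) != 7L) {
    stop("synthetic spec error: true_mortality_coefficients must have ",
         "length 7", call. = FALSE)
  }
  if (mortality_noise_sd < 0 || fraction_noise_sd < 0) {
    stop("synthetic spec error: noise sds must be >= 0", call. = FALSE)
  }
  if (frontier_params[[2]] <= 0 || frontier_params[[2]] >= 1 ||
      frontier_params[[1]] <= 0) {
    stop("synthetic spec error: frontier must be a * x^b with a > 0 and ",
         "0 < b < 1", call. = FALSE)
  }
  if (efficiency_range[1] <= 0 || efficiency_range[2] > 1 ||
      efficiency_range[1] > efficiency_range[2]) {
    stop("synthetic spec error: efficiency_range must lie within (0, 1]",
         call. = FALSE)
  }
  spec <- list(
    n_countries = as.integer(n_countries),
    year_start = as.integer(year_start),
    year_end_observed = as.integer(year_end_observed),
    year_end_forecast = as.integer(year_end_forecast),
    true_mortality_coefficients = true_mortality_coefficients,
    mortality_noise_sd = mortality_noise_sd,
    frontier_params = frontier_params,
    efficiency_range = efficiency_range,
    child_fraction_coefficients = child_fraction_coefficients,
    fraction_noise_sd = fraction_noise_sd,
    gdp_growth = gdp_growth,
    seed = as.integer(seed)
  )
  class(spec) <- "synthetic_spec"
  spec
}

# World Bank-style GDP-per-capita thresholds used to assign income groups at
# the base year (frozen thereafter).
income_group_of <- function(gdp_pc) {
  cut(gdp_pc, breaks = c(0, 1045, 4125, 12735, Inf),
      labels = INCOME_GROUPS, right = FALSE) |> as.character()
}

#' Generate a synthetic country panel with known truth
#'
#' Draws a panel according to a [synthetic_spec()]: per-country baseline GDP
#' per capita (log-normal), population, maternal education, a time-constant
#' DAH-per-capita level decreasing in income, and a spending efficiency;
#' then, per year, geometric GDP growth, frontier-scaled government health
#' spending, log-linear mortality with optional noise, and a child-health
#' spending share. Years after `year_end_observed` are flagged as forecast
#' rows (`is_observed = FALSE`); DAH per capita is constant over time, so
#' the generating mortality path holds donor spending fixed by construction.
#'
#' @param spec a [synthetic_spec()].
#' @return a list of class `synthetic_panel` with elements
#'   \describe{
#'     \item{panel}{a validated [as_country_panel()] panel covering
#'       `year_start` .. `year_end_forecast`;}
#'     \item{subaccounts}{child-health sub-account rows
#'       (country, year, child_fraction, ghe_s_pc, gdp_pc) for observed
#'       years;}
#'     \item{truth}{every generating parameter plus the per-country
#'       efficiencies, for recovery tests.}
#'   }
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)

  n <- spec$n_countries
  ids <- sprintf("C%03d", seq_len(n))
  years <- spec$year_start:spec$year_end_forecast
  base_year <- spec$year_end_observed

  gdp_pc0 <- exp(stats::rnorm(n, mean = 7.5, sd = 1.0))
  growth <- stats::rnorm(n, spec$gdp_growth[[1]], spec$gdp_growth[[2]])
  pop0 <- exp(stats::runif(n, log(1e6), log(8e7)))
  edu0 <- pmax(1, 2 + 1.3 * (log(gdp_pc0) - 6) + stats::rnorm(n, 0, 0.5))
  dah_pc <- pmax(0, 28 - 3 * log(gdp_pc0) + stats::rnorm(n, 0, 2))
  efficiency <- stats::runif(n, spec$efficiency_range[1],
                             spec$efficiency_range[2])

  a <- spec$frontier_params[[1]]
  b <- spec$frontier_params[[2]]
  cf <- spec$true_mortality_coefficients

  grid <- expand.grid(i = seq_len(n), year = years, KEEP.OUT.ATTRS = FALSE)
  i <- grid$i
  t_start <- grid$year - spec$year_start

  gdp_pc <- gdp_pc0[i] * exp(growth[i] * t_start)
  population <- pop0[i] * exp(0.01 * t_start)
  gdp <- gdp_pc * population
  education <- pmin(15, edu0[i] + 0.1 * t_start)
  ghe_s_pc <- a * gdp_pc^b * efficiency[i]
  cbr <- pmax(0.008, 0.10 - 0.009 * log(gdp_pc))
  live_births <- cbr * population

  lp <- cf[[1]] + cf[[2]] * log(gdp) + cf[[3]] * log(gdp_pc) +
    cf[[4]] * education + cf[[5]] * log1p(dah_pc[i]) +
    cf[[6]] * log1p(ghe_s_pc) + cf[[7]] * (grid$year - base_year)
  noise <- if (spec$mortality_noise_sd > 0) {
    stats::rnorm(nrow(grid), 0, spec$mortality_noise_sd)
  } else 0
  u5mr <- pmin(pmax(exp(lp + noise), 0.1), 999)

  group0 <- income_group_of(gdp_pc0 * exp(growth * (base_year - spec$year_start)))

  panel <- data.frame(
    country_id = ids[i],
    year = grid$year,
    gdp = gdp,
    gdp_pc = gdp_pc,
    maternal_education = education,
    dah_pc = dah_pc[i],
    ghe_s_pc = ghe_s_pc,
    population = population,
    live_births = live_births,
    u5mr = u5mr,
    income_group = group0[i],
    is_observed = grid$year <= base_year,
    stringsAsFactors = FALSE
  )
  panel <- as_country_panel(panel)

  obs <- panel[panel$is_observed, ]
  gf <- spec$child_fraction_coefficients
  frac_lp <- gf[[1]] + gf[[2]] * log(obs$ghe_s_pc) + gf[[3]] * log(obs$gdp_pc)
  frac_noise <- if (spec$fraction_noise_sd > 0) {
    stats::rnorm(nrow(obs), 0, spec$fraction_noise_sd)
  } else 0
  subaccounts <- data.frame(
    country_id = obs$country_id,
    year = obs$year,
    child_fraction = pmin(0.999, pmax(0.001, frac_lp + frac_noise)),
    ghe_s_pc = obs$ghe_s_pc,
    gdp_pc = obs$gdp_pc,
    stringsAsFactors = FALSE
  )

  truth <- list(
    mortality_coefficients = cf,
    mortality_noise_sd = spec$mortality_noise_sd,
    fraction_coefficients = gf,
    frontier_params = spec$frontier_params,
    efficiency = stats::setNames(efficiency, ids),
    dah_pc = stats::setNames(dah_pc, ids),
    growth = stats::setNames(growth, ids),
    base_year = base_year,
    spec = spec
  )

  out <- list(panel = panel, subaccounts = subaccounts, truth = truth)
  class(out) <- "synthetic_panel"
  out
}

#' True spending frontier of a synthetic panel
#'
#' @param truth the `truth` element of [generate_panel()] output.
#' @param gdp_pc GDP per capita values at which to evaluate.
#' @return frontier GHE-S per capita, `a * gdp_pc^b`.
#' @export
true_frontier <- function(truth, gdp_pc) {
  truth$frontier_params[[1]] * gdp_pc^truth$frontier_params[[2]]
}

#' Generating-parameter report for recovery tests
#'
#' Flattens a truth record into two tables: one row per country (efficiency,
#' DAH level, GDP growth drift) and one row per generating coefficient.
#' Writing it next to a simulated panel gives recovery tests and external
#' consumers a plain-text oracle.
#'
#' @param truth the `truth` element of [generate_panel()] output.
#' @param path optional CSV path; when given, both blocks are written as one
#'   long table with a `block` column.
#' @return a list with `countries` and `coefficients` data frames.
#' @export
truth_report <- function(truth, path = NULL) {
  countries <- data.frame(
    country_id = names(truth$efficiency),
    efficiency = as.numeric(truth$efficiency),
    dah_pc = as.numeric(truth$dah_pc),
    gdp_growth = as.numeric(truth$growth),
    stringsAsFactors = FALSE
  )
  coefficients <- data.frame(
    parameter = c(paste0("mortality.", names(truth$mortality_coefficients)),
                  paste0("fraction.", names(truth$fraction_coefficients)),
                  paste0("frontier.", names(truth$frontier_params)),
                  "mortality_noise_sd"),
    value = c(as.numeric(truth$mortality_coefficients),
              as.numeric(truth$fraction_coefficients),
              as.numeric(truth$frontier_params),
              truth$mortality_noise_sd),
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    long <- rbind(
      data.frame(block = "coefficient", key = coefficients$parameter,
                 country_id = NA_character_, value = coefficients$value),
      data.frame(block = "country", key = "efficiency",
                 country_id = countries$country_id,
                 value = countries$efficiency)
    )
    utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  }
  list(countries = countries, coefficients = coefficients)
}
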