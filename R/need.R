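#' Goal-compliant required mortality trajectory
#'
#' Builds the path a country must follow to meet the goal: a geometric
#' decline at a constant annual rate of reduction (ARR) from the base-year
#' rate to exactly the target rate at the target year,
#' `ARR = 1 - (target / baseline)^(1 / (T - t0))`. A country whose baseline
#' is already at or below the target needs no reduction: its required path
#' is the expected path capped at the target, so no need is generated.
#'
#' @param baseline_u5mr rate at the base year, per 1000 live births (> 0).
#' @param config a [run_config()]; `arr_method = "exponential"` replaces the
#'   geometric step by its continuous-time equivalent
#'   `exp(log(target / baseline) / (T - t0))` per year (numerically
#'   identical for these paths).
#' @param expected the country's [project_expected_trend()] rows; used only
#'   to cap the path when the baseline is already below the target.
#' @param base_year base year `t0`; default: year before the first expected
#'   year.
#' @return data frame (class `required_trajectory`) with `country_id`
#'   (taken from `expected`), `year`, `u5mr_required` and the constant
#'   `arr_required`.
#' @export
required_trajectory <- function(baseline_u5mr, config, expected,
                                base_year = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.finite(baseline_u5mr) || baseline_u5mr <= 0) {
    stop("required trajectory error: baseline u5mr must be > 0",
         call. = FALSE)
  }
  if (length(unique(expected$country_id)) != 1L) {
    stop("required trajectory error: 'expected' must cover exactly one ",
         "country", call. = FALSE)
  }
  years <- sort(unique(expected$year))
  if (is.null(base_year)) base_year <- min(years) - 1L
  target <- config$goal_target_rate
  T_span <- config$goal_target_year - base_year
  if (T_span <= 0) {
    stop("required trajectory error: target year must exceed base year",
         call. = FALSE)
  }

  if (baseline_u5mr > target) {
    arr <- switch(config$arr_method,
      geometric = 1 - (target / baseline_u5mr)^(1 / T_span),
      exponential = 1 - exp(log(target / baseline_u5mr) / T_span))
    req <- baseline_u5mr * (1 - arr)^(years - base_year)
  } else {
    arr <- 0
    exp_sorted <- expected[order(expected$year), , drop = FALSE]
    req <- pmin(exp_sorted$u5mr_expected, target)
  }

  out <- data.frame(
    country_id = rep(unique(expected$country_id)[1], length(years)),
    year = years,
    u5mr_required = req,
    arr_required = arr,
    stringsAsFactors = FALSE
  )
  class(out) <- c("required_trajectory", "data.frame")
  out
}

#' Additional child lives to save per year
#'
#' The gap between the expected trend and the required trajectory, converted
#' to deaths: `lives(t) = max(0, u5mr_expected(t) - u5mr_required(t)) / 1000
#' * births(t)`. Because 5q0 is a probability per live birth, live births is
#' the default denominator; total population can be selected in the config.
#'
#' @param expected [project_expected_trend()] output (one or many countries).
#' @param required per-country [required_trajectory()] rows, stacked.
#' @param panel panel supplying the denominator series on forecast years.
#' @param config a [run_config()].
#' @return data frame with `country_id`, `year`, `lives` (never negative).
#' @export
lives_to_save <- function(expected, required, panel, config) {
  stopifnot(inherits(config, "run_config"))
  key_e <- paste(expected$country_id, expected$year)
  key_r <- paste(required$country_id, required$year)
  if (!setequal(key_e, key_r)) {
    stop("lives-to-save error: expected and required trajectories are not ",
         "aligned on (country, year)", call. = FALSE)
  }
  m <- match(key_e, key_r)
  denom_col <- if (config$denominator == "births") "live_births" else "population"
  key_p <- paste(panel$country_id, panel$year)
  pm <- match(key_e, key_p)
  if (anyNA(pm) || anyNA(panel[[denom_col]][pm])) {
    bad <- key_e[is.na(pm) | is.na(panel[[denom_col]][pm])]
    stop("lives-to-save error: missing ", denom_col, " for ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  lives <- pmax(0, expected$u5mr_expected - required$u5mr_required[m]) / 1000 *
    panel[[denom_col]][pm]
  out <- data.frame(country_id = expected$country_id, year = expected$year,
                    lives = lives, stringsAsFactors = FALSE)
  out[order(out$country_id, out$year), , drop = FALSE]
}

#' Resources needed to reach the goal (N)
#'
#' Multiplies the additional lives that must be saved by the income-group
#' cost per child life saved, cumulated over the horizon:
#' `need_usd = sum_t lives(t) * cost_schedule[income_group]`. No cost is
#' defined for high-income countries; a high-income country with positive
#' lives-to-save is an error (callers normally exclude such countries).
#'
#' @param lives [lives_to_save()] output.
#' @param income_groups named character vector, country id -> income group.
#' @param config a [run_config()] carrying the cost schedule.
#' @return data frame (class `need_result`) with one row per country:
#'   `country_id`, `lives_total`, `unit_cost`, `need_usd`; the per-year
#'   breakdown is attached as attribute `by_year`.
#' @export
compute_need <- function(lives, income_groups, config) {
  stopifnot(inherits(config, "run_config"))
  totals <- stats::aggregate(lives ~ country_id, data = lives, FUN = sum)
  grp <- income_groups[totals$country_id]
  if (anyNA(grp)) {
    stop("need error: no income group for ",
         paste(totals$country_id[is.na(grp)], collapse = ", "), call. = FALSE)
  }
  no_cost <- !(grp %in% names(config$cost_schedule))
  if (any(no_cost & totals$lives > 0)) {
    stop("need error: no cost per life saved defined for income group '",
         paste(unique(grp[no_cost & totals$lives > 0]), collapse = "', '"),
         "' (country: ",
         paste(totals$country_id[no_cost & totals$lives > 0], collapse = ", "),
         ")", call. = FALSE)
  }
  unit_cost <- unname(config$cost_schedule[grp])
  unit_cost[no_cost] <- NA_real_  # zero lives, no cost needed
  need_usd <- ifelse(no_cost, 0, totals$lives * unit_cost)
  out <- data.frame(country_id = totals$country_id,
                    lives_total = totals$lives,
                    unit_cost = unit_cost,
                    need_usd = need_usd,
                    stringsAsFactors = FALSE)
  attr(out, "by_year") <- lives
  class(out) <- c("need_result", "data.frame")
  out
}
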