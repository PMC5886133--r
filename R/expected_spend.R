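#' Fit the child-health spending share model
#'
#' OLS of the fraction of government health spending (as agent) allocated to
#' child health on log GHE-S per capita and log GDP per capita, pooled over
#' the sub-account country-years. The default fits the raw fraction with
#' clipping to [0, 1] at prediction time; a logit link is available.
#'
#' @param subaccounts data frame with columns `country_id` (optional),
#'   `year` (optional), `child_fraction` in (0, 1), `ghe_s_pc` > 0,
#'   `gdp_pc` > 0. At least 10 rows.
#' @param link `"identity"` (default) or `"logit"`.
#' @return object of class `child_fraction_model` with `coefficients`
#'   (intercept, log_ghe_s_pc, log_gdp_pc), `residual_sd`, `n_obs`, `link`
#'   and the underlying `lm` fit.
#' @export
fit_fraction_model <- function(subaccounts, link = c("identity", "logit")) {
  link <- match.arg(link)
  req <- c("child_fraction", "ghe_s_pc", "gdp_pc")
  missing_cols <- setdiff(req, names(subaccounts))
  if (length(missing_cols) > 0L) {
    stop("sub-accounts schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(subaccounts) < 10L) {
    stop("fraction model error: need >= 10 sub-account rows, got ",
         nrow(subaccounts), call. = FALSE)
  }
  f <- subaccounts$child_fraction
  if (any(!is.finite(f)) || any(f <= 0 | f >= 1)) {
    stop("fraction model error: child_fraction values must lie in (0, 1)",
         call. = FALSE)
  }
  if (any(subaccounts$ghe_s_pc <= 0) || any(subaccounts$gdp_pc <= 0)) {
    stop("fraction model error: ghe_s_pc and gdp_pc must be > 0",
         call. = FALSE)
  }

  df <- data.frame(
    y = if (link == "logit") stats::qlogis(f) else f,
    log_ghe_s_pc = log(subaccounts$ghe_s_pc),
    log_gdp_pc = log(subaccounts$gdp_pc)
  )
  fit <- stats::lm(y ~ log_ghe_s_pc + log_gdp_pc, data = df)
  if (anyNA(stats::coef(fit))) {
    stop("fraction model error: collinear regressors (log GHE-S pc and ",
         "log GDP pc)", call. = FALSE)
  }
  sm <- suppressWarnings(summary(fit))  # zero-residual fits are legitimate
  out <- list(
    coefficients = stats::coef(fit),
    residual_sd = sm$sigma,
    n_obs = nrow(df),
    link = link,
    fit = fit
  )
  class(out) <- "child_fraction_model"
  out
}

#' @export
coef.child_fraction_model <- function(object, ...) object$coefficients

#' @export
print.child_fraction_model <- function(x, ...) {
  cat(sprintf("Child-health spending share model (%s link, n = %d)\n",
              x$link, x$n_obs))
  print(round(x$coefficients, 5))
  invisible(x)
}

#' Predict the child-health share
#'
#' @param object a `child_fraction_model`.
#' @param ghe_s_pc,gdp_pc positive per-capita series, USD.
#' @param ... unused.
#' @return predicted fractions clipped to [0, 1] (identity link) or mapped
#'   through the inverse logit.
#' @export
predict.child_fraction_model <- function(object, ghe_s_pc, gdp_pc, ...) {
  cf <- object$coefficients
  eta <- cf[[1]] + cf[[2]] * log(ghe_s_pc) + cf[[3]] * log(gdp_pc)
  if (object$link == "logit") stats::plogis(eta) else pmin(1, pmax(0, eta))
}

# Per-country log-linear trend extrapolation of observed GHE-S per capita,
# used only behind config$extrapolate_ghe when forecast rows lack GHE-S.
extrapolate_ghe_s <- function(panel, years_needed) {
  out <- panel
  for (cid in unique(panel$country_id)) {
    rows <- panel$country_id == cid
    obs <- panel[rows & panel$is_observed, ]
    fill <- rows & !panel$is_observed & is.na(panel$ghe_s_pc) &
      panel$year %in% years_needed
    if (!any(fill)) next
    if (nrow(obs) < 2L || any(obs$ghe_s_pc <= 0)) {
      stop("GHE-S extrapolation error: country ", cid,
           " lacks a positive observed spending history", call. = FALSE)
    }
    tr <- stats::lm(log(ghe_s_pc) ~ year, data = obs)
    out$ghe_s_pc[fill] <- exp(stats::predict(tr,
      newdata = data.frame(year = panel$year[fill])))
  }
  out
}

#' Forecast expected child-health spending (ES)
#'
#' Applies the fitted spending-share model to each country's (observed or
#' externally forecast) GHE-S per capita over the horizon:
#' `es_pc(t) = fraction(t) * ghe_s_pc(t)` and
#' `es_total = sum_t es_pc(t) * population(t)`. GHE-S forecasts are an input
#' column; if absent they can be filled by a per-country log-linear trend
#' when `config$extrapolate_ghe` is set.
#'
#' @param model a [fit_fraction_model()] fit.
#' @param panel panel with `ghe_s_pc`, `gdp_pc`, `population` on every
#'   horizon year.
#' @param config a [run_config()].
#' @return object of class `spend_forecast` with `by_year` (country_id,
#'   year, child_fraction, es_pc, es_usd) and `totals` (country_id,
#'   es_total_usd).
#' @export
forecast_expected_spend <- function(model, panel, config) {
  stopifnot(inherits(model, "child_fraction_model"),
            inherits(config, "run_config"))
  validate_panel(panel)
  base_year <- panel_base_year(panel, config)
  horizon <- (base_year + 1L):config$goal_target_year

  if (config$extrapolate_ghe) panel <- extrapolate_ghe_s(panel, horizon)
  fut <- panel[panel$year %in% horizon, , drop = FALSE]
  gaps <- is.na(fut$ghe_s_pc)
  if (any(gaps)) {
    stop("expected spend error: missing GHE-S forecast for ",
         paste(utils::head(paste0("(", fut$country_id[gaps], ", ",
                                  fut$year[gaps], ")"), 8), collapse = ", "),
         call. = FALSE)
  }
  want <- expand.grid(country_id = unique(panel$country_id), year = horizon,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  missing_rows <- !paste(want$country_id, want$year) %in%
    paste(fut$country_id, fut$year)
  if (any(missing_rows)) {
    stop("expected spend error: no panel row for ",
         paste(utils::head(paste0("(", want$country_id[missing_rows], ", ",
                                  want$year[missing_rows], ")"), 8),
               collapse = ", "), call. = FALSE)
  }

  frac <- predict(model, fut$ghe_s_pc, fut$gdp_pc)
  es_pc <- frac * fut$ghe_s_pc
  by_year <- data.frame(country_id = fut$country_id, year = fut$year,
                        child_fraction = frac, es_pc = es_pc,
                        es_usd = es_pc * fut$population,
                        stringsAsFactors = FALSE)
  by_year <- by_year[order(by_year$country_id, by_year$year), , drop = FALSE]
  rownames(by_year) <- NULL
  totals <- stats::aggregate(es_usd ~ country_id, data = by_year, FUN = sum)
  names(totals)[2] <- "es_total_usd"
  out <- list(by_year = by_year, totals = totals)
  class(out) <- "spend_forecast"
  out
}

#' @export
print.spend_forecast <- function(x, ...) {
  cat(sprintf("Spending forecast: %d countries, years %d-%d\n",
              nrow(x$totals), min(x$by_year$year), max(x$by_year$year)))
  print(utils::head(x$totals, 6))
  invisible(x)
}
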