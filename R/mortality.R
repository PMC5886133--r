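#' Fit the log-linear under-five mortality model
#'
#' Pooled ordinary least squares of the natural log of the under-five
#' mortality rate on log GDP, log GDP per capita, maternal education (years),
#' log(1 + DAH per capita), log(1 + GHE-S per capita) and a linear time
#' trend centred at the base year (a technology proxy). Only observed rows
#' (`is_observed = TRUE`) enter the fit. The shifted logs on the financing
#' regressors keep zero-DAH country-years in the sample.
#'
#' @param panel a [as_country_panel()] panel with at least 30 observed rows.
#' @param country_effects add country fixed effects (off by default: the
#'   pooled specification is the canonical one).
#' @param base_year year at which the time trend is centred; default the
#'   last observed year.
#' @return an object of class `u5mr_model`: coefficients (canonical order:
#'   intercept, log_gdp, log_gdp_pc, maternal_education, log1p_dah_pc,
#'   log1p_ghe_s_pc, year_c), `residual_sd`, fit diagnostics (`n`,
#'   `r_squared`, coefficient standard errors), the transform spec and the
#'   underlying `lm` fit.
#' @export
fit_mortality_model <- function(panel, country_effects = FALSE,
                                base_year = NULL) {
  validate_panel(panel)
  if (is.null(base_year)) base_year <- max(panel$year[panel$is_observed])
  obs <- panel[panel$is_observed, , drop = FALSE]
  if (nrow(obs) < 30L) {
    stop("mortality model error: need >= 30 observed country-year rows, got ",
         nrow(obs), call. = FALSE)
  }

  df <- data.frame(
    log_u5mr = log(obs$u5mr),
    log_gdp = log(obs$gdp),
    log_gdp_pc = log(obs$gdp_pc),
    maternal_education = obs$maternal_education,
    log1p_dah_pc = log1p(obs$dah_pc),
    log1p_ghe_s_pc = log1p(obs$ghe_s_pc),
    year_c = obs$year - base_year
  )
  form <- log_u5mr ~ log_gdp + log_gdp_pc + maternal_education +
    log1p_dah_pc + log1p_ghe_s_pc + year_c
  if (country_effects) {
    df$country_id <- factor(obs$country_id)
    form <- stats::update(form, . ~ . + country_id)
  }
  if (nrow(df) <= length(attr(stats::terms(form), "term.labels")) + 1L) {
    stop("mortality model error: fewer rows than parameters", call. = FALSE)
  }
  fit <- stats::lm(form, data = df)
  aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  if (length(aliased) > 0L) {
    stop("mortality model error: rank-deficient design; collinear column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }

  sm <- suppressWarnings(summary(fit))  # zero-residual fits are legitimate
  cf <- stats::coef(fit)
  canonical <- c("(Intercept)", "log_gdp", "log_gdp_pc",
                 "maternal_education", "log1p_dah_pc", "log1p_ghe_s_pc",
                 "year_c")
  out <- list(
    coefficients = cf[canonical],
    residual_sd = sm$sigma,
    diagnostics = list(n = nrow(df), r_squared = sm$r.squared,
                       se = sm$coefficients[, "Std. Error"]),
    transforms = c(gdp = "log", gdp_pc = "log", maternal_education = "identity",
                   dah_pc = "log1p", ghe_s_pc = "log1p",
                   year = paste0("centred at ", base_year)),
    base_year = base_year,
    country_effects = country_effects,
    fit = fit
  )
  class(out) <- "u5mr_model"
  out
}

#' @export
coef.u5mr_model <- function(object, ...) object$coefficients

#' @export
residuals.u5mr_model <- function(object, ...) stats::residuals(object$fit)

#' @export
print.u5mr_model <- function(x, ...) {
  cat("Log-linear under-five mortality model (pooled OLS)\n")
  cat(sprintf("  n = %d observed country-years, R^2 = %.4f, residual sd = %.4f\n",
              x$diagnostics$n, x$diagnostics$r_squared, x$residual_sd))
  print(round(x$coefficients, 5))
  invisible(x)
}

#' @export
summary.u5mr_model <- function(object, ...) summary(object$fit)

# Linear predictor on the log-mortality scale for arbitrary covariate values.
u5mr_linear_predictor <- function(model, gdp, gdp_pc, maternal_education,
                                  dah_pc, ghe_s_pc, year) {
  cf <- model$coefficients
  cf[["(Intercept)"]] + cf[["log_gdp"]] * log(gdp) +
    cf[["log_gdp_pc"]] * log(gdp_pc) +
    cf[["maternal_education"]] * maternal_education +
    cf[["log1p_dah_pc"]] * log1p(dah_pc) +
    cf[["log1p_ghe_s_pc"]] * log1p(ghe_s_pc) +
    cf[["year_c"]] * (year - model$base_year)
}

#' Predict under-five mortality for panel rows
#'
#' @param object a fitted `u5mr_model`.
#' @param newdata a data frame with panel covariate columns.
#' @param ... unused.
#' @return predicted rates per 1000 live births (exponentiated linear
#'   predictor; no retransformation correction is applied).
#' @export
predict.u5mr_model <- function(object, newdata, ...) {
  if (object$country_effects) {
    stop("predict on a country-effects fit is not supported for new data; ",
         "use the pooled model for projection", call. = FALSE)
  }
  exp(u5mr_linear_predictor(object, newdata$gdp, newdata$gdp_pc,
                            newdata$maternal_education, newdata$dah_pc,
                            newdata$ghe_s_pc, newdata$year))
}

#' Project the expected mortality trend
#'
#' Extends each country's mortality path from the year after the base year
#' to the goal target year, using forecast GDP, GDP per capita and maternal
#' education from the panel's forecast rows and the advancing time trend,
#' while freezing DAH per capita and GHE-S per capita at their base-year
#' values — the counterfactual of "no change in donor or government health
#' spending". Forecast financing columns in the panel are deliberately
#' ignored here.
#'
#' @param model a pooled `u5mr_model`.
#' @param panel panel containing forecast covariate rows through the target
#'   year for every country.
#' @param config a [run_config()].
#' @return data frame (class `expected_trend`) with columns `country_id`,
#'   `year`, `u5mr_expected`.
#' @export
project_expected_trend <- function(model, panel, config) {
  stopifnot(inherits(model, "u5mr_model"), inherits(config, "run_config"))
  validate_panel(panel)
  base_year <- panel_base_year(panel, config)
  horizon <- (base_year + 1L):config$goal_target_year

  countries <- unique(panel$country_id)
  base <- panel[panel$year == base_year, , drop = FALSE]
  missing_base <- setdiff(countries, base$country_id)
  if (length(missing_base) > 0L) {
    stop("expected trend error: no base-year (", base_year, ") row for: ",
         paste(missing_base, collapse = ", "), call. = FALSE)
  }

  fut <- panel[panel$year %in% horizon, , drop = FALSE]
  want <- expand.grid(country_id = countries, year = horizon,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  have <- paste(fut$country_id, fut$year)
  ok <- !is.na(fut$gdp) & !is.na(fut$gdp_pc) & !is.na(fut$maternal_education)
  have <- have[ok]
  gaps <- want[!paste(want$country_id, want$year) %in% have, , drop = FALSE]
  if (nrow(gaps) > 0L) {
    stop("expected trend error: missing forecast covariates for ",
         paste(utils::head(paste0("(", gaps$country_id, ", ", gaps$year, ")"), 8),
               collapse = ", "),
         if (nrow(gaps) > 8) sprintf(" and %d more", nrow(gaps) - 8) else "",
         call. = FALSE)
  }

  fut <- fut[order(fut$country_id, fut$year), , drop = FALSE]
  idx <- match(fut$country_id, base$country_id)
  pred <- exp(u5mr_linear_predictor(
    model,
    gdp = fut$gdp, gdp_pc = fut$gdp_pc,
    maternal_education = fut$maternal_education,
    dah_pc = base$dah_pc[idx],      # frozen at base year
    ghe_s_pc = base$ghe_s_pc[idx],  # frozen at base year
    year = fut$year))

  out <- data.frame(country_id = fut$country_id, year = fut$year,
                    u5mr_expected = pred, stringsAsFactors = FALSE)
  out <- out[out$year <= config$goal_target_year, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("expected_trend", "data.frame")
  out
}
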