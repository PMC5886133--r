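#' Run configuration
#'
#' Bundles the goal definition, costing schedule and allocation weights that
#' parameterise a full run of the framework. Defaults encode the child-health
#' case study: an under-five mortality target of 25 per 1000 live births by
#' 2030, and a cost per child life saved of $4205 (low income), $6496
#' (lower-middle) and $10 016 (upper-middle). No cost is defined for
#' high-income countries, which are excluded from need computation.
#'
#' @param goal_target_rate goal mortality level, deaths per 1000 live births.
#' @param goal_target_year calendar year by which the goal must be met.
#' @param base_year last observed year; `NULL` means "infer from the panel".
#' @param horizon_end final forecast year; defaults to `goal_target_year`.
#' @param cost_schedule named numeric vector, income group -> USD per child
#'   life saved.
#' @param alpha donor share of the financing gap, `>= 0`. Ignored when
#'   `budget` is supplied.
#' @param beta weight on Gap B (PS - ES), `<= 1`. Negative values reward
#'   domestic spending, positive values penalise it, 0 makes the allocation
#'   independent of expected spending.
#' @param budget optional donor budget in USD; when set, alpha is derived so
#'   allocations sum to the budget.
#' @param denominator series the lives-to-save computation multiplies rate
#'   gaps by: `"births"` (default; 5q0 applies to live births) or
#'   `"population"`.
#' @param arr_method `"geometric"` (constant annual proportional reduction)
#'   or `"exponential"` (continuous-time equivalent).
#' @param fraction_link link for the child-health share regression:
#'   `"identity"` (raw-scale fit with clipping, default) or `"logit"`.
#' @param ps_fraction_basis which spending level the child-health share is
#'   evaluated at when converting potential total health spending:
#'   `"potential"` (counterfactual-consistent, default) or `"expected"`.
#' @param extrapolate_ghe if `TRUE`, missing GHE-S forecasts are filled by a
#'   per-country log-linear trend of observed GHE-S per capita (an explicit
#'   stand-in for externally supplied forecasts).
#' @param seed integer seed for any stochastic step.
#' @return a list with class `run_config`.
#' @export
run_config <- function(goal_target_rate = 25,
                       goal_target_year = 2030L,
                       base_year = NULL,
                       horizon_end = NULL,
                       cost_schedule = c("low" = 4205,
                                         "lower-middle" = 6496,
                                         "upper-middle" = 10016),
                       alpha = NULL,
                       beta = 0,
                       budget = NULL,
                       denominator = c("births", "population"),
                       arr_method = c("geometric", "exponential"),
                       fraction_link = c("identity", "logit"),
                       ps_fraction_basis = c("potential", "expected"),
                       extrapolate_ghe = FALSE,
                       seed = 1L) {
  denominator <- match.arg(denominator)
  arr_method <- match.arg(arr_method)
  fraction_link <- match.arg(fraction_link)
  ps_fraction_basis <- match.arg(ps_fraction_basis)

  if (goal_target_rate <= 0) {
    stop("config error: goal_target_rate must be > 0", call. = FALSE)
  }
  if (!is.null(base_year) && goal_target_year <= base_year) {
    stop("config error: goal_target_year must exceed base_year", call. = FALSE)
  }
  if (is.null(names(cost_schedule)) ||
      !all(names(cost_schedule) %in% INCOME_GROUPS)) {
    stop("config error: cost_schedule must be named by income group",
         call. = FALSE)
  }
  if (any(cost_schedule <= 0)) {
    stop("config error: cost_schedule values must be > 0", call. = FALSE)
  }
  if (!is.null(alpha) && alpha < 0) {
    stop("config error: alpha must be >= 0", call. = FALSE)
  }
  if (beta > 1) {
    stop("config error: beta must be <= 1", call. = FALSE)
  }
  if (!is.null(budget) && budget <= 0) {
    stop("config error: budget must be > 0", call. = FALSE)
  }

  cost_schedule <- stats::setNames(as.numeric(cost_schedule),
                                   names(cost_schedule))
  cfg <- list(
    goal_target_rate = as.numeric(goal_target_rate),
    goal_target_year = as.integer(goal_target_year),
    base_year = if (is.null(base_year)) NULL else as.integer(base_year),
    horizon_end = as.integer(if (is.null(horizon_end)) goal_target_year
                             else horizon_end),
    cost_schedule = cost_schedule,
    alpha = if (is.null(alpha)) NULL else as.numeric(alpha),
    beta = as.numeric(beta),
    budget = if (is.null(budget)) NULL else as.numeric(budget),
    denominator = denominator,
    arr_method = arr_method,
    fraction_link = fraction_link,
    ps_fraction_basis = ps_fraction_basis,
    extrapolate_ghe = isTRUE(extrapolate_ghe),
    seed = as.integer(seed)
  )
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from a JSON or YAML file
#'
#' Keys absent from the file keep their [run_config()] defaults; explicit
#' values override them. The file format is inferred from the extension
#' (`.json` vs `.yml`/`.yaml`).
#'
#' @param path config file path.
#' @return a `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  values <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else {
    stop("config error: unsupported config format '.", ext,
         "' (use JSON or YAML)", call. = FALSE)
  }
  if (is.null(values)) values <- list()
  if (!is.null(values$cost_schedule)) {
    values$cost_schedule <- unlist(values$cost_schedule)
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(values), known)
  if (length(unknown) > 0L) {
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, values)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Financing-gaps run configuration\n")
  cat(sprintf("  goal: u5mr <= %g per 1000 live births by %d\n",
              x$goal_target_rate, x$goal_target_year))
  cat("  cost per child life saved (USD): ",
      paste(sprintf("%s = %g", names(x$cost_schedule), x$cost_schedule),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  weights: alpha = %s, beta = %g%s\n",
              if (is.null(x$alpha)) "<budget-derived>" else format(x$alpha),
              x$beta,
              if (is.null(x$budget)) "" else
                sprintf(", budget = %g USD", x$budget)))
  invisible(x)
}
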