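#' Fit the government health spending frontier (DEA reference set)
#'
#' Stores the base-year cross-section of (GDP per capita, GHE-S per capita)
#' points that defines the best-practice spending frontier. The frontier is
#' estimated by data envelopment analysis with a single input (GDP per
#' capita), a single output (GHE-S per capita), output orientation and
#' variable returns to scale; the envelopment program itself is solved per
#' evaluation by [evaluate_frontier()], so fitting is validation plus
#' storage.
#'
#' @param panel a [as_country_panel()] panel.
#' @param reference_year year of the frontier-defining cross-section
#'   (default: the last observed year).
#' @return object of class `dea_frontier` with the reference table,
#'   `orientation = "output"` and `returns_to_scale = "variable"`.
#' @export
fit_frontier <- function(panel, reference_year = NULL) {
  validate_panel(panel)
  if (is.null(reference_year)) {
    reference_year <- max(panel$year[panel$is_observed])
  }
  ref <- panel[panel$year == reference_year & panel$is_observed, , drop = FALSE]
  if (anyDuplicated(ref$country_id)) {
    stop("frontier error: duplicate country in the ", reference_year,
         " cross-section: ",
         paste(unique(ref$country_id[duplicated(ref$country_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (nrow(ref) < 3L) {
    stop("frontier error: need >= 3 reference points at ", reference_year,
         ", got ", nrow(ref), call. = FALSE)
  }
  if (any(ref$gdp_pc <= 0) || any(ref$ghe_s_pc <= 0)) {
    stop("frontier error: reference points must have positive GDP pc and ",
         "GHE-S pc", call. = FALSE)
  }
  ref <- ref[order(ref$country_id), c("country_id", "gdp_pc", "ghe_s_pc")]
  rownames(ref) <- NULL
  out <- list(reference = ref,
              reference_year = as.integer(reference_year),
              orientation = "output",
              returns_to_scale = "variable")
  class(out) <- "dea_frontier"
  out
}

#' Build a DEA frontier from an explicit reference set
#'
#' Low-level companion to [fit_frontier()] for benchmarking against a
#' hand-specified cross-section, e.g. in oracle checks.
#'
#' @param reference data frame with `country_id`, `gdp_pc`, `ghe_s_pc`
#'   (all positive, >= 2 points, unique countries).
#' @param reference_year optional year label.
#' @return a `dea_frontier`.
#' @export
as_dea_frontier <- function(reference, reference_year = NA_integer_) {
  req <- c("country_id", "gdp_pc", "ghe_s_pc")
  stopifnot(all(req %in% names(reference)))
  if (nrow(reference) < 2L) {
    stop("frontier error: need >= 2 reference points", call. = FALSE)
  }
  if (anyDuplicated(reference$country_id)) {
    stop("frontier error: duplicate country in reference set", call. = FALSE)
  }
  if (any(reference$gdp_pc <= 0) || any(reference$ghe_s_pc <= 0)) {
    stop("frontier error: reference points must have positive GDP pc and ",
         "GHE-S pc", call. = FALSE)
  }
  ref <- as.data.frame(reference)[req]
  ref <- ref[order(ref$country_id), , drop = FALSE]
  rownames(ref) <- NULL
  out <- list(reference = ref, reference_year = as.integer(reference_year),
              orientation = "output", returns_to_scale = "variable")
  class(out) <- "dea_frontier"
  out
}

#' @export
print.dea_frontier <- function(x, ...) {
  cat(sprintf(
    "DEA spending frontier: %d reference countries (%d cross-section),\n",
    nrow(x$reference), x$reference_year))
  cat("  single input GDP pc, single output GHE-S pc, output-oriented, VRS\n")
  invisible(x)
}

# Solves the output-oriented VRS envelopment LP for one evaluation point:
#   max phi  s.t.  sum_j lambda_j y_j >= phi * y,  sum_j lambda_j x_j <= x,
#                  sum_j lambda_j = 1,  lambda >= 0.
# Variables are (phi, lambda). Uses the simplex solver in pracma.
solve_vrs_lp <- function(xr, yr, x0, y0) {
  # the simplex implementation breaks pivot ties by sampling; pin the RNG
  # locally so identical programs solve identically, and restore the
  # caller's RNG state afterwards
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old_seed <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old_seed, envir = globalenv())
    } else {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }
  })
  n <- length(xr)
  cc <- c(1, rep(0, n))
  A <- rbind(c(y0, -yr),      # phi*y - sum lambda y <= 0
             c(0, xr))        # sum lambda x <= x0
  # the randomised pivoting can stall on degenerate bases; walk a fixed
  # ladder of pivot seeds and iteration caps, so every program still solves
  # identically on every run
  for (attempt in 0:7) {
    set.seed(271828L + 1000L * attempt)
    sol <- pracma::linprog(cc, A = A, b = c(0, x0),
                           Aeq = matrix(c(0, rep(1, n)), nrow = 1), beq = 1,
                           maximize = TRUE,
                           maxiter = (100 + 10L * n) * (1L + attempt))
    if (sol$errno == 1) return(list(phi = sol$fval, lambda = sol$x[-1]))
  }
  NULL
}

#' Evaluate the DEA frontier at one point
#'
#' Solves the output-oriented, variable-returns-to-scale envelopment program
#' for a country observing input `gdp_pc` and output `ghe_s_pc`: the output
#' expansion factor `phi >= 1` is the largest multiple of the country's
#' spending reachable by a convex combination of reference countries using
#' no more input. Potential spending is `phi * ghe_s_pc`, and the reference
#' countries with positive weight are the country's peers.
#'
#' When `gdp_pc` lies below the smallest reference input the program is
#' infeasible (the VRS hull cannot be entered); the documented fallback
#' returns the largest reference output among countries with `x_j <= x`, or
#' the observed output if there is none, flagged by `feasible = FALSE`.
#'
#' @param model a [fit_frontier()] object.
#' @param gdp_pc input value, > 0.
#' @param ghe_s_pc output value, > 0.
#' @param lambda_tol weights below this are treated as zero when reporting
#'   peers.
#' @return list with `phi`, `potential_ghe_pc`, `peers` (data frame
#'   `country_id`, `lambda`, sorted by country id) and `feasible`.
#' @export
evaluate_frontier <- function(model, gdp_pc, ghe_s_pc, lambda_tol = 1e-9) {
  stopifnot(inherits(model, "dea_frontier"))
  if (!is.finite(gdp_pc) || gdp_pc <= 0 || !is.finite(ghe_s_pc) ||
      ghe_s_pc <= 0) {
    stop("frontier evaluation error: gdp_pc and ghe_s_pc must be > 0",
         call. = FALSE)
  }
  ref <- model$reference
  if (gdp_pc < min(ref$gdp_pc)) {
    below <- ref[ref$gdp_pc <= gdp_pc, , drop = FALSE]
    pot <- if (nrow(below) > 0L) max(below$ghe_s_pc) else ghe_s_pc
    return(list(phi = pot / ghe_s_pc, potential_ghe_pc = pot,
                peers = data.frame(country_id = character(0),
                                   lambda = numeric(0)),
                feasible = FALSE))
  }
  sol <- solve_vrs_lp(ref$gdp_pc, ref$ghe_s_pc, gdp_pc, ghe_s_pc)
  if (is.null(sol)) {
    stop("frontier evaluation error: LP solver failed at gdp_pc = ", gdp_pc,
         call. = FALSE)
  }
  keep <- sol$lambda > lambda_tol
  peers <- data.frame(country_id = ref$country_id[keep],
                      lambda = sol$lambda[keep],
                      stringsAsFactors = FALSE)
  peers <- peers[order(peers$country_id), , drop = FALSE]
  rownames(peers) <- NULL
  list(phi = sol$phi, potential_ghe_pc = sol$phi * ghe_s_pc, peers = peers,
       feasible = TRUE)
}

# Frontier output level as a function of input alone (phi * y is invariant
# to y in the single-output program). Memoised over the distinct inputs of a
# query vector; inputs outside the reference range are clamped to it (the
# VRS frontier is never extrapolated).
frontier_value <- function(model, gdp_pc) {
  ref <- model$reference
  x <- pmin(pmax(gdp_pc, min(ref$gdp_pc)), max(ref$gdp_pc))
  ux <- unique(x)
  y_probe <- min(ref$ghe_s_pc)
  vals <- vapply(ux, function(xi) {
    evaluate_frontier(model, xi, y_probe)$potential_ghe_pc
  }, numeric(1))
  vals[match(x, ux)]
}

#' Forecast potential child-health spending (PS)
#'
#' Evaluates the spending frontier at each country's forecast GDP per capita
#' over the horizon to obtain potential total government health spending per
#' capita, converts it to child health with the spending-share model
#' (evaluated, by default, at the potential spending level — the
#' counterfactual-consistent choice), and cumulates:
#' `ps_total = sum_t fraction(t) * ps_ghe_pc(t) * population(t)`. Forecast
#' GDP outside the reference range is clamped to the frontier value at the
#' nearest reference point.
#'
#' @param model a [fit_frontier()] object.
#' @param fraction_model a [fit_fraction_model()] fit.
#' @param panel panel with GDP per capita and population on every horizon
#'   year.
#' @param config a [run_config()]; `ps_fraction_basis = "expected"`
#'   evaluates the share at observed/forecast GHE-S instead.
#' @return object of class `spend_forecast` with `by_year` (country_id,
#'   year, phi, ps_ghe_pc, ps_child_fraction, ps_pc, ps_usd) and `totals`
#'   (country_id, ps_total_usd, phi_reference); `phi_reference` is the
#'   expansion factor at the reference-year observation.
#' @export
forecast_potential_spend <- function(model, fraction_model, panel, config) {
  stopifnot(inherits(model, "dea_frontier"),
            inherits(fraction_model, "child_fraction_model"),
            inherits(config, "run_config"))
  validate_panel(panel)
  base_year <- panel_base_year(panel, config)
  horizon <- (base_year + 1L):config$goal_target_year

  fut <- panel[panel$year %in% horizon, , drop = FALSE]
  gaps <- is.na(fut$gdp_pc)
  if (any(gaps)) {
    stop("potential spend error: missing GDP forecast for ",
         paste(utils::head(paste0("(", fut$country_id[gaps], ", ",
                                  fut$year[gaps], ")"), 8), collapse = ", "),
         call. = FALSE)
  }

  ps_ghe_pc <- frontier_value(model, fut$gdp_pc)
  ghe_basis <- if (config$ps_fraction_basis == "potential") {
    ps_ghe_pc
  } else {
    if (anyNA(fut$ghe_s_pc)) {
      stop("potential spend error: ps_fraction_basis = 'expected' needs ",
           "GHE-S on every horizon year", call. = FALSE)
    }
    fut$ghe_s_pc
  }
  frac <- predict(fraction_model, ghe_basis, fut$gdp_pc)
  ps_pc <- frac * ps_ghe_pc

  by_year <- data.frame(country_id = fut$country_id, year = fut$year,
                        ps_ghe_pc = ps_ghe_pc, ps_child_fraction = frac,
                        ps_pc = ps_pc, ps_usd = ps_pc * fut$population,
                        stringsAsFactors = FALSE)
  by_year <- by_year[order(by_year$country_id, by_year$year), , drop = FALSE]
  rownames(by_year) <- NULL
  totals <- stats::aggregate(ps_usd ~ country_id, data = by_year, FUN = sum)
  names(totals)[2] <- "ps_total_usd"

  ref <- model$reference
  in_ref <- totals$country_id %in% ref$country_id
  phi_ref <- rep(NA_real_, nrow(totals))
  if (any(in_ref)) {
    idx <- match(totals$country_id[in_ref], ref$country_id)
    env_at_ref <- frontier_value(model, ref$gdp_pc[idx])
    phi_ref[in_ref] <- env_at_ref / ref$ghe_s_pc[idx]
  }
  totals$phi_reference <- phi_ref

  out <- list(by_year = by_year, totals = totals)
  class(out) <- "spend_forecast"
  out
}
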