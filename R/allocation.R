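#' Gap decomposition: Need vs Potential vs Expected spending
#'
#' Combines the three cumulative-horizon totals per country into the
#' framework's gaps: Gap A = N - PS (the shortfall beyond what the country
#' could itself fund), Gap B = PS - ES (the unrealised domestic spending
#' potential, which may be negative when expected spending exceeds potential
#' spending), and the total financing gap N - ES = Gap A + Gap B.
#'
#' @param need a [compute_need()] result.
#' @param es expected-spending totals: a `spend_forecast` from
#'   [forecast_expected_spend()] or a data frame with `country_id`,
#'   `es_total_usd`.
#' @param ps potential-spending totals: a `spend_forecast` from
#'   [forecast_potential_spend()] or a data frame with `country_id`,
#'   `ps_total_usd`.
#' @return data frame (class `gap_result`) with `country_id`, `need_usd`,
#'   `es_usd`, `ps_usd`, `gap_a`, `gap_b`, `gap_total`.
#' @export
compute_gaps <- function(need, es, ps) {
  if (inherits(es, "spend_forecast")) es <- es$totals
  if (inherits(ps, "spend_forecast")) ps <- ps$totals
  sets <- list(need = need$country_id, es = es$country_id,
               ps = ps$country_id)
  all_ids <- sort(Reduce(union, sets))
  missing <- lapply(sets, function(s) setdiff(all_ids, s))
  if (any(lengths(missing) > 0L)) {
    msg <- vapply(names(missing)[lengths(missing) > 0L], function(nm) {
      paste0(nm, " lacks: ", paste(missing[[nm]], collapse = ", "))
    }, character(1))
    stop("gap error: country sets differ across inputs; ",
         paste(msg, collapse = "; "), call. = FALSE)
  }
  N <- need$need_usd[match(all_ids, need$country_id)]
  ES <- es$es_total_usd[match(all_ids, es$country_id)]
  PS <- ps$ps_total_usd[match(all_ids, ps$country_id)]
  gap_a <- N - PS
  gap_b <- PS - ES
  out <- data.frame(country_id = all_ids,
                    need_usd = N, es_usd = ES, ps_usd = PS,
                    gap_a = gap_a, gap_b = gap_b,
                    # summed from the components so the decomposition
                    # identity holds bitwise
                    gap_total = gap_a + gap_b,
                    stringsAsFactors = FALSE)
  class(out) <- c("gap_result", "data.frame")
  out
}

#' Allocate development assistance for health
#'
#' Applies the allocation rule `DAH = alpha * [(N - PS) + beta * (PS - ES)]`
#' per country. With `beta = 1` the rule reduces to `alpha * (N - ES)`
#' (funding the total financing gap, which penalises domestic spending);
#' with `beta = 0` it reduces to `alpha * (N - PS)` (independent of expected
#' spending); `beta < 0` rewards domestic spending. Negative raw terms are
#' floored at zero — DAH cannot be negative.
#'
#' @param gaps a [compute_gaps()] result.
#' @param config a [run_config()]; when `config$budget` is set the call is
#'   forwarded to [allocate_budget()], otherwise `config$alpha` and
#'   `config$beta` are used.
#' @param alpha,beta optional overrides of the config weights.
#' @return data frame (class `allocation_result`) with `country_id`,
#'   `alpha`, `beta`, `raw_term`, `dah_usd`, `clipped`.
#' @export
allocate <- function(gaps, config, alpha = NULL, beta = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(beta)) beta <- config$beta
  if (!is.null(config$budget) && is.null(alpha)) {
    return(allocate_budget(gaps, config$budget, beta))
  }
  if (is.null(alpha)) alpha <- config$alpha
  if (is.null(alpha)) {
    stop("allocation error: supply either alpha or a budget", call. = FALSE)
  }
  if (alpha < 0) stop("allocation error: alpha must be >= 0", call. = FALSE)
  if (beta > 1) stop("allocation error: beta must be <= 1", call. = FALSE)

  raw <- alpha * (gaps$gap_a + beta * gaps$gap_b)
  out <- data.frame(country_id = gaps$country_id,
                    alpha = alpha, beta = beta,
                    raw_term = raw,
                    dah_usd = pmax(0, raw),
                    clipped = raw < 0,
                    stringsAsFactors = FALSE)
  class(out) <- c("allocation_result", "data.frame")
  out
}

#' Budget-normalised allocation
#'
#' Derives the donor share alpha so that allocations exhaust a fixed budget:
#' `alpha = budget / sum_i max(0, (N_i - PS_i) + beta * (PS_i - ES_i))`,
#' with each country receiving alpha times its (floored) gap term. Countries
#' with non-positive gap terms receive nothing.
#'
#' @param gaps a [compute_gaps()] result.
#' @param budget donor budget, USD, > 0.
#' @param beta weight on Gap B, `<= 1`.
#' @return an `allocation_result`; allocations sum to `budget`.
#' @export
allocate_budget <- function(gaps, budget, beta = 0) {
  if (budget <= 0) stop("allocation error: budget must be > 0", call. = FALSE)
  if (beta > 1) stop("allocation error: beta must be <= 1", call. = FALSE)
  raw <- gaps$gap_a + beta * gaps$gap_b
  positive <- pmax(0, raw)
  total <- sum(positive)
  if (total <= 0) {
    stop("allocation error: no country has a positive gap term; nothing to ",
         "fund", call. = FALSE)
  }
  alpha <- budget / total
  out <- data.frame(country_id = gaps$country_id,
                    alpha = alpha, beta = beta,
                    raw_term = alpha * raw,
                    dah_usd = alpha * positive,
                    clipped = raw < 0,
                    stringsAsFactors = FALSE)
  class(out) <- c("allocation_result", "data.frame")
  out
}

#' Rank countries under alternative prioritisation criteria
#'
#' Orders countries the way alternative allocation strategies would: by GDP
#' per capita ascending (the income-based status quo), by the total
#' financing gap or Gap A descending (the framework's criteria), or by
#' under-five mortality descending (burden-based). Ties are broken by
#' country id ascending, so rankings are deterministic.
#'
#' @param panel panel supplying base-year `gdp_pc` and `u5mr`.
#' @param gaps a [compute_gaps()] result.
#' @param criterion one of `"gdp_pc"`, `"gap_total"`, `"gap_a"`, `"u5mr"`.
#' @param base_year year at which panel criteria are read; default the last
#'   observed year.
#' @return data frame with `criterion`, `country_id`, `value`, `rank`.
#' @export
rank_countries <- function(panel, gaps, criterion = c("gdp_pc", "gap_total",
                                                      "gap_a", "u5mr"),
                           base_year = NULL) {
  criterion <- match.arg(criterion)
  ids <- gaps$country_id
  if (criterion %in% c("gdp_pc", "u5mr")) {
    if (is.null(base_year)) base_year <- max(panel$year[panel$is_observed])
    base <- panel[panel$year == base_year, , drop = FALSE]
    idx <- match(ids, base$country_id)
    if (anyNA(idx)) {
      stop("ranking error: no base-year row for ",
           paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    value <- base[[criterion]][idx]
  } else {
    value <- gaps[[criterion]]
  }
  decreasing <- criterion != "gdp_pc"
  ord <- order(if (decreasing) -value else value, ids)
  out <- data.frame(criterion = criterion,
                    country_id = ids[ord],
                    value = value[ord],
                    rank = seq_along(ids),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
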