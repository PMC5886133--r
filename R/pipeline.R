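#' Run the full financing-gaps pipeline
#'
#' Chains every stage of the framework on one panel: fit the log-mortality
#' model on observed rows; project the expected trend with spending frozen
#' at base-year levels; build the goal-compliant required trajectory and the
#' lives to save; cost them into Need; fit the child-health spending-share
#' model on the sub-accounts and forecast Expected spending; fit the DEA
#' frontier on the base-year cross-section and forecast Potential spending;
#' decompose the gaps; allocate DAH under the configured (alpha, beta) or
#' budget; and rank countries under the four comparison criteria.
#'
#' High-income countries have no cost-per-life-saved entry and are excluded
#' from the need/gap/allocation stages (they still contribute reference
#' points to the spending frontier).
#'
#' @param config a [run_config()] carrying the goal, cost schedule and
#'   either `alpha` or `budget`.
#' @param panel a panel object or a CSV path readable by [read_panel()].
#' @param subaccounts a sub-accounts data frame or CSV path (columns
#'   `country_id`, `year`, `child_fraction`, `ghe_s_pc`, `gdp_pc`).
#' @param out_dir optional output directory; when given, the stage outputs
#'   are written as `trends.csv`, `need.csv`, `es.csv`, `ps.csv`,
#'   `gaps.csv`, `alloc.csv`, `ranks.csv`, `top_need.csv` plus a
#'   `manifest.json` recording the config, input checksums, package version
#'   and seed.
#' @param top_k number of countries in the top-need table.
#' @return (invisibly when `out_dir` is set) a list with every stage result:
#'   `mortality_model`, `trends`, `required`, `lives`, `need`,
#'   `fraction_model`, `es`, `frontier`, `ps`, `gaps`, `allocation`,
#'   `rankings`, `top_need`.
#' @export
run_all <- function(config, panel, subaccounts, out_dir = NULL, top_k = 10L) {
  stopifnot(inherits(config, "run_config"))
  panel_path <- NULL
  if (is.character(panel)) {
    panel_path <- panel
    panel <- read_panel(panel)
  } else {
    panel <- as_country_panel(panel)
  }
  sub_path <- NULL
  if (is.character(subaccounts)) {
    sub_path <- subaccounts
    if (!file.exists(sub_path)) {
      stop("expected-spend stage error: sub-accounts file not found: ",
           sub_path, call. = FALSE)
    }
    subaccounts <- utils::read.csv(sub_path, stringsAsFactors = FALSE)
  }

  base_year <- panel_base_year(panel, config)
  base <- panel[panel$year == base_year, , drop = FALSE]
  income_groups <- stats::setNames(base$income_group, base$country_id)
  costed <- names(income_groups)[income_groups %in% names(config$cost_schedule)]

  model <- fit_mortality_model(panel, base_year = base_year)
  trends <- project_expected_trend(model, panel, config)

  required <- do.call(rbind, lapply(costed, function(cid) {
    exp_c <- trends[trends$country_id == cid, , drop = FALSE]
    required_trajectory(base$u5mr[base$country_id == cid], config, exp_c,
                        base_year = base_year)
  }))
  trends_costed <- trends[trends$country_id %in% costed, , drop = FALSE]
  lives <- lives_to_save(trends_costed, required, panel, config)
  need <- compute_need(lives, income_groups, config)

  fraction_model <- fit_fraction_model(subaccounts,
                                       link = config$fraction_link)
  es <- forecast_expected_spend(fraction_model, panel, config)
  frontier <- fit_frontier(panel, reference_year = base_year)
  ps <- forecast_potential_spend(frontier, fraction_model, panel, config)

  es_costed <- es$totals[es$totals$country_id %in% costed, , drop = FALSE]
  ps_costed <- ps$totals[ps$totals$country_id %in% costed, , drop = FALSE]
  gaps <- compute_gaps(need, es_costed, ps_costed)
  alloc <- allocate(gaps, config)

  criteria <- c("gdp_pc", "gap_total", "gap_a", "u5mr")
  rankings <- do.call(rbind, lapply(criteria, function(cr) {
    rank_countries(panel, gaps, cr, base_year = base_year)
  }))
  top_need <- top_need_table(need, gaps, k = min(top_k, nrow(gaps)))

  result <- list(mortality_model = model, trends = trends,
                 required = required, lives = lives, need = need,
                 fraction_model = fraction_model, es = es,
                 frontier = frontier, ps = ps, gaps = gaps,
                 allocation = alloc, rankings = rankings,
                 top_need = top_need, base_year = base_year)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) {
      utils::write.csv(as.data.frame(df), file.path(out_dir, name),
                       row.names = FALSE, quote = FALSE)
    }
    wr(trends, "trends.csv")
    wr(need, "need.csv")
    wr(merge(es$by_year, es$totals, by = "country_id"), "es.csv")
    wr(merge(ps$by_year, ps$totals, by = "country_id"), "ps.csv")
    wr(gaps, "gaps.csv")
    wr(alloc, "alloc.csv")
    wr(rankings, "ranks.csv")
    wr(top_need, "top_need.csv")
    checksums <- list()
    if (!is.null(panel_path)) {
      checksums$panel <- unname(tools::md5sum(panel_path))
    }
    if (!is.null(sub_path)) {
      checksums$subaccounts <- unname(tools::md5sum(sub_path))
    }
    manifest <- list(
      config = unclass(config),
      input_checksums = checksums,
      package_version = as.character(utils::packageVersion("fingaps")),
      seed = config$seed,
      base_year = base_year,
      n_countries = length(unique(panel$country_id)),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
    return(invisible(result))
  }
  result
}

#' Top-need summary table
#'
#' The countries with the largest cumulative need, with their expected and
#' potential spending and the gaps expressed as percentages: Gap A as a
#' share of need, `100 * (N - PS) / N`, and Gap B as a share of potential
#' spending, `100 * (PS - ES) / PS`.
#'
#' @param need a [compute_need()] result.
#' @param gaps a [compute_gaps()] result.
#' @param k number of countries to keep (largest need first).
#' @return data frame with `country_id`, `need_usd`, `es_usd`, `ps_usd`,
#'   `gap_a_pct_of_need`, `gap_b_pct_of_ps`.
#' @export
top_need_table <- function(need, gaps, k = 10L) {
  if (k > nrow(gaps)) {
    stop("top-need error: k = ", k, " exceeds the ", nrow(gaps),
         " available countries", call. = FALSE)
  }
  ord <- order(-gaps$need_usd, gaps$country_id)
  top <- gaps[ord[seq_len(k)], , drop = FALSE]
  data.frame(
    country_id = top$country_id,
    need_usd = top$need_usd,
    es_usd = top$es_usd,
    ps_usd = top$ps_usd,
    gap_a_pct_of_need = ifelse(top$need_usd > 0,
                               100 * top$gap_a / top$need_usd, NA_real_),
    gap_b_pct_of_ps = ifelse(top$ps_usd > 0,
                             100 * top$gap_b / top$ps_usd, NA_real_),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
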