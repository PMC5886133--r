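# Canonical long-format column order for country-year panels.
PANEL_COLUMNS <- c(
  "country_id", "year", "gdp", "gdp_pc", "maternal_education", "dah_pc",
  "ghe_s_pc", "population", "live_births", "u5mr", "income_group",
  "is_observed"
)

INCOME_GROUPS <- c("low", "lower-middle", "upper-middle", "high")

#' Construct and validate a country-year panel
#'
#' A country-year panel is the universal input of the framework: one row per
#' country and calendar year carrying demography (population, live births,
#' under-five mortality), the economy (GDP, GDP per capita, maternal
#' education) and health financing (DAH per capita, government health
#' expenditure as source per capita), plus a static income group and a flag
#' separating observed history from forecast covariate rows.
#'
#' All monetary columns are constant-USD of a single base year; no deflation
#' is performed by the package. On forecast rows (`is_observed = FALSE`) the
#' outcome `u5mr` and the financing columns `dah_pc`, `ghe_s_pc` may be `NA`;
#' everything else is required everywhere.
#'
#' @param x data frame with the columns listed in the package overview
#'   (`country_id`, `year`, `gdp`, `gdp_pc`, `maternal_education`, `dah_pc`,
#'   `ghe_s_pc`, `population`, `live_births`, `u5mr`, `income_group`,
#'   `is_observed`).
#' @return the validated panel, sorted by (`country_id`, `year`), with class
#'   `country_panel`.
#' @export
as_country_panel <- function(x) {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(PANEL_COLUMNS, names(x))
  if (length(missing_cols) > 0L) {
    stop("panel schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- as.data.frame(x)[PANEL_COLUMNS]
  x$country_id <- as.character(x$country_id)
  x$year <- as.integer(x$year)
  x$income_group <- as.character(x$income_group)
  x$is_observed <- as.logical(x$is_observed)
  for (col in c("gdp", "gdp_pc", "maternal_education", "dah_pc", "ghe_s_pc",
                "population", "live_births", "u5mr")) {
    x[[col]] <- as.numeric(x[[col]])
  }
  x <- x[order(x$country_id, x$year), , drop = FALSE]
  rownames(x) <- NULL
  validate_panel(x)
  class(x) <- c("country_panel", "data.frame")
  x
}

#' Validate a country-year panel
#'
#' Checks the panel invariants: unique (country, year) keys, contiguous year
#' ranges per country, positive rates and denominators, a recognised and
#' per-country-constant income group. Violations are reported with the
#' offending keys or row numbers; validation never silently drops rows.
#'
#' @param x data frame in panel column layout.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_panel <- function(x) {
  problems <- character(0)
  say <- function(...) problems <<- c(problems, paste0(...))

  key <- paste(x$country_id, x$year, sep = "/")
  dup <- unique(key[duplicated(key)])
  if (length(dup) > 0L) {
    say("duplicate (country_id, year): ", paste(dup, collapse = ", "))
  }

  bad_rows <- function(cond) which(!is.na(cond) & cond)

  num_required <- c("gdp", "gdp_pc", "maternal_education", "population",
                    "live_births")
  for (col in num_required) {
    miss <- which(is.na(x[[col]]))
    if (length(miss) > 0L) {
      say(col, " missing at row(s) ", paste(utils::head(miss, 5), collapse = ", "))
    }
  }
  for (col in c("gdp", "gdp_pc", "population", "live_births")) {
    neg <- bad_rows(x[[col]] <= 0)
    if (length(neg) > 0L) {
      say(col, " must be > 0; violated at row(s) ",
          paste(utils::head(neg, 5), collapse = ", "))
    }
  }
  for (col in c("dah_pc", "ghe_s_pc")) {
    neg <- bad_rows(x[[col]] < 0)
    if (length(neg) > 0L) {
      say(col, " must be >= 0; violated at row(s) ",
          paste(utils::head(neg, 5), collapse = ", "))
    }
    miss <- which(is.na(x[[col]]) & x$is_observed)
    if (length(miss) > 0L) {
      say(col, " missing on observed row(s) ",
          paste(utils::head(miss, 5), collapse = ", "))
    }
  }

  bad_rate <- bad_rows(x$u5mr <= 0 | x$u5mr >= 1000)
  if (length(bad_rate) > 0L) {
    say("u5mr must lie in (0, 1000); violated at row(s) ",
        paste(utils::head(bad_rate, 5), collapse = ", "))
  }
  miss_rate <- which(is.na(x$u5mr) & x$is_observed)
  if (length(miss_rate) > 0L) {
    say("u5mr missing on observed row(s) ",
        paste(utils::head(miss_rate, 5), collapse = ", "))
  }

  bad_grp <- bad_rows(!(x$income_group %in% INCOME_GROUPS))
  if (length(bad_grp) > 0L) {
    say("income_group must be one of {", paste(INCOME_GROUPS, collapse = ", "),
        "}; violated at row(s) ", paste(utils::head(bad_grp, 5), collapse = ", "))
  }
  if (any(is.na(x$is_observed))) {
    say("is_observed must be TRUE/FALSE with no missing values")
  }

  for (cid in unique(x$country_id)) {
    yrs <- sort(x$year[x$country_id == cid])
    if (length(yrs) > 1L && !identical(yrs, seq(min(yrs), max(yrs)))) {
      say("years for ", cid, " are not contiguous")
    }
    grp <- unique(x$income_group[x$country_id == cid])
    if (length(grp) > 1L) {
      say("income_group for ", cid, " is not constant (",
          paste(grp, collapse = ", "), ")")
    }
  }

  if (length(problems) > 0L) {
    stop("panel validation error:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(x)
}

#' Read a country-year panel from CSV
#'
#' @param path path to a comma-separated, UTF-8, header-first CSV file.
#' @param schema optional named character vector mapping canonical column
#'   names to the names used in the file, e.g. `c(country_id = "iso3")`.
#' @return a validated [as_country_panel()] panel.
#' @export
read_panel <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  if (!is.null(schema)) {
    for (canonical in names(schema)) {
      src <- schema[[canonical]]
      if (!src %in% names(raw)) {
        stop("panel schema error: column '", src, "' (mapped to '",
             canonical, "') not found in ", path, call. = FALSE)
      }
      names(raw)[names(raw) == src] <- canonical
    }
  }
  as_country_panel(raw)
}

#' Write a country-year panel to CSV
#'
#' Writes one header row and the canonical column order; the written file
#' round-trips exactly through [read_panel()] on all fields.
#'
#' @param panel a validated panel.
#' @param path output file path.
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  out <- as.data.frame(panel)[PANEL_COLUMNS]
  # 17 significant digits guarantee an exact double round-trip through text
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      v <- sprintf("%.17g", out[[col]])
      v[is.na(out[[col]])] <- "NA"
      out[[col]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.country_panel <- function(x, ...) {
  n_obs <- sum(x$is_observed)
  cat(sprintf(
    "Country-year panel: %d countries x years %d-%d (%d observed rows, %d forecast rows)\n",
    length(unique(x$country_id)), min(x$year), max(x$year),
    n_obs, nrow(x) - n_obs))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... ", nrow(x) - 6, " more rows\n", sep = "")
  invisible(x)
}

# Last observed year, the panel's base year unless the config overrides it.
panel_base_year <- function(panel, config = NULL) {
  if (!is.null(config) && !is.null(config$base_year)) return(config$base_year)
  max(panel$year[panel$is_observed])
}
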