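ref_frontier <- function(x, y, ids = sprintf("R%02d", seq_along(x))) {
  as_dea_frontier(data.frame(country_id = ids, gdp_pc = x, ghe_s_pc = y,
                             stringsAsFactors = FALSE))
}

test_that("the output-oriented VRS program solves textbook instances", {
  # frontier through (2,2): a country at (2,1) can double its output
  m <- ref_frontier(c(1, 2, 3), c(1, 2, 3))
  r <- evaluate_frontier(m, 2, 1)
  expect_equal(r$phi, 2, tolerance = 1e-9)
  expect_equal(r$potential_ghe_pc, 2, tolerance = 1e-9)
  expect_true(r$feasible)

  # a frontier point is its own peer with no expansion
  r3 <- evaluate_frontier(m, 3, 3)
  expect_equal(r3$phi, 1, tolerance = 1e-9)
  expect_equal(r3$potential_ghe_pc, 3, tolerance = 1e-9)

  # input disposability: the low-input high-output peer dominates
  m2 <- ref_frontier(c(1, 2), c(5, 1), ids = c("HI", "LO"))
  r2 <- evaluate_frontier(m2, 2, 1)
  expect_equal(r2$phi, 5, tolerance = 1e-9)
  expect_equal(r2$potential_ghe_pc, 5, tolerance = 1e-9)
  expect_identical(r2$peers$country_id, "HI")
})

test_that("the LP agrees with the concave-envelope oracle on random
           instances", {
  set.seed(42)
  for (k in 1:60) {
    n <- sample(3:12, 1)
    xr <- runif(n, 0.5, 10)
    yr <- runif(n, 0.5, 10)
    i <- sample(n, 1)
    r <- evaluate_frontier(ref_frontier(xr, yr), xr[i], yr[i])
    oracle <- envelope_oracle(xr, yr, xr[i])
    expect_lt(abs(r$potential_ghe_pc - oracle) / oracle, 1e-6)
    expect_gte(r$phi, 1 - 1e-9)  # domination at in-sample points
  }
})

test_that("peer weights are a convex combination and somebody is efficient", {
  set.seed(7)
  xr <- runif(10, 1, 50)
  yr <- runif(10, 1, 20)
  m <- ref_frontier(xr, yr)
  phis <- vapply(seq_along(xr), function(i) {
    r <- evaluate_frontier(m, xr[i], yr[i])
    expect_gte(min(r$peers$lambda), 0)
    expect_equal(sum(r$peers$lambda), 1, tolerance = 1e-6)
    r$phi
  }, numeric(1))
  expect_true(any(abs(phis - 1) < 1e-9))
  expect_true(all(phis >= 1 - 1e-9))
})

test_that("evaluation below the smallest reference input falls back,
           flagged", {
  m <- ref_frontier(c(5, 6, 7), c(2, 3, 4))
  r <- evaluate_frontier(m, 1, 0.5)
  expect_false(r$feasible)
  expect_equal(r$potential_ghe_pc, 0.5)  # observed spending kept
  expect_identical(nrow(r$peers), 0L)
})

test_that("frontier fitting validates its cross-section", {
  g <- generate_panel(synthetic_spec(n_countries = 12, seed = 5))
  m <- fit_frontier(g$panel, reference_year = 2015)
  expect_identical(nrow(m$reference), 12L)
  expect_identical(m$orientation, "output")
  expect_identical(m$returns_to_scale, "variable")

  few <- as.data.frame(g$panel)
  few <- few[few$country_id %in% c("C001", "C002"), ]
  expect_error(fit_frontier(as_country_panel(few), 2015), ">= 3")
  expect_error(fit_frontier(g$panel, reference_year = 1900), ">= 3")

  expect_error(ref_frontier(c(1, 2, 3), c(1, -2, 3)), "positive")
  expect_error(as_dea_frontier(data.frame(country_id = c("A", "A", "B"),
                                          gdp_pc = 1:3, ghe_s_pc = 1:3)),
               "duplicate")
})

test_that("forecast potential spending clamps outside the reference range
           and scales frontier countries by the share model only", {
  g <- generate_panel(synthetic_spec(n_countries = 20, seed = 8,
                                     efficiency_range = c(1, 1),
                                     gdp_growth = c(mean = 0, sd = 0)))
  cfg <- default_config()
  # with every country on the power-law frontier the sub-account regressors
  # are exactly collinear, so use a hand-built constant-share model
  fm <- fake_fraction_model(c(0.1, 0, 0))
  m <- fit_frontier(g$panel, 2015)
  ps <- forecast_potential_spend(m, fm, g$panel, cfg)

  # static GDP and everyone on the frontier: the convex-hull estimate never
  # exceeds the true concave frontier, and reference points are undominated
  merged <- merge(ps$by_year,
                  as.data.frame(g$panel)[c("country_id", "year", "gdp_pc",
                                           "ghe_s_pc")],
                  by = c("country_id", "year"))
  expect_true(all(merged$ps_ghe_pc <=
                    true_frontier(g$truth, merged$gdp_pc) + 1e-6))
  expect_true(all(merged$ps_ghe_pc >= merged$ghe_s_pc * (1 - 1e-9) |
                    merged$gdp_pc > max(m$reference$gdp_pc)))
  expect_true(all(ps$totals$phi_reference >= 1 - 1e-9))

  # GDP forecast far above the reference maximum clamps at the frontier top
  p2 <- as.data.frame(g$panel)
  top <- max(m$reference$ghe_s_pc)
  rich <- p2$country_id == "C001" & !p2$is_observed
  p2$gdp_pc[rich] <- max(m$reference$gdp_pc) * 10
  p2$gdp[rich] <- p2$gdp_pc[rich] * p2$population[rich]
  ps2 <- forecast_potential_spend(m, fm, as_country_panel(p2), cfg)
  expect_equal(unique(ps2$by_year$ps_ghe_pc[ps2$by_year$country_id == "C001"]),
               top, tolerance = 1e-9)
})

test_that("a dense reference set recovers a power-law frontier within 5%", {
  # constant efficiency puts every country on a smooth concave curve; the
  # hull estimate may only deviate by the piecewise-linear chord error
  g <- generate_panel(synthetic_spec(n_countries = 100, seed = 21,
                                     efficiency_range = c(0.5, 0.5)))
  m <- fit_frontier(g$panel, 2015)
  xs <- stats::quantile(m$reference$gdp_pc, probs = seq(0.1, 0.9, by = 0.1))
  for (x in xs) {
    r <- evaluate_frontier(m, x, min(m$reference$ghe_s_pc))
    truth <- 0.5 * true_frontier(g$truth, x)
    expect_lt(abs(r$potential_ghe_pc - truth) / truth, 0.05)
  }
})
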