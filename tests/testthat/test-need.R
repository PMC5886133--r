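make_expected <- function(cid, years, rates) {
  structure(data.frame(country_id = cid, year = years, u5mr_expected = rates,
                       stringsAsFactors = FALSE),
            class = c("expected_trend", "data.frame"))
}

test_that("the required path is geometric and hits the target exactly", {
  cfg <- default_config()
  exp_tr <- make_expected("A", 2016:2030, rep(90, 15))
  req <- required_trajectory(100, cfg, exp_tr, base_year = 2015)

  # closed form against 15-fold iterated multiplication
  arr <- req$arr_required[1]
  expect_equal(arr, 1 - (25 / 100)^(1 / 15), tolerance = 1e-12)
  iterated <- 100
  for (k in 1:15) iterated <- iterated * (1 - arr)
  expect_equal(iterated, 25, tolerance = 1e-9)
  expect_equal(req$u5mr_required[req$year == 2030], 25, tolerance = 25e-9)

  # constant proportional reduction: consecutive ratios identical
  ratios <- req$u5mr_required[-1] / req$u5mr_required[-15]
  expect_equal(ratios, rep(1 - arr, 14), tolerance = 1e-12)

  # the continuous-time variant yields the same geometric path
  cfg_exp <- run_config(alpha = 1, arr_method = "exponential")
  req2 <- required_trajectory(100, cfg_exp, exp_tr, base_year = 2015)
  expect_equal(req2$u5mr_required, req$u5mr_required, tolerance = 1e-12)
})

test_that("the target-year rate is exact for any baseline above target", {
  cfg <- default_config()
  exp_tr <- make_expected("A", 2016:2030, rep(50, 15))
  for (baseline in c(25.01, 30, 60, 100, 250, 700)) {
    req <- required_trajectory(baseline, cfg, exp_tr, base_year = 2015)
    final <- req$u5mr_required[req$year == 2030]
    expect_lt(abs(final - 25) / 25, 1e-9)
  }
})

test_that("baselines at or below target generate no need", {
  cfg <- default_config()
  exp_tr <- make_expected("A", 2016:2030, seq(24, 10, length.out = 15))
  req <- required_trajectory(25, cfg, exp_tr, base_year = 2015)
  expect_identical(req$arr_required, rep(0, 15))
  expect_equal(req$u5mr_required, pmin(exp_tr$u5mr_expected, 25))

  req20 <- required_trajectory(20, cfg, exp_tr, base_year = 2015)
  p <- tiny_panel()
  lives <- lives_to_save(exp_tr, req20,
                         transform(as.data.frame(p[p$country_id == "AFG", ]),
                                   country_id = "A"),
                         cfg)
  expect_true(all(lives$lives == 0))

  expect_error(required_trajectory(0, cfg, exp_tr), "baseline")
  expect_error(required_trajectory(-3, cfg, exp_tr), "baseline")
})

test_that("lives to save is direct rate-gap arithmetic, floored at zero", {
  cfg <- default_config()
  yrs <- 2016:2020
  exp_tr <- make_expected("A", yrs, c(50, 50, 30, 50, 50))
  req <- structure(data.frame(country_id = "A", year = yrs,
                              u5mr_required = c(40, 40, 40, 40, 40),
                              arr_required = 0.05),
                   class = c("required_trajectory", "data.frame"))
  panel <- data.frame(country_id = "A", year = yrs, live_births = 1e5,
                      population = 4e6)
  lives <- lives_to_save(exp_tr, req, panel, cfg)
  expect_equal(lives$lives, c(1000, 1000, 0, 1000, 1000))

  # population denominator option
  cfg_pop <- run_config(alpha = 1, denominator = "population")
  lives_pop <- lives_to_save(exp_tr, req, panel, cfg_pop)
  expect_equal(lives_pop$lives, c(40000, 40000, 0, 40000, 40000))

  # year misalignment is an error
  req_bad <- req[req$year != 2018, ]
  expect_error(lives_to_save(exp_tr, req_bad, panel, cfg), "aligned")
})

test_that("per-year lives match a brute-force year-by-year evaluation", {
  cfg <- default_config()
  yrs <- 2016:2020
  required_rates <- 60 * (25 / 60)^((1:5) / 5)
  exp_tr <- make_expected("A", yrs, rep(60, 5))
  req <- structure(data.frame(country_id = "A", year = yrs,
                              u5mr_required = required_rates,
                              arr_required = 1 - (25 / 60)^(1 / 5)),
                   class = c("required_trajectory", "data.frame"))
  panel <- data.frame(country_id = "A", year = yrs, live_births = 123456,
                      population = 5e6)
  lives <- lives_to_save(exp_tr, req, panel, cfg)
  expect_equal(lives$lives,
               lives_oracle(rep(60, 5), required_rates, rep(123456, 5)),
               tolerance = 1e-12)
})

test_that("need costs lives by the income-group schedule", {
  cfg <- default_config()
  lives <- data.frame(country_id = rep(c("L", "U", "Z"), each = 2),
                      year = rep(2016:2017, 3),
                      lives = c(400, 600, 5, 5, 0, 0))
  groups <- c(L = "low", U = "upper-middle", Z = "high")
  need <- compute_need(lives, groups, cfg)

  expect_equal(need$need_usd[need$country_id == "L"], 1000 * 4205)
  expect_equal(need$need_usd[need$country_id == "U"], 10 * 10016)
  # zero lives cost nothing even without a schedule entry
  expect_equal(need$need_usd[need$country_id == "Z"], 0)

  # a high-income country with positive lives has no defined cost
  lives$lives[lives$country_id == "Z"] <- 1
  expect_error(compute_need(lives, groups, cfg), "high")
})

test_that("need is monotone in the expected trend and in the unit cost", {
  cfg <- default_config()
  yrs <- 2016:2030
  base_exp <- make_expected("A", yrs, rep(80, 15))
  req <- required_trajectory(80, cfg, base_exp, base_year = 2015)
  panel <- data.frame(country_id = "A", year = yrs, live_births = 2e5,
                      population = 6e6)
  groups <- c(A = "low")
  need_at <- function(expected_rates, cfg) {
    lv <- lives_to_save(make_expected("A", yrs, expected_rates), req, panel,
                        cfg)
    compute_need(lv, groups, cfg)$need_usd
  }
  n0 <- need_at(rep(80, 15), cfg)
  n1 <- need_at(rep(81, 15), cfg)
  expect_gt(n1, n0)

  cfg_costly <- run_config(alpha = 1,
                           cost_schedule = c("low" = 5000,
                                             "lower-middle" = 6496,
                                             "upper-middle" = 10016))
  expect_gt(need_at(rep(80, 15), cfg_costly), n0)
})
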