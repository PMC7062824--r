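# Sigmoid urbanization: the upper-limit rule grid, reference-pool selection,
# OLS fitting, projection ordering, and the urban/rural split.

sigmoid_series <- function(b, c, d, years = 1995:2015, base = 1995) {
  tibble::tibble(year = years, pu = b / (1 + exp(-c * ((years - base) - d))))
}

test_that("upper limits follow the 2015-share rule grid", {
  expect_equal(assign_upper_limit(0.65, "medium"), 0.80)
  expect_equal(assign_upper_limit(0.65, "fast"), 0.90)
  expect_equal(assign_upper_limit(0.65, "slow"), 0.75)
  expect_equal(assign_upper_limit(0.72, "slow"), 1.00)
  expect_equal(assign_upper_limit(0.72, "fast"), 1.00)
  expect_equal(assign_upper_limit(0.55, "fast"), 0.85)
  expect_equal(assign_upper_limit(0.55, "medium"), 0.80)
  expect_equal(assign_upper_limit(0.55, "slow"), 0.70)
  # boundary membership: lower bound inclusive
  expect_equal(assign_upper_limit(0.60, "fast"), 0.90)
  expect_equal(assign_upper_limit(0.70, "slow"), 1.00)
  expect_error(assign_upper_limit(1.2, "fast"), "inside")
  expect_error(assign_upper_limit(0.5, "rapid"), "level")
})

test_that("reference provinces obey the band and growth-similarity rules", {
  lin <- function(prov, from, to) {
    tibble::tibble(province = prov, year = 1995:2015,
                   pu = seq(from, to, length.out = 21))
  }
  hist <- dplyr::bind_rows(
    lin("target", 0.30, 0.55),    # 2015 share 0.55, increase 0.25
    lin("fastgrow", 0.30, 0.58),  # in (0.55, 0.60) with a larger increase: kept
    lin("toohigh", 0.40, 0.62),   # outside the +5% band
    lin("slowgrow", 0.40, 0.53)   # in (0.50, 0.55) with a smaller increase
  )
  refs <- select_reference_provinces("target", hist, "fast")
  expect_setequal(refs, "fastgrow")
  refs_slow <- select_reference_provinces("target", hist, "slow")
  expect_setequal(refs_slow, "slowgrow")
  expect_error(select_reference_provinces("nowhere", hist, "fast"),
               "no history")
})

test_that("OLS on the logit scale recovers the sigmoid parameters", {
  s <- sigmoid_series(0.8, 0.05, 30)
  fit <- fit_sigmoid(s, b = 0.8)
  expect_equal(fit$c, 0.05, tolerance = 1e-6)
  expect_equal(fit$d, 30, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(tidy(fit)$estimate, c(0.8, fit$c, fit$d))

  # two points fit exactly
  two <- sigmoid_series(0.9, 0.04, 25, years = c(2000, 2010))
  fit2 <- fit_sigmoid(two, 0.9)
  expect_equal(predict_sigmoid(fit2, c(2000, 2010)), two$pu, tolerance = 1e-12)

  expect_error(fit_sigmoid(tibble::tibble(year = 1:3, pu = c(0.5, 0.9, 0.95)),
                           b = 0.9), "increase b")
  expect_warning(fit_sigmoid(tibble::tibble(year = 1995:2000,
                                            pu = seq(0.5, 0.4, length.out = 6)),
                             b = 0.8), "declining")

  # noisy series: the estimated pace stays within 3 standard errors at n = 21
  withr::with_seed(9, {
    noisy <- s
    noisy$pu <- 0.8 * stats::plogis(0.05 * ((s$year - 1995) - 30) +
                                    rnorm(21, 0, 0.05))
    fitn <- fit_sigmoid(noisy, 0.8)
    expect_lt(abs(fitn$c - 0.05), 3 * fitn$se_c)
    expect_gt(fitn$residual_sd, 0)
  })
})

test_that("projected urbanization is bounded, anchored, and pace-ordered", {
  # three provinces engineered so the target has both fast and slow references
  hist <- dplyr::bind_rows(
    sigmoid_series(0.8, 0.050, 30) |> dplyr::mutate(province = "mid"),
    sigmoid_series(0.8, 0.065, 27) |> dplyr::mutate(province = "upper"),
    sigmoid_series(0.8, 0.040, 34) |> dplyr::mutate(province = "lower")
  )
  med <- project_urbanization(hist, "medium", years = 2010:2100)
  expect_true(all(med$pu > 0))
  b_by <- assign_upper_limit(hist$pu[hist$year == 2015 & hist$province == "mid"],
                             "medium")
  mid_med <- dplyr::filter(med, province == "mid")
  expect_true(all(mid_med$pu < b_by))
  obs15 <- hist$pu[hist$year == 2015 & hist$province == "mid"]
  expect_equal(mid_med$pu[mid_med$year == 2015], obs15, tolerance = 0.02)

  # provinces at the edge of the pool fall back with a warning; only the
  # middle province's ordering is under test here
  fast <- suppressWarnings(project_urbanization(hist, "fast", years = 2010:2100))
  slow <- suppressWarnings(project_urbanization(hist, "slow", years = 2010:2100))
  expect_gte(dplyr::filter(fast, province == "mid", year == 2050)$pu,
             dplyr::filter(slow, province == "mid", year == 2050)$pu)

  # empty reference pool falls back to the own-history fit with a warning
  lone <- dplyr::bind_rows(
    sigmoid_series(0.8, 0.05, 30) |> dplyr::mutate(province = "a"),
    sigmoid_series(0.5, 0.05, 35) |> dplyr::mutate(province = "faraway")
  )
  warns <- testthat::capture_warnings(
    project_urbanization(lone, "fast", years = 2010:2020))
  expect_true(any(grepl("falling back", warns)))
})

test_that("urban plus rural equals the total exactly", {
  totals <- tibble::tibble(province = "a", year = 2010:2012,
                           total = c(1e7, 1.1e7, 1.2e7))
  pu <- tibble::tibble(province = "a", year = 2010:2012,
                       pu = c(0.64, 0, 0.5))
  out <- split_urban_rural(totals, pu)
  expect_equal(out$urban[1], 6.4e6)
  expect_equal(out$rural[1], 3.6e6)
  expect_equal(out$urban[2], 0)          # PU = 0: everyone rural
  expect_equal(out$rural[2], 1.1e7)
  expect_equal(out$urban + out$rural, out$total)
  expect_error(split_urban_rural(dplyr::mutate(totals, total = -total), pu),
               "nonnegative")
  expect_error(split_urban_rural(totals, dplyr::mutate(pu, pu = pu + 2)),
               "\\[0, 1\\]")
})

test_that("additivity holds across a full scenario run", {
  w <- tiny_world()
  proj <- project_population(w$population, w$rates, assemble_ssp("SSP2", w),
                             years = 2010:2030)
  pu <- project_urbanization(w$urban_history, "medium", years = 2010:2030)
  ur <- split_urban_rural(provincial_totals(proj), pu)
  expect_equal(ur$urban + ur$rural, ur$total, tolerance = 1e-12)
  expect_equal(nrow(ur), 3 * 21)
})
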