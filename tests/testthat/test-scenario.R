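# Scenario path builders: anchor values, interpolation rules, level ordering,
# and the SSP level-assignment table.

tfr_at <- function(level, yr) {
  build_tfr_path(level)$tfr[build_tfr_path(level)$year == yr]
}

test_that("the medium TFR path hits its policy anchors", {
  expect_equal(tfr_at("medium", 2010), 1.6)
  expect_equal(tfr_at("medium", 2020), 1.8)
  expect_equal(tfr_at("medium", 2030), 1.65)
  # after 2030 the path compounds at the constant UN-medium annual factor
  g <- (1.802 / 1.706)^(1 / 70)
  expect_equal(tfr_at("medium", 2050), 1.65 * g^20, tolerance = 1e-12)
  expect_equal(tfr_at("medium", 2100), 1.65 * g^70, tolerance = 1e-12)
})

test_that("high and low TFR paths scale off the medium 2050 value", {
  g <- (1.802 / 1.706)^(1 / 70)
  med50 <- 1.65 * g^20
  expect_equal(tfr_at("high", 2020), 2.0)
  expect_equal(tfr_at("high", 2050), 1.25 * med50, tolerance = 1e-12)
  expect_equal(tfr_at("high", 2100), 1.25 * med50, tolerance = 1e-12)
  expect_equal(tfr_at("low", 2020), 1.8) # follows the medium rise to 2020
  expect_equal(tfr_at("low", 2050), 0.75 * med50, tolerance = 1e-12)
  expect_equal(tfr_at("low", 2100), 0.75 * med50, tolerance = 1e-12)
  expect_error(build_tfr_path("extreme"), "level")

  # level ordering from 2020 on; all paths total and finite
  yrs <- 2020:2100
  hi <- build_tfr_path("high", yrs)$tfr
  me <- build_tfr_path("medium", yrs)$tfr
  lo <- build_tfr_path("low", yrs)$tfr
  expect_true(all(hi >= me & me >= lo))
  expect_true(all(is.finite(c(hi, me, lo))))
  expect_equal(nrow(build_tfr_path("medium")), 91L)
})

test_that("life-expectancy paths apply the convergence-adjusted decade rate", {
  base <- tibble::tibble(province = rep(c("a", "b"), each = 2),
                         sex = rep(c("M", "F"), 2),
                         le = c(75, 80, 75, 80))
  # provincial LE equal to the national mean: exactly one year per decade
  path <- build_le_path("medium", base)
  a2020 <- dplyr::filter(path, province == "a", sex == "M", year == 2020)
  expect_equal(a2020$le, 76)

  disp <- tibble::tibble(province = c("a", "b"), sex = "M", le = c(70, 80))
  p <- build_le_path("medium", disp,
                     national_le = tibble::tibble(sex = "M", le = 75))
  # oracle: increment per decade is rate * national / provincial
  inc <- p |>
    dplyr::group_by(province) |>
    dplyr::summarise(inc = (le[year == 2020] - le[year == 2010]))
  expect_equal(inc$inc, c(75 / 70, 75 / 80), tolerance = 1e-12)
  # population-weighted mean growth lands between the two adjustments
  w <- c(0.5, 0.5)
  expect_equal(sum(w * inc$inc), 0.5 * (75 / 70 + 75 / 80))

  hi <- build_le_path("high", disp)
  lo <- build_le_path("low", disp)
  expect_true(all(dplyr::filter(lo, year == 2100)$le >
                  dplyr::filter(hi, year == 2100)$le))
  expect_true(all(diff(dplyr::filter(p, province == "a")$le) >= 0))
  expect_error(build_le_path("medium", dplyr::mutate(disp, le = -le)),
               "positive")
})

test_that("provincial migration scalings follow the income-by-level grid", {
  sc <- function(inc, lev, yr) {
    p <- build_provincial_migration_path(inc, lev)
    p$scaling[p$year == yr]
  }
  expect_true(all(build_provincial_migration_path("high", "high")$scaling == 0))
  expect_equal(sc("high", "medium", 2015), 0.5)
  expect_equal(sc("high", "medium", 2020), 0)
  expect_equal(sc("high", "low", 2030), 0)
  expect_equal(sc("medium", "medium", 2050), 0.5)
  expect_equal(sc("medium", "medium", 2075), 0.25)
  expect_equal(sc("medium", "medium", 2100), 0)
  expect_equal(sc("medium", "high", 2100), 0.5)
  expect_equal(sc("low", "high", 2050), 1.5)
  expect_equal(sc("low", "high", 2100), 1.5) # constant after the last anchor
  expect_equal(sc("low", "medium", 2080), 1)
  expect_equal(sc("low", "low", 2090), 0.5)
  expect_error(build_provincial_migration_path("rich", "medium"), "level")
})

test_that("international migration paths decay to zero with ordered magnitudes", {
  med <- build_international_migration_path("medium")
  expect_equal(med$netgim_permille[med$year == 2010], -0.3015)
  expect_equal(med$netgim_permille[med$year == 2050], -0.3015)
  expect_equal(med$netgim_permille[med$year == 2075], -0.3015 / 2)
  expect_equal(med$netgim_permille[med$year == 2100], 0)
  hi <- build_international_migration_path("high")
  lo <- build_international_migration_path("low")
  expect_equal(hi$netgim_permille[hi$year == 2010], -0.45225)
  expect_true(all(abs(hi$netgim_permille) >= abs(med$netgim_permille)))
  expect_true(all(abs(med$netgim_permille) >= abs(lo$netgim_permille)))
})

test_that("sex ratios at birth converge linearly to 1.07 in 2050", {
  p <- build_srb_path(c(a = 1.18, b = 1.07))
  expect_equal(p$srb[p$province == "a" & p$year == 2050], 1.07)
  expect_equal(p$srb[p$province == "a" & p$year == 2030], 1.125)
  expect_true(all(p$srb[p$province == "b"] == 1.07))
  expect_true(all(p$srb[p$year > 2050] == 1.07))
  expect_equal(p$bm + p$bf, rep(1, nrow(p)))
  expect_equal(p$bm / p$bf, p$srb)
  expect_error(build_srb_path(c(a = -1)), "positive")
})

test_that("education progression paths grow, cap, and route by income", {
  provs <- c("a", "b")
  trans <- education_transitions()
  g <- array(0.5, dim = c(2, 2, 6),
             dimnames = list(provs, c("M", "F"), trans$label))
  g[, , 4] <- 0.25; g[, , 5] <- 0.55; g[, , 6] <- 0.28
  growth <- matrix(c(0.01, 0.02), 2, 6, dimnames = list(provs, trans$label))

  lo <- build_education_path("low", g, growth)
  expect_true(all(lo$g[lo$year == 2100] == lo$g[lo$year == 2010]))

  me <- build_education_path("medium", g, growth)
  a_pj <- dplyr::filter(me, province == "a", sex == "M",
                        transition == "primary_to_junior")
  expect_equal(a_pj$g, pmin(0.5 * 1.01^(a_pj$year - 2010), 0.999),
               tolerance = 1e-12)
  # the senior-to-bachelor cap of 0.60 is reached and held
  a_sb <- dplyr::filter(me, province == "b", sex == "M",
                        transition == "senior_to_bachelor")
  expect_true(any(a_sb$g == 0.60))
  expect_true(all(a_sb$g[a_sb$year >= 2050] == 0.60))
  expect_true(all(me$g <= rep(trans$cap[match(me$transition, trans$label)])))

  # high level applies the largest cross-province growth rate everywhere
  hi <- build_education_path("high", g, growth)
  hi_a <- dplyr::filter(hi, province == "a", sex == "M",
                        transition == "primary_to_junior")
  expect_equal(hi_a$g, pmin(0.5 * 1.02^(hi_a$year - 2010), 0.999),
               tolerance = 1e-12)

  mix <- build_education_path("income_dependent", g, growth,
                              income_category = c("high", "low"))
  expect_equal(dplyr::filter(mix, province == "a")$g,
               dplyr::filter(hi, province == "a")$g)
  expect_equal(dplyr::filter(mix, province == "b")$g,
               dplyr::filter(lo, province == "b")$g)
})

test_that("assemble_ssp reproduces the level-assignment table for all SSPs", {
  w <- tiny_world()
  for (i in 1:5) {
    spec <- assemble_ssp(i, w)
    expect_s3_class(spec, "scenario_spec")
    expect_equal(spec$levels,
                 dplyr::filter(ssp_levels(), ssp == paste0("SSP", i)))
    # every path covers every projection year
    expect_setequal(unique(spec$tfr_path$year), 2010:2100)
    expect_setequal(unique(spec$le_path$year), 2010:2100)
    expect_false(any(is.na(tidy(spec)$value)))
  }
  expect_error(assemble_ssp("SSP9", w), "unknown ssp")

  # SSP4: the high-income province follows the high education path
  spec4 <- assemble_ssp(4, w)
  hi_path <- build_education_path("high", w$rates$g, w$rates$pr_growth)
  hi_prov <- w$config$provinces[w$config$income_category == "high"][1]
  expect_equal(
    dplyr::filter(spec4$education_path, province == hi_prov)$g,
    dplyr::filter(hi_path, province == hi_prov)$g)
})
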