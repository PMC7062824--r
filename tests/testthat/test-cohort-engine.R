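# The cohort-component engine: birth arithmetic, cohort advancement boundary
# rules, migration rebalancing, loop-oracle equivalence, and full projections.

zero_bundle <- function(nprov = 1L) {
  b <- random_rate_bundle(nprov)
  b$mor[] <- 0; b$netpim[] <- 0; b$g[] <- 0; b$fer[] <- 0
  b
}

test_that("births follow the fertility equation hand arithmetic", {
  provs <- "prov01"
  fer <- array(0, dim = c(1, 101, 7),
               dimnames = list(provs, as.character(0:100), as.character(1:7)))
  fem <- fer
  fem[1, 26, 3] <- 1000   # 1000 women aged 25, junior high
  fer[1, 26, 3] <- 0.1
  out <- compute_births(fem, fer, bm = c(prov01 = 0.517),
                        bf = c(prov01 = 0.483))
  expect_equal(out$births, 100)
  expect_equal(out$male, 51.7)
  expect_equal(out$female, 48.3)

  none <- compute_births(fem, 0 * fer, c(prov01 = 0.5), c(prov01 = 0.5))
  expect_equal(none$births, 0)
  expect_error(compute_births(fem, fer, c(prov01 = 0.6), c(prov01 = 0.6)),
               "sum to 1")
})

test_that("total births are invariant to permuting province labels", {
  withr::with_seed(21, {
    b <- random_rate_bundle(3L)
    pop <- random_pop_array(3L)
  })
  fem <- pop[, "F", , ]
  out <- compute_births(fem, b$fer, b$bm, b$bf)
  perm <- c(3, 1, 2)
  out_p <- compute_births(fem[perm, , ], b$fer[perm, , ],
                          b$bm[perm], b$bf[perm])
  expect_equal(sum(out$births), sum(out_p$births), tolerance = 1e-12)
  expect_equal(out$births[perm], out_p$births)
})

test_that("zero rates age the population by exactly one year, conserving mass", {
  withr::with_seed(22, pop <- random_pop_array(2L))
  b <- zero_bundle(2L)
  nxt <- age_and_educate(pop, b$mor, b$netpim, b$g, 0)
  expect_equal(sum(nxt), sum(pop), tolerance = 1e-9)
  # each closed cohort moves up one age
  expect_equal(unname(nxt[, , 2:100, ]), unname(pop[, , 1:99, ]))
  # the open group absorbs ages 99 and 100+
  expect_equal(nxt[, , 101, ], pop[, , 100, ] + pop[, , 101, ])
  expect_true(all(nxt[, , 1, ] == 0))
})

test_that("the open 100+ interval pools survivors of 99 and 100+", {
  pop <- random_pop_array(1L) * 0
  pop[1, 1, 100, 2] <- 100  # age 99
  pop[1, 1, 101, 2] <- 50   # 100+
  b <- zero_bundle(1L)
  nxt <- age_and_educate(pop, b$mor, b$netpim, b$g, 0)
  expect_equal(nxt[1, 1, 101, 2], 150)
})

test_that("survival and migration multiply in the stated order", {
  pop <- random_pop_array(1L) * 0
  pop[1, 1, 31, 4] <- 1000  # age 30, senior high
  b <- zero_bundle(1L)
  b$mor[1, 1, 31, 4] <- 0.1
  b$netpim[1, 1, 31, 4] <- 0.05
  nxt <- age_and_educate(pop, b$mor, b$netpim, b$g, 0)
  expect_equal(nxt[1, 1, 32, 4], 1000 * 0.9 * 1.05)
})

test_that("education transitions fire only at gate ages and split branches", {
  trans <- education_transitions()
  pop <- random_pop_array(1L) * 0
  pop[1, 1, 19, 4] <- 1000  # age 18 senior high: the college/bachelor gate
  pop[1, 1, 41, 4] <- 500   # age 40 senior high: no gate
  b <- zero_bundle(1L)
  b$g[1, 1, 4] <- 0.2  # senior -> college
  b$g[1, 1, 5] <- 0.5  # senior -> bachelor
  nxt <- age_and_educate(pop, b$mor, b$netpim, b$g, 0)
  expect_equal(nxt[1, 1, 20, 5], 200)
  expect_equal(nxt[1, 1, 20, 6], 500)
  expect_equal(nxt[1, 1, 20, 4], 300)   # remainder stays senior
  expect_equal(nxt[1, 1, 42, 4], 500)   # off-gate cohort just ages
})

test_that("rebalancing cuts back the larger flow side proportionally", {
  provs <- sprintf("prov%02d", 1:3)
  dn <- list(provs, c("M", "F"), as.character(0:100), as.character(1:7))
  pop <- array(1, dim = c(3, 2, 101, 7), dimnames = dn)
  npim <- array(0, dim = dim(pop), dimnames = dn)
  cell <- 2 * 101 * 7 # persons at risk per province
  npim[1, , , ] <- 150 / cell
  npim[2, , , ] <- 50 / cell
  npim[3, , , ] <- -100 / cell
  adj <- rebalance_migration(npim, pop)
  flows <- sapply(1:3, function(p) sum(adj[p, , , ] * pop[p, , , ]))
  expect_equal(flows, c(75, 25, -100), tolerance = 1e-9)
  expect_equal(attr(adj, "inflow_factor"), 0.5)

  balanced <- npim
  balanced[1, , , ] <- 100 / cell
  balanced[2, , , ] <- 0
  adj2 <- rebalance_migration(balanced, pop)
  expect_equal(as.vector(adj2), as.vector(balanced))

  # property: flows sum to zero on random inputs
  withr::with_seed(33, {
    for (i in 1:5) {
      b <- random_rate_bundle(3L)
      pop_r <- random_pop_array(3L)
      adj_r <- rebalance_migration(b$netpim, pop_r)
      total <- sum(sapply(1:3, function(p) sum(adj_r[p, , , ] * pop_r[p, , , ])))
      expect_lt(abs(total), 1e-9)
    }
  })
})

test_that("the vectorized engine matches the scalar-loop oracle", {
  withr::with_seed(44, {
    for (rep in 1:3) {
      pop <- random_pop_array(3L)
      b <- random_rate_bundle(3L)
      netgim <- runif(1, -0.001, 0.001)
      fast <- age_and_educate(pop, b$mor, b$netpim, b$g, netgim)
      births <- compute_births(pop[, "F", , ], b$fer, b$bm, b$bf)
      fast[, "M", 1, 1] <- births$male
      fast[, "F", 1, 1] <- births$female
      slow <- naive_advance(pop, b$mor, b$netpim, b$g, netgim, b$bm, b$bf,
                            b$fer)
      expect_equal(as.vector(fast), as.vector(slow), tolerance = 1e-9)
    }
  })
})

test_that("projections are deterministic, nonnegative, and calibrated", {
  w <- tiny_world()
  spec <- assemble_ssp("SSP2", w)
  p1 <- project_population(w$population, w$rates, spec, years = 2010:2025)
  p2 <- project_population(w$population, w$rates, spec, years = 2010:2025)
  expect_identical(p1$counts, p2$counts)
  expect_true(all(p1$counts$count >= 0))
  expect_equal(unique(p1$counts$year), 2010:2025)

  # calibration round-trip at a projected year: recompute TFR/LE from the
  # calibrated matrices the engine would use in 2020
  arr <- popproj:::as_pop_array(
    population_state(dplyr::filter(p1$counts, year == 2019)[-1], 2019))
  fem <- arr[, "F", , ]
  tfr_target <- spec$tfr_path$tfr[spec$tfr_path$year == 2020]
  fer_2020 <- calibrate_fertility(w$rates$fer, tfr_target, fem)
  expect_equal(implied_tfr(fer_2020, fem), tfr_target, tolerance = 1e-9)
  le_row <- dplyr::filter(spec$le_path, year == 2020, province == "prov01",
                          sex == "F")
  cal <- calibrate_mortality(w$rates$mor["prov01", "F", , ], le_row$le)
  expect_equal(life_expectancy(rowMeans(cal)), le_row$le, tolerance = 1e-6)

  expect_error(project_population(w$population, w$rates, spec,
                                  years = 2011:2020), "base year")
})

test_that("high-fertility scenarios dominate low-fertility ones", {
  w <- tiny_world()
  p3 <- project_population(w$population, w$rates, assemble_ssp("SSP3", w),
                           years = 2010:2060)
  p1 <- project_population(w$population, w$rates, assemble_ssp("SSP1", w),
                           years = 2010:2060)
  t3 <- yearly_totals(p3); t1 <- yearly_totals(p1)
  expect_gt(t3$total[t3$year == 2060], t1$total[t1$year == 2060])
  # births each year are weakly larger under the high-fertility scenario
  b3 <- dplyr::filter(p3$counts, age == 0) |>
    dplyr::group_by(year) |> dplyr::summarise(n = sum(count))
  b1 <- dplyr::filter(p1$counts, age == 0) |>
    dplyr::group_by(year) |> dplyr::summarise(n = sum(count))
  expect_true(all(b3$n[b3$year >= 2020] >= b1$n[b1$year >= 2020]))
})
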