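# Synthetic census-like world with known ground truth: base-year population
# pyramids, Gompertz-Makeham mortality calibrated to known life expectancies,
# fertility schedules calibrated to known TFRs, logistic urbanization
# histories with known (b, c, d), and a small multi-province raster world.
# Every downstream calibration step is testable against these truths.

#' Configure a synthetic world
#'
#' @param n_provinces Number of provinces (>= 2).
#' @param income_category Character vector of per-province income categories
#'   (`"high"`, `"medium"`, `"low"`); defaults to a round-robin assignment.
#' @param base_year Base calendar year of the census-like snapshot.
#' @param raster_shape Integer `c(rows, cols)` of the fine population raster.
#' @param coarse_factor Side length, in fine pixels, of one coarse
#'   urban-fraction cell; must divide both raster dimensions.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A `world_config` list.
#' @export
#' @examples
#' world_config(n_provinces = 3, raster_shape = c(24, 24), coarse_factor = 6)
world_config <- function(n_provinces = 5, income_category = NULL,
                         base_year = 2010, raster_shape = c(120L, 120L),
                         coarse_factor = 12L, seed = 1L) {
  if (n_provinces < 2) rlang::abort("n_provinces must be >= 2")
  if (length(raster_shape) != 2L || any(raster_shape < coarse_factor)) {
    rlang::abort("raster_shape must be c(rows, cols), each >= coarse_factor")
  }
  if (any(raster_shape %% coarse_factor != 0)) {
    rlang::abort("raster_shape must be divisible by coarse_factor")
  }
  if (is.null(income_category)) {
    income_category <- rep(c("high", "medium", "low"), length.out = n_provinces)
  }
  if (length(income_category) != n_provinces ||
      !all(income_category %in% c("high", "medium", "low"))) {
    rlang::abort("income_category must name high/medium/low for every province")
  }
  structure(list(
    n_provinces = as.integer(n_provinces),
    provinces = sprintf("prov%02d", seq_len(n_provinces)),
    income_category = income_category,
    base_year = as.integer(base_year),
    raster_shape = as.integer(raster_shape),
    coarse_factor = as.integer(coarse_factor),
    seed = as.integer(seed)
  ), class = "world_config")
}

#' Draw the ground-truth parameters of a synthetic world
#'
#' @param config A [world_config()].
#' @return A tibble with one row per province: true TFR, true male/female life
#'   expectancy, true sigmoid urbanization parameters (b, c, d; d in years
#'   since 1995) and the true sex ratio at birth.
#' @export
generate_ground_truth <- function(config) {
  stopifnot(inherits(config, "world_config"))
  withr::with_seed(config$seed * 1009L + 1L, {
    n <- config$n_provinces
    tibble::tibble(
      province = config$provinces,
      income_category = config$income_category,
      tfr = runif(n, 1.3, 2.0),
      le_male = runif(n, 70, 76),
      le_female = runif(n, 70, 76) + runif(n, 3, 6),
      srb = runif(n, 1.10, 1.20),
      sigmoid_b = runif(n, 0.65, 0.95),
      sigmoid_c = runif(n, 0.04, 0.09),
      sigmoid_d = runif(n, 10, 30)
    )
  })
}

#' Generate the base-year population
#'
#' Builds a census-like snapshot: per-province totals of a few million people,
#' a smooth gamma-shaped age pyramid with multiplicative noise, a slightly
#' male-biased sex split, and an education distribution consistent with stage
#' entry ages (e.g. nobody holds a bachelor's degree below age 19).
#'
#' @param config A [world_config()].
#' @return A [population_state()] for the base year.
#' @export
generate_base_population <- function(config) {
  stopifnot(inherits(config, "world_config"))
  stages <- education_stages()
  # stationary-ish attainment profile used as stage weights, masked by entry age
  adult_share <- c(0.05, 0.25, 0.35, 0.15, 0.08, 0.10, 0.02)
  withr::with_seed(config$seed * 1009L + 2L, {
    rows <- purrr::map(seq_len(config$n_provinces), function(p) {
      total <- runif(1, 2e6, 8e6)
      agew <- stats::dgamma(AGES + 1, shape = 2.2, scale = 18) *
        runif(101, 0.9, 1.1)
      agew <- agew / sum(agew)
      male_share <- pmin(pmax(0.512 + rnorm(101, 0, 0.004), 0.45), 0.55)
      purrr::map(AGES, function(a) {
        adm <- stages$entry_age <= a
        w <- adult_share * adm * runif(7, 0.8, 1.2)
        w <- w / sum(w)
        n_a <- total * agew[a + 1]
        tibble::tibble(
          province = config$provinces[p],
          sex = rep(c("M", "F"), each = 7L),
          age = a,
          edu = rep(1:7, 2L),
          count = c(n_a * male_share[a + 1] * w,
                    n_a * (1 - male_share[a + 1]) * w)
        )
      }) %>% dplyr::bind_rows()
    }) %>% dplyr::bind_rows()
  })
  population_state(rows, year = config$base_year)
}

# Gompertz-Makeham yearly death probabilities for ages 0..100.
gompertz_makeham_qx <- function(makeham = 2e-4, b = 3e-5, theta = 0.095,
                                infant = 0.004) {
  hazard <- makeham + b * exp(theta * AGES)
  qx <- 1 - exp(-hazard)
  qx[1] <- qx[1] + infant # infant-mortality bump
  pmin(qx, 1)
}

#' Generate the base-year demographic rate matrices
#'
#' Fertility: a unimodal schedule over ages 15--49 differentiated across
#' education stages by fixed multipliers, scaled per province so the implied
#' TFR equals the ground-truth TFR exactly. Mortality: Gompertz-Makeham
#' schedules per sex scaled by [calibrate_mortality()] to hit the ground-truth
#' life expectancies. Also draws education progression probabilities (with
#' historical annual growth rates), age-structured provincial net-migration
#' rates signed by income category, and the sex ratio at birth.
#'
#' @param config A [world_config()].
#' @param truth Ground truth from [generate_ground_truth()].
#' @param population Base population from [generate_base_population()].
#' @return A `rate_set` list with elements `fer`, `mor`, `g`, `pr_growth`,
#'   `netpim`, `srb`, `provinces`, `income_category`.
#' @export
generate_rates <- function(config, truth, population) {
  stopifnot(inherits(config, "world_config"))
  n <- config$n_provinces
  provs <- config$provinces
  arr <- as_pop_array(population)
  female <- arr[, "F", , , drop = TRUE]
  if (n == 1L) dim(female) <- c(1L, 101L, 7L)
  dim(female) <- c(n, 101L, 7L)

  trans <- education_transitions()
  withr::with_seed(config$seed * 1009L + 3L, {
    # --- fertility ---
    age_shape <- stats::dnorm(AGES, mean = 27, sd = 6)
    age_shape[AGES < 15 | AGES > 49] <- 0
    edu_mult <- c(1.3, 1.2, 1.1, 1.0, 0.85, 0.7, 0.55)
    fer <- array(0, dim = c(n, 101L, 7L),
                 dimnames = list(provs, as.character(AGES), as.character(1:7)))
    for (p in seq_len(n)) {
      noise <- runif(101, 0.9, 1.1)
      for (e in 1:7) fer[p, , e] <- age_shape * noise * edu_mult[e]
      fem_p <- female[p, , , drop = FALSE]
      base_tfr <- implied_tfr(fer[p, , , drop = FALSE], fem_p)
      fer[p, , ] <- fer[p, , ] * (truth$tfr[p] / base_tfr)
    }

    # --- mortality (constant across education stages) ---
    mor <- array(0, dim = c(n, 2L, 101L, 7L),
                 dimnames = list(provs, c("M", "F"), as.character(AGES),
                                 as.character(1:7)))
    for (p in seq_len(n)) {
      q_m <- gompertz_makeham_qx(b = 3e-5 * runif(1, 0.8, 1.2))
      q_f <- gompertz_makeham_qx(b = 1.6e-5 * runif(1, 0.8, 1.2),
                                 infant = 0.0035)
      cal_m <- calibrate_mortality(q_m, truth$le_male[p])
      cal_f <- calibrate_mortality(q_f, truth$le_female[p])
      for (e in 1:7) {
        mor[p, "M", , e] <- cal_m
        mor[p, "F", , e] <- cal_f
      }
    }

    # --- education progression (per province x sex x transition) ---
    g_base <- c(0.985, 0.96, 0.85, 0.20, 0.35, 0.10)
    g <- array(0, dim = c(n, 2L, 6L),
               dimnames = list(provs, c("M", "F"), trans$label))
    for (p in seq_len(n)) {
      g[p, "M", ] <- pmin(g_base * runif(6, 0.88, 1.0), trans$cap)
      g[p, "F", ] <- pmin(g_base * runif(6, 0.90, 1.0), trans$cap)
    }
    pr_growth <- matrix(runif(n * 6L, 0.002, 0.012), nrow = n,
                        dimnames = list(provs, trans$label))

    # --- provincial net migration, peaked at working entry ages ---
    mig_level <- c(high = 0.006, medium = 0.001, low = -0.005)
    age_profile <- exp(-((AGES - 26) / 9)^2)
    netpim <- array(0, dim = c(n, 2L, 101L, 7L),
                    dimnames = dimnames(mor))
    for (p in seq_len(n)) {
      lev <- mig_level[[config$income_category[p]]] * runif(1, 0.7, 1.3)
      for (s in 1:2) for (e in 1:7) netpim[p, s, , e] <- lev * age_profile
    }
  })
  structure(list(
    fer = fer, mor = mor, g = g, pr_growth = pr_growth, netpim = netpim,
    srb = setNames(truth$srb, provs),
    provinces = provs, income_category = config$income_category
  ), class = "rate_set")
}

#' Base-year life expectancy implied by a rate set
#'
#' @param rates A `rate_set`.
#' @return Tibble with `province`, `sex`, `le` (years), plus the
#'   population-unweighted national mean per sex as attribute `"national"`.
#' @export
base_life_expectancy <- function(rates) {
  out <- tidyr::expand_grid(province = rates$provinces, sex = c("M", "F")) %>%
    dplyr::mutate(le = purrr::map2_dbl(.data$province, .data$sex, function(p, s) {
      life_expectancy(rowMeans(rates$mor[p, s, , ]))
    }))
  attr(out, "national") <- out %>%
    dplyr::group_by(.data$sex) %>%
    dplyr::summarise(le = mean(.data$le), .groups = "drop")
  out
}

#' Generate provincial urbanization histories 1995--2015
#'
#' Each province's urban share follows its ground-truth logistic curve
#' `b / (1 + exp(-c * (t - d)))` in years since 1995, optionally perturbed by
#' Gaussian noise on the logit scale so values stay strictly inside (0, b).
#'
#' @param config A [world_config()].
#' @param truth Ground truth from [generate_ground_truth()].
#' @param logit_noise_sd Standard deviation of the logit-scale noise
#'   (0 gives the exact curve).
#' @return Tibble with `province`, `year` (1995--2015), `pu`.
#' @export
generate_urbanization_history <- function(config, truth, logit_noise_sd = 0.05) {
  stopifnot(inherits(config, "world_config"))
  years <- 1995:2015
  withr::with_seed(config$seed * 1009L + 4L, {
    purrr::pmap(truth[c("province", "sigmoid_b", "sigmoid_c", "sigmoid_d")],
      function(province, sigmoid_b, sigmoid_c, sigmoid_d) {
        t <- years - 1995
        z <- sigmoid_c * (t - sigmoid_d) +
          rnorm(length(t), 0, logit_noise_sd)
        tibble::tibble(province = province, year = years,
                       pu = sigmoid_b * stats::plogis(z))
      }) %>% dplyr::bind_rows()
  })
}

#' Generate the synthetic raster world
#'
#' Builds the downscaling inputs: a Voronoi partition of the grid into
#' provinces, a water mask, a population weight field concentrated around
#' province centres, a Euclidean distance-to-roads field (roads join province
#' centres), an inverse-distance population-gravity field, and a coarse
#' urban-land-fraction series on decadal epochs 2010--2100.
#'
#' @param config A [world_config()].
#' @return A `raster_world` list: matrices `pop_raw`, `road_dist`, `gravity`,
#'   integer matrix `province_id` (values index `config$provinces`), logical
#'   `water`, and 3-d array `urban_fraction` `[coarse_row, coarse_col, epoch]`
#'   with epoch years in `dimnames`.
#' @export
generate_raster_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  nr <- config$raster_shape[1]; nc <- config$raster_shape[2]
  n <- config$n_provinces
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  withr::with_seed(config$seed * 1009L + 5L, {
    cr <- runif(n, 0.15, 0.85) * nr
    cc <- runif(n, 0.15, 0.85) * nc
    # Voronoi province partition
    d2 <- sapply(seq_len(n), function(p) (rows - cr[p])^2 + (cols - cc[p])^2)
    province_id <- matrix(max.col(-d2, ties.method = "first"), nr, nc)

    # water: low tail of a smooth blob field, never at province centres
    nblob <- max(3L, n)
    bx <- runif(nblob, 1, nr); by <- runif(nblob, 1, nc)
    bs <- runif(nblob, 0.08, 0.2) * max(nr, nc)
    field <- Reduce(`+`, lapply(seq_len(nblob), function(k) {
      exp(-((rows - bx[k])^2 + (cols - by[k])^2) / (2 * bs[k]^2))
    }))
    water <- field < stats::quantile(field, 0.06)
    water[cbind(round(cr), round(cc))] <- FALSE

    # population weight: distance decay from own centre, lognormal texture
    dist_centre <- sqrt(d2[cbind(seq_len(nr * nc),
                                 as.vector(province_id))])
    dim(dist_centre) <- c(nr, nc)
    pop_raw <- exp(-dist_centre / (0.18 * max(nr, nc))) *
      matrix(stats::rlnorm(nr * nc, 0, 0.6), nr, nc)
    pop_raw[water] <- 0

    # roads: straight segments linking successive province centres
    road_px <- do.call(rbind, lapply(seq_len(n - 1L), function(k) {
      steps <- seq(0, 1, length.out = 2L * max(nr, nc))
      cbind(pmin(pmax(round(cr[k] + steps * (cr[k + 1] - cr[k])), 1), nr),
            pmin(pmax(round(cc[k] + steps * (cc[k + 1] - cc[k])), 1), nc))
    }))
    road_px <- unique(road_px)
    px <- cbind(as.vector(rows), as.vector(cols))
    road_dist <- matrix(
      sqrt(apply((outer(px[, 1], road_px[, 1], "-"))^2 +
                 (outer(px[, 2], road_px[, 2], "-"))^2, 1, min)),
      nr, nc)

    # gravity: inverse distance to the population-weighted centroid of
    # each pixel's own province
    gravity <- matrix(0, nr, nc)
    for (p in seq_len(n)) {
      inp <- province_id == p & !water
      w <- pop_raw[inp]
      gr <- sum(rows[inp] * w) / sum(w)
      gc <- sum(cols[inp] * w) / sum(w)
      sel <- province_id == p
      gravity[sel] <- 1 / (1 + sqrt((rows[sel] - gr)^2 + (cols[sel] - gc)^2))
    }

    # coarse urban fractions: denser cells start more urban, all ramp upward
    ncr <- nr %/% config$coarse_factor; ncc <- nc %/% config$coarse_factor
    epochs <- seq(2010L, 2100L, by = 10L)
    cell_pop <- matrix(0, ncr, ncc)
    for (i in seq_len(ncr)) for (j in seq_len(ncc)) {
      ri <- ((i - 1) * config$coarse_factor + 1):(i * config$coarse_factor)
      cj <- ((j - 1) * config$coarse_factor + 1):(j * config$coarse_factor)
      cell_pop[i, j] <- sum(pop_raw[ri, cj])
    }
    f0 <- 0.45 * (rank(cell_pop) / length(cell_pop))^2 *
      matrix(runif(ncr * ncc, 0.7, 1.0), ncr, ncc)
    f_end <- pmin(f0 + matrix(runif(ncr * ncc, 0.05, 0.40), ncr, ncc), 0.95)
    urban_fraction <- array(0, dim = c(ncr, ncc, length(epochs)),
                            dimnames = list(NULL, NULL, as.character(epochs)))
    for (k in seq_along(epochs)) {
      lam <- (epochs[k] - 2010) / 90
      urban_fraction[, , k] <- (1 - lam) * f0 + lam * f_end
    }
  })
  if (!all(seq_len(n) %in% province_id[!water])) {
    rlang::abort("degenerate raster world: a province has no land pixel")
  }
  structure(list(
    pop_raw = pop_raw, province_id = province_id, water = water,
    road_dist = road_dist, gravity = gravity, urban_fraction = urban_fraction,
    config = config
  ), class = "raster_world")
}

#' Generate a complete synthetic world
#'
#' Bundles every input the projection pipeline needs: ground truth, base
#' population, rate matrices, urbanization histories and the raster world.
#'
#' @param config A [world_config()].
#' @param logit_noise_sd Noise level of the urbanization histories.
#' @return A `synthetic_world` list with elements `config`, `truth`,
#'   `population`, `rates`, `urban_history`, `raster`.
#' @export
#' @examples
#' w <- synthetic_world(world_config(n_provinces = 3,
#'                                   raster_shape = c(24, 24),
#'                                   coarse_factor = 6, seed = 42))
#' province_totals(w$population)
synthetic_world <- function(config = world_config(), logit_noise_sd = 0.05) {
  truth <- generate_ground_truth(config)
  population <- generate_base_population(config)
  rates <- generate_rates(config, truth, population)
  structure(list(
    config = config,
    truth = truth,
    population = population,
    rates = rates,
    urban_history = generate_urbanization_history(config, truth, logit_noise_sd),
    raster = generate_raster_world(config)
  ), class = "synthetic_world")
}
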