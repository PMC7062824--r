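# Year-by-year assumption trajectories, 2010-2100, for fertility, mortality,
# migration, sex ratio at birth and educational progression. Anchor points are
# interpolated linearly in calendar year unless a rule says otherwise.

PROJECTION_YEARS <- 2010:2100

# UN medium TFR growth 2030 (1.706) -> 2100 (1.802), applied as a constant
# annual multiplicative factor.
UN_TFR_GROWTH <- (1.802 / 1.706)^(1 / 70)

interp_anchors <- function(years, anchor_years, anchor_values) {
  approx(anchor_years, anchor_values, xout = years, rule = 2)$y
}

#' Build a national TFR trajectory
#'
#' The medium path starts at the adjusted 2010 baseline of 1.6 births/woman,
#' peaks at 1.8 in 2020 under the cumulative effect of the two-child policy,
#' settles to the policy-incentive level of 1.65 in 2030, and thereafter grows
#' at the constant UN-medium annual factor `(1.802/1.706)^(1/70)`. The high
#' (fully open policy) path reaches 2.0 in 2020, is 25% above the medium value
#' in 2050 and constant afterwards. The low path follows the medium rise to
#' 2020, is 25% below the medium value in 2050 and constant afterwards.
#'
#' @param level `"low"`, `"medium"` or `"high"`.
#' @param years Years to evaluate (default 2010--2100).
#' @return Tibble with `year` and `tfr` (births per woman).
#' @export
#' @examples
#' build_tfr_path("medium") |> dplyr::filter(year %in% c(2020, 2030))
build_tfr_path <- function(level, years = PROJECTION_YEARS) {
  match_level(level)
  medium <- function(y) {
    out <- interp_anchors(y, c(2010, 2020, 2030), c(1.6, 1.8, 1.65))
    late <- y > 2030
    out[late] <- 1.65 * UN_TFR_GROWTH^(y[late] - 2030)
    out
  }
  all_years <- PROJECTION_YEARS
  med50 <- medium(2050)
  tfr <- switch(level,
    medium = medium(all_years),
    high = {
      v <- interp_anchors(all_years, c(2010, 2020, 2050),
                          c(1.6, 2.0, 1.25 * med50))
      v[all_years > 2050] <- 1.25 * med50
      v
    },
    low = {
      v <- medium(all_years)
      mid <- all_years > 2020 & all_years <= 2050
      v[mid] <- interp_anchors(all_years[mid], c(2020, 2050),
                               c(medium(2020), 0.75 * med50))
      v[all_years > 2050] <- 0.75 * med50
      v
    })
  tibble::tibble(year = all_years, tfr = tfr) %>%
    dplyr::filter(.data$year %in% years)
}

#' Build provincial life-expectancy trajectories
#'
#' Life expectancy in every province rises linearly at a base rate of one year
#' per decade (medium; 0.5 under high mortality, 1.5 under low mortality),
#' adjusted by the ratio of the national to the provincial base-year life
#' expectancy so that provinces below the national level converge upward.
#'
#' @param level Mortality level: `"low"`, `"medium"` or `"high"`.
#' @param base_le Tibble with `province`, `sex`, `le`: base-year (2010) life
#'   expectancies.
#' @param national_le Optional tibble with `sex`, `le` giving the national
#'   base-year values; defaults to the mean over provinces per sex.
#' @param years Years to evaluate.
#' @return Tibble with `year`, `province`, `sex`, `le`.
#' @export
build_le_path <- function(level, base_le, national_le = NULL,
                          years = PROJECTION_YEARS) {
  match_level(level)
  if (any(base_le$le <= 0)) rlang::abort("base life expectancies must be positive")
  base_rate <- switch(level, high = 0.5, medium = 1.0, low = 1.5)
  if (is.null(national_le)) {
    national_le <- base_le %>%
      dplyr::group_by(.data$sex) %>%
      dplyr::summarise(le_nat = mean(.data$le), .groups = "drop")
  } else {
    national_le <- dplyr::rename(national_le, le_nat = "le")
  }
  if (any(national_le$le_nat <= 0)) {
    rlang::abort("national base life expectancy must be positive")
  }
  base_le %>%
    dplyr::inner_join(national_le, by = "sex") %>%
    dplyr::mutate(increment = base_rate / 10 * .data$le_nat / .data$le) %>%
    tidyr::expand_grid(year = years) %>%
    dplyr::mutate(le = .data$le + .data$increment * (.data$year - 2010)) %>%
    dplyr::select("year", "province", "sex", "le")
}

# Anchor tables for the provincial-migration scaling paths, by income category
# and migration level: each entry is (years, scalings); paths are piecewise
# linear and constant after the last anchor.
netpim_anchor_table <- function() {
  list(
    high = list(
      high   = list(y = c(2010, 2100), s = c(0, 0)),
      medium = list(y = c(2010, 2020, 2100), s = c(1, 0, 0)),
      low    = list(y = c(2010, 2030, 2100), s = c(1, 0, 0))
    ),
    medium = list(
      high   = list(y = c(2010, 2100), s = c(1, 0.5)),
      medium = list(y = c(2010, 2050, 2100), s = c(1, 0.5, 0)),
      low    = list(y = c(2010, 2030, 2100), s = c(1, 0.5, 0))
    ),
    low = list(
      high   = list(y = c(2010, 2050), s = c(1, 1.5)),
      medium = list(y = c(2010, 2100), s = c(1, 1)),
      low    = list(y = c(2010, 2050), s = c(1, 0.5))
    )
  )
}

#' Build the provincial net-migration scaling path
#'
#' Returns the multiplicative scaling applied to a province's base-year net
#' provincial in-migration rate (NetPIM) in each year, determined by the
#' province's income category and the scenario migration level. High-income
#' provinces phase migration out (population-ceiling policies), medium-income
#' provinces decay toward zero, low-income provinces move to 150%/100%/50% of
#' the current rate under the high/medium/low level.
#'
#' @param income_category `"high"`, `"medium"` or `"low"`.
#' @param level Migration level: `"high"`, `"medium"` or `"low"`.
#' @param years Years to evaluate.
#' @return Tibble with `year` and `scaling`.
#' @export
#' @examples
#' build_provincial_migration_path("medium", "medium") |>
#'   dplyr::filter(year %in% c(2050, 2075, 2100))
build_provincial_migration_path <- function(income_category, level,
                                            years = PROJECTION_YEARS) {
  match_level(income_category)
  match_level(level)
  a <- netpim_anchor_table()[[income_category]][[level]]
  tibble::tibble(year = years, scaling = interp_anchors(years, a$y, a$s))
}

#' Build the international net-migration rate path
#'
#' The medium path holds the 2010 national net international migration rate of
#' -0.3015 per thousand (the mean of the 2005--2010 and 2010--2015 estimates)
#' constant through 2050, then decays linearly to zero in 2100. High and low
#' paths are 50% larger and smaller in magnitude throughout.
#'
#' @param level `"low"`, `"medium"` or `"high"`.
#' @param years Years to evaluate.
#' @return Tibble with `year` and `netgim_permille` (per thousand persons).
#' @export
build_international_migration_path <- function(level, years = PROJECTION_YEARS) {
  match_level(level)
  base <- -0.3015
  medium <- interp_anchors(years, c(2010, 2050, 2100), c(base, base, 0))
  mult <- switch(level, low = 0.5, medium = 1.0, high = 1.5)
  tibble::tibble(year = years, netgim_permille = mult * medium)
}

#' Build sex-ratio-at-birth paths
#'
#' Each province's sex ratio at birth moves linearly from its base-year value
#' to the long-term policy target of 1.07 in 2050 and stays constant after.
#'
#' @param base_srb Named numeric vector: base-year male-to-female birth ratio
#'   per province.
#' @param years Years to evaluate.
#' @return Tibble with `year`, `province`, `srb`, and the newborn male and
#'   female fractions `bm = srb/(1+srb)`, `bf = 1/(1+srb)`.
#' @export
build_srb_path <- function(base_srb, years = PROJECTION_YEARS) {
  if (any(base_srb <= 0)) rlang::abort("base sex ratios must be positive")
  purrr::imap(base_srb, function(r0, prov) {
    srb <- interp_anchors(years, c(2010, 2050, 2100), c(r0, 1.07, 1.07))
    tibble::tibble(year = years, province = prov, srb = srb)
  }) %>%
    dplyr::bind_rows() %>%
    dplyr::mutate(bm = .data$srb / (1 + .data$srb), bf = 1 / (1 + .data$srb))
}

#' Build educational progression-rate paths
#'
#' Under the medium level each progression rate grows at its province-specific
#' historical annual growth rate; the low level freezes rates at their
#' base-year values; the high level applies the largest cross-province growth
#' rate (per transition) everywhere. Every path is capped at the transition's
#' policy ceiling (99.9% for compulsory-education transitions, 30%/60%/30% for
#' the post-senior transitions) and held constant once the cap is reached.
#' `income_dependent` (the SSP4 pattern) routes high/medium/low-income
#' provinces through the high/medium/low path respectively.
#'
#' @param level `"low"`, `"medium"`, `"high"` or `"income_dependent"`.
#' @param base_g Base progression array `[province, sex, transition]` (the
#'   `g` element of a `rate_set`).
#' @param growth Matrix `[province, transition]` of historical annual growth
#'   rates (e.g. 0.01 for 1%/year).
#' @param income_category Per-province income categories (required for
#'   `income_dependent`).
#' @param years Years to evaluate.
#' @return Tibble with `year`, `province`, `sex`, `transition`, `g`.
#' @export
build_education_path <- function(level, base_g, growth, income_category = NULL,
                                 years = PROJECTION_YEARS) {
  match_level(level, c("low", "medium", "high", "income_dependent"))
  trans <- education_transitions()
  provs <- dimnames(base_g)[[1]]
  if (level == "income_dependent") {
    if (is.null(income_category)) {
      rlang::abort("income_dependent education needs income categories")
    }
    lev_by_prov <- setNames(income_category, provs)
  } else {
    lev_by_prov <- setNames(rep(level, length(provs)), provs)
  }
  max_growth <- apply(growth, 2L, max)
  grid <- tidyr::expand_grid(province = provs, sex = c("M", "F"),
                             transition = trans$label)
  purrr::pmap(grid, function(province, sex, transition) {
    g0 <- base_g[province, sex, transition]
    cap <- trans$cap[match(transition, trans$label)]
    rate <- switch(lev_by_prov[[province]],
                   low = 0,
                   medium = growth[province, transition],
                   high = max_growth[[transition]])
    g <- pmin(g0 * (1 + rate)^(years - 2010), cap)
    if (any(g < 0)) {
      rlang::warn("progression rate clamped at 0")
      g <- pmax(g, 0)
    }
    tibble::tibble(year = years, province = province, sex = sex,
                   transition = transition, g = g)
  }) %>% dplyr::bind_rows()
}
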