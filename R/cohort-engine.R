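# The recursive multidimensional cohort-component engine. One projection year:
# calibrate rates to scenario targets, compute births from last year's women,
# then survive / migrate / educate every cohort forward one age.
#
# Within-year order per cohort: survival, provincial migration, education
# transition, then national (international) migration, matching the
# multiplicative structure of the state equations.

#' Newborns by province and sex
#'
#' Births are produced by the previous year's women aged 15--49 across all
#' education stages at the current year's fertility rates, and are split into
#' sexes by the newborn fractions `bm`/`bf`. Newborns enter at age 0 in the
#' illiterate stage.
#'
#' @param female_prev Female population array `[province, age, edu]` (previous
#'   year), or a full `[province, sex, age, edu]` array from which the female
#'   slice is taken.
#' @param fer Fertility array `[province, age, edu]`, births per woman-year.
#' @param bm,bf Named numeric: newborn male/female fractions per province
#'   (must sum to 1 per province).
#' @return Tibble with `province`, `births`, `male`, `female`.
#' @export
compute_births <- function(female_prev, fer, bm, bf) {
  if (length(dim(female_prev)) == 4L) {
    female_prev <- female_prev[, "F", , , drop = FALSE]
    dim(female_prev) <- dim(female_prev)[c(1, 3, 4)]
  }
  stopifnot(all(dim(female_prev) == dim(fer)))
  provs <- dimnames(fer)[[1]]
  if (any(abs(bm[provs] + bf[provs] - 1) > 1e-12)) {
    rlang::abort("newborn sex fractions must sum to 1")
  }
  births <- vapply(seq_along(provs), function(p) {
    sum(female_prev[p, , ] * fer[p, , ])
  }, numeric(1))
  tibble::tibble(
    province = provs,
    births = births,
    male = births * unname(bm[provs]),
    female = births * unname(bf[provs])
  )
}

#' Advance a population one year through survival, migration and education
#'
#' For every province, sex and education stage, survivors of age a (factor
#' 1 - MOR, then 1 + NetPIM) either remain in their stage or progress along a
#' stage transition whose gate age is a, landing at age a + 1; the whole
#' result is scaled by the national migration factor 1 + NetGIM. The open
#' "100+" group receives survivors of both age 99 and 100+ itself. The
#' illiterate stage has no feeder; senior high feeds both college and
#' bachelor; bachelor feeds master.
#'
#' @param prev Population array `[province, sex, age, edu]` (previous year).
#' @param mor Mortality array, same shape, yearly death probabilities.
#' @param netpim Provincial net-migration rate array, same shape (> -1).
#' @param g Progression array `[province, sex, transition]` (probabilities at
#'   the gate ages of [education_transitions()]).
#' @param netgim National net international migration rate (fraction, e.g.
#'   -0.0003).
#' @return Array of the same shape holding ages 1..100+; age 0 is zero (filled
#'   by [compute_births()]).
#' @export
age_and_educate <- function(prev, mor, netpim, g, netgim = 0) {
  stopifnot(all(dim(prev) == dim(mor)), all(dim(prev) == dim(netpim)))
  if (any(netpim <= -1)) rlang::abort("NetPIM rates must exceed -1")
  trans <- education_transitions()
  nprov <- dim(prev)[1]
  nxt <- array(0, dim = dim(prev), dimnames = dimnames(prev))
  for (p in seq_len(nprov)) for (s in 1:2) {
    M <- prev[p, s, , ]                       # 101 x 7
    surv <- M * (1 - mor[p, s, , ]) * (1 + netpim[p, s, , ])
    g_out <- matrix(0, 101L, 7L)
    for (e in seq_len(nrow(trans))) {
      g_out[trans$gate_age[e] + 1L, trans$from[e]] <-
        g_out[trans$gate_age[e] + 1L, trans$from[e]] + g[p, s, e]
    }
    stay <- surv * (1 - g_out)
    res <- matrix(0, 101L, 7L)
    res[2:101, ] <- stay[1:100, ]             # cohorts advance one age
    res[101, ] <- res[101, ] + stay[101, ]    # 100+ also retains itself
    for (e in seq_len(nrow(trans))) {
      a_i <- trans$gate_age[e] + 1L
      res[a_i + 1L, trans$to[e]] <- res[a_i + 1L, trans$to[e]] +
        surv[a_i, trans$from[e]] * g[p, s, e]
    }
    nxt[p, s, , ] <- res * (1 + netgim)
  }
  if (any(nxt < 0)) {
    rlang::warn("negative cohort counts clamped to zero")
    nxt[nxt < 0] <- 0
  }
  nxt
}

#' Rebalance provincial migration so implied person-flows sum to zero
#'
#' Net migration rates alone need not balance across provinces; the implied
#' person-flows (rate times at-risk population) are summed per province, and
#' whichever side is larger in total -- inflows or outflows -- is scaled down
#' multiplicatively so the national sum of flows is zero, preserving relative
#' proportions within that side.
#'
#' @param netpim Net-migration rate array `[province, sex, age, edu]`.
#' @param prev At-risk (previous-year) population array, same shape.
#' @return Adjusted rate array; attributes `"inflow_factor"` /
#'   `"outflow_factor"` record the applied scalings.
#' @export
rebalance_migration <- function(netpim, prev) {
  stopifnot(all(dim(netpim) == dim(prev)))
  nprov <- dim(netpim)[1]
  flows <- vapply(seq_len(nprov), function(p) {
    sum(netpim[p, , , ] * prev[p, , , ])
  }, numeric(1))
  inflow <- sum(flows[flows > 0])
  outflow <- -sum(flows[flows < 0])
  fin <- 1; fout <- 1
  if (inflow > 0 && outflow > 0) {
    if (inflow > outflow) fin <- outflow / inflow
    if (outflow > inflow) fout <- inflow / outflow
  } else if (inflow > 0 || outflow > 0) {
    # one-sided migration cannot balance: suppress it entirely
    if (inflow > 0) fin <- 0 else fout <- 0
  }
  out <- netpim
  for (p in seq_len(nprov)) {
    f <- if (flows[p] > 0) fin else if (flows[p] < 0) fout else 1
    if (f != 1) out[p, , , ] <- out[p, , , ] * f
  }
  attr(out, "inflow_factor") <- fin
  attr(out, "outflow_factor") <- fout
  out
}

# Scenario paths pre-split by year for fast lookup inside the loop.
split_by_year <- function(df) split(df, df$year)

#' Project a population 2010--2100 under a scenario
#'
#' Runs the recursive projection: every year the base fertility matrix is
#' rescaled to the scenario TFR, the base mortality schedules are rescaled by
#' life-table bisection to the scenario life-expectancy targets, provincial
#' migration is scaled by the scenario path and rebalanced to zero net
#' national flow, progression rates and the sex ratio at birth follow their
#' paths, and the state advances through [compute_births()] and
#' [age_and_educate()].
#'
#' @param population Base-year [population_state()].
#' @param rates Base `rate_set` (from [generate_rates()]).
#' @param scenario A `scenario_spec` (from [assemble_ssp()]).
#' @param years Years to project (first must be the base year of
#'   `population`).
#' @param rebalance Rebalance provincial migration flows (default TRUE).
#' @return A `population_projection`: list with `counts` (tidy tibble: `year`,
#'   `province`, `sex`, `age`, `edu`, `count`), `calibration` (per-year log of
#'   fertility/mortality scalars and rebalancing factors), `ssp`, `years`.
#' @export
project_population <- function(population, rates, scenario,
                               years = PROJECTION_YEARS, rebalance = TRUE) {
  base_year <- attr(population, "year")
  if (years[1] != base_year) {
    rlang::abort(sprintf("projection must start at the base year %d", base_year))
  }
  arr <- as_pop_array(population)
  provs <- dimnames(arr)[[1]]
  if (!identical(provs, sort(rates$provinces))) {
    rlang::abort("population and rates cover different provinces")
  }
  ord <- match(provs, rates$provinces)
  fer_base <- rates$fer[ord, , , drop = FALSE]
  mor_base <- rates$mor[ord, , , , drop = FALSE]
  netpim_base <- rates$netpim[ord, , , , drop = FALSE]

  tfr_by <- split_by_year(scenario$tfr_path)
  le_by <- split_by_year(scenario$le_path)
  mig_by <- split_by_year(scenario$migration_path)
  gim_by <- split_by_year(scenario$netgim_path)
  srb_by <- split_by_year(scenario$srb_path)
  edu_by <- split_by_year(scenario$education_path)
  trans <- education_transitions()

  counts <- vector("list", length(years))
  counts[[1]] <- dplyr::mutate(tibble::as_tibble(population), year = years[1],
                               .before = 1L)
  cal_log <- vector("list", length(years) - 1L)

  for (i in seq_along(years)[-1]) {
    yr <- years[i]
    yk <- as.character(yr)
    for (nm in c("tfr", "le", "mig", "gim", "srb", "edu")) {
      if (is.null(get(paste0(nm, "_by"))[[yk]])) {
        rlang::abort(sprintf("scenario paths do not cover year %d", yr))
      }
    }
    female_prev <- arr[, "F", , , drop = FALSE]
    dim(female_prev) <- dim(arr)[c(1, 3, 4)]
    dimnames(female_prev) <- dimnames(arr)[c(1, 3, 4)]

    # fertility to TFR target
    fer_yr <- tryCatch(
      calibrate_fertility(fer_base, tfr_by[[yk]]$tfr, female_prev),
      error = function(e) rlang::abort(
        sprintf("year %d fertility calibration failed: %s", yr, conditionMessage(e))))

    # mortality to LE targets, per province x sex
    le_yr <- le_by[[yk]]
    mor_yr <- mor_base
    mor_scale <- matrix(NA_real_, length(provs), 2L,
                        dimnames = list(provs, c("M", "F")))
    for (p in seq_along(provs)) for (s in c("M", "F")) {
      tgt <- le_yr$le[le_yr$province == provs[p] & le_yr$sex == s]
      cal <- tryCatch(
        calibrate_mortality(mor_base[p, s, , ], tgt),
        error = function(e) rlang::abort(
          sprintf("year %d mortality calibration failed (%s/%s): %s",
                  yr, provs[p], s, conditionMessage(e))))
      mor_yr[p, s, , ] <- cal
      mor_scale[p, s] <- attr(cal, "scale")
    }

    # provincial migration scaling + rebalancing
    mig_yr <- mig_by[[yk]]
    netpim_yr <- netpim_base
    for (p in seq_along(provs)) {
      sc <- mig_yr$scaling[mig_yr$province == provs[p]]
      netpim_yr[p, , , ] <- netpim_base[p, , , ] * sc
    }
    if (rebalance) netpim_yr <- rebalance_migration(netpim_yr, arr)

    # education progression for this year
    edu_yr <- edu_by[[yk]]
    g_yr <- array(0, dim = c(length(provs), 2L, 6L),
                  dimnames = list(provs, c("M", "F"), trans$label))
    g_yr[cbind(match(edu_yr$province, provs),
               match(edu_yr$sex, c("M", "F")),
               match(edu_yr$transition, trans$label))] <- edu_yr$g

    # sex ratio at birth and international migration
    srb_yr <- srb_by[[yk]]
    bm <- setNames(srb_yr$bm, srb_yr$province)
    bf <- setNames(srb_yr$bf, srb_yr$province)
    netgim <- gim_by[[yk]]$netgim_permille / 1000

    births <- compute_births(female_prev, fer_yr, bm, bf)
    nxt <- age_and_educate(arr, mor_yr, netpim_yr, g_yr, netgim)
    nxt[, "M", 1L, 1L] <- births$male[match(provs, births$province)]
    nxt[, "F", 1L, 1L] <- births$female[match(provs, births$province)]

    arr <- nxt
    counts[[i]] <- dplyr::mutate(
      tibble::as_tibble(pop_array_to_state(arr, yr)), year = yr, .before = 1L)
    cal_log[[i - 1L]] <- tibble::tibble(
      year = yr,
      fertility_scale = attr(fer_yr, "scale"),
      mortality_scale_mean = mean(mor_scale),
      inflow_factor = attr(netpim_yr, "inflow_factor") %||% 1,
      outflow_factor = attr(netpim_yr, "outflow_factor") %||% 1,
      netgim = netgim
    )
  }
  structure(list(
    counts = dplyr::bind_rows(counts),
    calibration = dplyr::bind_rows(cal_log),
    ssp = scenario$ssp,
    years = years
  ), class = "population_projection")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.population_projection <- function(x, ...) {
  tot <- yearly_totals(x)
  cat(sprintf("<population_projection> %s, %d-%d, %d province(s)\n",
              x$ssp %||% "?", min(x$years), max(x$years),
              length(unique(x$counts$province))))
  cat(sprintf("  total: %.0f (start) -> %.0f (end)\n",
              tot$total[1], tot$total[nrow(tot)]))
  invisible(x)
}

#' Yearly national totals of a projection
#'
#' @param projection A `population_projection`.
#' @return Tibble with `year`, `total`.
#' @export
yearly_totals <- function(projection) {
  projection$counts %>%
    dplyr::group_by(.data$year) %>%
    dplyr::summarise(total = sum(.data$count), .groups = "drop")
}

#' Yearly provincial totals of a projection
#'
#' @param projection A `population_projection`.
#' @return Tibble with `year`, `province`, `total`.
#' @export
provincial_totals <- function(projection) {
  projection$counts %>%
    dplyr::group_by(.data$year, .data$province) %>%
    dplyr::summarise(total = sum(.data$count), .groups = "drop")
}

#' @exportS3Method generics::tidy
tidy.population_projection <- function(x, ...) x$counts

#' @exportS3Method generics::glance
glance.population_projection <- function(x, ...) {
  tot <- yearly_totals(x)
  tibble::tibble(
    ssp = x$ssp %||% NA_character_,
    n_years = length(x$years),
    n_provinces = length(unique(x$counts$province)),
    total_start = tot$total[1],
    total_end = tot$total[nrow(tot)],
    peak_year = tot$year[which.max(tot$total)],
    peak_total = max(tot$total)
  )
}
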