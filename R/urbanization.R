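# Sigmoid urbanization: PU(T) = b / (1 + exp(-c (T - d))). The pace c and
# inflection d are estimated by OLS on the logit-linearized series; the upper
# limit b comes from a rule table keyed on the 2015 urban share.

#' Upper limit of the urbanization rate
#'
#' Rule grid keyed on a province's 2015 urban share: at or above 70% the limit
#' is 100% under every assumption; in \[60%, 70%) it is 90/80/75% under the
#' fast/medium/slow assumption; below 60% it is 85/80/70%. Lower bounds are
#' inclusive, upper bounds exclusive.
#'
#' @param pu_2015 Urban population share in 2015, in (0, 1).
#' @param assumption `"fast"`, `"medium"` or `"slow"`.
#' @return The upper limit b as a fraction.
#' @export
#' @examples
#' assign_upper_limit(0.65, "medium") # 0.80
assign_upper_limit <- function(pu_2015, assumption) {
  match_level(assumption, c("fast", "medium", "slow"))
  if (!is.numeric(pu_2015) || any(pu_2015 <= 0) || any(pu_2015 >= 1)) {
    rlang::abort("pu_2015 must lie strictly inside (0, 1)")
  }
  grid <- rbind(fast = c(1.00, 0.90, 0.85),
                medium = c(1.00, 0.80, 0.80),
                slow = c(1.00, 0.75, 0.70))
  row_of <- function(pu) if (pu >= 0.70) 1L else if (pu >= 0.60) 2L else 3L
  vapply(pu_2015, function(pu) grid[assumption, row_of(pu)], numeric(1))
}

#' Select reference provinces for the fast/slow urbanization fit
#'
#' Under the fast assumption the reference pool holds provinces whose 2015
#' urban share lies strictly within 5 percentage points *above* the target's,
#' excluding those whose 1995--2015 urbanization increase was smaller than the
#' target's; the slow assumption mirrors this below the target, excluding
#' larger increases.
#'
#' @param target Province name to be projected.
#' @param histories Tibble with `province`, `year`, `pu` covering 1995--2015.
#' @param assumption `"fast"` or `"slow"`.
#' @return Character vector of reference province names (possibly empty).
#' @export
select_reference_provinces <- function(target, histories, assumption) {
  match_level(assumption, c("fast", "slow"))
  ends <- histories %>%
    dplyr::filter(.data$year %in% c(1995L, 2015L)) %>%
    tidyr::pivot_wider(names_from = "year", values_from = "pu",
                       names_prefix = "y") %>%
    dplyr::mutate(delta = .data$y2015 - .data$y1995)
  tgt <- dplyr::filter(ends, .data$province == target)
  if (nrow(tgt) != 1L) rlang::abort(paste0("no history for province ", target))
  pool <- dplyr::filter(ends, .data$province != target)
  if (assumption == "fast") {
    pool <- pool %>%
      dplyr::filter(.data$y2015 > tgt$y2015, .data$y2015 < tgt$y2015 + 0.05,
                    .data$delta >= tgt$delta)
  } else {
    pool <- pool %>%
      dplyr::filter(.data$y2015 < tgt$y2015, .data$y2015 > tgt$y2015 - 0.05,
                    .data$delta <= tgt$delta)
  }
  pool$province
}

#' Fit the sigmoid urbanization curve by OLS
#'
#' With the upper limit b fixed, the curve is linear on the logit scale:
#' `log(PU / (b - PU)) = c (T - d)`. An ordinary least-squares regression of
#' the logit on time gives the pace c as the slope and the inflection
#' `d = -intercept / c`.
#'
#' @param series Tibble with `year` and `pu`; all `pu` must lie in (0, b).
#' @param b Upper limit of the urbanization rate.
#' @param base_year Year at which T = 0 (default 1995).
#' @return A `sigmoid_fit` object: parameters `b`, `c`, `d`, `base_year`,
#'   fitted years, `r_squared`, residuals and source provinces.
#' @export
fit_sigmoid <- function(series, b, base_year = 1995) {
  if (any(series$pu <= 0) || any(series$pu >= b)) {
    rlang::abort("urban shares must lie strictly inside (0, b); increase b")
  }
  tt <- series$year - base_year
  y <- log(series$pu / (b - series$pu))
  fit <- lm(y ~ tt)
  cc <- unname(coef(fit)[2]); icpt <- unname(coef(fit)[1])
  if (!is.finite(cc) || cc <= 0) {
    rlang::warn("fitted pace c <= 0: declining urbanization is outside the sigmoid model")
  }
  res <- stats::residuals(fit)
  r2 <- if (stats::var(y) > 0) 1 - sum(res^2) / sum((y - mean(y))^2) else 1
  structure(list(
    b = b, c = cc, d = -icpt / cc, base_year = base_year,
    n = length(y), r_squared = r2, residual_sd = stats::sd(res),
    se_c = tryCatch(suppressWarnings(summary(fit)$coefficients[2, 2]),
                    error = function(e) NA_real_),
    source = attr(series, "source") %||% "own-history"
  ), class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("<sigmoid_fit> b = %.3f, c = %.4f, d = %.2f (T since %d), R^2 = %.4f, n = %d\n",
              x$b, x$c, x$d, x$base_year, x$r_squared, x$n))
  invisible(x)
}

#' Evaluate a fitted sigmoid at calendar years
#'
#' @param fit A `sigmoid_fit`.
#' @param years Calendar years.
#' @return Urban shares `b / (1 + exp(-c (T - d)))`.
#' @export
predict_sigmoid <- function(fit, years) {
  fit$b * stats::plogis(fit$c * ((years - fit$base_year) - fit$d))
}

#' @exportS3Method generics::tidy
tidy.sigmoid_fit <- function(x, ...) {
  tibble::tibble(term = c("b", "c", "d"),
                 estimate = c(x$b, x$c, x$d),
                 std.error = c(NA_real_, x$se_c, NA_real_))
}

#' @exportS3Method generics::glance
glance.sigmoid_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, sigma = x$residual_sd, nobs = x$n,
                 base_year = x$base_year, source = x$source)
}

# Pooled logit OLS for c over reference provinces (target's b), with d
# re-anchored so the curve passes through the target's 2015 observation.
fit_pooled_sigmoid <- function(target, refs, histories, b, base_year = 1995) {
  ref_series <- dplyr::filter(histories, .data$province %in% refs)
  usable <- dplyr::filter(ref_series, .data$pu > 0, .data$pu < b)
  if (nrow(usable) < nrow(ref_series)) {
    rlang::warn("reference observations at or above the target's upper limit dropped")
  }
  if (nrow(usable) < 2L) return(NULL)
  tt <- usable$year - base_year
  y <- log(usable$pu / (b - usable$pu))
  cc <- unname(coef(lm(y ~ tt))[2])
  if (!is.finite(cc) || cc <= 0) return(NULL)
  pu15 <- histories$pu[histories$province == target & histories$year == 2015]
  y15 <- log(pu15 / (b - pu15))
  structure(list(
    b = b, c = cc, d = (2015 - base_year) - y15 / cc, base_year = base_year,
    n = length(y), r_squared = NA_real_, residual_sd = NA_real_,
    se_c = NA_real_, source = paste(refs, collapse = ",")
  ), class = "sigmoid_fit")
}

#' Project provincial urbanization rates
#'
#' Under the medium assumption each province's curve is fitted to its own
#' 1995--2015 history with its rule-table upper limit. Under fast/slow the
#' pace c is fitted on the pooled logit-transformed histories of the reference
#' provinces (selected by [select_reference_provinces()]) and the inflection d
#' is re-anchored through the province's own 2015 value; if the reference pool
#' is empty (or unusable) the fit falls back to the province's own history
#' with a warning.
#'
#' @param histories Tibble with `province`, `year`, `pu` covering 1995--2015.
#' @param assumption `"fast"`, `"medium"` or `"slow"`, recycled per province,
#'   or a named vector per province (e.g. the SSP4 income-dependent pattern).
#' @param years Years to project (default 2010--2100).
#' @return Tibble with `province`, `year`, `assumption`, `pu`; the underlying
#'   `sigmoid_fit`s are attached as attribute `"fits"`.
#' @export
project_urbanization <- function(histories, assumption = "medium",
                                 years = PROJECTION_YEARS) {
  provs <- sort(unique(histories$province))
  if (is.null(names(assumption))) {
    assumption <- setNames(rep(assumption, length.out = length(provs)), provs)
  }
  fits <- list()
  out <- purrr::map(provs, function(prov) {
    asm <- assumption[[prov]]
    match_level(asm, c("fast", "medium", "slow"))
    own <- dplyr::filter(histories, .data$province == prov)
    pu15 <- own$pu[own$year == 2015]
    b <- assign_upper_limit(pu15, asm)
    fit <- NULL
    if (asm != "medium") {
      refs <- select_reference_provinces(prov, histories, asm)
      if (length(refs) > 0L) {
        fit <- fit_pooled_sigmoid(prov, refs, histories, b)
      }
      if (is.null(fit)) {
        rlang::warn(sprintf(
          "province %s: empty/unusable %s reference pool, falling back to own history",
          prov, asm))
      }
    }
    if (is.null(fit)) fit <- fit_sigmoid(own, b)
    fits[[prov]] <<- fit
    tibble::tibble(province = prov, year = years, assumption = asm,
                   pu = predict_sigmoid(fit, years))
  }) %>% dplyr::bind_rows()
  attr(out, "fits") <- fits
  out
}

#' Split projected totals into urban and rural populations
#'
#' Urban population is the provincial total times the urbanization rate;
#' rural is the remainder, so urban + rural equals the total exactly.
#'
#' @param totals Tibble with `province`, `year`, `total`.
#' @param pu_path Tibble with `province`, `year`, `pu`.
#' @return Tibble with `province`, `year`, `total`, `pu`, `urban`, `rural`.
#' @export
split_urban_rural <- function(totals, pu_path) {
  if (any(totals$total < 0)) rlang::abort("totals must be nonnegative")
  if (any(pu_path$pu < 0 | pu_path$pu > 1)) {
    rlang::abort("urbanization rates must lie in [0, 1]")
  }
  totals %>%
    dplyr::inner_join(dplyr::select(pu_path, "province", "year", "pu"),
                      by = c("province", "year")) %>%
    dplyr::mutate(urban = .data$total * .data$pu,
                  rural = .data$total - .data$urban)
}
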