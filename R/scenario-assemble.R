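# Assembling one SSP's full assumption bundle from the path builders.

#' Assemble a full SSP scenario specification
#'
#' Looks up the level assignments for the requested SSP (see [ssp_levels()])
#' and builds every assumption trajectory for 2010--2100: national TFR,
#' provincial life expectancy by sex, provincial net-migration scalings,
#' the national international migration rate, sex ratios at birth, and
#' educational progression rates. SSP4 education is routed through the
#' provinces' income categories.
#'
#' @param ssp `"SSP1"`..`"SSP5"` (or 1..5).
#' @param world A `synthetic_world` (or any list with `rates` and `config`).
#' @param years Years the paths must cover.
#' @return A `scenario_spec` list with the level assignments and path tibbles
#'   `tfr_path`, `le_path`, `migration_path`, `netgim_path`, `srb_path`,
#'   `education_path`.
#' @export
#' @examples
#' w <- synthetic_world(world_config(n_provinces = 2, raster_shape = c(24, 24),
#'                                   coarse_factor = 6))
#' spec <- assemble_ssp("SSP2", w)
#' spec$levels
assemble_ssp <- function(ssp, world, years = PROJECTION_YEARS) {
  if (is.numeric(ssp)) ssp <- paste0("SSP", ssp)
  lev <- dplyr::filter(ssp_levels(), .data$ssp == !!ssp)
  if (nrow(lev) != 1L) {
    rlang::abort(paste0("unknown ssp: ", ssp, " (expected SSP1..SSP5)"))
  }
  rates <- world$rates
  base_le <- base_life_expectancy(rates)
  migration_path <- purrr::map2(
    rates$provinces, rates$income_category,
    function(p, inc) {
      build_provincial_migration_path(inc, lev$migration, years) %>%
        dplyr::mutate(province = p)
    }) %>% dplyr::bind_rows()
  structure(list(
    ssp = ssp,
    levels = lev,
    provinces = rates$provinces,
    income_category = rates$income_category,
    tfr_path = build_tfr_path(lev$fertility, years),
    le_path = build_le_path(lev$mortality, base_le,
                            national_le = attr(base_le, "national"),
                            years = years),
    migration_path = migration_path,
    netgim_path = build_international_migration_path(lev$migration, years),
    srb_path = build_srb_path(rates$srb, years),
    education_path = build_education_path(lev$education, rates$g,
                                          rates$pr_growth,
                                          rates$income_category, years)
  ), class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> %s: fertility %s, mortality %s, migration %s, education %s\n",
              x$ssp, x$levels$fertility, x$levels$mortality,
              x$levels$migration, x$levels$education))
  invisible(x)
}

#' Tidy a scenario specification into one long path table
#'
#' @param x A `scenario_spec`.
#' @param ... Unused.
#' @return Tibble with `year`, `province` (NA for national paths),
#'   `variable`, `value`.
#' @exportS3Method generics::tidy
tidy.scenario_spec <- function(x, ...) {
  dplyr::bind_rows(
    x$tfr_path %>%
      dplyr::transmute(year = .data$year, province = NA_character_,
                       variable = "tfr", value = .data$tfr),
    x$le_path %>%
      dplyr::transmute(year = .data$year, province = .data$province,
                       variable = paste0("le_", .data$sex), value = .data$le),
    x$migration_path %>%
      dplyr::transmute(year = .data$year, province = .data$province,
                       variable = "netpim_scaling", value = .data$scaling),
    x$netgim_path %>%
      dplyr::transmute(year = .data$year, province = NA_character_,
                       variable = "netgim_permille",
                       value = .data$netgim_permille),
    x$srb_path %>%
      dplyr::transmute(year = .data$year, province = .data$province,
                       variable = "srb", value = .data$srb),
    x$education_path %>%
      dplyr::transmute(year = .data$year, province = .data$province,
                       variable = paste0("pr_", .data$transition, "_", .data$sex),
                       value = .data$g)
  )
}
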