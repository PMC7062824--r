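# End-to-end orchestration: synthetic world -> scenario -> cohort projection
# -> urbanization -> downscaling -> self-consistency validation -> files.

#' Pipeline configuration
#'
#' @param ssp Scenario, `"SSP1"`..`"SSP5"`.
#' @param rcp Urban-fraction scenario, must form an admissible pair with
#'   `ssp` (see [admissible_ssp_rcp()]).
#' @param start,end Projection years (2010 <= start < end <= 2100).
#' @param seed Master seed; all randomness flows from it.
#' @param n_provinces,raster_shape,coarse_factor Synthetic-world size.
#' @param outdir Output directory (NULL = write nothing).
#' @param write_yearly_csv Write the per-province-year population CSVs.
#' @param write_grids Write yearly ASCII grids.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(ssp = "SSP2", rcp = "RCP6", start = 2010,
                            end = 2100, seed = 1L, n_provinces = 5L,
                            raster_shape = c(120L, 120L), coarse_factor = 12L,
                            outdir = NULL, write_yearly_csv = FALSE,
                            write_grids = FALSE) {
  if (is.numeric(ssp)) ssp <- paste0("SSP", ssp)
  adm <- admissible_ssp_rcp()
  if (!any(adm$ssp == ssp & adm$rcp == rcp)) {
    rlang::abort(sprintf("inadmissible scenario pair %s-%s", ssp, rcp))
  }
  if (start < 2010 || end > 2100 || start >= end) {
    rlang::abort("years must satisfy 2010 <= start < end <= 2100")
  }
  structure(list(ssp = ssp, rcp = rcp, start = as.integer(start),
                 end = as.integer(end), seed = as.integer(seed),
                 n_provinces = as.integer(n_provinces),
                 raster_shape = as.integer(raster_shape),
                 coarse_factor = as.integer(coarse_factor),
                 outdir = outdir, write_yearly_csv = write_yearly_csv,
                 write_grids = write_grids),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full projection and downscaling pipeline
#'
#' Generates a synthetic world, assembles the SSP scenario, projects the
#' population, projects urbanization under the SSP's pace assumption
#' (fast for SSP1/SSP5, medium for SSP2, slow for SSP3, income-dependent for
#' SSP4), splits totals into urban/rural, downscales onto the raster, and
#' verifies that the per-province grid sums reproduce the projected provincial
#' totals in every year. Optionally writes every data record plus a manifest
#' with MD5 checksums.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_result` list: `world`, `scenario`, `projection`,
#'   `urbanization`, `urban_rural`, `grids`, `consistency` (max absolute
#'   provincial grid-sum error per year, persons), `manifest` (tibble of
#'   written files and checksums, empty if nothing written).
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(pipeline_config(end = 2030, raster_shape = c(36, 36),
#'                                     coarse_factor = 6))
#' max(res$consistency$max_abs_error)
#' }
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  years <- config$start:config$end
  wc <- world_config(n_provinces = config$n_provinces,
                     raster_shape = config$raster_shape,
                     coarse_factor = config$coarse_factor,
                     seed = config$seed)
  world <- synthetic_world(wc)
  scenario <- assemble_ssp(config$ssp, world, years = years)
  projection <- project_population(world$population, world$rates, scenario,
                                   years = years)

  assumption <- ssp_urbanization_assumption(config$ssp,
                                            world$config$income_category)
  if (length(assumption) > 1L) names(assumption) <- world$config$provinces
  pu <- project_urbanization(world$urban_history, assumption, years = years)
  ur <- split_urban_rural(provincial_totals(projection), pu)

  base_grid <- build_base_grid(world$raster$pop_raw, world$raster$water,
                               world$raster$road_dist, world$raster$gravity)
  grids <- downscale_series(base_grid, ur, world$raster,
                            ssp = config$ssp, rcp = config$rcp)

  # the pipeline's own consistency check: grid sums == projected totals
  agg <- aggregate_grid(grids, world$raster$province_id, world$raster$water,
                        provinces = world$config$provinces)
  consistency <- agg %>%
    dplyr::inner_join(provincial_totals(projection) %>%
                        dplyr::rename(projected = "total"),
                      by = c("year", "province")) %>%
    dplyr::group_by(.data$year) %>%
    dplyr::summarise(max_abs_error = max(abs(.data$total - .data$projected)),
                     .groups = "drop")

  manifest <- tibble::tibble(file = character(), md5 = character())
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- character()
    p_total <- file.path(config$outdir, "Pop_TOTAL.csv")
    write_pop_total(projection, p_total)
    paths <- c(paths, p_total)
    p_pu <- file.path(config$outdir, sprintf("Urbanization_%s.csv", config$ssp))
    utils::write.csv(pu, p_pu, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p_pu)
    p_fit <- file.path(config$outdir, sprintf("Urbanization_fits_%s.json", config$ssp))
    fits <- attr(pu, "fits")
    jsonlite::write_json(purrr::map(fits, function(f) {
      list(b = f$b, c = f$c, d = f$d, r_squared = f$r_squared, n = f$n,
           source = f$source)
    }), p_fit, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p_fit)
    if (isTRUE(config$write_yearly_csv)) {
      for (yr in years) {
        st <- projection$counts %>%
          dplyr::filter(.data$year == yr) %>%
          dplyr::select(-"year") %>%
          population_state(year = yr)
        paths <- c(paths, write_population_csv(st, config$outdir, config$ssp))
      }
    }
    if (isTRUE(config$write_grids)) {
      for (yr in names(grids$grids)) {
        p_g <- file.path(config$outdir,
                         sprintf("%s_%s_%s.asc", config$ssp, config$rcp, yr))
        write_asc(grids$grids[[yr]], p_g, na_mask = world$raster$water)
        paths <- c(paths, p_g)
      }
    }
    manifest <- tibble::tibble(file = basename(paths),
                               md5 = unname(tools::md5sum(paths)))
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         dataframe = "rows", digits = NA)
  }
  structure(list(
    config = config, world = world, scenario = scenario,
    projection = projection, urbanization = pu, urban_rural = ur,
    grids = grids, consistency = consistency, manifest = manifest
  ), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %s-%s, %d-%d\n", x$config$ssp, x$config$rcp,
              x$config$start, x$config$end))
  cat(sprintf("  grid/total consistency: max |error| = %.3g persons\n",
              max(x$consistency$max_abs_error)))
  invisible(x)
}
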