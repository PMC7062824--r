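# Accuracy metrics used to evaluate projections and gridded products:
# algebraic / absolute percentage errors, RMSE, %RMSE, MAE and MAD (median
# absolute deviation from the median error).

#' Percentage errors between projected and actual values
#'
#' `pe = (projected - actual) / actual * 100`: positive when the projection
#' overestimates. `ape` is its absolute value.
#'
#' @param projected,actual Numeric vectors; `actual` must be nonzero.
#' @return Percentage error(s).
#' @export
#' @examples
#' pe(110, 100)  # +10
#' ape(90, 100)  # 10
pe <- function(projected, actual) {
  if (any(actual == 0)) {
    rlang::abort("percentage error undefined where actual value is 0")
  }
  (projected - actual) / actual * 100
}

#' @rdname pe
#' @export
ape <- function(projected, actual) abs(pe(projected, actual))

# Shared summary over an error vector e = projected - actual.
error_summary <- function(projected, actual) {
  e <- projected - actual
  tibble::tibble(
    rmse = sqrt(mean(e^2)),
    pct_rmse = sqrt(mean(e^2)) / mean(actual) * 100,
    mae = mean(abs(e)),
    mad = median(abs(e - median(e)))
  )
}

new_comparison_report <- function(level, mode, unit_values, summary) {
  structure(list(level = level, mode = mode, values = unit_values,
                 summary = summary), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %s (%s), %d unit(s)\n",
              x$level, x$mode, nrow(x$values)))
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.comparison_report <- function(x, ...) x$values

#' @exportS3Method generics::glance
glance.comparison_report <- function(x, ...) {
  dplyr::mutate(x$summary, level = x$level, mode = x$mode, .before = 1L)
}

#' Zonal accuracy metrics of a population grid
#'
#' Aggregates the grid over zones (e.g. prefectures or counties) and compares
#' the zonal sums to actual values, reporting RMSE, %RMSE, MAE and MAD either
#' on unit counts or on densities (counts divided by the zone's pixel count).
#'
#' @param grid Population grid matrix.
#' @param zones Integer zone-index matrix, same shape (NA = outside).
#' @param actual_by_zone Tibble with `zone` and `actual` (unit counts).
#' @param mode `"counts"` or `"densities"`.
#' @return A `comparison_report`.
#' @export
zonal_metrics <- function(grid, zones, actual_by_zone, mode = c("counts", "densities")) {
  mode <- match.arg(mode)
  if (!all(dim(grid) == dim(zones))) rlang::abort("zones raster is not aligned")
  keep <- !is.na(zones)
  sums <- tapply(grid[keep], zones[keep], sum)
  npix <- tapply(grid[keep], zones[keep], length)
  units <- tibble::tibble(zone = as.integer(names(sums)),
                          projected = as.numeric(sums),
                          n_pixels = as.integer(npix)) %>%
    dplyr::inner_join(actual_by_zone, by = "zone")
  missing <- setdiff(actual_by_zone$zone, units$zone)
  if (length(missing) > 0L) {
    rlang::warn(sprintf("zones with no pixels excluded: %s",
                        paste(missing, collapse = ", ")))
  }
  if (mode == "densities") {
    units <- dplyr::mutate(units,
                           projected = .data$projected / .data$n_pixels,
                           actual = .data$actual / .data$n_pixels)
  }
  units <- dplyr::mutate(units,
                         error = .data$projected - .data$actual,
                         pe = pe(.data$projected, .data$actual),
                         ape = abs(.data$pe))
  summary <- error_summary(units$projected, units$actual) %>%
    dplyr::mutate(mean_ape = mean(units$ape), mean_pe = mean(units$pe))
  new_comparison_report("zonal", mode, units, summary)
}

#' Cell-by-cell comparison of two population grids
#'
#' Compares `grid` against `reference` over the cells where the reference is
#' positive, reporting RMSE, MAE, MAD, and the mean and median absolute
#' percentage errors.
#'
#' @param grid,reference Same-shape matrices; `reference` is the baseline.
#' @return A `comparison_report`.
#' @export
cell_compare <- function(grid, reference) {
  if (!all(dim(grid) == dim(reference))) {
    rlang::abort("grids have different shapes")
  }
  keep <- reference > 0
  p <- grid[keep]; a <- reference[keep]
  values <- tibble::tibble(projected = p, actual = a,
                           error = p - a, ape = ape(p, a))
  summary <- error_summary(p, a) %>%
    dplyr::mutate(mean_ape = mean(values$ape),
                  median_ape = median(values$ape))
  new_comparison_report("cell", "counts", values, summary)
}
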