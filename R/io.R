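# Readers and writers for the data-record formats: per-province population
# CSVs (rows = age 0..99,"100+"; columns = sex x education codes M/F x E0..E6),
# the Pop_TOTAL summary, urbanization paths, and plain-text ESRI ASCII grids
# for the raster outputs (no binary formats).

sex_edu_columns <- function() {
  paste(rep(c("M", "F"), each = 7L), rep(paste0("E", 0:6), 2L), sep = "_")
}

age_labels <- function() c(as.character(0:99), "100+")

#' Write one province-year population table
#'
#' File name `Pop_E_<province>_<SSPx>_<year>.csv`; one row per age label
#' (0..99, "100+"), one column per sex x education code (M_E0..F_E6).
#'
#' @param state A [population_state()] (may hold several provinces; one file
#'   per province is written).
#' @param dir Output directory.
#' @param ssp Scenario label used in the file name.
#' @return Invisibly, the paths written.
#' @export
write_population_csv <- function(state, dir, ssp = "SSP2") {
  year <- attr(state, "year")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::map_chr(sort(unique(state$province)), function(prov) {
    wide <- state %>%
      dplyr::filter(.data$province == prov) %>%
      dplyr::mutate(column = paste0(.data$sex, "_E", .data$edu - 1L)) %>%
      dplyr::select("age", "column", "count") %>%
      tidyr::pivot_wider(names_from = "column", values_from = "count")
    wide <- wide[order(wide$age), c("age", sex_edu_columns())]
    wide$age <- age_labels()[wide$age + 1L]
    path <- file.path(dir, sprintf("Pop_E_%s_%s_%d.csv", prov, ssp, year))
    utils::write.csv(wide, path, row.names = FALSE, quote = FALSE)
    path
  })
  invisible(paths)
}

#' Read a province-year population table back into a population state
#'
#' @param path A file written by [write_population_csv()]; province, scenario
#'   and year are recovered from the file name.
#' @return A [population_state()] for that province.
#' @export
read_population_csv <- function(path) {
  m <- regmatches(basename(path),
                  regexec("^Pop_E_(.+)_(SSP[0-9]+)_([0-9]{4})\\.csv$", basename(path)))[[1]]
  if (length(m) != 4L) {
    rlang::abort("file name must match Pop_E_<province>_<SSPx>_<year>.csv")
  }
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (!identical(names(df), c("age", sex_edu_columns()))) {
    rlang::abort(sprintf("unexpected columns in %s: expected age, %s",
                         basename(path), paste(sex_edu_columns(), collapse = ", ")))
  }
  if (!identical(df$age, age_labels())) {
    rlang::abort(sprintf("age column of %s must hold exactly the 101 labels 0..99, 100+",
                         basename(path)))
  }
  long <- df %>%
    tidyr::pivot_longer(-"age", names_to = "column", values_to = "count") %>%
    tidyr::separate_wider_delim("column", "_", names = c("sex", "code")) %>%
    dplyr::mutate(
      province = m[2],
      age = as.integer(ifelse(.data$age == "100+", "100", .data$age)),
      edu = as.integer(sub("E", "", .data$code)) + 1L,
      count = as.numeric(.data$count)
    ) %>%
    dplyr::select("province", "sex", "age", "edu", "count")
  population_state(long, year = as.integer(m[4]))
}

#' Write the aggregate provincial totals file
#'
#' @param projection A `population_projection`.
#' @param path Output path (conventionally `Pop_TOTAL.csv`).
#' @param scenario Scenario label column value.
#' @return Invisibly, the path.
#' @export
write_pop_total <- function(projection, path, scenario = projection$ssp) {
  out <- provincial_totals(projection) %>%
    dplyr::mutate(scenario = scenario) %>%
    dplyr::select("province", "year", "scenario", "total")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a matrix as an ESRI ASCII grid
#'
#' Plain-text raster interchange: a 6-line header (ncols, nrows, xllcorner,
#' yllcorner, cellsize, NODATA_value) followed by rows from the top. Water (or
#' otherwise missing) cells are stored as the nodata value -1.
#'
#' @param x Numeric matrix (row 1 = top).
#' @param path Output path (`.asc`).
#' @param cellsize Cell size in degrees (default a toy 30 arc-seconds).
#' @param xll,yll Lower-left corner coordinates.
#' @param nodata Value standing for missing cells.
#' @param na_mask Optional logical matrix of cells to store as nodata.
#' @return `write_asc`: invisibly, the path. `read_asc`: the matrix, with
#'   nodata cells as NA and the header as attributes.
#' @export
write_asc <- function(x, path, cellsize = 0.00833, xll = 100, yll = 30,
                      nodata = -1, na_mask = NULL) {
  if (!is.null(na_mask)) x[na_mask] <- nodata
  x[is.na(x)] <- nodata
  header <- c(
    sprintf("ncols %d", ncol(x)),
    sprintf("nrows %d", nrow(x)),
    sprintf("xllcorner %.10g", xll),
    sprintf("yllcorner %.10g", yll),
    sprintf("cellsize %.10g", cellsize),
    sprintf("NODATA_value %.10g", nodata)
  )
  body <- apply(x, 1L, function(r) paste(format(r, trim = TRUE, digits = 17),
                                         collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1:6], "\\s+")
  vals <- setNames(as.numeric(vapply(hdr, `[`, "", 2L)),
                   tolower(vapply(hdr, `[`, "", 1L)))
  body <- lapply(lines[-(1:6)], function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, body)
  stopifnot(nrow(m) == vals[["nrows"]], ncol(m) == vals[["ncols"]])
  m[m == vals[["nodata_value"]]] <- NA
  attr(m, "cellsize") <- vals[["cellsize"]]
  attr(m, "xllcorner") <- vals[["xllcorner"]]
  attr(m, "yllcorner") <- vals[["yllcorner"]]
  m
}
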