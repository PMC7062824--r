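# The population state travels through the package as a tidy long tibble
# (province, sex, age, edu, count) with a year attribute; the cohort engine
# converts to/from a dense [province, sex, age, edu] array internally.

AGES <- 0:100 # single-year ages; 100 stands for the open "100+" group

#' Construct a population state
#'
#' @param counts A data frame with columns `province` (character), `sex`
#'   ("M"/"F"), `age` (integer 0--100, where 100 means "100+"), `edu`
#'   (integer 1--7) and `count` (persons, nonnegative). Missing combinations
#'   are filled with zero.
#' @param year Calendar year the counts refer to.
#' @return A `population_state` tibble covering the full
#'   province x sex x age x edu grid.
#' @export
population_state <- function(counts, year) {
  stopifnot(is.data.frame(counts))
  need <- c("province", "sex", "age", "edu", "count")
  if (!all(need %in% names(counts))) {
    rlang::abort(paste0("counts must have columns: ", paste(need, collapse = ", ")))
  }
  if (any(counts$count < 0)) rlang::abort("population counts must be nonnegative")
  if (!all(counts$sex %in% c("M", "F"))) rlang::abort("sex must be 'M' or 'F'")
  if (!all(counts$age %in% AGES)) rlang::abort("age must be in 0..100")
  if (!all(counts$edu %in% 1:7)) rlang::abort("edu must be in 1..7")
  provinces <- sort(unique(counts$province))
  full <- tidyr::expand_grid(
    province = provinces, sex = c("M", "F"), age = AGES, edu = 1:7
  )
  out <- full %>%
    dplyr::left_join(
      counts %>%
        dplyr::group_by(.data$province, .data$sex, .data$age, .data$edu) %>%
        dplyr::summarise(count = sum(.data$count), .groups = "drop"),
      by = c("province", "sex", "age", "edu")
    ) %>%
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0))
  attr(out, "year") <- as.integer(year)
  class(out) <- c("population_state", class(out))
  out
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("<population_state> year %s: %d province(s), total %.0f persons\n",
              attr(x, "year"), length(unique(x$province)), sum(x$count)))
  NextMethod()
}

# Dense array view: [province, sex, age (0..100), edu (1..7)].
as_pop_array <- function(state) {
  provinces <- sort(unique(state$province))
  arr <- array(
    0,
    dim = c(length(provinces), 2L, 101L, 7L),
    dimnames = list(provinces, c("M", "F"), as.character(AGES), as.character(1:7))
  )
  idx <- cbind(
    match(state$province, provinces),
    match(state$sex, c("M", "F")),
    state$age + 1L,
    state$edu
  )
  arr[idx] <- state$count
  arr
}

pop_array_to_state <- function(arr, year) {
  dn <- dimnames(arr)
  grid <- tidyr::expand_grid(
    province = dn[[1]], sex = c("M", "F"), age = AGES, edu = 1:7
  )
  grid$count <- as.vector(arr[cbind(
    match(grid$province, dn[[1]]),
    match(grid$sex, c("M", "F")),
    grid$age + 1L,
    grid$edu
  )])
  out <- grid
  attr(out, "year") <- as.integer(year)
  class(out) <- c("population_state", class(out))
  out
}

#' Provincial totals of a population state
#'
#' @param state A `population_state` (or any tibble with `province`, `count`).
#' @return Tibble with `province` and `total` (persons).
#' @export
province_totals <- function(state) {
  state %>%
    dplyr::group_by(.data$province) %>%
    dplyr::summarise(total = sum(.data$count), .groups = "drop")
}
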