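# ggplot2 views of the main result types.

#' Population pyramid of one projected year
#'
#' @param state A [population_state()] (or one year of a projection's counts).
#' @param by_edu Stack bars by education stage.
#' @return A ggplot.
#' @export
plot_population_pyramid <- function(state, by_edu = FALSE) {
  df <- state %>%
    dplyr::group_by(.data$sex, .data$age,
                    edu = if (by_edu) .data$edu else 1L) %>%
    dplyr::summarise(count = sum(.data$count), .groups = "drop") %>%
    dplyr::mutate(signed = ifelse(.data$sex == "M", -.data$count, .data$count))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$signed)) +
    ggplot2::coord_flip() +
    ggplot2::labs(y = "persons (men left, women right)", x = "age") +
    ggplot2::theme_minimal()
  if (by_edu) {
    p + ggplot2::geom_col(ggplot2::aes(fill = factor(.data$edu)), width = 1) +
      ggplot2::labs(fill = "education stage")
  } else {
    p + ggplot2::geom_col(ggplot2::aes(fill = .data$sex), width = 1)
  }
}

#' National trajectory of a projection
#'
#' @param object A `population_projection`.
#' @param ... Unused.
#' @return A ggplot of total population by year.
#' @exportS3Method ggplot2::autoplot
autoplot.population_projection <- function(object, ...) {
  df <- provincial_totals(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$total,
                                   colour = .data$province)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "persons", x = NULL,
                  title = paste0("Provincial population, ",
                                 object$ssp %||% "")) +
    ggplot2::theme_minimal()
}

#' Fitted urbanization curve against its history
#'
#' @param object A `sigmoid_fit`.
#' @param history Optional tibble with `year`, `pu` observations to overlay.
#' @param years Years to draw the curve over.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.sigmoid_fit <- function(object, history = NULL, years = 1995:2100, ...) {
  df <- tibble::tibble(year = years, pu = predict_sigmoid(object, years))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$pu)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$b, linetype = "dashed") +
    ggplot2::labs(y = "urban population share", x = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(history)) {
    p <- p + ggplot2::geom_point(data = history)
  }
  p
}

#' Heat map of one year's population grid
#'
#' @param series A `population_grid_series`.
#' @param year Year to draw (default last).
#' @return A ggplot raster map (log10 colour scale).
#' @export
plot_grid_year <- function(series, year = max(series$years)) {
  g <- series$grids[[as.character(year)]]
  df <- tibble::tibble(row = rep(seq_len(nrow(g)), ncol(g)),
                       col = rep(seq_len(ncol(g)), each = nrow(g)),
                       count = as.vector(g))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = log10(.data$count + 1))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log10(persons + 1)") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s-%s population grid, %s",
                                  series$ssp, series$rcp, year),
                  x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
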