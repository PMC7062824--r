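# Dasymetric downscaling: provincial urban/rural totals are spread over a fine
# raster proportionally to the previous year's grid, inside/outside an urban
# mask derived per coarse cell from urban-land fractions. The process recurses:
# each year's grid seeds the next year's mask.

#' Build the unique-valued base weight grid
#'
#' Zeroes water pixels, then adds two tie-breaking epsilon layers to the raw
#' population weights: the inverse distance to roads and the population
#' gravity field, each min-max rescaled into \[1.0e-5, 1.1e-5\]. The epsilons
#' make all non-water pixel values pairwise distinct (so the urban-mask sort
#' has no ties) while perturbing provincial sums by a negligible amount.
#'
#' @param pop_raw Raw population weight matrix.
#' @param water Logical water mask, same shape.
#' @param road_dist Distance-to-roads matrix, same shape.
#' @param gravity Population gravity matrix, same shape.
#' @return Base weight matrix; water pixels are exactly 0.
#' @export
build_base_grid <- function(pop_raw, water, road_dist, gravity) {
  dims <- dim(pop_raw)
  if (!all(dim(water) == dims) || !all(dim(road_dist) == dims) ||
      !all(dim(gravity) == dims)) {
    rlang::abort("raster layers are not co-registered (dimension mismatch)")
  }
  rescale_eps <- function(x) {
    rng <- range(x)
    if (rng[2] == rng[1]) return(matrix(1.05e-5, dims[1], dims[2]))
    1.0e-5 + (x - rng[1]) / (rng[2] - rng[1]) * 0.1e-5
  }
  base <- pop_raw + rescale_eps(1 / (1 + road_dist)) + rescale_eps(gravity)
  base[water] <- 0
  base
}

# Index helper: list of pixel indices per coarse cell, in fixed row-major
# (column-within-block) order for deterministic tie-breaking.
coarse_cells <- function(dims, coarse_factor) {
  nr <- dims[1]; nc <- dims[2]
  ncr <- nr %/% coarse_factor; ncc <- nc %/% coarse_factor
  cells <- vector("list", ncr * ncc)
  k <- 0L
  for (i in seq_len(ncr)) for (j in seq_len(ncc)) {
    k <- k + 1L
    ri <- ((i - 1L) * coarse_factor + 1L):(i * coarse_factor)
    cj <- ((j - 1L) * coarse_factor + 1L):(j * coarse_factor)
    cells[[k]] <- as.vector(outer(ri, (cj - 1L) * nr, `+`))
  }
  attr(cells, "shape") <- c(ncr, ncc)
  cells
}

#' Derive the fine urban mask from coarse urban fractions
#'
#' For each coarse cell, the number of urban pixels is the nearest integer
#' (half-up) of the urban-land fraction times the pixels per cell; the pixels
#' with the highest previous-year grid values are selected, ties broken by
#' fixed pixel order.
#'
#' @param prev_grid Previous year's population grid (fine matrix).
#' @param urban_fraction Coarse matrix of urban-land fractions in \[0, 1\].
#' @param coarse_factor Fine pixels per coarse-cell side.
#' @return Logical matrix marking urban pixels.
#' @export
compute_urban_mask <- function(prev_grid, urban_fraction, coarse_factor) {
  if (any(urban_fraction < 0 | urban_fraction > 1)) {
    rlang::abort("urban fractions must lie in [0, 1]")
  }
  cells <- coarse_cells(dim(prev_grid), coarse_factor)
  shape <- attr(cells, "shape")
  if (!all(dim(urban_fraction) == shape)) {
    rlang::abort("urban-fraction grid is not aligned to the fine raster")
  }
  mask <- matrix(FALSE, dim(prev_grid)[1], dim(prev_grid)[2])
  fr <- t(urban_fraction) # cells list is row-major over (i, j)
  for (k in seq_along(cells)) {
    px <- cells[[k]]
    n_urban <- round_half_up(fr[k] * length(px))
    if (n_urban > 0L) {
      ord <- px[order(prev_grid[px], px, decreasing = c(TRUE, FALSE),
                      method = "radix")]
      mask[ord[seq_len(min(n_urban, length(px)))]] <- TRUE
    }
  }
  mask
}

#' Allocate one year's provincial urban and rural populations onto the grid
#'
#' Within each province, the urban total is distributed over the province's
#' urban pixels proportionally to the previous year's grid values, and the
#' rural total over its non-urban, non-water pixels likewise. A province with
#' urban population but no urban pixels falls back to its top 1% (at least
#' one) highest-valued pixels, with a warning.
#'
#' @param prev_grid Previous year's population grid.
#' @param mask Logical urban mask from [compute_urban_mask()].
#' @param province_id Integer matrix of province indices.
#' @param water Logical water mask.
#' @param urban_pop,rural_pop Named numeric vectors (per province index as
#'   character, or in province order) of people to allocate.
#' @return Population grid matrix; per-province sums equal urban + rural.
#' @export
allocate_year <- function(prev_grid, mask, province_id, water,
                          urban_pop, rural_pop) {
  if (any(urban_pop < 0) || any(rural_pop < 0)) {
    rlang::abort("urban/rural totals must be nonnegative")
  }
  out <- matrix(0, dim(prev_grid)[1], dim(prev_grid)[2])
  provs <- sort(unique(as.vector(province_id[!water])))
  spread <- function(total, px) {
    w <- prev_grid[px]
    if (sum(w) <= 0) w <- rep(1, length(px)) # uniform when weights vanish
    out[px] <<- out[px] + total * w / sum(w)
  }
  for (p in provs) {
    inp <- which(province_id == p & !water)
    if (length(inp) == 0L) rlang::abort(sprintf("province %s has no land pixels", p))
    u <- if (!is.null(names(urban_pop))) urban_pop[[as.character(p)]] else urban_pop[[p]]
    r <- if (!is.null(names(rural_pop))) rural_pop[[as.character(p)]] else rural_pop[[p]]
    upx <- inp[mask[inp]]
    rpx <- inp[!mask[inp]]
    if (u > 0 && length(upx) == 0L) {
      rlang::warn(sprintf(
        "province %s has urban population but no urban pixels; using top 1%% of pixels", p))
      n_fb <- max(1L, round_half_up(0.01 * length(inp)))
      upx <- inp[order(prev_grid[inp], decreasing = TRUE)][seq_len(n_fb)]
      rpx <- setdiff(inp, upx)
    }
    if (r > 0 && length(rpx) == 0L) {
      rlang::warn(sprintf(
        "province %s is fully urban; rural population allocated to urban pixels", p))
      rpx <- upx
    }
    if (u > 0) spread(u, upx)
    if (r > 0) spread(r, rpx)
  }
  out
}

# Interpolate coarse urban fractions between stored epochs.
interpolate_urban_fraction <- function(urban_fraction, year) {
  epochs <- as.numeric(dimnames(urban_fraction)[[3]])
  if (year <= min(epochs)) return(urban_fraction[, , which.min(epochs)])
  if (year >= max(epochs)) return(urban_fraction[, , which.max(epochs)])
  hi <- which(epochs >= year)[1]
  lo <- hi - 1L
  lam <- (year - epochs[lo]) / (epochs[hi] - epochs[lo])
  (1 - lam) * urban_fraction[, , lo] + lam * urban_fraction[, , hi]
}

#' Downscale a provincial urban/rural series onto yearly grids
#'
#' The base-year grid rescales the base weight grid to the base-year
#' provincial totals; each following year derives its urban mask from the
#' previous year's grid and that year's (interpolated) urban fractions, then
#' allocates the urban and rural totals. Only SSP-RCP pairs with nonzero
#' scenario-matrix probability are accepted.
#'
#' @param base_grid Base weight grid from [build_base_grid()].
#' @param urban_rural Tibble with `province`, `year`, `urban`, `rural` (from
#'   [split_urban_rural()]); province names must be ordered consistently with
#'   the `province_id` indices.
#' @param raster A `raster_world` (supplies `province_id`, `water`,
#'   `urban_fraction`, `config`), or a list with those elements.
#' @param ssp,rcp Scenario labels, checked against [admissible_ssp_rcp()].
#' @return A `population_grid_series`: list of yearly matrices plus metadata.
#' @export
downscale_series <- function(base_grid, urban_rural, raster,
                             ssp = "SSP2", rcp = "RCP6") {
  adm <- admissible_ssp_rcp()
  if (!any(adm$ssp == ssp & adm$rcp == rcp)) {
    valid <- paste(adm$ssp, adm$rcp, sep = "-", collapse = ", ")
    rlang::abort(sprintf(
      "scenario pair %s-%s has zero probability; admissible pairs: %s",
      ssp, rcp, valid))
  }
  provs <- sort(unique(urban_rural$province))
  years <- sort(unique(urban_rural$year))
  coarse_factor <- raster$config$coarse_factor
  ur_by <- split(urban_rural, urban_rural$year)

  grids <- vector("list", length(years))
  names(grids) <- as.character(years)

  # base year: total population proportional to the base weight grid
  ur0 <- ur_by[[as.character(years[1])]]
  tot0 <- setNames(ur0$urban + ur0$rural, as.character(match(ur0$province, provs)))
  zero <- setNames(rep(0, length(provs)), as.character(seq_along(provs)))
  grids[[1]] <- allocate_year(base_grid, matrix(FALSE, nrow(base_grid), ncol(base_grid)),
                              raster$province_id, raster$water, zero, tot0)
  prev <- grids[[1]]

  for (i in seq_along(years)[-1]) {
    yr <- years[i]
    fr <- interpolate_urban_fraction(raster$urban_fraction, yr)
    mask <- compute_urban_mask(prev, fr, coarse_factor)
    ur <- ur_by[[as.character(yr)]]
    u <- setNames(ur$urban, as.character(match(ur$province, provs)))
    r <- setNames(ur$rural, as.character(match(ur$province, provs)))
    prev <- allocate_year(prev, mask, raster$province_id, raster$water, u, r)
    grids[[i]] <- prev
  }
  structure(list(
    grids = grids, years = years, provinces = provs,
    ssp = ssp, rcp = rcp
  ), class = "population_grid_series")
}

#' @export
print.population_grid_series <- function(x, ...) {
  cat(sprintf("<population_grid_series> %s-%s, %d yearly grids (%d x %d)\n",
              x$ssp, x$rcp, length(x$grids),
              nrow(x$grids[[1]]), ncol(x$grids[[1]])))
  invisible(x)
}

#' Aggregate a grid (or grid series) to provincial totals
#'
#' @param x A matrix or a `population_grid_series`.
#' @param province_id Integer province-index raster (required for a matrix).
#' @param water Logical water mask.
#' @param provinces Optional province names in index order.
#' @return Tibble with `province`, `total` (and `year` for a series).
#' @export
aggregate_grid <- function(x, province_id, water, provinces = NULL) {
  agg_one <- function(g) {
    idx <- as.vector(province_id[!water])
    v <- as.vector(g[!water])
    s <- tapply(v, idx, sum)
    tibble::tibble(
      province = if (is.null(provinces)) names(s) else provinces[as.integer(names(s))],
      total = as.numeric(s))
  }
  if (inherits(x, "population_grid_series")) {
    purrr::imap(x$grids, function(g, yr) {
      dplyr::mutate(agg_one(g), year = as.integer(yr), .before = 1L)
    }) %>% dplyr::bind_rows()
  } else {
    agg_one(x)
  }
}

#' Tidy a grid series into a long pixel table
#'
#' @param x A `population_grid_series`.
#' @param ... Unused.
#' @return Tibble with `year`, `row`, `col`, `count`.
#' @exportS3Method generics::tidy
tidy.population_grid_series <- function(x, ...) {
  purrr::imap(x$grids, function(g, yr) {
    tibble::tibble(year = as.integer(yr),
                   row = rep(seq_len(nrow(g)), ncol(g)),
                   col = rep(seq_len(ncol(g)), each = nrow(g)),
                   count = as.vector(g))
  }) %>% dplyr::bind_rows()
}
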