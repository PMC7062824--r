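# Shared fixtures. Worlds are cached per (seed, size) so test files do not
# regenerate them repeatedly.

.fixtures <- new.env(parent = emptyenv())

tiny_config <- function(seed = 11L, n = 3L, shape = c(36L, 36L), cf = 6L) {
  world_config(n_provinces = n, raster_shape = shape, coarse_factor = cf,
               seed = seed)
}

tiny_world <- function(seed = 11L, n = 3L, shape = c(36L, 36L), cf = 6L, ...) {
  key <- paste(seed, n, paste(shape, collapse = "x"), cf, sep = "_")
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- synthetic_world(tiny_config(seed, n, shape, cf), ...)
  }
  .fixtures[[key]]
}

# Small random population array [province, sex, age, edu] with dimnames.
random_pop_array <- function(nprov = 3L) {
  provs <- sprintf("prov%02d", seq_len(nprov))
  array(runif(nprov * 2 * 101 * 7, 0, 1000),
        dim = c(nprov, 2L, 101L, 7L),
        dimnames = list(provs, c("M", "F"), as.character(0:100),
                        as.character(1:7)))
}

# Random rate bundle compatible with age_and_educate()/compute_births().
random_rate_bundle <- function(nprov = 3L) {
  trans <- education_transitions()
  provs <- sprintf("prov%02d", seq_len(nprov))
  dn <- list(provs, c("M", "F"), as.character(0:100), as.character(1:7))
  mor <- array(runif(nprov * 2 * 101 * 7, 0, 0.2), dim = c(nprov, 2, 101, 7),
               dimnames = dn)
  netpim <- array(runif(nprov * 2 * 101 * 7, -0.05, 0.05),
                  dim = c(nprov, 2, 101, 7), dimnames = dn)
  g <- array(runif(nprov * 2 * 6, 0, 0.4), dim = c(nprov, 2, 6),
             dimnames = list(provs, c("M", "F"), trans$label))
  # keep total senior-stage outflow below 1
  g[, , 4] <- pmin(g[, , 4], 0.3); g[, , 5] <- pmin(g[, , 5], 0.6)
  fer <- array(0, dim = c(nprov, 101, 7),
               dimnames = list(provs, as.character(0:100), as.character(1:7)))
  fer[, 16:50, ] <- runif(nprov * 35 * 7, 0, 0.15)
  srb <- runif(nprov, 1.0, 1.2)
  list(mor = mor, netpim = netpim, g = g, fer = fer,
       bm = setNames(srb / (1 + srb), provs),
       bf = setNames(1 / (1 + srb), provs))
}
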