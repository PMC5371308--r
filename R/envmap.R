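#' Euclidean distance field of the simulation grid
#'
#' Distance (km) from the centre of every grid cell to the centre of the
#' island cell. The grid is square with the island at its centre.
#'
#' @param n grid side length in cells.
#' @param cell_km cell edge in km.
#' @param island integer vector `c(row, col)` of the island cell (1-based).
#'   Defaults to the central cell.
#' @return An `n x n` numeric matrix of km distances.
#' @examples
#' d <- build_distance_field()
#' d[51, 51]        # 0 at the island
#' d[51, 61]        # 10 cells east -> 100 km
#' @export
build_distance_field <- function(n = 100L, cell_km = 10,
                                 island = c(n %/% 2 + 1L, n %/% 2 + 1L)) {
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  cell_km * sqrt((rows - island[1])^2 + (cols - island[2])^2)
}

## stationary Gaussian random field on the torus: white noise smoothed by a
## Gaussian kernel via FFT, re-standardised to sample mean 0 / sd 1.
## sigma_cells = 0 returns plain (standardised) white noise.
gaussian_field <- function(n, sigma_cells) {
  z <- matrix(rnorm(n * n), n, n)
  if (sigma_cells > 0) {
    d <- c(0:(n %/% 2), (n %/% 2 - 1):1)       # wrapped lags
    k1 <- exp(-d^2 / (2 * sigma_cells^2))
    kern <- outer(k1, k1)
    kern <- kern / sum(kern)
    z <- Re(fft(fft(z) * fft(kern), inverse = TRUE)) / (n * n)
  }
  (z - mean(z)) / sd(z)
}

#' Mask a raw abundance field around the island
#'
#' Cells on the unsuitable shelf (within `plateau_km` of the island) or beyond
#' the outer foraging range (`max_range_km`) are set to zero. Between the
#' shelf edge and the distance-to-resource `dist`, cells are independently
#' retained with probability rising linearly from 0 at the shelf edge to 1 at
#' `dist` (Bernoulli thinning); beyond `dist` all cells are kept. Uses the
#' current RNG state.
#'
#' @param raw_field non-negative numeric matrix.
#' @param dist_field matching matrix of km distances (see
#'   [build_distance_field()]).
#' @param dist distance to the resource in km; must lie in
#'   (`plateau_km`, `max_range_km`].
#' @param params parameter list from [cpf_params()].
#' @return The masked matrix.
#' @export
apply_masks <- function(raw_field, dist_field, dist, params = cpf_params()) {
  if (dist <= params$plateau_km || dist > params$max_range_km)
    stop("dist must lie in (", params$plateau_km, ", ", params$max_range_km,
         "] km")
  if (any(raw_field < 0)) stop("raw_field must be non-negative")
  out <- raw_field
  out[dist_field <= params$plateau_km | dist_field > params$max_range_km] <- 0
  grad <- dist_field > params$plateau_km & dist_field < dist
  if (any(grad)) {
    keep_p <- (dist_field[grad] - params$plateau_km) / (dist - params$plateau_km)
    out[grad] <- out[grad] * (runif(sum(grad)) < keep_p)
  }
  ## the distance to the resource marks the inner edge of the richest zone:
  ## beyond it the amplitude tapers off towards the outer range limit
  outer <- dist_field >= dist & dist_field <= params$max_range_km
  if (any(outer) && params$ring_taper > 0) {
    f <- 1 - params$ring_taper * (dist_field[outer] - dist) /
      (params$max_range_km - dist)
    out[outer] <- out[outer] * f
  }
  out
}

#' Map configuration
#'
#' Validates and bundles the landscape design factors.
#'
#' @param aggreg aggregation level, one of 0, 1, 2, 3, 4, 6, 8, 10.
#' @param abund abundance level in g h^-1, one of 90, 180, 270, 360.
#' @param dist distance to the resource in km, one of 100, 150, ..., 500.
#' @param rep_map replicate index of the map.
#' @param seed integer RNG seed for the realisation.
#' @param params parameter list.
#' @return A list of class `map_config`.
#' @export
map_config <- function(aggreg, abund, dist, rep_map = 1L, seed = 1L,
                       params = cpf_params()) {
  if (!aggreg %in% params$aggreg_levels)
    stop("aggreg must be one of ", paste(params$aggreg_levels, collapse = ", "))
  if (!abund %in% params$abund_levels)
    stop("abund must be one of ", paste(params$abund_levels, collapse = ", "))
  if (!dist %in% params$dist_levels)
    stop("dist must be one of ", paste(params$dist_levels, collapse = ", "))
  structure(list(aggreg = aggreg, abund = abund, dist = dist,
                 rep_map = as.integer(rep_map), seed = as.integer(seed)),
            class = "map_config")
}

#' Generate an artificial resource landscape
#'
#' Draws a stationary Gaussian random field whose correlation length grows
#' with the aggregation level, truncates negative values to zero, applies the
#' island/shelf/outer-range masks and the linear accessibility gradient, and
#' normalises the surviving cells so that their mean abundance equals the
#' configured level. Abundances are expressed in map units (1 unit = 36.667 g
#' of catchable prey per fishing hour).
#'
#' @param aggreg,abund,dist,rep_map,seed design factors, see [map_config()];
#'   alternatively pass a ready `map_config` as `config`.
#' @param config optional `map_config` object overriding the scalar arguments.
#' @param params parameter list.
#' @return An object of class `resource_map`: list with elements `values`
#'   (matrix, map units), `dist_field` (km), `island` (row, col, 1-based),
#'   `cell_km`, `avg_env` (mean non-zero abundance, map units), `avg_env_g`
#'   (same in g h^-1) and `config`.
#' @examples
#' m <- generate_resource_map(aggreg = 3, abund = 180, dist = 150, seed = 1)
#' mean(m$values[m$values > 0]) * cpf_params()$g_per_unit  # = 180
#' @export
generate_resource_map <- function(aggreg = 3, abund = 180, dist = 150,
                                  rep_map = 1L, seed = 1L, config = NULL,
                                  params = cpf_params()) {
  if (is.null(config))
    config <- map_config(aggreg, abund, dist, rep_map, seed, params)
  n <- params$grid_n
  island <- c(n %/% 2 + 1L, n %/% 2 + 1L)
  dist_field <- build_distance_field(n, params$cell_km, island)
  sigma <- params$scale_per_aggreg * config$aggreg
  offset <- params$offset_per_aggreg * config$aggreg
  target <- config$abund / params$g_per_unit   # mean non-zero, map units

  set.seed(derive_seed(config$seed, config$rep_map))
  for (attempt in 1:10) {
    ## powered positive part: zero background with right-skewed abundance
    ## inside patches (prey concentrate within aggregations)
    raw <- pmax(gaussian_field(n, sigma) - offset, 0)^params$field_power
    vals <- apply_masks(raw, dist_field, config$dist, params)
    if (any(vals > 0)) break
    warning("degenerate all-zero field after masking; regenerating")
  }
  if (!any(vals > 0)) stop("could not generate a non-degenerate map")
  vals <- vals * target / mean(vals[vals > 0])

  structure(list(values = vals, dist_field = dist_field, island = island,
                 cell_km = params$cell_km,
                 avg_env = mean(vals[vals > 0]),
                 avg_env_g = mean(vals[vals > 0]) * params$g_per_unit,
                 config = config),
            class = "resource_map")
}

#' Mean abundance of the non-zero environment
#'
#' @param map a `resource_map` or a plain abundance matrix.
#' @return Arithmetic mean of the strictly positive cells (map units).
#' @export
avg_env <- function(map) {
  v <- if (inherits(map, "resource_map")) map$values else map
  pos <- v[v > 0]
  if (!length(pos)) stop("map has no non-zero cells")
  mean(pos)
}

#' Patch statistics of a resource map
#'
#' Counts connected components (4-neighbourhood) of cells at or above an
#' abundance threshold and their mean size. A patch is a cluster of cells
#' distinctly richer than the surrounding environment: the default threshold
#' is `patch_thr_factor` (1.5) times the map's mean non-zero abundance.
#'
#' @param map a `resource_map` or abundance matrix.
#' @param threshold abundance defining a resource cell (map units); defaults
#'   to 1.5 x the mean non-zero abundance of the map.
#' @param params parameter list.
#' @return List with `n_patches`, `mean_patch_size` (cells; `NaN` when there
#'   are no patches) and `n_cells` above threshold.
#' @export
patch_statistics <- function(map, threshold = NULL, params = cpf_params()) {
  v <- if (inherits(map, "resource_map")) map$values else map
  if (is.null(threshold))
    threshold <- if (any(v > 0))
      params$patch_thr_factor * mean(v[v > 0]) else params$min_fish_abund
  occ <- v >= threshold
  n <- nrow(v); m <- ncol(v)
  lab <- matrix(0L, n, m)
  cur <- 0L
  sizes <- integer(0)
  stack <- integer(n * m)
  for (start in which(occ)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    top <- 1L
    stack[1L] <- start
    lab[start] <- cur
    sz <- 0L
    while (top > 0L) {
      cell <- stack[top]; top <- top - 1L
      sz <- sz + 1L
      r <- ((cell - 1L) %% n) + 1L
      cc <- ((cell - 1L) %/% n) + 1L
      if (r > 1L) { nb <- cell - 1L
        if (occ[nb] && lab[nb] == 0L) { lab[nb] <- cur; top <- top + 1L; stack[top] <- nb } }
      if (r < n) { nb <- cell + 1L
        if (occ[nb] && lab[nb] == 0L) { lab[nb] <- cur; top <- top + 1L; stack[top] <- nb } }
      if (cc > 1L) { nb <- cell - n
        if (occ[nb] && lab[nb] == 0L) { lab[nb] <- cur; top <- top + 1L; stack[top] <- nb } }
      if (cc < m) { nb <- cell + n
        if (occ[nb] && lab[nb] == 0L) { lab[nb] <- cur; top <- top + 1L; stack[top] <- nb } }
    }
    sizes <- c(sizes, sz)
  }
  list(n_patches = cur,
       mean_patch_size = if (cur > 0L) mean(sizes) else NaN,
       n_cells = sum(occ))
}

#' @export
print.resource_map <- function(x, ...) {
  cfg <- x$config
  cat("resource_map:", nrow(x$values), "x", ncol(x$values), "cells of",
      x$cell_km, "km\n")
  cat(sprintf("  aggreg %s, abund %s g/h, dist %s km (map rep %d, seed %d)\n",
              cfg$aggreg, cfg$abund, cfg$dist, cfg$rep_map, cfg$seed))
  cat(sprintf("  non-zero cells: %d, mean abundance %.3f map units (%.1f g/h)\n",
              sum(x$values > 0), x$avg_env, x$avg_env_g))
  invisible(x)
}

#' @export
plot.resource_map <- function(x, ...) {
  n <- nrow(x$values)
  km <- (seq_len(n) - 0.5) * x$cell_km
  graphics::image(km, km, t(x$values), xlab = "km", ylab = "km",
                  col = grDevices::hcl.colors(64, "YlGnBu", rev = TRUE), ...)
  graphics::points((x$island[2] - 0.5) * x$cell_km,
                   (x$island[1] - 0.5) * x$cell_km, pch = 8, col = "red")
  invisible(x)
}

#' Write / read a resource map as plain text
#'
#' The abundance grid is written as a headerless CSV (one row per grid row)
#' with a JSON sidecar (`<file>.json`) holding the configuration.
#'
#' @param map a `resource_map`.
#' @param file CSV path.
#' @return `write_resource_map()` returns `file` invisibly;
#'   `read_resource_map()` returns a `resource_map`.
#' @export
write_resource_map <- function(map, file) {
  write.table(map$values, file, sep = ",", row.names = FALSE,
              col.names = FALSE)
  meta <- c(unclass(map$config),
            list(cell_km = map$cell_km, island = map$island))
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE)
  invisible(file)
}

#' @rdname write_resource_map
#' @param params parameter list used to rebuild derived fields.
#' @export
read_resource_map <- function(file, params = cpf_params()) {
  vals <- as.matrix(read.table(file, sep = ","))
  dimnames(vals) <- NULL
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  island <- as.integer(meta$island)
  structure(list(values = vals,
                 dist_field = build_distance_field(nrow(vals), meta$cell_km,
                                                   island),
                 island = island, cell_km = meta$cell_km,
                 avg_env = mean(vals[vals > 0]),
                 avg_env_g = mean(vals[vals > 0]) * params$g_per_unit,
                 config = structure(meta[c("aggreg", "abund", "dist",
                                           "rep_map", "seed")],
                                    class = "map_config")),
            class = "resource_map")
}
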