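# shared fixtures, built once per test session

.fixtures <- new.env(parent = emptyenv())

# reference landscape: intermediate aggregation and abundance, 150 km
ref_map <- function() {
  if (is.null(.fixtures$ref_map))
    .fixtures$ref_map <- generate_resource_map(aggreg = 3, abund = 180,
                                               dist = 150, seed = 1)
  .fixtures$ref_map
}

# a tiny hand-made resource_map wrapper around an arbitrary value matrix
toy_map <- function(values, params = cpf_params()) {
  n <- nrow(values)
  island <- c(n %/% 2 + 1L, n %/% 2 + 1L)
  structure(list(values = values,
                 dist_field = build_distance_field(n, params$cell_km, island),
                 island = island, cell_km = params$cell_km,
                 avg_env = mean(values[values > 0]),
                 avg_env_g = mean(values[values > 0]) * params$g_per_unit,
                 config = map_config(3, 180, 150, 1L, 1L, params)),
            class = "resource_map")
}

# brute-force connected-component census (4-neighbourhood), used as the
# independent oracle for patch_statistics
flood_fill_census <- function(occ) {
  n <- nrow(occ); m <- ncol(occ)
  seen <- matrix(FALSE, n, m)
  sizes <- integer(0)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (!occ[i, j] || seen[i, j]) next
    size <- 0L
    queue <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(queue)) {
      cell <- queue[[1]]; queue <- queue[-1]
      size <- size + 1L
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r <- cell[1] + d[1]; cc <- cell[2] + d[2]
        if (r >= 1 && r <= n && cc >= 1 && cc <= m && occ[r, cc] &&
            !seen[r, cc]) {
          seen[r, cc] <- TRUE
          queue <- c(queue, list(c(r, cc)))
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sizes
}
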