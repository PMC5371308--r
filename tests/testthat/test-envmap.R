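test_that("distance field is Euclidean from the island cell centre", {
  d <- build_distance_field()
  expect_equal(d[51, 51], 0)
  expect_equal(d[51, 61], 100)       # 10 cells east
  expect_equal(d[54, 55], 50)        # 3-4-5 triangle, 10 km cells
  expect_equal(d[48, 47], 50)
})

test_that("masks zero the shelf and the outer range and reject bad dist", {
  p <- cpf_params()
  ones <- matrix(1, 100, 100)
  df <- build_distance_field()
  set.seed(1)
  m <- apply_masks(ones, df, dist = 150, p)
  expect_true(all(m[df <= 50] == 0))
  expect_true(all(m[df > 500] == 0))
  expect_true(all(m[df > 150 & df <= 500] > 0))
  expect_error(apply_masks(ones, df, dist = 40, p), "dist")
  expect_error(apply_masks(ones, df, dist = 600, p), "dist")
  expect_error(apply_masks(ones - 2, df, dist = 150, p))
})

test_that("gradient thinning retains cells with the linear probability", {
  # Monte-Carlo oracle: with dist = 100, a cell 75 km out is kept with
  # probability (75 - 50) / (100 - 50) = 0.5
  p <- cpf_params()
  ones <- matrix(1, 100, 100)
  df <- build_distance_field()
  sel <- df > 73 & df < 77
  set.seed(42)
  kept <- replicate(200, {
    m <- apply_masks(ones, df, dist = 100, p)
    mean(m[sel] > 0)
  })
  expect_gt(mean(kept), 0.45)
  expect_lt(mean(kept), 0.55)
})

test_that("generated maps satisfy the zero-mask and normalization invariants", {
  p <- cpf_params()
  for (abund in c(90, 180, 360)) {
    m <- generate_resource_map(aggreg = 3, abund = abund, dist = 150,
                               seed = 7, params = p)
    expect_true(all(m$values >= 0))
    expect_true(all(m$values[m$dist_field <= p$plateau_km] == 0))
    expect_true(all(m$values[m$dist_field > p$max_range_km] == 0))
    # mean of the non-zero cells equals the abundance level (map units)
    expect_equal(mean(m$values[m$values > 0]), abund / p$g_per_unit,
                 tolerance = 1e-9)
    expect_equal(m$avg_env_g, abund, tolerance = 1e-9)
  }
})

test_that("map generation is deterministic given (config, seed)", {
  m1 <- generate_resource_map(aggreg = 4, abund = 270, dist = 200, seed = 3)
  m2 <- generate_resource_map(aggreg = 4, abund = 270, dist = 200, seed = 3)
  expect_identical(m1$values, m2$values)
  m3 <- generate_resource_map(aggreg = 4, abund = 270, dist = 200, seed = 4)
  expect_false(identical(m1$values, m3$values))
})

test_that("map configuration validates its levels", {
  expect_error(map_config(5, 180, 150), "aggreg")
  expect_error(map_config(3, 200, 150), "abund")
  expect_error(map_config(3, 180, 175), "dist")
})

test_that("avg_env is the mean of strictly positive cells", {
  v <- matrix(0, 4, 4); v[1, 1] <- 2; v[2, 2] <- 4
  expect_equal(avg_env(v), 3)
  expect_error(avg_env(matrix(0, 4, 4)), "non-zero")
})

test_that("patch statistics match a brute-force flood fill", {
  # hand-built two-blob grid
  v <- matrix(0, 8, 8)
  v[2:3, 2:3] <- 5              # 4-cell blob
  v[6, 5:7] <- 5                # 3-cell blob
  v[1, 8] <- 0.5                # below threshold
  ps <- patch_statistics(v, threshold = 1)
  expect_equal(ps$n_patches, 2)
  expect_equal(ps$mean_patch_size, 3.5)
  # oracle comparison on a random grid
  set.seed(11)
  r <- matrix(rexp(400), 20, 20)
  thr <- 1.2
  ps2 <- patch_statistics(r, threshold = thr)
  sizes <- flood_fill_census(r >= thr)
  expect_equal(ps2$n_patches, length(sizes))
  expect_equal(ps2$mean_patch_size, mean(sizes))
  # degenerate cases
  expect_equal(patch_statistics(matrix(0, 5, 5), threshold = 1)$n_patches, 0)
  one <- matrix(0, 5, 5); one[3, 3] <- 9
  ps3 <- patch_statistics(one, threshold = 1)
  expect_equal(ps3$n_patches, 1)
  expect_equal(ps3$mean_patch_size, 1)
})

test_that("aggregation monotonically coarsens the patch structure", {
  p <- cpf_params()
  levels <- c(0, 2, 4, 10)
  stats <- sapply(levels, function(a) {
    rowMeans(sapply(1:50, function(s) {
      m <- generate_resource_map(a, 180, 300, seed = 4000 + s, params = p)
      ps <- patch_statistics(m, params = p)
      c(ps$n_patches, ps$mean_patch_size)
    }))
  })
  expect_true(all(diff(stats[1, ]) < 0))   # patch count non-increasing
  expect_true(all(diff(stats[2, ]) > 0))   # patch size non-decreasing
})

test_that("maps round-trip through the plain-text format", {
  m <- ref_map()
  f <- tempfile(fileext = ".csv")
  write_resource_map(m, f)
  m2 <- read_resource_map(f)
  expect_equal(m2$values, m$values, tolerance = 1e-12)
  expect_equal(m2$config$aggreg, m$config$aggreg)
  expect_equal(m2$avg_env, m$avg_env, tolerance = 1e-12)
  unlink(c(f, paste0(f, ".json")))
})
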