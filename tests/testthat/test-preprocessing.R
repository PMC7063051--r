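test_that("map normalization applies threshold, median division and cap", {
  set.seed(1)
  g <- array(runif(20^3, 0, 10), c(20, 20, 20))
  dm <- density_map(g)
  p <- preprocess_map(dm, threshold = 2)
  expect_true(all(p$grid[g < 2] == 0))
  expect_equal(median(p$grid[p$grid > 0]), 1)
  # cap: max no larger than the pre-cap 98th percentile
  divided <- g / median(g[g >= 2][g[g >= 2] > 0])
  divided[g < 2] <- 0
  p98 <- quantile(divided[divided > 0], 0.98, type = 1, names = FALSE)
  expect_lte(max(p$grid), p98 + 1e-12)

  # constant map: all ones, cap a no-op
  cm <- density_map(array(4, c(5, 5, 5)))
  pc <- preprocess_map(cm, 0)
  expect_true(all(pc$grid == 1))

  expect_error(preprocess_map(dm, 100), "empty map")
  expect_error(preprocess_map(dm, -1), ">= 0")
})

test_that("normalization is idempotent on its own output", {
  set.seed(2)
  dm <- density_map(array(rexp(17^3), c(17, 17, 17)))
  p1 <- preprocess_map(dm, 0.5)
  p2 <- preprocess_map(p1, 0)
  expect_identical(p1$grid, p2$grid)
})

test_that("resampling to unit voxels is exact where it should be", {
  # already unit: identity
  dm <- density_map(array(rnorm(5^3), c(5, 5, 5)))
  expect_identical(resample_to_unit_voxel(dm), dm)

  # constant field at 0.5 A: constant output with halved voxel extent
  cm <- density_map(array(7, c(100, 21, 21)), voxel = 0.5)
  rc <- resample_to_unit_voxel(cm)
  expect_equal(rc$voxel, c(1, 1, 1))
  expect_equal(dim(rc$grid)[1], 50L)
  expect_true(all(abs(rc$grid - 7) < 1e-12))

  # linear ramp sampled at 0.8 A: trilinear interpolation is exact
  ramp <- array(0, c(80, 12, 12))
  for (i in 1:80) ramp[i, , ] <- (i - 1) * 0.8
  rr <- resample_to_unit_voxel(density_map(ramp, voxel = 0.8))
  d <- dim(rr$grid)
  interior <- rr$grid[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)]
  expected <- array(rep(1:(d[1] - 2), times = (d[2] - 2) * (d[3] - 2)),
                    dim(interior))
  expect_lt(max(abs(interior - expected)), 1e-6)

  expect_error(resample_to_unit_voxel(
    density_map(array(1, c(1, 5, 5)), voxel = 0.5)), "degenerate")
})

test_that("resampling keeps the world position of a Gaussian peak", {
  m <- atomic_model(data.frame(atom_name = "CA", element = "C",
                               chain_id = "A", residue_index = 1L,
                               residue_name = "ALA", x = 4.3, y = 5.1,
                               z = 6.2, stringsAsFactors = FALSE))
  dm <- simulate_density(m, resolution = 4, voxel = 0.7)
  rs <- resample_to_unit_voxel(dm)
  peak <- arrayInd(which.max(rs$grid), dim(rs$grid))
  pos <- rs$origin + (peak - 1) * rs$voxel
  expect_lt(max(abs(pos - c(4.3, 5.1, 6.2))), 1.0 + 1e-9)
})

test_that("cube split uses the 64/50/7 scheme and stitch inverts it", {
  set.seed(3)
  a <- array(rnorm(64^3), c(64, 64, 64))
  sp <- split_into_cubes(a)
  expect_equal(sp$grid$cube_edge, 64L)
  expect_equal(sp$grid$core_edge, 50L)
  expect_equal(sp$grid$margin, 7L)
  expect_length(sp$cubes, 8L)               # ceil(64/50)^3
  expect_identical(stitch_cubes(sp$cubes, sp$grid), a)

  b <- array(rnorm(50^3), c(50, 50, 50))
  spb <- split_into_cubes(b)
  expect_length(spb$cubes, 1L)
  expect_identical(stitch_cubes(spb$cubes, spb$grid), b)
})

test_that("split/stitch identity holds across volume shapes", {
  set.seed(4)
  shapes <- list(c(1, 1, 1), c(7, 3, 5), c(50, 50, 50), c(64, 50, 31),
                 c(101, 64, 55), c(130, 49, 72))
  for (sh in shapes) {
    a <- array(rnorm(prod(sh)), sh)
    sp <- split_into_cubes(a)
    expect_identical(stitch_cubes(sp$cubes, sp$grid), a)
  }
})

test_that("cube cores tile the volume disjointly", {
  sp <- split_into_cubes(array(0, c(120, 60, 60)))
  marked <- lapply(seq_along(sp$cubes), function(i) {
    array(i, rep(sp$grid$cube_edge, 3))
  })
  st <- stitch_cubes(marked, sp$grid)
  # every voxel belongs to exactly one core; block boundaries at
  # multiples of the 50-voxel core edge
  expect_true(all(st >= 1))
  expect_identical(unique(as.integer(st[1:50, 1:50, 1:50])), 1L)
  expect_true(all(diff(st[, 1, 1]) >= 0))
  expect_equal(unname(st[51, 1, 1] - st[50, 1, 1]), 1)
})

test_that("training-set builder augments 4x and round-trips bit-exactly", {
  models <- lapply(1:2, function(i) generate_synthetic_protein(
    list(c("helix", 6), c("loop", 3)), seed = 20 + i))
  f <- tempfile(fileext = ".rds")
  build_training_set(models, c(3, 4), f, augment = TRUE, seed = 3,
                     sample_edge = 24L)
  ds <- read_training_set(f)
  expect_length(ds$samples, 8L)  # 4 rotations x 2 models
  expect_equal(vapply(ds$samples, function(s) s$attrs$rotation, 0L),
               rep(c(0L, 90L, 180L, 270L), 2))
  # joint rotation: rotating labels back recovers the unrotated labels
  r0 <- ds$samples[[1]]; r180 <- ds$samples[[3]]
  back <- cryotrace:::rotate_z90(r180$calpha, 2)
  expect_identical(back, r0$calpha)
  expect_identical(cryotrace:::rotate_z90(r180$density, 2), r0$density)

  # reload reproduces tensors bit-exactly
  ds2 <- read_training_set(f)
  expect_identical(ds2$samples[[5]]$density, ds$samples[[5]]$density)

  # deterministic per seed
  f2 <- tempfile(fileext = ".rds")
  build_training_set(models, c(3, 4), f2, augment = TRUE, seed = 3,
                     sample_edge = 24L)
  expect_identical(read_training_set(f2)$samples[[2]]$density,
                   ds$samples[[2]]$density)
})
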