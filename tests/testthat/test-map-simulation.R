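single_atom_model <- function(p, name = "CA") {
  atomic_model(data.frame(atom_name = name, element = "C", chain_id = "A",
                          residue_index = 1L, residue_name = "ALA",
                          x = p[1], y = p[2], z = p[3],
                          stringsAsFactors = FALSE))
}

test_that("simulated density peaks at the atom and sums linearly", {
  m1 <- single_atom_model(c(3, 4, 5))
  d1 <- simulate_density(m1, resolution = 3, voxel = 1, padding = 5)
  peak <- arrayInd(which.max(d1$grid), dim(d1$grid))
  expect_equal(as.numeric(index_pos <- d1$origin + (peak - 1) * d1$voxel),
               c(3, 4, 5))

  m2 <- single_atom_model(c(8, 4, 5))
  atoms <- rbind(m1$atoms, m2$atoms)
  atoms$residue_index <- 1:2
  m12 <- atomic_model(atoms)
  d12 <- simulate_density(m12, resolution = 3, voxel = 1, padding = 5)
  # voxelwise sum of the single-atom maps on the joint grid
  g1 <- vapply(1:2, function(a) {
    mm <- m12; mm$atoms <- mm$atoms[a, ]
    dd <- simulate_density(atomic_model(mm$atoms), resolution = 3)
    off <- round((dd$origin - d12$origin) / d12$voxel)
    out <- array(0, dim(d12$grid))
    idx <- list(seq_len(dim(dd$grid)[1]) + off[1],
                seq_len(dim(dd$grid)[2]) + off[2],
                seq_len(dim(dd$grid)[3]) + off[3])
    keep <- lapply(seq_len(3), function(ax) which(idx[[ax]] >= 1 &
                                                    idx[[ax]] <= dim(d12$grid)[ax]))
    out[idx[[1]][keep[[1]]], idx[[2]][keep[[2]]], idx[[3]][keep[[3]]]] <-
      dd$grid[keep[[1]], keep[[2]], keep[[3]]]
    out
  }, array(0, dim(d12$grid)))
  expect_lt(max(abs(d12$grid - (g1[, , , 1] + g1[, , , 2]))), 1e-6)
})

test_that("well-separated atoms contribute N times the single-atom mass", {
  p0 <- c(0, 0, 0)
  single <- simulate_density(single_atom_model(p0), resolution = 3,
                             padding = 8)
  mass1 <- sum(single$grid)
  pts <- rbind(c(0, 0, 0), c(25, 0, 0), c(0, 25, 0), c(0, 0, 25))
  atoms <- do.call(rbind, lapply(seq_len(4), function(i) {
    a <- single_atom_model(pts[i, ])$atoms
    a$residue_index <- i
    a
  }))
  multi <- simulate_density(atomic_model(atoms), resolution = 3, padding = 8)
  expect_lt(abs(sum(multi$grid) - 4 * mass1) / (4 * mass1), 0.01)
})

test_that("density simulation is translation-equivariant", {
  m <- generate_synthetic_protein(list(c("helix", 8)), seed = 2)
  d0 <- simulate_density(m, resolution = 3, voxel = 1)
  m2 <- m
  m2$atoms$x <- m2$atoms$x + 1  # one voxel
  d1 <- simulate_density(m2, resolution = 3, voxel = 1)
  expect_equal(d1$origin - d0$origin, c(1, 0, 0))
  expect_lt(max(abs(d1$grid - d0$grid)), 1e-5 * max(d0$grid))
})

test_that("label maps mark the right voxels", {
  # single CA on a voxel center: exactly the 7 voxels within 1 A
  m <- single_atom_model(c(5, 5, 5))
  ref <- density_map(array(0, c(11, 11, 11)))
  labs <- generate_label_maps(m, ref, r_ca = 1.0, r_bb = 1.2)
  expect_equal(sum(labs$calpha), 7L)
  expect_true(all(labs$backbone[labs$calpha]))

  prot <- generate_synthetic_protein(list(c("strand", 6), c("loop", 4)),
                                     seed = 1)
  dm <- simulate_density(prot, resolution = 3, voxel = 1)
  lm <- generate_label_maps(prot, dm)
  expect_equal(sum(lm$helix), 0L)            # no helix residues
  expect_true(all(lm$backbone[lm$calpha]))   # calpha subset of backbone
  # helix/sheet/loop mutually exclusive
  expect_true(all(lm$helix + lm$sheet + lm$loop <= 1))
  expect_identical(dim(lm$calpha), dim(dm$grid))

  out <- m
  out$atoms$x <- 1e4
  expect_error(generate_label_maps(out, ref), "outside")
})

test_that("MRC round-trip preserves grid, voxel sizes and origin", {
  set.seed(4)
  g <- array(rnorm(6 * 7 * 8), c(6, 7, 8))
  dm <- density_map(g, voxel = c(1.2, 0.9, 1.5), origin = c(5, -3, 2))
  f <- tempfile(fileext = ".mrc")
  write_mrc(dm, f)
  back <- read_mrc(f)
  expect_identical(dim(back$grid), dim(g))
  expect_lt(max(abs(back$grid - g)), 1e-5)      # float32 data block
  expect_equal(back$voxel, dm$voxel, tolerance = 1e-6)
  expect_equal(back$origin, dm$origin, tolerance = 1e-6)

  con <- file(f, "r+b")
  writeBin(c(10L, 10L, 10L), con, size = 4, endian = "little")
  close(con)
  expect_error(read_mrc(f), "truncated|malformed")
})

test_that("permuted MRC axis order is normalized on read", {
  set.seed(5)
  g <- array(rnorm(4 * 5 * 6), c(4, 5, 6))  # asymmetric volume
  dm <- density_map(g, voxel = c(1, 1, 1))
  f <- tempfile(fileext = ".mrc")
  write_mrc(dm, f)
  # rewrite header as if sections were the X axis: file stores (z,x,y)
  perm <- aperm(g, c(3, 1, 2))
  dmp <- density_map(perm)
  f2 <- tempfile(fileext = ".mrc")
  write_mrc(dmp, f2)
  con <- file(f2, "r+b")
  hdr <- readBin(con, "raw", 1024)
  # MAPC/MAPR/MAPS words 17:19 -> file axes are world z, x, y
  hdr[65:76] <- writeBin(c(3L, 1L, 2L), raw(), size = 4, endian = "little")
  seek(con, 0)
  writeBin(hdr, con)
  close(con)
  back <- read_mrc(f2)
  expect_identical(dim(back$grid), dim(g))
  expect_lt(max(abs(back$grid - g)), 1e-5)
})
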