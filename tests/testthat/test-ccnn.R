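# small training set shared across network tests
tiny_dataset <- function(n = 2, edge = 12L, seed = 30) {
  models <- lapply(seq_len(n), function(i) generate_synthetic_protein(
    list(c("helix", 5), c("loop", 3)), seed = seed + i))
  f <- tempfile(fileext = ".rds")
  build_training_set(models, c(3, 4), f, augment = FALSE, seed = seed,
                     sample_edge = edge)
  f
}

test_that("the cascade exposes the documented layer plan", {
  net <- build_ccnn(seed = 1)
  spec <- ccnn_spec(net)
  sse <- spec[spec$stage == "sse", ]
  expect_equal(sse$filters, c(32L, 64L, 64L, 3L))
  expect_equal(sse$kernel, rep(5L, 4))
  expect_equal(spec[spec$stage == "backbone", "filters"],
               c(32L, 64L, 64L, 2L))
  expect_equal(spec[spec$stage == "calpha", "kernel"], rep(4L, 4))
  expect_equal(spec$dilation[spec$layer %in% 2:3], rep(2L, 6))
  expect_equal(spec$dilation[spec$layer %in% c(1, 4)], rep(1L, 6))
  expect_equal(spec$activation[spec$layer %in% 2:3], rep("lrelu", 6))
  # cascade input channels: density; +SSE; +SSE+backbone
  expect_equal(spec$cin[spec$layer == 1], c(1L, 4L, 6L))
  expect_equal(net$alpha, 0.1)
})

test_that("zero weights give uniform confidences and input-shaped output", {
  net <- build_ccnn(zero_weights = TRUE)
  dm <- density_map(array(rnorm(6^3), c(6, 6, 6)))
  cm <- predict_confidence(net, dm, cube_edge = 20L, margin = 7L)
  expect_identical(dim(cm$calpha), dim(dm$grid))
  expect_true(all(abs(cm$helix - 1 / 3) < 1e-12))
  expect_true(all(abs(cm$sheet - 1 / 3) < 1e-12))
  expect_true(all(abs(cm$backbone - 1 / 2) < 1e-12))
  expect_true(all(abs(cm$calpha - 1 / 2) < 1e-12))
})

test_that("forward pass preserves shape and emits proper probabilities", {
  net <- build_ccnn(seed = 2)
  x <- array(rnorm(10 * 12 * 14), c(10, 12, 14))
  fw <- cryotrace:::ccnn_forward(net, x)
  expect_identical(dim(fw$p_sse), c(10L, 12L, 14L, 3L))
  expect_identical(dim(fw$p_bb), c(10L, 12L, 14L, 2L))
  expect_identical(dim(fw$p_ca), c(10L, 12L, 14L, 2L))
  sums <- fw$p_sse[, , , 1] + fw$p_sse[, , , 2] + fw$p_sse[, , , 3]
  expect_lt(max(abs(sums - 1)), 1e-6)
  expect_true(all(fw$p_ca >= 0 & fw$p_ca <= 1))
})

test_that("each stage is translation-equivariant beyond its receptive field", {
  # a single stage has one-sided receptive field 12 voxels (2+4+4+2),
  # so content shifted within a 48-cube must reproduce exactly in the
  # region at least 12 voxels from every array edge in both frames
  net <- build_ccnn(seed = 3)
  set.seed(6)
  for (stage in c("sse", "calpha")) {
    st <- net$stages[[stage]]
    cin <- st$layers[[1]]$cin
    y <- array(0, c(48, 48, 48, cin))
    y[20:27, 20:27, 20:27, ] <- runif(512 * cin)
    y2 <- array(0, c(48, 48, 48, cin))
    y2[28:35, 20:27, 20:27, ] <- y[20:27, 20:27, 20:27, ]  # +8 in x
    g1 <- cryotrace:::stage_forward(st, y, net$alpha)$logits
    g2 <- cryotrace:::stage_forward(st, y2, net$alpha)$logits
    expect_lt(max(abs(g2[21:36, 13:36, 13:36, ] -
                        g1[13:28, 13:36, 13:36, ])), 1e-4)
  }
})

test_that("zero-padding the input does not change deep-interior output", {
  # the full cascade sees up to 36 voxels away, so compare only the
  # region beyond that distance from every array edge in both frames
  net <- build_ccnn(seed = 4)
  set.seed(7)
  x <- array(runif(72^3), c(72, 72, 72))
  padded <- array(0, c(92, 92, 92))
  padded[11:82, 11:82, 11:82] <- x
  f1 <- cryotrace:::ccnn_forward(net, x)
  f2 <- cryotrace:::ccnn_forward(net, padded)
  win1 <- 31:36           # >= 30 from the low edge, >= 36 from the high
  win2 <- win1 + 10
  expect_lt(max(abs(f2$p_ca[win2, win2, win2, 2] -
                      f1$p_ca[win1, win1, win1, 2])), 1e-5)
  expect_lt(max(abs(f2$p_sse[win2, win2, win2, 1] -
                      f1$p_sse[win1, win1, win1, 1])), 1e-5)
})

test_that("training reduces the loss and is deterministic per seed", {
  ds <- tiny_dataset()
  net <- build_ccnn(seed = 5)
  fit1 <- train_ccnn(net, ds, epochs = 3, max_steps = 6, lr = 1e-3, seed = 9)
  expect_length(fit1$history, 6L)
  fit2 <- train_ccnn(net, ds, epochs = 3, max_steps = 6, lr = 1e-3, seed = 9)
  expect_identical(fit1$history, fit2$history)
  expect_error(train_ccnn(net, list(samples = list()), epochs = 1), "empty")
})

test_that("the network can overfit a single sample", {
  ds <- read_training_set(tiny_dataset(n = 1))
  net <- build_ccnn(seed = 6)
  fit <- train_ccnn(net, ds, epochs = 50, max_steps = 50, lr = 1e-3,
                    seed = 10)
  h <- fit$history
  expect_lt(h[50], h[1])
  expect_lt(median(h[41:50]), 0.5 * median(h[1:10]))
  # probabilities stay normalized after training
  fw <- cryotrace:::ccnn_forward(fit$model, ds$samples[[1]]$density)
  sums <- fw$p_sse[, , , 1] + fw$p_sse[, , , 2] + fw$p_sse[, , , 3]
  expect_lt(max(abs(sums - 1)), 1e-6)
})

test_that("checkpoints round-trip through save/load with a JSON sidecar", {
  net <- build_ccnn(seed = 7)
  f <- tempfile(fileext = ".ccnn")
  save_ccnn(net, f)
  expect_true(file.exists(paste0(f, ".json")))
  back <- load_ccnn(f)
  expect_equal(back$stages$sse$layers[[2]]$w, net$stages$sse$layers[[2]]$w)
  expect_error(load_ccnn(tempfile()), "not found")
})

test_that("stitched prediction is independent of cube bookkeeping", {
  # prediction through the cube pipeline equals a direct forward pass
  # when the map fits a single cube core
  net <- build_ccnn(seed = 8)
  dm <- density_map(array(rnorm(8^3), c(8, 8, 8)))
  p <- predict_confidence(net, dm, cube_edge = 22L, margin = 7L)
  fw <- cryotrace:::ccnn_forward(net, cryotrace:::split_into_cubes(
    dm$grid, 22L, 7L)$cubes[[1]])
  expect_lt(max(abs(p$calpha -
                      fw$p_ca[8:15, 8:15, 8:15, 2])), 1e-12)
})

test_that("oracle confidence maps are idealized and well-formed", {
  m <- generate_synthetic_protein(list(c("helix", 8), c("loop", 4)),
                                  seed = 12)
  dm <- simulate_density(m, resolution = 3, voxel = 1)
  cm <- oracle_confidence(m, dm)
  expect_s3_class(cm, "confidence_maps")
  expect_equal(max(cm$calpha), 1)
  # the voxel nearest each CA reads exactly 1
  cc <- ca_coords(m)
  idx <- round(cryotrace:::world_to_index(cc, cm$origin, cm$voxel))
  expect_true(all(abs(cm$calpha[idx] - 1) < 1e-12))
  sums <- cm$helix + cm$sheet + cm$loop
  expect_lt(max(abs(sums - 1)), 1e-12)
  # empty model: background maps with a warning
  empty <- m
  empty$atoms <- empty$atoms[empty$atoms$atom_name == "XX", ]
  expect_warning(cm0 <- oracle_confidence(
    structure(list(atoms = empty$atoms, sse = m$sse),
              class = "atomic_model"), dm), "empty")
  expect_true(all(cm0$calpha == 0))
  expect_true(all(abs(cm0$helix - 1 / 3) < 1e-12))
})
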