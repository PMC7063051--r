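#' Confidence maps container
#'
#' Five per-voxel probability volumes aligned to the input grid: the
#' three-class secondary-structure group (`helix + sheet + loop = 1` at
#' every voxel) plus the positive-class probabilities of the two-class
#' backbone and C-alpha heads.
#'
#' @param helix,sheet,loop,backbone,calpha 3D probability arrays.
#' @param voxel,origin grid metadata (as in [density_map()]).
#' @return Object of class `confidence_maps`.
#' @export
confidence_maps <- function(helix, sheet, loop, backbone, calpha,
                            voxel = c(1, 1, 1), origin = c(0, 0, 0)) {
  d <- dim(helix)
  stopifnot(identical(dim(sheet), d), identical(dim(loop), d),
            identical(dim(backbone), d), identical(dim(calpha), d))
  structure(list(helix = helix, sheet = sheet, loop = loop,
                 backbone = backbone, calpha = calpha,
                 voxel = rep_len(as.numeric(voxel), 3),
                 origin = rep_len(as.numeric(origin), 3)),
            class = "confidence_maps")
}

#' @export
print.confidence_maps <- function(x, ...) {
  d <- dim(x$calpha)
  cat(sprintf("<confidence_maps> %d x %d x %d voxels\n", d[1], d[2], d[3]))
  cat(sprintf("  max calpha %.3f, max backbone %.3f\n",
              max(x$calpha), max(x$backbone)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Network definition
# ---------------------------------------------------------------------------

# Per-stage layer plan. Every stage has four layers, filters 32/64/64/n
# with n the number of output classes; layers 2-3 are dilated (rate 2)
# and followed by leaky-ReLU(0.1); strides are all 1 and padding is
# "same", so spatial shape is preserved end to end. Kernels are 5^3 for
# the SSE and backbone stages and 4^3 for the C-alpha stage.
ccnn_plan <- function() {
  list(
    sse      = list(cin = 1L, classes = 3L, kernel = 5L),
    backbone = list(cin = 4L, classes = 2L, kernel = 5L),
    calpha   = list(cin = 6L, classes = 2L, kernel = 4L)
  )
}

new_conv_layer <- function(k, cin, cout, dil, act) {
  fan_in <- k^3 * cin
  w <- matrix(stats::rnorm(k^3 * cin * cout, sd = sqrt(2 / fan_in)),
              nrow = k^3 * cin, ncol = cout)
  list(w = w, b = numeric(cout), k = as.integer(k), cin = as.integer(cin),
       cout = as.integer(cout), dil = as.integer(dil), act = act)
}

build_stage <- function(plan) {
  k <- plan$kernel
  widths <- c(plan$cin, 32L, 64L, 64L, plan$classes)
  dils <- c(1L, 2L, 2L, 1L)
  acts <- c("linear", "lrelu", "lrelu", "linear")
  layers <- lapply(1:4, function(i) {
    new_conv_layer(k, widths[i], widths[i + 1], dils[i], acts[i])
  })
  list(kernel = k, layers = layers)
}

#' Build the cascaded segmentation network
#'
#' Three four-layer dilated 3D CNN stages evaluated in cascade: the SSE
#' stage sees the density (1 channel); the backbone stage sees density
#' plus the three SSE probabilities (4 channels); the C-alpha stage sees
#' density, SSE and backbone probabilities (6 channels). Each stage uses
#' filters 32/64/64/n_classes, dilation rate 2 on layers 2-3 with
#' leaky-ReLU(0.1) activations, stride 1 and zero ("same") padding, so
#' every output volume matches the input volume voxel for voxel.
#' Softmax heads turn the final layer into per-class confidences.
#'
#' @param seed optional seed for reproducible weight initialization.
#' @param zero_weights logical; start from all-zero weights (the forward
#'   pass then yields uniform class probabilities everywhere).
#' @return Object of class `ccnn`.
#' @export
build_ccnn <- function(seed = NULL, zero_weights = FALSE) {
  plans <- ccnn_plan()
  stages <- with_seed(seed, lapply(plans, build_stage))
  if (zero_weights) {
    stages <- lapply(stages, function(st) {
      st$layers <- lapply(st$layers, function(l) { l$w[] <- 0; l })
      st
    })
  }
  structure(list(stages = stages, alpha = 0.1, trained = FALSE),
            class = "ccnn")
}

#' @export
print.ccnn <- function(x, ...) {
  cat("<ccnn> cascaded 3-stage dilated 3D CNN",
      if (x$trained) "(trained)" else "(untrained)", "\n")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-8s kernel %d^3, filters %s\n", nm, st$kernel,
                paste(vapply(st$layers, function(l) l$cout, 0L),
                      collapse = "/")))
  }
  invisible(x)
}

#' Query the layer specification of a built network
#'
#' @param model a `ccnn`.
#' @return Data frame with one row per layer: stage, layer index, kernel
#'   size, dilation, input/output channel counts, activation.
#' @export
ccnn_spec <- function(model) {
  stopifnot(inherits(model, "ccnn"))
  do.call(rbind, lapply(names(model$stages), function(nm) {
    st <- model$stages[[nm]]
    do.call(rbind, lapply(seq_along(st$layers), function(i) {
      l <- st$layers[[i]]
      data.frame(stage = nm, layer = i, kernel = l$k, dilation = l$dil,
                 cin = l$cin, filters = l$cout, activation = l$act,
                 stringsAsFactors = FALSE)
    }))
  }))
}

lrelu <- function(z, alpha) pmax(z, 0) + alpha * pmin(z, 0)
lrelu_grad <- function(z, alpha) (z > 0) + alpha * (z <= 0)

# softmax over the 4th (channel) dimension
softmax4 <- function(z) {
  d <- dim(z)
  m <- matrix(z, ncol = d[4])
  mx <- m[, 1]
  for (j in 2:d[4]) mx <- pmax(mx, m[, j])
  e <- exp(m - mx)
  p <- e / rowSums(e)
  array(p, d)
}

# channel concatenation (column-major layout makes this a plain c())
concat4 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])[1:3]
  ch <- sum(vapply(parts, function(p) dim(p)[4], 0))
  array(unlist(parts, use.names = FALSE), c(d, ch))
}

stage_forward <- function(stage, x, alpha, keep_cache = FALSE) {
  h <- x
  cache <- if (keep_cache) vector("list", length(stage$layers)) else NULL
  for (i in seq_along(stage$layers)) {
    l <- stage$layers[[i]]
    z <- conv3d_fwd(h, dim(h), l$w, l$b, l$k, l$dil)
    if (keep_cache) cache[[i]] <- list(x = h, z = if (l$act == "lrelu") z)
    h <- if (l$act == "lrelu") lrelu(z, alpha) else z
  }
  list(logits = h, cache = cache)
}

stage_backward <- function(stage, cache, dlogits, alpha, need_dx = TRUE) {
  grads <- vector("list", length(stage$layers))
  dh <- dlogits
  for (i in rev(seq_along(stage$layers))) {
    l <- stage$layers[[i]]
    dz <- if (l$act == "lrelu") dh * lrelu_grad(cache[[i]]$z, alpha) else dh
    want_dx <- need_dx || i > 1
    bw <- conv3d_bwd(cache[[i]]$x, dim(cache[[i]]$x), dz, l$w, l$k, l$dil,
                     want_dx)
    grads[[i]] <- list(dw = bw$dw, db = bw$db)
    dh <- if (want_dx) bw$dx else NULL
  }
  list(grads = grads, dx = dh)
}

# Full cascade forward on a single-channel density volume (3D array).
ccnn_forward <- function(model, density, keep_cache = FALSE) {
  d3 <- dim(density)
  x1 <- array(density, c(d3, 1L))
  f1 <- stage_forward(model$stages$sse, x1, model$alpha, keep_cache)
  p_sse <- softmax4(f1$logits)
  x2 <- concat4(x1, p_sse)
  f2 <- stage_forward(model$stages$backbone, x2, model$alpha, keep_cache)
  p_bb <- softmax4(f2$logits)
  x3 <- concat4(x1, p_sse, p_bb)
  f3 <- stage_forward(model$stages$calpha, x3, model$alpha, keep_cache)
  p_ca <- softmax4(f3$logits)
  list(p_sse = p_sse, p_bb = p_bb, p_ca = p_ca,
       caches = if (keep_cache) list(sse = f1$cache, backbone = f2$cache,
                                     calpha = f3$cache))
}

# Weighted softmax cross-entropy over voxels.
# probs, onehot: (nvox x C); wts: per-class weights.
# Returns loss and gradient w.r.t. logits (normalized by total weight).
ce_loss_grad <- function(probs, onehot, wts) {
  vw <- as.numeric(onehot %*% wts)
  tot <- sum(vw)
  p_true <- rowSums(probs * onehot)
  loss <- -sum(vw * log(pmax(p_true, 1e-12))) / tot
  dlogits <- (probs - onehot) * (vw / tot)
  list(loss = loss, dlogits = dlogits)
}

# Jacobian-vector product of softmax: dz from dp at probabilities p.
softmax_vjp <- function(dp, p) {
  inner <- rowSums(dp * p)
  p * (dp - inner)
}

# one-hot targets from a training sample record
sample_targets <- function(rec) {
  d <- dim(rec$density)
  nvox <- prod(d)
  hx <- as.numeric(rec$helix) > 0
  sh <- as.numeric(rec$sheet) > 0
  lp <- as.numeric(rec$loop) > 0
  bb <- as.numeric(rec$backbone) > 0
  ca <- as.numeric(rec$calpha) > 0
  # background voxels fall into the loop/turn class of the 3-class group
  lp_all <- lp | !(hx | sh)
  t_sse <- cbind(helix = hx, sheet = sh, loop = lp_all & !hx & !sh) * 1
  t_bb <- cbind(bg = !bb, bb = bb) * 1
  t_ca <- cbind(bg = !ca, ca = ca) * 1
  list(sse = t_sse, bb = t_bb, ca = t_ca, nvox = nvox)
}

# Inverse-frequency class weights over a dataset, normalized to mean 1.
dataset_class_weights <- function(samples) {
  cnt_sse <- c(0, 0, 0); cnt_bb <- c(0, 0); cnt_ca <- c(0, 0)
  for (rec in samples) {
    tg <- sample_targets(rec)
    cnt_sse <- cnt_sse + colSums(tg$sse)
    cnt_bb <- cnt_bb + colSums(tg$bb)
    cnt_ca <- cnt_ca + colSums(tg$ca)
  }
  inv <- function(cnt) {
    w <- sum(cnt) / (length(cnt) * pmax(cnt, 1))
    w / mean(w)
  }
  list(sse = inv(cnt_sse), bb = inv(cnt_bb), ca = inv(cnt_ca))
}

# Loss and parameter gradients for one sample, backpropagating through
# the cascade (earlier stages receive gradients from later stages unless
# stop_gradient is set).
ccnn_loss_grad <- function(model, rec, wts, stop_gradient = FALSE) {
  fw <- ccnn_forward(model, rec$density, keep_cache = TRUE)
  tg <- sample_targets(rec)
  d4 <- dim(fw$p_sse)
  nvox <- tg$nvox

  m_sse <- matrix(fw$p_sse, ncol = 3)
  m_bb <- matrix(fw$p_bb, ncol = 2)
  m_ca <- matrix(fw$p_ca, ncol = 2)

  ce_sse <- ce_loss_grad(m_sse, tg$sse, wts$sse)
  ce_bb <- ce_loss_grad(m_bb, tg$bb, wts$bb)
  ce_ca <- ce_loss_grad(m_ca, tg$ca, wts$ca)
  loss <- ce_sse$loss + ce_bb$loss + ce_ca$loss

  # calpha stage
  dlog_ca <- array(ce_ca$dlogits, c(d4[1:3], 2L))
  bw_ca <- stage_backward(model$stages$calpha, fw$caches$calpha, dlog_ca,
                          model$alpha, need_dx = !stop_gradient)
  dp_sse_m <- matrix(0, nvox, 3)
  dp_bb_m <- matrix(0, nvox, 2)
  if (!stop_gradient) {
    dx3 <- matrix(bw_ca$dx, ncol = 6)
    dp_sse_m <- dp_sse_m + dx3[, 2:4]
    dp_bb_m <- dp_bb_m + dx3[, 5:6]
  }

  # backbone stage: cross-entropy plus downstream probability gradient
  dlog_bb_m <- ce_bb$dlogits + softmax_vjp(dp_bb_m, m_bb)
  bw_bb <- stage_backward(model$stages$backbone, fw$caches$backbone,
                          array(dlog_bb_m, c(d4[1:3], 2L)),
                          model$alpha, need_dx = !stop_gradient)
  if (!stop_gradient) {
    dx2 <- matrix(bw_bb$dx, ncol = 4)
    dp_sse_m <- dp_sse_m + dx2[, 2:4]
  }

  # SSE stage
  dlog_sse_m <- ce_sse$dlogits + softmax_vjp(dp_sse_m, m_sse)
  bw_sse <- stage_backward(model$stages$sse, fw$caches$sse,
                           array(dlog_sse_m, c(d4[1:3], 3L)),
                           model$alpha, need_dx = FALSE)

  list(loss = loss,
       parts = c(sse = ce_sse$loss, backbone = ce_bb$loss, calpha = ce_ca$loss),
       grads = list(sse = bw_sse$grads, backbone = bw_bb$grads,
                    calpha = bw_ca$grads))
}

adam_init <- function(model) {
  lapply(model$stages, function(st) {
    lapply(st$layers, function(l) {
      list(mw = l$w * 0, vw = l$w * 0, mb = l$b * 0, vb = l$b * 0)
    })
  })
}

adam_step <- function(model, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  corr1 <- 1 - beta1^t
  corr2 <- 1 - beta2^t
  for (nm in names(model$stages)) {
    for (i in seq_along(model$stages[[nm]]$layers)) {
      g <- grads[[nm]][[i]]
      s <- state[[nm]][[i]]
      s$mw <- beta1 * s$mw + (1 - beta1) * g$dw
      s$vw <- beta2 * s$vw + (1 - beta2) * g$dw^2
      s$mb <- beta1 * s$mb + (1 - beta1) * g$db
      s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
      model$stages[[nm]]$layers[[i]]$w <-
        model$stages[[nm]]$layers[[i]]$w -
        lr * (s$mw / corr1) / (sqrt(s$vw / corr2) + eps)
      model$stages[[nm]]$layers[[i]]$b <-
        model$stages[[nm]]$layers[[i]]$b -
        lr * (s$mb / corr1) / (sqrt(s$vb / corr2) + eps)
      state[[nm]][[i]] <- s
    }
  }
  list(model = model, state = state)
}

#' Train the cascaded network
#'
#' Joint training of all three stages: the loss is the sum of the three
#' per-voxel weighted cross-entropies (3-class SSE, 2-class backbone,
#' 2-class C-alpha) with inverse-frequency class weights computed from
#' the dataset, and gradients flow end to end through the forwarded
#' probability maps (disable with `stop_gradient`). Optimization uses
#' Adam with batch size one sample cube; sample order is reshuffled
#' every epoch under the given seed, so the loss history is
#' deterministic for a fixed seed.
#'
#' @param model a `ccnn` from [build_ccnn()].
#' @param dataset a training-set path or the object from
#'   [read_training_set()].
#' @param epochs maximum passes over the dataset (default 15).
#' @param max_steps optional cap on total optimizer steps.
#' @param lr Adam learning rate.
#' @param seed RNG seed controlling the sample order.
#' @param stop_gradient block gradient flow between cascade stages.
#' @return List with `model` (trained `ccnn`), `history` (per-step
#'   total loss) and `class_weights`.
#' @export
train_ccnn <- function(model, dataset, epochs = 15L, max_steps = NULL,
                       lr = 1e-4, seed = 1, stop_gradient = FALSE) {
  stopifnot(inherits(model, "ccnn"), epochs >= 1)
  ds <- if (is.character(dataset)) read_training_set(dataset) else dataset
  samples <- ds$samples
  if (length(samples) == 0) stop("empty dataset")
  wts <- dataset_class_weights(samples)
  state <- adam_init(model)
  history <- numeric(0)
  step <- 0L
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(samples))
      for (si in ord) {
        step <- step + 1L
        lg <- ccnn_loss_grad(model, samples[[si]], wts, stop_gradient)
        upd <- adam_step(model, lg$grads, state, lr, step)
        model <- upd$model
        state <- upd$state
        history[step] <- lg$loss
        if (!is.null(max_steps) && step >= max_steps) break
      }
      if (!is.null(max_steps) && step >= max_steps) break
    }
  })
  model$trained <- TRUE
  list(model = model, history = history, class_weights = wts)
}

#' Predict confidence maps for a density map
#'
#' Splits the (unit-voxel, preprocessed) map into overlapping cubes,
#' runs each through the cascade, and stitches the five output volumes
#' back from the cube cores, yielding probability volumes congruent to
#' the input grid.
#'
#' @param model a `ccnn` (typically the `$model` of [train_ccnn()]).
#' @param map a [density_map()] with 1 A voxels.
#' @param cube_edge,margin cube tiling parameters (defaults 64 and 7).
#' @return A [confidence_maps()] object.
#' @export
predict_confidence <- function(model, map, cube_edge = 64L, margin = 7L) {
  stopifnot(inherits(model, "ccnn"), inherits(map, "density_map"))
  if (any(abs(map$voxel - 1) > 1e-6)) {
    stop("predict_confidence expects a map resampled to 1 A voxels")
  }
  sp <- split_into_cubes(map$grid, cube_edge, margin)
  outs <- list(helix = list(), sheet = list(), loop = list(),
               backbone = list(), calpha = list())
  for (i in seq_along(sp$cubes)) {
    fw <- ccnn_forward(model, sp$cubes[[i]], keep_cache = FALSE)
    outs$helix[[i]] <- fw$p_sse[, , , 1]
    outs$sheet[[i]] <- fw$p_sse[, , , 2]
    outs$loop[[i]] <- fw$p_sse[, , , 3]
    outs$backbone[[i]] <- fw$p_bb[, , , 2]
    outs$calpha[[i]] <- fw$p_ca[, , , 2]
  }
  vols <- lapply(outs, stitch_cubes, grid = sp$grid)
  confidence_maps(vols$helix, vols$sheet, vols$loop, vols$backbone,
                  vols$calpha, map$voxel, map$origin)
}

#' Idealized confidence maps from ground-truth coordinates
#'
#' Generates the confidence volumes a perfect segmentation network
#' would produce, directly from an atomic model: `calpha` is a
#' max-combined Gaussian splat (width `sigma`) at each CA position,
#' normalized so the voxel nearest each CA reads 1; `backbone` is the
#' same over N/CA/C atoms; the SSE group is one-hot by the label of the
#' nearest residue where backbone confidence is appreciable and uniform
#' (1/3) elsewhere. Used to exercise tracing, refinement and scoring
#' without a trained network.
#'
#' @param model an [atomic_model()]; an empty model yields
#'   all-background maps with a warning.
#' @param reference a [density_map()] supplying the grid.
#' @param sigma splat width in A; the default 0.8 keeps CA pairs at
#'   bonding distance (>= 2.8 A) separable as local maxima.
#' @param bb_floor backbone confidence above which SSE voxels are
#'   one-hot labeled.
#' @return A [confidence_maps()] object.
#' @export
oracle_confidence <- function(model, reference, sigma = 0.8, bb_floor = 0.25) {
  stopifnot(inherits(reference, "density_map"))
  dims <- dim(reference$grid)
  voxel <- reference$voxel
  origin <- reference$origin
  zero <- array(0, dims)
  bb <- model$atoms[model$atoms$atom_name %in% c("N", "CA", "C"), ]
  if (nrow(bb) == 0) {
    warning("empty model: oracle confidence maps are all background")
    return(confidence_maps(array(1 / 3, dims), array(1 / 3, dims),
                           array(1 / 3, dims), zero, zero, voxel, origin))
  }
  lab_by_res <- setNames(model$sse$sse,
                         paste(model$sse$chain_id, model$sse$residue_index))
  atom_lab <- unname(lab_by_res[paste(bb$chain_id, bb$residue_index)])
  atom_lab[is.na(atom_lab)] <- "loop"
  lab_code <- c(helix = 1L, sheet = 2L, loop = 3L)

  calpha <- array(0, dims)
  backbone <- array(0, dims)
  nearest_d2 <- array(Inf, dims)
  nearest_lab <- array(3L, dims)
  xyz <- as.matrix(bb[, c("x", "y", "z")])
  cutoff <- 4 * sigma
  for (a in seq_len(nrow(xyz))) {
    p <- xyz[a, ]
    ic <- (p - origin) / voxel + 1
    lo <- pmax(1L, floor(ic - cutoff / voxel))
    hi <- pmin(dims, ceiling(ic + cutoff / voxel))
    if (any(lo > hi)) next
    xs <- origin[1] + (seq(lo[1], hi[1]) - 1) * voxel[1]
    ys <- origin[2] + (seq(lo[2], hi[2]) - 1) * voxel[2]
    zs <- origin[3] + (seq(lo[3], hi[3]) - 1) * voxel[3]
    d2 <- outer(outer((xs - p[1])^2, (ys - p[2])^2, "+"), (zs - p[3])^2, "+")
    # normalize so the nearest voxel center reads exactly 1
    splat <- exp(-(d2 - min(d2)) / (2 * sigma^2))
    sl <- list(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3])
    cur <- backbone[sl[[1]], sl[[2]], sl[[3]]]
    backbone[sl[[1]], sl[[2]], sl[[3]]] <- pmax(cur, splat)
    if (bb$atom_name[a] == "CA") {
      cur <- calpha[sl[[1]], sl[[2]], sl[[3]]]
      calpha[sl[[1]], sl[[2]], sl[[3]]] <- pmax(cur, splat)
    }
    nd <- nearest_d2[sl[[1]], sl[[2]], sl[[3]]]
    closer <- d2 < nd
    if (any(closer)) {
      nd[closer] <- d2[closer]
      nearest_d2[sl[[1]], sl[[2]], sl[[3]]] <- nd
      nl <- nearest_lab[sl[[1]], sl[[2]], sl[[3]]]
      nl[closer] <- lab_code[[atom_lab[a]]]
      nearest_lab[sl[[1]], sl[[2]], sl[[3]]] <- nl
    }
  }
  on_bb <- backbone >= bb_floor
  helix <- array(1 / 3, dims); sheet <- array(1 / 3, dims)
  loop <- array(1 / 3, dims)
  helix[on_bb] <- (nearest_lab[on_bb] == 1L) * 1
  sheet[on_bb] <- (nearest_lab[on_bb] == 2L) * 1
  loop[on_bb] <- (nearest_lab[on_bb] == 3L) * 1
  confidence_maps(helix, sheet, loop, backbone, calpha, voxel, origin)
}

#' Save / load a network checkpoint
#'
#' The checkpoint is a serialized model plus a human-readable JSON
#' sidecar (`<path>.json`) describing the layer specification.
#'
#' @param model a `ccnn`.
#' @param path checkpoint path.
#' @return `path` invisibly ([save_ccnn()]); a `ccnn` ([load_ccnn()]).
#' @export
save_ccnn <- function(model, path) {
  stopifnot(inherits(model, "ccnn"))
  saveRDS(model, path)
  jsonlite::write_json(ccnn_spec(model), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_ccnn
#' @export
load_ccnn <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  model <- readRDS(path)
  if (!inherits(model, "ccnn")) stop("not a ccnn checkpoint: ", path)
  model
}
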