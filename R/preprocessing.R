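#' Normalize a density map
#'
#' Staged normalization applied to every map before segmentation:
#' (1) voxels below `threshold` are zeroed; (2) remaining values are
#' divided by the median of the positive values; (3) values are capped
#' at the 98th percentile of the positive values (percentile computed
#' after the division, before capping). The output grid is congruent to
#' the input.
#'
#' @param map a [density_map()].
#' @param threshold density threshold (>= 0) below which voxels are
#'   treated as background noise.
#' @param cap_quantile quantile used for outlier capping; default 0.98.
#' @return A normalized [density_map()].
#' @export
preprocess_map <- function(map, threshold, cap_quantile = 0.98) {
  stopifnot(inherits(map, "density_map"))
  if (threshold < 0) stop("threshold must be >= 0")
  g <- map$grid
  g[g < threshold] <- 0
  pos <- g[g > 0]
  if (length(pos) == 0) stop("empty map: no voxels above threshold")
  g <- g / stats::median(pos)
  # type = 1 (an order statistic) keeps the transform exactly idempotent
  cap <- stats::quantile(g[g > 0], cap_quantile, names = FALSE, type = 1)
  g[g > cap] <- cap
  out <- density_map(g, map$voxel, map$origin)
  attr(out, "preprocess") <- list(threshold = threshold, cap = cap)
  out
}

#' Resample a map to 1 Angstrom voxels
#'
#' Trilinearly interpolates the map at the centers of a new grid with
#' voxel size exactly (1, 1, 1) A, preserving the origin and covering
#' the same world-space extent.
#'
#' @param map a [density_map()].
#' @return A [density_map()] with unit voxels; the input is returned
#'   unchanged when it is already on a unit grid.
#' @export
resample_to_unit_voxel <- function(map) {
  stopifnot(inherits(map, "density_map"))
  if (all(abs(map$voxel - 1) < 1e-12)) return(map)
  d <- dim(map$grid)
  if (any(d < 2)) stop("cannot resample a degenerate (single-plane) map")
  extent <- (d - 1) * map$voxel
  nd <- pmax(2L, floor(extent + 1e-9) + 1L)
  xs <- (seq_len(nd[1]) - 1)
  ys <- (seq_len(nd[2]) - 1)
  zs <- (seq_len(nd[3]) - 1)
  pts <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  idx <- sweep(pts, 2, map$voxel, "/") + 1
  vals <- trilinear_at(map$grid, idx)
  density_map(array(vals, nd), c(1, 1, 1), map$origin)
}

#' Cube tiling descriptor
#'
#' Describes how a volume was tiled into overlapping cubes: cubes of
#' edge `cube_edge` advance with stride `core_edge = cube_edge - 2 *
#' margin`, so that the central cores tile the (zero-padded) volume
#' disjointly while each cube sees `margin` voxels of context on every
#' face.
#'
#' @keywords internal
cube_grid <- function(dims, cube_edge = 64L, margin = 7L) {
  cube_edge <- as.integer(cube_edge); margin <- as.integer(margin)
  core <- cube_edge - 2L * margin
  if (core <= 0) stop("cube_edge must exceed twice the margin")
  n_ax <- pmax(1L, as.integer(ceiling(dims / core)))
  offsets <- as.matrix(expand.grid(
    x = (seq_len(n_ax[1]) - 1L) * core,
    y = (seq_len(n_ax[2]) - 1L) * core,
    z = (seq_len(n_ax[3]) - 1L) * core))
  structure(list(cube_edge = cube_edge, core_edge = core, margin = margin,
                 offsets = offsets, dims = as.integer(dims), n_axis = n_ax),
            class = "cube_grid")
}

#' Split a volume into overlapping cubes
#'
#' Tiles the volume with cubes of edge `cube_edge` that overlap by
#' `margin` voxels on each face; cube corners advance with stride
#' `cube_edge - 2 * margin`. The volume is zero-padded so that every
#' voxel falls in exactly one cube core.
#'
#' @param map a [density_map()] or a plain 3D array.
#' @param cube_edge cube edge length in voxels (default 64).
#' @param margin overlap per face in voxels (default 7).
#' @return List with `cubes` (list of `cube_edge`^3 arrays, ordered x
#'   fastest) and `grid` (a `cube_grid` descriptor for [stitch_cubes()]).
#' @export
split_into_cubes <- function(map, cube_edge = 64L, margin = 7L) {
  arr <- if (inherits(map, "density_map")) map$grid else map
  stopifnot(length(dim(arr)) == 3)
  g <- cube_grid(dim(arr), cube_edge, margin)
  core <- g$core_edge
  pad_dims <- g$n_axis * core + 2L * g$margin
  padded <- array(0, pad_dims)
  d <- dim(arr)
  padded[g$margin + seq_len(d[1]), g$margin + seq_len(d[2]),
         g$margin + seq_len(d[3])] <- arr
  cubes <- vector("list", nrow(g$offsets))
  for (i in seq_len(nrow(g$offsets))) {
    o <- g$offsets[i, ]
    cubes[[i]] <- padded[o[1] + seq_len(cube_edge),
                         o[2] + seq_len(cube_edge),
                         o[3] + seq_len(cube_edge)]
  }
  list(cubes = cubes, grid = g)
}

#' Reassemble cubes produced by [split_into_cubes()]
#'
#' Each cube contributes only its central core; the overlap margins are
#' discarded and the zero padding is cropped, so `stitch_cubes(
#' split_into_cubes(m))` reproduces `m` exactly.
#'
#' @param cubes list of cube arrays (full cube edge, or bare cores).
#' @param grid the `cube_grid` returned by [split_into_cubes()].
#' @return 3D array with the original volume shape.
#' @export
stitch_cubes <- function(cubes, grid) {
  stopifnot(inherits(grid, "cube_grid"))
  if (length(cubes) != nrow(grid$offsets)) {
    stop("cube count does not match the tiling descriptor")
  }
  core <- grid$core_edge
  m <- grid$margin
  out <- array(0, grid$n_axis * core)
  for (i in seq_along(cubes)) {
    cb <- cubes[[i]]
    ce <- dim(cb)[1]
    if (ce == grid$cube_edge) {
      cb <- cb[m + seq_len(core), m + seq_len(core), m + seq_len(core)]
    } else if (ce != core) {
      stop("cube ", i, " has unexpected edge length ", ce)
    }
    o <- grid$offsets[i, ]
    out[o[1] + seq_len(core), o[2] + seq_len(core), o[3] + seq_len(core)] <- cb
  }
  out[seq_len(grid$dims[1]), seq_len(grid$dims[2]), seq_len(grid$dims[3]),
      drop = FALSE]
}

# Rotate a 3D (or 4D, per-channel) array by k * 90 degrees about z.
rotate_z90 <- function(arr, k) {
  k <- ((k %% 4) + 4) %% 4
  if (k == 0) return(arr)
  rot1 <- function(a) {
    # (x, y) -> (y, -x): new[i, j, ] = old[j, nx + 1 - i, ]
    b <- aperm(a, c(2, 1, 3))
    b[, rev(seq_len(dim(b)[2])), , drop = FALSE]
  }
  for (i in seq_len(k)) arr <- rot1(arr)
  arr
}

#' Build a simulated training set
#'
#' For each input model: simulate a density map at a resolution drawn
#' uniformly from `resolution_range`, normalize it, generate the five
#' voxel label maps, crop/pad everything jointly to a fixed sample
#' cube, and optionally emit the four axis-aligned rotations about z
#' (0/90/180/270 degrees) of density and labels together, quadrupling
#' the sample count. The result is written to `out` as a single file:
#' one record per sample holding datasets `density`, `helix`, `sheet`,
#' `loop`, `backbone`, `calpha` plus attributes (`resolution`,
#' `voxel_size`, `source`, `rotation`). Serialization uses R's native
#' format; [read_training_set()] restores the tensors bit-exactly.
#'
#' @param models list of [atomic_model()] objects.
#' @param resolution_range length-2 numeric, A; each map's simulated
#'   resolution is drawn uniformly from this interval.
#' @param out output file path.
#' @param augment logical; emit 4 joint z-rotations per map.
#' @param seed integer seed controlling resolutions (and any RNG use).
#' @param sample_edge edge of the stored sample cube in voxels.
#' @param threshold_frac fraction of each map's maximum used as its
#'   normalization threshold.
#' @return `out`, invisibly.
#' @export
build_training_set <- function(models, resolution_range = c(2.5, 4.5),
                               out, augment = FALSE, seed = 1,
                               sample_edge = 64L, threshold_frac = 0.05) {
  if (length(models) == 0) stop("no models supplied")
  stopifnot(all(vapply(models, inherits, TRUE, "atomic_model")))
  sample_edge <- as.integer(sample_edge)

  samples <- with_seed(seed, {
    res <- stats::runif(length(models), resolution_range[1], resolution_range[2])
    recs <- list()
    for (mi in seq_along(models)) {
      dm <- simulate_density(models[[mi]], resolution = res[mi], voxel = 1)
      dm <- preprocess_map(dm, threshold = threshold_frac * max(dm$grid))
      labs <- generate_label_maps(models[[mi]], dm)
      vols <- list(density = dm$grid,
                   helix = labs$helix * 1, sheet = labs$sheet * 1,
                   loop = labs$loop * 1, backbone = labs$backbone * 1,
                   calpha = labs$calpha * 1)
      vols <- lapply(vols, crop_pad_center, edge = sample_edge)
      rots <- if (augment) 0:3 else 0L
      for (k in rots) {
        rec <- lapply(vols, rotate_z90, k = k)
        rec$attrs <- list(resolution = res[mi], voxel_size = c(1, 1, 1),
                          source = mi, rotation = 90L * k)
        recs[[length(recs) + 1L]] <- rec
      }
    }
    recs
  })
  obj <- list(format = "cryotrace-training-set", version = 1L,
              seed = seed, resolution_range = resolution_range,
              samples = samples)
  saveRDS(obj, out)
  invisible(out)
}

#' Read a training set written by [build_training_set()]
#' @param path training-set file.
#' @return The training-set object (list with `$samples`).
#' @export
read_training_set <- function(path) {
  if (!file.exists(path)) stop("cannot read training set: ", path)
  obj <- readRDS(path)
  if (!identical(obj$format, "cryotrace-training-set")) {
    stop("not a cryotrace training-set file: ", path)
  }
  obj
}

# Center-crop / zero-pad a 3D array to edge^3.
crop_pad_center <- function(arr, edge) {
  d <- dim(arr)
  out <- array(0, rep(edge, 3))
  src_lo <- pmax(1L, ceiling((d - edge) / 2) + 1L)
  src_hi <- pmin(d, src_lo + edge - 1L)
  n <- src_hi - src_lo + 1L
  dst_lo <- floor((edge - n) / 2) + 1L
  out[dst_lo[1]:(dst_lo[1] + n[1] - 1),
      dst_lo[2]:(dst_lo[2] + n[2] - 1),
      dst_lo[3]:(dst_lo[3] + n[3] - 1)] <-
    arr[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
  out
}
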