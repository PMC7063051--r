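# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Any unit vector perpendicular to d.
perp_unit <- function(d) {
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit(cross3(d, ref))
}

# World Angstrom coordinates -> fractional 1-based voxel indices.
world_to_index <- function(pts, origin, voxel) {
  pts <- rbind(pts)
  sweep(sweep(pts, 2, origin, "-"), 2, voxel, "/") + 1
}

index_to_world <- function(idx, origin, voxel) {
  idx <- rbind(idx)
  sweep(sweep(idx - 1, 2, voxel, "*"), 2, origin, "+")
}

# Trilinear interpolation of a 3D array at fractional 1-based indices
# (n x 3 matrix). Points outside the grid sample as `fill`.
trilinear_at <- function(grid, idx, fill = 0) {
  idx <- rbind(idx)
  d <- dim(grid)
  n <- nrow(idx)
  out <- rep(fill, n)
  i0 <- floor(idx)
  fr <- idx - i0
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
    idx[, 2] >= 1 & idx[, 2] <= d[2] &
    idx[, 3] >= 1 & idx[, 3] <= d[3]
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE]
  fr <- fr[ok, , drop = FALSE]
  # clamp so the upper corner stays in bounds (exact-boundary points)
  for (a in 1:3) {
    hit <- i0[, a] >= d[a]
    i0[hit, a] <- d[a] - 1
    fr[hit, a] <- 1
    low <- i0[, a] < 1
    i0[low, a] <- 1
    fr[low, a] <- 0
  }
  acc <- numeric(nrow(i0))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
      (if (dy) fr[, 2] else 1 - fr[, 2]) *
      (if (dz) fr[, 3] else 1 - fr[, 3])
    vals <- grid[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
    acc <- acc + w * vals
  }
  out[ok] <- acc
  out
}

# Voxel-center offsets (integer triples) with |offset| <= radius voxels,
# assuming a cubic voxel of size `voxel` (scalar).
sphere_offsets <- function(radius, voxel = 1) {
  r <- ceiling(radius / voxel)
  g <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  g <- as.matrix(g)
  keep <- rowSums((g * voxel)^2) <= radius^2 + 1e-9
  g[keep, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
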