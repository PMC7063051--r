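#' Density map container
#'
#' A 3D scalar grid with world-coordinate metadata. The array is indexed
#' `grid[x, y, z]` with x the fastest-varying axis; the world coordinate
#' of voxel `(i, j, k)` (1-based) is `origin + (i-1, j-1, k-1) * voxel`.
#' This axis convention is shared by every module in the package.
#'
#' @param grid 3D numeric array of density values.
#' @param voxel voxel size, Angstrom per voxel, length-3 (or scalar).
#' @param origin world position (A) of voxel `(1, 1, 1)`.
#' @return Object of class `density_map`.
#' @export
density_map <- function(grid, voxel = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(length(dim(grid)) == 3)
  voxel <- rep_len(as.numeric(voxel), 3)
  origin <- rep_len(as.numeric(origin), 3)
  if (any(voxel <= 0)) stop("voxel sizes must be positive")
  if (!all(is.finite(grid))) stop("grid values must be finite")
  structure(list(grid = grid, voxel = voxel, origin = origin),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<density_map> %d x %d x %d voxels, voxel %.3g/%.3g/%.3g A, origin (%.6g, %.6g, %.6g)\n",
              d[1], d[2], d[3], x$voxel[1], x$voxel[2], x$voxel[3],
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  density range [%.4g, %.4g]\n", min(x$grid), max(x$grid)))
  invisible(x)
}

#' Simulate a Gaussian-sum density map from an atomic model
#'
#' Every atom contributes an isotropic Gaussian of the same width
#' regardless of atom type or B-factor; the map value at a voxel is the
#' sum over atoms of `exp(-||x_v - x_atom||^2 / (2 sigma^2))`. The width
#' follows the EMAN2-style convention `sigma = resolution / (pi *
#' sqrt(2))` (Fourier amplitude falls to 1/e at spatial frequency
#' 1/resolution); the convention is recorded in the returned map's
#' attributes.
#'
#' @param model an [atomic_model()].
#' @param resolution nominal map resolution, A (> 0).
#' @param voxel voxel size in A (scalar or length 3); default 1.
#' @param padding margin (A) added around the model bounding box so that
#'   Gaussian tails are captured; default 5.
#' @param sigma optional explicit Gaussian width overriding the
#'   resolution-derived value.
#' @return A [density_map()].
#' @export
simulate_density <- function(model, resolution, voxel = 1, padding = 5,
                             sigma = NULL) {
  stopifnot(inherits(model, "atomic_model"))
  if (resolution <= 0) stop("resolution must be positive")
  voxel <- rep_len(as.numeric(voxel), 3)
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  if (nrow(xyz) == 0) stop("empty model")
  sigma <- sigma %||% (resolution / (pi * sqrt(2)))

  lo <- apply(xyz, 2, min) - padding
  hi <- apply(xyz, 2, max) + padding
  # snap the origin onto an integer voxel lattice for stable geometry
  origin <- floor(lo / voxel) * voxel
  dims <- pmax(2L, ceiling((hi - origin) / voxel) + 1L)
  grid <- array(0, dims)

  cutoff <- 4 * sigma
  for (a in seq_len(nrow(xyz))) {
    p <- xyz[a, ]
    ic <- (p - origin) / voxel + 1
    lo_i <- pmax(1L, floor(ic - cutoff / voxel))
    hi_i <- pmin(dims, ceiling(ic + cutoff / voxel))
    xs <- origin[1] + (seq(lo_i[1], hi_i[1]) - 1) * voxel[1]
    ys <- origin[2] + (seq(lo_i[2], hi_i[2]) - 1) * voxel[2]
    zs <- origin[3] + (seq(lo_i[3], hi_i[3]) - 1) * voxel[3]
    gx <- exp(-(xs - p[1])^2 / (2 * sigma^2))
    gy <- exp(-(ys - p[2])^2 / (2 * sigma^2))
    gz <- exp(-(zs - p[3])^2 / (2 * sigma^2))
    blk <- outer(outer(gx, gy), gz)  # separable Gaussian
    grid[lo_i[1]:hi_i[1], lo_i[2]:hi_i[2], lo_i[3]:hi_i[3]] <-
      grid[lo_i[1]:hi_i[1], lo_i[2]:hi_i[2], lo_i[3]:hi_i[3]] + blk
  }
  out <- density_map(grid, voxel, origin)
  attr(out, "sigma") <- sigma
  attr(out, "resolution") <- resolution
  out
}

#' Generate binary voxel label maps from an atomic model
#'
#' Produces the five training-label volumes congruent to a reference
#' map: `calpha` marks voxels whose centers lie within `r_ca` of any CA
#' atom, `backbone` those within `r_bb` of any backbone atom (N, CA, C),
#' and `helix`/`sheet`/`loop` partition the backbone-positive voxels by
#' the secondary-structure label of the nearest backbone atom's residue.
#'
#' @param model an [atomic_model()].
#' @param reference a [density_map()] providing grid, voxel and origin.
#' @param r_ca CA labeling radius, A (default 1.0).
#' @param r_bb backbone labeling radius, A (default 1.2).
#' @return List of class `label_maps` with binary arrays `helix`,
#'   `sheet`, `loop`, `backbone`, `calpha` plus `voxel`/`origin`.
#' @export
generate_label_maps <- function(model, reference, r_ca = 1.0, r_bb = 1.2) {
  stopifnot(inherits(model, "atomic_model"), inherits(reference, "density_map"))
  dims <- dim(reference$grid)
  voxel <- reference$voxel
  origin <- reference$origin

  bb <- model$atoms[model$atoms$atom_name %in% c("N", "CA", "C"), ]
  if (nrow(bb) == 0) stop("model has no backbone atoms")
  xyz <- as.matrix(bb[, c("x", "y", "z")])
  idx <- world_to_index(xyz, origin, voxel)
  inside <- idx[, 1] >= 1 & idx[, 1] <= dims[1] &
    idx[, 2] >= 1 & idx[, 2] <= dims[2] &
    idx[, 3] >= 1 & idx[, 3] <= dims[3]
  if (!all(inside)) {
    bad <- which(!inside)
    stop("model atoms outside reference grid: rows ",
         paste(utils::head(bad, 10), collapse = ", "))
  }

  # residue SSE label per backbone atom
  lab_by_res <- setNames(model$sse$sse,
                         paste(model$sse$chain_id, model$sse$residue_index))
  atom_lab <- unname(lab_by_res[paste(bb$chain_id, bb$residue_index)])
  atom_lab[is.na(atom_lab)] <- "loop"

  calpha <- array(FALSE, dims)
  backbone <- array(FALSE, dims)
  nearest_d2 <- array(Inf, dims)
  nearest_lab <- array(0L, dims)  # 1 helix, 2 sheet, 3 loop
  lab_code <- c(helix = 1L, sheet = 2L, loop = 3L)

  mark <- function(mask, p, radius) {
    ic <- (p - origin) / voxel + 1
    lo <- pmax(1L, floor(ic - radius / voxel))
    hi <- pmin(dims, ceiling(ic + radius / voxel))
    xs <- origin[1] + (seq(lo[1], hi[1]) - 1) * voxel[1]
    ys <- origin[2] + (seq(lo[2], hi[2]) - 1) * voxel[2]
    zs <- origin[3] + (seq(lo[3], hi[3]) - 1) * voxel[3]
    d2 <- outer(outer((xs - p[1])^2, (ys - p[2])^2, "+"), (zs - p[3])^2, "+")
    list(lo = lo, hi = hi, d2 = d2, within = d2 <= radius^2 + 1e-9)
  }

  is_ca <- bb$atom_name == "CA"
  for (a in seq_len(nrow(xyz))) {
    p <- xyz[a, ]
    m <- mark(NULL, p, r_bb)
    sl <- list(m$lo[1]:m$hi[1], m$lo[2]:m$hi[2], m$lo[3]:m$hi[3])
    backbone[sl[[1]], sl[[2]], sl[[3]]] <-
      backbone[sl[[1]], sl[[2]], sl[[3]]] | m$within
    # nearest-atom SSE assignment
    nd <- nearest_d2[sl[[1]], sl[[2]], sl[[3]]]
    closer <- m$d2 < nd
    if (any(closer)) {
      nd[closer] <- m$d2[closer]
      nearest_d2[sl[[1]], sl[[2]], sl[[3]]] <- nd
      nl <- nearest_lab[sl[[1]], sl[[2]], sl[[3]]]
      nl[closer] <- lab_code[[atom_lab[a]]]
      nearest_lab[sl[[1]], sl[[2]], sl[[3]]] <- nl
    }
    if (is_ca[a]) {
      mc <- mark(NULL, p, r_ca)
      slc <- list(mc$lo[1]:mc$hi[1], mc$lo[2]:mc$hi[2], mc$lo[3]:mc$hi[3])
      calpha[slc[[1]], slc[[2]], slc[[3]]] <-
        calpha[slc[[1]], slc[[2]], slc[[3]]] | mc$within
    }
  }

  helix <- backbone & (nearest_lab == 1L)
  sheet <- backbone & (nearest_lab == 2L)
  loop <- backbone & (nearest_lab == 3L)
  structure(list(helix = helix, sheet = sheet, loop = loop,
                 backbone = backbone, calpha = calpha,
                 voxel = voxel, origin = origin),
            class = "label_maps")
}

# ---------------------------------------------------------------------------
# MRC2014 I/O. Hand-written: 1024-byte header (56 words used + labels),
# mode 0/1/2 data, MAPC/MAPR/MAPS axis normalization, MRC2014 ORIGIN field
# with NXSTART fallback. Little-endian only.
# ---------------------------------------------------------------------------

#' Read an MRC2014 density map
#'
#' Parses the 1024-byte header, normalizes a permuted axis order
#' (MAPC/MAPR/MAPS) to the package convention (x fastest), and derives
#' per-axis voxel sizes from the cell dimensions. The origin is taken
#' from the MRC2014 ORIGIN field, falling back to
#' `NXSTART/NYSTART/NZSTART * voxel` when ORIGIN is all zero.
#'
#' @param path path to an `.mrc`/`.map` file.
#' @return A [density_map()].
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("cannot read MRC file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", 1024)
  if (length(hdr_raw) < 1024) stop("malformed MRC header: file too short")
  ints <- readBin(hdr_raw, "integer", 256, size = 4, endian = "little")
  flts <- readBin(hdr_raw, "double", 256, size = 4, endian = "little")
  nxyz <- ints[1:3]          # columns, rows, sections
  mode <- ints[4]
  nstart <- ints[5:7]
  mxyz <- ints[8:10]
  cella <- flts[11:13]
  mapcrs <- ints[17:19]
  origin_f <- flts[50:52]
  map_tag <- rawToChar(hdr_raw[209:212])
  if (any(nxyz <= 0) || any(nxyz > 1e5)) stop("malformed MRC header: bad dimensions")
  if (!(mode %in% c(0L, 1L, 2L))) stop("unsupported MRC mode: ", mode)
  if (!identical(sort(mapcrs), 1:3)) {
    if (all(mapcrs == 0L)) mapcrs <- 1:3 else
      stop("malformed MRC header: MAPC/MAPR/MAPS = ",
           paste(mapcrs, collapse = ","))
  }
  if (!grepl("^MAP", map_tag)) {
    # tolerate pre-2014 files but keep going only if dims look sane
    warning("file lacks the 'MAP ' tag; attempting to read anyway")
  }
  n <- prod(nxyz)
  data <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n, size = 2, signed = TRUE,
                             endian = "little")),
    "2" = readBin(con, "double", n, size = 4, endian = "little"))
  if (length(data) < n) stop("malformed MRC file: truncated data block")
  arr <- array(data, nxyz)

  # file axis i holds world axis mapcrs[i]; put world axes in x,y,z order
  perm <- match(1:3, mapcrs)
  if (!identical(perm, 1:3)) arr <- aperm(arr, perm)
  mx_world <- mxyz
  mx_world[mx_world <= 0] <- nxyz[perm][mx_world <= 0]
  voxel <- cella / mx_world
  voxel[!is.finite(voxel) | voxel <= 0] <- 1
  origin <- origin_f
  if (all(origin == 0) && any(nstart != 0)) {
    start_world <- numeric(3)
    start_world[mapcrs] <- nstart
    origin <- start_world * voxel
  }
  density_map(arr, voxel, origin)
}

#' Write a density map as MRC2014
#'
#' Emits a mode-2 (32-bit float) MRC2014 file with canonical axis order
#' (MAPC/MAPR/MAPS = 1/2/3), cell dimensions from the voxel size, and
#' the origin in the MRC2014 ORIGIN header field.
#'
#' @param map a [density_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  d <- dim(map$grid)
  vals <- as.numeric(map$grid)
  ints <- integer(256)
  flts <- numeric(256)
  ints[1:3] <- d
  ints[4] <- 2L
  ints[8:10] <- d
  flts[11:13] <- d * map$voxel
  flts[14:16] <- 90
  ints[17:19] <- 1:3
  flts[20] <- min(vals); flts[21] <- max(vals); flts[22] <- mean(vals)
  ints[23] <- 1L   # ISPG: 3D volume
  flts[50:52] <- map$origin
  flts[55] <- stats::sd(vals)
  ints[56] <- 0L

  hdr <- raw(1024)
  for (w in seq_len(256)) {
    bytes <- if (w %in% c(11:16, 20:22, 50:52, 55)) {
      writeBin(flts[w], raw(), size = 4, endian = "little")
    } else {
      writeBin(ints[w], raw(), size = 4, endian = "little")
    }
    hdr[(4 * w - 3):(4 * w)] <- bytes
  }
  hdr[209:212] <- charToRaw("MAP ")
  hdr[213:216] <- as.raw(c(0x44, 0x44, 0x00, 0x00))  # little-endian MACHST

  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write to ", path))
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(vals, con, size = 4, endian = "little")
  invisible(path)
}
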