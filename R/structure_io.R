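#' Atomic model container
#'
#' A light container for an atomic structure: a data frame of atoms plus
#' per-residue secondary-structure labels. This is the ground-truth object
#' used both to simulate density maps and to score predicted traces.
#'
#' @param atoms data frame with columns `atom_name`, `element`, `chain_id`,
#'   `residue_index`, `residue_name`, `x`, `y`, `z` (Angstrom).
#' @param sse data frame with columns `chain_id`, `residue_index`, `sse`
#'   (one of `"helix"`, `"sheet"`, `"loop"`). Residues not listed default
#'   to `"loop"`.
#' @return An object of class `atomic_model`.
#' @export
atomic_model <- function(atoms, sse = NULL) {
  req <- c("atom_name", "element", "chain_id", "residue_index",
           "residue_name", "x", "y", "z")
  stopifnot(is.data.frame(atoms), all(req %in% names(atoms)))
  if (nrow(atoms) == 0L) stop("empty model: no atoms")
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) ||
      !all(is.finite(atoms$z))) {
    stop("all atom coordinates must be finite")
  }
  ca <- atoms[atoms$atom_name == "CA", ]
  if (anyDuplicated(ca[, c("chain_id", "residue_index")])) {
    stop("a residue carries more than one CA atom")
  }
  if (is.null(sse)) {
    sse <- data.frame(chain_id = character(), residue_index = integer(),
                      sse = character(), stringsAsFactors = FALSE)
  }
  stopifnot(all(sse$sse %in% c("helix", "sheet", "loop")))
  structure(list(atoms = atoms, sse = sse), class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  nca <- sum(x$atoms$atom_name == "CA")
  cat("<atomic_model> ", nrow(x$atoms), " atoms, ", nca, " CA, ",
      length(unique(x$atoms$chain_id)), " chain(s)\n", sep = "")
  tab <- table(factor(ca_sse(x), levels = c("helix", "sheet", "loop")))
  cat("  SSE (per CA): helix ", tab[["helix"]], ", sheet ", tab[["sheet"]],
      ", loop ", tab[["loop"]], "\n", sep = "")
  invisible(x)
}

#' C-alpha coordinates of a model
#'
#' @param model an [atomic_model()].
#' @return Numeric matrix (n x 3) of CA coordinates in chain/residue order.
#' @export
ca_coords <- function(model) {
  ca <- model$atoms[model$atoms$atom_name == "CA", ]
  ca <- ca[order(ca$chain_id, ca$residue_index), ]
  as.matrix(ca[, c("x", "y", "z")])
}

#' Per-CA secondary structure labels
#'
#' @param model an [atomic_model()].
#' @return Character vector parallel to [ca_coords()] rows; residues with
#'   no recorded label are `"loop"`.
#' @export
ca_sse <- function(model) {
  ca <- model$atoms[model$atoms$atom_name == "CA", ]
  ca <- ca[order(ca$chain_id, ca$residue_index), ]
  key <- paste(ca$chain_id, ca$residue_index)
  lab <- setNames(model$sse$sse, paste(model$sse$chain_id, model$sse$residue_index))
  out <- unname(lab[key])
  out[is.na(out)] <- "loop"
  out
}

#' C-alpha trace
#'
#' An ordered chain of CA positions, optionally labeled with a secondary
#' structure class per point.
#'
#' @param xyz numeric matrix (n x 3), Angstrom.
#' @param sse optional character vector of length n with values in
#'   `helix`/`sheet`/`loop`.
#' @return Object of class `ca_trace`.
#' @export
ca_trace <- function(xyz, sse = NULL) {
  xyz <- rbind(xyz)
  stopifnot(ncol(xyz) == 3, nrow(xyz) >= 1, all(is.finite(xyz)))
  if (nrow(xyz) > 1) {
    steps <- sqrt(rowSums((xyz[-1, , drop = FALSE] -
                             xyz[-nrow(xyz), , drop = FALSE])^2))
    if (any(steps <= 0)) stop("repeated consecutive points in trace")
  }
  if (!is.null(sse)) {
    stopifnot(length(sse) == nrow(xyz), all(sse %in% c("helix", "sheet", "loop")))
  }
  structure(list(xyz = unname(xyz), sse = sse), class = "ca_trace")
}

#' @export
print.ca_trace <- function(x, ...) {
  cat("<ca_trace> ", nrow(x$xyz), " points\n", sep = "")
  invisible(x)
}

#' Read an atomic model from a PDB file
#'
#' Parses ATOM records (coordinates at PDB precision, 0.001 A) and, when
#' present, HELIX/SHEET records into per-residue secondary-structure
#' labels; residues not covered by any record are labeled `loop`.
#' HETATM records, alternate locations and insertion codes are ignored
#' with a warning.
#'
#' @param path path to a PDB file.
#' @return An [atomic_model()].
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file ", path, ": ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  n_het <- sum(at$type == "HETATM")
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("empty model: no ATOM records in ", path)
  n_alt <- sum(!(at$alt %in% c("", " ", NA)) & at$alt != "A")
  n_ins <- sum(!(at$insert %in% c("", " ", NA)))
  if (n_het > 0 || n_alt > 0 || n_ins > 0) {
    warning(sprintf(
      "ignoring %d HETATM, %d non-primary altloc, %d insertion-code atoms",
      n_het, n_alt, n_ins))
  }
  at <- at[(at$alt %in% c("", " ", NA)) | at$alt == "A", , drop = FALSE]
  at <- at[at$insert %in% c("", " ", NA), , drop = FALSE]
  chain <- ifelse(is.na(at$chain), "A", at$chain)
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- substr(trimws(at$elety), 1, 1)
  }
  atoms <- data.frame(
    atom_name = trimws(at$elety), element = trimws(elem),
    chain_id = chain, residue_index = at$resno,
    residue_name = at$resid, x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE)

  sse <- NULL
  add_range <- function(sse, rec, label) {
    if (is.null(rec) || length(rec$start) == 0) return(sse)
    for (i in seq_along(rec$start)) {
      ri <- seq(rec$start[i], rec$end[i])
      ch <- rec$chain[i]
      sse <- rbind(sse, data.frame(chain_id = ch, residue_index = ri,
                                   sse = label, stringsAsFactors = FALSE))
    }
    sse
  }
  sse <- add_range(sse, pdb$helix, "helix")
  sse <- add_range(sse, pdb$sheet, "sheet")
  atomic_model(atoms, sse)
}

#' Write C-alpha traces to a PDB file
#'
#' Each trace becomes one chain of CA-only ATOM records terminated by a
#' TER record; helix and sheet labels, when present, are encoded as
#' HELIX/SHEET records so that a round trip through [read_pdb()]
#' recovers them.
#'
#' @param traces a [ca_trace()] or a list of them; all must be non-empty.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace_pdb <- function(traces, path) {
  if (inherits(traces, "ca_trace")) traces <- list(traces)
  if (length(traces) == 0L) stop("empty trace set")
  stopifnot(all(vapply(traces, inherits, TRUE, "ca_trace")))
  chains <- make_chain_ids(length(traces))

  header <- character()
  nhel <- 0L; nsht <- 0L
  for (ti in seq_along(traces)) {
    sse <- traces[[ti]]$sse
    if (is.null(sse)) next
    runs <- rle(sse)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (ri in seq_along(runs$values)) {
      lab <- runs$values[ri]
      if (lab == "helix") {
        nhel <- nhel + 1L
        header <- c(header, sprintf(
          "HELIX  %3d %3s ALA %1s %4d  ALA %1s %4d %2d%30s%6d",
          nhel, sprintf("%3d", nhel %% 1000), chains[ti], starts[ri],
          chains[ti], ends[ri], 1L, "", runs$lengths[ri]))
      } else if (lab == "sheet") {
        nsht <- nsht + 1L
        header <- c(header, sprintf(
          "SHEET  %3d %3s%2d ALA %1s%4d  ALA %1s%4d%2d",
          nsht, sprintf("%3s", "S"), 1L, chains[ti], starts[ri],
          chains[ti], ends[ri], 0L))
      }
    }
  }

  body <- character()
  serial <- 0L
  for (ti in seq_along(traces)) {
    xyz <- traces[[ti]]$xyz
    for (i in seq_len(nrow(xyz))) {
      serial <- serial + 1L
      body <- c(body, sprintf(
        "ATOM  %5d  CA  ALA %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial %% 100000L, chains[ti], i,
        xyz[i, 1], xyz[i, 2], xyz[i, 3]))
    }
    serial <- serial + 1L
    body <- c(body, sprintf("TER   %5d      ALA %1s%4d",
                            serial %% 100000L, chains[ti], nrow(xyz)))
  }
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write to ", path))
  on.exit(close(con))
  writeLines(c(header, body, "END"), con)
  invisible(path)
}

make_chain_ids <- function(n) {
  pool <- c(LETTERS, letters, as.character(0:9))
  if (n <= length(pool)) return(pool[seq_len(n)])
  rep_len(pool, n)  # chain ids recycle for very large trace sets
}

#' Generate a synthetic C-alpha protein model
#'
#' Builds a self-avoiding CA chain from a list of secondary-structure
#' segments. Helix segments follow ideal alpha-helix geometry (1.5 A
#' rise per residue, ~100 degrees turn per residue, 2.3 A radius),
#' strand segments are near-straight zig-zags with ~3.5 A rise, and
#' loops are smooth random walks with 3.8 A steps. Two pseudo backbone
#' atoms (C, N) are interpolated between consecutive CA so that the
#' model also exercises backbone-atom code paths. Deterministic for a
#' fixed seed.
#'
#' @param segments list of 2-element vectors `c(type, length)` with type
#'   in `helix`/`strand`/`sheet`/`loop`, or a 2-column data frame.
#' @param seed integer RNG seed.
#' @param min_separation minimum allowed distance (A) between CA atoms
#'   more than one residue apart; segments are re-drawn on violation.
#' @return An [atomic_model()] with chain `"A"` and residues `1..n`.
#' @export
generate_synthetic_protein <- function(segments, seed = 1,
                                       min_separation = 3.0) {
  segs <- normalize_segments(segments)
  if (any(segs$length < 1)) stop("each segment must have length >= 1")
  n_res <- sum(segs$length)
  if (n_res < 2) stop("need at least 2 residues in total")

  with_seed(seed, {
    coords <- matrix(numeric(0), ncol = 3)
    labels <- character(0)
    dir <- unit(stats::rnorm(3))
    for (si in seq_len(nrow(segs))) {
      type <- segs$sse[si]
      len <- segs$length[si]
      placed <- FALSE
      for (try in seq_len(1000L)) {
        new_dir <- if (nrow(coords) == 0 && try == 1) dir else
          unit(dir * 0.6 + stats::rnorm(3) * 0.6)
        pts <- switch(type,
          helix = helix_segment(len, new_dir),
          sheet = strand_segment(len, new_dir),
          loop  = loop_segment(len, new_dir))
        if (nrow(coords) > 0) {
          # anchor: first new point continues the chain at ~3.8 A
          anchor <- coords[nrow(coords), ] + 3.8 * new_dir
          pts <- sweep(pts, 2, pts[1, ] - anchor, "-")
        }
        if (self_avoiding(coords, pts, min_separation)) {
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("failed to place segment ", si,
                        " without steric clash; try another seed")
      coords <- rbind(coords, pts)
      labels <- c(labels, rep(type, len))
      if (nrow(coords) >= 2) {
        dir <- unit(coords[nrow(coords), ] - coords[nrow(coords) - 1, ])
      }
    }

    atoms <- build_backbone_atoms(coords)
    sse <- data.frame(chain_id = "A", residue_index = seq_len(n_res),
                      sse = labels, stringsAsFactors = FALSE)
    atomic_model(atoms, sse)
  })
}

normalize_segments <- function(segments) {
  if (is.data.frame(segments)) {
    out <- data.frame(sse = as.character(segments[[1]]),
                      length = as.integer(segments[[2]]),
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(
      sse = vapply(segments, function(s) as.character(s[[1]]), ""),
      length = vapply(segments, function(s) as.integer(s[[2]]), 0L),
      stringsAsFactors = FALSE)
  }
  out$sse[out$sse == "strand"] <- "sheet"
  if (!all(out$sse %in% c("helix", "sheet", "loop"))) {
    stop("segment types must be helix, strand/sheet, or loop")
  }
  out
}

# Ideal helix about a straight axis along `d`: rise 1.5 A/residue,
# angular advance 1.149 rad per A of rise (~98.7 degrees/residue, the
# canonical alpha-helix pitch), radius 2.3 A; consecutive CA distance
# comes out at 3.80 A.
helix_segment <- function(n, d, rise = 1.5, turn = 1.149 * 1.5,
                          radius = 2.3) {
  u <- perp_unit(d)
  v <- cross3(d, u)
  phi0 <- stats::runif(1, 0, 2 * pi)
  i <- seq_len(n) - 1
  t(vapply(i, function(k) {
    k * rise * d + radius * (cos(phi0 + k * turn) * u +
                               sin(phi0 + k * turn) * v)
  }, numeric(3)))
}

# Near-straight strand: 3.5 A rise with alternating 0.8 A lateral offset
# (consecutive CA distance ~3.85 A).
strand_segment <- function(n, d, rise = 3.5, wobble = 0.8) {
  w <- perp_unit(d)
  i <- seq_len(n) - 1
  t(vapply(i, function(k) k * rise * d + ((-1)^k) * wobble * w, numeric(3)))
}

# Smooth random walk with 3.8 A steps.
loop_segment <- function(n, d) {
  pts <- matrix(0, n, 3)
  cur_dir <- d
  for (k in 2:max(n, 2)) {
    if (k > n) break
    cur_dir <- unit(cur_dir + stats::rnorm(3) * 0.45)
    pts[k, ] <- pts[k - 1, ] + 3.8 * cur_dir
  }
  pts
}

self_avoiding <- function(existing, new_pts, min_sep) {
  all_pts <- rbind(existing, new_pts)
  n <- nrow(all_pts)
  if (n < 3) return(TRUE)
  # check new points only, against all points >= 2 residues away
  start_new <- nrow(existing) + 1
  for (i in start_new:n) {
    js <- setdiff(seq_len(n), (i - 1):(i + 1))
    js <- js[js < i]
    if (length(js) == 0) next
    d2 <- rowSums((all_pts[js, , drop = FALSE] -
                     matrix(all_pts[i, ], length(js), 3, byrow = TRUE))^2)
    if (any(d2 < min_sep^2)) return(FALSE)
  }
  TRUE
}

# CA chain -> atoms data frame with interpolated pseudo C/N atoms between
# consecutive residues (at 1/3 and 2/3 of the CA-CA segment).
build_backbone_atoms <- function(coords) {
  n <- nrow(coords)
  rows <- vector("list", 3 * n)
  k <- 0
  for (i in seq_len(n)) {
    if (i > 1) {
      p <- coords[i - 1, ] + (coords[i, ] - coords[i - 1, ]) * (2 / 3)
      k <- k + 1
      rows[[k]] <- data.frame(atom_name = "N", element = "N", chain_id = "A",
                              residue_index = i, residue_name = "ALA",
                              x = p[1], y = p[2], z = p[3],
                              stringsAsFactors = FALSE)
    }
    k <- k + 1
    rows[[k]] <- data.frame(atom_name = "CA", element = "C", chain_id = "A",
                            residue_index = i, residue_name = "ALA",
                            x = coords[i, 1], y = coords[i, 2], z = coords[i, 3],
                            stringsAsFactors = FALSE)
    if (i < n) {
      p <- coords[i, ] + (coords[i + 1, ] - coords[i, ]) * (1 / 3)
      k <- k + 1
      rows[[k]] <- data.frame(atom_name = "C", element = "C", chain_id = "A",
                              residue_index = i, residue_name = "ALA",
                              x = p[1], y = p[2], z = p[3],
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows[seq_len(k)])
}
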