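#' Path-walking parameters
#'
#' Tunable parameters of the tabu-search C-alpha tracer. Candidate CA
#' positions must carry at least `ca_conf_min` C-alpha confidence (the
#' 50% display threshold) and the backbone confidence sampled along a
#' step must average at least `bb_conf_min` (the 40% display
#' threshold). Steps are restricted to the `step_band` distance window
#' around the ideal 3.8 A CA-CA spacing, and each accepted CA excludes
#' further visits within `exclusion_radius`.
#'
#' @param ca_conf_min minimum C-alpha confidence for a candidate (0.50).
#' @param bb_conf_min minimum mean backbone confidence along a step (0.40).
#' @param step_band allowed CA-CA step distances, A (2.8, 4.2).
#' @param ideal_step ideal CA-CA distance, A (3.8).
#' @param w_conf,w_bb,w_dist,w_angle non-negative score weights for the
#'   candidate confidence, segment backbone confidence, distance
#'   deviation penalty and backtracking angle penalty.
#' @param w_helix weight of the optional helix-radius bonus (0 disables
#'   it; see Details).
#' @param exclusion_radius tabu radius around accepted CA positions, A.
#' @param nms_radius non-maximum-suppression radius used when
#'   enumerating candidate CA positions from the confidence map, A.
#'
#' @details The optional helix-radius term adds `w_helix *
#' helix_confidence(candidate)` when the candidate lies at 1.8-2.8 A
#' from the local trace axis, rewarding geometry consistent with the
#' common alpha-helix radius; it is disabled by default pending
#' calibration.
#'
#' @return Object of class `walk_params`.
#' @export
walk_params <- function(ca_conf_min = 0.50, bb_conf_min = 0.40,
                        step_band = c(2.8, 4.2), ideal_step = 3.8,
                        w_conf = 1.0, w_bb = 0.5, w_dist = 1.0,
                        w_angle = 0.5, w_helix = 0.0,
                        exclusion_radius = 2.0, nms_radius = 1.5) {
  stopifnot(step_band[1] < ideal_step, ideal_step < step_band[2],
            w_conf >= 0, w_bb >= 0, w_dist >= 0, w_angle >= 0, w_helix >= 0)
  structure(list(ca_conf_min = ca_conf_min, bb_conf_min = bb_conf_min,
                 step_band = step_band, ideal_step = ideal_step,
                 w_conf = w_conf, w_bb = w_bb, w_dist = w_dist,
                 w_angle = w_angle, w_helix = w_helix,
                 exclusion_radius = exclusion_radius,
                 nms_radius = nms_radius),
            class = "walk_params")
}

# sample a confidence volume at world points
conf_at <- function(maps, field, pts) {
  trilinear_at(maps[[field]], world_to_index(pts, maps$origin, maps$voxel))
}

#' Select the next walk seed
#'
#' Returns the world coordinate of the unvisited voxel with maximal
#' C-alpha confidence, or `NULL` once no unvisited voxel reaches
#' `ca_conf_min`. Ties resolve to the first voxel in column-major
#' (x-fastest) order, making seeding deterministic.
#'
#' @param calpha C-alpha probability volume (3D array).
#' @param visited congruent logical array of already-explored voxels.
#' @param params a [walk_params()].
#' @param voxel,origin grid metadata of `calpha`.
#' @return Length-3 world coordinate, or `NULL`.
#' @export
select_seed <- function(calpha, visited, params = walk_params(),
                        voxel = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(identical(dim(calpha), dim(visited)))
  conf <- calpha
  conf[visited] <- -Inf
  best <- which.max(conf)
  if (conf[best] < params$ca_conf_min) return(NULL)
  ijk <- arrayInd(best, dim(calpha))
  as.numeric(index_to_world(ijk, origin, voxel))
}

# Candidate CA positions: local maxima of the calpha volume above the
# confidence floor, thinned by non-maximum suppression and refined to
# the confidence-weighted centroid of their neighborhood.
find_ca_candidates <- function(maps, params = walk_params()) {
  a <- maps$calpha
  d <- dim(a)
  keep <- a >= params$ca_conf_min
  if (!any(keep)) {
    return(list(xyz = matrix(numeric(0), ncol = 3), conf = numeric(0),
                vox = integer(0)))
  }
  # 26-neighborhood local maxima via shifted comparisons
  is_max <- keep
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    sh <- array(-Inf, d)
    xs <- seq_len(d[1]); ys <- seq_len(d[2]); zs <- seq_len(d[3])
    xv <- xs + dx; yv <- ys + dy; zv <- zs + dz
    okx <- xv >= 1 & xv <= d[1]; oky <- yv >= 1 & yv <= d[2]
    okz <- zv >= 1 & zv <= d[3]
    sh[xs[okx], ys[oky], zs[okz]] <- a[xv[okx], yv[oky], zv[okz]]
    is_max <- is_max & (a >= sh)
  }
  vox <- which(is_max)
  ord <- order(a[vox], -vox, decreasing = TRUE)
  vox <- vox[ord]
  ijk <- arrayInd(vox, d)
  pts <- index_to_world(ijk, maps$origin, maps$voxel)
  conf <- a[vox]

  # greedy NMS, highest confidence first (ties: lowest voxel index)
  sel <- logical(length(vox))
  for (i in seq_along(vox)) {
    if (i == 1) { sel[1] <- TRUE; next }
    prev <- which(sel)
    d2 <- rowSums((pts[prev, , drop = FALSE] -
                     matrix(pts[i, ], length(prev), 3, byrow = TRUE))^2)
    if (all(d2 >= params$nms_radius^2)) sel[i] <- TRUE
  }
  pts <- pts[sel, , drop = FALSE]
  vox <- vox[sel]
  conf <- conf[sel]

  # sub-voxel refinement: confidence-weighted centroid within nms_radius
  offs <- sphere_offsets(params$nms_radius, min(maps$voxel))
  ijk <- arrayInd(vox, d)
  for (i in seq_len(nrow(pts))) {
    nb <- sweep(offs, 2, ijk[i, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    w <- a[nb]
    if (sum(w) > 0) {
      pts[i, ] <- colSums(index_to_world(nb, maps$origin, maps$voxel) * w) /
        sum(w)
    }
  }
  list(xyz = pts, conf = conf, vox = vox)
}

#' Score one candidate step of the path walker
#'
#' Linear combination of the candidate's C-alpha confidence, the mean
#' backbone confidence sampled along the segment from the current
#' position, a penalty for deviating from the ideal 3.8 A step, and a
#' penalty for near-backtracking measured on the pseudo-bond angle at
#' the current position. A candidate is rejected (score `-Inf`) when
#' its C-alpha confidence or the segment backbone confidence falls
#' below the respective floor.
#'
#' @param current,candidate world coordinates (length 3).
#' @param prev previous trace point or `NULL` at a trace start.
#' @param maps a [confidence_maps()].
#' @param params a [walk_params()].
#' @return Numeric score, `-Inf` for a rejected candidate.
#' @export
score_step <- function(current, prev, candidate, maps,
                       params = walk_params()) {
  ca_c <- conf_at(maps, "calpha", rbind(candidate))
  if (ca_c < params$ca_conf_min) return(-Inf)
  frac <- seq(0.1, 0.9, length.out = 9)
  seg <- outer(frac, candidate - current) +
    matrix(current, length(frac), 3, byrow = TRUE)
  bb_mean <- mean(conf_at(maps, "backbone", seg))
  if (bb_mean < params$bb_conf_min) return(-Inf)
  dstep <- vnorm(candidate - current)
  score <- params$w_conf * ca_c + params$w_bb * bb_mean -
    params$w_dist * abs(dstep - params$ideal_step) / params$ideal_step
  if (!is.null(prev)) {
    v1 <- prev - current
    v2 <- candidate - current
    cosang <- sum(v1 * v2) / (vnorm(v1) * vnorm(v2))
    score <- score - params$w_angle * max(0, cosang - cos(150 * pi / 180))
  }
  if (params$w_helix > 0 && !is.null(prev)) {
    axis_dir <- unit(current - prev)
    radial <- vnorm((candidate - current) -
                      sum((candidate - current) * axis_dir) * axis_dir)
    if (radial >= 1.8 && radial <= 2.8) {
      score <- score + params$w_helix * conf_at(maps, "helix", rbind(candidate))
    }
  }
  score
}

# internal walk state shared by walk_trace / trace_all
walk_state <- function(maps, params) {
  list(visited = array(FALSE, dim(maps$calpha)), params = params)
}

mark_visited <- function(state, maps, pt) {
  d <- dim(state$visited)
  ijk <- round(world_to_index(pt, maps$origin, maps$voxel))
  offs <- sphere_offsets(state$params$exclusion_radius, min(maps$voxel))
  nb <- sweep(offs, 2, as.integer(ijk), "+")
  ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
    nb[, 3] >= 1 & nb[, 3] <= d[3]
  state$visited[nb[ok, , drop = FALSE]] <- TRUE
  state
}

is_visited <- function(state, maps, pts) {
  d <- dim(state$visited)
  ijk <- round(world_to_index(pts, maps$origin, maps$voxel))
  ijk[, 1] <- pmin(pmax(ijk[, 1], 1), d[1])
  ijk[, 2] <- pmin(pmax(ijk[, 2], 1), d[2])
  ijk[, 3] <- pmin(pmax(ijk[, 3], 1), d[3])
  state$visited[ijk]
}

# one directed walk leg; returns accumulated points and updated state
walk_leg <- function(start, prev0, cands, maps, state) {
  params <- state$params
  pts <- matrix(numeric(0), ncol = 3)
  current <- start
  prev <- prev0
  repeat {
    if (nrow(cands$xyz) == 0) break
    d2 <- rowSums((cands$xyz -
                     matrix(current, nrow(cands$xyz), 3, byrow = TRUE))^2)
    in_band <- d2 >= params$step_band[1]^2 & d2 <= params$step_band[2]^2
    open <- in_band & !is_visited(state, maps, cands$xyz)
    if (!any(open)) break
    idx <- which(open)
    scores <- vapply(idx, function(i) {
      score_step(current, prev, cands$xyz[i, ], maps, params)
    }, 0)
    if (all(!is.finite(scores))) break
    best <- idx[which.max(scores)]
    nxt <- cands$xyz[best, ]
    state <- mark_visited(state, maps, nxt)
    pts <- rbind(pts, nxt)
    prev <- current
    current <- nxt
  }
  list(pts = pts, state = state)
}

#' Walk a single C-alpha trace from a seed
#'
#' Starting from an unvisited seed, repeatedly scores candidate CA
#' positions (local maxima of the C-alpha confidence map) inside the
#' step-distance band and appends the best-accepted candidate, marking
#' its surroundings visited, until no acceptable candidate remains or
#' the walk enters already-visited territory. The walk then restarts
#' from the seed in the opposite direction and the two legs are
#' concatenated.
#'
#' @param seed world coordinate to start from (must be unvisited).
#' @param maps a [confidence_maps()].
#' @param params a [walk_params()].
#' @param state internal state (visited mask); when `NULL` a fresh
#'   state is created.
#' @return A [ca_trace()]; with a fresh state the trace has at least
#'   the seed point.
#' @export
walk_trace <- function(seed, maps, params = walk_params(), state = NULL) {
  internal <- !is.null(state)
  if (is.null(state)) state <- walk_state(maps, params)
  if (any(is_visited(state, maps, rbind(seed)))) stop("seed already visited")
  cands <- find_ca_candidates(maps, params)
  res <- walk_trace_impl(seed, cands, maps, state)
  if (internal) res else res$trace
}

walk_trace_impl <- function(seed, cands, maps, state) {
  state <- mark_visited(state, maps, seed)
  leg1 <- walk_leg(seed, NULL, cands, maps, state)
  state <- leg1$state
  fwd <- rbind(seed, leg1$pts)
  # walk the other direction from the seed, aware of the first leg
  prev0 <- if (nrow(leg1$pts) > 0) leg1$pts[1, ] else NULL
  leg2 <- walk_leg(seed, prev0, cands, maps, state)
  state <- leg2$state
  xyz <- rbind(leg2$pts[rev(seq_len(nrow(leg2$pts))), , drop = FALSE], fwd)
  sse <- trace_sse_labels(xyz, maps)
  list(trace = ca_trace(xyz, sse), state = state)
}

# label trace points by the argmax of the three SSE confidences
trace_sse_labels <- function(xyz, maps) {
  h <- conf_at(maps, "helix", xyz)
  s <- conf_at(maps, "sheet", xyz)
  l <- conf_at(maps, "loop", xyz)
  c("helix", "sheet", "loop")[max.col(cbind(h, s, l), ties.method = "last")]
}

#' Trace all C-alpha chains in a confidence map
#'
#' Repeats seed selection and bidirectional walking until no unvisited
#' candidate reaches the confidence floor, returning every trace found
#' (single-point traces included). Fully deterministic: seeds are
#' processed in decreasing confidence order with lexicographic
#' tie-breaks.
#'
#' @param maps a [confidence_maps()].
#' @param params a [walk_params()].
#' @return List of [ca_trace()] objects.
#' @export
trace_all <- function(maps, params = walk_params()) {
  stopifnot(inherits(maps, "confidence_maps"))
  cands <- find_ca_candidates(maps, params)
  state <- walk_state(maps, params)
  traces <- list()
  repeat {
    open <- which(!is_visited(state, maps, cands$xyz))
    if (length(open) == 0) break
    seed_i <- open[which.max(cands$conf[open])]
    res <- walk_trace_impl(cands$xyz[seed_i, ], cands, maps, state)
    state <- res$state
    traces[[length(traces) + 1L]] <- res$trace
  }
  traces
}
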