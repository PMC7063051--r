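#' Ideal alpha-helix parameters
#'
#' Constants of the ideal alpha-helix wound about a screw axis: radius
#' 2.11 A, angular pitch 1.149 rad per Angstrom of axis travel, rise
#' 1.5 A per residue. `s` (axial phase shift, A) and `r` (phase
#' rotation, rad) position a particular helix: a C-alpha placed at
#' axial position `t` sits at angle `theta = 1.149 * (t - s) + r` and
#' radius 2.11 from the axis.
#'
#' @param s phase shift in `[0, rise)`, A.
#' @param r phase rotation in `[0, 2*pi)`, rad.
#' @param radius helix radius, A.
#' @param omega angular pitch, rad per A of axis.
#' @param rise axial rise per residue, A.
#' @return Object of class `helix_params`.
#' @export
helix_params <- function(s = 0, r = 0, radius = 2.11, omega = 1.149,
                         rise = 1.5) {
  structure(list(s = s, r = r, radius = radius, omega = omega, rise = rise),
            class = "helix_params")
}

#' Estimate the screw axis of a helix point sequence
#'
#' The center line about which the helix winds is approximated by the
#' centroids of a sliding window (hop 1) over the ordered points; one
#' turn of an alpha-helix spans about 3.6 residues, so the default
#' window of 4 makes consecutive centroids nearly cancel the radial
#' component. The centroid polyline is smoothed with a 3-point moving
#' average, extrapolated by half a window span at both ends, and
#' arclength-parameterized.
#'
#' @param points ordered numeric matrix (n x 3); needs `window + 1`
#'   points or more.
#' @param window centroid window length in residues.
#' @return Object of class `screw_axis` with the polyline, cumulative
#'   arclength and total `length`.
#' @export
estimate_screw_axis <- function(points, window = 4L) {
  points <- rbind(points)
  n <- nrow(points)
  if (n < window + 1) {
    stop("need at least window + 1 = ", window + 1, " points, got ", n)
  }
  m <- n - window + 1
  cent <- t(vapply(seq_len(m), function(i) {
    colMeans(points[i:(i + window - 1), , drop = FALSE])
  }, numeric(3)))
  # two passes of interior 3-point moving average damp the residual
  # helical wobble of the raw centroids without moving the ends along
  # the axis; the ends are stabilized by line projection below
  smooth_pass <- function(cc) {
    k <- nrow(cc)
    if (k < 3) return(cc)
    sm <- cc
    for (i in 2:(k - 1)) sm[i, ] <- (cc[i - 1, ] + cc[i, ] + cc[i + 1, ]) / 3
    sm
  }
  cent <- smooth_pass(smooth_pass(cent))
  # drop consecutive duplicates
  if (nrow(cent) > 1) {
    keep <- c(TRUE, sqrt(rowSums(diff(cent)^2)) > 1e-9)
    cent <- cent[keep, , drop = FALSE]
  }
  if (nrow(cent) < 2) stop("degenerate axis: centroids coincide")
  # stabilize each end with a quadratic (in arclength) fit through the
  # nearest few interior centroids -- the raw end centroids still carry
  # helical wobble -- then extrapolate by half a window span so the
  # axis ends line up with the terminal residues
  ext <- 1.5 * (window - 1) / 2
  k <- nrow(cent)
  u <- c(0, cumsum(sqrt(rowSums(diff(cent)^2))))
  end_fit <- function(idx, at_u, extrap_u) {
    pp <- cent[idx, , drop = FALSE]
    uu <- u[idx]
    degree <- min(2L, nrow(pp) - 1L)
    if (degree < 1) {
      return(list(at = cent[which.min(abs(u - at_u)), ],
                  extrap = NULL))
    }
    basis <- stats::poly(uu, degree = degree, raw = TRUE)
    fit <- stats::lm.fit(cbind(1, basis), pp)
    eval_at <- function(uq) {
      as.numeric(crossprod(fit$coefficients,
                           c(1, uq^seq_len(degree))))
    }
    list(at = eval_at(at_u), extrap = eval_at(extrap_u))
  }
  skip <- min(2L, max(0L, k - 2L))  # end centroids still carry wobble
  h <- min(6L, k - skip)
  st <- end_fit(seq(1L + skip, skip + h), u[1], u[1] - ext)
  en <- end_fit(seq(k - skip - h + 1L, k - skip), u[k], u[k] + ext)
  cent[1, ] <- st$at
  cent[k, ] <- en$at
  if (skip >= 2L && k >= 4L) {
    # the second/penultimate centroids are polluted through smoothing
    st2 <- end_fit(seq(1L + skip, skip + h), u[2], u[2])
    en2 <- end_fit(seq(k - skip - h + 1L, k - skip), u[k - 1], u[k - 1])
    cent[2, ] <- st2$at
    cent[k - 1, ] <- en2$at
  }
  poly <- cent
  if (!is.null(st$extrap)) poly <- rbind(st$extrap, poly)
  if (!is.null(en$extrap)) poly <- rbind(poly, en$extrap)
  seglen <- sqrt(rowSums(diff(poly)^2))
  structure(list(polyline = poly, cumlen = c(0, cumsum(seglen)),
                 length = sum(seglen)),
            class = "screw_axis")
}

#' @export
print.screw_axis <- function(x, ...) {
  cat(sprintf("<screw_axis> %d polyline points, arclength %.2f A\n",
              nrow(x$polyline), x$length))
  invisible(x)
}

# point and unit tangent at arclength t
axis_eval <- function(axis, t) {
  if (t < -1e-9 || t > axis$length + 1e-9) {
    stop("t = ", t, " outside axis arclength range [0, ", axis$length, "]")
  }
  t <- min(max(t, 0), axis$length)
  seg <- findInterval(t, axis$cumlen, rightmost.closed = TRUE)
  seg <- min(max(seg, 1L), nrow(axis$polyline) - 1L)
  a <- axis$polyline[seg, ]
  b <- axis$polyline[seg + 1, ]
  u <- (t - axis$cumlen[seg]) / (axis$cumlen[seg + 1] - axis$cumlen[seg])
  list(point = a + u * (b - a), tangent = unit(b - a))
}

#' Evaluate the ideal helix at an axis position
#'
#' Builds a local frame at arclength `t` along the screw axis (local z
#' = axis tangent; local y from the cross product of z with the global
#' x axis, falling back to global y when the tangent is parallel to x)
#' and offsets by the helix radius at phase angle `theta = omega * (t -
#' s) + r`. The returned point lies at exactly `radius` from the axis.
#'
#' @param t position along the axis (arclength, A).
#' @param axis a `screw_axis`.
#' @param params a [helix_params()].
#' @return Length-3 world coordinate.
#' @export
ideal_helix_point <- function(t, axis, params = helix_params()) {
  ev <- axis_eval(axis, t)
  z <- ev$tangent
  ref <- c(1, 0, 0)
  cp <- cross3(z, ref)
  if (vnorm(cp) < 1e-6) {
    ref <- c(0, 1, 0)
    cp <- cross3(z, ref)
  }
  y <- unit(cp)
  x <- cross3(y, z)  # unit by construction
  theta <- params$omega * (t - params$s) + params$r
  # cos toward local y, -sin toward local x: advancing t winds
  # counterclockwise about the tangent, a right-handed helix (the
  # handedness of a natural alpha-helix)
  offset <- params$radius * (cos(theta) * y - sin(theta) * x)
  ev$point + offset
}

# mean distance from each placed point to its nearest original point
helix_fit_objective <- function(placed, original) {
  mean(vapply(seq_len(nrow(placed)), function(i) {
    sqrt(min(rowSums((original - matrix(placed[i, ], nrow(original), 3,
                                        byrow = TRUE))^2)))
  }, 0))
}

place_helix_cas <- function(axis, params) {
  ts <- seq(0, axis$length, by = params$rise)
  t(vapply(ts, ideal_helix_point, numeric(3), axis = axis, params = params))
}

#' Refit a helix segment onto the ideal helix
#'
#' Estimates the screw axis of the segment, places new C-alpha atoms
#' every 1.5 A of axis travel on the ideal 2.11 A radius helix, and
#' picks the phase parameters (s, r) minimizing the mean distance from
#' the placed atoms to the original prediction (coarse grid search
#' followed by a derivative-free local polish; fully deterministic).
#'
#' @param segment_points ordered numeric matrix (n x 3) of predicted
#'   helix C-alpha positions.
#' @param maps optional [confidence_maps()]; accepted for interface
#'   symmetry with the detection step and reserved for
#'   confidence-weighted fitting (the current fit is purely geometric).
#' @param window centroid window for [estimate_screw_axis()].
#' @return A [ca_trace()] labeled `helix`; if the estimated axis is
#'   shorter than one rise the segment is returned unchanged with a
#'   warning.
#' @export
refit_helix <- function(segment_points, maps = NULL, window = 4L) {
  segment_points <- rbind(segment_points)
  params0 <- helix_params()
  axis <- estimate_screw_axis(segment_points, window)
  if (axis$length < params0$rise) {
    warning("degenerate axis (shorter than one rise); segment unchanged")
    return(ca_trace(segment_points, rep("helix", nrow(segment_points))))
  }
  obj <- function(sr) {
    p <- helix_params(s = sr[1], r = sr[2])
    helix_fit_objective(place_helix_cas(axis, p), segment_points)
  }
  grid <- expand.grid(s = seq(0, params0$rise - 0.05, by = 0.05),
                      r = seq(0, 2 * pi, by = 0.05))
  vals <- apply(grid, 1, obj)
  best <- as.numeric(grid[which.min(vals), ])
  polish <- stats::optim(best, obj, method = "Nelder-Mead",
                         control = list(maxit = 200, reltol = 1e-8))
  final <- if (polish$value <= min(vals)) polish$par else best
  out <- place_helix_cas(axis, helix_params(s = final[1], r = final[2]))
  tr <- ca_trace(out, rep("helix", nrow(out)))
  attr(tr, "fit") <- list(s = final[1], r = final[2],
                          objective = min(polish$value, min(vals)),
                          grid_min = min(vals), axis = axis)
  tr
}

#' Detect helix segments in a trace graph
#'
#' A node is helix-labeled when the mean helix confidence within 2 A of
#' it exceeds both the sheet and loop means; maximal simple-path runs
#' of at least `min_len` consecutive helix nodes are returned.
#'
#' @param graph a [trace_graph()].
#' @param maps a [confidence_maps()] in the same frame.
#' @param min_len minimum run length (default 6).
#' @return List of integer node-index sequences.
#' @export
detect_helix_segments <- function(graph, maps, min_len = 6L) {
  n <- nrow(graph$coords)
  if (n == 0) return(list())
  offs <- sphere_offsets(2.0, min(maps$voxel))
  d <- dim(maps$helix)
  is_helix <- vapply(seq_len(n), function(i) {
    ijk <- round(world_to_index(graph$coords[i, , drop = FALSE],
                                maps$origin, maps$voxel))
    nb <- sweep(offs, 2, as.integer(ijk), "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    if (nrow(nb) == 0) return(FALSE)
    mean(maps$helix[nb]) > mean(maps$sheet[nb]) &&
      mean(maps$helix[nb]) > mean(maps$loop[nb])
  }, TRUE)

  adj <- tg_adjacency(graph)
  deg <- tg_degree(graph)
  segments <- list()
  seen_edge <- new.env(parent = emptyenv())
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  # run starts: helix nodes whose helix-neighborhood does not extend
  # backwards along a simple path
  helix_deg <- vapply(seq_len(n), function(i) sum(is_helix[adj[[i]]]), 0L)
  starts <- which(is_helix & (helix_deg <= 1L | deg != 2L))
  for (s0 in starts) {
    nbs <- adj[[s0]][is_helix[adj[[s0]]]]
    extended <- FALSE
    for (nb in nbs) {
      if (!is.null(seen_edge[[ekey(s0, nb)]])) next
      run <- c(s0, nb)
      seen_edge[[ekey(s0, nb)]] <- TRUE
      prev <- s0; cur <- nb
      while (deg[cur] == 2L) {
        nxt <- setdiff(adj[[cur]], prev)
        if (length(nxt) != 1 || !is_helix[nxt] ||
            !is.null(seen_edge[[ekey(cur, nxt)]])) break
        seen_edge[[ekey(cur, nxt)]] <- TRUE
        run <- c(run, nxt)
        prev <- cur; cur <- nxt
      }
      if (length(run) >= min_len) {
        segments[[length(segments) + 1L]] <- run
      }
      extended <- TRUE
    }
  }
  segments
}

#' Refit all detected helices in a graph
#'
#' Detects helix runs, refits each onto the ideal helix, and splices
#' the refitted atoms back into the graph: the original run nodes are
#' replaced by the new trace, reconnected to the flanking nodes by
#' nearest endpoints.
#'
#' @param graph a [trace_graph()].
#' @param maps a [confidence_maps()].
#' @param min_len minimum helix run length to refit.
#' @param window centroid window for the screw-axis estimate.
#' @return The refined [trace_graph()].
#' @export
refine_helices <- function(graph, maps, min_len = 6L, window = 4L) {
  g <- graph
  segs <- detect_helix_segments(g, maps, min_len)
  segs <- Filter(function(s) length(s) >= window + 1, segs)
  if (length(segs) == 0) return(g)
  adj <- tg_adjacency(g)

  coords <- g$coords
  sse <- g$sse
  edges <- g$edges
  drop <- integer(0)
  for (seg in segs) {
    if (any(seg %in% drop)) next  # overlapping run already handled
    head_fl <- setdiff(adj[[seg[1]]], seg)
    tail_fl <- setdiff(adj[[seg[length(seg)]]], seg)
    refit <- withCallingHandlers(
      refit_helix(g$coords[seg, , drop = FALSE], maps, window = window),
      warning = function(w) invokeRestart("muffleWarning"))
    new_xyz <- refit$xyz
    # orient the refit along the run so flanks reconnect to the right end
    if (vnorm(new_xyz[1, ] - g$coords[seg[1], ]) >
        vnorm(new_xyz[nrow(new_xyz), ] - g$coords[seg[1], ])) {
      new_xyz <- new_xyz[rev(seq_len(nrow(new_xyz))), , drop = FALSE]
    }
    k <- nrow(new_xyz)
    new_ids <- nrow(coords) + seq_len(k)
    coords <- rbind(coords, new_xyz)
    sse <- c(sse, rep("helix", k))
    if (k > 1) edges <- rbind(edges, cbind(new_ids[-k], new_ids[-1]))
    for (fl in head_fl) edges <- rbind(edges, c(fl, new_ids[1]))
    for (fl in tail_fl) edges <- rbind(edges, c(fl, new_ids[k]))
    drop <- c(drop, seg)
  }
  g2 <- trace_graph(coords, edges, sse, check = FALSE)
  tg_drop_nodes(g2, drop)
}
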