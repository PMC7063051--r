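#' Trace graph
#'
#' Undirected graph over C-alpha nodes: node coordinates (A), optional
#' per-node SSE labels, and an edge list. No self-loops or duplicate
#' edges are allowed; edges longer than 4.5 A are rejected at
#' construction (refinement passes may merge nodes and keep the
#' resulting rewired edges).
#'
#' @param coords numeric matrix (n x 3).
#' @param edges integer matrix (m x 2) of 1-based node index pairs.
#' @param sse optional character vector of per-node labels.
#' @param check validate the 4.5 A edge-length invariant.
#' @return Object of class `trace_graph`.
#' @export
trace_graph <- function(coords, edges, sse = NULL, check = TRUE) {
  coords <- rbind(coords)
  n <- nrow(coords)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0) {
    edges <- t(apply(edges, 1, sort))
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    edges <- unique(edges)
    if (any(edges < 1 | edges > n)) stop("edge index out of range")
    if (check) {
      len <- sqrt(rowSums((coords[edges[, 1], , drop = FALSE] -
                             coords[edges[, 2], , drop = FALSE])^2))
      if (any(len > 4.5)) {
        stop("edge longer than 4.5 A; traces should not contain such bonds")
      }
    }
  }
  if (is.null(sse)) sse <- rep("loop", n)
  structure(list(coords = unname(coords), edges = edges, sse = sse),
            class = "trace_graph")
}

#' @export
print.trace_graph <- function(x, ...) {
  cat(sprintf("<trace_graph> %d nodes, %d edges, %d component(s)\n",
              nrow(x$coords), nrow(x$edges), n_components(x)))
  invisible(x)
}

tg_adjacency <- function(g) {
  n <- nrow(g$coords)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (nrow(g$edges) > 0) {
    for (e in seq_len(nrow(g$edges))) {
      a <- g$edges[e, 1]; b <- g$edges[e, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  lapply(adj, sort)
}

tg_degree <- function(g) {
  n <- nrow(g$coords)
  deg <- integer(n)
  if (nrow(g$edges) > 0) {
    t1 <- tabulate(g$edges[, 1], n)
    t2 <- tabulate(g$edges[, 2], n)
    deg <- t1 + t2
  }
  deg
}

n_components <- function(g) {
  length(unique(component_labels(g)))
}

component_labels <- function(g) {
  n <- nrow(g$coords)
  adj <- tg_adjacency(g)
  lab <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack) > 0) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (lab[v] != 0L) next
      lab[v] <- cur
      stack <- c(stack, adj[[v]][lab[adj[[v]]] == 0L])
    }
  }
  lab
}

# drop nodes (and incident edges), renumbering the survivors
tg_drop_nodes <- function(g, drop) {
  if (length(drop) == 0) return(g)
  n <- nrow(g$coords)
  keep <- setdiff(seq_len(n), drop)
  remap <- integer(n)
  remap[keep] <- seq_along(keep)
  ed <- g$edges
  if (nrow(ed) > 0) {
    ok <- !(ed[, 1] %in% drop) & !(ed[, 2] %in% drop)
    ed <- matrix(remap[ed[ok, , drop = FALSE]], ncol = 2)
  }
  trace_graph(g$coords[keep, , drop = FALSE], ed, g$sse[keep], check = FALSE)
}

tg_drop_edge <- function(g, a, b) {
  ed <- g$edges
  hit <- (ed[, 1] == min(a, b)) & (ed[, 2] == max(a, b))
  trace_graph(g$coords, ed[!hit, , drop = FALSE], g$sse, check = FALSE)
}

#' Convert traces to a graph
#'
#' Each trace becomes a simple path of nodes; traces stay disconnected
#' from one another (no cross-trace edges).
#'
#' @param traces list of [ca_trace()] objects.
#' @return A [trace_graph()].
#' @export
traces_to_graph <- function(traces) {
  if (inherits(traces, "ca_trace")) traces <- list(traces)
  coords <- NULL; sse <- character(0); edges <- NULL
  off <- 0L
  for (tr in traces) {
    n <- nrow(tr$xyz)
    coords <- rbind(coords, tr$xyz)
    sse <- c(sse, tr$sse %||% rep("loop", n))
    if (n > 1) edges <- rbind(edges, cbind(off + 1:(n - 1), off + 2:n))
    off <- off + n
  }
  if (is.null(edges)) edges <- matrix(integer(0), ncol = 2)
  trace_graph(coords, edges, sse, check = FALSE)
}

#' Combine nearby trace endpoints
#'
#' For every endpoint (node of degree <= 1), if any other node lies
#' within `merge_radius`, the endpoint is merged onto that node: its
#' location is reassigned to the absorbing node and its edges are
#' rewired there. Repeats until no endpoint can be merged, fusing
#' neighboring disjoint traces into connected components.
#'
#' @param graph a [trace_graph()].
#' @param merge_radius merge distance in A (default 3.0).
#' @return The refined [trace_graph()].
#' @export
combine_paths <- function(graph, merge_radius = 3.0) {
  g <- graph
  repeat {
    deg <- tg_degree(g)
    adj <- tg_adjacency(g)
    ends <- which(deg <= 1L)
    merged <- FALSE
    for (e in ends) {
      others <- setdiff(seq_len(nrow(g$coords)), c(e, adj[[e]]))
      if (length(others) == 0) next
      d2 <- rowSums((g$coords[others, , drop = FALSE] -
                       matrix(g$coords[e, ], length(others), 3,
                              byrow = TRUE))^2)
      j <- which.min(d2)
      if (d2[j] > merge_radius^2) next
      target <- others[j]
      # rewire e's edges onto target, drop e
      ed <- g$edges
      if (nrow(ed) > 0) {
        ed[ed == e] <- target
        ok <- ed[, 1] != ed[, 2]
        ed <- unique(t(apply(ed[ok, , drop = FALSE], 1, sort)))
        if (length(ed) == 0) ed <- matrix(integer(0), ncol = 2)
      }
      g$edges <- matrix(as.integer(ed), ncol = 2)
      g <- tg_drop_nodes(g, e)
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  g
}

# Walk one branch leaving `junction` through `first`: follow degree-2
# nodes until an end node (degree 1) or another junction (degree >= 3).
# Returns the interior nodes walked (excluding both the junction and a
# terminal junction, including a terminal end node), the terminal node
# and its kind.
branch_walk <- function(adj, deg, junction, first) {
  path <- integer(0)
  prev <- junction
  cur <- first
  repeat {
    if (deg[cur] >= 3L || (deg[cur] == 1L && cur != first) ||
        (deg[cur] == 1L && cur == first)) {
      if (deg[cur] >= 3L) {
        return(list(interior = path, terminal = cur, kind = "junction"))
      }
      return(list(interior = c(path, cur), terminal = cur, kind = "end"))
    }
    path <- c(path, cur)
    nxt <- setdiff(adj[[cur]], prev)
    if (length(nxt) == 0) {  # isolated oddity; treat as end
      return(list(interior = path, terminal = cur, kind = "end"))
    }
    prev <- cur
    cur <- nxt[1]
    if (cur == junction) {  # cycle back to the anchor
      return(list(interior = path, terminal = junction, kind = "junction"))
    }
  }
}

branch_depth <- function(branch) {
  length(branch$interior)
}

#' Remove side-chain branches
#'
#' At every junction (node of degree >= 3) each incident branch is
#' walked to its end node or to the next junction. When the unique
#' shortest branch has depth three or less (counting nodes beyond the
#' junction) and every other branch is strictly deeper, that branch is
#' classified as a side-chain connection and removed. Iterates to a
#' fixed point.
#'
#' @param graph a [trace_graph()].
#' @return The refined [trace_graph()].
#' @export
remove_side_chains <- function(graph) {
  g <- graph
  repeat {
    deg <- tg_degree(g)
    adj <- tg_adjacency(g)
    junctions <- which(deg >= 3L)
    changed <- FALSE
    for (j in junctions) {
      branches <- lapply(adj[[j]], function(nb) branch_walk(adj, deg, j, nb))
      depths <- vapply(branches, branch_depth, 0L)
      shortest <- which(depths == min(depths))
      if (length(shortest) != 1L) next
      b <- branches[[shortest]]
      if (depths[shortest] > 3L) next
      if (!all(depths[-shortest] > depths[shortest])) next
      if (length(b$interior) == 0) {
        # a direct junction-junction shortcut: remove just the edge
        g <- tg_drop_edge(g, j, b$terminal)
      } else {
        g <- tg_drop_nodes(g, b$interior)
      }
      changed <- TRUE
      break
    }
    if (!changed) break
  }
  g
}

# voxel centers within `radius` of the polyline through `pts` (world A)
cylinder_voxels <- function(pts, density, radius = 1.0) {
  d <- dim(density$grid)
  hits <- integer(0)
  for (s in seq_len(nrow(pts) - 1)) {
    a <- pts[s, ]; b <- pts[s + 1, ]
    lo <- pmin(a, b) - radius; hi <- pmax(a, b) + radius
    li <- pmax(1, floor(world_to_index(rbind(lo), density$origin,
                                       density$voxel)))
    hi_i <- pmin(d, ceiling(world_to_index(rbind(hi), density$origin,
                                           density$voxel)))
    if (any(li > hi_i)) next
    gx <- li[1]:hi_i[1]; gy <- li[2]:hi_i[2]; gz <- li[3]:hi_i[3]
    nb <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
    pw <- index_to_world(nb, density$origin, density$voxel)
    ab <- b - a
    len2 <- sum(ab^2)
    tpar <- if (len2 == 0) rep(0, nrow(pw)) else
      pmin(1, pmax(0, as.numeric((sweep(pw, 2, a) %*% ab) / len2)))
    near <- sweep(outer(tpar, ab), 2, -a, "-")  # a + t * ab
    d2 <- rowSums((pw - near)^2)
    keep <- nb[d2 <= radius^2, , drop = FALSE]
    if (nrow(keep) > 0) {
      hits <- c(hits, keep[, 1] + d[1] * (keep[, 2] - 1) +
                  d[1] * d[2] * (keep[, 3] - 1))
    }
  }
  unique(hits)
}

#' Remove false-positive loop paths
#'
#' When two branch paths leave one junction and terminate in the same
#' other junction they form a loop, typically a shortcut across an
#' alpha-helix. The mean map density inside a 1 A radius cylinder along
#' each path decides which is real: the lower-density path is removed
#' (ties remove the longer path). Iterates to a fixed point.
#'
#' @param graph a [trace_graph()].
#' @param density a [density_map()] in the same frame as the graph.
#' @param radius cylinder sampling radius, A.
#' @return The refined [trace_graph()].
#' @export
remove_loops <- function(graph, density, radius = 1.0) {
  stopifnot(inherits(density, "density_map"))
  g <- graph
  repeat {
    deg <- tg_degree(g)
    adj <- tg_adjacency(g)
    junctions <- which(deg >= 3L)
    changed <- FALSE
    for (j in junctions) {
      branches <- lapply(adj[[j]], function(nb) branch_walk(adj, deg, j, nb))
      term <- vapply(branches, function(b) {
        if (b$kind == "junction") b$terminal else NA_integer_
      }, 0L)
      for (tt in unique(term[!is.na(term)])) {
        pair <- which(term == tt)
        if (length(pair) < 2) next
        # score each parallel path by mean cylinder density
        path_pts <- lapply(pair, function(pi) {
          rbind(g$coords[j, ],
                g$coords[branches[[pi]]$interior, , drop = FALSE],
                g$coords[tt, ])
        })
        dens <- vapply(path_pts, function(pp) {
          vox <- cylinder_voxels(pp, density, radius)
          if (length(vox) == 0) -Inf else mean(density$grid[vox])
        }, 0)
        lens <- vapply(pair, function(pi) length(branches[[pi]]$interior), 0L)
        loser <- order(dens, -lens)[1]
        b <- branches[[pair[loser]]]
        if (length(b$interior) == 0) {
          g <- tg_drop_edge(g, j, tt)
        } else {
          g <- tg_drop_nodes(g, b$interior)
        }
        changed <- TRUE
        break
      }
      if (changed) break
    }
    if (!changed) break
  }
  g
}

#' Remove short dead-end spurs
#'
#' Branches leaving a junction that reach a dead end (degree-1 node)
#' within a depth of two are protruding side-chains and are removed.
#' Terminal stretches of a simple path (no junction) are never touched.
#' Iterates to a fixed point.
#'
#' @param graph a [trace_graph()].
#' @return The refined [trace_graph()].
#' @export
remove_dead_ends <- function(graph) {
  g <- graph
  repeat {
    deg <- tg_degree(g)
    adj <- tg_adjacency(g)
    junctions <- which(deg >= 3L)
    changed <- FALSE
    for (j in junctions) {
      for (nb in adj[[j]]) {
        b <- branch_walk(adj, deg, j, nb)
        if (b$kind == "end" && branch_depth(b) <= 2L) {
          g <- tg_drop_nodes(g, b$interior)
          changed <- TRUE
          break
        }
      }
      if (changed) break
    }
    if (!changed) break
  }
  g
}

#' Run all four graph-refinement passes
#'
#' Path combination, side-chain removal, loop removal and dead-end
#' removal, in that order, each to its own fixed point.
#'
#' @param graph a [trace_graph()].
#' @param density a [density_map()] used by the loop pass.
#' @param merge_radius endpoint merge radius for [combine_paths()].
#' @return The refined [trace_graph()].
#' @export
refine_graph <- function(graph, density, merge_radius = 3.0) {
  g <- combine_paths(graph, merge_radius)
  g <- remove_side_chains(g)
  g <- remove_loops(g, density)
  remove_dead_ends(g)
}

#' Decompose a graph into C-alpha traces
#'
#' Splits every connected component into maximal simple paths (walks
#' through degree-2 nodes), starting at endpoints and junctions, so the
#' result can be written with [write_trace_pdb()].
#'
#' @param graph a [trace_graph()].
#' @return List of [ca_trace()] objects.
#' @export
graph_to_traces <- function(graph) {
  g <- graph
  n <- nrow(g$coords)
  if (n == 0) return(list())
  adj <- tg_adjacency(g)
  deg <- tg_degree(g)
  edge_used <- new.env(parent = emptyenv())
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  traces <- list()
  starts <- c(which(deg == 1L | deg >= 3L), which(deg == 2L))
  for (s in starts) {
    for (nb in adj[[s]]) {
      if (!is.null(edge_used[[ekey(s, nb)]])) next
      path <- c(s, nb)
      edge_used[[ekey(s, nb)]] <- TRUE
      prev <- s; cur <- nb
      while (deg[cur] == 2L) {
        nxt <- setdiff(adj[[cur]], prev)
        if (length(nxt) == 0 || !is.null(edge_used[[ekey(cur, nxt[1])]])) break
        edge_used[[ekey(cur, nxt[1])]] <- TRUE
        path <- c(path, nxt[1])
        prev <- cur; cur <- nxt[1]
      }
      traces[[length(traces) + 1L]] <-
        ca_trace(g$coords[path, , drop = FALSE], g$sse[path])
    }
  }
  # isolated nodes become single-point traces
  for (v in which(deg == 0L)) {
    traces[[length(traces) + 1L]] <-
      ca_trace(g$coords[v, , drop = FALSE], g$sse[v])
  }
  traces
}
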