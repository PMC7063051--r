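# Shared fixtures and independent oracles for the test suite.

# straight screw axis along z of the given length
straight_axis <- function(len = 40) {
  structure(list(polyline = cbind(c(0, 0), c(0, 0), c(0, len)),
                 cumlen = c(0, len), length = len),
            class = "screw_axis")
}

# densely sampled circular-arc screw axis in the xz plane
arc_axis <- function(R = 30, span = 1, step = 0.002) {
  th <- seq(0, span, by = step)
  poly <- cbind(R * sin(th), 0 * th, R - R * cos(th))
  sl <- sqrt(rowSums(diff(poly)^2))
  structure(list(polyline = poly, cumlen = c(0, cumsum(sl)),
                 length = sum(sl)),
            class = "screw_axis")
}

# ideal-helix CA points along an axis
ideal_helix_points <- function(n = 19, axis = straight_axis(), s = 0, r = 0) {
  ts <- seq(0, by = 1.5, length.out = n)
  t(vapply(ts, ideal_helix_point, numeric(3), axis = axis,
           params = helix_params(s = s, r = r)))
}

# standard mid-size test protein used by several modules
fixture_protein <- function(seed = 11) {
  generate_synthetic_protein(
    list(c("helix", 20), c("loop", 6), c("strand", 8), c("loop", 6),
         c("helix", 18), c("loop", 6), c("strand", 8), c("loop", 6),
         c("helix", 20), c("loop", 22)),
    seed = seed)
}

# oracle maps + preprocessed density for a model
fixture_maps <- function(model, resolution = 3) {
  dm <- simulate_density(model, resolution = resolution, voxel = 1)
  pre <- preprocess_map(dm, 0.05 * max(dm$grid))
  list(pre = pre, maps = oracle_confidence(model, pre))
}

# nearest distance from each row of a to the point set b
nearest_dist <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    sqrt(min(rowSums((b - matrix(a[i, ], nrow(b), 3, byrow = TRUE))^2)))
  }, 0)
}

# Independent oracle: maximum one-to-one matching within a cutoff,
# via augmenting paths on the bipartite "within cutoff" graph.
max_bipartite_matching <- function(pred, native, cutoff = 3.0) {
  np <- nrow(pred); nn <- nrow(native)
  ok <- matrix(FALSE, np, nn)
  for (i in seq_len(np)) {
    ok[i, ] <- sqrt(rowSums((native -
      matrix(pred[i, ], nn, 3, byrow = TRUE))^2)) <= cutoff
  }
  match_n <- rep(0L, nn)  # native j -> pred i (0 = free)
  try_augment <- function(i, seen) {
    for (j in which(ok[i, ])) {
      if (seen[j]) next
      seen[j] <- TRUE
      if (match_n[j] == 0L) {
        match_n[j] <<- i
        return(TRUE)
      }
      old <- match_n[j]
      match_n[j] <<- i
      if (try_augment(old, seen)) return(TRUE)
      match_n[j] <<- old
    }
    FALSE
  }
  count <- 0L
  for (i in seq_len(np)) {
    if (try_augment(i, rep(FALSE, nn))) count <- count + 1L
  }
  count
}

# tiny graph constructors for refinement tests ------------------------------

# chain of n nodes along x at 3.8 A spacing, starting at `start`
chain_coords <- function(n, start = c(0, 0, 0), dir = c(1, 0, 0)) {
  t(vapply(seq_len(n) - 1, function(i) start + 3.8 * i * dir, numeric(3)))
}

# a long chain with a short spur attached at node `at`
spur_graph <- function(chain_n = 9, spur_n = 2, at = 5) {
  main <- chain_coords(chain_n)
  spur <- t(vapply(seq_len(spur_n), function(i) {
    main[at, ] + c(0, 3.0 * i, 0)
  }, numeric(3)))
  coords <- rbind(main, spur)
  edges <- rbind(cbind(1:(chain_n - 1), 2:chain_n),
                 c(at, chain_n + 1))
  if (spur_n > 1) {
    edges <- rbind(edges, cbind(chain_n + 1:(spur_n - 1),
                                chain_n + 2:spur_n))
  }
  trace_graph(coords, edges, check = FALSE)
}
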