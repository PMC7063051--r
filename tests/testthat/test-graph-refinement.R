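test_that("traces convert to path graphs with coordinates preserved", {
  tr1 <- ca_trace(chain_coords(6))
  tr2 <- ca_trace(chain_coords(4, start = c(0, 10, 0)))
  g <- traces_to_graph(list(tr1, tr2))
  expect_equal(nrow(g$coords), 10L)
  expect_equal(nrow(g$edges), 8L)  # (6-1) + (4-1)
  expect_equal(cryotrace:::n_components(g), 2L)
  expect_identical(g$coords[1:6, ], unname(tr1$xyz))
})

test_that("combine_paths merges endpoints within 3 A and no further", {
  # two collinear chains, nearest endpoints 2.0 A apart
  a <- chain_coords(4)
  b <- chain_coords(4, start = c(3.8 * 3 + 2.0, 0, 0))
  g <- traces_to_graph(list(ca_trace(a), ca_trace(b)))
  gc <- combine_paths(g)
  expect_equal(cryotrace:::n_components(gc), 1L)
  expect_equal(nrow(gc$coords), 7L)  # endpoint absorbed
  # merged endpoint took the absorbing node's coordinate
  expect_true(any(apply(gc$coords, 1, function(p) all(p == b[1, ]))) ||
                any(apply(gc$coords, 1, function(p) all(p == a[4, ]))))

  # endpoints 3.5 A apart stay separate
  b2 <- chain_coords(4, start = c(3.8 * 3 + 3.5, 0, 0))
  g2 <- traces_to_graph(list(ca_trace(a), ca_trace(b2)))
  expect_equal(cryotrace:::n_components(combine_paths(g2)), 2L)
})

test_that("side-chain removal follows the depth rule", {
  run_case <- function(depths) {
    # star of three branches from one junction with the given depths
    dirs <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
    coords <- matrix(0, 1, 3)
    edges <- NULL
    for (bi in seq_along(depths)) {
      prev <- 1L
      for (d in seq_len(depths[bi])) {
        coords <- rbind(coords, 3.8 * d * dirs[[bi]])
        edges <- rbind(edges, c(prev, nrow(coords)))
        prev <- nrow(coords)
      }
    }
    g <- trace_graph(coords, edges, check = FALSE)
    remove_side_chains(g)
  }
  expect_equal(nrow(run_case(c(2, 5, 6))$coords), 1 + 5 + 6)  # depth-2 cut
  expect_equal(nrow(run_case(c(4, 5, 6))$coords), 1 + 4 + 5 + 6)  # kept
  expect_equal(nrow(run_case(c(2, 3, 6))$coords), 1 + 3 + 6)  # 2 <= 3 cut
  expect_equal(nrow(run_case(c(3, 3, 6))$coords), 1 + 3 + 3 + 6)  # tie kept
})

test_that("loop removal drops the low-density arc of a theta graph", {
  # two junctions joined by a straight 3-node arc and a detour arc
  top <- rbind(c(0, 0, 0), c(3.5, 0, 0), c(7, 0, 0), c(10.5, 0, 0),
               c(14, 0, 0))
  bottom <- rbind(c(3.5, -3.5, 0), c(7, -4.5, 0), c(10.5, -3.5, 0))
  stubs <- rbind(c(-3.5, 0, 0), c(17.5, 0, 0))
  coords <- rbind(top, bottom, stubs)
  edges <- rbind(cbind(1:4, 2:5),        # top path
                 c(1, 6), cbind(6:7, 7:8), c(8, 5),  # bottom path
                 c(9, 1), c(5, 10))      # stubs keep junction degree 3
  g <- trace_graph(coords, edges, check = FALSE)
  # density high along the top path only
  dgrid <- array(0, c(30, 20, 7))
  dens <- density_map(dgrid, origin = c(-8, -10, -3))
  for (i in 1:5) {
    ijk <- round(cryotrace:::world_to_index(top[i, , drop = FALSE],
                                            dens$origin, dens$voxel))
    dens$grid[ijk[1] + (-1:1), ijk[2] + (-1:1), ijk[3] + (-1:1)] <- 5
  }
  gr <- remove_loops(g, dens)
  expect_equal(nrow(gr$coords), 7L)  # bottom interior (3 nodes) removed
  expect_true(all(nearest_dist(gr$coords, rbind(top, stubs)) < 1e-9))
  # acyclic graph is untouched
  g_path <- traces_to_graph(ca_trace(chain_coords(6)))
  expect_identical(remove_loops(g_path, dens)$coords, g_path$coords)
})

test_that("dead-end removal cuts short spurs only at junctions", {
  g <- spur_graph(chain_n = 9, spur_n = 2, at = 5)
  gr <- remove_dead_ends(g)
  expect_equal(nrow(gr$coords), 9L)     # 2-node spur removed
  g3 <- spur_graph(chain_n = 9, spur_n = 3, at = 5)
  expect_equal(nrow(remove_dead_ends(g3)$coords), 12L)  # depth 3 kept
  # terminal nodes of a simple path are never dead-ends
  p <- traces_to_graph(ca_trace(chain_coords(5)))
  expect_equal(nrow(remove_dead_ends(p)$coords), 5L)
})

test_that("all refinement passes are idempotent and never grow the graph", {
  m <- fixture_protein(seed = 31)
  fx <- fixture_maps(m)
  g0 <- traces_to_graph(trace_all(fx$maps))
  # inject a synthetic spur to give the passes something to do
  n0 <- nrow(g0$coords)
  g0$coords <- rbind(g0$coords, g0$coords[5, ] + c(0, 0, 3.0))
  g0$sse <- c(g0$sse, "loop")
  g0$edges <- rbind(g0$edges, c(5L, n0 + 1L))

  passes <- list(
    combine = function(g) combine_paths(g),
    side = function(g) remove_side_chains(g),
    loops = function(g) remove_loops(g, fx$pre),
    dead = function(g) remove_dead_ends(g))
  g <- g0
  for (nm in names(passes)) {
    g1 <- passes[[nm]](g)
    expect_lte(nrow(g1$coords), nrow(g$coords))
    g2 <- passes[[nm]](g1)
    expect_identical(g2$coords, g1$coords)
    expect_identical(g2$edges, g1$edges)
    g <- g1
  }
})

test_that("refinement restores the ground-truth topology on a clean run", {
  m <- fixture_protein(seed = 32)
  fx <- fixture_maps(m)
  g <- traces_to_graph(trace_all(fx$maps))
  n_before <- nrow(g$coords)
  # inject a depth-2 side-chain spur and a dead-end off the main chain
  g$coords <- rbind(g$coords,
                    g$coords[10, ] + c(0, 3.0, 0),
                    g$coords[10, ] + c(0, 6.0, 0),
                    g$coords[30, ] + c(3.0, 0, 0))
  g$sse <- c(g$sse, rep("loop", 3))
  g$edges <- rbind(g$edges,
                   c(10L, n_before + 1L), c(n_before + 1L, n_before + 2L),
                   c(30L, n_before + 3L))
  gr <- refine_graph(g, fx$pre)
  expect_equal(nrow(gr$coords), n_before)
  deg <- cryotrace:::tg_degree(gr)
  expect_true(all(deg <= 2))
})
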