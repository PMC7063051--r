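# confidence maps with splats at given CA positions (builds a CA-only
# model and uses the oracle generator)
splat_maps <- function(ca, extent = NULL, sse = NULL) {
  n <- nrow(ca)
  atoms <- data.frame(atom_name = "CA", element = "C", chain_id = "A",
                      residue_index = seq_len(n), residue_name = "ALA",
                      x = ca[, 1], y = ca[, 2], z = ca[, 3],
                      stringsAsFactors = FALSE)
  sse_df <- if (!is.null(sse)) {
    data.frame(chain_id = "A", residue_index = seq_len(n), sse = sse,
               stringsAsFactors = FALSE)
  }
  model <- atomic_model(atoms, sse_df)
  dm <- simulate_density(model, resolution = 3, voxel = 1, padding = 6)
  list(model = model, maps = oracle_confidence(model, dm))
}

test_that("seed selection honors confidence and the visited mask", {
  conf <- array(0, c(8, 8, 8))
  conf[3, 4, 5] <- 0.9
  conf[6, 2, 2] <- 0.8
  visited <- array(FALSE, dim(conf))
  expect_equal(select_seed(conf, visited), c(2, 3, 4))  # 0-origin world
  visited[3, 4, 5] <- TRUE
  expect_equal(select_seed(conf, visited), c(5, 1, 1))
  expect_null(select_seed(conf * 0.5, array(FALSE, dim(conf))))
})

test_that("step scoring follows the documented linear form", {
  ca <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0))
  sm <- splat_maps(ca)
  params <- walk_params()
  # independent scalar re-implementation of the score
  ref_score <- function(current, prev, cand) {
    maps <- sm$maps
    w2i <- function(p) (p - maps$origin) / maps$voxel + 1
    tri <- function(field, p) {
      cryotrace:::trilinear_at(maps[[field]], rbind(w2i(p)))
    }
    ca_c <- tri("calpha", cand)
    seg <- sapply(seq(0.1, 0.9, length.out = 9), function(f) {
      tri("backbone", current + f * (cand - current))
    })
    s <- params$w_conf * ca_c + params$w_bb * mean(seg) -
      params$w_dist * abs(sqrt(sum((cand - current)^2)) - 3.8) / 3.8
    if (!is.null(prev)) {
      v1 <- prev - current; v2 <- cand - current
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      s <- s - params$w_angle * max(0, cosang - cos(150 * pi / 180))
    }
    s
  }
  cur <- c(3.8, 0, 0)
  cand <- c(0.05, 0.05, 0)
  expect_equal(score_step(cur, c(7.6, 0, 0), cand, sm$maps, params),
               ref_score(cur, c(7.6, 0, 0), cand))
  expect_equal(score_step(cur, NULL, cand, sm$maps, params),
               ref_score(cur, NULL, cand))
  # low-confidence candidate is rejected
  expect_identical(score_step(cur, NULL, c(3.8, 4.0, 0), sm$maps, params),
                   -Inf)
})

test_that("equal-confidence candidates rank by distance to the ideal step", {
  # two candidates on the same splat ring: 3.8 A beats 4.1 A
  ca <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(-3.8, 0, 0))
  sm <- splat_maps(ca)
  s_ideal <- score_step(c(0, 0, 0), NULL, c(3.8, 0, 0), sm$maps)
  s_long <- score_step(c(0, 0, 0), NULL, c(-4.1, 0, 0), sm$maps)
  expect_gt(s_ideal, s_long)
})

test_that("walking recovers a collinear chain from either direction", {
  ca <- cbind(3.8 * (0:4), 0, 0)
  sm <- splat_maps(ca)
  tr <- walk_trace(c(7.6, 0, 0), sm$maps)  # seed mid-chain
  expect_s3_class(tr, "ca_trace")
  expect_equal(nrow(tr$xyz), 5L)
  # order matches the chain or its reverse
  xs <- tr$xyz[, 1]
  expect_true(all(diff(xs) > 0) || all(diff(xs) < 0))
  expect_lt(max(nearest_dist(tr$xyz, ca)), 0.5)
})

test_that("an isolated splat yields a single-point trace", {
  sm <- splat_maps(rbind(c(0, 0, 0)))
  tr <- walk_trace(c(0, 0, 0), sm$maps)
  expect_equal(nrow(tr$xyz), 1L)
  expect_error(walk_trace(c(50, 50, 50), sm$maps), NA)
})

test_that("trace_all separates disjoint chains and covers the protein", {
  ca1 <- cbind(3.8 * (0:4), 0, 0)
  ca2 <- cbind(3.8 * (0:3), 15, 0)
  sm <- splat_maps(rbind(ca1, ca2))
  traces <- trace_all(sm$maps)
  expect_length(traces, 2L)
  expect_setequal(vapply(traces, function(t) nrow(t$xyz), 0L), c(5L, 4L))

  # all-zero map -> no traces
  empty <- sm$maps
  empty$calpha[] <- 0
  expect_length(trace_all(empty), 0L)
})

test_that("walking a clean synthetic protein finds every CA", {
  m <- generate_synthetic_protein(
    list(c("helix", 10), c("loop", 5), c("strand", 7)), seed = 21)
  fx <- fixture_maps(m)
  traces <- trace_all(fx$maps)
  pts <- do.call(rbind, lapply(traces, function(t) t$xyz))
  nat <- ca_coords(m)
  expect_true(all(nearest_dist(nat, pts) < 3.0))
  # tabu exclusion: no two trace points closer than the exclusion radius
  d <- as.matrix(dist(pts))
  diag(d) <- Inf
  expect_gte(min(d), walk_params()$exclusion_radius - 0.3)
})

test_that("re-walking a traced region terminates immediately", {
  ca <- cbind(3.8 * (0:4), 0, 0)
  sm <- splat_maps(ca)
  state <- cryotrace:::walk_state(sm$maps, walk_params())
  cands <- cryotrace:::find_ca_candidates(sm$maps, walk_params())
  res <- cryotrace:::walk_trace_impl(ca[3, ], cands, sm$maps, state)
  expect_equal(nrow(res$trace$xyz), 5L)
  expect_error(walk_trace(ca[3, ], sm$maps, state = res$state),
               "already visited")
})
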