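test_that("node expansion interpolates linearly and hits nodes exactly", {
  # nodes at every index: identity
  v <- runif(11, 0, 1)
  expect_equal(expand_nodes(0:10, v, 10L), v)
  # two equal endpoint nodes: constant vector
  expect_equal(expand_nodes(c(0L, 10L), c(3, 3), 10L), rep(3, 11))
  # three nodes: hand-computed line segments
  w <- expand_nodes(c(0L, 4L, 10L), c(0, 8, 2), 10L)
  expect_equal(w[3], 4)        # midpoint of first segment
  expect_equal(w[8], 5)        # (8 + 2) / 2 at index 7
  expect_equal(w[c(1, 5, 11)], c(0, 8, 2))
  expect_error(expand_nodes(c(1L, 10L), c(1, 1), 10L), "endpoints")
  expect_error(expand_nodes(c(0L, 5L, 5L, 10L), c(1, 1, 1, 1), 10L),
               "increasing")
})

test_that("chi2 objective equals a brute-force double loop on small instances", {
  set.seed(42)
  for (rep in 1:5) {
    n_d <- 5L; n_b <- 10L
    lib <- structure(list(
      values = matrix(runif(n_d * n_b), n_d, n_b),
      energy_grid = energy_grid(n_b, 1, 0),
      depth_grid = structure(list(depths = 0:(n_d - 1), kind = "fine",
                                  dt = 1), class = "spe_depth_grid"),
      material = builtin_material("water"), beam = beam_spec(100)),
      class = "spe_spectra_library")
    tgt <- spe_spectrum(energy_grid(n_b, 1, 0), runif(n_b))
    win <- apply_window(tgt, 0, n_b)
    nodes <- c(0L, 2L, 4L)
    nv <- runif(3)
    got <- chi2_objective(nv, nodes, lib, tgt, win, i_max = 4L)
    w <- expand_nodes(nodes, nv, 4L)
    brute <- 0
    for (j in seq_len(n_b)) {
      acc <- 0
      for (i in seq_len(n_d)) acc <- acc + lib$values[i, j] * w[i]
      brute <- brute + (acc - tgt$values[j])^2
    }
    expect_equal(got, brute, tolerance = 1e-12)
  }
})

test_that("chi2 objective closed forms: perfect fit and all-zero weights", {
  br <- toy_broadened()
  i_max <- 150L
  nodes <- node_grid(i_max, 8L)
  nv <- seq(0.2, 1, length.out = length(nodes))
  w_true <- expand_nodes(nodes, nv, i_max)
  tgt <- reconstruct_spectrum(w_true, br)
  win <- apply_window(tgt, 10, 90)
  expect_equal(chi2_objective(nv, nodes, br, tgt, win, i_max), 0,
               tolerance = 1e-14)
  expect_equal(chi2_objective(rep(0, length(nodes)), nodes, br, tgt, win,
                              i_max),
               sum(tgt$values[win$bins]^2), tolerance = 1e-12)
})

test_that("reconstruction is the linear matrix-vector superposition", {
  br <- toy_broadened()
  n <- 30L
  # unit weight on depth 0 returns the entrance spectrum
  w <- c(1, rep(0, n - 1))
  expect_equal(reconstruct_spectrum(w, br)$values, br$values[1, ])
  # linearity
  set.seed(7)
  w2 <- runif(n)
  expect_equal(reconstruct_spectrum(5 * w2, br)$values,
               5 * reconstruct_spectrum(w2, br)$values, tolerance = 1e-12)
  # explicit summation on a small instance
  manual <- numeric(ncol(br$values))
  for (i in seq_len(n)) manual <- manual + br$values[i, ] * w2[i]
  expect_equal(reconstruct_spectrum(w2, br)$values, manual,
               tolerance = 1e-12)
})

test_that("optimizer recovers node-representable synthetic targets", {
  br <- toy_broadened()
  i_max <- 200L
  nodes <- node_grid(i_max, 10L)
  nv <- exp(-seq(0, 3, length.out = length(nodes)))
  w_true <- expand_nodes(nodes, nv, i_max)
  tgt <- reconstruct_spectrum(w_true, br)
  win <- apply_window(tgt, 10, 95)
  fit <- optimize_weights(br, tgt, win, i_max = i_max, n_nodes = 10L,
                          node_indices = nodes)
  rel_l2 <- sqrt(sum((fit$reconstructed$values[win$bins] -
                        tgt$values[win$bins])^2) /
                   sum(tgt$values[win$bins]^2))
  expect_lt(rel_l2, 1e-4)
  expect_equal(fit$chi2, 0, tolerance = 1e-10)
})

test_that("optimizer output is normalized, non-negative and improves on the start", {
  br <- toy_broadened()
  tgt <- parametric_spe(1, 18, br$energy_grid)
  win <- apply_window(tgt, 20, 90)
  fit <- optimize_weights(br, tgt, win, i_max = 200L, n_nodes = 12L)
  expect_equal(sum(fit$weights$w), 1, tolerance = 1e-12)
  expect_true(all(fit$weights$w >= 0))
  expect_lte(fit$chi2, fit$chi2_initial)
  # determinism
  fit2 <- optimize_weights(br, tgt, win, i_max = 200L, n_nodes = 12L)
  expect_identical(fit$weights$w, fit2$weights$w)
})

test_that("a single library spectrum as target concentrates the weight", {
  br <- toy_broadened()
  i_max <- 200L
  i_star <- 120L
  tgt <- spe_spectrum(br$energy_grid, br$values[i_star + 1L, ])
  win <- apply_window(tgt, 10, 95)
  fit <- optimize_weights(br, tgt, win, i_max = i_max, n_nodes = 16L,
                          node_indices = sort(unique(c(node_grid(i_max, 16L),
                                                       i_star))))
  w <- fit$weights$w
  near <- abs(fit$weights$i - i_star) <= 15
  expect_gt(sum(w[near]), 0.8)
})

test_that("energy-spaced nodes cover the depth span monotonically", {
  nodes <- node_grid(300L, 12L)
  expect_identical(nodes[1], 0L)
  expect_identical(nodes[length(nodes)], 300L)
  expect_true(all(diff(nodes) > 0))
})
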