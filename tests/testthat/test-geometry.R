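test_that("clipped-circle open area matches branch limits and pixel counting", {
  lam <- 5
  # continuity at r = lambda/2 from both branches
  a_lo <- radius_to_area(lam / 2 - 1e-10, lam)
  a_hi <- radius_to_area(lam / 2 + 1e-10, lam)
  expect_equal(a_lo, pi * (lam / 2)^2, tolerance = 1e-8)
  expect_equal(a_hi, a_lo, tolerance = 1e-8)
  # the open area fills the whole cell at r = lambda/sqrt(2)
  expect_equal(radius_to_area(lam / sqrt(2), lam), lam^2,
               tolerance = 1e-12)
  # strict monotonicity over the full branch
  r <- seq(0, lam / sqrt(2), length.out = 400)
  expect_true(all(diff(radius_to_area(r, lam)) > 0))
  # pixel-counting oracle at and around the clipped branch
  for (rr in c(0.3, 0.45, 0.55, 0.6, 0.67) * lam) {
    expect_equal(radius_to_area(rr, lam), pixel_area_oracle(rr, lam),
                 tolerance = 1e-5)
  }
  expect_error(radius_to_area(0.8 * lam, lam), "radius")
})

test_that("Newton inversion round-trips 100 random areas to 1e-10 lambda^2", {
  lam <- 5
  set.seed(11)
  a <- runif(100, 0, lam^2)
  r <- area_to_radius(a, lam)
  expect_lt(max(abs(radius_to_area(r, lam) - a)), 1e-10 * lam^2)
  expect_equal(area_to_radius(pi * lam^2 / 4, lam), lam / 2,
               tolerance = 1e-10)
  expect_equal(area_to_radius(lam^2, lam), lam / sqrt(2),
               tolerance = 1e-10)
  expect_error(area_to_radius(lam^2 * 1.01, lam), "open area")
})

test_that("layer areas telescope exactly to the cell area", {
  lam <- 5
  set.seed(3)
  w <- runif(300)
  w <- w / sum(w)
  st <- weights_to_layers(w, lam, dt = 0.1)
  expect_equal(sum(st$dA), lam^2, tolerance = 1e-12)
  expect_equal(st$dA, lam^2 * w, tolerance = 1e-12)
  expect_true(all(diff(st$A) <= 1e-12))        # A non-increasing
  expect_true(all(diff(st$r) >= -1e-12))       # r non-decreasing
  expect_equal(st$A[nrow(st)], lam^2 * w[length(w)], tolerance = 1e-12)
  expect_error(weights_to_layers(w * 2, lam, dt = 0.1), "normalized")
})

test_that("uniform weights produce the linear area profile", {
  N <- 50L
  st <- weights_to_layers(rep(1 / N, N), 5, dt = 0.5)
  expect_equal(st$A, 25 * (N - (0:(N - 1))) / N, tolerance = 1e-12)
  # all weight on w_0: a fully open cell above the first layer
  st0 <- weights_to_layers(c(1, rep(0, 9)), 5, dt = 0.5)
  expect_equal(st0$A[-1], rep(0, 9), tolerance = 1e-12)
})

test_that("hole clamp only widens, restores monotonicity, reports perturbation", {
  w <- c(1e-6, 1e-6, 0.3, 0.7 - 2e-6)
  st <- weights_to_layers(w, 5, dt = 0.5)
  expect_lt(2 * st$r[1], 0.1)
  cl <- clamp_hole(st, 0.1)
  expect_equal(cl$r[1], 0.05)
  expect_identical(attr(cl, "clamp_report")$hole_diameter_mm, 0.1)
  expect_true(all(cl$r >= st$r - 1e-15))
  expect_true(all(diff(cl$r) >= 0))
  expect_gt(attr(cl, "clamp_report")$open_area_added_mm2, 0)
  # an already-wide hole is untouched
  st2 <- weights_to_layers(c(0.4, 0.3, 0.3), 5, dt = 0.5)
  cl2 <- clamp_hole(st2, 0.1)
  expect_equal(cl2$r, st2$r)
  expect_identical(attr(cl2, "clamp_report")$layers_touched, 0L)
})
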