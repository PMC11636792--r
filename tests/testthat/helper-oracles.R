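# Independent oracles and shared fixtures for the test suite. Oracles never
# call the code path they check (beyond the closed-form stopping power they
# are meant to integrate independently).

# -- transport oracles -------------------------------------------------------

# residual energy by RK4 integration of dE/dt = -S(E) over depth
ode_residual_oracle <- function(material, e0, depth, n_steps = 4000L) {
  h <- depth / n_steps
  e <- e0
  f <- function(en) -stopping_power(material, en)
  for (k in seq_len(n_steps)) {
    k1 <- f(e)
    k2 <- f(e + h / 2 * k1)
    k3 <- f(e + h / 2 * k2)
    k4 <- f(e + h * k3)
    e <- e + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  e
}

# CSDA range by fine composite-Simpson quadrature of 1/S from the 1 MeV
# cutoff (the sub-cutoff constant is the package's stated convention and is
# reproduced here from its definition, not from the implementation)
quad_range_oracle <- function(material, e0, h = 0.005) {
  n <- ceiling((e0 - 1) / h / 2) * 2
  e <- seq(1, e0, length.out = n + 1)
  f <- 1 / stopping_power(material, e)
  w <- c(1, rep(c(4, 2), length.out = n - 1), 1)
  simp <- sum(w * f) * (e[2] - e[1]) / 3
  simp + 1 / (1.77 * stopping_power(material, 1))
}

# Bohr range-straggling variance by direct quadrature over energy
quad_straggling_oracle <- function(material, e0, depth, h = 0.002) {
  e_res <- ode_residual_oracle(material, e0, depth)
  n <- ceiling((e0 - e_res) / h / 2) * 2
  e <- seq(e_res, e0, length.out = n + 1)
  s <- stopping_power(material, e)
  gam <- 1 + e / 938.27209
  b2 <- 1 - 1 / gam^2
  k <- 0.307075 * 0.51099895 * material$z_over_a * (1 - b2 / 2) / (1 - b2)
  f <- k / s^3
  w <- c(1, rep(c(4, 2), length.out = n - 1), 1)
  sqrt(sum(w * f) * (e[2] - e[1]) / 3)
}

# -- geometry oracle ---------------------------------------------------------

# circle-clipped-to-square area by exact pixel-centre counting on an n x n
# grid over the cell (per-row closed-form count, so n = 4000 is cheap)
pixel_area_oracle <- function(r, lambda, n = 4000L) {
  h <- lambda / n
  yc <- (seq_len(n) - 0.5) * h - lambda / 2
  xh <- pmin(sqrt(pmax(r^2 - yc^2, 0)), lambda / 2)
  counts <- pmin(2 * floor(xh / h + 0.5), n)
  sum(counts) * h^2
}

# -- ripple oracle -----------------------------------------------------------

# fundamental attenuation of a 50%-duty square wave under periodic Gaussian
# convolution, measured as the ratio of Fourier amplitudes at 1/lambda
squarewave_ripple_oracle <- function(fwhm, lambda, n = 512L) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  h <- lambda / n
  x <- (0:(n - 1L)) * h
  sq <- as.numeric((x %% lambda) < lambda / 2)
  half <- ceiling(8 * sigma / h)
  m <- -half:half
  k <- exp(-(m * h)^2 / (2 * sigma^2))
  k <- k / sum(k)
  idx <- (outer(0:(n - 1L), m, "+") %% n) + 1L
  y <- as.numeric(matrix(sq[idx], nrow = n) %*% k)
  amp <- function(v) sqrt(sum(v * cos(2 * pi * x / lambda))^2 +
                            sum(v * sin(2 * pi * x / lambda))^2)
  amp(y) / amp(sq)
}

# -- shared fixtures (built once per test run) -------------------------------

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# small water library (fast; used by foam/optimizer unit tests)
toy_library <- function(tail = 0, n_coarse = 30L, i_fine = 240L) {
  mat <- builtin_material("water")
  beam <- beam_spec(100, 0.01)
  tpk <- csda_range(mat, 100)
  lib <- generate_spectra_library(
    mat, beam, coarse_depth_grid(tpk, n_coarse), energy_grid(120L, 1, 0),
    nuclear_params(tail_fraction = tail))
  interpolate_library(lib, fine_depth_grid(tpk, i_fine))
}

toy_broadened <- function() {
  fixture("toy_broadened", function() {
    lib <- toy_library()
    mat <- builtin_material("water")
    broaden_library(lib, convert_foam(foam_spec(5, 300, 12), mat,
                                      beam_spec(100, 0.01)))
  })
}

# the full design-scale broadened library and fit (shared by acceptance
# and pipeline tests)
full_broadened <- function() {
  fixture("full_broadened", function() {
    mat <- builtin_material("steel")
    beam <- beam_spec()
    lib <- generate_spectra_library(mat, beam, coarse_depth_grid(42.7),
                                    energy_grid(), nuclear_params())
    lib <- interpolate_library(lib, fine_depth_grid(42.7))
    broaden_library(lib, convert_foam(foam_preset("design_ln300"), mat,
                                      beam))
  })
}

full_fit <- function() {
  fixture("full_fit", function() {
    tgt <- spe1972_like()
    optimize_weights(full_broadened(), tgt, apply_window(tgt))
  })
}

# 12-triangle unit cube mesh (for STL round-trip checks)
cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = c(0, 1), y = c(0, 1), z = c(0, 1)))
  tri <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0, outward -z
    c(5, 6, 7), c(6, 8, 7),   # z = 1, outward +z
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = 1
  structure(list(vertices = v, triangles = tri), class = "spe_mesh")
}
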