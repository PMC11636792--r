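test_that("range sigma is the square root of Pmod times areal density", {
  expect_equal(range_sigma(50.4, 5760), 538.8, tolerance = 1e-4)
  expect_identical(range_sigma(0, 4000), 0)
  s <- range_sigma(35, 4000)
  expect_equal(s^2, 35 * 4000, tolerance = 1e-12)
  expect_error(range_sigma(-1, 10), "non-negative")
})

test_that("foam presets carry the design and experiment parameters", {
  d <- foam_preset("design_ln300")
  expect_equal(d$weq_mg_cm2, 4000)
  expect_equal(d$pmod_water_mg_cm2, 35)
  e <- foam_preset("experiment_ln300")
  expect_equal(e$density_g_cm3, 0.288, tolerance = 1e-12)
})

test_that("foam conversion scales by the range-equivalence factor", {
  beam <- beam_spec(220)
  fe <- convert_foam(foam_preset("design_ln300"), builtin_material("iron"),
                     beam)
  expect_equal(fe$tm_mg_cm2 / 4000, 5760 / 4000, tolerance = 0.04)
  # areal density and Pmod scale by the same factor
  expect_equal(fe$tm_mg_cm2 / fe$weq_mg_cm2,
               fe$pmod_material_mg_cm2 / fe$pmod_water_mg_cm2,
               tolerance = 1e-12)
  expect_equal(fe$sigma_mg_cm2,
               sqrt(fe$pmod_material_mg_cm2 * fe$tm_mg_cm2),
               tolerance = 1e-12)
  # converting to water is the identity
  fw <- convert_foam(foam_preset("design_ln300"),
                     builtin_material("water"), beam)
  expect_equal(fw$tm_mg_cm2, 4000)
  expect_equal(fw$pmod_material_mg_cm2, 35)
})

test_that("broadening kernel sums to one for every output depth", {
  # a library that is constant in depth must be invariant under the
  # broadening, which holds iff every kernel row has unit sum
  lib <- toy_library(tail = 0, n_coarse = 5L, i_fine = 120L)
  lib$values <- matrix(1, nrow = nrow(lib$values), ncol = ncol(lib$values))
  mat <- builtin_material("water")
  br <- broaden_library(lib, convert_foam(foam_spec(5, 300, 12), mat,
                                          beam_spec(100, 0.01)))
  expect_equal(br$values,
               matrix(1, nrow(lib$values), ncol(lib$values)),
               tolerance = 1e-9)
})

test_that("the sigma -> 0 limit of broadening is a pure shift by tm", {
  lib <- toy_library(tail = 0, n_coarse = 30L, i_fine = 200L)
  dt <- lib$depth_grid$dt
  shift_bins <- 20L
  foam <- foam_spec(1, shift_bins * dt * 1000, 1e-9)  # tm = 20 dt, sigma ~ 0
  br <- suppressWarnings(broaden_library(lib, foam))
  n <- nrow(lib$values)
  src <- pmin(seq_len(n) + shift_bins, n)
  expect_equal(br$values, lib$values[src, ], tolerance = 1e-9)
})

test_that("broadening is linear in the library values", {
  br1 <- toy_broadened()
  lib <- toy_library()
  mat <- builtin_material("water")
  foam <- convert_foam(foam_spec(5, 300, 12), mat, beam_spec(100, 0.01))
  lib3 <- lib
  lib3$values <- 3 * lib3$values
  br3 <- broaden_library(lib3, foam)
  expect_equal(br3$values, 3 * br1$values, tolerance = 1e-12)
})

test_that("the broadened entrance spectrum is wider and shifted down", {
  br <- toy_broadened()
  lib <- toy_library()
  ec <- bin_centers(lib$energy_grid)
  m0 <- sum(lib$values[1, ] * ec) / sum(lib$values[1, ])
  mb <- sum(br$values[1, ] * ec) / sum(br$values[1, ])
  sd0 <- sqrt(sum(lib$values[1, ] * (ec - m0)^2) / sum(lib$values[1, ]))
  sdb <- sqrt(sum(br$values[1, ] * (ec - mb)^2) / sum(br$values[1, ]))
  expect_gt(sdb, sd0)          # broader
  expect_lt(mb, m0)            # foam only removes energy
  expect_lte(ec[which.max(br$values[1, ])], 100)
})

test_that("foam energy sigma has the closed composition form", {
  foam <- foam_preset("design_ln300")
  water <- builtin_material("water")
  e_res <- residual_energy(water, 220, 4)
  expect_equal(foam_energy_sigma(foam, beam_spec(220)),
               sqrt(35 * 4000) / 1000 * stopping_power(water, e_res),
               tolerance = 1e-12)
})
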