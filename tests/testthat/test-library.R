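test_that("entrance spectrum is a narrow peak at the beam energy", {
  mat <- builtin_material("iron")
  lib <- generate_spectra_library(mat, beam_spec(220, 0.001),
                                  coarse_depth_grid(42.7, 5L),
                                  energy_grid())
  sp0 <- lib$values[1, ]
  ec <- bin_centers(lib$energy_grid)
  expect_equal(ec[which.max(sp0)], 220.25, tolerance = 0.01)
  # 0.1% FWHM: everything within +/- 1 MeV of the beam energy
  expect_equal(sum(sp0[abs(ec - 220) > 1]), 0, tolerance = 1e-12)
  expect_equal(sum(sp0) * 0.5, 1, tolerance = 1e-9)  # unit fluence
})

test_that("depths beyond the primary range hold at most the tail residue", {
  mat <- builtin_material("iron")
  grid <- coarse_depth_grid(42.7, 77L)
  r0 <- csda_range(mat, 220)
  lib <- generate_spectra_library(mat, beam_spec(), grid, energy_grid(),
                                  nuclear_params(tail_fraction = 0))
  beyond <- grid$depths > r0
  expect_true(any(beyond))
  expect_true(all(lib$values[beyond, ] == 0))
  # with the tail enabled, no fluence may appear above 40 MeV beyond range
  lib2 <- generate_spectra_library(mat, beam_spec(), grid, energy_grid(),
                                   nuclear_params(tail_fraction = 0.5))
  ec <- bin_centers(lib2$energy_grid)
  expect_true(all(lib2$values[beyond, ec > 40] == 0))
})

test_that("total fluence follows the exponential primary attenuation", {
  mat <- builtin_material("iron")
  lam <- 132
  grid <- coarse_depth_grid(42.7, 31L)
  lib <- generate_spectra_library(
    mat, beam_spec(), grid, energy_grid(),
    nuclear_params(attenuation_length = lam, tail_fraction = 0))
  # restrict to depths whose peak is far from the spectrum edges
  use <- grid$depths < 0.9 * csda_range(mat, 220)
  tot <- rowSums(lib$values[use, ]) * lib$energy_grid$bin_width
  expect_equal(tot, exp(-grid$depths[use] / lam), tolerance = 1e-6)
})

test_that("per-depth integral is non-increasing with depth (tail off)", {
  lib <- toy_library(tail = 0)
  tot <- rowSums(lib$values)
  expect_true(all(diff(tot) <= 1e-12))
  expect_true(all(lib$values >= 0))
})

test_that("depth interpolation is exact at coarse nodes and linear between", {
  mat <- builtin_material("iron")
  coarse <- coarse_depth_grid(42.7, 77L)
  lib <- generate_spectra_library(mat, beam_spec(), coarse, energy_grid())
  fine <- fine_depth_grid(42.7, 2400L)
  expect_equal(fine$dt, 0.02135, tolerance = 1e-12)
  libf <- interpolate_library(lib, fine)
  # identity where fine depths hit coarse depths (depth 0 always does)
  expect_equal(libf$values[1, ], lib$values[1, ])
  # interpolating onto the coarse grid itself is the identity
  libc <- interpolate_library(lib, structure(
    list(depths = coarse$depths, kind = "coarse", dt = NA_real_),
    class = "spe_depth_grid"))
  expect_equal(libc$values, lib$values)
  # midpoints are arithmetic means of the neighbours
  mid <- structure(list(
    depths = (coarse$depths[-1] + coarse$depths[-77]) / 2,
    kind = "coarse", dt = NA_real_), class = "spe_depth_grid")
  libm <- interpolate_library(lib, mid)
  expect_equal(libm$values, (lib$values[-1, ] + lib$values[-77, ]) / 2,
               tolerance = 1e-12)
  expect_error(interpolate_library(lib, fine_depth_grid(50, 100L)),
               "extrapolation")
})

test_that("library TSV round-trips and rejects malformed input", {
  lib <- toy_library(tail = 0.3, n_coarse = 7L, i_fine = 20L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectra_library(lib, path)
  back <- read_spectra_library(path)
  expect_equal(back$values, lib$values, tolerance = 1e-14)
  expect_equal(back$depth_grid$depths, lib$depth_grid$depths)
  expect_equal(back$energy_grid$bin_width, lib$energy_grid$bin_width)
  expect_equal(back$material$name, "water")

  # a negative fluence must be refused with the offending line named
  lines <- readLines(path)
  bad <- sub("\t[0-9.eE+-]+$", "\t-1", lines[5])
  bad_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(lines[1:4], bad, lines[6:length(lines)]), bad_path)
  expect_error(read_spectra_library(bad_path), "line 5.*negative")

  # non-monotone depths
  bad2 <- lines
  bad2[2] <- paste(rev(strsplit(lines[2], "\t")[[1]]), collapse = "\t")
  bad2_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(bad2, bad2_path)
  expect_error(read_spectra_library(bad2_path), "increasing")
})

test_that("a 77-column library file yields a 77-depth grid", {
  mat <- builtin_material("iron")
  lib <- generate_spectra_library(mat, beam_spec(),
                                  coarse_depth_grid(42.7, 77L),
                                  energy_grid(40L, 6, 0))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectra_library(lib, path)
  expect_length(read_spectra_library(path)$depth_grid$depths, 77L)
})
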