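test_that("a table given exactly on bin centres is copied", {
  eg <- energy_grid(50L, 2, 0)
  ec <- bin_centers(eg)
  vals <- exp(-ec / 30)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# energy fluence", sprintf("%.10g\t%.10g", ec, vals)), path)
  sp <- load_target(path, eg)
  expect_equal(sp$values, vals, tolerance = 1e-9)
})

test_that("log-linear resampling reproduces an exponential to < 0.1%", {
  eg <- energy_grid(200L, 1, 0)
  e_tab <- seq(5, 195, by = 10)          # coarse tabulation, off-centre
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(sprintf("%.10g\t%.10g", e_tab, 7 * exp(-e_tab / 22)), path)
  sp <- load_target(path, eg)
  ec <- bin_centers(eg)
  inside <- ec >= 5 & ec <= 195
  expect_equal(sp$values[inside], 7 * exp(-ec[inside] / 22),
               tolerance = 1e-3)
  # bins outside the tabulated span are exactly zero
  expect_true(all(sp$values[!inside] == 0))
})

test_that("malformed target tables are refused", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("10\t1", "5\t2"), path)
  expect_error(load_target(path, energy_grid()), "increasing")
  writeLines(c("10\t1", "20\t-2"), path)
  expect_error(load_target(path, energy_grid()), "non-negative")
  writeLines("10\t1", path)
  expect_error(load_target(path, energy_grid()), "2 rows")
})

test_that("parametric spectrum has the exponential closed form", {
  eg <- energy_grid()
  sp <- parametric_spe(2, 30, eg)
  ratio <- sp$values[-1] / sp$values[-500]
  expect_equal(ratio, rep(exp(-0.5 / 30), 499), tolerance = 1e-12)
  sp2 <- parametric_spe(4, 30, eg)
  expect_equal(sp2$values, 2 * sp$values, tolerance = 1e-12)
})

test_that("the 1972-like fixture spans four decades over the window", {
  sp <- spe1972_like()
  ec <- bin_centers(sp$energy_grid)
  v40 <- sp$values[which.min(abs(ec - 40))]
  v200 <- sp$values[which.min(abs(ec - 200))]
  expect_equal(v40 / v200, 1e4, tolerance = 0.02)
})

test_that("write_target / load_target round-trips a generated spectrum", {
  sp <- spe1972_like()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_target(sp, path)
  back <- load_target(path, sp$energy_grid)
  expect_equal(back$values, sp$values, tolerance = 1e-9)
})

test_that("window indices follow j = E / bin_width", {
  w <- apply_window(spe1972_like(), 40, 203)
  expect_identical(w$j_lo, 80L)
  expect_identical(w$j_hi, 406L)
  expect_identical(bin_edges(energy_grid())[w$j_hi + 1L], 203)
  expect_identical(apply_window(spe1972_like(), 50, 203)$j_lo, 100L)
  full <- apply_window(spe1972_like(), 0, 250)
  expect_identical(full$j_lo, 0L)
  expect_identical(full$j_hi, 499L)
  # values inside the window are untouched
  expect_equal(w$spectrum$values, spe1972_like()$values)
  expect_error(apply_window(spe1972_like(), 40, 260), "outside")
})
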