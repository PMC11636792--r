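steel <- builtin_material("steel")

# a small but representative stack: smooth funnel entering the clipped
# branch, plus a clamped hole channel
demo_stack <- function(n = 120L) {
  i <- 0:(n - 1)
  w <- exp(-3 * i / n) * 0.02 + (i / n)^2
  w <- rev(w) / sum(w)
  clamp_hole(weights_to_layers(w, 5, dt = 36.4 / (n - 1)), 0.1)
}

test_that("cell mesh is watertight, 2-manifold and oriented outward", {
  cell <- build_cell(demo_stack(), steel, n_segments = 32L,
                     decimate_tol_mm = 0.01)
  wt <- mesh_is_watertight(cell$mesh)
  expect_true(wt$watertight)
  expect_identical(wt$boundary_edges, 0L)
  expect_identical(wt$nonmanifold_edges, 0L)
  expect_gt(mesh_volume(cell$mesh), 0)
  expect_equal(cell$height, 36.4 * 10 / 7.9, tolerance = 1e-12)
})

test_that("mesh volume matches the analytic open-area integral within 1%", {
  cell <- build_cell(demo_stack(), steel, n_segments = 64L,
                     decimate_tol_mm = 0.005)
  expect_equal(mesh_volume(cell$mesh), cell_volume_analytic(cell),
               tolerance = 0.01)
  # uniform weights give the half-filled cell in closed form
  N <- 200L
  stu <- clamp_hole(weights_to_layers(rep(1 / N, N), 5, dt = 36.4 / (N - 1)),
                    0.1)
  cellu <- build_cell(stu, steel, n_segments = 64L, decimate_tol_mm = 0.005)
  expect_equal(mesh_volume(cellu$mesh), 25 * cellu$height / 2,
               tolerance = 0.01)
})

test_that("a weight vector with only the top layer yields a solid block", {
  n <- 20L
  w <- c(rep(0, n - 1), 1)
  st <- clamp_hole(weights_to_layers(w, 5, dt = 36.4 / (n - 1)), 0.1)
  cell <- build_cell(st, steel, n_segments = 16L)
  # block minus the 100 um channel: essentially the full block volume
  expect_equal(mesh_volume(cell$mesh), 25 * cell$height,
               tolerance = 2e-3)
  expect_true(mesh_is_watertight(cell$mesh)$watertight)
})

test_that("array assembly tiles volume additively and stays manifold", {
  cell <- build_cell(demo_stack(60L), steel, n_segments = 16L,
                     decimate_tol_mm = 0.05)
  one <- assemble_array(cell, 1L)
  expect_equal(one$lateral_size_mm, 5)
  expect_equal(mesh_volume(one$mesh), mesh_volume(cell$mesh),
               tolerance = 1e-9)
  arr <- assemble_array(cell, 3L)
  expect_equal(arr$lateral_size_mm, 15)
  wt <- mesh_is_watertight(arr$mesh)
  expect_true(wt$watertight)
  expect_identical(wt$nonmanifold_edges, 0L)
  expect_equal(mesh_volume(arr$mesh), 9 * mesh_volume(cell$mesh),
               tolerance = 1e-3)
  expect_error(assemble_array(cell, 0L), ">= 1")
})

test_that("binary STL round-trips the mesh", {
  cell <- build_cell(demo_stack(40L), steel, n_segments = 16L,
                     decimate_tol_mm = 0.05)
  path <- withr::local_tempfile(fileext = ".stl")
  write_stl(cell$mesh, path)
  back <- read_stl(path)
  expect_identical(nrow(back$triangles), nrow(cell$mesh$triangles))
  # volume recomputed from the file agrees within float32 precision
  expect_equal(mesh_volume(back), mesh_volume(cell$mesh),
               tolerance = 1e-5)
  # vertex sets match within float32 rounding
  expect_equal(sort(back$vertices[, 1]),
               sort(cell$mesh$vertices[, 1]), tolerance = 1e-6)
})

test_that("a unit cube writes 12 triangles in binary and ASCII", {
  cube <- cube_mesh()
  expect_true(mesh_is_watertight(cube)$watertight)
  expect_equal(mesh_volume(cube), 1, tolerance = 1e-12)
  pb <- withr::local_tempfile(fileext = ".stl")
  write_stl(cube, pb)
  expect_identical(nrow(read_stl(pb)$triangles), 12L)
  expect_identical(file.info(pb)$size, 84 + 50 * 12)
  pa <- withr::local_tempfile(fileext = ".stl")
  write_stl(cube, pa, ascii = TRUE)
  back <- read_stl(pa)
  expect_identical(nrow(back$triangles), 12L)
  expect_equal(mesh_volume(back), 1, tolerance = 1e-9)
})

test_that("open meshes are refused with diagnostics", {
  cube <- cube_mesh()
  cube$triangles <- cube$triangles[-1, ]
  path <- withr::local_tempfile(fileext = ".stl")
  expect_error(write_stl(cube, path), "open mesh: 3 boundary")
})
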