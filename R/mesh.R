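# Triangle-mesh generation for the modulator solid and binary STL export.
#
# The material solid of one cell is the lambda x lambda x H block minus the
# funnel of revolution (clipped to the cell). Because the funnel radius
# profile r(z) is monotone, the whole beam-facing boundary is a continuous
# height field over the cell cross-section: at lateral radius s the
# material column starts at z = r^-1(s) (0 outside the entry radius, H at
# the hole). The mesh therefore consists of a single "terrain" sheet
# (funnel wall + flat entry face), the exit face (square minus hole disc),
# and the outer side walls whose top edges follow the terrain rim; clipped
# funnel stations collapse onto the cell border, which keeps the sheet
# crack-free. Arrays are meshed as one periodic terrain, so interior cell
# walls never exist and the result stays 2-manifold.

# square-boundary radius at angle theta for a cell of period lambda
.square_radius <- function(theta, lambda) {
  (lambda / 2) / pmax(abs(cos(theta)), abs(sin(theta)))
}

# Decimate a monotone (z, r) profile: drop points whose radius differs from
# the last kept one by less than tol (endpoints always kept).
.decimate_profile <- function(z, r, tol) {
  n <- length(r)
  if (n <= 2L) return(list(z = z, r = r))
  keep <- logical(n)
  keep[1L] <- keep[n] <- TRUE
  last <- r[1L]
  for (k in 2:(n - 1L)) {
    if (abs(r[k] - last) >= tol) {
      keep[k] <- TRUE
      last <- r[k]
    }
  }
  list(z = z[keep], r = r[keep])
}

# Collapse a clamped/monotone stack into the strictly increasing radius
# profile used for meshing: r ascending, z = column start height
# (plateaus keep their smallest z, i.e. the earliest material start).
.stack_profile <- function(stack, material) {
  h_scale <- 10 / material$density            # g/cm^2 -> mm
  H <- stack$t[nrow(stack)] * h_scale
  z <- H - stack$t * h_scale                  # z = 0 at beam entry
  r <- stack$r
  ord <- order(r, -z)                         # r ascending; ties: min z last
  r <- r[ord]; z <- z[ord]
  keep <- !duplicated(r, fromLast = TRUE)     # per radius keep min z
  r <- r[keep]; z <- cummin(z[keep])          # enforce monotone descent
  list(z = z, r = r, height = H)
}

# Height-field lookup z_tau(s): H at/below the hole radius, 0 at/above the
# entry radius, monotone interpolation in between.
.profile_zfun <- function(prof) {
  r <- prof$r; z <- prof$z
  if (length(r) == 1L)
    return(function(s) ifelse(s < r[1L], prof$height, z[1L]))
  f <- stats::approxfun(r, z, rule = 2)
  function(s) f(s)
}

# Build the terrain + bottom + per-face wall patches of a single cell,
# centred at the origin. Returns vertex matrix and triangle lists.
.cell_patches <- function(prof, lambda, n_segments) {
  if (n_segments %% 8L != 0L)
    stop("n_segments must be a multiple of 8")
  M <- n_segments
  theta <- 2 * pi * (0:(M - 1L)) / M
  ct <- cos(theta); st <- sin(theta)
  sq <- .square_radius(theta, lambda)
  zfun <- .profile_zfun(prof)
  H <- prof$height
  rk <- prof$r                                 # ascending radial stations
  K <- length(rk)
  # station radii per angle: funnel stations clamped to the border, then
  # the border itself
  rho <- pmin(matrix(rk, nrow = M, ncol = K, byrow = TRUE), sq)  # M x K
  rho <- cbind(rho, sq)                       # + boundary station
  zz <- matrix(zfun(as.vector(rho)), nrow = M)
  zz[, K + 1L][sq >= rk[K]] <- 0              # flat entry outside funnel
  nst <- K + 1L
  verts <- cbind(as.vector(rho * ct), as.vector(rho * st), as.vector(zz))
  id <- function(m, k) (k - 1L) * M + m        # column-major station rings
  tris <- vector("list", 4L)
  mm <- 1:M; mp <- c(2:M, 1L)
  # terrain quads between consecutive stations (winding chosen so the
  # outward normal of the flat entry region points to -z)
  t1 <- t2 <- vector("list", nst - 1L)
  for (k in seq_len(nst - 1L)) {
    qa <- id(mm, k); qb <- id(mp, k)
    qc <- id(mp, k + 1L); qd <- id(mm, k + 1L)
    t1[[k]] <- cbind(qa, qb, qc)
    t2[[k]] <- cbind(qa, qc, qd)
  }
  terrain <- rbind(do.call(rbind, t1), do.call(rbind, t2))
  # exit face at z = H: square minus hole disc (outward +z), plus the
  # aperture tube wall from the terrain rim down to the exit plane (the
  # clamped 100 um channel; degenerates harmlessly when the rim already
  # sits at z = H)
  nb <- nrow(verts)
  verts <- rbind(verts, cbind(sq * ct, sq * st, rep(H, M)),
                 cbind(rk[1L] * ct, rk[1L] * st, rep(H, M)))
  bid <- nb + (1:M)
  hid <- nb + M + (1:M)
  rim <- id(mm, 1L); rimp <- id(mp, 1L)
  tube <- rbind(cbind(rim, hid[mm], hid[mp]),
                cbind(rim, hid[mp], rimp))
  bottom <- rbind(tube,
                  cbind(hid[mp], hid[mm], bid[mm]),
                  cbind(hid[mp], bid[mm], bid[mp]))
  # side walls per face (outward away from the axis), split by angle
  topid <- id(mm, nst)
  face_of <- (floor((theta + pi / 4) / (pi / 2)) %% 4L) + 1L  # sector faces
  walls <- vector("list", 4L)
  wa <- topid[mm]; wb <- topid[mp]; wc <- bid[mp]; wd <- bid[mm]
  wtri <- rbind(cbind(wa, wc, wd), cbind(wa, wb, wc))
  sector_face <- c(face_of, face_of)           # one entry per wall quad tri
  for (f in 1:4) walls[[f]] <- wtri[sector_face == f, , drop = FALSE]
  list(verts = verts, terrain = terrain, bottom = bottom, walls = walls,
       height = H)
}

# Deduplicate vertices (rounded to `digits` decimals in mm) and drop
# degenerate triangles.
.finalize_mesh <- function(verts, tris, digits = 7L) {
  key <- paste(round(verts[, 1L], digits), round(verts[, 2L], digits),
               round(verts[, 3L], digits), sep = "|")
  map <- match(key, key[!duplicated(key)])
  verts <- verts[!duplicated(key), , drop = FALSE]
  tris <- matrix(map[tris], ncol = 3L)
  keep <- tris[, 1L] != tris[, 2L] & tris[, 2L] != tris[, 3L] &
    tris[, 1L] != tris[, 3L]
  tris <- tris[keep, , drop = FALSE]
  structure(list(vertices = verts, triangles = tris), class = "spe_mesh")
}

#' @export
print.spe_mesh <- function(x, ...) {
  cat(sprintf("<spe_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

#' Build the solid mesh of a single modulator cell
#'
#' Converts a (clamped) layer stack into a watertight triangle mesh of the
#' cell solid. Layer depths are scaled to heights by the material density;
#' the stepped stack is replaced by its monotone piecewise-linear radius
#' profile (the smooth-gradient funnel), decimated by merging consecutive
#' radii closer than `decimate_tol_mm`. The wide funnel opening faces the
#' beam (z = 0); the hole sits in the exit face (z = H).
#'
#' @param stack A clamped `spe_layer_stack` (see [clamp_hole()]).
#' @param material Modulator [spe_material()] (density sets the height).
#' @param n_segments Angular facets of the funnel (multiple of 8).
#' @param decimate_tol_mm Radius decimation tolerance in mm; the default
#'   0.02 mm matches the resolution of metal 3D printing.
#' @return An object of class `spe_cell`: the profile, cell `height` in
#'   mm, `lambda`, the `mesh` (`spe_mesh`) and the meshing parameters.
#' @export
build_cell <- function(stack, material = builtin_material("steel"),
                       n_segments = 64L, decimate_tol_mm = 0.02) {
  stopifnot(inherits(stack, "spe_layer_stack"), is_spe_material(material))
  lambda <- attr(stack, "lambda")
  if (any(diff(stack$r) < -1e-12))
    stop("layer radii must be monotone non-decreasing (run clamp_hole)")
  if (max(stack$r) > lambda / sqrt(2) + 1e-9)
    stop("radius exceeds lambda/sqrt(2)")
  prof <- .stack_profile(stack, material)
  dec <- .decimate_profile(prof$z, prof$r, decimate_tol_mm)
  prof$z <- dec$z; prof$r <- dec$r
  p <- .cell_patches(prof, lambda, as.integer(n_segments))
  mesh <- .finalize_mesh(p$verts,
                         rbind(p$terrain, p$bottom, do.call(rbind, p$walls)))
  structure(list(profile = prof, lambda = lambda, height = p$height,
                 material = material, mesh = mesh,
                 n_segments = as.integer(n_segments),
                 decimate_tol_mm = decimate_tol_mm),
            class = "spe_cell")
}

#' @export
print.spe_cell <- function(x, ...) {
  cat(sprintf(
    "<spe_cell> lambda = %g mm, height = %.3f mm, %d profile points\n",
    x$lambda, x$height, length(x$profile$r)))
  print(x$mesh)
  invisible(x)
}

#' Tile a cell into the periodic modulator array
#'
#' Lays out `n x n` copies of the cell terrain and exit face on a shared
#' vertex grid (interior cell walls are never generated, so coincident
#' walls need no merging) and closes the solid with the outer perimeter
#' walls. Lateral size is `n * lambda`.
#'
#' @param cell An `spe_cell` from [build_cell()].
#' @param n Cells per side (>= 1).
#' @return An object of class `spe_array` with the assembled `mesh`,
#'   `n_cells`, `lateral_size_mm` and `height_mm`.
#' @export
assemble_array <- function(cell, n = 8L) {
  stopifnot(inherits(cell, "spe_cell"))
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  p <- .cell_patches(cell$profile, cell$lambda, cell$n_segments)
  nv <- nrow(p$verts)
  offs <- (seq_len(n) - (n + 1) / 2) * cell$lambda
  verts_list <- vector("list", n * n)
  tris_list <- vector("list", n * n)
  idx <- 0L
  for (iy in seq_len(n)) {
    for (ix in seq_len(n)) {
      idx <- idx + 1L
      v <- p$verts
      v[, 1L] <- v[, 1L] + offs[ix]
      v[, 2L] <- v[, 2L] + offs[iy]
      tr <- rbind(p$terrain, p$bottom)
      # outer walls only: face order is +x, +y, -x, -y
      if (ix == n) tr <- rbind(tr, p$walls[[1L]])
      if (iy == n) tr <- rbind(tr, p$walls[[2L]])
      if (ix == 1L) tr <- rbind(tr, p$walls[[3L]])
      if (iy == 1L) tr <- rbind(tr, p$walls[[4L]])
      verts_list[[idx]] <- v
      tris_list[[idx]] <- tr + (idx - 1L) * nv
    }
  }
  mesh <- .finalize_mesh(do.call(rbind, verts_list),
                         do.call(rbind, tris_list))
  structure(list(mesh = mesh, n_cells = n,
                 lateral_size_mm = n * cell$lambda,
                 height_mm = cell$height, cell = cell),
            class = "spe_array")
}

#' @export
print.spe_array <- function(x, ...) {
  cat(sprintf("<spe_array> %d x %d cells, %g x %g mm^2, height %.3f mm\n",
              x$n_cells, x$n_cells, x$lateral_size_mm, x$lateral_size_mm,
              x$height_mm))
  print(x$mesh)
  invisible(x)
}

#' Signed volume of a closed mesh
#'
#' Divergence-theorem volume (positive for outward-oriented surfaces).
#'
#' @param mesh An `spe_mesh` (or an object carrying one in `$mesh`).
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  if (!inherits(mesh, "spe_mesh")) mesh <- mesh$mesh
  v <- mesh$vertices; f <- mesh$triangles
  pa <- v[f[, 1L], , drop = FALSE]
  pb <- v[f[, 2L], , drop = FALSE]
  pc <- v[f[, 3L], , drop = FALSE]
  cx <- pb[, 2L] * pc[, 3L] - pb[, 3L] * pc[, 2L]
  cy <- pb[, 3L] * pc[, 1L] - pb[, 1L] * pc[, 3L]
  cz <- pb[, 1L] * pc[, 2L] - pb[, 2L] * pc[, 1L]
  sum(pa[, 1L] * cx + pa[, 2L] * cy + pa[, 3L] * cz) / 6
}

#' Watertightness / manifoldness diagnostics
#'
#' A closed, consistently oriented 2-manifold surface has every undirected
#' edge shared by exactly two triangles with opposite directions.
#'
#' @param mesh An `spe_mesh` (or an object carrying one in `$mesh`).
#' @return List: `watertight` (logical), `boundary_edges` (count of edges
#'   used once), `nonmanifold_edges` (count used more than twice).
#' @export
mesh_is_watertight <- function(mesh) {
  if (!inherits(mesh, "spe_mesh")) mesh <- mesh$mesh
  f <- mesh$triangles
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  cnt <- table(key)
  list(watertight = all(cnt == 2L),
       boundary_edges = sum(cnt == 1L),
       nonmanifold_edges = sum(cnt > 2L))
}

#' Analytic volume of the cell solid
#'
#' `lambda^2 H - integral of the open area over height`, evaluated by the
#' trapezoid rule on a refined profile. Used as the independent check of
#' the mesh volume (the meshed funnel is an inscribed polygon, so the mesh
#' volume exceeds this by at most the small polygonization deficit).
#'
#' @param cell An `spe_cell`.
#' @param n_z Number of height samples.
#' @return Volume in mm^3.
#' @export
cell_volume_analytic <- function(cell, n_z = 20000L) {
  prof <- cell$profile
  H <- cell$height
  z <- seq(0, H, length.out = n_z)
  rz <- stats::approx(rev(prof$z), rev(prof$r), xout = z, rule = 2)$y
  open_a <- radius_to_area(pmin(rz, cell$lambda / sqrt(2)), cell$lambda)
  cell$lambda^2 * H - sum((open_a[-1L] + open_a[-n_z]) / 2 * diff(z))
}

# per-triangle unit normals
.tri_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$triangles
  a <- v[f[, 1L], , drop = FALSE]
  u <- v[f[, 2L], , drop = FALSE] - a
  w <- v[f[, 3L], , drop = FALSE] - a
  nx <- u[, 2L] * w[, 3L] - u[, 3L] * w[, 2L]
  ny <- u[, 3L] * w[, 1L] - u[, 1L] * w[, 3L]
  nz <- u[, 1L] * w[, 2L] - u[, 2L] * w[, 1L]
  len <- sqrt(nx^2 + ny^2 + nz^2)
  len[len == 0] <- 1
  cbind(nx / len, ny / len, nz / len)
}

#' Write a mesh as an STL file
#'
#' Binary (default) or ASCII STL in mm units, little-endian, with the
#' standard 80-byte header. Open meshes are refused with the boundary edge
#' count unless `force = TRUE`.
#'
#' @param mesh An `spe_mesh` (or `spe_cell` / `spe_array`).
#' @param path Output path.
#' @param ascii Write ASCII STL instead of binary.
#' @param force Write even if the mesh is not watertight.
#' @return The path, invisibly.
#' @export
write_stl <- function(mesh, path, ascii = FALSE, force = FALSE) {
  if (!inherits(mesh, "spe_mesh")) mesh <- mesh$mesh
  if (!force) {
    wt <- mesh_is_watertight(mesh)
    if (!wt$watertight)
      stop(sprintf(
        "refusing to export an open mesh: %d boundary, %d non-manifold edges",
        wt$boundary_edges, wt$nonmanifold_edges))
  }
  nrm <- .tri_normals(mesh)
  f <- mesh$triangles
  v <- mesh$vertices
  ntri <- nrow(f)
  if (ascii) {
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines("solid spemod", con)
    block <- sprintf(
      paste0("facet normal %.9g %.9g %.9g\n outer loop\n",
             "  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n",
             "  vertex %.9g %.9g %.9g\n endloop\nendfacet"),
      nrm[, 1L], nrm[, 2L], nrm[, 3L],
      v[f[, 1L], 1L], v[f[, 1L], 2L], v[f[, 1L], 3L],
      v[f[, 2L], 1L], v[f[, 2L], 2L], v[f[, 2L], 3L],
      v[f[, 3L], 1L], v[f[, 3L], 2L], v[f[, 3L], 3L])
    writeLines(block, con)
    writeLines("endsolid spemod", con)
    return(invisible(path))
  }
  # 12 float32 per triangle (normal + 3 vertices), then a zero uint16
  dat <- rbind(t(nrm), t(v[f[, 1L], , drop = FALSE]),
               t(v[f[, 2L], , drop = FALSE]),
               t(v[f[, 3L], , drop = FALSE]))  # 12 x ntri, column = triangle
  raw_f <- writeBin(as.numeric(dat), raw(), size = 4L, endian = "little")
  raw_m <- matrix(raw_f, nrow = 48L)
  payload <- rbind(raw_m, matrix(as.raw(0L), nrow = 2L, ncol = ntri))
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- charToRaw(sprintf("%-80s", "spemod binary STL (mm)"))[1:80]
  writeBin(hdr, con)
  writeBin(as.integer(ntri), con, size = 4L, endian = "little")
  writeBin(as.vector(payload), con)
  invisible(path)
}

#' Read an STL file
#'
#' Binary or ASCII autodetected; vertices are deduplicated exactly.
#'
#' @param path STL path.
#' @return An `spe_mesh`.
#' @export
read_stl <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, open = "rb")
  head_raw <- readBin(con, raw(), n = min(84L, sz))
  is_binary <- FALSE
  if (sz >= 84L) {
    ntri <- readBin(head_raw[81:84], integer(), size = 4L,
                    endian = "little")
    if (!is.na(ntri) && sz == 84 + 50 * as.numeric(ntri)) is_binary <- TRUE
  }
  if (is_binary) {
    body <- readBin(con, raw(), n = sz - 84L)
    close(con)
    m <- matrix(body, nrow = 50L)
    fl <- readBin(as.vector(m[1:48, , drop = FALSE]), numeric(),
                  n = 12L * ntri, size = 4L, endian = "little")
    tri <- matrix(fl, nrow = 12L)
    vall <- rbind(t(tri[4:6, , drop = FALSE]), t(tri[7:9, , drop = FALSE]),
                  t(tri[10:12, , drop = FALSE]))
    ord <- as.vector(t(matrix(seq_len(3L * ntri), ncol = 3L)))
    vall <- vall[ord, , drop = FALSE]  # interleave v1,v2,v3 per triangle
  } else {
    close(con)
    lines <- readLines(path)
    vx <- grep("^\\s*vertex", lines, value = TRUE)
    vall <- do.call(rbind, lapply(strsplit(trimws(vx), "\\s+"), function(p)
      as.numeric(p[2:4])))
    if (nrow(vall) %% 3L != 0L) stop("malformed ASCII STL")
    ntri <- nrow(vall) / 3L
  }
  key <- paste(vall[, 1L], vall[, 2L], vall[, 3L])
  map <- match(key, key[!duplicated(key)])
  verts <- vall[!duplicated(key), , drop = FALSE]
  tris <- matrix(map, ncol = 3L, byrow = TRUE)
  structure(list(vertices = verts, triangles = tris), class = "spe_mesh")
}
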