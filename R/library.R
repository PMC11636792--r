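# Depth-indexed proton energy-spectra library: analytic generation (Gaussian
# primary peak + parametric nuclear attenuation and secondary tail), depth
# interpolation, and TSV import/export for externally computed libraries.

#' Primary beam definition
#'
#' @param kinetic_energy Kinetic energy in MeV (> 0).
#' @param energy_spread_fwhm_rel Relative FWHM of the initial energy
#'   distribution (Delta E / E); the design beam uses 0.1%.
#' @return An object of class `spe_beam`.
#' @export
#' @examples
#' beam_spec(220, 0.001)
beam_spec <- function(kinetic_energy = 220, energy_spread_fwhm_rel = 0.001) {
  stopifnot(kinetic_energy > 0, energy_spread_fwhm_rel >= 0)
  structure(list(kinetic_energy = kinetic_energy,
                 energy_spread_fwhm_rel = energy_spread_fwhm_rel),
            class = "spe_beam")
}

#' Nuclear-interaction parameters of the analytic library generator
#'
#' The generator removes primaries exponentially with depth
#' (`exp(-t / attenuation_length)`) and re-deposits a configurable fraction
#' of the removed protons as a flat low-energy secondary tail between 0 and
#' the local residual energy. Defaults: the hadronic interaction lengths of
#' the two design materials (iron/steel 132 g/cm^2, water 85 g/cm^2) and a
#' secondary-proton yield of 0.5 per removed primary.
#'
#' @param attenuation_length Primary attenuation length in g/cm^2, or `NULL`
#'   to pick the per-material default.
#' @param tail_fraction Fraction of removed primaries carried by the
#'   low-energy tail (0 disables the tail).
#' @return A list with the two parameters.
#' @export
nuclear_params <- function(attenuation_length = NULL, tail_fraction = 0.5) {
  stopifnot(is.null(attenuation_length) || attenuation_length > 0,
            tail_fraction >= 0, tail_fraction <= 1)
  list(attenuation_length = attenuation_length,
       tail_fraction = tail_fraction)
}

.default_attenuation_length <- function(material) {
  switch(material$name, iron = 132, steel = 132, water = 85, 100)
}

.fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Generate an analytic depth-spectra library
#'
#' For each depth the spectrum is a Gaussian primary peak centred at the
#' residual energy, with a width combining the initial beam spread and Bohr
#' range straggling (converted to energy via the local stopping power),
#' integrated exactly over the energy bins. The peak area decays as
#' `exp(-t / Lambda)`; optionally a flat low-energy tail carries a fraction
#' of the removed primaries. Depths at or beyond the primary range yield an
#' empty spectrum (all primaries stopped).
#'
#' @param material An [spe_material()].
#' @param beam A [beam_spec()].
#' @param depth_grid An [coarse_depth_grid()] (or any `spe_depth_grid`).
#' @param egrid An [energy_grid()].
#' @param nuclear A [nuclear_params()] list.
#' @return An object of class `spe_spectra_library` with a
#'   `length(depths) x n_bins` matrix `values` of differential fluence
#'   dN/dE (arbitrary units; unit peak area at depth 0).
#' @export
#' @examples
#' lib <- generate_spectra_library(builtin_material("iron"), beam_spec(),
#'                                 coarse_depth_grid(42.7, 21), energy_grid())
generate_spectra_library <- function(material, beam, depth_grid,
                                     egrid = energy_grid(),
                                     nuclear = nuclear_params()) {
  stopifnot(is_spe_material(material), inherits(beam, "spe_beam"),
            inherits(depth_grid, "spe_depth_grid"),
            inherits(egrid, "spe_energy_grid"))
  depths <- depth_grid$depths
  .check_depth_grid(depths)
  lambda_nuc <- nuclear$attenuation_length
  if (is.null(lambda_nuc)) lambda_nuc <- .default_attenuation_length(material)
  e0 <- beam$kinetic_energy
  r0 <- csda_range(material, e0)
  s0 <- stopping_power(material, e0)
  sigma_e0 <- .fwhm_to_sigma(beam$energy_spread_fwhm_rel * e0)
  edges <- bin_edges(egrid)
  vals <- matrix(0, nrow = length(depths), ncol = egrid$n_bins)
  for (k in seq_along(depths)) {
    t <- depths[k]
    if (t >= r0) next  # beyond range: all primaries stopped
    e_res <- residual_energy(material, e0, t)
    s_res <- stopping_power(material, max(e_res, .E_CUT))
    sig_r <- straggling_sigma(material, e0, t)
    # initial spread propagated as a range shift, plus range straggling,
    # both mapped to energy at the local stopping power
    sig_e <- sqrt((sigma_e0 * s_res / s0)^2 + (sig_r * s_res)^2)
    area <- exp(-t / lambda_nuc)
    if (sig_e > 0) {
      cdf <- stats::pnorm(edges, mean = e_res, sd = sig_e)
      vals[k, ] <- area * diff(cdf) / egrid$bin_width
    } else {
      j <- findInterval(e_res, edges, rightmost.closed = FALSE)
      if (j >= 1 && j <= egrid$n_bins)
        vals[k, j] <- area / egrid$bin_width
    }
    if (nuclear$tail_fraction > 0 && e_res > egrid$e_min) {
      tail_mass <- nuclear$tail_fraction * (1 - area)
      # flat dN/dE between 0 and the residual energy
      frac <- pmax(0, pmin(e_res, edges[-1L]) - pmin(e_res, edges[-length(edges)]))
      vals[k, ] <- vals[k, ] + tail_mass / e_res * frac / egrid$bin_width
    }
  }
  structure(list(material = material, beam = beam, depth_grid = depth_grid,
                 energy_grid = egrid, values = vals),
            class = "spe_spectra_library")
}

#' @export
print.spe_spectra_library <- function(x, ...) {
  cat(sprintf(
    "<spe_spectra_library> %s, %g MeV beam: %d depths x %d energy bins\n",
    x$material$name, x$beam$kinetic_energy, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Interpolate a spectra library onto a fine depth grid
#'
#' Per-energy-bin linear interpolation in depth (positivity-preserving and
#' exact at the coarse depths). Extrapolation beyond the coarse depth span
#' is refused.
#'
#' @param lib An `spe_spectra_library`.
#' @param fine_grid The target [fine_depth_grid()].
#' @return An `spe_spectra_library` on the fine grid.
#' @export
interpolate_library <- function(lib, fine_grid) {
  stopifnot(inherits(lib, "spe_spectra_library"),
            inherits(fine_grid, "spe_depth_grid"))
  xc <- lib$depth_grid$depths
  xf <- fine_grid$depths
  if (min(xf) < min(xc) - 1e-12 || max(xf) > max(xc) + 1e-12)
    stop("fine grid extends beyond the library depth span (extrapolation)")
  xf <- pmin(pmax(xf, min(xc)), max(xc))
  vals <- apply(lib$values, 2L, function(col)
    stats::approx(xc, col, xout = xf, method = "linear")$y)
  lib$values <- vals
  lib$depth_grid <- fine_grid
  lib
}

#' Read / write a spectra library as tab-separated text
#'
#' Format: line 1 `# material=<name> density=<g/cm3> beam=<MeV>`; line 2 the
#' tab-separated depths in g/cm^2; then one line per energy bin holding the
#' bin left edge followed by the fluence at each depth (15 significant
#' digits, so a write/read round trip is value-identical).
#'
#' @param path File path.
#' @return For `read_spectra_library`, an `spe_spectra_library`; the
#'   material is matched against the builtins by name (unknown names fall
#'   back to water electron constants at the stated density, with a
#'   warning) and the beam energy spread is not stored in the file.
#' @export
read_spectra_library <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("library file too short")
  hdr <- lines[1L]
  m <- regmatches(hdr, regexec(
    "^#\\s*material=(\\S+)\\s+density=([0-9.eE+-]+)\\s+beam=([0-9.eE+-]+)", hdr))[[1L]]
  if (length(m) != 4L) stop("line 1: malformed library header")
  mat_name <- m[2L]; dens <- as.numeric(m[3L]); beam_e <- as.numeric(m[4L])
  material <- if (mat_name %in% c("water", "iron", "steel")) {
    b <- builtin_material(mat_name); b$density <- dens; b
  } else {
    warning(sprintf("unknown material '%s': using water electron constants",
                    mat_name))
    spe_material(mat_name, dens, 0.5551, 75)
  }
  depths <- scan(text = lines[2L], sep = "\t", quiet = TRUE)
  if (any(diff(depths) <= 0)) stop("line 2: depths not strictly increasing")
  body <- lapply(seq.int(3L, length(lines)), function(i) {
    v <- scan(text = lines[i], sep = "\t", quiet = TRUE)
    if (length(v) != length(depths) + 1L)
      stop(sprintf("line %d: expected %d fields, got %d",
                   i, length(depths) + 1L, length(v)))
    if (any(v[-1L] < 0)) stop(sprintf("line %d: negative fluence", i))
    v
  })
  body <- do.call(rbind, body)
  e_left <- body[, 1L]
  bw <- diff(e_left)
  if (any(abs(bw - bw[1L]) > 1e-9 * bw[1L]))
    stop("energy bins are not equidistant")
  egrid <- energy_grid(n_bins = nrow(body), bin_width = bw[1L],
                       e_min = e_left[1L])
  dgrid <- structure(list(depths = depths,
                          kind = if (length(depths) > 100L) "fine" else "coarse",
                          dt = if (max(abs(diff(depths) - diff(depths)[1L])) <
                                     1e-9) diff(depths)[1L] else NA_real_),
                     class = "spe_depth_grid")
  structure(list(material = material, beam = beam_spec(beam_e, 0),
                 depth_grid = dgrid, energy_grid = egrid,
                 values = t(body[, -1L, drop = FALSE])),
            class = "spe_spectra_library")
}

#' @rdname read_spectra_library
#' @param lib An `spe_spectra_library`.
#' @export
write_spectra_library <- function(lib, path) {
  stopifnot(inherits(lib, "spe_spectra_library"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# material=%s density=%.15g beam=%.15g",
                     lib$material$name, lib$material$density,
                     lib$beam$kinetic_energy), con)
  writeLines(paste(sprintf("%.15g", lib$depth_grid$depths), collapse = "\t"),
             con)
  e_left <- bin_edges(lib$energy_grid)[-(lib$energy_grid$n_bins + 1L)]
  body <- cbind(e_left, t(lib$values))
  writeLines(apply(body, 1L, function(r)
    paste(sprintf("%.15g", r), collapse = "\t")), con)
  invisible(path)
}
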