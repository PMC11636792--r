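# Porous-foam (LN300) filter model: the foam induces a Gaussian smearing of
# the proton range whose variance grows as Pmod x traversed areal density.
# The library is broadened by a depth-domain Gaussian convolution whose mean
# is shifted by the foam's material-equivalent thickness.

#' Porous foam filter description
#'
#' Water-side parameters of a porous energy-spread filter: physical
#' thickness, mean water-equivalent areal density and modulation power.
#' The equivalent bulk density (areal density / thickness) is derived.
#' [convert_foam()] adds the target-material equivalents and the resulting
#' range sigma.
#'
#' @param thickness_cm Physical thickness in cm.
#' @param weq_mg_cm2 Mean water-equivalent areal density in mg/cm^2.
#' @param pmod_water_mg_cm2 Modulation power in mg/cm^2 (water).
#' @return An object of class `spe_foam`.
#' @export
#' @examples
#' foam_spec(14, 4000, 35)
#' foam_preset("design_ln300")
foam_spec <- function(thickness_cm, weq_mg_cm2, pmod_water_mg_cm2) {
  stopifnot(thickness_cm > 0, weq_mg_cm2 > 0, pmod_water_mg_cm2 >= 0)
  structure(list(
    thickness_cm = thickness_cm,
    weq_mg_cm2 = weq_mg_cm2,
    pmod_water_mg_cm2 = pmod_water_mg_cm2,
    density_g_cm3 = weq_mg_cm2 / 1000 / thickness_cm,
    sigma_water_mg_cm2 = range_sigma(pmod_water_mg_cm2, weq_mg_cm2),
    material = "water",
    tm_mg_cm2 = weq_mg_cm2,
    pmod_material_mg_cm2 = pmod_water_mg_cm2,
    sigma_mg_cm2 = range_sigma(pmod_water_mg_cm2, weq_mg_cm2)),
    class = "spe_foam")
}

#' @rdname foam_spec
#' @param name `"design_ln300"` (14 cm, 4000 mg/cm^2 water, Pmod 35 mg/cm^2,
#'   the block assumed during modulator design) or `"experiment_ln300"`
#'   (20 cm, 5760 mg/cm^2 water, Pmod 21 mg/cm^2, the block used in the
#'   verification beam time; equivalent density 0.288 g/cm^3).
#' @export
foam_preset <- function(name = c("design_ln300", "experiment_ln300")) {
  name <- match.arg(name)
  switch(name,
    design_ln300     = foam_spec(14, 4000, 35),
    experiment_ln300 = foam_spec(20, 5760, 21))
}

#' @export
print.spe_foam <- function(x, ...) {
  cat(sprintf(paste0(
    "<spe_foam> %g cm, %g mg/cm^2 (H2O), Pmod %g mg/cm^2 (H2O), ",
    "rho_eq %.3f g/cm^3\n"),
    x$thickness_cm, x$weq_mg_cm2, x$pmod_water_mg_cm2, x$density_g_cm3))
  if (x$material != "water")
    cat(sprintf("  in %s: tm = %g, Pmod = %g, sigma = %.4g mg/cm^2\n",
                x$material, x$tm_mg_cm2, x$pmod_material_mg_cm2,
                x$sigma_mg_cm2))
  invisible(x)
}

#' Range sigma of a porous filter
#'
#' The range smear-out accumulated in a porous slab:
#' `sigma = sqrt(Pmod x areal density)` (both in the same material).
#'
#' @param pmod Modulation power in mg/cm^2.
#' @param areal Traversed mean areal density in mg/cm^2.
#' @return Range sigma in mg/cm^2.
#' @export
#' @examples
#' range_sigma(50.4, 5760)  # 538.8 mg/cm^2 (Fe)
range_sigma <- function(pmod, areal) {
  if (any(pmod < 0) || any(areal < 0))
    stop("pmod and areal density must be non-negative")
  sqrt(pmod * areal)
}

#' Convert foam parameters from water to a target material
#'
#' Scales the water-side areal density and modulation power by the
#' water-to-material range-equivalence factor: the ratio of the material
#' thickness to the water thickness that produce the same residual energy
#' for the design beam. Both quantities scale by the same factor and the
#' range sigma is recomputed.
#'
#' @param foam An [foam_spec()].
#' @param material Target [spe_material()].
#' @param beam The design [beam_spec()] (sets the energy at which range
#'   equivalence is evaluated).
#' @return The foam with `tm_mg_cm2`, `pmod_material_mg_cm2`,
#'   `sigma_mg_cm2` and `material` filled in.
#' @export
#' @examples
#' convert_foam(foam_preset("design_ln300"), builtin_material("iron"),
#'              beam_spec(220))
convert_foam <- function(foam, material, beam = beam_spec()) {
  stopifnot(inherits(foam, "spe_foam"), is_spe_material(material),
            inherits(beam, "spe_beam"))
  water <- builtin_material("water")
  if (identical(material$z_over_a, water$z_over_a) &&
      identical(material$mean_excitation, water$mean_excitation)) {
    factor <- 1
  } else {
    t_w <- foam$weq_mg_cm2 / 1000  # g/cm^2
    e_res <- residual_energy(water, beam$kinetic_energy, t_w)
    d_mat <- csda_range(material, beam$kinetic_energy) -
             csda_range(material, e_res)
    factor <- d_mat / t_w
  }
  foam$material <- material$name
  foam$tm_mg_cm2 <- foam$weq_mg_cm2 * factor
  foam$pmod_material_mg_cm2 <- foam$pmod_water_mg_cm2 * factor
  foam$sigma_mg_cm2 <- range_sigma(foam$pmod_material_mg_cm2, foam$tm_mg_cm2)
  foam
}

#' Energy sigma induced by a foam on the primary beam
#'
#' Water-side range sigma of the foam multiplied by the water stopping
#' power at the post-foam residual energy. For the design foam and a
#' 220 MeV beam this is the sigma_E used for the simplified beam model.
#'
#' @inheritParams convert_foam
#' @return Energy sigma in MeV.
#' @export
#' @examples
#' foam_energy_sigma(foam_preset("design_ln300"), beam_spec(220))
foam_energy_sigma <- function(foam, beam = beam_spec()) {
  stopifnot(inherits(foam, "spe_foam"), inherits(beam, "spe_beam"))
  water <- builtin_material("water")
  t_w <- foam$weq_mg_cm2 / 1000
  e_res <- residual_energy(water, beam$kinetic_energy, t_w)
  (foam$sigma_water_mg_cm2 / 1000) * stopping_power(water, e_res)
}

#' Broaden a spectra library by a porous foam
#'
#' Discrete Gaussian convolution over the depth index (the foam's Gaussian
#' range-modulation model): the output spectrum at depth `t_i` draws from
#' input depths around `t_i + tm` (the foam's material-equivalent mean
#' thickness) with standard deviation `sigma`. The kernel is truncated at
#' +/- 5 sigma and renormalized to unit sum per output depth, which fixes
#' the arbitrary normalization constant so that fluence is conserved and
#' the sigma -> 0 limit is an exact shift. Source depths beyond the library
#' span reuse the last available spectrum.
#'
#' @param lib An `spe_spectra_library` on an equidistant (fine) depth grid.
#' @param foam A material-converted [foam_spec()] (see [convert_foam()]);
#'   its `sigma_mg_cm2` and `tm_mg_cm2` must refer to the library material.
#' @return The broadened library (same grids).
#' @export
broaden_library <- function(lib, foam) {
  stopifnot(inherits(lib, "spe_spectra_library"), inherits(foam, "spe_foam"))
  if (!identical(foam$material, lib$material$name))
    warning(sprintf(
      "foam parameters are for '%s' but the library material is '%s'",
      foam$material, lib$material$name))
  dt <- lib$depth_grid$dt
  if (is.na(dt)) stop("broaden_library needs an equidistant depth grid")
  sigma <- foam$sigma_mg_cm2 / 1000  # g/cm^2
  tm <- foam$tm_mg_cm2 / 1000
  if (sigma <= 0) stop("foam sigma must be positive")
  if (sigma < dt / 2)
    warning(sprintf(
      "foam sigma (%.4g g/cm^2) under-resolves the depth grid (dt = %.4g)",
      sigma, dt))
  n <- nrow(lib$values)
  half <- ceiling(5 * sigma / dt)
  out <- matrix(0, nrow = n, ncol = ncol(lib$values))
  depths <- lib$depth_grid$depths
  for (i in seq_len(n)) {
    centre <- depths[i] + tm
    j0 <- floor((centre - 5 * sigma) / dt)
    jj <- j0:(j0 + 2L * half)          # source depth indices (0-based)
    w <- exp(-(centre - jj * dt)^2 / (2 * sigma^2))
    w <- w / sum(w)
    rows <- pmin(pmax(jj + 1L, 1L), n)  # clamp: reuse edge spectra
    out[i, ] <- w %*% lib$values[rows, , drop = FALSE]
  }
  lib$values <- out
  lib
}
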