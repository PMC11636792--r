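# Material constants used by the transport stand-in.
#
# Z/A and mean excitation energies are the ICRU values; densities are the
# nominal bulk densities (the printed steel density 7.9 g/cm^3 is kept as a
# separate builtin because areal densities are scaled by it when converting
# layer thicknesses to printed heights).

#' Define a homogeneous material for proton transport
#'
#' A material is fully described, for the purposes of this package, by its
#' bulk density, its electron content ratio Z/A and its mean excitation
#' energy I (the only parameters entering the Bethe stopping-power formula).
#'
#' @param name Short material name (used for caching and file headers).
#' @param density Bulk density in g/cm^3 (> 0).
#' @param z_over_a Ratio of atomic number to mass number (0 < Z/A < 1).
#' @param mean_excitation Mean excitation energy I in eV (> 0).
#' @return An object of class `spe_material`.
#' @seealso [builtin_material()] for the packaged water/iron/steel constants.
#' @export
#' @examples
#' spe_material("water", 1.0, 0.5551, 75)
spe_material <- function(name, density, z_over_a, mean_excitation) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(density) || length(density) != 1L || density <= 0)
    stop("material density must be a positive scalar [g/cm^3]")
  if (!is.numeric(z_over_a) || length(z_over_a) != 1L ||
      z_over_a <= 0 || z_over_a >= 1)
    stop("z_over_a must lie strictly between 0 and 1")
  if (!is.numeric(mean_excitation) || length(mean_excitation) != 1L ||
      mean_excitation <= 0)
    stop("mean_excitation must be a positive scalar [eV]")
  structure(
    list(name = name, density = density, z_over_a = z_over_a,
         mean_excitation = mean_excitation),
    class = "spe_material")
}

#' Packaged material constants
#'
#' Water (Z/A = 0.5551, I = 75 eV), elemental iron (Z/A = 0.4656,
#' I = 286 eV, 7.874 g/cm^3) and printing steel (iron electron constants at
#' the printed density of 7.9 g/cm^3, approximating stainless 1.4404).
#'
#' @param name One of `"water"`, `"iron"`, `"steel"`.
#' @return An `spe_material`.
#' @export
#' @examples
#' builtin_material("iron")
builtin_material <- function(name = c("water", "iron", "steel")) {
  name <- match.arg(name)
  switch(name,
    water = spe_material("water", 1.0,   0.5551, 75),
    iron  = spe_material("iron",  7.874, 0.4656, 286),
    steel = spe_material("steel", 7.9,   0.4656, 286))
}

#' @export
print.spe_material <- function(x, ...) {
  cat(sprintf("<spe_material> %s: rho = %g g/cm^3, Z/A = %g, I = %g eV\n",
              x$name, x$density, x$z_over_a, x$mean_excitation))
  invisible(x)
}

is_spe_material <- function(x) inherits(x, "spe_material")
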