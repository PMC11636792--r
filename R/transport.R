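# Analytic 1D proton transport: Bethe stopping power, CSDA range and its
# inverse, Bohr range straggling. This replaces Monte Carlo base data at the
# fidelity the downstream optimizer needs (peak position, peak width,
# primary attenuation); externally computed libraries can be imported with
# read_spectra_library() when full nuclear physics matters.

# physical constants [MeV]
.K_BETHE <- 0.307075    # 4 pi N_A r_e^2 m_e c^2, MeV cm^2 / mol
.ME_C2   <- 0.51099895  # electron rest energy
.MP_C2   <- 938.27209   # proton rest energy
.E_CUT   <- 1           # low-energy validity cutoff, MeV
.E_MAX   <- 300         # high-energy validity cutoff, MeV

# package-local cache for per-material range/straggling tables
.spemod_cache <- new.env(parent = emptyenv())

#' Mass stopping power of protons (relativistic Bethe formula)
#'
#' Mean electronic stopping power -dE/d(rho x) for protons, using the
#' relativistic Bethe formula with the maximum energy transfer to a free
#' electron and no shell or density-effect corrections (both are negligible
#' over the 1--300 MeV validity window at the accuracy needed here).
#'
#' @param material An [spe_material()].
#' @param energy Proton kinetic energy in MeV (vectorized); must lie in
#'   `[1, 300]` MeV.
#' @return Mass stopping power in MeV cm^2/g.
#' @export
#' @examples
#' stopping_power(builtin_material("water"), 220)
stopping_power <- function(material, energy) {
  stopifnot(is_spe_material(material))
  if (any(!is.finite(energy)) || any(energy < .E_CUT) || any(energy > .E_MAX))
    stop(sprintf("energy outside stopping-power validity range [%g, %g] MeV",
                 .E_CUT, .E_MAX))
  gam  <- 1 + energy / .MP_C2
  b2   <- 1 - 1 / gam^2
  I    <- material$mean_excitation * 1e-6  # eV -> MeV
  me_r <- .ME_C2 / .MP_C2
  tmax <- 2 * .ME_C2 * b2 * gam^2 / (1 + 2 * gam * me_r + me_r^2)
  .K_BETHE * material$z_over_a / b2 *
    (0.5 * log(2 * .ME_C2 * b2 * gam^2 * tmax / I^2) - b2)
}

# Bohr straggling kernel: d(sigma_E^2)/d(rho x) in MeV^2 cm^2 / g, with the
# standard relativistic factor.
.straggling_kernel <- function(material, energy) {
  gam <- 1 + energy / .MP_C2
  b2  <- 1 - 1 / gam^2
  .K_BETHE * .ME_C2 * material$z_over_a * (1 - b2 / 2) / (1 - b2)
}

# Cached monotone tables: R(E), E(R), and the cumulative straggling
# integral Phi(E) = int_1^E k(E') / S(E')^3 dE' (used for range straggling
# via sigma_R^2(depth) = Phi(E0) - Phi(E_res)).
.transport_tables <- function(material) {
  key <- sprintf("%s|%g|%g|%g", material$name, material$density,
                 material$z_over_a, material$mean_excitation)
  tab <- .spemod_cache[[key]]
  if (!is.null(tab)) return(tab)
  e <- seq(.E_CUT, .E_MAX, by = 0.05)
  s <- stopping_power(material, e)
  inv_s <- 1 / s
  # cumulative trapezoid of 1/S, plus the sub-cutoff residual treated as a
  # constant (R ~ E^1.77 below 1 MeV => residual ~ E_cut / (1.77 S(E_cut)))
  r0 <- .E_CUT / (1.77 * s[1L])
  r  <- r0 + c(0, cumsum(0.5 * diff(e) * (inv_s[-1L] + inv_s[-length(e)])))
  k  <- .straggling_kernel(material, e) / s^3
  phi <- c(0, cumsum(0.5 * diff(e) * (k[-1L] + k[-length(e)])))
  tab <- list(
    r_low   = r0,
    e_grid  = e,
    r_grid  = r,
    range_of_energy = stats::splinefun(e, r, method = "hyman"),
    energy_of_range = stats::splinefun(r, e, method = "hyman"),
    phi_of_energy   = stats::splinefun(e, phi, method = "hyman"))
  .spemod_cache[[key]] <- tab
  tab
}

#' CSDA range of protons
#'
#' Continuous-slowing-down range, i.e. the integral of 1/S(E) from a 1 MeV
#' cutoff up to the given energy, plus a constant sub-cutoff residual.
#' Below the cutoff the range falls off as E^1.77 (continuous at 1 MeV).
#'
#' @inheritParams stopping_power
#' @param energy Kinetic energy in MeV, `0 <= energy <= 300` (vectorized).
#' @return Range as areal density in g/cm^2.
#' @export
#' @examples
#' csda_range(builtin_material("water"), 220)
csda_range <- function(material, energy) {
  stopifnot(is_spe_material(material))
  if (any(!is.finite(energy)) || any(energy < 0) || any(energy > .E_MAX))
    stop("energy must lie in [0, 300] MeV")
  tab <- .transport_tables(material)
  out <- numeric(length(energy))
  lo <- energy < .E_CUT
  out[lo]  <- tab$r_low * (energy[lo] / .E_CUT)^1.77
  out[!lo] <- tab$range_of_energy(energy[!lo])
  out
}

#' Residual energy after a material slab
#'
#' Inverts the range function: solves `range(E_res) = range(E0) - depth`.
#'
#' @inheritParams stopping_power
#' @param energy Initial kinetic energy in MeV (scalar).
#' @param depth Traversed areal density in g/cm^2 (vectorized);
#'   `0 <= depth < csda_range(material, energy)`.
#' @return Residual kinetic energy in MeV.
#' @export
#' @examples
#' residual_energy(builtin_material("water"), 220, 4.0)
residual_energy <- function(material, energy, depth) {
  stopifnot(is_spe_material(material), length(energy) == 1L)
  r0 <- csda_range(material, energy)
  if (any(depth < 0)) stop("depth must be non-negative")
  if (any(depth >= r0))
    stop(sprintf("depth >= csda_range(%s, %g MeV) = %.4f g/cm^2: beyond range",
                 material$name, energy, r0))
  tab <- .transport_tables(material)
  res <- r0 - depth
  out <- numeric(length(depth))
  lo <- res < tab$r_low
  out[lo]  <- .E_CUT * (res[lo] / tab$r_low)^(1 / 1.77)
  out[!lo] <- pmin(tab$energy_of_range(res[!lo]), energy)
  out
}

#' Range straggling sigma (Bohr)
#'
#' Standard deviation of the range distribution accumulated over `depth`,
#' from the Bohr energy-straggling rate transported to range units:
#' `sigma_R^2 = int_0^depth k(E(t)) / S(E(t))^2 dt`.
#'
#' @inheritParams residual_energy
#' @param depth Depth in g/cm^2, `0 <= depth <= range` (vectorized).
#' @return Straggling sigma in g/cm^2; 0 at depth 0, monotone in depth.
#' @export
#' @examples
#' straggling_sigma(builtin_material("iron"), 220, 42)
straggling_sigma <- function(material, energy, depth) {
  stopifnot(is_spe_material(material), length(energy) == 1L)
  r0 <- csda_range(material, energy)
  if (any(depth < 0) || any(depth > r0))
    stop("depth must lie in [0, range]")
  tab <- .transport_tables(material)
  # residual energy, clamped to the cutoff for (near-)full-range depths
  e_res <- pmax(.E_CUT, tab$energy_of_range(pmax(r0 - depth, tab$r_low)))
  v <- tab$phi_of_energy(energy) - tab$phi_of_energy(e_res)
  sqrt(pmax(v, 0))
}
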