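# Run configuration: every printed design constant is a named default so
# that reproducing the reference modulator is the default run and any
# other SPE spectrum or beamline is a config change, not a code change.

#' Default run configuration
#'
#' The defaults reproduce the reference design case: 220 MeV protons with
#' 0.1% FWHM energy spread on a steel (7.9 g/cm^3) modulator, the 14 cm
#' LN300 design foam, the 42.7 g/cm^2 reference peak depth sampled at 77
#' coarse / 2400 fine depths (dt = 21.35 mg/cm^2), optimization window
#' 40--203 MeV over depth indices 0..1700, cell period 5 mm, 8 x 8 cells,
#' 100 um minimum hole diameter.
#'
#' @return A nested configuration list of class `spe_config`.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$geometry$lambda_mm
default_config <- function() {
  structure(list(
    seed = 1L,
    beam = list(kinetic_energy_mev = 220, energy_spread_fwhm_rel = 0.001),
    material = list(name = "steel"),
    foam = list(preset = "design_ln300",
                thickness_cm = NULL, weq_mg_cm2 = NULL,
                pmod_water_mg_cm2 = NULL),
    grids = list(t_peak_g_cm2 = 42.7, n_coarse = 77L, i_fine_max = 2400L,
                 n_energy_bins = 500L, bin_width_mev = 0.5, e_min_mev = 0),
    nuclear = list(attenuation_length_g_cm2 = NULL, tail_fraction = 0.5),
    target = list(fixture = "spe1972_like", path = NULL),
    optimization = list(window_mev = c(40, 203), i_max = 1700L,
                        n_nodes = 32L, weighting = "plain"),
    geometry = list(lambda_mm = 5, n_cells = 8L, min_hole_diameter_mm = 0.1,
                    n_segments = 64L, decimate_tol_mm = 0.02),
    verification = list(normalization_depth_g_cm2 = 10,
                        homogeneity_threshold = 1e-3,
                        beam_fwhm_mm = 8.1,
                        scattering_angle_rad = 0.013,
                        dead_material_g_cm2 = 0,
                        ddp_dx_g_cm2 = 0.02)),
    class = "spe_config")
}

#' Load / save a run configuration (YAML)
#'
#' Values present in the file override the defaults; everything else keeps
#' its default, so a config file only needs the deviations.
#'
#' @param path YAML file path.
#' @return An `spe_config`.
#' @export
load_config <- function(path) {
  usr <- yaml::read_yaml(path)
  cfg <- default_config()
  merge_in <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]]))
        base[[nm]] <- merge_in(base[[nm]], over[[nm]])
      else base[[nm]] <- over[[nm]]
    }
    base
  }
  cfg <- merge_in(unclass(cfg), usr)
  class(cfg) <- "spe_config"
  validate_config(cfg)
  cfg
}

#' @rdname load_config
#' @param config An `spe_config`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname load_config
#' @export
validate_config <- function(config) {
  stopifnot(config$beam$kinetic_energy_mev > 0,
            config$beam$energy_spread_fwhm_rel >= 0,
            config$grids$t_peak_g_cm2 > 0,
            config$grids$n_coarse >= 2,
            config$grids$i_fine_max > config$optimization$i_max,
            config$optimization$n_nodes >= 4,
            length(config$optimization$window_mev) == 2L,
            config$geometry$lambda_mm > 0,
            config$geometry$n_cells >= 1,
            config$geometry$min_hole_diameter_mm >= 0,
            config$geometry$n_segments %% 8 == 0)
  if (!config$material$name %in% c("water", "iron", "steel"))
    stop("material must be one of the builtins: water, iron, steel")
  invisible(config)
}

# resolve config sections into package objects
.cfg_material <- function(config) builtin_material(config$material$name)

.cfg_beam <- function(config)
  beam_spec(config$beam$kinetic_energy_mev,
            config$beam$energy_spread_fwhm_rel)

.cfg_foam <- function(config) {
  f <- config$foam
  if (!is.null(f$thickness_cm) && !is.null(f$weq_mg_cm2) &&
      !is.null(f$pmod_water_mg_cm2))
    return(foam_spec(f$thickness_cm, f$weq_mg_cm2, f$pmod_water_mg_cm2))
  foam_preset(f$preset)
}

.cfg_egrid <- function(config)
  energy_grid(config$grids$n_energy_bins, config$grids$bin_width_mev,
              config$grids$e_min_mev)

.cfg_target <- function(config, egrid) {
  if (!is.null(config$target$path))
    return(load_target(config$target$path, egrid))
  switch(config$target$fixture,
         spe1972_like = spe1972_like(egrid),
         stop(sprintf("unknown target fixture '%s'",
                      config$target$fixture)))
}
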