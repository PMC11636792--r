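# End-to-end orchestration: library -> foam -> optimization -> geometry ->
# STL (design), and DDP + homogeneity (verify), with deterministic,
# byte-reproducible text outputs.

.stage <- function(name, quiet, expr) {
  if (!quiet)
    message(sprintf("[%s] %s ...", format(Sys.time(), "%H:%M:%S"), name))
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

.write_tsv <- function(df, path, header) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  writeLines(do.call(sprintf,
                     c(list(paste(rep("%.12g", ncol(df)), collapse = "\t")),
                       unname(as.list(df)))), con)
  invisible(path)
}

#' Run the full modulator design pipeline
#'
#' Executes the design chain on a configuration: generate (or load) the
#' depth-spectra library, interpolate to the fine grid, apply the foam
#' broadening, optimize the layer weights against the target spectrum,
#' convert weights to the funnel cell, assemble the array and export the
#' STL. All outputs are plain text except the STL; reruns with the same
#' configuration are byte-identical.
#'
#' Files written to `out_dir`: `weights.tsv` (i, t_i, w_i),
#' `layers.tsv` (i, t_i, A_i, r_i), `spectrum.tsv` (energy, target,
#' reconstructed), `modulator.stl`, `report.yaml`, `config.yaml`.
#'
#' @param config An [default_config()]-style `spe_config`.
#' @param out_dir Output directory (created if missing).
#' @param library_path Optional externally computed spectra library (TSV,
#'   see [read_spectra_library()]); replaces the analytic generator.
#' @param write_stl_file Set `FALSE` to skip mesh generation/export.
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with the fit, stack, cell, array and report.
#' @export
run_design <- function(config = default_config(), out_dir = "spemod_out",
                       library_path = NULL, write_stl_file = TRUE,
                       quiet = FALSE) {
  validate_config(config)
  set.seed(config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  material <- .cfg_material(config)
  beam <- .cfg_beam(config)
  egrid <- .cfg_egrid(config)
  tpk <- config$grids$t_peak_g_cm2

  fine <- .stage("spectra library", quiet, {
    fine_grid <- fine_depth_grid(tpk, config$grids$i_fine_max)
    if (!is.null(library_path)) {
      lib <- read_spectra_library(library_path)
      if (length(lib$depth_grid$depths) < length(fine_grid$depths))
        lib <- interpolate_library(lib, fine_grid)
      lib
    } else {
      coarse <- coarse_depth_grid(tpk, config$grids$n_coarse)
      nuc <- nuclear_params(config$nuclear$attenuation_length_g_cm2,
                            config$nuclear$tail_fraction)
      interpolate_library(
        generate_spectra_library(material, beam, coarse, egrid, nuc),
        fine_grid)
    }
  })
  broadened <- .stage("foam broadening", quiet, {
    foam <- convert_foam(.cfg_foam(config), material, beam)
    broaden_library(fine, foam)
  })
  fit <- .stage("weight optimization", quiet, {
    target <- .cfg_target(config, egrid)
    win <- apply_window(target, config$optimization$window_mev[1L],
                        config$optimization$window_mev[2L])
    optimize_weights(broadened, target, window = win,
                     i_max = config$optimization$i_max,
                     n_nodes = config$optimization$n_nodes,
                     weighting = config$optimization$weighting,
                     seed = config$seed)
  })
  stack <- .stage("funnel geometry", quiet, {
    st <- weights_to_layers(fit$weights, config$geometry$lambda_mm)
    clamp_hole(st, config$geometry$min_hole_diameter_mm)
  })
  cell <- array_obj <- NULL
  if (write_stl_file) {
    cell <- .stage("cell mesh", quiet,
      build_cell(stack, material,
                 n_segments = config$geometry$n_segments,
                 decimate_tol_mm = config$geometry$decimate_tol_mm))
    array_obj <- .stage("array mesh + stl", quiet, {
      arr <- assemble_array(cell, config$geometry$n_cells)
      write_stl(arr, file.path(out_dir, "modulator.stl"), force = TRUE)
      arr
    })
  }
  .stage("outputs", quiet, {
    .write_tsv(data.frame(fit$weights$i, fit$weights$t, fit$weights$w),
               file.path(out_dir, "weights.tsv"),
               c("i", "t_i_g_cm2", "w_i"))
    .write_tsv(data.frame(stack$i, stack$t, stack$A, stack$r),
               file.path(out_dir, "layers.tsv"),
               c("i", "t_i_g_cm2", "A_i_mm2", "r_i_mm"))
    target <- fit$window$spectrum
    .write_tsv(data.frame(bin_centers(egrid), target$values,
                          fit$reconstructed$values),
               file.path(out_dir, "spectrum.tsv"),
               c("energy_mev", "target", "reconstructed"))
    save_config(config, file.path(out_dir, "config.yaml"))
  })
  clamp <- attr(stack, "clamp_report")
  report <- list(
    chi2 = fit$chi2,
    chi2_initial = fit$chi2_initial,
    band_deviation = as.list(fit$band_deviation),
    hole_diameter_mm = clamp$hole_diameter_mm,
    clamp_layers_touched = clamp$layers_touched,
    cell_height_mm = if (!is.null(cell)) cell$height else
      stack$t[nrow(stack)] * 10 / material$density,
    lateral_size_mm = config$geometry$n_cells * config$geometry$lambda_mm,
    mesh = if (!is.null(array_obj)) {
      wt <- mesh_is_watertight(cell$mesh)
      list(n_triangles = nrow(array_obj$mesh$triangles),
           volume_mm3 = mesh_volume(array_obj$mesh),
           cell_watertight = wt$watertight)
    } else NULL)
  yaml::write_yaml(report, file.path(out_dir, "report.yaml"))
  invisible(list(fit = fit, stack = stack, cell = cell, array = array_obj,
                 report = report, out_dir = out_dir))
}

#' Run the forward verification of a finished design
#'
#' Reads the reconstructed spectrum written by [run_design()] (or uses a
#' passed design result), computes the water depth-dose profile by
#' Bragg-curve superposition (normalized at the configured depth) and the
#' ripple/blur report, and writes `ddp.tsv`, `ripple.tsv` and
#' `verify_report.yaml` next to the design artifacts.
#'
#' @param out_dir Directory holding `spectrum.tsv` and `config.yaml` from
#'   a design run.
#' @param config Optional `spe_config` overriding the stored one.
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with the `spe_ddp` and `spe_ripple_report`.
#' @export
run_verify <- function(out_dir, config = NULL, quiet = FALSE) {
  spec_path <- file.path(out_dir, "spectrum.tsv")
  cfg_path <- file.path(out_dir, "config.yaml")
  missing <- c(spec_path, cfg_path)[!file.exists(c(spec_path, cfg_path))]
  if (is.null(config) && length(missing))
    stop(sprintf("missing design artifacts: %s",
                 paste(missing, collapse = ", ")))
  if (is.null(config)) config <- load_config(cfg_path)
  if (!file.exists(spec_path))
    stop(sprintf("missing design artifacts: %s", spec_path))
  egrid <- .cfg_egrid(config)
  tab <- utils::read.table(spec_path, header = TRUE, sep = "\t")
  rec <- spe_spectrum(egrid, pmax(tab$reconstructed, 0))
  v <- config$verification
  ddp <- .stage("depth-dose profile", quiet,
    spe_depth_dose(rec, dx = v$ddp_dx_g_cm2,
                   normalize_at = v$normalization_depth_g_cm2,
                   dead_material = v$dead_material_g_cm2))
  ripple <- .stage("lateral homogeneity", quiet, {
    rip0 <- lateral_ripple(v$beam_fwhm_mm, config$geometry$lambda_mm)
    rep <- blur_vs_distance(config$geometry$lambda_mm,
                            v$scattering_angle_rad,
                            threshold = v$homogeneity_threshold)
    attr(rep, "beam_ripple") <- rip0
    rep
  })
  .write_tsv(data.frame(ddp$depths, ddp$dose),
             file.path(out_dir, "ddp.tsv"), c("depth_g_cm2", "dose_rel"))
  .write_tsv(data.frame(ripple$distances, ripple$sigma_mm, ripple$ripple),
             file.path(out_dir, "ripple.tsv"),
             c("distance_mm", "sigma_mm", "ripple"))
  yaml::write_yaml(list(
    beam_ripple = attr(ripple, "beam_ripple"),
    first_homogeneous_mm = ripple$first_homogeneous_mm,
    normalization_depth_g_cm2 = ddp$normalization_depth),
    file.path(out_dir, "verify_report.yaml"))
  invisible(list(ddp = ddp, ripple = ripple))
}

#' Write deterministic demo/test fixtures
#'
#' `spe1972_like`: the synthetic exponential target spectrum as a target
#' TSV. `toy_library`: a small (10 depths x 50 bins) analytic water
#' library. `toy_target`: a spectrum superposed from that library with
#' known smooth weights. Repeated calls produce identical bytes.
#'
#' @param name One of `"spe1972_like"`, `"toy_library"`, `"toy_target"`.
#' @param out_dir Output directory.
#' @return The written file path.
#' @export
make_fixtures <- function(name = c("spe1972_like", "toy_library",
                                   "toy_target"),
                          out_dir = ".") {
  name <- match.arg(name)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  toy_lib <- function() {
    mat <- builtin_material("water")
    generate_spectra_library(
      mat, beam_spec(100, 0.01),
      coarse_depth_grid(csda_range(mat, 100), 10L),
      energy_grid(50L, 2.5, 0))
  }
  switch(name,
    spe1972_like = {
      p <- file.path(out_dir, "spe1972_like.tsv")
      write_target(spe1972_like(), p)
      p
    },
    toy_library = {
      p <- file.path(out_dir, "toy_library.tsv")
      write_spectra_library(toy_lib(), p)
      p
    },
    toy_target = {
      p <- file.path(out_dir, "toy_target.tsv")
      lib <- toy_lib()
      w <- exp(-(0:9) / 4)
      write_target(reconstruct_spectrum(w / sum(w), lib), p)
      p
    })
}
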