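# Energy and depth grids shared by the spectra library, the target spectrum
# and the weight optimizer.

#' Energy histogram grid
#'
#' Half-open, left-edge-labelled energy bins `[E_j, E_j + bin_width)` with
#' `E_j = e_min + j * bin_width`, `j = 0, ..., n_bins - 1`. The default is
#' the design scheme: 500 equidistant 0.5 MeV bins from 0 to 250 MeV.
#'
#' @param n_bins Number of bins.
#' @param bin_width Bin width in MeV.
#' @param e_min Left edge of the first bin in MeV.
#' @return An object of class `spe_energy_grid` with fields `n_bins`,
#'   `bin_width`, `e_min`.
#' @export
#' @examples
#' g <- energy_grid()
#' head(bin_centers(g))
energy_grid <- function(n_bins = 500L, bin_width = 0.5, e_min = 0) {
  stopifnot(n_bins >= 2L, bin_width > 0, e_min >= 0)
  structure(list(n_bins = as.integer(n_bins), bin_width = bin_width,
                 e_min = e_min),
            class = "spe_energy_grid")
}

#' @rdname energy_grid
#' @param grid An `spe_energy_grid`.
#' @export
bin_edges <- function(grid) {
  grid$e_min + (0:grid$n_bins) * grid$bin_width
}

#' @rdname energy_grid
#' @export
bin_centers <- function(grid) {
  grid$e_min + (seq_len(grid$n_bins) - 0.5) * grid$bin_width
}

#' @export
print.spe_energy_grid <- function(x, ...) {
  cat(sprintf("<spe_energy_grid> %d bins of %g MeV from %g to %g MeV\n",
              x$n_bins, x$bin_width, x$e_min,
              x$e_min + x$n_bins * x$bin_width))
  invisible(x)
}

#' Depth grid for the spectra library
#'
#' Strictly increasing areal densities at which depth spectra are tabulated.
#' The coarse grid mirrors the base-data layout (77 equidistant depths from
#' 0, meaning "no target", to 1.2 t_peak); the fine grid has `i_max + 1`
#' depths `t_i = i * dt` with `dt = 1.2 t_peak / i_max` (default
#' `i_max = 2400`, so dt = 21.35 mg/cm^2 for the 42.7 g/cm^2 reference
#' peak depth).
#'
#' @param t_peak Reference Bragg-peak areal density in g/cm^2.
#' @param n_points Number of coarse depths (including depth 0).
#' @return An object of class `spe_depth_grid` with fields `depths`
#'   (g/cm^2), `kind`, and for fine grids the spacing `dt`.
#' @export
#' @examples
#' coarse_depth_grid(42.7)
#' fine_depth_grid(42.7)$dt   # 0.02135 g/cm^2
coarse_depth_grid <- function(t_peak, n_points = 77L) {
  stopifnot(t_peak > 0, n_points >= 2L)
  structure(list(depths = seq(0, 1.2 * t_peak, length.out = n_points),
                 kind = "coarse", dt = NA_real_),
            class = "spe_depth_grid")
}

#' @rdname coarse_depth_grid
#' @param i_max Largest fine depth index (depths are `0:i_max * dt`).
#' @export
fine_depth_grid <- function(t_peak, i_max = 2400L) {
  stopifnot(t_peak > 0, i_max >= 2L)
  dt <- 1.2 * t_peak / i_max
  structure(list(depths = (0:i_max) * dt, kind = "fine", dt = dt),
            class = "spe_depth_grid")
}

#' @export
print.spe_depth_grid <- function(x, ...) {
  cat(sprintf("<spe_depth_grid> %s, %d depths, 0 to %.4f g/cm^2%s\n",
              x$kind, length(x$depths), max(x$depths),
              if (is.na(x$dt)) "" else sprintf(", dt = %g g/cm^2", x$dt)))
  invisible(x)
}

.check_depth_grid <- function(depths) {
  if (any(diff(depths) <= 0)) stop("depths must be strictly increasing")
  if (depths[1L] < 0) stop("depths must be non-negative")
  invisible(TRUE)
}
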