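# Target SPE spectra: TSV ingestion with log-linear resampling, a
# parametric exponential generator standing in for the (figure-only)
# August-1972 event tabulation, and the optimization window.

#' SPE spectrum container
#'
#' @param egrid An [energy_grid()].
#' @param values Differential fluence per bin (arbitrary units, >= 0).
#' @param window Energy window `c(e_lo, e_hi)` in MeV or `NULL`.
#' @return An object of class `spe_spectrum`.
#' @export
spe_spectrum <- function(egrid, values, window = NULL) {
  stopifnot(inherits(egrid, "spe_energy_grid"),
            length(values) == egrid$n_bins)
  if (any(values < 0)) stop("spectrum values must be non-negative")
  structure(list(energy_grid = egrid, values = as.numeric(values),
                 window = window),
            class = "spe_spectrum")
}

#' @export
print.spe_spectrum <- function(x, ...) {
  cat(sprintf("<spe_spectrum> %d bins; fluence span [%.3g, %.3g]%s\n",
              x$energy_grid$n_bins, min(x$values), max(x$values),
              if (is.null(x$window)) "" else
                sprintf("; window %g-%g MeV", x$window[1L], x$window[2L])))
  invisible(x)
}

#' Load a tabulated target spectrum
#'
#' Reads a two-column text table (energy in MeV, differential fluence;
#' `#` comments allowed) and resamples it to the bin centres of the grid by
#' log-linear interpolation (linear in log fluence versus energy, the
#' appropriate scheme for spectra spanning decades). Bins outside the
#' tabulated energy span are zero; zero table entries fall back to linear
#' interpolation in the adjacent intervals.
#'
#' @param path Path to the TSV/whitespace table.
#' @param egrid Target [energy_grid()].
#' @return An `spe_spectrum`.
#' @export
load_target <- function(path, egrid = energy_grid()) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("energy", "fluence"))
  if (nrow(tab) < 2L) stop("target table needs at least 2 rows")
  if (any(diff(tab$energy) <= 0))
    stop("target energies must be strictly increasing")
  if (any(tab$fluence < 0)) stop("target fluence must be non-negative")
  ec <- bin_centers(egrid)
  vals <- numeric(egrid$n_bins)
  inside <- ec >= tab$energy[1L] & ec <= tab$energy[nrow(tab)]
  if (any(inside)) {
    pos <- tab$fluence > 0
    if (all(pos)) {
      lv <- stats::approx(tab$energy, log(tab$fluence), xout = ec[inside],
                          method = "linear")$y
      vals[inside] <- exp(lv)
    } else {
      # zeros present: log-interpolate where both neighbours are positive,
      # otherwise interpolate linearly (keeps exact zeros exact)
      f <- stats::approxfun(tab$energy, tab$fluence, method = "linear")
      lf <- stats::approxfun(tab$energy, log(pmax(tab$fluence, 1e-300)),
                             method = "linear")
      idx <- findInterval(ec[inside], tab$energy,
                          rightmost.closed = TRUE, all.inside = TRUE)
      ok <- pos[idx] & pos[pmin(idx + 1L, nrow(tab))]
      v <- ifelse(ok, exp(lf(ec[inside])), f(ec[inside]))
      vals[inside] <- pmax(v, 0)
    }
  }
  spe_spectrum(egrid, vals)
}

#' Write a spectrum as a two-column TSV
#'
#' Bin centres versus fluence, loadable by [load_target()].
#'
#' @param spec An `spe_spectrum`.
#' @param path Output path.
#' @export
write_target <- function(spec, path) {
  stopifnot(inherits(spec, "spe_spectrum"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# energy_MeV\tfluence", con)
  writeLines(sprintf("%.15g\t%.15g", bin_centers(spec$energy_grid),
                     spec$values), con)
  invisible(path)
}

#' Parametric exponentially falling SPE-like spectrum
#'
#' `J(E) = j0 exp(-E / e0)` evaluated at the bin centres: the canonical
#' shape of solar-particle-event proton spectra in the tens-to-hundreds of
#' MeV region.
#'
#' @param j0 Amplitude (arbitrary units).
#' @param e0 e-folding energy in MeV (> 0).
#' @param egrid Target [energy_grid()].
#' @return An `spe_spectrum`.
#' @export
#' @examples
#' sp <- parametric_spe(1, 25, energy_grid())
parametric_spe <- function(j0 = 1, e0 = 25, egrid = energy_grid()) {
  stopifnot(e0 > 0, j0 >= 0)
  spe_spectrum(egrid, j0 * exp(-bin_centers(egrid) / e0))
}

#' August-1972-like synthetic target spectrum
#'
#' A clearly synthetic stand-in for the 1972 SPE tabulation (which exists
#' only graphically): an exponential with e-folding energy chosen so the
#' differential fluence falls by four orders of magnitude between 40 and
#' 200 MeV, the dynamic range characteristic of that event over the design
#' window.
#'
#' @inheritParams parametric_spe
#' @export
spe1972_like <- function(egrid = energy_grid(), j0 = 1) {
  parametric_spe(j0 = j0, e0 = 160 / log(1e4), egrid = egrid)
}

#' Apply the optimization energy window
#'
#' Marks the window `[e_lo, e_hi]` on the spectrum and returns the 0-based
#' bin indices whose left edges equal the window limits (for the default
#' grid, 40 MeV -> j = 80 and 203 MeV -> j = 406, matching `j = E / 0.5`).
#' Values are not altered.
#'
#' @param spec An `spe_spectrum`.
#' @param e_lo,e_hi Window limits in MeV; must coincide with bin left edges
#'   inside the grid span.
#' @return A list: `spectrum` (with window set), `j_lo`, `j_hi` (0-based
#'   bin indices) and `bins` (1-based R column indices `j_lo+1 .. j_hi+1`).
#' @export
#' @examples
#' apply_window(spe1972_like())$j_lo  # 80
apply_window <- function(spec, e_lo = 40, e_hi = 203) {
  stopifnot(inherits(spec, "spe_spectrum"), e_lo < e_hi)
  g <- spec$energy_grid
  span_hi <- g$e_min + g$n_bins * g$bin_width
  if (e_lo < g$e_min || e_hi > span_hi)
    stop(sprintf("window [%g, %g] MeV outside grid span [%g, %g]",
                 e_lo, e_hi, g$e_min, span_hi))
  j_lo <- (e_lo - g$e_min) / g$bin_width
  j_hi <- (e_hi - g$e_min) / g$bin_width
  if (abs(j_lo - round(j_lo)) > 1e-9 || abs(j_hi - round(j_hi)) > 1e-9)
    stop("window limits must coincide with bin left edges")
  j_lo <- as.integer(round(j_lo)); j_hi <- as.integer(round(j_hi))
  j_hi <- min(j_hi, g$n_bins - 1L)
  spec$window <- c(e_lo, e_hi)
  list(spectrum = spec, j_lo = j_lo, j_hi = j_hi,
       bins = seq.int(j_lo + 1L, j_hi + 1L))
}
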