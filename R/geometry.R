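# Funnel cell geometry: optimized weights -> layer areas -> opening radii.
# Each square cell (period lambda) contains a circular funnel whose
# cross-sectional open area per layer encodes the layer weight; above
# r = lambda/2 the circle is clipped by the cell border.

#' Open area of a circular opening clipped to the cell square
#'
#' For a circle of radius `r` centred in a `lambda x lambda` cell, the open
#' area is `pi r^2` while the circle fits (`r <= lambda/2`) and the exact
#' circle-clipped-to-square area
#' `sqrt((2 lambda r)^2 - lambda^4) + (pi - 4 acos(lambda / 2r)) r^2`
#' for `lambda/2 < r <= lambda/sqrt(2)`; it is continuous at `lambda/2`,
#' strictly increasing, and reaches `lambda^2` at `lambda/sqrt(2)`.
#'
#' @param r Opening radius in mm (vectorized), `0 <= r <= lambda/sqrt(2)`.
#' @param lambda Cell period in mm.
#' @return Open area in mm^2.
#' @export
#' @examples
#' radius_to_area(2.5, 5)           # pi * 6.25
#' radius_to_area(5 / sqrt(2), 5)   # 25
radius_to_area <- function(r, lambda) {
  stopifnot(lambda > 0)
  if (any(r < 0) || any(r > lambda / sqrt(2) + 1e-12 * lambda))
    stop("radius must lie in [0, lambda/sqrt(2)]")
  r <- pmin(r, lambda / sqrt(2))
  out <- pi * r^2
  cl <- r > lambda / 2
  if (any(cl)) {
    rc <- r[cl]
    out[cl] <- sqrt(pmax((2 * lambda * rc)^2 - lambda^4, 0)) +
      (pi - 4 * acos(pmin(lambda / (2 * rc), 1))) * rc^2
  }
  out
}

#' Opening radius from an open area (Newton inversion)
#'
#' Inverse of [radius_to_area()]: closed form `sqrt(area / pi)` while the
#' result stays below `lambda/2`, otherwise safeguarded Newton iteration
#' (the derivative is the in-cell arc length `2 r (pi - 4 acos(lambda/2r))`,
#' which vanishes at `lambda/sqrt(2)`, so every step is clamped to a
#' shrinking bisection bracket). Round-trip error is below
#' `1e-10 lambda^2` in area.
#'
#' @param open_area Open area in mm^2 (vectorized), `0 <= a <= lambda^2`.
#' @param lambda Cell period in mm.
#' @return Radius in mm.
#' @export
area_to_radius <- function(open_area, lambda) {
  stopifnot(lambda > 0)
  if (any(open_area < 0) || any(open_area > lambda^2 * (1 + 1e-12)))
    stop("open area must lie in [0, lambda^2]")
  a <- pmin(open_area, lambda^2)
  r <- sqrt(a / pi)
  full <- a >= lambda^2
  r[full] <- lambda / sqrt(2)   # degenerate corner: derivative vanishes
  cl <- which(r > lambda / 2 & !full)
  if (length(cl)) {
    ac <- a[cl]
    lo <- rep(lambda / 2, length(ac))
    hi <- rep(lambda / sqrt(2), length(ac))
    x <- 0.5 * (lo + hi)
    for (iter in 1:100) {
      f <- radius_to_area(x, lambda) - ac
      lo[f < 0] <- x[f < 0]
      hi[f >= 0] <- x[f >= 0]
      fp <- 2 * x * (pi - 4 * acos(pmin(lambda / (2 * x), 1)))
      step <- ifelse(fp > 0, f / fp, 0)
      xn <- x - step
      bad <- !(xn > lo & xn < hi) | fp <= 0
      xn[bad] <- 0.5 * (lo[bad] + hi[bad])
      if (max(abs(f)) < 1e-13 * lambda^2 && max(hi - lo) < 1e-12 * lambda)
        break
      x <- xn
    }
    r[cl] <- x
  }
  r
}

#' Convert normalized weights to the layer stack of a cell
#'
#' Implements the telescoping area assignment: with `Aq = lambda^2`,
#' `A_i = Aq * sum_{k=i..i_top} w_k` (so `dA_i = Aq * w_i`, the hole at
#' zero thickness has area `Aq * w_0`, and `A_itop = Aq * w_itop`). The
#' opening radius at layer `i >= 1` realizes the open area `Aq - A_i`; the
#' hole radius realizes `Aq * w_0`.
#'
#' @param weights Normalized weight vector or the `weights` element of an
#'   [optimize_weights()] fit (carrying depths).
#' @param lambda Cell period in mm.
#' @param dt Depth spacing in g/cm^2 (only needed when `weights` is a
#'   plain vector).
#' @return An object of class `spe_layer_stack`: data frame with 0-based
#'   `i`, depth `t` (g/cm^2), remaining material area `A`, per-layer area
#'   `dA`, radius `r` (mm); attributes `lambda`, `Aq`.
#' @export
weights_to_layers <- function(weights, lambda = 5, dt = NULL) {
  if (is.list(weights)) {
    w <- weights$w; t <- weights$t
  } else {
    w <- weights
    if (is.null(dt)) stop("dt is required when weights is a plain vector")
    t <- (seq_along(w) - 1) * dt
  }
  if (any(w < 0)) stop("weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-8)
    stop("weights must be normalized to unit sum")
  aq <- lambda^2
  n <- length(w)
  A <- aq * rev(cumsum(rev(w)))          # A_i = Aq * sum_{k>=i} w_k
  dA <- aq * w
  open_area <- c(dA[1L], aq - A[-1L])    # hole, then Aq - A_i for i >= 1
  r <- area_to_radius(pmin(open_area, aq), lambda)
  stack <- data.frame(i = 0:(n - 1L), t = t, A = A, dA = dA, r = r)
  structure(stack, lambda = lambda, Aq = aq, class = c("spe_layer_stack",
                                                       "data.frame"))
}

#' Enforce the minimum printable hole diameter
#'
#' Raises the hole radius `r_0` to at least `min_diameter / 2` (100 um by
#' default, the smallest opening printable in steel) and restores radial
#' monotonicity by propagating the clamp upward through any layer it
#' overtakes. The clamp can only ever widen openings.
#'
#' @param stack An `spe_layer_stack`.
#' @param min_diameter Minimum hole diameter in mm.
#' @return The clamped stack; attribute `clamp_report` lists the number of
#'   layers touched and the total open-area perturbation in mm^2.
#' @export
clamp_hole <- function(stack, min_diameter = 0.1) {
  stopifnot(inherits(stack, "spe_layer_stack"), min_diameter >= 0)
  lambda <- attr(stack, "lambda")
  r_old <- stack$r
  r_new <- r_old
  r_new[1L] <- max(r_new[1L], min_diameter / 2)
  r_new <- cummax(r_new)
  touched <- sum(r_new > r_old + 1e-15)
  d_area <- sum(radius_to_area(r_new, lambda) -
                  radius_to_area(r_old, lambda))
  stack$r <- r_new
  attr(stack, "clamp_report") <- list(layers_touched = touched,
                                      open_area_added_mm2 = d_area,
                                      hole_diameter_mm = 2 * r_new[1L])
  stack
}
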