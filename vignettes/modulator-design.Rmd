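---
title: "Designing SPE beam modulators: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing SPE beam modulators: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spemod)
```

`spemod` designs passive range modulators that reshape a monoenergetic
proton beam into a solar-particle-event-like energy spectrum. This
vignette documents the physical models behind each stage, the parameters
that matter (with units and defaults), the choices made where the design
was genuinely open, and the limits of what the package's synthetic inputs
can demonstrate.

## 1. The analytic transport stand-in

Production designs of this kind are optimized on Monte Carlo base data: a
library of proton energy spectra scored at many depths in the modulator
material. `spemod` ships an analytic replacement adequate for the
features the optimizer actually consumes — peak position, peak width and
primary attenuation — and imports externally computed libraries
(`read_spectra_library()`) when full nuclear fidelity matters.

* **Stopping power.** The relativistic Bethe formula with the maximum
  free-electron energy transfer and no shell or density-effect
  corrections, valid for 1–300 MeV. Packaged constants: water
  Z/A = 0.5551, I = 75 eV; iron Z/A = 0.4656, I = 286 eV; "steel" is iron
  at the printed density of 7.9 g/cm³. Water CSDA ranges from this
  closed form agree with standard reference tables to about 0.1% over
  70–250 MeV.
* **Ranges.** `csda_range()` integrates 1/S(E) from a 1 MeV cutoff on a
  cached 0.05 MeV grid (cumulative trapezoid + monotone splines); the
  sub-cutoff residual is the constant E/(1.77·S) implied by the local
  power law R ∝ E^1.77. `residual_energy()` inverts the range spline, so
  range(E_res) + depth = range(E₀) holds to 1e-9 relative.
* **Straggling.** Bohr's energy-straggling rate with the standard
  relativistic factor, transported to range units by
  σ_R² = ∫ k(E)/S(E)³ dE. This grows monotonically from zero and sets the
  Gaussian peak widths of the library.
* **Nuclear interactions.** Primaries attenuate as exp(−t/Λ) with
  Λ = 132 g/cm² (iron/steel) or 85 g/cm² (water), the hadronic
  interaction lengths of those materials; a configurable fraction
  (default 0.5) of removed primaries reappears as a flat low-energy tail
  between 0 and the local residual energy. Depths at or beyond the
  primary range yield empty spectra. This is deliberately the simplest
  model with the right first moments; it does not reproduce quasi-elastic
  peak shapes, and backscatter has no analogue in a 1D model.

One known consequence of using path-length (CSDA) ranges: the projected
depth of a Bragg peak observed in a Monte Carlo or measured depth-dose
curve sits a few percent shallower than the CSDA range in a high-Z
material, because multiple scattering makes trajectories detour and
straggling plus attenuation shift the dose maximum upstream. For iron at
220 MeV the package's CSDA range is 43.8 g/cm², about 2.5% beyond the
42.7 g/cm² reference peak depth used for the design grids. The design
pipeline is unaffected — the depth grid is built from the configured
reference peak depth (`grids$t_peak_g_cm2 = 42.7`, giving the fine
spacing dt = 1.2·42.7/2400 = 21.35 mg/cm² exactly) — but comparisons of
`csda_range()` against projected peak depths inherit this offset.

**Grids.** Energies: 500 half-open, left-edge-labelled bins of 0.5 MeV
from 0 to 250 MeV. Depths: 77 coarse depths from 0 ("no target") to
1.2·t_peak, interpolated per energy bin (linearly in depth — spline
interpolation can undershoot zero on peaked columns, linear cannot) onto
2401 fine depths.

**Beam.** 220 MeV kinetic energy with a relative energy FWHM of 0.1%
(interpreted as an energy, not momentum, spread; FWHM = 2√(2 ln 2)·σ).
Peak spectra are integrated exactly over the bins via the Gaussian CDF,
so the near-monoenergetic entrance spectrum is binned without aliasing.

## 2. Foam broadening

A porous lung-substitute foam (LN300) upstream of the modulator smears
the beam's range with variance Pmod·t — the modulation-power model of
porous media — which smooths the otherwise very sharp spectra at shallow
modulator depths. The design block is 14 cm with water-equivalent
thickness 4000 mg/cm² and Pmod = 35 mg/cm² (water); an
`experiment_ln300` preset (20 cm, 5760 mg/cm², Pmod 21 mg/cm²,
equivalent density 0.288 g/cm³) describes the thicker block used in
beam-time verification.

`convert_foam()` rescales both water-side parameters by one
range-equivalence factor — the ratio of material to water thickness
producing the same residual energy for the design beam — and recomputes
σ = √(Pmod·tm). `broaden_library()` then convolves the library over
depth with a Gaussian centred `tm` deeper than the output depth. The
normalization constant of the kernel is fixed by requiring unit kernel
sum per output depth: that conserves fluence exactly, makes the σ → 0
limit an exact shift, and handles the truncated kernels at the grid
boundary gracefully. The kernel is truncated at ±5σ (mass loss < 1e-6
before renormalization); source depths beyond the grid reuse the last
spectrum, which avoids artificial edge dips (those spectra are empty
anyway beyond the range). A kernel narrower than half the depth spacing
triggers a warning (under-resolved) but is still computed.

The shift direction — output depth i samples input depths around
i + tm/dt — reflects that material placed upstream *adds* to the depth a
proton has effectively traversed: the broadened entrance spectrum is
wider than, and shifted below, the bare beam energy. Both properties are
asserted in the tests.

## 3. Weight optimization

The reconstruction `SPE_opt[j] = Σ_i SpcF[i, j]·w_i` is linear in the
weights, and the objective is the plain sum of squared residuals over the
window (energy bins 80–406, i.e. 40–203 MeV; depth indices 0–1700, i.e.
0–36.3 g/cm² — the upper window edge is exposed as configuration because
the adaptation range is usually quoted as 40–200 MeV while the last
optimized bin starts at 203 MeV). Direct optimization of 1701 weights on
a 0.5 MeV grid oscillates; instead only subset nodes are free and the
full vector is their linear interpolation over the depth index
(positivity-preserving, no overshoot).

Design choices here, and why:

* **Node placement.** The depth-to-energy mapping is strongly nonlinear:
  the last few g/cm² of depth sweep the whole 40–100 MeV region, while
  the first 10 g/cm² cover only ~220 → 180 MeV. Nodes equidistant in the
  *peak-energy coordinate* of the broadened library (the default,
  `node_placement = "energy"`) therefore keep the interpolation error of
  the weight profile roughly uniform across the reconstructed spectrum.
  With 32 nodes the node-to-node energy step is ~5 MeV and the
  scalloping of an exponential target stays at the percent level;
  index-spaced nodes (`node_grid()`) concentrated near depth 0 produced
  15–30% mid-band scalloping and are kept only as an option.
* **Solver.** With the node parameterization the problem is convex
  non-negative least squares in ≤ 32 variables; it is solved exactly by
  the Lawson–Hanson active-set algorithm (`pracma::lsqnonneg`) rather
  than iteratively. The deterministic warm start (node values
  proportional to the target fluence at each node spectrum's peak
  energy, amplitude-matched) is still evaluated and reported, so the
  monotone-improvement property is testable; `seed` is accepted for
  configuration symmetry but nothing is random.
* **Residual weighting.** The objective follows the plain squared
  residual definition by default. Because the target spans four decades,
  plain least squares effectively fits the low-energy end hardest; a
  relative weighting (residuals divided by SPE_j + ε) is exposed as
  `weighting = "relative"` for targets where the tail matters more.
* **Normalization.** Weights are normalized to Σw = 1 after the fit (the
  fitted amplitude is reported as `scale`); non-negativity is enforced
  because the weights become physical areas.

For the packaged synthetic target the reconstruction stays within ~4% of
the target over 40–100 MeV. The largest relative deviations (~30%) sit in
the last few bins below 203 MeV: the primary loses ~20 MeV in the design
foam, so no superposition of broadened spectra can populate energies
above ~200 MeV. The fluence there is four orders of magnitude below the
40 MeV level, so the effect on any integral quantity is negligible.

## 4. Funnel geometry and meshing

`weights_to_layers()` applies the telescoping assignment ΔA_i = Aq·w_i in
a λ² cell (λ = 5 mm by default — a compromise between printable aspect
ratios and the distance needed to blur the lateral pattern). The open
area at layer i ≥ 1 is Aq·Σ_{k<i} w_k, and the zero-thickness opening
(the hole) has area Aq·w₀. Open areas map to radii through the
circle-clipped-to-square formula; its inverse uses the closed form below
λ/2 and safeguarded Newton above (the derivative, the in-cell arc length
2r(π − 4 acos(λ/2r)), vanishes at λ/√2, so each Newton step is clamped
into a shrinking bisection bracket; the exact top endpoint is
special-cased). Round-trip accuracy is below 1e-10·λ² in area.

`clamp_hole()` raises the hole to the printable minimum (100 µm diameter,
the resolution limit of selective laser melting in steel, also needed
because the beam arrives with ≥ 13 mrad divergence from foam scattering)
and propagates the clamp upward to restore radial monotonicity; the clamp
can only widen openings, and the induced open-area perturbation is
reported.

**Meshing.** Because the radius profile r(z) is monotone, the whole
beam-facing boundary of the cell solid is a continuous height field over
the cell cross-section. The mesh is built as one "terrain" sheet (funnel
wall plus flat entry face, with funnel stations clamped onto the cell
border where the circle is clipped — clamped stations collapse to shared
border vertices, so the sheet is crack-free by construction), a planar
exit face (square minus hole disc), a cylindrical 100 µm channel
connecting the terrain rim to the exit plane, and outer side walls whose
top edges follow the terrain rim. Arrays are meshed as a single periodic
terrain: interior cell walls never exist, so no coincident-wall merging
is needed and the result is watertight and 2-manifold (asserted by edge
accounting: every undirected edge shared by exactly two triangles).

Mesh resolution defaults: 64 angular segments (a multiple of 8 so cell
corners are exact grid points) and 20 µm radius decimation — the printer
resolution; there is no point meshing features the process cannot
produce. Both are configurable (1 µm decimation roughly octuples the
triangle count). The angular polygonization makes the meshed funnel an
inscribed polygon, biasing the solid volume up by at most
(2π²/3)/64² ≈ 0.16% of the air volume; the tests compare mesh volume
against the trapezoid integral of the open-area profile at 1%. The
default 8×8 array is ~0.7 M triangles (≈ 35 MB binary STL). Coordinates:
z = 0 at the beam entry face, z increasing along the beam, mm units; no
base plate is added by default (`assemble_array()` output is the bare
modulator).

## 5. Forward verification

* **Depth dose.** Dose is fluence × mass stopping power, so the water
  depth-dose profile of a spectrum is the fluence-weighted superposition
  of per-bin Bragg curves: the stopping power along the slowing-down
  trajectory, convolved over range with the Bohr straggling accumulated
  to the full range. Each 0.5 MeV bin is a uniform fluence slice, so its
  range signature is a boxcar, not a Gaussian; bins are additionally
  subdivided (4 sub-energies by default) because representing a bin by
  its centre-energy curve alone leaves ~1% bin-structure ripples where
  the peaks are sharp. A smoothing floor of 1.5 grid steps (default
  dx = 0.02 g/cm²) suppresses sampling aliasing. Profiles are normalized
  at 10 g/cm², the convention used when comparing modulator depth-dose
  measurements; a `dead_material` offset records the water-equivalent
  budget of tank walls and detector cover in the depth axis. Nuclear
  buildup in the phantom is not modelled (an optional exponential
  primary attenuation is available); for an exponentially falling SPE
  spectrum the resulting profile decreases monotonically beyond
  2 g/cm², which the tests assert.
* **Lateral homogeneity.** After Gaussian blur of width σ, the
  fundamental of any λ-periodic pattern survives with amplitude
  exp(−2π²σ²/λ²) — an upper bound on the relative ripple, since higher
  harmonics decay much faster. For the 8.1 mm FWHM beam over λ = 5 mm
  this gives 8.8e-5, comfortably below the 0.1% homogeneity threshold.
  The analytic factor is cross-validated in the tests against direct
  periodic convolution of a 50%-duty square wave (agreement within 5%
  for FWHM/λ between 0.2 and 1.6). `blur_vs_distance()` composes
  σ = distance × scattering angle with this bound; the 13 mrad default
  is a *lower bound* on the post-foam divergence, so the distance at
  which the report declares homogeneity (~23 cm at 13 mrad for a 0.1%
  threshold) is conservative — in practice in-modulator scattering and
  the beam's own width blur the pattern within 5–10 cm.

## 6. What the synthetic inputs do and do not show

The true August-1972 SPE tabulation exists in the literature only as a
figure, so the packaged target `spe1972_like()` is an explicit synthetic
stand-in: a pure exponential whose e-folding energy (160/ln 10⁴ ≈
17.4 MeV) makes the differential fluence fall four orders of magnitude
between 40 and 200 MeV, the dynamic range characteristic of that event
over the design window. Any user tabulation (two-column TSV) is accepted
and resampled log-linearly — linear interpolation in log-fluence, the
appropriate scheme for spectra spanning decades; linear interpolation of
the raw fluence would bias the steep tail.

Passing tests on this fixture demonstrate that the chain — transport,
broadening, unfolding, geometry, meshing, verification — is internally
consistent and that a smooth, steeply falling target is reproducible to
a few percent. They do not demonstrate fidelity to a real SPE field: the
analytic library lacks genuine secondary-proton spectra and angular
effects (the optimization is strictly longitudinal), real SPE spectra
deviate from a single exponential, and manufacturing realities (the
cylinder-like final segment of the printed hole) add high-frequency
structure at the top of the spectrum that a 1D model cannot predict.
Designs intended for an actual beam line should re-run the optimization
on an imported Monte Carlo library and confirm with a full transport
simulation and a measured depth-dose profile.

## 7. Problem sizes and reproducibility

The default configuration (full 2401-depth library, 500 bins, 32 nodes,
8×8 cells at 64 segments) runs the entire design in well under a minute
on one core; the test suite exercises the module properties on reduced
problem sizes (a 100 MeV water library with 241 depths and 120 bins, 2×2
or 3×3 arrays at 16–32 segments) chosen so the whole suite completes in
tens of seconds, and runs the full-scale design case once in the
acceptance tests. All pipeline outputs are plain text written with fixed
formatting, so reruns under the same configuration are byte-identical;
the only stochastic elements anywhere are the random instances inside
the test suite, which are seeded.
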