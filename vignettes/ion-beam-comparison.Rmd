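---
title: "Comparing therapy ions on depth-dose, LET and DSB-based RBE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing therapy ions on depth-dose, LET and DSB-based RBE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sobpr)
```

# The question

Protons and carbon ions are in clinical use; helium, lithium, beryllium and
boron are candidates. Their trade-offs live in three depth-resolved curves:
the physical dose (entrance and tail burden versus target dose), the
dose-averaged linear energy transfer (LET_d), and the relative biological
effectiveness indexed by DNA double-strand-break (DSB) induction
(RBE_DSB). `sobpr` builds all three for single-field spread-out Bragg
peaks (SOBPs) and compares species after either physical or biological
weight optimization. The reference geometry throughout is a 5-cm target
lying at 8 cm depth (80–130 mm) in a 20-cm water phantom, scored in 1-mm
depth bins.

# Transport model

Each mono-energetic beam is transported analytically:

* **Range–energy closure.** Stopping powers S(E, Z) in water come from
  bundled per-species tables (log-log interpolated, never extrapolated).
  The tables are a synthetic coarse parameterization approximating
  published stopping powers of protons in water to a few percent, scaled to
  heavier species by Barkas effective charge,
  Z_eff = Z(1 − exp(−125 β Z^(−2/3))); the same scaling serves as runtime
  fallback for fragment species without tables. Integrating A·dE/S gives
  CSDA ranges, fitted by the Bragg–Kleeman law R = α (A·E)^p over
  20–300 MeV/n (the fit reproduces the integrated ranges to better than 2 %
  over 50–200 MeV/n for protons, a property the test suite checks).
* **Straggling.** A primary's range is Gaussian, R ~ N(R0, σ_R) with
  σ_R = f_s · R0. Mapping the straggled residual range through the
  range–energy relation yields the per-depth energy spectrum: the spectral
  width automatically grows toward the peak as dE/dR diverges. The default
  f_s = 0.012/√A is the Bohr scaling anchored at the accepted 1.2 % of
  range for protons; carbon peaks are therefore intrinsically ~3.5× sharper.
* **Ripple filter.** Depth-convolution with a Gaussian kernel,
  renormalized at the phantom edges so the depth-integrated dose is
  conserved to 10⁻⁶. The default sigma is chosen per species to bring every
  peak to a common total width of 1.5 mm at the distal edge of the
  geometry: protons, whose native straggling already exceeds that, get no
  filter — as in clinical practice — while carbon receives nearly the full
  1.5 mm. A common peak width is what permits the uniform ~2-mm range
  spacing of the beam library.
* **Nuclear attenuation and fragmentation.** Primary fluence decays as
  exp(−z/λ) with interaction lengths (mm) of ∞ (p), 400 (⁴He), 320 (⁷Li),
  260 (¹⁰Be), 240 (¹⁰B) and 220 (¹²C), i.e. ≈55 % of carbon primaries
  survive to 13 cm, consistent with measured carbon attenuation in water.
  Lost primaries convert to single-generation fragments (production
  fractions per channel), created with the primary's velocity and
  transported ballistically with their own range–energy relation. Fragments
  with smaller Z²/A than the primary overshoot its range — that is the
  entire dose tail. The ⁴He channels are dominated by protons of equal
  A/Z², which have the same range as the primary, so its tail is
  negligible by construction.

The per-depth spectra are scored into 100 log-spaced energy bins between
0.5 MeV/n and 1.2× the highest beam energy (one shared grid per library so
mixed fields can be summed). The *depth-dose* of a peak is evaluated in the
continuum limit of the fluence × stopping-power product — an 81-node
quadrature over the straggled range distribution — rather than from the
binned spectrum: at 100 bins the binned sum is a ~4 % staircase in depth,
which is harmless for the ratio quantities (LET_d, RBE) but destabilizes
the weight optimization. Sub-grid residual energies (< 0.025 MeV/n, the
last ~0.01 mm of path) are dropped.

# LET and RBE aggregation

Dose per cell is D(E_j, Z_i) = Φ(E_j, Z_i) · S(E_j, Z_i) at bin-center
energies. LET_d(z) is the dose-weighted mean stopping power over all
contributing cells; it is scale-invariant in Φ and bounded by the extreme
stopping powers present, properties the tests assert against brute-force
loop oracles. Depth bins without dose report a missing value, never zero,
so downstream curves cannot fabricate LET or RBE in the far tail.

RBE_DSB uses a yield surrogate in place of a track-structure damage code:

yield(E, Z) = Y_Co60 · (1 + 2.2 · (1 − exp(−x/733))),  x = (Z_eff/β)²

with Y_Co60 = 8.28584 DSB Gbp⁻¹ Gy⁻¹ the Co-60 reference. The form is the
standard track-structure scaling variable with a saturation cap near
3.2 · Y_Co60, as damage-simulation yields show for stopping heavy ions; the
two constants were calibrated once against published proton RBE_DSB
anchors (1.07/1.13/1.26 at dose-averaged LET of 2–3/3–6/6–9 keV/µm), which
the acceptance suite re-derives end to end rather than asserting from the
table. Yields are tabulated at 17 log-spaced energies per species
(0.2–1000 MeV/n, bundled as a CSV fixture regenerable by
`synthetic_yield_model()`) and interpolated log-log. Only the
well-oxygenated case is modelled. Per-species RBE_i is the dose-weighted
mean yield over the species' local spectrum divided by Y_Co60; the total
RBE_DSB is the dose-weighted convex combination over species. A species
present in the field but missing from the yield tables is a hard error:
silently dropping its dose would bias the aggregate.

Two readings of ambiguously typeset source formulas are fixed here: the
reference yield divides the dose-weighted mean yield (the only reading that
gives RBE = 1 for a photon-equivalent field), and the biological dose uses
the *total* RBE profile, not a single-species one.

# Weight optimization

The physical mode solves min ‖A f − p‖², f ≥ 0, where A's columns are the
library's depth-dose curves on the region bins and p is the flat
prescription. Overlapping Bragg-peak columns are nearly collinear, so many
weight vectors reach almost the same residual; `nnls_weights()` therefore
adds a minimum-norm tie-break (a ridge of 10⁻⁴ of the mean squared column
norm) that biases the region fit by well under 0.1 % of prescription while
excluding degenerate solutions with inflated weights. Weight-space
uniqueness is *not* claimed — the tests assert recovery in dose space.

The biological mode iterates: compute RBE_DSB(z) for the current weights,
re-solve against per-bin targets p/RBE(z), repeat until the maximum
relative weight change drops below 10⁻³ (defaults: at most 50 iterations;
non-convergence is a reported error with the residual history, never a
silent result). RBE varies smoothly with the weights, so convergence takes
a handful of iterations; the fixed point is verified idempotent, and with a
uniform-yield model (RBE ≡ 1) the iteration reproduces the physical plan
after one step.

Both modes enforce the 95–107 % homogeneity window on their respective dose
(physical or biological) at every region bin and raise a diagnostic with
the achieved range otherwise.

# Flatness, width and the region convention

"Lying at a depth of 8 cm" is read as the proximal edge of the 5-cm target,
i.e. the optimization region is 80–130 mm and ratio curves normalize at the
105-mm bin; both are configurable. The beam library tiles ranges across
[78, 132] mm (a 2-mm margin each side) at ≤ 2-mm spacing so the edge bins
are controllable.

`flatness_metrics()` reports min/max dose over the region, the width
between the linearly interpolated 95 %-of-prescription crossings, the
SOBP-mean/entrance ratio (entrance = mean of the first 5 bins, robust to
the first-bin edge), and the tail ratio (mean dose 2–10 mm past the distal
edge). A curve that never reaches 95 % reports width 0 with a degeneracy
flag. One systematic of this 1-D model is worth stating: the measured
95 %-to-95 % width slightly exceeds the nominal 50 mm, most for the
heaviest ions. Attenuation-boosted distal weights raise the heavy-ion
proximal shoulder to ~92 % of prescription just before the target, so the
proximal 95 % crossing sits a few mm early; real beams temper this shoulder
through lateral scattering, which a depth-only model cannot represent. The
test suite computes these widths and records the exceedance rather than
masking it.

# What the synthetic beams do and do not emulate

Emulated: Bragg-peak shape and range ordering across species, spectrum
broadening with depth, the fragmentation dose tail and its Z-ordering, the
LET_d rise at the distal edge, RBE ordering and magnitudes in the
therapeutic window, SOBP stacking with ripple-filtered peaks.

Not emulated: lateral scatter and penumbra (all curves are per unit fluence
on the axis; scored fields in measured data are finite), neutron dose,
higher-generation fragmentation, energy-loss fluctuations beyond a Gaussian
range model, cell-line-specific response (repair kinetics, oxygen effect),
and multi-field plans. Passing tests therefore validate the pipeline's
internal consistency and its agreement with the published scalar anchors,
not dosimetric fidelity of any single absolute curve.

# Numerical choices and degenerate inputs

* 1-mm half-open depth bins [k−1, k), centers at (k−0.5) mm; all width
  measurements interpolate linearly between bin centers.
* Stopping power at energy-bin centers (geometric mean of the edges); with
  100 log bins the bin-center bias is below the few-percent level of the
  ratio quantities.
* Log-log interpolation everywhere (stopping power, yields); queries
  outside a table raise range errors rather than extrapolating.
* The 4He profiles are masked beyond 2 mm past the distal edge by default
  (`mask_helium_tail`), mirroring how tail values whose relative
  uncertainty would exceed 10 % in a Monte Carlo estimate are suppressed;
  a flag unmasks them.
* Zero-dose bins propagate as missing values through LET, RBE, biological
  dose and ratio curves; ratio curves additionally require a positive
  denominator at the normalization bin.
* Everything is deterministic: identical configurations export
  byte-identical CSVs, which the tests check.

# Problem sizes

The shipped study conditions are the reference geometry themselves: ~32
beams per species, 200 depth bins, 100 energy bins, six species, physical
plus biological optimization — a full comparison runs in seconds on one
core, so tests and the acceptance script run the real conditions rather
than scaled-down ones.

# Known limitations

The stopping-power fixtures are deliberately coarse (a few percent of
published values); users with full PSTAR/ASTAR/MSTAR tables can load them
via `load_nist_table()` (total versus collision column selectable — the
default is total). The fragmentation model conserves neither charge nor
energy channel-by-channel (unscored neutrals carry the remainder), and its
production fractions are stylized constants. The yield surrogate is
calibrated to proton anchors and a heavy-ion saturation cap; per-species
yield data would sharpen the heavy-ion RBE magnitudes. None of these
affect the package's comparative statements qualitatively, but absolute
values — especially in the fragment tail — should be read as
model-relative.
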