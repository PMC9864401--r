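# sobpr

Radiobiological comparison of light-ion beams forming spread-out Bragg peaks
(SOBPs), for medical physicists and computational radiobiologists who want a
fast, fully deterministic sandbox for depth-dose, LET and RBE trade-offs
between candidate therapy ions (p, ⁴He, ⁷Li, ¹⁰Be, ¹⁰B, ¹²C).

The package replaces a Monte Carlo transport + track-structure tool chain
with an analytic, tested pipeline:

1. **Beam transport** — pristine Bragg peaks in a 20-cm water phantom on a
   1-mm grid, built from Bragg–Kleeman range–energy fits to bundled
   stopping-power tables, with Gaussian range straggling, ripple-filter
   smearing and a single-generation nuclear fragmentation model that
   produces the characteristic dose tail of heavy ions.
2. **Dose-averaged LET** — from the per-depth energy-fluence spectra
   Φ(E_j, Z_i) of all primaries and fragments:

   LET_d(z) = Σ_ij D(E_j,Z_i) · S(E_j,Z_i) / Σ_ij D(E_j,Z_i),
   with D = Φ · S and S = dE/dx the stopping power in water.

3. **DSB-based RBE** — per-species RBE as the dose-weighted DNA
   double-strand-break yield over the local energy spectrum, normalized to
   the Co-60 reference yield (8.28584 DSB Gbp⁻¹ Gy⁻¹), and the total
   RBE_DSB(z) as the dose-weighted mean over species (well-oxygenated
   cells; yields come from a calibrated track-structure surrogate).
4. **SOBP weight optimization** — non-negative least squares for the beam
   weights f_i of D(z) = Σ_i f_i D_i(z), targeting a homogeneous
   (95–107 %) *physical* dose, or a fixed-point iteration targeting a
   homogeneous *biological* dose D_bio(z) = D_phys(z) × RBE_DSB(z).
5. **Study pipeline** — all six species end to end, with flatness/width
   metrics, center-normalized dose-ratio curves (e.g. ⁷Li/¹²C) and CSV
   exports; a thin command-line wrapper lives in `inst/cli/sobp.R`.

## Worked example

```r
library(sobpr)

lib  <- build_library(beam_species()$`12C`)     # 5-cm target at 8 cm depth
plan <- optimize_physical(lib)
field <- mixed_field(plan, lib)

flatness_metrics(field$dose)
#> <flatness_report> [99.9, 100.1]% of prescription, width 54.4 mm,
#>                   SOBP/entrance 1.28, tail 0.208

rbe_profile(field$fluence, default_yield_model(), default_sp_provider())
#> <rbe_profile> 200 depth bins (200 defined), total RBE 1.213-2.622

let_profile(field$fluence, default_sp_provider())
#> <depth_profile> LET_d [keV/um]: 200 bins (200 defined), max 170.2
```

Reading: the optimized carbon SOBP is flat to ±0.1 % of prescription over
80–130 mm; its entrance dose is 1/1.28 ≈ 78 % of the plateau and the
fragment tail just past the target carries ≈ 21 % of the prescription.
RBE_DSB climbs from 1.2 at the entrance to 2.6 at the distal edge, where
the dose-averaged LET of the slowing carbon ions peaks. Swapping
`optimize_biological()` for `optimize_physical()` flattens
dose × RBE instead, which lowers the distal physical dose.

The full six-species comparison is one call:

```r
bundle <- run_beam_study(study_config())
export_study(bundle, "sobpr_out")
```

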