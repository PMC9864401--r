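# Regenerates the plain-text fixtures under inst/extdata/.
#
# The proton stopping-power anchors below are a synthetic coarse
# parameterization approximating published stopping powers of protons in
# liquid water to a few percent over 0.025-1000 MeV (constructed by hand, not
# NIST data; hence the *_synthetic.csv naming). Heavier-species tables are
# produced from the proton curve by Barkas effective-charge scaling at equal
# energy per nucleon, the same fallback formula the package applies at query
# time when no species table is loaded. The DSB-yield fixture is a snapshot
# of synthetic_yield_model().
#
# Run from the repository root:  Rscript tools/generate_fixtures.R

pkg <- "."
for (f in list.files(file.path(pkg, "R"), full.names = TRUE)) source(f)

out_dir <- file.path(pkg, "inst", "extdata")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

# energy (MeV = MeV/n for protons), mass stopping power (MeV cm^2/g)
proton_anchors <- data.frame(
  energy = c(0.025, 0.04, 0.06, 0.08, 0.10, 0.15, 0.20, 0.30, 0.50, 0.70,
             1.0, 1.5, 2.0, 3.0, 5.0, 7.0, 10, 15, 20, 30, 50, 70, 100,
             150, 200, 250, 300, 400, 500, 700, 1000),
  mass_sp = c(640, 730, 790, 810, 800, 730, 660, 545, 417, 343,
              260.8, 199, 159.1, 117.1, 79.1, 60.4, 45.67, 33.0, 26.07,
              18.76, 12.45, 9.56, 7.289, 5.445, 4.492, 3.911, 3.52, 3.03,
              2.743, 2.43, 2.211)
)

proton <- sp_table(ion_species("1H", 1L, 1L),
                   proton_anchors$energy, proton_anchors$mass_sp * 0.1)
write_sp_table(proton, file.path(out_dir, "stopping_power_1H_synthetic.csv"))

for (s in beam_species()[-1]) {
  scaled <- sp_table(s, proton$energy,
                     effective_charge_stopping(s, proton$energy, proton))
  write_sp_table(scaled, file.path(
    out_dir, sprintf("stopping_power_%s_synthetic.csv", s$symbol)))
}

write_yield_table(synthetic_yield_model(),
                  file.path(out_dir, "dsb_yields_synthetic.csv"))

cat("fixtures written to", out_dir, "\n")
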