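Package: sobpr
Title: Radiobiological Comparison of Ion Beams Forming Spread-Out Bragg Peaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing light-ion beams (protons through carbon) for
    particle therapy at the depth-dose level. Generates analytic pristine
    Bragg peaks with range straggling, ripple-filter smearing and a simplified
    single-generation fragmentation model in a water phantom; computes
    dose-averaged linear energy transfer and DNA double-strand-break based
    relative biological effectiveness (RBE) versus depth from per-depth energy
    fluence spectra; optimizes spread-out Bragg peak (SOBP) beam weights by
    non-negative least squares for a homogeneous physical or biological dose;
    and runs a full multi-species comparison study with CSV exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    pracma,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
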