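Package: helixtomo
Title: Helical Filament Analysis for Cryo-Electron Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of helical filaments in cryo-electron
    tomograms of cellular protrusions: synthetic scene generation
    (microtubule lattices, luminal actin/cofilactin filaments, noise and a
    missing wedge), per-filament classification-vote calling of microtubule
    protofilament number and polarity, Fourier layer-line measurement of
    filament cross-over distances, real-space helical-symmetry grid search
    (twist/rise), Fourier shell correlation, and summary statistics for
    luminal-filament occupancy, coverage and orientation. Reads and writes
    MRC density volumes and STAR/TSV particle tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), optparse, jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
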