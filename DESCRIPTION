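Package: psmclock
Title: Physical Model of the Zebrafish Segmentation Clock in a Deforming Presomitic Mesoderm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulator of the zebrafish segmentation clock: locally
    coupled noisy phase oscillators carried by mechanically interacting cells in a
    U-shaped presomitic mesoderm (PSM) and tailbud domain that can shorten, narrow
    and change its advection pattern over developmental time. Includes the
    measurement machinery used to compare such simulations with embryos: local
    Kuramoto phase order in thin axial slices, off-lattice phase-vorticity
    detection, segment-boundary detection and scoring (anterior limit of defects,
    first recovered segment, posterior limit of defects), defect-run statistics and
    a left-right independence model of single versus double segment defects.
    Synthetic phase-field and segment-record generators are provided as fixtures,
    together with a small command-line interface for running simulations, computing
    observables and scoring segment records.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp (>= 1.0.0), jsonlite, yaml, stats, utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
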