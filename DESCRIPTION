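Package: racpax
Title: Multi-Timescale Rac-Rho-Paxillin Dynamics and Cellular Potts Migration Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Models mesenchymal cell migration driven by Rho-GTPase signalling.
    Implements a three-timescale Rac-Rho-paxillin kinetics model (six-, two- and
    four-variable forms) producing mixed-mode and relaxation oscillations, a 1D
    periodic-domain reaction-diffusion solver exhibiting wave-pinning, a
    single-cell Cellular Potts simulator whose protrusion energy is driven by
    membrane active Rac, trajectory and binary-mask metrics (instantaneous
    speed, MSD exponent, directionality ratio, membrane activity, event
    detection), and a small neural classifier assigning paxillin-phenotype
    labels (WT-like, S273A-like, S273D-like) from track metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
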