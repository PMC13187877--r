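Package: vedmap
Title: Vibrational Energy Diffusivity and Communication Maps for Coarse-Grained Protein Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Normal-mode analysis of elastic-network and bead-spring protein
    models, Allen-Feldman vibrational energy diffusivity with frequency-band
    averaging, residue-residue communication maps at multiple temperatures,
    harmonic heat capacity, trajectory stability metrics (RMSD, RMSF, salt
    bridges, hydrogen bonds), and constant-velocity steered pulling of
    coarse-grained chains with breakable cross-links and rupture analysis.
    Includes synthetic-structure generators (helices, homolog pairs differing
    by a phospho-like modification and cross-link count, harmonic trajectories)
    so the full pipeline is testable without external structure files, plus a
    brute-force wave-packet oracle for independent validation of the
    mode-diffusivity calculation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
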