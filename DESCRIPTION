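Package: tmdscan
Title: Transmembrane Helix Delimitation by Sliding-Window Stochastic
    Peptide Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Delimits single-spanning helical transmembrane domains from
    sequence alone.  A 19-residue window slides along the target sequence;
    each window peptide is modelled by a Boltzmann-stochastic search over a
    64-state backbone phi/psi alphabet scored with an all-atom non-bonded
    energy (Lennard-Jones, Coulomb with a distance-dependent dielectric,
    and an atomic hydrophobicity term), and the 99 best-energy models per
    window are retained.  Models are scored for helicity, the ratio of
    hydrophobic to hydrophilic solvent-accessible surface area (ASAr),
    membrane insertion depth in an implicit DPPC bilayer, and a calibrated
    residue-environment (mean-force-potential) percentage.  Per-residue
    aggregation of these descriptors across windows, optionally averaged
    over homologous sequences from several species, locates the membrane
    center residue and the domain limits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
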