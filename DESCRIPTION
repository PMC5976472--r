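Package: pepscape
Title: Conformational Ensemble Analysis for Short Peptide Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of conformational ensembles of short peptides sampled by
    (scaled) molecular dynamics: backbone and side-chain torsion extraction,
    Kabsch-Sander secondary-structure timelines, hydrogen-bond, side-chain
    contact and aromatic-interaction occupancy tables, population reweighting
    of lambda-scaled trajectories, free-energy surfaces over Ramachandran
    coordinates, dihedral principal component analysis with density peak
    clustering, and least-squares structural superposition. Includes an
    internal-coordinate peptide builder and a two-state torsion simulator so
    that every stage can be exercised against synthetic trajectories with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
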