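Package: odorspace
Title: Structure-Odor Relationship Analysis via Chemical-Space Clustering
    and Common-Feature Pharmacophores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing structure-odor relationships in odorant
    databases. Molecules described by SMILES and verbal odor notes are
    encoded as extended-connectivity fingerprints, embedded into a
    three-dimensional chemical space with UMAP, and partitioned with
    k-means or self-organizing maps, with cluster-number selection by
    elbow curve and Kelley penalty. Per-cluster odor-note profiles and
    note co-occurrence matrices summarise how odor vocabulary distributes
    over chemical space. Rule-based selection extracts subsets of
    molecules with odor profiles similar to a reference odorant, and an
    open common-feature pharmacophore engine (hydrogen-bond acceptor,
    hydrophobic and aromatic-ring features over force-field conformer
    ensembles, with transparent scoring and pairwise hypothesis alignment
    by least-squares superposition) characterises their shared 3D feature
    geometry. A synthetic odorant-database generator with known
    structural families and family-conditional note distributions
    supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    uwot,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    mclust,
    testthat (>= 3.0.0),
    withr
SystemRequirements: OpenBabel (obabel on PATH), Python 3 with RDKit
    (python on PATH) for conformer generation
Config/testthat/edition: 3
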