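Package: haplodyn
Title: Haplotype-Aware Protein Variant Scoring and Molecular Dynamics Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An integrative toolkit linking common protein-coding haplotypes to
    protein structural dynamics. Enumerates transcript-level haplotypes from
    phased genotypes and translates them into protein sequences; scores variant
    sequences with a pseudo-log-likelihood ratio under a pluggable ensemble of
    per-position sequence scorers; and quantifies structural and dynamic
    differences between protein variants from molecular-dynamics trajectories
    using a metric suite built around simplified secondary-structure
    assignment, ordered fractions, kink angles, occurrence-weighted protein
    structure networks with Jaccard comparison, essential-dynamics subspace
    overlap (PCA/RMSIP), density-peaks clustering of dihedral and interface
    featurizations, and moving-block-bootstrap uncertainties aware of
    autocorrelation. Ships a synthetic-data module that generates phased
    panels, toy scorers, helix/coil backbone trajectories with planted
    contacts, and AR(1) series with known ground truth for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml,
    Biostrings,
    vcfR
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
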