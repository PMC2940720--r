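Package: coevomut
Title: Residue Co-Evolution and Disease-Mutation Enrichment in Protein Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects co-evolving residue pairs in ortholog multiple sequence
    alignments with the OMES (Observed Minus Expected Squared) statistic and
    tests whether correlated positions are enriched in disease-associated
    point mutations. Provides alignment filtering (coverage, redundancy,
    cluster-size gating, capped subsampling), BLOSUM62 and fractional-identity
    column conservation scores, structural contact maps and solvent
    accessibility stratification, evolutionarily tolerated (benign)
    substitution extraction, and a log-odds (LOD) enrichment framework with
    Fisher's exact tests, permutation nulls and alignment-column bootstraps.
    A synthetic-data generator plants co-evolving column pairs, conserved
    columns, label enrichment and toy 3D structures with known ground truth
    for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
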