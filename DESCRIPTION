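Package: virosig
Title: Gut Virome Disease-Signature Analysis for Case-Control Metagenomic Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for metagenome-wide analysis of the human gut virome in
    case-control cohorts: construction of a nonredundant viral operational
    taxonomic unit (vOTU) catalogue from alignment evidence, protein-voting
    family annotation and auxiliary-metabolic-gene (AMG) labelling,
    CRISPR-spacer and homology based virus-host prediction, rarefied
    community profiling with diversity, ordination and PERMANOVA, a
    two-cohort Wilcoxon/Fisher differential-abundance meta-analysis yielding
    disease-associated vOTUs, a virus-bacterium dependency network built
    from host links, SparCC co-abundance and Fisher co-occurrence, and a
    cross-cohort consistency-rate transfer analysis with permutation tests
    and random-forest classification. Includes a seeded synthetic-data
    generator with planted structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    Biostrings,
    randomForest,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
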