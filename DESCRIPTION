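Package: phragpath
Title: Pathogenicity Bioassay Scoring and Literature Microbiome Meta-Analysis for Phragmites australis
Version: 1.0.0
Authors@R: person("Phragpath", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for scoring plant-microbe pathogenicity bioassays on common
    reed (Phragmites australis) and for meta-analysing literature reports of
    the reed microbiome. Implements a count-weighted leaf disease index on a
    0-4 ordinal scale, through-origin regression standardization to 10-day
    disease-index values with death-truncation and age-exclusion rules,
    mature-leaf lesion scoring on a 0-1 scale, and threshold-based
    pathogenicity classification. Provides self-contained implementations of
    paired t-tests with Bonferroni correction, Bray-Curtis dissimilarity,
    one-way permutational multivariate analysis of variance (PerMANOVA) and a
    group-dispersion check; literature-report lineage and tissue
    classification rules, community filters, taxon-overlap and coverage
    computations; fungal trophic-mode assignment from a local guild lookup
    table and Pathogen:Endophyte:Saprophyte ratio summaries; barcode-hit
    screening, WPGMA clustering and fixed-threshold species-hypothesis
    clustering; plus a seed-deterministic synthetic-data generator and a
    command-line pipeline driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
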