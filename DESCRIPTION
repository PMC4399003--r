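Package: haphseg
Title: Dominant-Model Co-Segregation Filtering and Association Statistics
    for Bovine High-Altitude Pulmonary Hypertension
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for extreme-phenotype exome studies of bovine
    high-altitude pulmonary hypertension (HAPH). Implements
    microsatellite-based diversity scoring and diverse-subset selection,
    an autosomal-dominant co-segregation filter cascade over exome
    genotype matrices with cis-haplotype collapsing, the full set of
    2x2 case-control association statistics (Pearson chi-square,
    Cochran-Armitage trend, exact Wilcoxon rank-sum, relative risk and
    odds ratio with Wald intervals, predictive values under assumed
    prevalence, multi-herd pooling), and a three-category gene-set
    expression-enrichment chi-square with empirical background rates.
    A synthetic-cohort generator with dominant inheritance, incomplete
    penetrance and phenocopies makes every stage testable end to end,
    and a pipeline driver orchestrates simulate, diversity, filter,
    association and enrichment runs from a single seeded configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse
Config/testthat/edition: 3
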