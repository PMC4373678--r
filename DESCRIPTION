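Package: mpsscore
Title: Multiparametric Scoring of SGSH Missense Mutations in MPS-IIIA
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a ten-parameter evidence-based severity score (0-11)
    for missense mutations in N-sulfoglucosamine sulfohydrolase (SGSH), the
    lysosomal sulfatase deficient in mucopolysaccharidosis type IIIA
    (Sanfilippo syndrome type A). Bundles a scored catalogue of 86 patient
    mutations, per-parameter scorers driven by an explicit evidence bundle
    (coding sequence and codon usage, aggregation-propensity profiling,
    external stability calls, secondary structure and solvent accessibility,
    structural proximity to functional sites, N-glycosylation sequons,
    alignment conservation), statistical characterisation of the score
    distribution (D'Agostino-Pearson omnibus normality, Gaussian histogram
    fitting, standard errors of skewness and kurtosis), and genotype-phenotype
    cohort analysis with a multiplicative rule for compound-heterozygous
    genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
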