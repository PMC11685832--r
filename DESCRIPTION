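Package: omicLoops
Title: Signed Multi-Omic Association Networks and Coherent-Loop Detection
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A three-phase pipeline that integrates candidate-gene genotypes,
    longitudinal 16S genus-level microbiome profiles, plasma metabolomics and
    childhood BMI into a typed, signed co-association network. Phase one runs
    a targeted microbiome GWAS against alpha diversity and robust Aitchison
    principal components, a persistent-association scan of minor allele counts
    against BMI across consecutive ages, and genus-level differential
    abundance; phase two screens metabolites against BMI and then against
    variables of the other omics; phase three assembles the pairwise
    associations into a network and enumerates three- and four-node
    cross-omic cycles, flagging those whose edge-sign product is coherent
    ("meaningful loops"). A predictive 70/30 cross-validation fits one model
    per loop variable and reports normalised mean squared errors. A fully
    specified synthetic-cohort generator with plantable cross-omic effect
    chains makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'utils.R'
    'cohort-config.R'
    'linear-model.R'
    'crossval.R'
    'edges.R'
    'diffabund.R'
    'io.R'
    'metabolites.R'
    'microbiome-features.R'
    'mgwas.R'
    'network.R'
    'omicLoops-package.R'
    'persistence.R'
    'simulate-cohort.R'
    'pipeline.R'
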