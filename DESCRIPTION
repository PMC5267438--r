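Package: gsheval
Title: Genomic Prediction Scenarios for Multi-Breed Sheep Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating genomic selection in composite (multi-breed)
    sheep populations: construction of pedigree (A) and VanRaden genomic (G)
    relationship matrices with optional polygenic blending and base-population
    allele frequencies, SNP and phenotype quality control, AI-REML variance
    components, GBLUP molecular breeding values with theoretical accuracies
    from the mixed-model equations, a registry of forward, random and
    cluster-based cross-validation designs, and the derived statistics used to
    summarise them (observed and expected accuracy, effective number of
    progeny, and the K spread factor). A gene-dropping population simulator
    with admixed breed clusters makes the whole pipeline testable end to end
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'containers.R'
    'gblup.R'
    'io.R'
    'metrics.R'
    'phenotype_model.R'
    'qc.R'
    'relationships.R'
    'simulate.R'
    'validation.R'
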