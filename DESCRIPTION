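Package: nambin
Title: Recombination Bin Maps and Joint Linkage QTL Analysis for Nested
    Association Mapping Populations
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for turning low-coverage genotyping-by-sequencing SNP
    calls on recombinant inbred line (RIL) families of a nested association
    mapping (NAM) design into error-corrected recombination bin maps,
    per-family and composite genetic maps, and joint-linkage QTL scans with
    family-nested marker effects. Includes maximum-parsimony inference of
    parental origin, a two-state hidden Markov model for genotype error
    correction, block/breakpoint/bin calling, Haldane map construction with
    selfed-RIL correction, segregation-distortion screening, multi-environment
    BLUP and broad-sense heritability, permutation-calibrated stepwise QTL
    selection with 2-LOD support intervals, and a fully seeded NAM simulator
    that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    vcfR,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: Genetics, QualityControl, SNP, HiddenMarkovModel, Software
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'io_formats.R'
    'synthetic_data.R'
    'qc_outliers.R'
    'parental_inference.R'
    'genotype_hmm.R'
    'bin_builder.R'
    'genetic_map.R'
    'phenotype_blup.R'
    'joint_linkage.R'
    'pipeline.R'
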