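Package: mtHijack
Title: Horizontal Transfer, Selfish Selection and Haplotype Dynamics of
    Mitochondrial DNA in Transmissible Cancer
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and characterises mitochondrial DNA horizontal transfer
    in clonally transmissible cancers from discordance between nuclear and
    mitochondrial phylogenies. Provides haplogroup assignment from variant
    profiles, Fitch parsimony with full most-parsimonious-reconstruction
    state sets, heteroplasmy calling from variant allele fractions, an
    empirical enrichment test for donor-haplotype over-representation with
    an exact binomial oracle, molecular-clock calibration and event dating,
    mtDNA copy-number estimation from coverage and tumour fractions,
    phasing of recombinant mtDNA haplotypes from long-read allele patterns
    on a circular genome, and haplotype-stratified transcript-abundance
    comparison with batch correction. A synthetic-cohort generator with
    known ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    vcfR,
    yaml,
    jsonlite,
    Biostrings,
    SummarizedExperiment,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'copyNumber.R'
    'utils.R'
    'phyloCore.R'
    'htDetection.R'
    'transcriptAbundance.R'
    'recombination.R'
    'selectionStats.R'
    'variantStore.R'
    'profiles.R'
    'syntheticCohort.R'
    'pipeline.R'
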