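Package: carbotrait
Title: Genotype-Phenotype Analysis of Carbohydrate Utilization in Oenococcus oeni
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking carbohydrate-utilization phenotypes of
    Oenococcus oeni strains to gene functionality states. Implements
    phenotype calling from fermentation assay readouts, substrate-usage
    summary statistics over a strain-by-sugar matrix, gene-trait
    association with exact and lineage-aware permutation tests,
    Boolean pathway-completeness prediction with isoform complementation,
    exhaustive monotone rule inference, heterofermentative
    phosphoketolase stoichiometry modelling, and a synthetic-data
    generator (Yule trees with three-state gene gain/loss/pseudogenization
    histories) so every stage is testable with known ground truth.
    A transcription of the published 41-strain by 18-sugar phenotype
    table and prose-derived gene-state fixtures ship with the package.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'policy.R'
    'io.R'
    'fixtures.R'
    'phenotyping.R'
    'gene_trait.R'
    'pathway_logic.R'
    'infer_rules.R'
    'stoichiometry.R'
    'simulate.R'
    'pipeline.R'
    'carbotrait-package.R'
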