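Package: spurphos
Title: Quantitative Analysis of Spurious Tyrosine Phosphorylation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end quantitative analysis of spurious (non-native)
    protein phosphorylation from data-independent-acquisition (DIA)
    phosphoproteomics. Covers precursor-level filtering, moderated-t
    differential-regulation calls between wild-type and kinase-dead
    conditions, phosphosite occupancy (stoichiometry) estimation from
    paired phospho/non-phospho precursor intensities with maxLFQ protein
    normalisation, structural profiling of phosphosites (solvent
    accessibility, disorder, destabilisation, interfaces, linear motifs),
    similarity-weighted variant-effect scoring of phosphotyrosines,
    evolutionary tests for tyrosine counter-selection (amino-acid desert
    null simulations, permutation conservation tests, phylogenetic
    independent contrasts, equilibrium-frequency shifts), and
    colony-growth fitness-screen scoring. A synthetic-data module
    generates every input class with known ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    limma,
    ape,
    bio3d,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
biocViews: Proteomics, MassSpectrometry, Phylogenetics, StructuralPrediction
Config/testthat/edition: 3
RoxygenNote: 7.3.3
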