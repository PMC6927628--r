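Package: hybridband
Title: Detection and Classification of Interspecific Hybrids from
    Dominant Molecular Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting and classifying interspecific hybrids
    (F1, backcross, introgressed, pure) from dominant molecular-marker
    presence/absence matrices (RAPD, AFLP) and from parental-group
    sequence alignments. Provides band classification into monomorphic,
    polymorphic, unique and species-diagnostic categories; Dice
    similarity and genetic distance; UPGMA and neighbor-joining trees
    with locus bootstrap support; principal coordinate analysis; a
    diagnostic-marker hybrid index with hybrid-class calls; a Bayesian
    admixture model for dominant (recessive-null) markers with Gibbs
    sampling, Evanno delta-K cluster selection and replicate alignment;
    diagnostic SNP/indel discovery between parental alignments with
    hybrid-clone scoring; in-silico PCR-RFLP haplotyping; and a fully
    seeded synthetic-data generator for two parental taxa with F1 and
    first-backcross hybrid classes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
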