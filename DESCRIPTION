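Package: pbwtimpute
Title: PBWT-Accelerated Genotype Imputation with the Li and Stephens Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Haploid genotype imputation from large phased reference panels.
    Copying states for each target haplotype are selected with a streaming
    positional Burrows-Wheeler transform (PBWT) of the reference panel at
    genotyped markers, and posterior allele probabilities are computed with a
    haploid Li and Stephens hidden Markov model restricted to the selected
    states. Posteriors are sparsified, linearly interpolated to untyped
    markers, and rare variants are emitted through a delayed lazy path.
    Includes an indexed binary reference-panel container with sparse/bitset
    per-marker records, a coalescent-like haplotype simulator, chip-site
    masking, switch-error injection, and MAF-binned r-squared scoring for
    accuracy evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
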