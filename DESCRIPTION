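Package: mtPopGen
Title: Population Genetics of mtDNA Control-Region Haplotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the classical population-level analysis of mitochondrial
    DNA hypervariable segment 1 (HVS-1) alignments: haplotype and nucleotide
    diversity, Tajima's D, Fu's Fs and R2 neutrality tests with coalescent
    null distributions, mismatch-distribution fitting under the sudden
    demographic expansion model (SSD, Harpending's raggedness) with parametric
    bootstrap, pairwise Phi-ST and hierarchical AMOVA with permutation tests
    under Kimura two-parameter gamma-corrected distances, nonmetric
    multidimensional scaling of linearised distances, and rho-statistic TMRCA
    dating of mutation-annotated clade trees under calibrated mitochondrial
    clocks. Includes a finite-sites coalescent simulator (constant size,
    sudden expansion, island migration) that emits data in the package's own
    input dialect so every stage can be validated against analytic
    expectations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    ape,
    vegan,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
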