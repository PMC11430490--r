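Package: mitoprofile
Title: Characterization and Pairwise Comparison of Circular Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing annotated circular mitochondrial genomes
    and comparing pairs of them. Provides circular coordinate arithmetic for
    origin-spanning features, gene inventory and intergenic spacer/overlap
    accounting, base composition with AT- and GC-skew, codon usage and
    relative synonymous codon usage (RSCU) under the vertebrate mitochondrial
    genetic code, control-region motif and exact tandem-repeat scanning,
    anchored global alignment with affine gaps, variant calling with
    codon-level consequence annotation, and a synthetic-genome generator with
    implanted-mutation truth sets for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
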