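Package: alloscan
Title: Phylogenetic Dissection of Recurrent C4 Origins: Annotation,
    Branch-Site Selection Tests, Relaxed-Clock Dating and Introgression
    Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A four-stage inference pipeline for tracing the independent
    origins and cross-species spread of the molecular components of C4
    photosynthesis in closely related grasses. Stage one assigns
    transcriptome contigs to labeled gene lineages by similarity search
    and phylogenetic placement and aggregates read counts into rpm/rpkm
    abundances. Stage two tests alternative origin scenarios with
    branch-site codon models (M1a null versus BSA/BSA1 alternatives)
    selected by small-sample-corrected AIC. Stage three estimates
    per-gene divergence times on third codon positions under an
    uncorrelated lognormal relaxed clock with a fixed-root calibration
    and a constant-size coalescent prior. Stage four screens the
    genome-wide distribution of gene-wise age medians for young outliers
    indicative of introgression. A synthetic-data module generates codon
    alignments, gene histories and transcriptome fixtures with known
    truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    ape,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    Matrix,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
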