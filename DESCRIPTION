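Package: igseqr
Title: Antibody Repertoire Sequencing Analysis Pipeline
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of immunoglobulin variable-region sequencing
    (Ig-Seq / AIRR-Seq) data from one to six replicates. Merges paired-end
    reads, extracts and collapses unique molecular identifiers (UMIs) into
    consensus molecules, assigns V(D)J germline genes against user-supplied
    reference sets, delineates CDR3, assigns antibody isotypes by
    fingerprint-peptide matching downstream of the framework-4 anchor, and
    computes repertoire statistics: somatic hypermutation profiles with
    synonymous/non-synonymous (Ka/Ks) stratification, CDR3 length
    distributions, subgroup and V(D)J combination usage, and isotype
    distributions. Clusters sequences into clones by identical CDRH3 amino
    acid sequence and reports clonal expansion, per-clone alignments,
    consensus and logo matrices. Joint multi-replicate analysis quantifies
    reproducibility via pairwise Pearson correlation and Venn intersection
    counts. Exports proteomics-ready variable-region databases with trypsin
    cleavage-site suffixes. Includes a seeded repertoire simulator producing
    germline sets, paired-end FASTQ with UMIs, and ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
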