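Package: tboxscan
Title: Survey of T-Box Riboswitch Leaders Upstream of Aminoacyl-tRNA
    Synthetase Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects candidate T-box riboswitch leaders in annotated
    bacterial genomes. Aminoacyl-tRNA synthetase (AARS) genes are located
    by local-alignment homology against a reference protein set with a
    Karlin-Altschul E-value filter, strand-aware upstream regions are
    extracted, and each leader is scanned for the degenerate T-box motif
    TGGNACCGCG (up to two mismatches in the last six positions). Candidate
    leaders are then tested for a Rho-independent terminator, an
    overlapping antiterminator, mutual exclusivity of the two structures,
    and a specifier codon displayed in a stem I bulge, yielding a per-gene
    regulation call with a predicted cognate amino acid including
    mixed-codon-box partners (e.g. Lys/Asn). A synthetic-genome generator
    with a machine-readable truth table supports end-to-end validation
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
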