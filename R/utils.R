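#' Normalize a nucleotide sequence
#'
#' Upper-cases, converts RNA U to DNA T, and checks the alphabet. Ambiguity
#' codes other than N are rejected so that downstream matching rules stay
#' unambiguous.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector over the alphabet A, C, G, T, N.
#' @export
normalize_dna <- function(x) {
  x <- chartr("u", "U", toupper(as.character(x)))
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("sequence contains characters outside {A,C,G,T,U,N}: ",
         substr(x[bad][1], 1, 40))
  }
  x
}

#' Reverse complement
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  x <- normalize_dna(x)
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# one-letter -> three-letter amino-acid names, stop mapped to "Stop"
aa_three_letter <- function(aa1) {
  map <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
           Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
           L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
           S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
           "*" = "Stop")
  out <- unname(map[aa1])
  out[is.na(out)] <- "unknown"
  out
}

# translate a CDS (forward-sense DNA, no introns) to protein, dropping the
# terminal stop if present; codons containing N translate to X
translate_cds <- function(dna) {
  dna <- normalize_dna(dna)
  if (nchar(dna) %% 3L != 0L) {
    stop("CDS length ", nchar(dna), " is not a multiple of 3")
  }
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                           if.fuzzy.codon = "solve"))
  sub("\\*$", "", aa)
}

#' Mirror a genome and its annotations
#'
#' Reverse-complements every contig and flips all gene coordinates and
#' strands accordingly. Because upstream-region extraction is strand-aware,
#' a survey of the mirrored genome must reproduce the original calls up to
#' mirrored genomic coordinates; this utility supports that consistency
#' check.
#'
#' @param genome Named character vector of contig sequences.
#' @param genes Gene annotation data frame as returned by [read_genome()].
#' @return List with mirrored `genome` and `genes`.
#' @export
mirror_genome <- function(genome, genes) {
  lens <- nchar(genome)
  mg <- revcomp(genome)
  names(mg) <- names(genome)
  g <- genes
  L <- lens[g$contig_id]
  new_start <- L - g$end
  new_end <- L - g$start
  g$start <- unname(new_start)
  g$end <- unname(new_end)
  g$strand <- ifelse(genes$strand == "+", "-", "+")
  g <- g[order(g$contig_id, g$start), , drop = FALSE]
  rownames(g) <- NULL
  list(genome = mg, genes = g)
}

# deterministic child seed derived from a user seed and an index,
# kept inside 32-bit integer range
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 7919 + as.double(i) * 104729) %% 2147483629)
}

# run code with a temporarily seeded RNG, restoring prior state afterwards
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
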