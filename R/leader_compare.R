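#' Global pairwise alignment of two nucleotide sequences
#'
#' Needleman-Wunsch with simple transparent scoring (defaults +1 match,
#' -1 mismatch, -2 per gap position), used to quantify conservation
#' between leader elements. Case and U/T spelling are normalized before
#' alignment.
#'
#' @param a,b Nucleotide strings.
#' @param match,mismatch Per-column scores.
#' @param gap Per-gap-position score (linear gap penalty).
#' @return A list of class `nw_alignment`: `aligned_a`, `aligned_b`
#'   (with `-` gaps), `score`.
#' @export
needleman_wunsch <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  a <- normalize_dna(a); b <- normalize_dna(b)
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = -gap)
  structure(
    list(aligned_a = as.character(Biostrings::alignedPattern(al)),
         aligned_b = as.character(Biostrings::alignedSubject(al)),
         score = Biostrings::score(al),
         id_a = NA_character_, id_b = NA_character_),
    class = "nw_alignment"
  )
}

#' Percent identity of a global alignment
#'
#' Matched columns over all aligned columns, times 100; gap columns count
#' in the denominator (alignment-length identity). 100 iff the sequences
#' are identical.
#'
#' @param alignment An `nw_alignment` from [needleman_wunsch()].
#' @return A list of class `identity_result`: `id_a`, `id_b`,
#'   `aligned_len`, `matches`, `percent_identity`.
#' @export
percent_identity <- function(alignment) {
  stopifnot(inherits(alignment, "nw_alignment"))
  ca <- strsplit(alignment$aligned_a, "")[[1]]
  cb <- strsplit(alignment$aligned_b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  matches <- sum(ca == cb & ca != "-")
  structure(
    list(id_a = alignment$id_a, id_b = alignment$id_b,
         aligned_len = length(ca), matches = matches,
         percent_identity = 100 * matches / length(ca)),
    class = "identity_result"
  )
}

#' Pairwise identity matrix of leader sequences
#'
#' @param leaders Named character vector of nucleotide sequences, or a
#'   FASTA path.
#' @param match,mismatch,gap Alignment scores (see [needleman_wunsch()]).
#' @return Symmetric numeric matrix of percent identities with 100 on the
#'   diagonal.
#' @export
compare_leaders <- function(leaders, match = 1, mismatch = -1, gap = -2) {
  if (length(leaders) == 1L && file.exists(leaders[[1]])) {
    x <- Biostrings::readDNAStringSet(leaders[[1]])
    leaders <- as.character(x)
    names(leaders) <- sub("\\s.*$", "", names(x))
  }
  if (length(leaders) < 2L) stop("need at least two sequences")
  if (is.null(names(leaders)) || any(!nzchar(names(leaders)))) {
    names(leaders) <- paste0("seq", seq_along(leaders))
  }
  n <- length(leaders)
  m <- matrix(100, n, n, dimnames = list(names(leaders), names(leaders)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      al <- needleman_wunsch(leaders[[i]], leaders[[j]],
                             match = match, mismatch = mismatch,
                             gap = gap)
      pid <- percent_identity(al)$percent_identity
      m[i, j] <- pid
      m[j, i] <- pid
    }
  }
  m
}
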