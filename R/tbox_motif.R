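#' The degenerate T-box motif specification
#'
#' The screening rule is a literal degenerate string match: the 10-mer
#' TGGNACCGCG, where the first three positions must match exactly, the
#' fourth (the variable T-box position, UGGN at the RNA level) is free,
#' and at most `max_suffix_mismatches` substitutions are tolerated over
#' the last six positions. Insertions/deletions are not considered.
#'
#' @param pattern Motif pattern (DNA alphabet; N = wildcard).
#' @param fixed_prefix_len Length of the exact-match prefix (the pattern's
#'   N positions inside the prefix still match any base).
#' @param max_suffix_mismatches Mismatch budget over the remaining
#'   positions.
#' @return A list of class `motif_spec`.
#' @export
tbox_motif_spec <- function(pattern = "TGGNACCGCG",
                            fixed_prefix_len = 4L,
                            max_suffix_mismatches = 2L) {
  pattern <- chartr("U", "T", toupper(pattern))
  if (grepl("[^ACGTN]", pattern)) stop("motif pattern must be over A/C/G/T/N")
  fixed_prefix_len <- as.integer(fixed_prefix_len)
  max_suffix_mismatches <- as.integer(max_suffix_mismatches)
  stopifnot(fixed_prefix_len >= 0L,
            fixed_prefix_len <= nchar(pattern),
            max_suffix_mismatches >= 0L)
  structure(
    list(pattern = pattern,
         fixed_prefix_len = fixed_prefix_len,
         max_suffix_mismatches = max_suffix_mismatches),
    class = "motif_spec"
  )
}

#' Test windows against the degenerate T-box motif rule
#'
#' A window is accepted iff every constrained prefix position matches the
#' pattern exactly and the number of suffix mismatches does not exceed the
#' budget. A genomic N never matches a constrained position (it counts as
#' a mismatch, and rejects at the prefix); it does match the pattern's own
#' N.
#'
#' @param windows Character vector of candidate windows, each exactly as
#'   long as the pattern.
#' @param spec A [tbox_motif_spec()].
#' @return Data frame with columns `window`, `accepted`,
#'   `suffix_mismatches` (NA when the window was rejected at the prefix)
#'   and `variable_base` (the base aligned to the pattern's first N).
#' @export
match_tbox_window <- function(windows, spec = tbox_motif_spec()) {
  windows <- chartr("Uu", "Tt", toupper(as.character(windows)))
  plen <- nchar(spec$pattern)
  if (any(nchar(windows) != plen)) {
    stop("all windows must have length ", plen)
  }
  pat <- strsplit(spec$pattern, "")[[1]]
  n <- length(windows)
  if (n == 0L) {
    return(data.frame(window = character(), accepted = logical(),
                      suffix_mismatches = integer(),
                      variable_base = character(),
                      stringsAsFactors = FALSE))
  }
  wm <- matrix(unlist(strsplit(windows, ""), use.names = FALSE),
               nrow = n, byrow = TRUE)
  is_prefix <- seq_len(plen) <= spec$fixed_prefix_len
  constrained <- pat != "N"
  prefix_ok <- rep(TRUE, n)
  for (j in which(is_prefix & constrained)) {
    prefix_ok <- prefix_ok & wm[, j] == pat[j]
  }
  mm <- rep(0L, n)
  for (j in which(!is_prefix & constrained)) {
    mm <- mm + as.integer(wm[, j] != pat[j])
  }
  accepted <- prefix_ok & mm <= spec$max_suffix_mismatches
  var_pos <- which(pat == "N")
  variable_base <- if (length(var_pos)) wm[, var_pos[1]]
                   else rep(NA_character_, n)
  data.frame(window = windows, accepted = accepted,
             suffix_mismatches = ifelse(prefix_ok, mm, NA_integer_),
             variable_base = variable_base,
             stringsAsFactors = FALSE)
}

#' Scan an upstream region for T-box motif matches
#'
#' Slides the motif over the region (single-stranded: upstream regions are
#' already in the transcribed orientation) and reports every accepted
#' window, including overlapping ones, in ascending position.
#'
#' @param region An `upstream_region` or a plain nucleotide string.
#' @param spec A [tbox_motif_spec()].
#' @return Data frame with columns `gene_id`, `offset` (0-based position
#'   in the region), `window`, `suffix_mismatches`, `variable_base`.
#'   Regions shorter than the pattern yield zero rows.
#' @export
scan_tbox <- function(region, spec = tbox_motif_spec()) {
  seq <- region_sequence(region)
  gid <- region_gene_id(region)
  plen <- nchar(spec$pattern)
  empty <- data.frame(gene_id = character(), offset = integer(),
                      window = character(), suffix_mismatches = integer(),
                      variable_base = character(), stringsAsFactors = FALSE)
  if (nchar(seq) < plen) return(empty)
  starts <- seq_len(nchar(seq) - plen + 1L)
  windows <- substring(seq, starts, starts + plen - 1L)
  res <- match_tbox_window(windows, spec)
  keep <- which(res$accepted)
  if (!length(keep)) return(empty)
  data.frame(gene_id = rep(gid, length(keep)), offset = starts[keep] - 1L,
             window = res$window[keep],
             suffix_mismatches = res$suffix_mismatches[keep],
             variable_base = res$variable_base[keep],
             stringsAsFactors = FALSE)
}
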