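#' Maximum base-pair folding (Nussinov)
#'
#' Computes a maximum-cardinality nested (pseudoknot-free) set of base
#' pairs over Watson-Crick pairs, optionally including G:U wobble pairs,
#' with a minimum hairpin loop. Base-pair maximization rather than an
#' energy model is used deliberately: the downstream question (can the
#' leader form mutually exclusive structures?) is topological, and the
#' engine stays free of thermodynamic parameter sets.
#'
#' Traceback is deterministic: a base is left unpaired whenever doing so is
#' co-optimal, so no pair is reported that the maximum pair count does not
#' force; when a base must pair, the smallest-index partner achieving the
#' optimum is chosen.
#'
#' @param seq RNA- or DNA-sense nucleotide string (U and T equivalent).
#' @param min_loop Minimum number of unpaired bases enclosed by any pair
#'   (default 3); a pair (i, j) requires j - i > min_loop.
#' @param allow_GU Allow G:U wobble pairs (default TRUE).
#' @param traceback Also return the pair list (default TRUE); disable for
#'   bulk pair-count computations.
#' @return A list of class `pairing_result`: `sequence` (normalized to
#'   DNA letters), `pairs` (two-column matrix of 1-based indices, i < j,
#'   or NULL when `traceback = FALSE`), `pair_count`, `paired` (logical
#'   vector) and `dot_bracket`.
#' @export
nussinov_maxpair <- function(seq, min_loop = 3L, allow_GU = TRUE,
                             traceback = TRUE) {
  seq <- normalize_dna(seq)
  n <- nchar(seq)
  res <- .nussinov_fold(seq, as.integer(min_loop), isTRUE(allow_GU),
                        isTRUE(traceback))
  paired <- rep(FALSE, n)
  db <- NULL
  pairs <- NULL
  if (traceback) {
    pairs <- res$pairs
    if (nrow(pairs)) {
      paired[pairs[, 1]] <- TRUE
      paired[pairs[, 2]] <- TRUE
    }
    db <- rep(".", n)
    if (nrow(pairs)) {
      db[pairs[, 1]] <- "("
      db[pairs[, 2]] <- ")"
    }
    db <- paste(db, collapse = "")
  }
  structure(
    list(sequence = seq, pairs = pairs, pair_count = res$count,
         paired = paired, dot_bracket = db,
         min_loop = as.integer(min_loop), allow_GU = isTRUE(allow_GU)),
    class = "pairing_result"
  )
}

#' @export
print.pairing_result <- function(x, ...) {
  cat("Base-pair maximization over", nchar(x$sequence), "nt:",
      x$pair_count, "pairs\n")
  if (!is.null(x$dot_bracket) && nchar(x$sequence) <= 120) {
    cat(" ", x$sequence, "\n ", x$dot_bracket, "\n")
  }
  invisible(x)
}

# can two DNA-letter bases pair (RNA sense, T read as U)?
bases_pair <- function(a, b, allow_GU = TRUE) {
  ab <- paste0(pmin(a, b), pmax(a, b))
  ok <- ab %in% c("AT", "CG")
  if (allow_GU) ok <- ok | ab == "GT"
  ok
}

#' Find Rho-independent terminator hairpins in a leader
#'
#' Enumerates hairpins with a stem of at least `min_stem` base pairs
#' (G:U allowed), an apical loop of `loop_min`-`loop_max` nt, maximal stem
#' extension, and evaluates the U-tract rule: at least `min_u` T residues
#' within the `u_window` nt that follow the 3' stem arm. Hairpins
#' satisfying the stem/loop geometry are always reported so that partial
#' evidence is preserved; `passes` records whether the U-tract rule also
#' holds.
#'
#' @param region An `upstream_region` or nucleotide string.
#' @param params A [tbox_params()] list.
#' @return List of `terminator_call` objects sorted by 5' arm position.
#'   Each holds `stem5`, `stem3` (0-based half-open intervals), `loop_len`,
#'   `stem_len`, `u_tract_count` and `passes`.
#' @export
find_terminators <- function(region, params = tbox_params()) {
  seq <- region_sequence(region)
  n <- nchar(seq)
  calls <- list()
  if (n < 2L * params$min_stem + params$loop_min) return(calls)
  ch <- strsplit(seq, "")[[1]]
  seen <- character(0)
  for (loop_start in seq_len(n)) {          # 1-based first loop base
    for (loop_len in params$loop_min:params$loop_max) {
      i <- loop_start - 1L                  # last 5' arm base, 1-based
      j <- loop_start + loop_len            # first 3' arm base, 1-based
      if (i < 1L || j > n) next
      s <- 0L
      while (i - s >= 1L && j + s <= n &&
             bases_pair(ch[i - s], ch[j + s], params$allow_GU)) {
        s <- s + 1L
      }
      if (s < params$min_stem) next
      key <- paste(i - s + 1L, loop_len, s, sep = ":")
      if (key %in% seen) next
      seen <- c(seen, key)
      stem5 <- c(i - s, i)                  # 0-based half-open
      stem3 <- c(j - 1L, j - 1L + s)
      u_from <- stem3[2] + 1L               # 1-based
      u_to <- min(n, stem3[2] + params$u_window)
      u_count <- if (u_from <= u_to)
        sum(ch[u_from:u_to] == "T") else 0L
      calls[[length(calls) + 1L]] <- structure(
        list(stem5 = stem5, stem3 = stem3,
             loop_len = loop_len, stem_len = s,
             u_tract_count = as.integer(u_count),
             passes = u_count >= params$min_u),
        class = "terminator_call"
      )
    }
  }
  if (length(calls)) {
    ord <- order(vapply(calls, function(x) x$stem5[1], numeric(1)),
                 vapply(calls, function(x) x$stem3[2], numeric(1)))
    calls <- calls[ord]
  }
  calls
}

#' @export
print.terminator_call <- function(x, ...) {
  cat(sprintf(
    "Terminator hairpin: 5' arm [%d,%d), loop %d nt, 3' arm [%d,%d), %d bp, U-tract %d (%s)\n",
    x$stem5[1], x$stem5[2], x$loop_len, x$stem3[1], x$stem3[2],
    x$stem_len, x$u_tract_count, if (x$passes) "passes" else "fails"))
  invisible(x)
}

#' Search for an antiterminator hairpin sequestering the terminator 5' arm
#'
#' The antiterminator competes with the terminator by pairing bases of the
#' terminator's 5' stem arm with a segment at or upstream of the T-box
#' motif. The search window runs from `anti_window_upstream` nt upstream
#' of the motif through the terminator's 5' arm; a hairpin qualifies when
#' its stem has at least `anti_min_stem` pairs, its 5' arm lies 5' of the
#' motif start, its 3' arm falls inside the terminator 5' arm, and its
#' total span does not exceed `anti_max_span`.
#'
#' @param region An `upstream_region` or nucleotide string.
#' @param tbox_hit One row of a [scan_tbox()] result.
#' @param terminator A `terminator_call`.
#' @param params A [tbox_params()] list.
#' @return A list of class `antiterminator_call`: `found`, `span`,
#'   `arm5`, `arm3` (0-based half-open), `stem_len`, `paired_indices`
#'   (0-based), `contains_tbox`, `overlaps_terminator`.
#' @export
find_antiterminator <- function(region, tbox_hit, terminator,
                                params = tbox_params()) {
  seq <- region_sequence(region)
  n <- nchar(seq)
  motif_start <- as.integer(tbox_hit$offset)            # 0-based
  motif_end <- motif_start + nchar(tbox_hit$window)     # exclusive
  if (motif_end > terminator$stem3[1]) {
    stop("T-box motif [", motif_start, ",", motif_end,
         ") does not lie 5' of the terminator 3' arm [",
         terminator$stem3[1], ",", terminator$stem3[2], ")")
  }
  none <- structure(
    list(found = FALSE, span = NULL, arm5 = NULL, arm3 = NULL,
         stem_len = 0L, paired_indices = integer(0),
         contains_tbox = FALSE, overlaps_terminator = FALSE),
    class = "antiterminator_call"
  )
  t5 <- terminator$stem5
  if (motif_end > t5[1]) return(none)
  ch <- strsplit(seq, "")[[1]]
  win_start <- max(0L, motif_start - params$anti_window_upstream)
  if (motif_start - 1L < win_start || t5[2] - 1L < t5[1]) return(none)
  best <- NULL
  for (a in win_start:(motif_start - 1L)) {             # 0-based arm5 start
    if (a < 0L) next
    for (b in (t5[1]):(t5[2] - 1L)) {                   # 0-based arm3 last base
      if (b - a + 1L > params$anti_max_span) next
      s <- 0L
      while (a + s < motif_start &&                      # arm5 stays 5' of motif
             b - s >= motif_end &&                       # arm3 stays 3' of motif
             (b - s) - (a + s) > params$anti_min_loop &&
             bases_pair(ch[a + s + 1L], ch[b - s + 1L], params$allow_GU)) {
        s <- s + 1L
      }
      if (s < params$anti_min_stem) next
      cand <- list(a = a, b = b, s = s)
      if (is.null(best) || s > best$s ||
          (s == best$s && (a < best$a || (a == best$a && b < best$b)))) {
        best <- cand
      }
    }
  }
  if (is.null(best)) return(none)
  arm5 <- c(best$a, best$a + best$s)                    # half-open
  arm3 <- c(best$b - best$s + 1L, best$b + 1L)
  paired <- c(seq.int(arm5[1], arm5[2] - 1L),
              seq.int(arm3[1], arm3[2] - 1L))
  span <- c(best$a, best$b + 1L)
  structure(
    list(found = TRUE, span = span, arm5 = arm5, arm3 = arm3,
         stem_len = best$s, paired_indices = as.integer(paired),
         contains_tbox = span[1] <= motif_start && span[2] >= motif_end,
         overlaps_terminator =
           any(paired >= t5[1] & paired < t5[2])),
    class = "antiterminator_call"
  )
}

#' @export
print.antiterminator_call <- function(x, ...) {
  if (!x$found) {
    cat("No antiterminator hairpin found\n")
  } else {
    cat(sprintf(
      "Antiterminator: span [%d,%d), arms [%d,%d)/[%d,%d), %d bp; contains T-box: %s; overlaps terminator: %s\n",
      x$span[1], x$span[2], x$arm5[1], x$arm5[2], x$arm3[1], x$arm3[2],
      x$stem_len, x$contains_tbox, x$overlaps_terminator))
  }
  invisible(x)
}

#' Are terminator and antiterminator mutually exclusive?
#'
#' TRUE iff the antiterminator's paired bases intersect the terminator's
#' 5' stem arm, i.e. the two structures compete for the same nucleotides
#' and cannot form simultaneously.
#'
#' @param term A `terminator_call`.
#' @param anti An `antiterminator_call` on the same leader.
#' @return Logical scalar.
#' @export
mutually_exclusive <- function(term, anti) {
  if (!isTRUE(anti$found)) return(FALSE)
  any(anti$paired_indices >= term$stem5[1] &
      anti$paired_indices < term$stem5[2])
}

#' Locate candidate specifier codons in stem I bulges
#'
#' Folds the stem I portion of the leader (or accepts a precomputed
#' pairing) and reports every trinucleotide lying fully inside an unpaired
#' stretch of at least `min_bulge` bases, translated with the standard
#' genetic code. The specifier codon of a genuine T-box leader sits in
#' such a bulge and determines the cognate tRNA family.
#'
#' @param region An `upstream_region` or nucleotide string.
#' @param stemI_interval 0-based half-open interval of the stem I portion
#'   (typically from the leader start to the antiterminator window).
#' @param pairing Optional `pairing_result` for the stem I subsequence;
#'   computed with [nussinov_maxpair()] when NULL.
#' @param params A [tbox_params()] list.
#' @return Data frame with columns `codon`, `position` (0-based leader
#'   offset of the codon), `bulge_start`, `bulge_end` (half-open, leader
#'   coordinates) and `amino_acid` (three-letter name), ordered 5' to 3'.
#' @export
find_specifier <- function(region, stemI_interval, pairing = NULL,
                           params = tbox_params()) {
  seq <- region_sequence(region)
  lo <- as.integer(stemI_interval[1])
  hi <- as.integer(stemI_interval[2])
  empty <- data.frame(codon = character(), position = integer(),
                      bulge_start = integer(), bulge_end = integer(),
                      amino_acid = character(), stringsAsFactors = FALSE)
  if (hi - lo < 3L) return(empty)
  sub <- substr(seq, lo + 1L, hi)
  if (is.null(pairing)) {
    pairing <- nussinov_maxpair(sub, min_loop = params$min_loop,
                                allow_GU = params$allow_GU)
  }
  paired <- pairing$paired
  if (length(paired) != nchar(sub)) {
    stop("pairing length does not match the stem I interval")
  }
  runs <- rle(!paired)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- empty
  for (r in which(runs$values & runs$lengths >= params$min_bulge)) {
    for (p in starts[r]:(ends[r] - 2L)) {
      codon <- substr(sub, p, p + 2L)
      out <- rbind(out, data.frame(
        codon = codon, position = lo + p - 1L,
        bulge_start = lo + starts[r] - 1L, bulge_end = lo + ends[r],
        amino_acid = codon_to_aa(codon), stringsAsFactors = FALSE))
    }
  }
  out[order(out$position), , drop = FALSE]
}
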