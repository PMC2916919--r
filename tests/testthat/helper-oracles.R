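# Independent oracles and small fixture builders used across the suite.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")
rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                     replace = TRUE), collapse = "")

as_region <- function(seq, gene_id = "test") {
  structure(list(gene_id = gene_id, sequence = seq, start = 0L,
                 end = nchar(seq), truncated_by_neighbor = FALSE),
            class = "upstream_region")
}

# per-window motif oracle: literal restatement of the rule, tested
# position by position on a character matrix (independent of the
# package's substring-based scanner)
oracle_motif_accept <- function(windows) {
  pat <- c("T", "G", "G", "N", "A", "C", "C", "G", "C", "G")
  vapply(strsplit(windows, ""), function(w) {
    if (w[1] != "T" || w[2] != "G" || w[3] != "G") return(FALSE)
    sum(w[5:10] != pat[5:10]) <= 2L
  }, logical(1))
}

# vectorized variant for the exhaustive window enumeration
oracle_motif_accept_cols <- function(cols) {
  pat <- c("T", "G", "G", "N", "A", "C", "C", "G", "C", "G")
  acc <- cols[[1]] == "T" & cols[[2]] == "G" & cols[[3]] == "G"
  mm <- 0L
  for (j in 5:10) mm <- mm + (cols[[j]] != pat[j])
  acc & mm <= 2L
}

all_kmers <- function(k, bases = c("A", "C", "G", "T")) {
  idx <- 0:(length(bases)^k - 1)
  cols <- lapply(0:(k - 1), function(p)
    bases[(idx %/% (length(bases)^p)) %% length(bases) + 1])
  list(strings = do.call(paste0, cols), cols = cols)
}

# plain Needleman-Wunsch score DP (linear gap), independent of Biostrings
oracle_nw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  M <- matrix(0, n + 1, m + 1)
  M[, 1] <- gap * (0:n); M[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      M[i + 1, j + 1] <- max(
        M[i, j] + if (ca[i] == cb[j]) match else mismatch,
        M[i, j + 1] + gap,
        M[i + 1, j] + gap)
    }
  }
  M[n + 1, m + 1]
}

# exhaustive global alignment score by recursion over edit scripts
# (enumerates every alignment; only for very short sequences)
oracle_global_enum <- function(a, b, match = 1, mismatch = -1,
                               gap = -2) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      s <- if (ca[i] == cb[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1))
    }
    if (i <= length(ca)) best <- max(best, gap + rec(i + 1, j))
    if (j <= length(cb)) best <- max(best, gap + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

# exhaustive affine-gap local alignment by enumerating start points and
# every continuation (gap of length L costs open + L * ext); tiny inputs
oracle_sw_enum <- function(a, b, submat, open = 11, ext = 1) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  best <- 0
  rec <- function(i, j, state, acc) {
    if (acc > best) best <<- acc
    if (i <= length(ca) && j <= length(cb)) {
      rec(i + 1, j + 1, "m", acc + submat[ca[i], cb[j]])
    }
    if (i <= length(ca)) {
      rec(i + 1, j, "d", acc - ext - if (state == "d") 0 else open)
    }
    if (j <= length(cb)) {
      rec(i, j + 1, "i", acc - ext - if (state == "i") 0 else open)
    }
  }
  for (i0 in seq_along(ca)) {
    for (j0 in seq_along(cb)) {
      rec(i0, j0, "m", 0)
    }
  }
  best
}

# seeded residue shuffle (composition-preserving decoy)
with_seed_shuffle <- function(seq, seed) {
  ch <- strsplit(seq, "")[[1]]
  set.seed(seed)
  paste(sample(ch), collapse = "")
}

# structural validity of a pairing_result
expect_valid_pairing <- function(p) {
  expect_s3_class(p, "pairing_result")
  if (is.null(p$pairs) || !nrow(p$pairs)) return(invisible(p))
  i <- p$pairs[, 1]; j <- p$pairs[, 2]
  expect_true(all(i < j))
  expect_true(all(j - i > p$min_loop))
  expect_equal(anyDuplicated(c(i, j)), 0L)
  ch <- strsplit(p$sequence, "")[[1]]
  pairstr <- paste0(pmin(ch[i], ch[j]), pmax(ch[i], ch[j]))
  allowed <- c("AT", "CG", if (p$allow_GU) "GT")
  expect_true(all(pairstr %in% allowed))
  # non-crossing: for any two pairs, intervals are nested or disjoint
  if (nrow(p$pairs) > 1L) {
    for (r in seq_len(nrow(p$pairs) - 1L)) {
      for (s in (r + 1L):nrow(p$pairs)) {
        a <- p$pairs[r, ]; b <- p$pairs[s, ]
        crossing <- (a[1] < b[1] & b[1] < a[2] & a[2] < b[2]) |
                    (b[1] < a[1] & a[1] < b[2] & b[2] < a[2])
        expect_false(crossing)
      }
    }
  }
  invisible(p)
}

# write a tiny FASTA + GFF3 pair to a temp dir; returns the two paths
write_tiny_genome <- function(contigs, gff_lines, dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  fa <- file.path(dir, "g.fasta")
  gff <- file.path(dir, "g.gff3")
  fasta <- unlist(lapply(names(contigs), function(n)
    c(paste0(">", n), contigs[[n]])))
  writeLines(fasta, fa)
  writeLines(c("##gff-version 3", gff_lines), gff)
  c(fasta = fa, gff = gff)
}
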