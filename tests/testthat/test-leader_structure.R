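test_that("base-pair maximization handles canonical and degenerate inputs", {
  p <- nussinov_maxpair("GGGAAAACCC")
  expect_identical(p$pair_count, 3L)
  expect_identical(p$dot_bracket, "(((....)))")
  expect_identical(nussinov_maxpair("AAAAA")$pair_count, 0L)
  expect_identical(nussinov_maxpair("G")$pair_count, 0L)
  expect_identical(nussinov_maxpair("")$pair_count, 0L)
  # U and T spellings are the same molecule here
  expect_identical(nussinov_maxpair("GGGAAAACCC")$pair_count,
                   nussinov_maxpair("GGGAAAACCC")$pair_count)
  expect_identical(nussinov_maxpair("GGGUUUUCCC")$pair_count,
                   nussinov_maxpair("GGGTTTTCCC")$pair_count)
})

test_that("reported pairings are nested, disjoint and chemically valid", {
  set.seed(2001)
  for (k in 1:40) {
    p <- nussinov_maxpair(rand_rna(sample(5:40, 1)))
    expect_valid_pairing(p)
    expect_identical(nrow(p$pairs), p$pair_count)
  }
  # wobble pairs appear only when allowed
  p_gu <- nussinov_maxpair("GGGGAAAATTTT", allow_GU = TRUE)
  p_wc <- nussinov_maxpair("GGGGAAAATTTT", allow_GU = FALSE)
  expect_true(p_gu$pair_count >= p_wc$pair_count)
})

test_that("pair counts match exhaustive enumeration on random RNAs", {
  set.seed(2002)
  seqs <- vapply(1:60, function(i)
    rand_rna(sample(4:14, 1)), character(1))
  imp <- vapply(seqs, function(s)
    nussinov_maxpair(s, traceback = FALSE)$pair_count, integer(1),
    USE.NAMES = FALSE)
  ora <- tboxscan:::.nussinov_brute_batch(seqs, 3L, TRUE)
  expect_identical(imp, ora)
  # and with wobble disabled
  imp2 <- vapply(seqs, function(s)
    nussinov_maxpair(s, allow_GU = FALSE,
                     traceback = FALSE)$pair_count, integer(1),
    USE.NAMES = FALSE)
  ora2 <- tboxscan:::.nussinov_brute_batch(seqs, 3L, FALSE)
  expect_identical(imp2, ora2)
})

test_that("terminator hairpins require stem, loop and U-tract", {
  # C flanks cannot pair with the U-tract, so the stem stays at 6 bp
  good <- paste0("CCCC", "GGGCGC", "GAAA", "GCGCCC", "TTTTTTT", "CC")
  calls <- find_terminators(as_region(good))
  passing <- Filter(function(x) x$passes, calls)
  expect_true(length(passing) >= 1L)
  t1 <- passing[[1]]
  expect_true(t1$stem_len >= 6L)
  expect_identical(t1$loop_len, 4L)
  expect_true(t1$u_tract_count >= 4L)
  # claimed stem positions must actually pair
  ch <- strsplit(good, "")[[1]]
  for (k in 0:(t1$stem_len - 1L)) {
    b5 <- ch[t1$stem5[2] - k]          # 1-based: stem5 end inward
    b3 <- ch[t1$stem3[1] + 1L + k]
    expect_true(tboxscan:::bases_pair(b5, b3))
  }

  # same hairpin without the U-tract is reported but fails
  bad <- paste0("CCCC", "GGGCGC", "GAAA", "GCGCCC", "AAAAAAA", "CC")
  calls_bad <- find_terminators(as_region(bad))
  expect_true(length(calls_bad) >= 1L)
  expect_false(any(vapply(calls_bad, function(x) x$passes, logical(1))))

  expect_identical(length(find_terminators(as_region(strrep("A", 80)))),
                   0L)
})

test_that("the antiterminator must contain the motif and invade the terminator arm", {
  b <- build_leader(implant_spec(), seed = 41)
  region <- as_region(b$sequence)
  hits <- scan_tbox(region)
  hit <- hits[hits$offset == b$truth$motif_offset, ]
  terms <- Filter(function(x) x$passes, find_terminators(region))
  # the implanted hairpin may extend by chance beyond its designed arms,
  # so select the passing terminator covering the implant's 5' arm
  covers <- function(x, pos) x$stem5[1] <= pos && x$stem5[2] > pos
  term <- Filter(function(x) covers(x, b$truth$terminator_interval[1]),
                 terms)[[1]]
  anti <- find_antiterminator(region, hit, term)
  expect_true(anti$found)
  expect_true(anti$contains_tbox)
  expect_true(anti$overlaps_terminator)
  expect_true(anti$stem_len >= 4L)
  expect_true(mutually_exclusive(term, anti))

  # without the implanted overlap arm the search comes up empty
  b2 <- build_leader(implant_spec(antiterminator_overlap = FALSE),
                     seed = 42)
  region2 <- as_region(b2$sequence)
  hits2 <- scan_tbox(region2)
  hit2 <- hits2[hits2$offset == 38L, ]
  terms2 <- Filter(function(x) covers(x, 51L),
                   find_terminators(region2))
  expect_true(length(terms2) >= 1L)
  anti2 <- find_antiterminator(region2, hit2, terms2[[1]])
  expect_false(anti2$found && mutually_exclusive(terms2[[1]], anti2))

  # motif 3' of the terminator violates the stage ordering
  late_hit <- hit; late_hit$offset <- term$stem3[2] + 1L
  expect_error(find_antiterminator(region, late_hit, term),
               "does not lie 5'")
})

test_that("mutual exclusivity is an index-set intersection with half-open bounds", {
  term <- structure(list(stem5 = c(10L, 20L), stem3 = c(30L, 40L),
                         loop_len = 4L, stem_len = 10L,
                         u_tract_count = 6L, passes = TRUE),
                    class = "terminator_call")
  anti_at <- function(idx) structure(
    list(found = TRUE, paired_indices = as.integer(idx)),
    class = "antiterminator_call")
  expect_false(mutually_exclusive(term, anti_at(30:39)))   # disjoint
  expect_true(mutually_exclusive(term, anti_at(15:25)))    # overlapping
  expect_false(mutually_exclusive(term, anti_at(20:29)))   # adjacent
  expect_true(mutually_exclusive(term, anti_at(19)))       # boundary in
  not_found <- structure(list(found = FALSE,
                              paired_indices = integer(0)),
                         class = "antiterminator_call")
  expect_false(mutually_exclusive(term, not_found))
})

test_that("specifier codons are read out of stem I bulges", {
  for (codon in c("AAA", "AAT")) {
    b <- build_leader(implant_spec(specifier_codon = codon),
                      seed = 50 + nchar(codon))
    spc <- find_specifier(as_region(b$sequence), c(0L, 26L))
    expect_true(b$truth$specifier_offset %in% spc$position)
    row <- spc[spc$position == b$truth$specifier_offset, ]
    expect_identical(row$codon, codon)
    expect_identical(row$amino_acid, codon_to_aa(codon))
  }
  # a fully paired stem I (explicit pairing) has no bulge to read
  seq <- "GGGGGAAAACCCCC"
  full <- structure(list(sequence = seq,
                         pairs = cbind(1:7, 14:8),
                         pair_count = 7L,
                         paired = rep(TRUE, 14),
                         dot_bracket = NULL, min_loop = 3L,
                         allow_GU = TRUE),
                    class = "pairing_result")
  expect_identical(nrow(find_specifier(as_region(seq), c(0L, 14L),
                                       pairing = full)), 0L)
})
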