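test_that("codons translate under the standard genetic code", {
  expect_identical(codon_to_aa(c("AAA", "AAC", "TTT")),
                   c("Lys", "Asn", "Phe"))
  expect_identical(codon_to_aa("AAU"), "Asn")   # RNA spelling
  expect_identical(codon_to_aa("ANA"), "unknown")
  expect_identical(codon_to_aa("TAA"), "Stop")
  expect_error(codon_to_aa("AA"), "length 3")
})

test_that("mixed-codon-box partners follow the standard code's split boxes", {
  expect_identical(mixed_box_partner("Lys"), "Asn")
  expect_identical(mixed_box_partner("Asn"), "Lys")
  expect_identical(mixed_box_partner("Asp"), "Glu")
  expect_identical(mixed_box_partner("His"), "Gln")
  expect_identical(mixed_box_partner("Phe"), "Leu")
  expect_identical(mixed_box_partner("Cys"), "Trp")
  # family boxes have no partner
  expect_identical(mixed_box_partner("Gly"), NA_character_)
  expect_identical(mixed_box_partner("Pro"), NA_character_)
  # serine spans TCN (family) and the split AGN box
  expect_true("Arg" %in% mixed_box_partner("Ser"))
  expect_identical(mixed_box_partner("none"), NA_character_)
  expect_error(mixed_box_partner("Xyz"), "not a standard")
})

test_that("a clean implant yields a positive call with its cognate", {
  b <- build_leader(implant_spec(specifier_codon = "AAA"), seed = 61)
  call <- call_tbox_regulation(list(gene_id = "g1", aars_name = "lysK",
                                    class = "I"),
                               as_region(b$sequence))
  expect_true(call$tbox_regulated)
  expect_true(call$exclusive)
  expect_identical(call$motif$offset, 38L)
  expect_true(call$terminator$passes)
  expect_true(call$antiterminator$contains_tbox)
  expect_identical(call$predicted_cognate, "Lys")
  expect_identical(call$mixed_box_partner, "Asn")
})

test_that("breaking any conjunct flips the call to negative", {
  # U-tract destroyed
  b1 <- build_leader(implant_spec(u_tract = 0L), seed = 62)
  c1 <- call_tbox_regulation(list(gene_id = "g", aars_name = "x"),
                             as_region(b1$sequence))
  expect_false(c1$tbox_regulated)
  # terminator stem below threshold
  b2 <- build_leader(implant_spec(terminator_stem = 4L), seed = 63)
  c2 <- call_tbox_regulation(list(gene_id = "g", aars_name = "x"),
                             as_region(b2$sequence))
  expect_false(c2$tbox_regulated)
  # no antiterminator overlap
  b3 <- build_leader(implant_spec(antiterminator_overlap = FALSE),
                     seed = 64)
  c3 <- call_tbox_regulation(list(gene_id = "g", aars_name = "x"),
                             as_region(b3$sequence))
  expect_false(c3$tbox_regulated)
  # no motif at all
  c4 <- call_tbox_regulation(list(gene_id = "g", aars_name = "x"),
                             as_region(strrep("A", 120)))
  expect_false(c4$tbox_regulated)
  expect_null(c4$motif)
  expect_identical(c4$predicted_cognate, "none")
})

test_that("relaxing thresholds never flips a positive call to negative", {
  for (seed in 71:75) {
    b <- build_leader(implant_spec(), seed = seed)
    region <- as_region(b$sequence)
    hit <- list(gene_id = "g", aars_name = "x")
    base <- call_tbox_regulation(hit, region)
    expect_true(base$tbox_regulated)
    relaxed <- list(
      tbox_params(max_suffix_mismatches = 3L),
      tbox_params(min_stem = 5L),
      tbox_params(min_u = 3L),
      tbox_params(anti_min_stem = 3L))
    for (p in relaxed) {
      expect_true(call_tbox_regulation(hit, region, p)$tbox_regulated)
    }
  }
})

test_that("the survey table mirrors the two-LysRS genome pattern", {
  pos <- build_leader(implant_spec(specifier_codon = "AAA"), seed = 81)
  neg <- tboxscan:::scrambled_leader(pos$sequence, tbox_params())
  calls <- list(
    call_tbox_regulation(list(gene_id = "lysS_gene",
                              aars_name = "lysS", class = "II"),
                         as_region(neg$sequence, "lysS_gene")),
    call_tbox_regulation(list(gene_id = "lysK_gene",
                              aars_name = "lysK", class = "I"),
                         as_region(pos$sequence, "lysK_gene")))
  rep <- survey_report(calls)
  expect_identical(rep$genes$tbox_regulated, c("No", "Yes"))
  expect_identical(rep$genes$class, c("II", "I"))
  expect_identical(rep$genes$predicted_cognate[2], "Lys")
  expect_identical(rep$genes$specifier[2], "AAA")
  expect_identical(rep$summary$n_tbox[rep$summary$aars_name == "lysK"],
                   1L)
})

test_that("an empty call list yields an empty table with a header", {
  rep <- survey_report(list())
  expect_identical(nrow(rep$genes), 0L)
  expect_true(all(c("gene_id", "aars_name", "tbox_regulated") %in%
                  names(rep$genes)))
})

test_that("synthetic cohort summary counts equal the truth table's", {
  g <- generate_genome(n_genes = 12, fraction_tbox = 0.5, seed = 11)
  res <- survey_genome(g$genome, g$genes)
  rep <- res$report$genes
  m <- merge(rep, g$truth[, c("gene_id", "expected_call")],
             by = "gene_id")
  expect_identical(nrow(m), nrow(g$truth))
  expect_identical(m$tbox_regulated == "Yes", m$expected_call)
  expect_identical(sum(res$report$summary$n_tbox),
                   sum(g$truth$expected_call))
})
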