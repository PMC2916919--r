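test_that("GFF3 coordinates convert to 0-based half-open and proteins translate", {
  contig <- paste0(strrep("A", 30),
                   "ATGAAACTGTAA",           # + strand CDS at [30, 42)
                   strrep("C", 20))
  # - strand CDS: revcomp(ATGGAATAA) placed at [62, 71)
  contig <- paste0(contig, revcomp("ATGGAATAA"), strrep("G", 10))
  paths <- write_tiny_genome(
    list(ctg = contig),
    c("ctg\ttest\tCDS\t31\t42\t.\t+\t0\tID=gp;product=plus protein",
      "ctg\ttest\tCDS\t63\t71\t.\t-\t0\tID=gm;product=minus protein"))
  dat <- read_genome(paths["fasta"], paths["gff"])
  expect_identical(unname(nchar(dat$genome)), nchar(contig))
  gp <- dat$genes[dat$genes$gene_id == "gp", ]
  expect_identical(gp$start, 30L)
  expect_identical(gp$end, 42L)
  expect_identical(gp$strand, "+")
  expect_identical(gp$protein, "MKL")
  gm <- dat$genes[dat$genes$gene_id == "gm", ]
  expect_identical(gm$start, 62L)
  expect_identical(gm$end, 71L)
  expect_identical(gm$protein, "ME")
})

test_that("annotation without CDS features yields records and no genes", {
  paths <- write_tiny_genome(
    list(ctg = "ACGTACGTACGT"),
    "ctg\ttest\tgene\t1\t4\t.\t+\t.\tID=notacds")
  dat <- read_genome(paths["fasta"], paths["gff"])
  expect_identical(names(dat$genome), "ctg")
  expect_identical(nrow(dat$genes), 0L)
})

test_that("malformed inputs are reported with the offending file", {
  paths <- write_tiny_genome(
    list(ctg = "ACGT"),
    "other_ctg\ttest\tCDS\t1\t3\t.\t+\t0\tID=x")
  expect_error(read_genome(paths["fasta"], paths["gff"]),
               "absent from FASTA")
  expect_error(read_genome("no/such.fasta", paths["gff"]), "not found")
  # joined CDS (two segments sharing an ID) rejected
  paths2 <- write_tiny_genome(
    list(ctg = strrep("ACGT", 10)),
    c("ctg\ttest\tCDS\t1\t6\t.\t+\t0\tID=j1",
      "ctg\ttest\tCDS\t10\t15\t.\t+\t0\tID=j1"))
  expect_error(read_genome(paths2["fasta"], paths2["gff"]),
               "multiple segments")
})

test_that("upstream extraction follows strand, truncation and contig edges", {
  set.seed(404)
  contig <- rand_dna(2500)
  genome <- c(ctg = contig)
  plus <- data.frame(gene_id = "p", contig_id = "ctg", start = 1000L,
                     end = 2000L, strand = "+", product = NA,
                     protein = NA, stringsAsFactors = FALSE)
  minus <- plus; minus$gene_id <- "m"; minus$strand <- "-"

  up <- extract_upstream(plus, genome, max_len = 300)
  expect_identical(c(up$start, up$end), c(700L, 1000L))
  expect_identical(up$sequence, substr(contig, 701, 1000))
  expect_false(up$truncated_by_neighbor)

  um <- extract_upstream(minus, genome, max_len = 300)
  expect_identical(c(um$start, um$end), c(2000L, 2300L))
  expect_identical(um$sequence, revcomp(substr(contig, 2001, 2300)))

  # neighbor ending at 900 truncates the + window
  nb <- data.frame(gene_id = "n", contig_id = "ctg", start = 500L,
                   end = 900L, strand = "+", product = NA, protein = NA,
                   stringsAsFactors = FALSE)
  ut <- extract_upstream(plus, genome, max_len = 300,
                         neighbors = rbind(plus, nb))
  expect_identical(c(ut$start, ut$end), c(900L, 1000L))
  expect_identical(nchar(ut$sequence), 100L)
  expect_true(ut$truncated_by_neighbor)
  # truncation can be disabled
  un <- extract_upstream(plus, genome, max_len = 300,
                         neighbors = rbind(plus, nb),
                         truncate_at_neighbor = FALSE)
  expect_identical(c(un$start, un$end), c(700L, 1000L))

  # gene flush at the contig start has no upstream space
  edge <- plus; edge$start <- 0L; edge$end <- 50L
  ue <- extract_upstream(edge, genome, max_len = 300)
  expect_identical(ue$sequence, "")
  expect_identical(c(ue$start, ue$end), c(0L, 0L))
})

test_that("upstream regions never include the gene itself and survive mirroring", {
  g <- generate_genome(n_genes = 6, fraction_tbox = 0.5, seed = 21)
  mir <- mirror_genome(g$genome, g$genes)
  for (gid in g$truth$gene_id) {
    gene <- g$genes[g$genes$gene_id == gid, ]
    up <- extract_upstream(gene, g$genome, neighbors = g$genes)
    # no overlap with the gene interval
    expect_true(up$end <= gene$start || up$start >= gene$end)
    gene_m <- mir$genes[mir$genes$gene_id == gid, ]
    up_m <- extract_upstream(gene_m, mir$genome, neighbors = mir$genes)
    expect_identical(up_m$sequence, up$sequence)
  }
})

test_that("synthetic genomes round-trip bit-identically through FASTA + GFF3", {
  g <- generate_genome(n_genes = 5, fraction_tbox = 0.4, seed = 9,
                       out_dir = tempfile())
  dat <- read_genome(g$files["genome"], g$files["gff"])
  expect_identical(dat$genome, g$genome)
  a <- g$genes[order(g$genes$gene_id), ]
  b <- dat$genes[order(dat$genes$gene_id), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})
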