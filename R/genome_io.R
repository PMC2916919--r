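#' Read a genome and its gene annotations
#'
#' Loads contig sequences from a nucleotide FASTA file and CDS features from
#' a GFF3 file. GFF3 coordinates (1-based, inclusive) are converted to the
#' package-internal 0-based half-open convention at this boundary and used
#' consistently everywhere downstream. Proteins are taken from the
#' annotation when present and otherwise translated from the genome with
#' the standard genetic code.
#'
#' @param fasta_path Path to the nucleotide FASTA.
#' @param gff_path Path to the GFF3 annotation (CDS features are used;
#'   attributes `ID`, `locus_tag` and `product` are honoured).
#' @return A list with
#'   \describe{
#'     \item{genome}{Named character vector of contig sequences (A/C/G/T/N).}
#'     \item{genes}{Data frame with columns `gene_id`, `contig_id`,
#'       `start`, `end` (0-based half-open), `strand`, `product`,
#'       `protein`.}
#'   }
#' @details Joined (multi-segment) CDS features are rejected: the pipeline
#'   targets bacterial genomes, where CDS features are single intervals.
#'   A CDS referencing a contig absent from the FASTA is an error.
#' @export
read_genome <- function(fasta_path, gff_path) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  if (!file.exists(gff_path)) stop("GFF3 file not found: ", gff_path)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(fasta_path),
    error = function(e) stop("malformed FASTA '", fasta_path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  genome <- normalize_dna(as.character(seqs))
  # FASTA headers may carry descriptions after the identifier
  names(genome) <- sub("\\s.*$", "", names(seqs))

  gff <- tryCatch(
    rtracklayer::import(gff_path, format = "gff3"),
    error = function(e) stop("malformed GFF3 '", gff_path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  cds <- gff[!is.na(gff$type) & gff$type == "CDS"]
  if (length(cds) == 0L) {
    return(list(genome = genome, genes = empty_gene_table()))
  }
  ids <- as.character(cds$ID)
  if (!is.null(cds$locus_tag)) {
    lt <- as.character(cds$locus_tag)
    ids <- ifelse(is.na(ids) | ids == "", lt, ids)
  }
  if (anyNA(ids) || any(ids == "")) {
    stop("GFF3 '", gff_path, "': CDS feature without ID or locus_tag ",
         "(feature #", which(is.na(ids) | ids == "")[1], ")")
  }
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop("GFF3 '", gff_path, "': CDS '", dup, "' has multiple segments; ",
         "joined/spliced CDS features are not supported")
  }
  contig <- as.character(GenomicRanges::seqnames(cds))
  missing <- setdiff(unique(contig), names(genome))
  if (length(missing)) {
    stop("GFF3 '", gff_path, "' references contig(s) absent from FASTA: ",
         paste(missing, collapse = ", "))
  }
  start0 <- GenomicRanges::start(cds) - 1L
  end0 <- GenomicRanges::end(cds)
  strand <- as.character(GenomicRanges::strand(cds))
  if (any(strand == "*")) {
    stop("GFF3 '", gff_path, "': CDS without strand: ",
         ids[strand == "*"][1])
  }
  clen <- nchar(genome)[contig]
  bad <- start0 < 0L | end0 > clen | start0 >= end0
  if (any(bad)) {
    stop("GFF3 '", gff_path, "': CDS '", ids[bad][1],
         "' has coordinates outside its contig")
  }
  product <- if (!is.null(cds$product)) as.character(cds$product)
             else rep(NA_character_, length(cds))
  genes <- data.frame(
    gene_id = ids, contig_id = contig,
    start = start0, end = end0, strand = strand,
    product = product, protein = NA_character_,
    stringsAsFactors = FALSE
  )
  genes$protein <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    dna <- substr(genome[[g$contig_id]], g$start + 1L, g$end)
    if (g$strand == "-") dna <- revcomp(dna)
    if (nchar(dna) %% 3L != 0L) return(NA_character_)
    translate_cds(dna)
  }, character(1))
  genes <- genes[order(genes$contig_id, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  list(genome = genome, genes = genes)
}

empty_gene_table <- function() {
  data.frame(gene_id = character(), contig_id = character(),
             start = integer(), end = integer(), strand = character(),
             product = character(), protein = character(),
             stringsAsFactors = FALSE)
}

#' Write a genome and annotations to FASTA + GFF3
#'
#' Inverse of [read_genome()] for pipeline outputs and synthetic genomes;
#' internal 0-based half-open coordinates are converted back to GFF3
#' 1-based inclusive coordinates.
#'
#' @param genome Named character vector of contig sequences.
#' @param genes Gene annotation data frame (see [read_genome()]).
#' @param fasta_path,gff_path Output paths.
#' @return Invisibly, a character vector of the two paths.
#' @export
write_genome <- function(genome, genes, fasta_path, gff_path) {
  dna <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(dna, fasta_path)
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig_id,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  gr$source <- "tboxscan"
  gr$type <- "CDS"
  gr$phase <- 0L
  gr$ID <- genes$gene_id
  gr$locus_tag <- genes$gene_id
  gr$product <- genes$product
  rtracklayer::export(gr, gff_path, format = "gff3")
  invisible(c(fasta_path, gff_path))
}

#' Extract the upstream region of a gene
#'
#' Returns up to `max_len` nucleotides immediately 5' of a gene in the
#' gene's own reading orientation: for minus-strand genes the forward
#' slice downstream of the gene end is taken and reverse-complemented.
#' When `truncate_at_neighbor` is enabled the window additionally stops at
#' the nearest annotated gene boundary so leaders never run through a
#' neighbouring coding sequence.
#'
#' @param gene One-row gene annotation (a row of the `genes` data frame).
#' @param genome Named character vector of contig sequences.
#' @param max_len Maximum window length in nt (default 500; T-box leaders
#'   are typically 200-300 nt, so this covers them with margin).
#' @param neighbors Optional annotation data frame used for truncation
#'   (the gene itself is ignored).
#' @param truncate_at_neighbor Stop at the nearest gene boundary?
#' @return A list of class `upstream_region` with `gene_id`, `sequence`
#'   (5'->3' in gene orientation), `start`, `end` (forward-strand 0-based
#'   half-open interval) and `truncated_by_neighbor`. A gene flush against
#'   the contig edge yields a zero-length region, not an error.
#' @export
extract_upstream <- function(gene, genome, max_len = 500L,
                             neighbors = NULL,
                             truncate_at_neighbor = TRUE) {
  stopifnot(max_len >= 1L)
  if (is.data.frame(gene)) {
    stopifnot(nrow(gene) == 1L)
    gene <- as.list(gene)
  }
  contig <- genome[[gene$contig_id]]
  if (is.null(contig)) stop("unknown contig: ", gene$contig_id)
  clen <- nchar(contig)
  truncated <- FALSE
  if (gene$strand == "+") {
    lo <- max(0L, gene$start - as.integer(max_len))
    hi <- gene$start
    if (truncate_at_neighbor && !is.null(neighbors)) {
      nb <- neighbors[neighbors$contig_id == gene$contig_id &
                      neighbors$gene_id != gene$gene_id &
                      neighbors$end <= gene$start, , drop = FALSE]
      if (nrow(nb) && max(nb$end) > lo) {
        lo <- max(nb$end)
        truncated <- TRUE
      }
    }
    seq <- if (hi > lo) substr(contig, lo + 1L, hi) else ""
  } else {
    lo <- gene$end
    hi <- min(clen, gene$end + as.integer(max_len))
    if (truncate_at_neighbor && !is.null(neighbors)) {
      nb <- neighbors[neighbors$contig_id == gene$contig_id &
                      neighbors$gene_id != gene$gene_id &
                      neighbors$start >= gene$end, , drop = FALSE]
      if (nrow(nb) && min(nb$start) < hi) {
        hi <- min(nb$start)
        truncated <- TRUE
      }
    }
    seq <- if (hi > lo) revcomp(substr(contig, lo + 1L, hi)) else ""
  }
  structure(
    list(gene_id = gene$gene_id, sequence = seq,
         start = as.integer(lo), end = as.integer(hi),
         truncated_by_neighbor = truncated),
    class = "upstream_region"
  )
}

#' @export
print.upstream_region <- function(x, ...) {
  cat("Upstream region of", x$gene_id, "\n")
  cat("  forward interval [", x$start, ",", x$end, ") ",
      if (x$truncated_by_neighbor) "(truncated at neighbor)" else "",
      "\n", sep = "")
  cat("  ", nchar(x$sequence), " nt: ",
      if (nchar(x$sequence) > 60)
        paste0(substr(x$sequence, 1, 57), "...")
      else x$sequence, "\n", sep = "")
  invisible(x)
}

region_sequence <- function(region) {
  if (inherits(region, "upstream_region")) region$sequence
  else normalize_dna(region)
}

region_gene_id <- function(region) {
  if (inherits(region, "upstream_region")) region$gene_id else NA_character_
}
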