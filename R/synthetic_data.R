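#' Implant specification for a synthetic T-box leader
#'
#' Describes one implanted leader: the specifier codon shown in the stem I
#' bulge, the number of forced substitutions in the last six motif
#' positions (3 makes the motif undetectable by the scanning rule), the
#' terminator stem length and U-tract length, whether the antiterminator
#' arm overlapping the terminator 5' arm is implanted, the leader length
#' and the protein identity of the attached AARS-like gene to its
#' reference.
#'
#' @param specifier_codon 3-nt codon (default "AAA", lysine).
#' @param motif_mismatches Integer 0-3.
#' @param terminator_stem Terminator stem length in bp (default 7).
#' @param u_tract Number of T residues after the terminator (default 6).
#' @param antiterminator_overlap Implant the overlapping antiterminator
#'   arm (default TRUE)?
#' @param leader_len Total leader length in nt (default 160; canonical
#'   T-box leaders are 200-300 nt, and the implanted architecture is a
#'   compact version of the same element order).
#' @param aars_identity Protein identity of the implanted gene to its
#'   reference, in (0, 1] (default 0.8).
#' @return A list of class `implant_spec`.
#' @export
implant_spec <- function(specifier_codon = "AAA",
                         motif_mismatches = 0L,
                         terminator_stem = 7L,
                         u_tract = 6L,
                         antiterminator_overlap = TRUE,
                         leader_len = 160L,
                         aars_identity = 0.8) {
  specifier_codon <- chartr("U", "T", toupper(specifier_codon))
  stopifnot(nchar(specifier_codon) == 3L,
            !grepl("[^ACGT]", specifier_codon),
            motif_mismatches >= 0L, motif_mismatches <= 3L,
            terminator_stem >= 1L, u_tract >= 0L,
            aars_identity > 0, aars_identity <= 1)
  structure(
    list(specifier_codon = specifier_codon,
         motif_mismatches = as.integer(motif_mismatches),
         terminator_stem = as.integer(terminator_stem),
         u_tract = as.integer(u_tract),
         antiterminator_overlap = isTRUE(antiterminator_overlap),
         leader_len = as.integer(leader_len),
         aars_identity = aars_identity),
    class = "implant_spec"
  )
}

# synonymous codon (DNA spelling) of a codon with minimal G+C content,
# used as the stem I apical loop so loop candidates agree with the bulge
synonymous_loop_codon <- function(codon) {
  code <- Biostrings::GENETIC_CODE   # named by DNA codons
  aa <- code[[codon]]
  syn <- names(code)[code == aa]
  gc <- vapply(syn, function(x)
    sum(strsplit(x, "")[[1]] %in% c("G", "C")), integer(1))
  syn[order(gc, syn)][1]
}

#' Mutate a protein to a target identity
#'
#' Substitutes a deterministic (seeded) random set of positions with
#' different residues so that the realized identity equals the target up
#' to rounding (within 2 percentage points).
#'
#' @param reference Amino-acid string.
#' @param target_identity Target identity in (0, 1].
#' @param seed Integer seed; the same seed reproduces the same output.
#' @return Mutated amino-acid string.
#' @export
mutate_protein <- function(reference, target_identity, seed) {
  stopifnot(target_identity > 0, target_identity <= 1)
  L <- nchar(reference)
  n_sub <- round((1 - target_identity) * L)
  if (n_sub == 0L) return(reference)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  with_seed(seed, {
    pos <- sample.int(L, n_sub)
    ch <- strsplit(reference, "")[[1]]
    for (p in pos) {
      ch[p] <- sample(setdiff(aas, ch[p]), 1L)
    }
    paste(ch, collapse = "")
  })
}

# reverse-translate a protein with randomly chosen synonymous codons,
# appending a TAA stop; consumes the ambient RNG stream
reverse_translate <- function(protein) {
  code <- Biostrings::GENETIC_CODE
  by_aa <- split(names(code), code)
  ch <- strsplit(protein, "")[[1]]
  codons <- vapply(ch, function(a) {
    opts <- by_aa[[a]]
    if (is.null(opts)) stop("cannot reverse-translate residue '", a, "'")
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1), USE.NAMES = FALSE)
  paste0(paste(codons, collapse = ""), "TAA")
}

# assemble one leader sequence from an implant spec; geometry is fixed so
# that the stem I interval used by the classifier ([0, motif - 12)) ends
# exactly at the stem I hairpin
leader_geometry <- function(spec) {
  stem <- spec$terminator_stem
  min_len <- 55L + 2L * stem + spec$u_tract
  if (spec$leader_len < min_len) {
    stop("leader_len ", spec$leader_len, " too small for this implant; ",
         "need at least ", min_len)
  }
  list(motif_offset = 38L, t5_start = 51L,
       t5_end = 51L + stem, tloop = 4L,
       t3_start = 55L + stem, t3_end = 55L + 2L * stem,
       specifier_offset = 7L, hairpin_end = 26L, min_len = min_len)
}

build_leader_once <- function(spec) {
  geo <- leader_geometry(spec)
  gc_arm <- function(n) paste(sample(c("G", "C"), n, replace = TRUE),
                              collapse = "")
  arm1 <- gc_arm(5L); arm2 <- gc_arm(4L)
  loop <- synonymous_loop_codon(spec$specifier_codon)
  hairpin <- paste0(arm1, spec$specifier_codon, arm2, loop,
                    revcomp(arm2), revcomp(arm1))
  lead <- random_dna(2L)

  # motif with the requested number of forced suffix substitutions
  motif <- strsplit("TGGNACCGCG", "")[[1]]
  motif[4] <- sample(c("A", "C", "G", "T"), 1L)
  if (spec$motif_mismatches > 0L) {
    at <- sample(5:10, spec$motif_mismatches)
    for (p in at) {
      motif[p] <- sample(setdiff(c("A", "C", "G", "T"), motif[p]), 1L)
    }
  }
  motif <- paste(motif, collapse = "")

  t5 <- gc_arm(spec$terminator_stem)
  tloop <- paste(sample(c("G", "A"), geo$tloop, replace = TRUE),
                 collapse = "")
  t3 <- revcomp(t5)
  a1 <- if (spec$antiterminator_overlap) revcomp(substr(t5, 1L, 6L))
        else random_dna(6L)
  gap1 <- random_dna(2L); gap2 <- random_dna(4L); gap3 <- random_dna(3L)
  utract <- strrep("T", spec$u_tract)
  core <- paste0(lead, hairpin, gap1, a1, gap2, motif, gap3,
                 t5, tloop, t3, utract)
  tail <- random_dna(spec$leader_len - nchar(core))
  paste0(core, tail)
}

# evaluate a leader with the pipeline's own calling logic
evaluate_leader <- function(sequence, params) {
  region <- structure(list(gene_id = "synthetic", sequence = sequence,
                           start = 0L, end = nchar(sequence),
                           truncated_by_neighbor = FALSE),
                      class = "upstream_region")
  call_tbox_regulation(list(gene_id = "synthetic",
                            aars_name = "synthetic"),
                       region, params)
}

#' Build a synthetic T-box leader
#'
#' Assembles, 5' to 3': a stem I hairpin whose bulge displays the
#' specifier codon, the antiterminator 5' arm, the (optionally mutated)
#' T-box motif, a terminator hairpin whose 5' arm is complementary to the
#' antiterminator arm when overlap is requested, a U-tract and random
#' filler to the requested length. The construct is then checked with the
#' pipeline's own calling logic at default parameters; random components
#' are redrawn (deterministically, bounded) until the realized call
#' matches the implant's expected outcome, and the redraw count is
#' recorded.
#'
#' @param spec An [implant_spec()].
#' @param seed Integer seed; output is a pure function of `spec` and
#'   `seed`.
#' @param params Pipeline parameters the expected outcome refers to.
#' @param max_redraws Bound on redraw attempts (default 50).
#' @return A list with `sequence` and `truth` (a list with
#'   `expected_call`, `motif_offset`, `terminator_interval`,
#'   `specifier_offset`, `redraws`).
#' @export
build_leader <- function(spec, seed, params = tbox_params(),
                         max_redraws = 50L) {
  geo <- leader_geometry(spec)
  expected <- spec$motif_mismatches <= params$max_suffix_mismatches &&
    spec$terminator_stem >= params$min_stem &&
    spec$u_tract >= params$min_u &&
    spec$antiterminator_overlap
  with_seed(seed, {
    for (attempt in 0:max_redraws) {
      sequence <- build_leader_once(spec)
      call <- evaluate_leader(sequence, params)
      ok <- if (expected) {
        call$tbox_regulated &&
          !is.null(call$motif) &&
          call$motif$offset == geo$motif_offset &&
          nrow(call$specifier_candidates) > 0L &&
          geo$specifier_offset %in% call$specifier_candidates$position &&
          call$predicted_cognate == codon_to_aa(spec$specifier_codon)
      } else {
        !call$tbox_regulated
      }
      if (ok) {
        return(list(
          sequence = sequence,
          truth = list(expected_call = expected,
                       motif_offset = if (spec$motif_mismatches <=
                                          params$max_suffix_mismatches)
                         geo$motif_offset else NA_integer_,
                       terminator_interval = c(geo$t5_start, geo$t3_end),
                       specifier_offset = geo$specifier_offset,
                       redraws = attempt)))
      }
    }
    stop("could not realize implant after ", max_redraws, " redraws ",
         "(specifier ", spec$specifier_codon, ")")
  })
}

# scrambled negative leader: same base composition, no functional element;
# redrawn until the pipeline calls it negative
scrambled_leader <- function(template, params, max_redraws = 50L) {
  ch <- strsplit(template, "")[[1]]
  for (attempt in 0:max_redraws) {
    sequence <- paste(sample(ch), collapse = "")
    if (!evaluate_leader(sequence, params)$tbox_regulated) {
      return(list(sequence = sequence, redraws = attempt))
    }
  }
  stop("could not scramble a negative leader after ", max_redraws,
       " redraws")
}

#' Generate an annotated synthetic genome with implanted T-box leaders
#'
#' Builds a single-contig genome of AARS-like genes (families drawn from
#' the bundled synthetic reference set, proteins mutated to a controlled
#' identity), each preceded by either an implanted T-box leader or a
#' scrambled negative leader of identical composition. Genes are placed
#' on random strands; a short "hypothetical protein" CDS abuts each
#' leader so that neighbor-truncated upstream extraction recovers exactly
#' the implanted leader. A machine-readable truth table records every
#' implant.
#'
#' @param n_genes Number of AARS-like genes (>= 1).
#' @param fraction_tbox Fraction of genes receiving a functional implant.
#' @param seed Integer seed; the output is fully reproducible from it.
#' @param out_dir Optional directory; when given, writes `genome.fasta`,
#'   `genes.gff3`, `proteins.faa`, `truth.tsv` and `manifest.json`.
#' @param refs Reference protein data frame (default: bundled synthetic
#'   set).
#' @param implant Base [implant_spec()] applied to every positive gene.
#' @param identity_range Range the per-gene AARS protein identity is
#'   drawn from (default 0.65-0.95).
#' @param params Pipeline parameters the truth table refers to.
#' @return A list with `genome` (named character vector), `genes`
#'   (annotation data frame), `proteins` (named character vector),
#'   `truth` (data frame), `manifest` (list) and, when `out_dir` is
#'   given, `files`.
#' @export
generate_genome <- function(n_genes, fraction_tbox = 0.5, seed = 1L,
                            out_dir = NULL, refs = NULL,
                            implant = implant_spec(),
                            identity_range = c(0.65, 0.95),
                            params = tbox_params()) {
  stopifnot(n_genes >= 1L, fraction_tbox >= 0, fraction_tbox <= 1)
  if (is.null(refs)) refs <- read_reference_proteins()
  n_pos <- round(n_genes * fraction_tbox)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

  res <- with_seed(seed, {
    pos_idx <- if (n_pos > 0L) sort(sample.int(n_genes, n_pos))
               else integer(0)
    blocks <- character(0)
    gene_rows <- list()
    truth_rows <- list()
    proteins <- character(0)
    cursor <- 0L

    for (i in seq_len(n_genes)) {
      ref_i <- sample.int(nrow(refs), 1L)
      identity <- runif(1L, identity_range[1], identity_range[2])
      prot <- mutate_protein(refs$sequence[ref_i], identity,
                             derive_seed(seed, i))
      cds <- reverse_translate(prot)
      strand <- sample(c("+", "-"), 1L)
      gid <- sprintf("SYN_%04d", i)
      did <- sprintf("DUM_%04d", i)
      dummy_prot <- paste0("M", paste(sample(aas, 49L, replace = TRUE),
                                      collapse = ""))
      dummy_cds <- reverse_translate(dummy_prot)

      positive <- i %in% pos_idx
      if (positive) {
        built <- build_leader(implant, derive_seed(seed, 1000000L + i),
                              params = params)
        leader <- built$sequence
        tr <- built$truth
      } else {
        template <- build_leader_once(implant)
        scr <- scrambled_leader(template, params)
        leader <- scr$sequence
        tr <- list(expected_call = FALSE, motif_offset = NA_integer_,
                   terminator_interval = c(NA_integer_, NA_integer_),
                   specifier_offset = NA_integer_, redraws = scr$redraws)
      }

      L <- nchar(leader); lg <- nchar(cds); ld <- nchar(dummy_cds)
      if (strand == "+") {
        # [dummy][leader][gene]
        block <- paste0(dummy_cds, leader, cds)
        d_start <- cursor; g_start <- cursor + ld + L
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          gene_id = did, start = d_start, end = d_start + ld,
          strand = "+", product = "hypothetical protein",
          stringsAsFactors = FALSE)
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          gene_id = gid, start = g_start, end = g_start + lg,
          strand = "+",
          product = paste0(refs$aars_name[ref_i],
                           " aminoacyl-tRNA synthetase-like protein"),
          stringsAsFactors = FALSE)
      } else {
        # [gene (rc)][leader (rc)][dummy]
        block <- paste0(revcomp(cds), revcomp(leader), dummy_cds)
        g_start <- cursor; d_start <- cursor + lg + L
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          gene_id = gid, start = g_start, end = g_start + lg,
          strand = "-",
          product = paste0(refs$aars_name[ref_i],
                           " aminoacyl-tRNA synthetase-like protein"),
          stringsAsFactors = FALSE)
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          gene_id = did, start = d_start, end = d_start + ld,
          strand = "+", product = "hypothetical protein",
          stringsAsFactors = FALSE)
      }
      blocks <- c(blocks, block)
      cursor <- cursor + nchar(block)
      proteins[gid] <- prot
      proteins[did] <- dummy_prot

      truth_rows[[i]] <- data.frame(
        gene_id = gid, aars_name = refs$aars_name[ref_i],
        class = refs$class[ref_i], strand = strand,
        aars_identity = identity,
        specifier_codon = implant$specifier_codon,
        expected_call = tr$expected_call,
        motif_offset = tr$motif_offset,
        terminator_start = tr$terminator_interval[1],
        terminator_end = tr$terminator_interval[2],
        specifier_offset = tr$specifier_offset,
        redraws = tr$redraws, stringsAsFactors = FALSE)
    }

    genome <- c(synthetic_contig_1 = paste(blocks, collapse = ""))
    genes <- do.call(rbind, gene_rows)
    genes$contig_id <- "synthetic_contig_1"
    genes$protein <- unname(proteins[genes$gene_id])
    genes <- genes[, c("gene_id", "contig_id", "start", "end", "strand",
                       "product", "protein")]
    rownames(genes) <- NULL
    truth <- do.call(rbind, truth_rows)
    rownames(truth) <- NULL
    list(genome = genome, genes = genes, proteins = proteins,
         truth = truth)
  })

  res$manifest <- list(
    n_genes = n_genes, fraction_tbox = fraction_tbox, seed = seed,
    implant = unclass(implant), identity_range = identity_range,
    n_positive = sum(res$truth$expected_call))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(out_dir, "genome.fasta")
    gff <- file.path(out_dir, "genes.gff3")
    faa <- file.path(out_dir, "proteins.faa")
    tsv <- file.path(out_dir, "truth.tsv")
    man <- file.path(out_dir, "manifest.json")
    write_genome(res$genome, res$genes, fa, gff)
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(res$proteins), faa)
    write.table(res$truth, tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
    jsonlite::write_json(res$manifest, man, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    res$files <- c(genome = fa, gff = gff, proteins = faa, truth = tsv,
                   manifest = man)
  }
  res
}
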