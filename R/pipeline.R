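#' Survey an in-memory genome for T-box regulated AARS genes
#'
#' Core orchestration: AARS homology classification, strand-aware
#' upstream extraction, motif scanning and structure assessment, one
#' `tbox_call` per homology hit.
#'
#' @param genome Named character vector of contig sequences.
#' @param genes Gene annotation data frame (see [read_genome()]).
#' @param refs Reference protein data frame
#'   (default: bundled synthetic set).
#' @param params A [tbox_params()] list.
#' @return A list with `hits` (homology table), `regions` (named list of
#'   `upstream_region`s), `calls` (list of `tbox_call`s) and `report`
#'   (a `tbox_survey`).
#' @export
survey_genome <- function(genome, genes, refs = NULL,
                          params = tbox_params()) {
  if (is.null(refs)) refs <- read_reference_proteins()
  hits <- classify_aars(genes, refs, params)
  regions <- list()
  calls <- list()
  if (nrow(hits)) {
    for (i in seq_len(nrow(hits))) {
      gid <- hits$gene_id[i]
      if (is.null(regions[[gid]])) {
        gene <- genes[genes$gene_id == gid, , drop = FALSE]
        regions[[gid]] <- extract_upstream(
          gene, genome, max_len = params$max_len, neighbors = genes,
          truncate_at_neighbor = params$truncate_at_neighbor)
      }
      calls[[i]] <- call_tbox_regulation(hits[i, ], regions[[gid]],
                                         params)
    }
  }
  list(hits = hits, regions = regions, calls = calls,
       report = survey_report(calls))
}

#' Run the survey pipeline on genome files
#'
#' File-level wrapper around [survey_genome()]: reads the genome and
#' annotations, runs all stages, and writes a survey TSV, a homology TSV,
#' a JSON evidence document and a per-stage run log into `out_dir`.
#'
#' @param genome_fasta,gff_path Genome sequence and annotation paths.
#' @param refs_path Optional reference protein FASTA (default: bundled
#'   synthetic set).
#' @param out_dir Output directory (created if needed).
#' @param params A [tbox_params()] list (or use `config` for a YAML file).
#' @param config Optional YAML config path; overrides `params`.
#' @return Invisibly, the [survey_genome()] result with an added `files`
#'   element.
#' @export
run_survey <- function(genome_fasta, gff_path, refs_path = NULL,
                       out_dir = ".", params = tbox_params(),
                       config = NULL) {
  if (!is.null(config)) params <- read_config(config)
  dat <- read_genome(genome_fasta, gff_path)
  refs <- read_reference_proteins(refs_path)
  res <- survey_genome(dat$genome, dat$genes, refs, params)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  survey_tsv <- file.path(out_dir, "survey.tsv")
  hits_tsv <- file.path(out_dir, "homology_hits.tsv")
  evidence_json <- file.path(out_dir, "evidence.json")
  log_path <- file.path(out_dir, "run.log")

  write.table(res$report$genes, survey_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(res$hits, hits_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(lapply(res$calls, serialize_call), evidence_json,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  log_lines <- c(
    paste0("tboxscan survey ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("genome: ", genome_fasta),
    paste0("annotations: ", gff_path),
    paste0("stage genes: ", nrow(dat$genes), " CDS"),
    paste0("stage homology: ", nrow(res$hits), " AARS hit(s)"),
    paste0("stage motif+structure: ", length(res$calls), " call(s), ",
           sum(vapply(res$calls, function(x) x$tbox_regulated,
                      logical(1))), " T-box regulated"))
  writeLines(log_lines, log_path)
  res$files <- c(survey = survey_tsv, hits = hits_tsv,
                 evidence = evidence_json, log = log_path)
  invisible(res)
}

# flatten a tbox_call into JSON-friendly plain lists
serialize_call <- function(call) {
  term <- call$terminator
  anti <- call$antiterminator
  list(
    gene_id = call$gene_id,
    aars_name = call$aars_name,
    class = call$class,
    tbox_regulated = call$tbox_regulated,
    motif = if (!is.null(call$motif)) as.list(call$motif),
    terminator = if (!is.null(term))
      list(stem5 = term$stem5, stem3 = term$stem3,
           loop_len = term$loop_len, stem_len = term$stem_len,
           u_tract_count = term$u_tract_count, passes = term$passes),
    antiterminator = if (!is.null(anti) && anti$found)
      list(span = anti$span, arm5 = anti$arm5, arm3 = anti$arm3,
           stem_len = anti$stem_len,
           contains_tbox = anti$contains_tbox,
           overlaps_terminator = anti$overlaps_terminator),
    exclusive = call$exclusive,
    specifier_candidates = if (nrow(call$specifier_candidates))
      call$specifier_candidates,
    predicted_cognate = call$predicted_cognate,
    mixed_box_partner = call$mixed_box_partner)
}

#' Pairwise leader comparison to a TSV identity matrix
#'
#' @param leaders_fasta FASTA of leader sequences (at least two).
#' @param out_path Output TSV path for the symmetric identity matrix.
#' @param ... Scoring arguments passed to [compare_leaders()].
#' @return Invisibly, the identity matrix.
#' @export
run_compare <- function(leaders_fasta, out_path, ...) {
  m <- compare_leaders(leaders_fasta, ...)
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, out_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(m)
}
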