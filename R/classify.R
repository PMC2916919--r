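#' Translate a codon to a three-letter amino-acid name
#'
#' Standard genetic code; DNA and RNA spellings are equivalent. Codons
#' containing an ambiguous base translate to "unknown"; stop codons to
#' "Stop".
#'
#' @param codon Character vector of 3-nt codons.
#' @return Character vector of three-letter names.
#' @export
codon_to_aa <- function(codon) {
  codon <- chartr("Uu", "Tt", toupper(as.character(codon)))
  if (any(nchar(codon) != 3L)) stop("codons must have length 3")
  code <- Biostrings::GENETIC_CODE   # named by DNA codons
  aa1 <- unname(code[codon])
  aa1[is.na(aa1)] <- "?"
  aa_three_letter(aa1)
}

# split-codon-box partner table, computed from the standard genetic code:
# for every box (first two codon bases), the amino acids sharing it; an
# amino acid in a split box gains the other members as partners.
mixed_box_table <- function() {
  code <- Biostrings::GENETIC_CODE
  box <- substr(names(code), 1, 2)
  partners <- list()
  for (b in unique(box)) {
    aas <- setdiff(unique(code[box == b]), "*")
    if (length(aas) < 2L) next
    for (a in aas) {
      partners[[a]] <- union(partners[[a]], setdiff(aas, a))
    }
  }
  partners
}

#' Mixed-codon-box partner of an amino acid
#'
#' A mixed (split) codon box is a four-codon family whose members encode
#' two different amino acids; the AAN box, split between lysine (AAA/AAG)
#' and asparagine (AAU/AAC), is the case relevant to LysRS T-box leaders:
#' a Lys specifier codon can in principle be read by both tRNA families.
#' Amino acids encoded only by full family boxes have no partner.
#'
#' @param aa Three-letter amino-acid name (e.g. "Lys").
#' @return Character vector of partner names (possibly length > 1 for
#'   amino acids spanning several boxes), or `NA_character_` when the
#'   amino acid has no split-box partner.
#' @export
mixed_box_partner <- function(aa) {
  tbl <- mixed_box_table()
  names(tbl) <- aa_three_letter(names(tbl))
  if (length(aa) != 1L) stop("supply a single amino-acid name")
  all20 <- aa_three_letter(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]])
  if (!aa %in% all20) {
    if (aa %in% c("none", "ambiguous", "unknown", "Stop"))
      return(NA_character_)
    stop("not a standard amino-acid name: ", aa)
  }
  p <- tbl[[aa]]
  if (is.null(p) || !length(p)) return(NA_character_)
  sort(aa_three_letter(p))
}

#' Assemble the per-gene T-box regulation call
#'
#' Applies the full calling conjunction to one gene: a T-box motif match
#' in the upstream region, a passing Rho-independent terminator 3' of the
#' motif, an antiterminator hairpin containing the motif, and mutual
#' exclusivity of the two structures. When several motif/terminator
#' combinations qualify, the 5'-most motif (then the 5'-most terminator)
#' anchoring a valid antiterminator is selected. Partial evidence is kept
#' on negative calls so criteria can be revisited without rerunning the
#' scan.
#'
#' The predicted cognate amino acid is the unique amino acid among the
#' stem I specifier candidates; "ambiguous" when candidates disagree and
#' "none" when there are no candidates.
#'
#' @param hit A homology hit (list or one-row data frame with `gene_id`,
#'   `aars_name`, optionally `class`).
#' @param region The gene's `upstream_region`.
#' @param params A [tbox_params()] list.
#' @return A list of class `tbox_call`.
#' @export
call_tbox_regulation <- function(hit, region, params = tbox_params()) {
  if (is.data.frame(hit)) hit <- as.list(hit[1, ])
  spec <- tbox_motif_spec(params$motif_pattern, params$fixed_prefix_len,
                          params$max_suffix_mismatches)
  motifs <- scan_tbox(region, spec)
  terms <- find_terminators(region, params)
  passing <- Filter(function(t) t$passes, terms)

  sel_motif <- NULL; sel_term <- NULL; sel_anti <- NULL
  if (nrow(motifs) && length(passing)) {
    for (mi in seq_len(nrow(motifs))) {
      m <- motifs[mi, ]
      m_end <- m$offset + nchar(m$window)
      for (t in passing) {
        if (m_end > t$stem5[1]) next
        anti <- find_antiterminator(region, m, t, params)
        if (anti$found && anti$contains_tbox &&
            mutually_exclusive(t, anti)) {
          sel_motif <- m; sel_term <- t; sel_anti <- anti
          break
        }
      }
      if (!is.null(sel_motif)) break
    }
  }

  regulated <- !is.null(sel_motif)
  # partial evidence for negative calls
  ev_motif <- if (regulated) sel_motif
              else if (nrow(motifs)) motifs[1, ] else NULL
  ev_term <- if (regulated) sel_term
             else if (length(passing)) passing[[1]]
             else if (length(terms)) terms[[1]] else NULL
  ev_anti <- sel_anti
  if (!regulated && !is.null(ev_motif) && !is.null(ev_term)) {
    m_end <- ev_motif$offset + nchar(ev_motif$window)
    if (m_end <= ev_term$stem3[1]) {
      ev_anti <- find_antiterminator(region, ev_motif, ev_term, params)
    }
  }

  specifier <- data.frame()
  cognate <- "none"
  partner <- NA_character_
  if (!is.null(ev_motif)) {
    stemI_end <- max(0L, ev_motif$offset - params$anti_window_upstream)
    specifier <- find_specifier(region, c(0L, stemI_end), params = params)
    if (nrow(specifier)) {
      aas <- unique(specifier$amino_acid)
      cognate <- if (length(aas) == 1L) aas else "ambiguous"
    }
    if (!cognate %in% c("none", "ambiguous", "unknown", "Stop")) {
      p <- mixed_box_partner(cognate)
      partner <- if (all(is.na(p))) NA_character_
                 else paste(p, collapse = "/")
    }
  }

  structure(
    list(gene_id = hit$gene_id,
         aars_name = hit$aars_name,
         class = if (!is.null(hit$class)) hit$class else NA_character_,
         tbox_regulated = regulated,
         motif = ev_motif,
         terminator = ev_term,
         antiterminator = ev_anti,
         exclusive = regulated,
         specifier_candidates = specifier,
         predicted_cognate = cognate,
         mixed_box_partner = partner),
    class = "tbox_call"
  )
}

#' @export
print.tbox_call <- function(x, ...) {
  cat("T-box call for", x$gene_id, "(", x$aars_name, ")\n")
  cat("  regulated:", x$tbox_regulated,
      "| cognate:", x$predicted_cognate,
      if (!is.na(x$mixed_box_partner))
        paste("(mixed box partner:", x$mixed_box_partner, ")") else "",
      "\n")
  invisible(x)
}

#' Tabulate T-box calls for a genome survey
#'
#' One row per surveyed AARS gene (gene, AARS family, enzyme class,
#' regulation verdict, specifier codon, predicted cognate and mixed-box
#' partner) plus a per-family summary of gene and positive-call counts.
#'
#' @param calls List of `tbox_call` objects.
#' @return A list of class `tbox_survey` with data frames `genes` and
#'   `summary`.
#' @export
survey_report <- function(calls) {
  cols <- c("gene_id", "aars_name", "class", "tbox_regulated",
            "specifier", "predicted_cognate", "mixed_box_partner")
  if (!length(calls)) {
    genes <- data.frame(gene_id = character(), aars_name = character(),
                        class = character(), tbox_regulated = character(),
                        specifier = character(),
                        predicted_cognate = character(),
                        mixed_box_partner = character(),
                        stringsAsFactors = FALSE)
    summary <- data.frame(aars_name = character(), n_genes = integer(),
                          n_tbox = integer(), stringsAsFactors = FALSE)
    return(structure(list(genes = genes, summary = summary),
                     class = "tbox_survey"))
  }
  genes <- do.call(rbind, lapply(calls, function(x) {
    spc <- if (nrow(x$specifier_candidates) &&
               !x$predicted_cognate %in% c("none", "ambiguous"))
      x$specifier_candidates$codon[1] else NA_character_
    data.frame(gene_id = x$gene_id, aars_name = x$aars_name,
               class = x$class,
               tbox_regulated = if (x$tbox_regulated) "Yes" else "No",
               specifier = spc,
               predicted_cognate = x$predicted_cognate,
               mixed_box_partner = x$mixed_box_partner,
               stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL
  agg <- stats::aggregate(
    list(n_genes = rep(1L, nrow(genes)),
         n_tbox = as.integer(genes$tbox_regulated == "Yes")),
    by = list(aars_name = genes$aars_name), FUN = sum)
  agg <- agg[order(agg$aars_name), , drop = FALSE]
  rownames(agg) <- NULL
  structure(list(genes = genes, summary = agg), class = "tbox_survey")
}

#' @export
print.tbox_survey <- function(x, ...) {
  cat("T-box survey:", nrow(x$genes), "AARS gene(s),",
      sum(x$genes$tbox_regulated == "Yes"), "T-box regulated\n\n")
  print(x$genes, row.names = FALSE)
  invisible(x)
}
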