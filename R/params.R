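#' Default pipeline parameters
#'
#' Returns the full parameter list used by the survey pipeline. Two values
#' are fixed by the published screening rule the pipeline reproduces: the
#' homology E-value cutoff (`e_cutoff = 1e-10`) and the motif mismatch
#' budget (`max_suffix_mismatches = 2` over the last six motif positions).
#' All remaining thresholds are this package's explicit, configurable
#' surrogates for what was originally a manual structure inspection.
#'
#' @param ... Named overrides for individual parameters.
#' @return A list of class `tbox_params`.
#'
#' @details Parameters (units in nucleotides unless stated):
#' \describe{
#'   \item{e_cutoff}{Karlin-Altschul E-value threshold for AARS homology.}
#'   \item{substitution_matrix, gap_open, gap_extend}{Protein local
#'     alignment scoring (BLOSUM62, 11, 1).}
#'   \item{lambda, K}{Karlin-Altschul parameters for gapped BLOSUM62-11-1
#'     scoring (0.267, 0.041).}
#'   \item{max_len}{Maximum upstream window (500 nt).}
#'   \item{truncate_at_neighbor}{Stop the upstream window at the nearest
#'     annotated gene boundary (default TRUE).}
#'   \item{motif_pattern, fixed_prefix_len, max_suffix_mismatches}{The
#'     degenerate T-box motif rule: TGGNACCGCG, exact TGG prefix with a
#'     free fourth position, at most 2 mismatches over the final 6.}
#'   \item{min_stem, loop_min, loop_max, min_u, u_window}{Rho-independent
#'     terminator rule: hairpin stem of at least 6 bp (G:U allowed), loop
#'     3-8 nt, and at least 4 T residues in the 6 nt past the 3' arm.}
#'   \item{anti_min_stem, anti_min_loop, anti_window_upstream,
#'     anti_max_span}{Antiterminator hairpin rule: stem of at least 4 bp,
#'     5' arm starting within 12 nt upstream of the motif, total span at
#'     most 60 nt.}
#'   \item{min_loop, allow_GU}{Base-pair maximization settings: minimum
#'     hairpin loop of 3 unpaired bases; wobble G:U pairs allowed.}
#'   \item{min_bulge}{Minimum unpaired stretch hosting a specifier codon.}
#'   \item{seed}{Seed controlling all randomized helpers.}
#' }
#' @export
tbox_params <- function(...) {
  p <- list(
    # homology stage
    e_cutoff = 1e-10,
    substitution_matrix = "BLOSUM62",
    gap_open = 11L,
    gap_extend = 1L,
    lambda = 0.267,
    K = 0.041,
    # upstream extraction
    max_len = 500L,
    truncate_at_neighbor = TRUE,
    # motif stage
    motif_pattern = "TGGNACCGCG",
    fixed_prefix_len = 4L,
    max_suffix_mismatches = 2L,
    # terminator stage
    min_stem = 6L,
    loop_min = 3L,
    loop_max = 8L,
    min_u = 4L,
    u_window = 6L,
    # antiterminator stage
    anti_min_stem = 4L,
    anti_min_loop = 3L,
    anti_window_upstream = 12L,
    anti_max_span = 60L,
    # folding
    min_loop = 3L,
    allow_GU = TRUE,
    min_bulge = 3L,
    seed = 1L
  )
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(p))
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    }
    p <- modifyList(p, overrides)
  }
  validate_params(p)
  class(p) <- "tbox_params"
  p
}

validate_params <- function(p) {
  stopifnot(
    p$e_cutoff > 0,
    p$max_len >= 1L,
    p$max_suffix_mismatches >= 0L,
    p$min_stem >= 1L, p$loop_min >= 1L, p$loop_max >= p$loop_min,
    p$min_u >= 0L, p$u_window >= 1L,
    p$anti_min_stem >= 1L, p$anti_max_span >= 1L,
    p$min_loop >= 0L, p$min_bulge >= 1L,
    p$lambda > 0, p$K > 0
  )
  invisible(p)
}

#' Read pipeline parameters from a YAML config file
#'
#' Values in the file override the defaults of [tbox_params()]; keys absent
#' from the file keep their defaults.
#'
#' @param path Path to a YAML file of parameter overrides.
#' @return A `tbox_params` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  do.call(tbox_params, raw)
}

#' Write pipeline parameters to a YAML config file
#'
#' The written file round-trips losslessly through [read_config()].
#'
#' @param params A `tbox_params` list.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(params, path) {
  p <- unclass(params)
  yaml::write_yaml(p, path)
  invisible(path)
}
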