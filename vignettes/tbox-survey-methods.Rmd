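---
title: "Detecting T-box riboswitch leaders upstream of aminoacyl-tRNA synthetase genes"
author: "tboxscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting T-box riboswitch leaders upstream of aminoacyl-tRNA synthetase genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tboxscan)
```

## The biological question

T-box riboswitches are untranslated leader RNAs, typically 200-300 nt,
found upstream of many amino-acid-related genes in Gram-positive
bacteria. The leader senses the charging state of a specific tRNA: a
specifier codon displayed in a bulge of stem I pairs with the tRNA
anticodon, and the NCCA acceptor end of an *uncharged* tRNA pairs with
the UGGN bases of the conserved T-box sequence. That second contact
stabilizes an antiterminator hairpin which sequesters the 5' arm of a
Rho-independent terminator; with a charged tRNA the terminator forms
instead and transcription stops. A genome survey for such elements
upstream of aminoacyl-tRNA synthetase (AARS) genes therefore needs four
ingredients: finding the AARS genes, extracting their upstream leaders,
finding the conserved motif, and checking that the leader can form the
two mutually exclusive structures.

`tboxscan` implements that survey as a deterministic, fully configurable
pipeline, together with a synthetic-genome generator that implants
leaders with known properties so the whole chain can be validated
end-to-end without downloading any genome.

## Pipeline stages and their parameters

### 1. AARS identification by homology

Every annotated protein is aligned locally (affine gaps, BLOSUM62, gap
open 11, gap extend 1) against a reference AARS protein set, and hits
are converted to E-values with the Karlin-Altschul formula

$$E = K \, m \, n \, e^{-\lambda S}$$

using the standard gapped BLOSUM62-11-1 constants $\lambda = 0.267$,
$K = 0.041$. Only hits with $E < 10^{-10}$ are retained — this cutoff is
one of the two numeric filters the screening procedure is built around.
A gene keeps its best hit per AARS family, and *all* families passing
the cutoff are reported, so a genome encoding both a class I and a
class II lysyl-tRNA synthetase yields two records. Enzyme class (I/II)
is inherited from the best-matching reference protein, not from any
structural classification; a highly diverged LysRS could in principle
be mis-assigned, which is a documented limitation rather than a solved
problem.

The comparison is fixed as protein-vs-protein. Alignment scoring is
delegated to `Biostrings::pairwiseAlignment()`; the package's own tests
check it against an exhaustive alignment enumeration on small inputs.

### 2. Upstream region extraction

Coordinates are 0-based half-open internally; GFF3's 1-based inclusive
convention is converted exactly once, at the parser boundary. For a
plus-strand gene the window is the `max_len` nucleotides ending at the
gene start; for a minus-strand gene it is the forward-strand slice
starting at the gene end, reverse-complemented, so every leader is
handled 5' to 3' in its transcribed orientation.

How far "upstream" extends is genuinely underdetermined: a leader
could be bounded by a fixed window or by the neighbouring gene. Both
behaviours are provided. The defaults are `max_len = 500` nt — T-box
leaders are 200-300 nt, so 500 covers them with margin — and
`truncate_at_neighbor = TRUE`, because leaders do not run through
annotated coding sequences. A gene flush against a contig edge yields an
empty region flagged as such, never an error.

### 3. Degenerate motif scan

The motif rule is a literal degenerate string match, deliberately not a
weight matrix or covariance model: the 10-mer `TGGNACCGCG`, with

* positions 1-3 (`TGG`) matched exactly,
* position 4 (the variable T-box base, UGGN at RNA level) free,
* at most `max_suffix_mismatches = 2` substitutions over the final six
  positions (`ACCGCG`).

Only substitutions are tolerated; whether an indel should count as a
"mismatch" is unspecified in the rule's usual statement, and allowing
indels would make the match length ambiguous, so this package scans
fixed-length windows only. Genomic `N` never matches a constrained
position (conservative calling), but does match the pattern's own `N`.
All accepted windows are reported, including overlapping ones; the
classifier decides later which hit anchors a valid antiterminator.
Scanning is single-stranded because regions are already gene-oriented.

### 4. Structure assessment

The original structural check of candidate leaders was manual
inspection. The automation here replaces the expert's eye with explicit,
configurable rules; they are surrogates, and every threshold below is a
package decision, not a published number.

* **Terminator**: a hairpin with stem $\geq$ `min_stem` = 6 bp (G:U
  allowed), apical loop of 3-8 nt, and at least `min_u` = 4 T residues
  in the `u_window` = 6 nt following the 3' arm. Hairpins with a valid
  stem but a failing U-tract are still reported with `passes = FALSE`
  so that partial evidence survives.
* **Antiterminator**: a hairpin of stem $\geq$ `anti_min_stem` = 4 bp
  whose 5' arm starts within `anti_window_upstream` = 12 nt upstream of
  the motif, whose span contains the motif, whose 3' arm lies inside
  the terminator's 5' arm, and whose total span is at most
  `anti_max_span` = 60 nt (antiterminators are compact; without a span
  bound, a motif hundreds of nucleotides from the terminator could be
  "connected" to it by an absurd hairpin).
* **Mutual exclusivity**: true iff the antiterminator's paired bases
  intersect the terminator's 5' stem arm — a purely topological test of
  whether the two structures compete for the same nucleotides.
* **Specifier codon**: stem I is defined operationally as the leader
  prefix up to the antiterminator window start. The prefix is folded by
  base-pair maximization and every trinucleotide inside an unpaired
  stretch of $\geq$ `min_bulge` = 3 bases is reported as a candidate,
  translated with the standard genetic code.

A note on chemistry: these elements function at the RNA level, and the
package folds in RNA sense (T read as U, wobble G:U pairs allowed by
default), while motif and sequence handling use DNA spelling as
genomic surveys conventionally do. The two spellings are interconverted
losslessly and never mixed.

### The folding engine

Structures are predicted by Nussinov-style base-pair maximization over
Watson-Crick (+ optional G:U) pairs with a minimum hairpin loop of
`min_loop` = 3 (a pair $(i, j)$ requires $j - i > 3$). Base-pair
maximization was chosen over thermodynamic folding deliberately: the
mutual-exclusivity question is topological, no free-energy parameter
set is part of the procedure being reproduced, and an energy-model
backend would add a large dependency surface for no change in the
decision rule. An energy-based engine is an extension point, not a
default.

Two numerical choices make outputs reproducible:

* **Traceback determinism.** Among co-optimal structures the traceback
  (a) leaves a base unpaired whenever that is co-optimal, and (b)
  otherwise pairs it with the smallest-index partner achieving the
  optimum. Rule (a) means no pair is reported that the maximum pair
  count does not force; this "minimal structure" convention keeps
  specifier bulges open instead of filling them with arbitrary
  tie-breaking pairs, which matters because specifier detection reads
  *unpaired* stretches.
* **Independent verification.** The DP engine (C++) is tested against a
  separate exhaustive-enumeration reference that recurses over every
  nested structure with no memoisation: all $\sum_{n \le 9} 4^n$ RNAs up
  to length 9 exhaustively, plus seeded random RNAs up to length 14.

### 5. The call and the cognate amino acid

A gene is called T-box regulated only under the strict conjunction:
motif present AND passing terminator 3' of it AND antiterminator
containing the motif AND mutual exclusivity. When several
motif/terminator combinations qualify, the 5'-most motif (then the
5'-most terminator) wins. All partial evidence is kept in the call
record, so a user can relax criteria post hoc without rescanning. The
call is monotone: relaxing any single threshold never turns a positive
call negative (a property the tests check directly).

The predicted cognate amino acid is the unique amino acid among the
specifier candidates, `"ambiguous"` when candidates disagree — a single
specifier per element is assumed, so no majority vote — and `"none"`
without candidates. For cognates in a split ("mixed") codon box the
partner amino acid is reported: the AAN box is shared between lysine
(AAA/AAG) and asparagine (AAU/AAC), so a Lys-specific element could in
principle respond to uncharged tRNA^Asn as well. The partner table is
computed from the standard genetic code, not hard-coded, and covers all
split boxes (Lys/Asn, Asp/Glu, His/Gln, Phe/Leu, Cys/Trp, Ile/Met,
Ser/Arg); it is a codon-table lookup, not a biological prediction.

## The synthetic-genome generator

`generate_genome()` builds a single-contig genome in which each of
`n_genes` AARS-like genes is preceded by either a functional implanted
leader or a scrambled negative of identical base composition. What it
emulates:

* **Genes**: protein sequences drawn from the bundled reference set and
  mutated to a controlled identity (default uniform in 0.65-0.95;
  `mutate_protein()` hits any target within 2 points), then
  reverse-translated with random synonymous codons, so homology
  detection is exercised under realistic divergence. The bundled
  reference set consists of synthetic, length-realistic random proteins
  labelled by family (22 families including both LysRS classes), so the
  package ships no database sequence data.
* **Leaders** (default 160 nt, a compact version of the canonical
  element order): stem I with the specifier codon in a 3-nt bulge, the
  antiterminator 5' arm, the motif with 0-3 forced suffix
  substitutions, a G/C terminator hairpin whose 5' arm is complementary
  to the antiterminator arm when overlap is requested, a U-tract, and
  random filler. The stem I apical loop is a synonymous codon of the
  specifier, so every stem I bulge candidate agrees on the amino acid
  and the cognate prediction is unambiguous by construction.
* **Geometry**: each leader exactly fills the gap between its gene and
  a short "hypothetical protein" CDS, so neighbor-truncated extraction
  recovers precisely the implanted sequence; genes are placed on random
  strands, which is what makes the mirror-genome consistency check
  meaningful.

Truth semantics encode the pipeline's default thresholds: an implant is
expected positive iff motif mismatches $\leq 2$, terminator stem
$\geq 6$, U-tract $\geq 4$ and the antiterminator overlap is present.
Because random linkers can create accidental structure (and scrambled
leaders can contain chance motifs — about 6 in 10 000 windows match the
degenerate rule), the generator evaluates every built leader with the
pipeline's own calling logic and redraws the random components until
the realized call matches the intended truth, recording the redraw
count in the truth table. This rejection-sampling step is what turns
"probably correct by construction" into a guaranteed ground truth; it
also means truth tables are only valid for the parameter set they were
generated under, and tests that vary thresholds regenerate truth
accordingly.

What the generator does *not* emulate: realistic base composition or
codon usage, operon structure, overlapping genes, regulatory contexts
other than the leader itself, and sequencing artifacts. Passing the
end-to-end tests therefore demonstrates the pipeline's internal
consistency and the correctness of each rule, not field performance on
real genomes, where leader architectures are more diverse than the
implanted one.

## Leader comparison

`compare_leaders()` quantifies conservation between leader elements by
global (Needleman-Wunsch) alignment with transparent scores (+1 match,
-1 mismatch, -2 per gap position) and reports alignment-length percent
identity: matches over *all* aligned columns, gaps included in the
denominator. A quoted identity percentage admits several conventions;
this one is the most conservative and is stated here because the
choice can move a reported value by a few points. Scores are checked
against an independent dynamic program and an exhaustive alignment
enumeration in the tests.

## Determinism and problem sizes

Every randomized component takes an explicit integer seed, all derived
seeds stay within 32-bit range, and repeated runs produce byte-identical
outputs (the GFF3 header's write-date comment aside). The shipped
validation uses: all $4^{10}$ windows for the motif rule; all RNAs to
length 9 plus 200 seeded RNAs to length 14 for the folding engine; a
100-gene genome (50 implants, 50 scrambled negatives) for end-to-end
recovery; a 20-gene genome for the mirror check; and the 22-family
reference set at 60% identity, with residue-shuffled decoys, for the
homology filter. These sizes were chosen so that each property is
exercised exhaustively where enumeration is feasible and at comfortable
statistical depth where it is not.

## Known limitations

* The structural thresholds are surrogates for expert inspection;
  genuine leaders with unusual geometry (long interior loops, distant
  antiterminators) would be missed at defaults.
* The tRNA acceptor-end NCCA : UGGN interaction is not modelled; the
  cognate tRNA is predicted from the specifier codon alone.
* No pseudoknots and no free-energy estimates.
* Multi-segment (joined) CDS features are rejected: the pipeline
  assumes bacterial gene structure. Input is FASTA + GFF3.
* The survey is per-genome; multi-genome tallies are a matter of
  running it per genome and concatenating reports.

```{r demo}
g <- generate_genome(n_genes = 6, fraction_tbox = 0.5, seed = 42)
res <- survey_genome(g$genome, g$genes)
res$report
```
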