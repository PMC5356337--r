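#' GeneCatalog: per-gene sequence features of a coding-sequence set
#'
#' Container tying together a set of coding sequences, their deduced
#' proteins, and the per-gene feature table (ORF length in bp, residue
#' count, theoretical pI, average molecular weight). Built by
#' [buildCatalog()].
#'
#' @slot cds A [Biostrings::DNAStringSet] of coding sequences.
#' @slot proteins An [Biostrings::AAStringSet] of deduced proteins
#'   (terminal stop stripped).
#' @slot features A [S4Vectors::DataFrame] with one row per gene and
#'   columns `gene_id`, `orf_bp`, `aa_len`, `pi`, `mw`, `frame_ok`.
#'
#' @aliases GeneCatalog
#' @export
setClass("GeneCatalog",
  representation(cds = "DNAStringSet", proteins = "AAStringSet",
                 features = "DataFrame"))

setValidity("GeneCatalog", function(object) {
  msg <- NULL
  if (length(object@cds) != nrow(object@features))
    msg <- c(msg, "features must have one row per coding sequence")
  if (!all(c("gene_id", "orf_bp", "aa_len", "pi", "mw", "frame_ok") %in%
           colnames(object@features)))
    msg <- c(msg, "features is missing required columns")
  if (anyDuplicated(names(object@cds)))
    msg <- c(msg, "duplicated gene ids")
  if (is.null(msg)) TRUE else msg
})

#' HairpinCandidate: a folded genomic window evaluated as a miRNA precursor
#'
#' One candidate precursor: a genomic window containing a small-RNA match,
#' its predicted secondary structure (dot-bracket), the folding
#' pseudo-energy, the placement of the mature small RNA within the window,
#' and (after [annotateMirna()]) the inferred star sequence and the
#' per-criterion annotation verdict.
#'
#' @slot seqname Chromosome/scaffold name of the window.
#' @slot start,end 1-based inclusive genomic coordinates of the window.
#' @slot strand `"+"` or `"-"`; the window sequence is always given 5'->3'
#'   on the strand carrying the mature small RNA.
#' @slot window_seq Window sequence (DNA alphabet, 5'->3').
#' @slot structure Dot-bracket string, same length as `window_seq`.
#' @slot energy Folding score from the backend (kcal/mol for RNAfold,
#'   negative pair weight for the built-in folder); lower is better.
#' @slot mature_start,mature_end 1-based positions of the mature small RNA
#'   within `window_seq`.
#' @slot arm `"5p"`, `"3p"`, or `NA` before annotation.
#' @slot star_seq Inferred miRNA* sequence (with 2-nt 3' overhang), or `NA`.
#' @slot criteria Named logical vector of annotation criteria.
#' @slot verdict `TRUE` when all structural criteria pass; `NA` before
#'   annotation.
#'
#' @aliases HairpinCandidate
#' @export
setClass("HairpinCandidate",
  representation(seqname = "character", start = "numeric", end = "numeric",
                 strand = "character", window_seq = "character",
                 structure = "character", energy = "numeric",
                 mature_start = "numeric", mature_end = "numeric",
                 arm = "character", star_seq = "character",
                 criteria = "logical", verdict = "logical"),
  prototype(arm = NA_character_, star_seq = NA_character_,
            criteria = logical(0), verdict = NA))

setValidity("HairpinCandidate", function(object) {
  msg <- NULL
  if (nchar(object@structure) != nchar(object@window_seq))
    msg <- c(msg, "structure length must equal window length")
  op <- lengths(regmatches(object@structure,
                           gregexpr("\\(", object@structure)))
  cl <- lengths(regmatches(object@structure,
                           gregexpr("\\)", object@structure)))
  if (op != cl) msg <- c(msg, "unbalanced brackets in structure")
  if (object@mature_start < 1 ||
      object@mature_end > nchar(object@window_seq) ||
      object@mature_start > object@mature_end)
    msg <- c(msg, "mature coordinates outside window")
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be + or -")
  if (is.null(msg)) TRUE else msg
})

#' DegradomeProfile: per-position degradome 5'-end counts on a transcript
#'
#' @slot transcript_id Transcript identifier.
#' @slot counts Integer vector of 5'-end tag counts, position `i` of the
#'   vector is transcript position `i` (1-based).
#'
#' @aliases DegradomeProfile
#' @export
setClass("DegradomeProfile",
  representation(transcript_id = "character", counts = "integer"))

setValidity("DegradomeProfile", function(object) {
  if (any(object@counts < 0)) "counts must be non-negative" else TRUE
})

#' CleavageEvidence: degradome support for one predicted cleavage site
#'
#' Produced by [degradomeValidate()]. The `category` follows the degradome
#' peak-classification convention: 0 = the peak at the expected site is the
#' unique transcript-wide maximum (> 1 read); 1 = tied maximum; 2 = above
#' the median of non-zero positions; 3 = at or below that median;
#' 4 = a single read.
#'
#' @slot transcript_id Transcript identifier.
#' @slot cleavage_pos Expected cleavage position (transcript coordinate
#'   paired to miRNA nucleotide 10).
#' @slot peak_count Maximum count within the search window.
#' @slot category Integer 0-4, or `NA` when no reads fall in the window.
#' @slot supported Logical; `TRUE` when category <= the configured cutoff.
#'
#' @aliases CleavageEvidence
#' @export
setClass("CleavageEvidence",
  representation(transcript_id = "character", cleavage_pos = "numeric",
                 peak_count = "numeric", category = "integer",
                 supported = "logical"))

#' @describeIn GeneCatalog Coding sequences of the catalog.
#' @param x A `GeneCatalog`.
#' @export
codingSeqs <- function(x) x@cds

#' @describeIn GeneCatalog Deduced protein sequences.
#' @export
proteinSeqs <- function(x) x@proteins

#' @describeIn GeneCatalog Per-gene feature table.
#' @export
geneFeatures <- function(x) x@features

#' @describeIn HairpinCandidate Annotation verdict (`NA` before
#'   [annotateMirna()]).
#' @param object A `HairpinCandidate`.
#' @export
verdict <- function(object) object@verdict

setMethod("show", "GeneCatalog", function(object) {
  cat("GeneCatalog with", length(object@cds), "genes\n")
  f <- object@features
  cat("  ORF bp:", paste(range(f$orf_bp), collapse = "-"),
      " AA len:", paste(range(f$aa_len, na.rm = TRUE), collapse = "-"), "\n")
  if (!all(f$frame_ok))
    cat("  note:", sum(!f$frame_ok), "ORF length(s) not divisible by 3\n")
})

setMethod("show", "HairpinCandidate", function(object) {
  cat(sprintf("HairpinCandidate %s:%d-%d(%s), %d nt, energy %.1f\n",
              object@seqname, as.integer(object@start),
              as.integer(object@end), object@strand,
              nchar(object@window_seq), object@energy))
  cat(sprintf("  mature at %d-%d", as.integer(object@mature_start),
              as.integer(object@mature_end)))
  if (!is.na(object@verdict))
    cat(sprintf(" | arm %s | verdict %s", object@arm,
                if (isTRUE(object@verdict)) "PASS" else "FAIL"))
  cat("\n")
})

setMethod("show", "DegradomeProfile", function(object) {
  cat(sprintf("DegradomeProfile %s: %d positions, %d tags\n",
              object@transcript_id, length(object@counts),
              sum(object@counts)))
})

setMethod("show", "CleavageEvidence", function(object) {
  cat(sprintf("CleavageEvidence %s @%d: peak %d, category %s, %s\n",
              object@transcript_id, as.integer(object@cleavage_pos),
              as.integer(object@peak_count),
              ifelse(is.na(object@category), "NA", object@category),
              if (isTRUE(object@supported)) "supported" else "unsupported"))
})

#' Construct a DegradomeProfile
#'
#' @param transcript_id Transcript identifier.
#' @param counts Non-negative integer vector of per-position 5'-end counts.
#' @return A [DegradomeProfile] object.
#' @export
degradomeProfile <- function(transcript_id, counts) {
  new("DegradomeProfile", transcript_id = as.character(transcript_id),
      counts = as.integer(counts))
}
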