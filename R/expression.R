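# RPKM, expressed-gene filtering, Fisher-exact differential expression,
# 2^-ddCt quantification and one-way ANOVA.

#' Reads per kilobase per million mapped reads
#'
#' `RPKM = 1e9 * count / (total_mapped * length_bp)`.
#'
#' @param counts Matrix (genes x libraries) of non-negative integer read
#'   counts.
#' @param lengths Transcript lengths in bp, one per gene (> 0).
#' @param totals Total mapped reads per library (> 0); must be at least
#'   the column sums of `counts`.
#' @return Matrix of RPKM values, same dimensions as `counts`.
#' @export
rpkm <- function(counts, lengths, totals) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(lengths <= 0)) stop("lengths must be positive")
  if (any(totals <= 0)) stop("totals must be positive")
  if (length(lengths) != nrow(counts) || length(totals) != ncol(counts))
    stop("dimension mismatch")
  if (any(colSums(counts) > totals))
    stop("library totals smaller than column sums")
  1e9 * counts / outer(lengths, totals)
}

#' Filter to expressed genes
#'
#' A gene is expressed when its RPKM exceeds `threshold` (strictly) in at
#' least one library.
#'
#' @param rpkmMat Matrix from [rpkm()], with rownames.
#' @param threshold RPKM cutoff (default 2).
#' @return Character vector of expressed gene ids.
#' @export
expressedFilter <- function(rpkmMat, threshold = 2) {
  rpkmMat <- as.matrix(rpkmMat)
  rownames(rpkmMat)[apply(rpkmMat > threshold, 1, any)]
}

#' Two-library differential expression by Fisher's exact test
#'
#' For each gene, tests the 2x2 table
#' `[[count_a, total_a - count_a], [count_b, total_b - count_b]]` with a
#' two-sided Fisher exact test (the sum of hypergeometric outcomes at most
#' as probable as the observed one). No multiple-testing correction is
#' applied by default, matching the single-contrast convention; set
#' `adjust = "BH"` for Benjamini-Hochberg.
#'
#' @param countA,countB Read count vectors (same genes, same order).
#' @param totalA,totalB Scalar library totals.
#' @param alpha Significance level (default 0.05).
#' @param adjust `"none"` (default) or a [stats::p.adjust()] method.
#' @return data.frame with `count_a`, `count_b`, `p_value`, `significant`.
#' @export
fisherDE <- function(countA, totalA, countB, totalB, alpha = 0.05,
                     adjust = "none") {
  if (any(c(countA, countB, totalA, totalB) < 0))
    stop("negative entries")
  if (any(countA > totalA) || any(countB > totalB))
    stop("counts exceed totals")
  p <- mapply(function(a, b) {
    fisher.test(matrix(c(a, totalA - a, b, totalB - b), 2,
                       byrow = TRUE))$p.value
  }, countA, countB)
  if (adjust != "none") p <- stats::p.adjust(p, method = adjust)
  data.frame(count_a = countA, count_b = countB, p_value = p,
             significant = p < alpha,
             row.names = names(countA) %||% NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Relative quantification by the 2^-ddCt method
#'
#' Per condition, `dCt = mean(Ct_target) - mean(Ct_ref)`;
#' `ddCt = dCt_condition - dCt_control`; `fold = 2^-ddCt`. The control
#' condition has fold 1 by construction.
#'
#' @param ct data.frame with columns `condition`, `target_ct`, `ref_ct`
#'   (one row per replicate; reference Ct measured alongside the target).
#' @param control Name of the control/reference condition.
#' @return data.frame with `condition`, `n`, `dct`, `ddct`, `fold`.
#' @export
ddctFoldChange <- function(ct, control) {
  need <- c("condition", "target_ct", "ref_ct")
  if (!all(need %in% colnames(ct)))
    stop("ct table must have columns: ", paste(need, collapse = ", "))
  if (!control %in% ct$condition)
    stop("control condition '", control, "' not present")
  if (any(is.na(ct$ref_ct))) stop("missing reference Ct value(s)")
  sp <- split(ct, ct$condition)
  dct <- vapply(sp, function(d) mean(d$target_ct) - mean(d$ref_ct), 0)
  n <- vapply(sp, nrow, 0L)
  ddct <- dct - dct[[control]]
  conds <- names(sp)
  ord <- c(control, setdiff(conds, control))
  data.frame(condition = ord, n = n[ord], dct = unname(dct[ord]),
             ddct = unname(ddct[ord]), fold = unname(2^-ddct[ord]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' One-way ANOVA across groups of fold changes
#'
#' Classical (pooled-variance) F statistic with significance flags at
#' 0.05 and 0.01. All values identical across groups returns `F = 0`,
#' `p = 1`.
#'
#' @param groups A named list of numeric vectors (>= 2 groups, >= 2
#'   values each).
#' @return list with `F`, `p`, `significant` (p < 0.05),
#'   `extremely_significant` (p < 0.01).
#' @export
oneWayAnova <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) < 2))
    stop("need >= 2 groups with >= 2 values each")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (stats::var(values) == 0)
    return(list(F = 0, p = 1, significant = FALSE,
                extremely_significant = FALSE))
  ow <- oneway.test(values ~ g, var.equal = TRUE)
  list(F = unname(ow$statistic), p = ow$p.value,
       significant = ow$p.value < 0.05,
       extremely_significant = ow$p.value < 0.01)
}

#' Minimal exact-match transcript read counter
#'
#' Counts reads that match a transcript exactly (full read length, either
#' strand); reads hitting more than one transcript are discarded
#' (unique-hit counting). This is a deliberately simple stand-in for a
#' short-read mapper, sufficient for synthetic error-free reads.
#'
#' @param reads Character vector of read sequences (may repeat), or a
#'   data.frame with columns `seq` and `count`.
#' @param transcripts Named [Biostrings::DNAStringSet] or character
#'   vector.
#' @return Named integer vector of per-transcript counts.
#' @export
mapReadsExact <- function(reads, transcripts) {
  tx <- .as_named_chr(transcripts)
  if (is.null(names(tx))) stop("transcripts must be named")
  if (is.data.frame(reads)) {
    seqs <- reads$seq; mult <- reads$count
  } else {
    tab <- table(reads)
    seqs <- names(tab); mult <- as.integer(tab)
  }
  seqs <- .normalize_dna(seqs)
  counts <- setNames(integer(length(tx)), names(tx))
  rc <- as.character(reverseComplement(DNAStringSet(seqs)))
  for (i in seq_along(seqs)) {
    hit <- vapply(tx, function(t) {
      grepl(seqs[i], t, fixed = TRUE) || grepl(rc[i], t, fixed = TRUE)
    }, TRUE)
    if (sum(hit) == 1)
      counts[hit] <- counts[hit] + mult[i]
  }
  counts
}
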