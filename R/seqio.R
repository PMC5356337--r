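# Sequence I/O and per-gene sequence features.

# ExPASy-style average residue masses (Da) and the mass of one water.
.AA_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.H2O <- 18.0153

# Bjellqvist pKa constants (as used by the ExPASy Compute pI/Mw tool).
# N-/C-terminal pKa depends on the terminal residue; side chains are
# position-independent. Kept in one table so alternative sets can be
# swapped in.
.PK_NTERM_DEFAULT <- 7.5
.PK_NTERM <- c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82,
               V = 7.44, E = 7.70)
.PK_CTERM_DEFAULT <- 3.55
.PK_CTERM <- c(D = 4.55, E = 4.75)
.PK_SIDE_POS <- c(K = 10.00, R = 12.00, H = 5.98)
.PK_SIDE_NEG <- c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00)

# Conserved motifs of plant polyphenol oxidases; x = any residue.
.PPO_MOTIFS <- c(
  HCAYC = "HCAYC", HxxxC = "H...C", HxxxH = "H...H", DWL = "DWL",
  YxY = "Y.Y", KFDV = "KFDV", AxA = "A.A",
  EEEEEVLVI = "EEEEEVLVI", EFAGSF = "EFAGSF")

.normalize_dna <- function(x) {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGT]", x)
  if (any(bad))
    stop("invalid nucleotide character(s) in sequence(s): ",
         paste(head(which(bad), 3), collapse = ", "))
  x
}

#' Read coding sequences from a FASTA file
#'
#' Accepts DNA or RNA input (U is converted to T); identifiers must be
#' unique. Sequences whose length is not divisible by 3 are kept but
#' flagged with a warning, since cloned coding regions occasionally carry
#' length annotations inconsistent with a clean ORF.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by record id.
#' @export
readCodingSequences <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- .normalize_dna(as.character(x))
  out <- DNAStringSet(seqs)
  names(out) <- ids
  off <- width(out) %% 3 != 0
  if (any(off))
    warning("length not divisible by 3 for: ",
            paste(ids[off], collapse = ", "))
  out
}

#' Read protein sequences from a FASTA file
#'
#' A single terminal `*` (stop) is stripped; duplicate ids are an error.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::AAStringSet] named by record id.
#' @export
readProteins <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- sub("\\*$", "", as.character(x))
  out <- AAStringSet(seqs)
  names(out) <- ids
  out
}

#' Translate an open reading frame to protein
#'
#' Standard genetic code. The sequence length must be divisible by 3. A
#' terminal stop codon is stripped; an internal stop is an error unless
#' `permissive = TRUE`, in which case the protein is truncated at the
#' first stop with a warning.
#'
#' @param cds A [Biostrings::DNAString], or a character scalar (U allowed).
#' @param permissive Truncate at an internal stop instead of failing.
#' @return An [Biostrings::AAString] without the terminal stop.
#' @export
translateOrf <- function(cds, permissive = FALSE) {
  s <- .normalize_dna(as.character(cds))
  if (nchar(s) == 0) stop("empty coding sequence")
  if (nchar(s) %% 3 != 0)
    stop("coding sequence length (", nchar(s), ") not divisible by 3")
  aa <- as.character(suppressWarnings(translate(DNAString(s))))
  stops <- gregexpr("\\*", aa)[[1]]
  n <- nchar(aa)
  if (stops[1] != -1) {
    internal <- stops[stops < n]
    if (length(internal) > 0) {
      if (!permissive)
        stop("internal stop codon at residue ", internal[1])
      warning("internal stop codon at residue ", internal[1],
              "; truncating")
      aa <- substr(aa, 1, internal[1] - 1)
    } else {
      aa <- substr(aa, 1, n - 1) # strip terminal stop
    }
  }
  AAString(aa)
}

.check_protein <- function(p) {
  s <- toupper(as.character(p))
  if (nchar(s) == 0) stop("empty protein sequence")
  s <- sub("\\*$", "", s)
  res <- strsplit(s, "")[[1]]
  bad <- setdiff(unique(res), names(.AA_MASS))
  if (length(bad) > 0)
    stop("unknown residue(s): ", paste(bad, collapse = ", "))
  res
}

#' Average protein molecular weight (Da)
#'
#' Sum of average residue masses plus one water, the convention of the
#' ExPASy Compute pI/Mw tool. Reported to 2 decimals.
#'
#' @param p Protein sequence ([Biostrings::AAString] or character).
#' @return Molecular weight in Daltons.
#' @export
proteinMw <- function(p) {
  res <- .check_protein(p)
  round(sum(.AA_MASS[res]) + .H2O, 2)
}

.protein_charge <- function(pH, counts, nterm, cterm) {
  pos <- 1 / (1 + 10^(pH - .PK_NTERM_DEFAULT))
  if (nterm %in% names(.PK_NTERM))
    pos <- 1 / (1 + 10^(pH - .PK_NTERM[[nterm]]))
  for (r in names(.PK_SIDE_POS))
    pos <- pos + counts[[r]] / (1 + 10^(pH - .PK_SIDE_POS[[r]]))
  pk_c <- if (cterm %in% names(.PK_CTERM)) .PK_CTERM[[cterm]]
          else .PK_CTERM_DEFAULT
  neg <- 1 / (1 + 10^(pk_c - pH))
  for (r in names(.PK_SIDE_NEG))
    neg <- neg + counts[[r]] / (1 + 10^(.PK_SIDE_NEG[[r]] - pH))
  pos - neg
}

#' Theoretical isoelectric point (Bjellqvist pKa set)
#'
#' pH at which the modeled net charge is zero, found by bisection on
#' the pH interval 0-14 to a tolerance of 1e-4 and reported to 2
#' decimals. Uses the
#' Bjellqvist pKa constants (N- and C-terminal pKa depend on the terminal
#' residue), matching the ExPASy Compute pI/Mw tool.
#'
#' @param p Protein sequence ([Biostrings::AAString] or character).
#' @return Isoelectric point in pH units.
#' @export
proteinPi <- function(p) {
  res <- .check_protein(p)
  counts <- as.list(table(factor(res, levels = names(.AA_MASS))))
  nterm <- res[1]
  cterm <- res[length(res)]
  lo <- 0; hi <- 14
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (.protein_charge(mid, counts, nterm, cterm) > 0) lo <- mid
    else hi <- mid
  }
  round((lo + hi) / 2, 2)
}

#' Scan a protein for conserved PPO motifs
#'
#' Finds all non-overlapping occurrences (left to right) of the conserved
#' plant-PPO motifs: HCAYC, HxxxC and HxxxH (x = exactly one arbitrary
#' residue, three wildcards), DWL, YxY, KFDV, the AxA cleavage motif, and
#' the C-terminal EEEEEVLVI and EFAGSF motifs.
#'
#' @param p Protein sequence ([Biostrings::AAString] or character).
#' @param motifs Named character vector of regular expressions; defaults
#'   to the PPO set.
#' @return A data.frame with columns `motif`, `start` (1-based), `matched`.
#' @export
scanMotifs <- function(p, motifs = .PPO_MOTIFS) {
  s <- paste(.check_protein(p), collapse = "")
  out <- lapply(names(motifs), function(m) {
    hits <- gregexpr(motifs[[m]], s)[[1]]
    if (hits[1] == -1) return(NULL)
    data.frame(motif = m, start = as.integer(hits),
               matched = substring(s, hits,
                                   hits + attr(hits, "match.length") - 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(motif = character(), start = integer(),
                      matched = character(), stringsAsFactors = FALSE)
  out[order(out$motif, out$start), , drop = FALSE]
}

#' Position frequency matrix and information content of an alignment
#'
#' Per-column residue frequencies (gap characters `-` and `.` excluded
#' from the counts) and the per-column information content in bits,
#' `log2(20) - H(column)` with `H` the Shannon entropy of the observed
#' frequencies. No small-sample correction is applied.
#'
#' @param alignment Character vector (or [Biostrings::AAStringSet]) of
#'   equal-length aligned protein sequences; at least 2.
#' @return A list with `columns` (20 x L frequency matrix) and
#'   `info_bits` (length-L numeric). Columns with only gaps get zero
#'   frequencies and `info_bits` of 0.
#' @export
logoMatrix <- function(alignment) {
  seqs <- toupper(.as_named_chr(alignment))
  if (length(seqs) < 2) stop("need at least 2 sequences")
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop("sequences must have equal length")
  mat <- do.call(rbind, strsplit(seqs, ""))
  aas <- names(.AA_MASS)
  freq <- matrix(0, nrow = 20, ncol = L, dimnames = list(aas, NULL))
  info <- numeric(L)
  for (j in seq_len(L)) {
    col <- mat[, j]
    col <- col[!col %in% c("-", ".")]
    if (length(col) == 0) next
    bad <- setdiff(unique(col), aas)
    if (length(bad) > 0)
      stop("unknown residue(s) in column ", j, ": ",
           paste(bad, collapse = ", "))
    f <- table(factor(col, levels = aas)) / length(col)
    freq[, j] <- as.numeric(f)
    nz <- f[f > 0]
    info[j] <- log2(20) + sum(nz * log2(nz))
  }
  list(columns = freq, info_bits = info)
}

#' Intron phases of a gene model
#'
#' The phase of an intron is the cumulative coding length upstream of it,
#' modulo 3 (0 = between codons; 1/2 = after the first/second codon
#' position). Exon coordinates are 1-based inclusive on the coding region
#' and must be ascending and non-overlapping.
#'
#' @param exons A data.frame with columns `start` and `end`.
#' @return A data.frame with columns `intron` (index) and `phase`;
#'   zero rows for a single-exon gene.
#' @export
intronPhases <- function(exons) {
  if (nrow(exons) < 1) stop("need at least one exon")
  ord <- order(exons$start)
  exons <- exons[ord, , drop = FALSE]
  if (any(exons$end < exons$start)) stop("exon end < start")
  if (nrow(exons) > 1 &&
      any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop("overlapping exons")
  if (nrow(exons) == 1)
    return(data.frame(intron = integer(), phase = integer()))
  cumlen <- cumsum(exons$end - exons$start + 1)
  data.frame(intron = seq_len(nrow(exons) - 1),
             phase = as.integer(cumlen[-length(cumlen)] %% 3))
}

#' Read a tab-delimited exon table
#'
#' Expected columns: `gene_id`, `exon_start`, `exon_end`, `strand`
#' (GFF3-like, 1-based inclusive).
#'
#' @param path Path to the TSV file.
#' @return A data.frame split-ready by `gene_id`.
#' @export
readExonTable <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "exon_start", "exon_end", "strand")
  if (!all(need %in% colnames(x)))
    stop("exon table must have columns: ", paste(need, collapse = ", "))
  x
}

#' Build a gene catalog from coding sequences
#'
#' Translates each ORF and computes residue count, molecular weight and
#' isoelectric point. Sequences whose length is not divisible by 3 are
#' retained with `NA` protein features and `frame_ok = FALSE`.
#'
#' @param cds Named [Biostrings::DNAStringSet] (e.g. from
#'   [readCodingSequences()]).
#' @param permissive Passed to [translateOrf()].
#' @return A [GeneCatalog].
#' @export
buildCatalog <- function(cds, permissive = FALSE) {
  ids <- names(cds)
  if (is.null(ids) || anyDuplicated(ids))
    stop("coding sequences must have unique names")
  prots <- character(length(cds))
  aa_len <- pi_v <- mw_v <- rep(NA_real_, length(cds))
  frame_ok <- width(cds) %% 3 == 0
  for (i in seq_along(cds)) {
    if (!frame_ok[i]) next
    p <- as.character(translateOrf(cds[[i]], permissive = permissive))
    prots[i] <- p
    aa_len[i] <- nchar(p)
    mw_v[i] <- proteinMw(p)
    pi_v[i] <- proteinPi(p)
  }
  keep <- frame_ok
  prot_set <- AAStringSet(prots[keep])
  names(prot_set) <- ids[keep]
  feat <- DataFrame(gene_id = ids, orf_bp = width(cds),
                    aa_len = as.integer(aa_len), pi = pi_v, mw = mw_v,
                    frame_ok = frame_ok)
  new("GeneCatalog", cds = cds, proteins = prot_set, features = feat)
}
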