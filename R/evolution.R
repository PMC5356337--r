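# Pairwise alignment, CIP/CALP paralog grouping, NG86 Ka/Ks with domain
# slices, group t-tests, NJ trees with bootstrap support.

.GCODE <- Biostrings::GENETIC_CODE
.BASES <- c("A", "C", "G", "T")

#' Global pairwise protein alignment
#'
#' Needleman-Wunsch with affine gaps via [Biostrings::pairwiseAlignment()].
#' Defaults (BLOSUM62, gap open 10, gap extend 0.5) are conventional.
#'
#' @param a,b Protein sequences (character or [Biostrings::AAString]);
#'   `a` and `b` may carry names used as ids.
#' @param substitutionMatrix Scoring matrix name or matrix.
#' @param gapOpening,gapExtension Affine gap penalties (positive costs).
#' @return A list with `id_a`, `id_b`, `aligned_a`, `aligned_b` (gapped
#'   strings of equal length), `score`, `identities` (identical
#'   residue-residue columns), `aligned_cols` (columns with a residue in
#'   both), `len_a`, `len_b`.
#' @export
globalAlign <- function(a, b, substitutionMatrix = "BLOSUM62",
                        gapOpening = 10, gapExtension = 0.5) {
  id_a <- if (!is.null(names(a))) names(a)[1] else "a"
  id_b <- if (!is.null(names(b))) names(b)[1] else "b"
  sa <- toupper(as.character(a)[1])
  sb <- toupper(as.character(b)[1])
  if (nchar(sa) == 0 || nchar(sb) == 0) stop("empty input sequence")
  pa <- pairwiseAlignment(AAString(sa), AAString(sb),
                          substitutionMatrix = substitutionMatrix,
                          gapOpening = gapOpening,
                          gapExtension = gapExtension, type = "global")
  ga <- as.character(alignedPattern(pa))
  gb <- as.character(alignedSubject(pa))
  ca <- strsplit(ga, "")[[1]]
  cb <- strsplit(gb, "")[[1]]
  both <- ca != "-" & cb != "-"
  list(id_a = id_a, id_b = id_b, aligned_a = ga, aligned_b = gb,
       score = unname(Biostrings::score(pa)),
       identities = sum(both & ca == cb), aligned_cols = sum(both),
       len_a = nchar(sa), len_b = nchar(sb))
}

#' Cumulative identity and alignment length percentages
#'
#' `CIP = 100 * identities / aligned_cols` and
#' `CALP = 100 * aligned_cols / min(len_a, len_b)` computed on one global
#' alignment; the shorter unaligned sequence is the CALP denominator.
#'
#' @param aln Result of [globalAlign()].
#' @return Named numeric vector `c(cip = ..., calp = ...)`; `cip` is `NA`
#'   when no column aligns a residue to a residue.
#' @export
cipCalp <- function(aln) {
  if (aln$aligned_cols == 0)
    return(c(cip = NA_real_, calp = 0))
  c(cip = 100 * aln$identities / aln$aligned_cols,
    calp = 100 * aln$aligned_cols / min(aln$len_a, aln$len_b))
}

#' Identify paralogous groups by pairwise homology filters
#'
#' Aligns every pair globally, keeps edges with CIP >= `cipMin` and
#' CALP >= `calpMin`, and reports connected components with at least two
#' members (single-linkage grouping). The classical BLASTP E-value filter
#' is redundant at these identity/coverage thresholds for within-genome
#' comparisons of a single family and is not applied in this
#' global-alignment mode.
#'
#' @param proteins Named character vector or [Biostrings::AAStringSet],
#'   length >= 2.
#' @param cipMin,calpMin Percent thresholds (defaults 60 and 70).
#' @param ... Passed to [globalAlign()].
#' @return A list with `groups` (list of member-id vectors, each sorted,
#'   groups ordered by first member), `singletons` (ids in no group) and
#'   `pairs` (data.frame of all pairwise CIP/CALP values).
#' @export
paralogGroups <- function(proteins, cipMin = 60, calpMin = 70, ...) {
  seqs <- .as_named_chr(proteins)
  ids <- names(seqs)
  if (length(seqs) < 2) stop("need at least 2 proteins")
  if (is.null(ids) || anyDuplicated(ids)) stop("proteins must have unique names")
  cmb <- utils::combn(length(seqs), 2)
  pairs <- data.frame(id_a = ids[cmb[1, ]], id_b = ids[cmb[2, ]],
                      cip = NA_real_, calp = NA_real_,
                      stringsAsFactors = FALSE)
  for (k in seq_len(ncol(cmb))) {
    aln <- globalAlign(seqs[cmb[1, k]], seqs[cmb[2, k]], ...)
    cc <- cipCalp(aln)
    pairs$cip[k] <- cc[["cip"]]
    pairs$calp[k] <- cc[["calp"]]
  }
  edges <- pairs[!is.na(pairs$cip) & pairs$cip >= cipMin &
                 pairs$calp >= calpMin, c("id_a", "id_b")]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  membership <- split(names(comp$membership), comp$membership)
  groups <- Filter(function(m) length(m) >= 2, membership)
  groups <- lapply(groups, sort)
  groups <- groups[order(vapply(groups, `[`, "", 1))]
  names(groups) <- NULL
  singletons <- sort(setdiff(ids, unlist(groups)))
  list(groups = groups, singletons = singletons, pairs = pairs)
}

#' Thread coding sequences through a protein alignment
#'
#' Produces the gap-free codon columns used for Ka/Ks: each protein
#' alignment column with a residue in both sequences contributes one codon
#' from each CDS; columns with a gap in either sequence are excluded.
#'
#' @param cdsA,cdsB Coding sequences (character or
#'   [Biostrings::DNAString]); each must translate to the corresponding
#'   ungapped aligned protein.
#' @param aln Result of [globalAlign()] on the two deduced proteins.
#' @return A list with `codons_a`, `codons_b` (character vectors),
#'   `pos_a`, `pos_b` (1-based codon indices on the respective ORFs).
#' @export
codonAlign <- function(cdsA, cdsB, aln) {
  sA <- .normalize_dna(as.character(cdsA))
  sB <- .normalize_dna(as.character(cdsB))
  pa <- gsub("-", "", aln$aligned_a)
  pb <- gsub("-", "", aln$aligned_b)
  ta <- as.character(translateOrf(sA))
  tb <- as.character(translateOrf(sB))
  if (ta != pa || tb != pb)
    stop("coding sequences do not translate to the aligned proteins")
  codA <- substring(sA, seq(1, nchar(sA) - 2, 3), seq(3, nchar(sA), 3))
  codB <- substring(sB, seq(1, nchar(sB) - 2, 3), seq(3, nchar(sB), 3))
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  ia <- cumsum(ca != "-")
  ib <- cumsum(cb != "-")
  both <- ca != "-" & cb != "-"
  list(codons_a = codA[ia[both]], codons_b = codB[ib[both]],
       pos_a = ia[both], pos_b = ib[both])
}

# Fraction of the three single-nucleotide changes at each codon position
# that are synonymous; changes to stop codons count as nonsynonymous.
# Returns total synonymous sites for one codon (0..3).
.syn_sites <- function(codon) {
  aa <- .GCODE[[codon]]
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(.BASES, substr(codon, p, p))) {
      alt <- codon
      substr(alt, p, p) <- b
      if (.GCODE[[alt]] == aa) s <- s + 1 / 3
    }
  }
  s
}

# Average synonymous/nonsynonymous substitution counts between two codons
# over all mutational pathways; pathways through stop codons are excluded
# (unless all are, in which case all are used).
.path_counts <- function(c1, c2) {
  diffs <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(diffs)
  if (nd == 0) return(c(sd = 0, nd = 0))
  perms <- if (nd == 1) list(diffs) else {
    idx <- seq_len(nd)
    ords <- if (nd == 2) list(1:2, 2:1) else {
      out <- list(); for (i in 1:3) for (j in setdiff(1:3, i))
        out[[length(out) + 1]] <- c(i, j, setdiff(1:3, c(i, j)))
      out
    }
    lapply(ords, function(o) diffs[o])
  }
  tally <- function(path, allow_stop) {
    cur <- c1; sd <- 0; ndv <- 0
    for (p in path) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (!allow_stop && .GCODE[[nxt]] == "*") return(NULL)
      if (.GCODE[[cur]] == .GCODE[[nxt]]) sd <- sd + 1 else ndv <- ndv + 1
      cur <- nxt
    }
    c(sd = sd, nd = ndv)
  }
  res <- Filter(Negate(is.null), lapply(perms, tally, allow_stop = FALSE))
  if (length(res) == 0)
    res <- lapply(perms, tally, allow_stop = TRUE)
  cm <- do.call(rbind, res)
  c(sd = mean(cm[, "sd"]), nd = mean(cm[, "nd"]))
}

.jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_) # saturated; undefined under JC
  -0.75 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori (1986) Ka/Ks on aligned codon columns
#'
#' Synonymous-site fractions are computed per codon (changes to stop
#' codons counted as nonsynonymous) and averaged between the two
#' sequences; codons differing at several positions are averaged over all
#' mutational pathways, excluding pathways through stop codons. Proportions
#' `pS = Sd/S` and `pN = Nd/N` are Jukes-Cantor corrected,
#' `d = -(3/4) log(1 - 4p/3)`; `p >= 3/4` is flagged undefined (`NA`).
#'
#' @param codons Result of [codonAlign()], or a list with `codons_a` and
#'   `codons_b` character vectors of equal length.
#' @return A list with `S`, `N` (site counts), `Sd`, `Nd` (substitution
#'   counts), `ks`, `ka` (corrected rates, `NA` when saturated), `ratio`
#'   (`ka/ks`, `NA` when `ks` is 0 or undefined), and `codons` analyzed.
#' @export
neiGojobori <- function(codons) {
  ca <- toupper(codons$codons_a)
  cb <- toupper(codons$codons_b)
  if (length(ca) != length(cb) || length(ca) == 0)
    stop("need equal, non-empty codon vectors")
  if (any(c(.GCODE[ca], .GCODE[cb]) == "*"))
    stop("stop codon inside the analyzed columns")
  sA <- sum(vapply(ca, .syn_sites, 0))
  sB <- sum(vapply(cb, .syn_sites, 0))
  S <- (sA + sB) / 2
  N <- 3 * length(ca) - S
  counts <- mapply(function(x, y) .path_counts(x, y), ca, cb)
  Sd <- sum(counts["sd", ])
  Nd <- sum(counts["nd", ])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  ks <- .jc_correct(pS)
  ka <- .jc_correct(pN)
  ratio <- if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       ks = ks, ka = ka, ratio = ratio, codons = length(ca))
}

#' Ka/Ks for the whole ORF and for domain slices
#'
#' Restricts the aligned codon columns to those whose codon index falls
#' inside the region in **both** sequences, then applies [neiGojobori()].
#' Region `ORF` (the full alignment) is always included.
#'
#' @param cdsA,cdsB Coding sequences.
#' @param aln Result of [globalAlign()] on the deduced proteins.
#' @param regionsA,regionsB Data frames with columns `region`, `start`,
#'   `end` (1-based inclusive codon indices on each ORF). Regions present
#'   in both are sliced.
#' @return A data.frame with one row per region and columns `region`,
#'   `codons`, `S`, `N`, `Sd`, `Nd`, `ka`, `ks`, `ratio`.
#' @export
domainKaKs <- function(cdsA, cdsB, aln, regionsA = NULL, regionsB = NULL) {
  cols <- codonAlign(cdsA, cdsB, aln)
  run_one <- function(keep, label) {
    if (sum(keep) == 0) stop("region ", label, " empty after slicing")
    est <- neiGojobori(list(codons_a = cols$codons_a[keep],
                            codons_b = cols$codons_b[keep]))
    data.frame(region = label, codons = est$codons, S = est$S, N = est$N,
               Sd = est$Sd, Nd = est$Nd, ka = est$ka, ks = est$ks,
               ratio = est$ratio, stringsAsFactors = FALSE)
  }
  out <- run_one(rep(TRUE, length(cols$codons_a)), "ORF")
  if (!is.null(regionsA) && !is.null(regionsB)) {
    shared <- intersect(regionsA$region, regionsB$region)
    for (r in shared) {
      ra <- regionsA[regionsA$region == r, ][1, ]
      rb <- regionsB[regionsB$region == r, ][1, ]
      keep <- cols$pos_a >= ra$start & cols$pos_a <= ra$end &
              cols$pos_b >= rb$start & cols$pos_b <= rb$end
      out <- rbind(out, run_one(keep, r))
    }
  }
  out
}

#' Heuristic default domain coordinates from motif anchors
#'
#' Derives approximate codon intervals for the CuA, CuB, DWL and KFDV
#' domains of a PPO protein by anchoring on conserved-motif hits: CuA runs
#' from the first histidine of the HxxxC motif to 30 residues past the
#' third conserved histidine downstream of it; CuB spans the HxxxH motif
#' plus 30 residues on each side; DWL and KFDV are windows around their
#' name-giving motifs (DWL - 10 to + 40; KFDV - 10 to + 140). These are
#' documented defaults, intended to be overridden by curated coordinates.
#'
#' @param p Protein sequence.
#' @return A data.frame with columns `region`, `start`, `end` (codon
#'   indices, clamped to the protein length); regions whose anchor motif
#'   is absent are omitted.
#' @export
defaultDomainCoords <- function(p) {
  s <- paste(.check_protein(p), collapse = "")
  L <- nchar(s)
  hits <- scanMotifs(s)
  out <- list()
  clamp <- function(x) max(1, min(L, x))
  hx <- hits[hits$motif == "HxxxC", ]
  if (nrow(hx) > 0) {
    a <- hx$start[1]
    hpos <- gregexpr("H", substring(s, a))[[1]] + a - 1
    end_anchor <- if (length(hpos) >= 3) hpos[3] else a + 40
    out[["CuA"]] <- c(a, end_anchor + 30)
  }
  cub_from <- if (length(out) > 0) out[["CuA"]][2] else 1
  hh <- hits[hits$motif == "HxxxH" & hits$start > cub_from, ]
  if (nrow(hh) > 0)
    out[["CuB"]] <- c(hh$start[1] - 30, hh$start[1] + 4 + 30)
  dw <- hits[hits$motif == "DWL", ]
  if (nrow(dw) > 0)
    out[["DWL"]] <- c(dw$start[1] - 10, dw$start[1] + 40)
  kf <- hits[hits$motif == "KFDV", ]
  if (nrow(kf) > 0)
    out[["KFDV"]] <- c(kf$start[1] - 10, kf$start[1] + 140)
  if (length(out) == 0)
    return(data.frame(region = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  data.frame(region = names(out),
             start = vapply(out, function(x) clamp(x[1]), 0),
             end = vapply(out, function(x) clamp(x[2]), 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Welch two-sample t-test between groups of rate estimates
#'
#' @param valuesA,valuesB Numeric vectors (e.g. Ka estimates of two
#'   domains), at least 2 values each; `NA`s dropped.
#' @return A list with `t` and `p` (two-sided). Both groups constant with
#'   equal means gives `p = 1`; constant with different means gives
#'   `p = 0`.
#' @export
groupTTest <- function(valuesA, valuesB) {
  a <- valuesA[!is.na(valuesA)]
  b <- valuesB[!is.na(valuesB)]
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 values per group")
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0))
  }
  tt <- t.test(a, b)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Pairwise p-distance matrix of aligned proteins
#'
#' For each pair, the proportion of mismatching residues over columns
#' where both sequences carry a residue (gaps excluded pairwise).
#'
#' @param alignment Equal-length aligned sequences (character vector or
#'   [Biostrings::AAStringSet]), named.
#' @param poisson Apply the Poisson correction `-log(1 - p)`.
#' @return A symmetric distance matrix.
#' @export
pDistance <- function(alignment, poisson = FALSE) {
  seqs <- toupper(.as_named_chr(alignment))
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop("sequences must have equal length")
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- names(seqs)
  .pdist_mat(mat, poisson)
}

# p-distance on a character matrix (rows = sequences)
.pdist_mat <- function(mat, poisson = FALSE) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- mat[i, ] != "-" & mat[j, ] != "-"
    p <- if (sum(ok) == 0) 0 else mean(mat[i, ok] != mat[j, ok])
    if (poisson) p <- if (p < 1) -log(1 - p) else NA_real_
    d[i, j] <- d[j, i] <- p
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]); negative branch lengths,
#' which NJ can produce on non-additive matrices, are clamped to 0 with a
#' warning.
#'
#' @param d Symmetric non-negative matrix with zero diagonal (or `dist`).
#' @return An [ape::phylo] tree.
#' @export
njTree <- function(d) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (!isSymmetric(unname(d), tol = 1e-8)) stop("matrix must be symmetric")
    if (any(d < 0)) stop("distances must be non-negative")
    if (any(abs(diag(d)) > 1e-12)) stop("diagonal must be zero")
    d <- stats::as.dist(d)
  }
  tr <- ape::nj(d)
  if (any(tr$edge.length < 0)) {
    warning("negative branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Bootstrap support for a neighbor-joining protein tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree from
#' the protein p-distance of each replicate, and reports for every internal
#' edge of the full-alignment tree the percentage of replicates containing
#' the same bipartition. Supports are stored in `node.label`.
#'
#' @param alignment Named, equal-length aligned proteins.
#' @param nReplicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; the run is reproducible bit-for-bit.
#' @param poisson Use Poisson-corrected distances.
#' @return The NJ tree ([ape::phylo]) with bootstrap percentages as
#'   `node.label`.
#' @export
bootstrapSupport <- function(alignment, nReplicates = 1000, seed = 1,
                             poisson = FALSE) {
  seqs <- toupper(.as_named_chr(alignment))
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop("sequences must have equal length")
  if (L < 2) stop("alignment must have at least 2 columns")
  if (nReplicates < 1) stop("need at least 1 replicate")
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- names(seqs)
  ref <- njTree(.pdist_mat(mat, poisson))
  set.seed(seed)
  reps <- vector("list", nReplicates)
  for (r in seq_len(nReplicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    reps[[r]] <- suppressWarnings(
      njTree(.pdist_mat(mat[, cols, drop = FALSE], poisson)))
  }
  cnt <- ape::prop.clades(ref, reps, rooted = FALSE)
  cnt[is.na(cnt)] <- 0
  ref$node.label <- round(100 * cnt / nReplicates)
  ref
}
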