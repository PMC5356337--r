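# Target-driven miRNA discovery: expectation-scored complementarity
# scanning, genome matching, hairpin extraction/annotation, degradome
# cleavage validation, known-miRNA absence check.

.COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Read a small-RNA library
#'
#' Accepts FASTA (read count parsed from a `_xN` header suffix, count 1
#' when absent) or TSV with columns `seq` and `count` (optional `id`).
#' U is normalized to T.
#'
#' @param path Input file.
#' @return data.frame with columns `id`, `seq`, `count`.
#' @export
readSrnaLibrary <- function(path) {
  first <- readLines(path, n = 1)
  if (length(first) > 0 && startsWith(first, ">")) {
    x <- readBStringSet(path)
    ids <- sub("\\s.*$", "", names(x))
    count <- rep(1L, length(ids))
    has <- grepl("_x\\d+$", ids)
    count[has] <- as.integer(sub(".*_x(\\d+)$", "\\1", ids[has]))
    lib <- data.frame(id = ids, seq = .normalize_dna(as.character(x)),
                      count = count, stringsAsFactors = FALSE)
  } else {
    x <- read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("seq", "count") %in% colnames(x)))
      stop("TSV library must have columns seq, count")
    lib <- data.frame(id = x$id %||% paste0("sRNA", seq_len(nrow(x))),
                      seq = .normalize_dna(x$seq),
                      count = as.integer(x$count), stringsAsFactors = FALSE)
  }
  rownames(lib) <- NULL
  lib
}

#' Filter a small-RNA library by read support
#'
#' Keeps small RNAs with read count strictly greater than
#' `minReads - 1` (default: more than four reads), ordered by count
#' (descending) then sequence.
#'
#' @param lib data.frame with columns `seq` and `count` (see
#'   [readSrnaLibrary()]).
#' @param minReads Minimum read count to keep (default 5).
#' @return The filtered, reordered data.frame.
#' @export
filterSrna <- function(lib, minReads = 5) {
  out <- lib[lib$count >= minReads, , drop = FALSE]
  out <- out[order(-out$count, out$seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Score one register layout. mi: miRNA 5'->3' chars; site: transcript
# chars 5'->3' paired antiparallel. `partner[i]` = index into site for
# miRNA position i (NA = miRNA bulge). Unpaired site positions are a
# target bulge. Penalties: mismatch 1, G:U 0.5, indel 2; doubled at
# miRNA positions 2-13 (a target bulge between miRNA positions j and j+1
# is charged at position j+1).
.score_layout <- function(mi, site, partner, bulge_mi = NA,
                          bulge_after = NA) {
  m <- length(mi)
  pen <- 0
  sym <- character(m)
  for (i in seq_len(m)) {
    w <- if (i >= 2 && i <= 13) 2 else 1
    if (is.na(partner[i])) { # miRNA nucleotide bulged out
      pen <- pen + 2 * w
      sym[i] <- "-"
      next
    }
    y <- site[partner[i]]
    x <- mi[i]
    if (y == .COMP[[x]]) {
      sym[i] <- "|"
    } else if ((x == "G" && y == "T") || (x == "T" && y == "G")) {
      pen <- pen + 0.5 * w
      sym[i] <- "o"
    } else {
      pen <- pen + 1 * w
      sym[i] <- "."
    }
  }
  if (!is.na(bulge_after)) { # extra target nucleotide
    j <- bulge_after + 1
    w <- if (j >= 2 && j <= 13) 2 else 1
    pen <- pen + 2 * w
  }
  list(expectation = pen, duplex = paste(sym, collapse = ""))
}

#' Scan transcripts for small-RNA complementary sites
#'
#' Slides the reverse complement of the small RNA over each transcript,
#' allowing at most one single-nucleotide bulge (in either strand), and
#' scores each register with the plant-miRNA expectation penalty:
#' mismatch 1.0, G:U wobble 0.5, indel 2.0, each doubled at miRNA
#' positions 2-13 from the 5' end (a target-side bulge between miRNA
#' positions j and j+1 is charged at position j+1). Sites with expectation
#' at most `maxExpectation` are returned with the expected cleavage
#' position: the transcript coordinate paired to miRNA nucleotide 10.
#'
#' @param srna Small-RNA sequence (character, 5'->3'; U allowed) or a
#'   one-row data.frame with a `seq` column.
#' @param transcripts Named character vector or
#'   [Biostrings::DNAStringSet].
#' @param maxExpectation Score cutoff (default 3.0).
#' @param allowBulge Permit single-nucleotide bulges (default TRUE).
#' @return data.frame with columns `transcript_id`, `start`, `end`
#'   (1-based site coordinates), `expectation`, `cleavage_pos`, `duplex`
#'   (miRNA 5'->3': `|` Watson-Crick, `o` G:U, `.` mismatch, `-` bulged
#'   miRNA base), `bulge`; best variant per site start, sorted by
#'   expectation then coordinate.
#' @export
targetScan <- function(srna, transcripts, maxExpectation = 3,
                       allowBulge = TRUE) {
  if (is.data.frame(srna)) srna <- srna$seq[1]
  mi <- strsplit(.normalize_dna(srna), "")[[1]]
  m <- length(mi)
  tx <- .as_named_chr(transcripts)
  if (length(tx) == 0) stop("transcripts must be non-empty")
  if (is.null(names(tx))) names(tx) <- paste0("tx", seq_along(tx))
  res <- list()
  for (id in names(tx)) {
    tc <- strsplit(.normalize_dna(tx[[id]]), "")[[1]]
    L <- length(tc)
    if (L < m) stop("transcript ", id, " shorter than the small RNA")
    layouts <- list(list(len = m, partner = m:1, bulge_mi = NA,
                         bulge_after = NA, label = "none"))
    if (allowBulge) {
      for (j in seq_len(m - 1)) { # target bulge between miRNA j and j+1
        partner <- integer(m)
        for (i in seq_len(m)) {
          p <- m - i + 1            # ungapped site offset for miRNA i
          q <- m - j                # site offsets 1..q precede the bulge
          partner[i] <- if (p <= q) p else p + 1
        }
        layouts[[length(layouts) + 1]] <-
          list(len = m + 1, partner = partner, bulge_mi = NA,
               bulge_after = j, label = sprintf("target@%d", j))
      }
      for (j in seq_len(m)) {       # miRNA nucleotide j bulged out
        partner <- rep(NA_integer_, m)
        for (i in seq_len(m)) {
          if (i == j) next
          p <- m - i + 1
          pj <- m - j + 1
          partner[i] <- if (p < pj) p else p - 1
        }
        layouts[[length(layouts) + 1]] <-
          list(len = m - 1, partner = partner, bulge_mi = j,
               bulge_after = NA, label = sprintf("mirna@%d", j))
      }
    }
    hits <- list()
    wts <- ifelse(seq_len(m) >= 2 & seq_len(m) <= 13, 2, 1)
    for (lay in layouts) {
      if (lay$len > L) next
      starts <- seq_len(L - lay$len + 1)
      base <- 0
      if (!is.na(lay$bulge_after)) {
        j <- lay$bulge_after + 1
        base <- base + 2 * (if (j >= 2 && j <= 13) 2 else 1)
      }
      for (i in which(is.na(lay$partner)))
        base <- base + 2 * wts[i]
      pen <- rep(base, length(starts))
      for (i in which(!is.na(lay$partner))) {
        y <- tc[starts + lay$partner[i] - 1]
        x <- mi[i]
        pv <- as.numeric(y != .COMP[[x]])
        if (x == "G") pv[y == "T"] <- 0.5
        if (x == "T") pv[y == "G"] <- 0.5
        pen <- pen + wts[i] * pv
      }
      pass <- starts[pen <= maxExpectation]
      if (length(pass) == 0) next
      p10 <- lay$partner[10]
      cleave <- if (!is.na(p10)) pass + p10 - 1
                else pass + lay$partner[9] - 2 # nt 10 bulged out
      duplex <- vapply(pass, function(s)
        .score_layout(mi, tc[s:(s + lay$len - 1)], lay$partner,
                      bulge_after = lay$bulge_after)$duplex, "")
      hits[[length(hits) + 1]] <- data.frame(
        transcript_id = id, start = pass, end = pass + lay$len - 1,
        expectation = pen[pen <= maxExpectation],
        cleavage_pos = cleave, duplex = duplex, bulge = lay$label,
        stringsAsFactors = FALSE)
    }
    if (length(hits) > 0) {
      h <- do.call(rbind, hits)
      h <- h[order(h$start, h$expectation), , drop = FALSE]
      h <- h[!duplicated(h$start), , drop = FALSE] # best variant per start
      res[[id]] <- h
    }
  }
  out <- if (length(res) > 0) do.call(rbind, res) else
    data.frame(transcript_id = character(), start = integer(),
               end = integer(), expectation = numeric(),
               cleavage_pos = integer(), duplex = character(),
               bulge = character(), stringsAsFactors = FALSE)
  out <- out[order(out$expectation, out$transcript_id, out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match a small RNA against a genome
#'
#' Exact (default) or near-exact matching on both strands; coordinates
#' are 1-based on the forward strand.
#'
#' @param srna Small-RNA sequence (character; U allowed).
#' @param genome Named [Biostrings::DNAStringSet] or character vector.
#' @param maxMismatch Allowed mismatches (default 0).
#' @return data.frame with columns `seqname`, `start`, `end`, `strand`.
#' @export
genomeMatch <- function(srna, genome, maxMismatch = 0) {
  if (is.data.frame(srna)) srna <- srna$seq[1]
  pat <- DNAString(.normalize_dna(srna))
  gen <- DNAStringSet(.normalize_dna(.as_named_chr(genome)))
  if (is.null(names(gen))) names(gen) <- paste0("seq", seq_along(gen))
  out <- list()
  for (nm in names(gen)) {
    for (std in c("+", "-")) {
      p <- if (std == "+") pat else reverseComplement(pat)
      mt <- matchPattern(p, gen[[nm]], max.mismatch = maxMismatch)
      if (length(mt) > 0)
        out[[length(out) + 1]] <- data.frame(
          seqname = nm, start = BiocGenerics::start(mt),
          end = BiocGenerics::end(mt), strand = std,
          stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(seqname = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$seqname, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Fold a nucleotide sequence into a secondary structure
#'
#' Pluggable backend: `"nussinov"` (built-in weighted base-pair
#' maximization, minimum loop 3; energy is the negative total pair
#' weight) or `"rnafold"` (ViennaRNA's RNAfold minimum-free-energy
#' structure, kcal/mol; requires the `RNAfold` binary on the PATH).
#'
#' @param seq Nucleotide sequence (U allowed).
#' @param backend `"auto"` (RNAfold when the binary is found, otherwise
#'   the built-in folder), `"nussinov"` or `"rnafold"`.
#' @param minLoop Minimum hairpin loop size for the built-in folder.
#' @return list with `structure` (dot-bracket) and `energy`.
#' @export
foldSequence <- function(seq, backend = c("auto", "nussinov", "rnafold"),
                         minLoop = 3) {
  backend <- match.arg(backend)
  if (backend == "auto")
    backend <- if (Sys.which("RNAfold") != "") "rnafold" else "nussinov"
  s <- .normalize_dna(as.character(seq))
  if (backend == "nussinov")
    return(.nussinov_fold(s, minLoop))
  if (Sys.which("RNAfold") == "")
    stop("RNAfold binary not found; use backend = 'nussinov'")
  out <- system2("RNAfold", c("--noPS"), input = chartr("T", "U", s),
                 stdout = TRUE)
  line <- out[length(out)]
  struct <- sub("^(\\S+).*$", "\\1", line)
  energy <- as.numeric(sub("^\\S+\\s+\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1",
                           line))
  list(structure = struct, energy = energy)
}

#' Extract genomic windows around a small-RNA locus and fold them
#'
#' Takes the symmetric window (`flank` nt each side) plus two asymmetric
#' sub-windows (long flank on one side, 60 nt on the other, covering
#' precursors whose star arm lies mostly up- or downstream), folds each
#' with the chosen backend, and keeps the lowest-energy structure per
#' window. Windows in which no mature nucleotide is paired are dropped.
#' For minus-strand loci the window sequence is reverse-complemented so
#' the mature small RNA always reads 5'->3' in `window_seq`.
#'
#' @param genome Named [Biostrings::DNAStringSet] or character vector.
#' @param locus One-row data.frame (or list) with `seqname`, `start`,
#'   `end`, `strand` (e.g. a row of [genomeMatch()] output).
#' @param flank Flank length in nt (default 300).
#' @param backend,minLoop Passed to [foldSequence()].
#' @return List of [HairpinCandidate] objects sorted by energy.
#' @export
extractAndFold <- function(genome, locus, flank = 300,
                           backend = "auto", minLoop = 3) {
  gen <- DNAStringSet(.normalize_dna(.as_named_chr(genome)))
  if (is.null(names(gen))) names(gen) <- paste0("seq", seq_along(gen))
  if (!locus$seqname %in% names(gen))
    stop("unknown sequence: ", locus$seqname)
  chrom <- as.character(gen[[locus$seqname]])
  L <- nchar(chrom)
  s0 <- as.integer(locus$start); e0 <- as.integer(locus$end)
  if (s0 < 1 || e0 > L || s0 > e0) stop("invalid locus coordinates")
  short <- 60
  windows <- unique(list(
    c(max(1, s0 - flank), min(L, e0 + flank)),
    c(max(1, s0 - flank), min(L, e0 + short)),
    c(max(1, s0 - short), min(L, e0 + flank)),
    c(max(1, s0 - short), min(L, e0 + short))))
  cands <- list()
  for (w in windows) {
    ws <- substr(chrom, w[1], w[2])
    ms <- s0 - w[1] + 1
    me <- e0 - w[1] + 1
    if (identical(as.character(locus$strand), "-")) {
      ws <- as.character(reverseComplement(DNAString(ws)))
      wlen <- nchar(ws)
      new_ms <- wlen - me + 1
      me <- wlen - ms + 1
      ms <- new_ms
    }
    fold <- foldSequence(ws, backend = backend, minLoop = minLoop)
    partner <- .pair_table(fold$structure)
    if (all(is.na(partner[ms:me]))) next # mature entirely unpaired
    cands[[length(cands) + 1]] <- new("HairpinCandidate",
      seqname = as.character(locus$seqname), start = w[1], end = w[2],
      strand = as.character(locus$strand), window_seq = ws,
      structure = fold$structure, energy = fold$energy,
      mature_start = ms, mature_end = me)
  }
  cands[order(vapply(cands, function(x) x@energy, 0))]
}

# Partner table from a dot-bracket string: partner[i] = paired position
# or NA.
.pair_table <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  partner <- rep(NA_integer_, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  partner
}

#' Default structural criteria for miRNA annotation
#'
#' Thresholds following the community annotation criteria for plant
#' miRNAs: mature length 20-22 nt, mature contained in one arm of a
#' single stem-loop, at most 4 unpaired mature bases in the
#' miRNA/miRNA* duplex, at most 2 nt of asymmetric bulge, star inferred
#' with a 2-nt 3' overhang. Read support is checked separately
#' ([filterSrna()]).
#'
#' @return Named list of thresholds.
#' @export
mirnaCriteria <- function() {
  list(mature_len = c(20L, 22L), max_mismatches = 4L, max_bulge_nt = 2L,
       star_overhang = 2L)
}

#' Annotate a hairpin candidate against structural miRNA criteria
#'
#' Evaluates, on the folded window: mature length in range; all paired
#' mature bases pairing to one side (mature within one arm, not spanning
#' the loop); number of unpaired mature bases (duplex mismatches) within
#' the limit; asymmetry between unpaired nucleotides on the mature and
#' star sides of the duplex within the bulge limit. The star sequence is
#' read off the partner arm with a 2-nt 3' overhang. The verdict is the
#' conjunction of the structural criteria.
#'
#' @param candidate A [HairpinCandidate] from [extractAndFold()].
#' @param mature Mature small-RNA sequence (character; U allowed); must
#'   match the candidate window at the recorded mature coordinates.
#' @param criteria List of thresholds, see [mirnaCriteria()].
#' @return The candidate with `arm`, `star_seq`, `criteria` and `verdict`
#'   filled in.
#' @export
annotateMirna <- function(candidate, mature, criteria = mirnaCriteria()) {
  mat <- .normalize_dna(as.character(mature))
  ws <- candidate@window_seq
  ms <- candidate@mature_start; me <- candidate@mature_end
  if (substr(ws, ms, me) != mat) {
    loc <- regexpr(mat, ws, fixed = TRUE)
    if (loc == -1) stop("mature sequence not found in the window")
    ms <- as.integer(loc); me <- ms + nchar(mat) - 1
    candidate@mature_start <- ms; candidate@mature_end <- me
  }
  partner <- .pair_table(candidate@structure)
  mpos <- ms:me
  part <- partner[mpos]
  # The miRNA/miRNA* duplex is antiparallel, so partner + position is
  # (nearly) constant along it; pairs whose offset deviates from the
  # duplex median by more than the bulge allowance (+1) are spurious
  # long-range contacts of the fold and count as unpaired.
  off <- part + mpos
  keep <- !is.na(part) &
    abs(off - median(off, na.rm = TRUE)) <= criteria$max_bulge_nt + 1
  self_paired <- any(!is.na(part) & part >= ms & part <= me)
  part[!keep] <- NA_integer_
  paired <- !is.na(part)
  crit <- c(length_ok = NA, one_arm = NA, mismatch_ok = NA, bulge_ok = NA)
  crit["length_ok"] <- nchar(mat) >= criteria$mature_len[1] &&
                       nchar(mat) <= criteria$mature_len[2]
  if (!any(paired)) {
    crit[c("one_arm", "mismatch_ok", "bulge_ok")] <- FALSE
    candidate@criteria <- crit
    candidate@verdict <- FALSE
    return(candidate)
  }
  p <- part[paired]
  one_arm <- (all(p > me) || all(p < ms)) && !self_paired
  crit["one_arm"] <- one_arm
  crit["mismatch_ok"] <- sum(!paired) <= criteria$max_mismatches
  first <- mpos[paired][1]; last <- mpos[paired][sum(paired)]
  unpaired_mature <- sum(!paired[mpos >= first & mpos <= last])
  star_lo <- min(p); star_hi <- max(p)
  unpaired_star <- (star_hi - star_lo + 1) - sum(paired)
  crit["bulge_ok"] <- one_arm &&
    abs(unpaired_star - unpaired_mature) <= criteria$max_bulge_nt
  if (one_arm) {
    candidate@arm <- if (all(p > me)) "5p" else "3p"
    hi <- min(star_hi + criteria$star_overhang, nchar(ws))
    candidate@star_seq <- substr(ws, star_lo, hi)
  }
  candidate@criteria <- crit
  candidate@verdict <- all(crit)
  candidate
}

#' Validate a predicted cleavage site against a degradome profile
#'
#' Classifies the degradome signal at the expected cleavage position
#' (the transcript coordinate paired to miRNA nucleotide 10, +/-
#' `window`): category 0 = the peak is the unique transcript-wide
#' maximum and exceeds one read; 1 = a tied maximum; 2 = above the median
#' of non-zero positions; 3 = at or below that median; 4 = a single
#' read. The site is supported when the category is at most
#' `supportedMax`.
#'
#' @param profile A [DegradomeProfile].
#' @param site One-row data.frame or list with `cleavage_pos` (e.g. a row
#'   of [targetScan()] output).
#' @param window Search window around the expected position (default 1).
#' @param supportedMax Largest supported category (default 2).
#' @return A [CleavageEvidence].
#' @export
degradomeValidate <- function(profile, site, window = 1,
                              supportedMax = 2) {
  counts <- profile@counts
  if (length(counts) == 0)
    return(new("CleavageEvidence", transcript_id = profile@transcript_id,
               cleavage_pos = NA_real_, peak_count = 0,
               category = NA_integer_, supported = FALSE))
  cp <- as.integer(site$cleavage_pos)
  if (cp < 1 || cp > length(counts))
    stop("cleavage position outside the profile")
  win <- max(1, cp - window):min(length(counts), cp + window)
  peak <- max(counts[win])
  if (peak == 0) {
    cat_ <- NA_integer_
  } else if (peak == 1) {
    cat_ <- 4L
  } else {
    mx <- max(counts)
    med <- median(counts[counts > 0])
    if (peak == mx && sum(counts == mx) == 1) cat_ <- 0L
    else if (peak == mx) cat_ <- 1L
    else if (peak > med) cat_ <- 2L
    else cat_ <- 3L
  }
  new("CleavageEvidence", transcript_id = profile@transcript_id,
      cleavage_pos = as.numeric(cp), peak_count = as.numeric(peak),
      category = cat_,
      supported = !is.na(cat_) && cat_ <= supportedMax)
}

#' Check whether a known miRNA is absent from a library and genome
#'
#' Reports (i) whether the mature sequence occurs in the small-RNA
#' library (same length, at most `maxLibMismatch` mismatches) and (ii)
#' whether any genomic locus matching the mature folds into a hairpin
#' passing the structural annotation criteria. The miRNA is called absent
#' when both are negative.
#'
#' @param mature Known mature sequence (character; U allowed).
#' @param srnaLib data.frame with a `seq` column (see
#'   [readSrnaLibrary()]).
#' @param genome Named [Biostrings::DNAStringSet] or character vector.
#' @param maxLibMismatch Library mismatch allowance (default 1).
#' @param genomeMaxMismatch Genome matching mismatches (default 0).
#' @param flank,backend Passed to [extractAndFold()].
#' @return list with `in_library`, `genomic_hairpin`, `verdict` (one of
#'   `"absent"`, `"library-only"`, `"genome-only"`, `"present"`).
#' @export
absenceCheck <- function(mature, srnaLib, genome, maxLibMismatch = 1,
                         genomeMaxMismatch = 0, flank = 300,
                         backend = "auto") {
  mat <- .normalize_dna(as.character(mature))
  in_lib <- FALSE
  if (nrow(srnaLib) > 0) {
    same_len <- srnaLib$seq[nchar(srnaLib$seq) == nchar(mat)]
    if (length(same_len) > 0) {
      mm <- vapply(strsplit(same_len, ""), function(x)
        sum(x != strsplit(mat, "")[[1]]), 0L)
      in_lib <- any(mm <= maxLibMismatch)
    }
  }
  loci <- genomeMatch(mat, genome, maxMismatch = genomeMaxMismatch)
  hairpin <- FALSE
  if (nrow(loci) > 0) {
    for (k in seq_len(nrow(loci))) {
      cands <- extractAndFold(genome, loci[k, ], flank = flank,
                              backend = backend)
      for (cd in cands) {
        ann <- tryCatch(annotateMirna(cd, mat), error = function(e) NULL)
        if (!is.null(ann) && isTRUE(ann@verdict)) { hairpin <- TRUE; break }
      }
      if (hairpin) break
    }
  }
  verdict <- if (!in_lib && !hairpin) "absent"
             else if (in_lib && !hairpin) "library-only"
             else if (!in_lib && hairpin) "genome-only"
             else "present"
  list(in_library = in_lib, genomic_hairpin = hairpin, verdict = verdict)
}

#' Read degradome 5'-end tags into per-transcript profiles
#'
#' @param path TSV with columns `transcript_id`, `position`, `count`.
#' @param transcriptLengths Named integer vector of transcript lengths.
#' @return Named list of [DegradomeProfile] objects (all transcripts in
#'   `transcriptLengths`, zero-filled when absent from the file).
#' @export
readDegradomeTags <- function(path, transcriptLengths) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "position", "count")
  if (!all(need %in% colnames(x)))
    stop("degradome table must have columns: ",
         paste(need, collapse = ", "))
  out <- list()
  for (id in names(transcriptLengths)) {
    counts <- integer(transcriptLengths[[id]])
    rows <- x[x$transcript_id == id, , drop = FALSE]
    if (nrow(rows) > 0) {
      if (any(rows$position < 1 | rows$position > length(counts)))
        stop("position outside transcript ", id)
      counts[rows$position] <- counts[rows$position] + rows$count
    }
    out[[id]] <- degradomeProfile(id, counts)
  }
  out
}
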