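# Seeded generators producing inputs with the statistical structure each
# pipeline stage assumes. Every generator is a pure function of its
# arguments (seed included): repeated calls are byte-identical.

.NONSTOP_CODONS <- names(Biostrings::GENETIC_CODE)[
  Biostrings::GENETIC_CODE != "*"]

# One accepted point substitution on a codon vector. Proposals creating
# stop codons are rejected; nonsynonymous proposals are accepted with
# probability `dnds` (synonymous always), so the realized Ka/Ks tracks
# the target. Codons inside `slow` (a logical vector) halve the
# nonsynonymous acceptance probability.
.mutate_codons <- function(codons, n_events, dnds, slow) {
  nc <- length(codons)
  done <- 0
  while (done < n_events) {
    ci <- 1 + sample.int(nc - 2, 1) # keep start/stop codons fixed
    p <- sample.int(3, 1)
    cur <- codons[ci]
    b <- sample(setdiff(.BASES, substr(cur, p, p)), 1)
    alt <- cur
    substr(alt, p, p) <- b
    if (.GCODE[[alt]] == "*") next
    if (.GCODE[[alt]] != .GCODE[[cur]]) {
      acc <- if (slow[ci]) dnds / 2 else dnds
      if (stats::runif(1) > acc) next
    }
    codons[ci] <- alt
    done <- done + 1
  }
  codons
}

#' Simulate a duplicated gene family with controlled dN/dS
#'
#' Generates one random ancestral ORF per paralogous group (independent
#' ancestors, so between-group similarity is at background level), then
#' derives each member by applying `branchRate * ancestorCodons` accepted
#' codon substitutions with synonymous/nonsynonymous acceptance tuned to
#' the `dnds` target (proposals creating stops rejected). A designated
#' "CuA-like" codon interval evolves with half the nonsynonymous
#' acceptance, emulating a domain under stronger purifying selection.
#'
#' @param nGroups Number of paralogous groups, or ignored when
#'   `genesPerGroup` is a vector.
#' @param genesPerGroup Genes per group; a vector gives per-group sizes
#'   (default `c(3, 3, 2, 3, 4, 2)`, the study family's group sizes).
#' @param ancestorCodons ORF length in codons excluding start/stop
#'   (default 570, >= 60).
#' @param branchRate Accepted substitutions per codon on each
#'   ancestor-to-gene branch (default 0.25).
#' @param dnds Target Ka/Ks (> 0, default 0.3).
#' @param slowStart,slowLen Codon interval evolving at `dnds / 2`
#'   (defaults: 60 codons starting at codon 101).
#' @param seed Integer seed.
#' @return list with `cds` (named [Biostrings::DNAStringSet], lengths
#'   divisible by 3, ATG...stop), `groups` (list of member-id vectors,
#'   the planted partition), `domains` (data.frame `gene_id`, `region`,
#'   `start`, `end` in codon indices on the ORF) and `config`.
#' @export
simulateGeneFamily <- function(nGroups = 6,
                               genesPerGroup = c(3, 3, 2, 3, 4, 2),
                               ancestorCodons = 570, branchRate = 0.25,
                               dnds = 0.3, slowStart = 101, slowLen = 60,
                               seed = 1) {
  if (ancestorCodons < 60) stop("ancestorCodons must be >= 60")
  if (dnds <= 0) stop("dnds target must be > 0")
  if (length(genesPerGroup) == 1)
    genesPerGroup <- rep(genesPerGroup, nGroups)
  nGroups <- length(genesPerGroup)
  set.seed(seed)
  slow <- rep(FALSE, ancestorCodons + 2)
  slow_end <- min(slowStart + slowLen - 1, ancestorCodons)
  slow[(slowStart + 1):(slow_end + 1)] <- TRUE # offset for ATG codon
  seqs <- character(0)
  groups <- list()
  gi <- 0
  for (g in seq_len(nGroups)) {
    anc <- c("ATG", sample(.NONSTOP_CODONS, ancestorCodons,
                           replace = TRUE), "TAA")
    members <- character(0)
    for (k in seq_len(genesPerGroup[g])) {
      gi <- gi + 1
      id <- sprintf("gene%02d", gi)
      n_events <- stats::rpois(1, branchRate * ancestorCodons)
      cod <- .mutate_codons(anc, n_events, dnds, slow)
      seqs[[id]] <- paste(cod, collapse = "")
      members <- c(members, id)
    }
    groups[[g]] <- members
  }
  cds <- DNAStringSet(seqs)
  ids <- names(seqs)
  # ORF codon indices (ATG is codon 1)
  domains <- data.frame(gene_id = rep(ids, each = 1),
                        region = "CuA",
                        start = slowStart + 1,
                        end = slow_end + 1,
                        stringsAsFactors = FALSE)
  list(cds = cds, groups = groups, domains = domains,
       config = list(genesPerGroup = genesPerGroup,
                     ancestorCodons = ancestorCodons,
                     branchRate = branchRate, dnds = dnds,
                     slowStart = slowStart, slowLen = slowLen,
                     seed = seed))
}

.rand_dna <- function(n) paste(sample(.BASES, n, replace = TRUE),
                               collapse = "")

#' Simulate a miRNA precursor locus and planted target sites
#'
#' Builds a fold-back precursor (mature + loop + near-reverse-complement
#' star with the configured number of mismatches), embeds it in random
#' flanking sequence, and plants a complementary site (expectation <= 1
#' by construction: at most one G:U-scoring change outside positions
#' 2-13) into the 3'-quarter of each designated target CDS, at a
#' codon-aligned position chosen so no stop codon is created.
#'
#' @param mature Mature sequence, 20-22 nt (default: the mature small RNA
#'   of the novel PPO-targeting miRNA, `CGATCTTGATACCACCAATGG`).
#' @param stemMismatches Mismatched mature bases in the miRNA/miRNA*
#'   duplex (0-4, default 1).
#' @param loopLen Terminal loop length (default 9 nt).
#' @param flank Random flank on each side of the precursor (default 300).
#' @param targets Optional named character vector /
#'   [Biostrings::DNAStringSet] of CDSs to plant sites into.
#' @param nTargets How many of `targets` receive a site (default all).
#' @param seed Integer seed.
#' @return list with `genome` (one-sequence [Biostrings::DNAStringSet]
#'   named `frag1`), `mature`, `star`, `mature_start`, `mature_end`,
#'   `precursor_start`, `precursor_end`, `strand`, `transcripts` (the
#'   target CDSs, with sites planted) and `truth` (data.frame
#'   `transcript_id`, `site_start`, `site_end`, `cleavage_pos`).
#' @export
simulateMirLocus <- function(mature = "CGATCTTGATACCACCAATGG",
                             stemMismatches = 1, loopLen = 9,
                             flank = 300, targets = NULL,
                             nTargets = NULL, seed = 1) {
  mat <- .normalize_dna(mature)
  m <- nchar(mat)
  if (m < 20 || m > 22) stop("mature length must be 20-22 nt")
  if (stemMismatches > 4)
    stop("more than 4 stem mismatches cannot pass the duplex criteria")
  set.seed(seed)
  star <- as.character(reverseComplement(DNAString(mat)))
  if (stemMismatches > 0) {
    # mismatches placed away from the star ends so the duplex stays
    # anchored; positions spaced to avoid a 2-nt bulge illusion
    pos <- seq(4, nchar(star) - 3, length.out = stemMismatches)
    pos <- unique(as.integer(round(pos)))
    for (p in pos) {
      cur <- substr(star, p, p)
      mb <- substr(mat, m - p + 1, m - p + 1)
      # exclude the current base, the Watson-Crick complement and the
      # G:U wobble partner, so the planted change cannot pair at all
      excl <- c(cur, .COMP[[mb]],
                switch(mb, G = "T", T = "G", character(0)))
      substr(star, p, p) <- sample(setdiff(.BASES, excl), 1)
    }
  }
  loop <- .rand_dna(loopLen)
  precursor <- paste0(mat, loop, star)
  left <- .rand_dna(flank)
  right <- .rand_dna(flank)
  frag <- paste0(left, precursor, right)
  genome <- DNAStringSet(c(frag1 = frag))
  mature_start <- flank + 1
  mature_end <- flank + m
  out <- list(genome = genome, mature = mat, star = star,
              mature_start = mature_start, mature_end = mature_end,
              precursor_start = flank + 1,
              precursor_end = flank + nchar(precursor), strand = "+",
              transcripts = NULL, truth = NULL)
  if (!is.null(targets)) {
    tx <- .as_named_chr(targets)
    if (is.null(names(tx))) names(tx) <- paste0("tx", seq_along(tx))
    if (is.null(nTargets)) nTargets <- length(tx)
    site <- as.character(reverseComplement(DNAString(mat)))
    chosen <- names(tx)[seq_len(nTargets)]
    truth <- list()
    for (id in chosen) {
      s <- tx[[id]]
      L <- nchar(s)
      # codon-aligned insertion point in the 3' quarter of the ORF,
      # shifted by codons until no stop codon is created in frame
      base <- (floor(L * 0.75 / 3)) * 3 + 1
      placed <- FALSE
      for (shift in seq(0, 30, by = 3)) {
        st <- base + shift
        en <- st + m - 1
        if (en > L - 3) break
        cand <- s
        substr(cand, st, en) <- site
        cod_start <- st - (st - 1) %% 3
        cods <- substring(cand, seq(cod_start, en, 3),
                          seq(cod_start, en, 3) + 2)
        if (!any(.GCODE[cods] == "*")) {
          tx[[id]] <- cand
          truth[[id]] <- data.frame(transcript_id = id, site_start = st,
                                    site_end = en,
                                    cleavage_pos = en - 9,
                                    stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not plant a stop-free site in ", id)
    }
    out$transcripts <- DNAStringSet(tx)
    out$truth <- do.call(rbind, c(truth, list(make.row.names = FALSE)))
  }
  out
}

#' Simulate a small-RNA library around a planted mature sequence
#'
#' The mature small RNA receives `matureFraction` of the requested depth,
#' the star roughly 10% of the mature count (binomial), and the remainder
#' is background: random 18-26-nt sequences with counts 1-4, below the
#' reads-greater-than-four filter. Total reads equal `depth` exactly.
#'
#' @param truth Result of [simulateMirLocus()] (uses `mature` and
#'   `star`).
#' @param depth Total read count (default 10000).
#' @param matureFraction Fraction of depth given to the mature read
#'   (default 0.2).
#' @param seed Integer seed.
#' @return data.frame with `id`, `seq`, `count`.
#' @export
simulateSrnaLibrary <- function(truth, depth = 10000,
                                matureFraction = 0.2, seed = 1) {
  set.seed(seed)
  mature_count <- max(5L, as.integer(round(depth * matureFraction)))
  star_count <- rbinom(1, mature_count, 0.1)
  rest <- depth - mature_count - star_count
  bg_seq <- character(0); bg_cnt <- integer(0)
  while (rest > 0) {
    cnt <- min(sample.int(4, 1), rest)
    bg_seq <- c(bg_seq, .rand_dna(sample(18:26, 1)))
    bg_cnt <- c(bg_cnt, cnt)
    rest <- rest - cnt
  }
  lib <- data.frame(
    id = c("mature", "star", sprintf("bg%05d", seq_along(bg_seq))),
    seq = c(truth$mature, truth$star, bg_seq),
    count = c(mature_count, star_count, bg_cnt),
    stringsAsFactors = FALSE)
  lib[lib$count > 0, , drop = FALSE]
}

#' Simulate degradome profiles with planted cleavage peaks
#'
#' Poisson background (mean `background`) at every transcript position,
#' plus a Poisson spike with mean `signalToBackground * background` at
#' each true cleavage position.
#'
#' @param transcripts Named character vector or
#'   [Biostrings::DNAStringSet].
#' @param truth data.frame with `transcript_id` and `cleavage_pos`
#'   (e.g. from [simulateMirLocus()]); transcripts absent from it get
#'   background only.
#' @param signalToBackground Peak-to-background ratio (default 10; 0
#'   plants no peak).
#' @param background Background mean per position (default 1).
#' @param seed Integer seed.
#' @return Named list of [DegradomeProfile] objects.
#' @export
simulateDegradome <- function(transcripts, truth = NULL,
                              signalToBackground = 10, background = 1,
                              seed = 1) {
  set.seed(seed)
  tx <- .as_named_chr(transcripts)
  if (is.null(names(tx))) names(tx) <- paste0("tx", seq_along(tx))
  out <- list()
  for (id in names(tx)) {
    L <- nchar(tx[[id]])
    counts <- rpois(L, background)
    if (!is.null(truth) && id %in% truth$transcript_id &&
        signalToBackground > 0) {
      cp <- truth$cleavage_pos[truth$transcript_id == id][1]
      counts[cp] <- counts[cp] +
        rpois(1, signalToBackground * background)
    }
    out[[id]] <- degradomeProfile(id, counts)
  }
  out
}

#' Simulate a two-library count table with planted fold changes
#'
#' Gene counts are Poisson with expectation
#' `share * librarySize * fold`, where per-gene shares are drawn once
#' and scaled so the genes jointly take a small fraction of each
#' library; transcript lengths are drawn uniformly from 900-1900 bp
#' (a typical plant ORF range).
#'
#' @param nGenes Number of genes.
#' @param foldChanges Per-gene fold change of library B relative to A
#'   (recycled; default 1).
#' @param librarySizes Total mapped reads per library (length 2).
#' @param geneMassFraction Fraction of each library allotted to the
#'   simulated genes in aggregate (default 0.02).
#' @param seed Integer seed.
#' @return list with `counts` (nGenes x 2 matrix), `lengths`, `totals`,
#'   `fold` (the planted vector).
#' @export
simulateCounts <- function(nGenes = 19, foldChanges = 1,
                           librarySizes = c(1e6, 1e6),
                           geneMassFraction = 0.02, seed = 1) {
  if (any(librarySizes <= 0)) stop("library sizes must be positive")
  set.seed(seed)
  fold <- rep_len(foldChanges, nGenes)
  share <- stats::rexp(nGenes) + 0.1
  share <- share / sum(share) * geneMassFraction
  lenv <- sample(900:1900, nGenes, replace = TRUE)
  mu_a <- share * librarySizes[1]
  mu_b <- share * librarySizes[2] * fold
  counts <- cbind(A = rpois(nGenes, mu_a), B = rpois(nGenes, mu_b))
  rownames(counts) <- sprintf("gene%02d", seq_len(nGenes))
  names(lenv) <- rownames(counts)
  list(counts = counts, lengths = lenv,
       totals = setNames(librarySizes, c("A", "B")), fold = fold)
}

#' Simulate replicated qPCR Ct tables with planted fold changes
#'
#' Target Ct is `baselineCt - log2(fold)` plus Gaussian noise; the
#' reference gene is constant across conditions (internal-control
#' analogue) with the same noise.
#'
#' @param folds Named numeric vector of planted fold changes per
#'   condition; the control condition must have fold 1.
#' @param control Name of the control condition (default the first).
#' @param baselineCt Target Ct in the control (default 26).
#' @param refCt Reference-gene Ct (default 20).
#' @param sigma Ct noise standard deviation (default 0.1).
#' @param replicates Biological replicates per condition (default 3).
#' @param seed Integer seed.
#' @return data.frame with `condition`, `replicate`, `target_ct`,
#'   `ref_ct`.
#' @export
simulateQpcr <- function(folds = c(CK = 1, MeJA = 4),
                         control = names(folds)[1], baselineCt = 26,
                         refCt = 20, sigma = 0.1, replicates = 3,
                         seed = 1) {
  set.seed(seed)
  rows <- list()
  for (cond in names(folds)) {
    mu <- baselineCt - log2(folds[[cond]])
    rows[[cond]] <- data.frame(
      condition = cond, replicate = seq_len(replicates),
      target_ct = mu + rnorm(replicates, 0, sigma),
      ref_ct = refCt + rnorm(replicates, 0, sigma),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "control") <- control
  out
}
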