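# Independent oracles used to cross-check the package implementations.
# Each is written from the definition, not from the package code paths.

.oracle_code <- Biostrings::GENETIC_CODE
.oracle_bases <- c("A", "C", "G", "T")

# --- Nei-Gojobori: exhaustive pathway enumeration ---------------------

oracle_syn_sites <- function(codon) {
  aa <- .oracle_code[[codon]]
  s <- 0
  for (p in 1:3) {
    cur <- substr(codon, p, p)
    for (b in .oracle_bases[.oracle_bases != cur]) {
      alt <- paste0(substr(codon, 1, p - 1), b, substr(codon, p + 1, 3))
      if (.oracle_code[[alt]] == aa) s <- s + 1 / 3
    }
  }
  s
}

# all orderings of the differing positions, built explicitly
oracle_orderings <- function(idx) {
  if (length(idx) <= 1) return(list(idx))
  out <- list()
  for (i in seq_along(idx)) {
    rest <- oracle_orderings(idx[-i])
    for (r in rest) out[[length(out) + 1]] <- c(idx[i], r)
  }
  out
}

oracle_pair_path <- function(c1, c2) {
  diffs <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(diffs) == 0) return(c(0, 0))
  walk <- function(path, allow_stop) {
    cur <- c1; sd <- 0; nd <- 0
    for (p in path) {
      nxt <- paste0(substr(cur, 1, p - 1), substr(c2, p, p),
                    substr(cur, p + 1, 3))
      if (!allow_stop && .oracle_code[[nxt]] == "*") return(NULL)
      if (.oracle_code[[cur]] == .oracle_code[[nxt]]) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  paths <- oracle_orderings(diffs)
  res <- Filter(Negate(is.null), lapply(paths, walk, allow_stop = FALSE))
  if (length(res) == 0) res <- lapply(paths, walk, allow_stop = TRUE)
  colMeans(do.call(rbind, res))
}

oracle_ng86 <- function(codons_a, codons_b) {
  S <- (sum(vapply(codons_a, oracle_syn_sites, 0)) +
        sum(vapply(codons_b, oracle_syn_sites, 0))) / 2
  N <- 3 * length(codons_a) - S
  sd_nd <- rowSums(mapply(oracle_pair_path, codons_a, codons_b))
  jc <- function(p) if (is.na(p) || p >= 0.75) NA_real_
                    else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = sd_nd[1], Nd = sd_nd[2],
       ks = jc(if (S > 0) sd_nd[1] / S else NA),
       ka = jc(if (N > 0) sd_nd[2] / N else NA))
}

random_codon_pair <- function(n_codons) {
  sense <- names(.oracle_code)[.oracle_code != "*"]
  list(a = sample(sense, n_codons, replace = TRUE),
       b = sample(sense, n_codons, replace = TRUE))
}

# --- Needleman-Wunsch with affine gaps (Gotoh) ------------------------

oracle_nw_score <- function(a, b, gap_open = 10, gap_ext = 0.5,
                            matrix_name = "BLOSUM62") {
  e <- new.env()
  utils::data(list = matrix_name, package = "Biostrings", envir = e)
  S <- get(matrix_name, envir = e)
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -gap_open - gap_ext * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- -gap_open - gap_ext * (j - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- S[A[i - 1], B[j - 1]]
      M[i, j] <- s + max(M[i - 1, j - 1], X[i - 1, j - 1],
                         Y[i - 1, j - 1])
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_ext,
                     X[i - 1, j] - gap_ext)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_ext,
                     Y[i, j - 1] - gap_ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# --- Fisher two-sided p by explicit hypergeometric enumeration --------

oracle_fisher2 <- function(a, Na, b, Nb) {
  k <- a + b            # first-column margin
  pr <- function(x) choose(Na, x) * choose(Nb, k - x) / choose(Na + Nb, k)
  xs <- max(0, k - Nb):min(k, Na)
  probs <- vapply(xs, pr, 0)
  obs <- pr(a)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# --- Expectation score: explicit register enumeration -----------------

oracle_comp <- c(A = "T", C = "G", G = "C", T = "A")

oracle_pos_pen <- function(x, y, i) {
  w <- if (i >= 2 && i <= 13) 2 else 1
  if (y == oracle_comp[[x]]) return(0)
  if ((x == "G" && y == "T") || (x == "T" && y == "G")) return(0.5 * w)
  1 * w
}

# Precomputed penalty lookup: pen_tab[x, y, i] for miRNA base x against
# transcript base y at miRNA position i, built from oracle_pos_pen.
oracle_pen_tab <- function(m) {
  tab <- array(0, dim = c(4, 4, m),
               dimnames = list(.oracle_bases, .oracle_bases, NULL))
  for (x in .oracle_bases) for (y in .oracle_bases)
    for (i in seq_len(m)) tab[x, y, i] <- oracle_pos_pen(x, y, i)
  tab
}

# Enumerates every ungapped register and every single-bulge register
# (target bulge between miRNA j and j+1 charged at j+1; miRNA bulge at j
# charged at j) and returns the minimum expectation over all of them.
oracle_min_expectation <- function(mirna, transcript) {
  mi <- match(strsplit(mirna, "")[[1]], .oracle_bases)
  tc <- match(strsplit(transcript, "")[[1]], .oracle_bases)
  m <- length(mi); L <- length(tc)
  tab <- oracle_pen_tab(m)
  score_at <- function(s, offsets, keep_i, extra) {
    # keep_i: miRNA positions that pair; offsets: site offset per kept i
    extra + sum(tab[cbind(mi[keep_i], tc[s + offsets - 1], keep_i)])
  }
  best <- Inf
  all_i <- seq_len(m)
  for (s in seq_len(max(0, L - m + 1)))   # ungapped
    best <- min(best, score_at(s, m - all_i + 1, all_i, 0))
  for (j in seq_len(m - 1)) {             # target bulge
    wj <- if ((j + 1) >= 2 && (j + 1) <= 13) 2 else 1
    off <- m - all_i + 1
    off[off > m - j] <- off[off > m - j] + 1
    for (s in seq_len(max(0, L - m)))
      best <- min(best, score_at(s, off, all_i, 2 * wj))
  }
  for (j in seq_len(m)) {                 # miRNA bulge
    wj <- if (j >= 2 && j <= 13) 2 else 1
    keep <- all_i[all_i != j]
    off <- m - keep + 1
    off[off > m - j + 1] <- off[off > m - j + 1] - 1
    for (s in seq_len(max(0, L - m + 2)))
      best <- min(best, score_at(s, off, keep, 2 * wj))
  }
  best
}

random_dna <- function(n) paste(sample(.oracle_bases, n, replace = TRUE),
                                collapse = "")

revcomp <- function(x) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(x)))

# --- Isoelectric point: brute-force charge curve on a fine grid -------

oracle_pi_grid <- function(seq) {
  pk_nt <- c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82,
             V = 7.44, E = 7.70)
  pk_ct <- c(D = 4.55, E = 4.75)
  pos_pk <- c(K = 10.0, R = 12.0, H = 5.98)
  neg_pk <- c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
  res <- strsplit(seq, "")[[1]]
  nt <- if (res[1] %in% names(pk_nt)) pk_nt[[res[1]]] else 7.5
  ct <- if (res[length(res)] %in% names(pk_ct)) pk_ct[[res[length(res)]]]
        else 3.55
  charge <- function(ph) {
    q <- 1 / (1 + 10^(ph - nt)) - 1 / (1 + 10^(ct - ph))
    for (r in res) {
      if (r %in% names(pos_pk)) q <- q + 1 / (1 + 10^(ph - pos_pk[[r]]))
      if (r %in% names(neg_pk)) q <- q - 1 / (1 + 10^(neg_pk[[r]] - ph))
    }
    q
  }
  grid <- seq(0, 14, by = 0.001)
  grid[which.min(abs(vapply(grid, charge, 0)))]
}
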