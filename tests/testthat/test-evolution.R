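# Alignment, paralog grouping, Ka/Ks, trees

test_that("global alignment is optimal and self-alignment is gapless", {
  a <- globalAlign(c(x = "HEAGAWGHEE"), c(y = "HEAGAWGHEE"))
  expect_equal(a$identities, 10)
  expect_equal(a$aligned_cols, 10)
  expect_false(grepl("-", a$aligned_a))

  b <- globalAlign(c(x = "HEAGAWGHEE"), c(y = "PAWHEAE"))
  expect_equal(b$score, oracle_nw_score("HEAGAWGHEE", "PAWHEAE"))
  # independent DP oracle on random peptides
  set.seed(21)
  aas <- names(ppomir:::.AA_MASS)
  for (k in 1:5) {
    p <- paste(sample(aas, sample(6:12, 1), TRUE), collapse = "")
    q <- paste(sample(aas, sample(6:12, 1), TRUE), collapse = "")
    expect_equal(globalAlign(p, q)$score, oracle_nw_score(p, q))
  }
  expect_error(globalAlign("", "AAA"), "empty")
})

test_that("CIP and CALP follow their definitions", {
  id <- globalAlign(c(a = "MKVLHE"), c(b = "MKVLHE"))
  expect_equal(unname(cipCalp(id)), c(100, 100))
  # synthetic alignment object: 50 identities over 100 columns
  fake <- list(identities = 50, aligned_cols = 100, len_a = 100,
               len_b = 100)
  expect_equal(cipCalp(fake)[["cip"]], 50)
  fake2 <- list(identities = 70, aligned_cols = 70, len_a = 100,
                len_b = 120)
  expect_equal(cipCalp(fake2)[["calp"]], 70)
  none <- list(identities = 0, aligned_cols = 0, len_a = 5, len_b = 5)
  expect_true(is.na(cipCalp(none)[["cip"]]))
  expect_equal(cipCalp(none)[["calp"]], 0)
})

test_that("paralog grouping recovers planted partitions, order-invariant", {
  fam <- simulateGeneFamily(genesPerGroup = c(3, 3), ancestorCodons = 150,
                            seed = 1)
  prots <- vapply(seq_along(fam$cds), function(i)
    as.character(translateOrf(fam$cds[[i]])), "")
  names(prots) <- names(fam$cds)
  pg <- paralogGroups(prots)
  expect_equal(pg$groups, lapply(fam$groups, sort))
  expect_length(pg$singletons, 0)
  # invariant to input order
  pg2 <- paralogGroups(prots[c(4, 1, 6, 2, 5, 3)])
  expect_equal(pg2$groups, pg$groups)
  # groups form a partition
  expect_false(anyDuplicated(unlist(pg$groups)) > 0)
  # unrelated random proteins give no groups
  set.seed(2)
  aas <- names(ppomir:::.AA_MASS)
  rnd <- setNames(replicate(4, paste(sample(aas, 60, TRUE),
                                     collapse = "")), paste0("r", 1:4))
  expect_length(paralogGroups(rnd)$groups, 0)
})

test_that("codon alignment threads CDS through the protein alignment", {
  c1 <- "ATGAAAGGGTTTTAA" # M K G F *
  c2 <- "ATGAAATTTTAA"    # M K F *
  aln <- globalAlign(c(a = "MKGF"), c(b = "MKF"))
  cols <- codonAlign(c1, c2, aln)
  expect_equal(length(cols$codons_a), 3) # G column dropped
  expect_false("GGG" %in% cols$codons_a)
  # identical CDS: all columns, zero gaps
  aln2 <- globalAlign(c(a = "MKGF"), c(b = "MKGF"))
  cols2 <- codonAlign(c1, c1, aln2)
  expect_equal(cols2$codons_a, cols2$codons_b)
  expect_length(cols2$codons_a, 4)
  # mismatched CDS/protein is an error
  expect_error(codonAlign(c2, c2, aln), "translate")
})

test_that("NG86 counts match the hand-derived example and the oracle", {
  est <- neiGojobori(list(codons_a = c("TTT", "GGG", "AAA"),
                          codons_b = c("TTC", "GGG", "AAA")))
  expect_equal(est$S, 5 / 3)
  expect_equal(est$N, 22 / 3)
  expect_equal(est$Sd, 1)
  expect_equal(est$Nd, 0)
  expect_equal(est$ks, -0.75 * log(1 - 4 * 0.6 / 3), tolerance = 1e-9)
  expect_equal(est$ka, 0)

  ident <- neiGojobori(list(codons_a = c("ATG", "CCC"),
                            codons_b = c("ATG", "CCC")))
  expect_equal(ident$ka, 0)
  expect_equal(ident$ks, 0)

  expect_error(neiGojobori(list(codons_a = "TAA", codons_b = "TAA")),
               "stop codon")

  # exhaustive-pathway oracle on random pairs of <= 5 codons
  set.seed(31)
  for (k in 1:40) {
    pr <- random_codon_pair(sample(1:5, 1))
    got <- neiGojobori(list(codons_a = pr$a, codons_b = pr$b))
    want <- oracle_ng86(pr$a, pr$b)
    expect_equal(got$S, want$S, tolerance = 1e-9)
    expect_equal(got$Sd, want$Sd, tolerance = 1e-9)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-9)
    expect_equal(got$ka, want$ka, tolerance = 1e-9)
    expect_equal(got$ks, want$ks, tolerance = 1e-9)
    # symmetry in the two sequences
    swap <- neiGojobori(list(codons_a = pr$b, codons_b = pr$a))
    expect_equal(swap$ka, got$ka, tolerance = 1e-12)
    expect_equal(swap$ks, got$ks, tolerance = 1e-12)
  }
})

test_that("domain slices restrict Ka/Ks to the region in both genes", {
  fam <- simulateGeneFamily(genesPerGroup = c(2), ancestorCodons = 120,
                            seed = 4)
  a <- names(fam$cds)[1]; b <- names(fam$cds)[2]
  pa <- as.character(translateOrf(fam$cds[[a]]))
  pb <- as.character(translateOrf(fam$cds[[b]]))
  aln <- globalAlign(setNames(pa, a), setNames(pb, b))
  whole <- data.frame(region = "ALL", start = 1, end = 121)
  kk <- domainKaKs(fam$cds[[a]], fam$cds[[b]], aln, whole, whole)
  # region covering the whole ORF equals the whole-ORF estimate
  expect_equal(kk$ka[kk$region == "ALL"], kk$ka[kk$region == "ORF"])
  expect_equal(kk$ks[kk$region == "ALL"], kk$ks[kk$region == "ORF"])

  # substitutions planted only outside a region: region Ka = Ks = 0
  base <- paste(c("ATG", rep("GGT", 60), "TAA"), collapse = "")
  mut <- base
  substr(mut, 160, 160) <- "A" # one change far outside codons 2-21
  alnp <- globalAlign(
    setNames(as.character(translateOrf(base)), "w"),
    setNames(as.character(translateOrf(mut)), "m"))
  reg <- data.frame(region = "quiet", start = 2, end = 21)
  kq <- domainKaKs(base, mut, alnp, reg, reg)
  expect_equal(kq$ka[kq$region == "quiet"], 0)
  expect_equal(kq$ks[kq$region == "quiet"], 0)
  expect_error(domainKaKs(base, mut, alnp,
                          data.frame(region = "x", start = 200,
                                     end = 210),
                          data.frame(region = "x", start = 200,
                                     end = 210)),
               "empty")
})

test_that("Ka/Ks grows with planted substitutions and is seed-stable", {
  ratios <- c()
  for (rate in c(0.05, 0.15, 0.3)) {
    fam <- simulateGeneFamily(genesPerGroup = 2, nGroups = 1,
                              ancestorCodons = 200, branchRate = rate,
                              dnds = 0.5, seed = 9)
    a <- names(fam$cds)[1]; b <- names(fam$cds)[2]
    aln <- globalAlign(
      setNames(as.character(translateOrf(fam$cds[[a]])), a),
      setNames(as.character(translateOrf(fam$cds[[b]])), b))
    kk <- domainKaKs(fam$cds[[a]], fam$cds[[b]], aln)
    ratios <- c(ratios, kk$Sd + kk$Nd)
  }
  expect_true(all(diff(ratios) > 0)) # more events, more substitutions
})

test_that("Welch t-test handles degenerate groups", {
  expect_equal(groupTTest(c(1, 1, 1), c(1, 1, 1))$p, 1)
  expect_equal(groupTTest(c(1, 1), c(2, 2))$p, 0)
  jit <- groupTTest(c(0, 1e-6, -1e-6), c(1, 1 + 1e-6, 1 - 1e-6))
  expect_lt(jit$p, 0.001)
  # direction agrees with an exhaustive permutation test on small samples
  a <- c(0.1, 0.2, 0.3); b <- c(0.8, 0.9, 1.0)
  obs <- abs(mean(a) - mean(b))
  pool <- c(a, b)
  perms <- utils::combn(6, 3)
  stat <- apply(perms, 2, function(ix)
    abs(mean(pool[ix]) - mean(pool[-ix])))
  p_perm <- mean(stat >= obs - 1e-12)
  expect_lt(groupTTest(a, b)$p, 0.05)
  expect_equal(p_perm, 1 / 10) # both orderings of the extreme split
})

test_that("NJ recovers additive trees and clamps degenerate input", {
  # 3 taxa: closed-form branch lengths
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  tr <- njTree(d)
  expect_equal(sort(tr$tip.label), c("a", "b", "c"))
  el <- setNames(tr$edge.length,
                 tr$tip.label[tr$edge[, 2]])
  expect_equal(el[["a"]], (3 + 4 - 5) / 2)
  expect_equal(el[["b"]], (3 + 5 - 4) / 2)
  expect_equal(el[["c"]], (4 + 5 - 3) / 2)

  # additive 5-taxon distances from a random tree: exact recovery
  set.seed(7)
  true <- ape::rtree(5)
  dd <- ape::cophenetic.phylo(true)
  rec <- njTree(dd[true$tip.label, true$tip.label])
  expect_equal(ape::dist.topo(ape::unroot(true), rec),
               structure(0, class = NULL), ignore_attr = TRUE)

  z <- suppressWarnings(njTree(matrix(0, 4, 4,
    dimnames = list(letters[1:4], letters[1:4]))))
  expect_true(all(z$edge.length == 0)) # zero-length star, no negatives
  # non-additive noise can force negative branches; they are clamped
  set.seed(2)
  nz <- matrix(stats::runif(16, 0.5, 1), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  nz <- (nz + t(nz)) / 2; diag(nz) <- 0
  zt <- tryCatch(njTree(nz), warning = function(w) {
    expect_match(conditionMessage(w), "clamped")
    suppressWarnings(njTree(nz))
  })
  expect_true(all(zt$edge.length >= 0))
  expect_error(njTree(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("bootstrap support is 100 for congruent signal, reproducible", {
  aln <- c(t1 = "AAAAAAAA", t2 = "AAAAAAAA",
           t3 = "CCCCCCCC", t4 = "CCCCCCCC")
  tr <- bootstrapSupport(aln, nReplicates = 50, seed = 3)
  expect_true(all(tr$node.label == 100))
  # n = 1 gives supports in {0, 100}
  set.seed(12)
  aas <- names(ppomir:::.AA_MASS)
  rnd <- setNames(replicate(5, paste(sample(aas, 30, TRUE),
                                     collapse = "")), paste0("s", 1:5))
  t1 <- bootstrapSupport(rnd, nReplicates = 1, seed = 5)
  expect_true(all(t1$node.label %in% c(0, 100)))
  # bit-reproducible under a fixed seed
  t2 <- bootstrapSupport(rnd, nReplicates = 20, seed = 8)
  t3 <- bootstrapSupport(rnd, nReplicates = 20, seed = 8)
  expect_identical(ape::write.tree(t2), ape::write.tree(t3))
  expect_identical(t2$node.label, t3$node.label)
  expect_error(bootstrapSupport(c(a = "A", b = "A"), 10, 1),
               "at least 2 columns")
})
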