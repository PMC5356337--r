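---
title: "Methods: gene-family characterization and target-directed miRNA discovery"
author: "ppomir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-family characterization and target-directed miRNA discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models and procedures implemented in
`ppomir`, the assumptions behind them, the tunable parameters and their
defaults, what the synthetic-data generators do and do not emulate, and
the numerical choices made where the design was genuinely open.

## The analysis in one paragraph

A duplicated plant gene family (the motivating case is the 19-member
polyphenol oxidase family of *Salvia miltiorrhiza*) is catalogued
(ORF/protein features, motifs, intron phases), partitioned into
paralogous groups by pairwise homology filters, and characterized for
selective pressure by codon-level Ka/Ks on whole ORFs and on domain
slices. Expression stages quantify transcript abundance (RPKM,
Fisher-exact contrasts, 2^-ddCt). The discovery stage then inverts the
usual miRNA annotation workflow: starting from the *targets*, small RNAs
complementary to the family are collected, traced back to genomic loci
that must fold into annotatable hairpins, and confirmed by degradome
evidence of guided cleavage.

## Sequence features

Molecular weight is the sum of average (not monoisotopic) residue
masses plus one water, matching the convention of the standard web
tool used for such tables; values are reported to 2 decimals. The
isoelectric point solves `Q(pH) = 0` for the Bjellqvist charge model by
bisection on pH 0-14 to a tolerance of 1e-4. The pKa constants —
including the residue-specific N- and C-terminal values — live in one
editable table (`R/seqio.R`), because the choice of pKa set moves pI by
several tenths of a pH unit and must be swappable to match other tools.
Both are cross-checked in the test suite against `seqinr`, an
independent implementation of the same published constants.

Logo matrices report per-column information content
`log2(20) - H(column)` from the observed residue frequencies, without
the small-sample correction used by some rendering services: the
matrices feed displays, not inference, and the uncorrected quantity is
the one with a direct entropy interpretation. Gap characters are
excluded from column counts.

Coordinates are 1-based and inclusive everywhere — files, reports,
return values. U is accepted in nucleotide input and normalized to T at
parse time; all internal comparisons are on the DNA alphabet.

An ORF whose length is not divisible by 3 is flagged by the catalog
(`frame_ok = FALSE`) rather than rejected: published per-gene feature
tables occasionally contain rows whose printed ORF length and residue
count are mutually inconsistent, and a validator that errors out would
make such tables unloadable. The bundled example table
(`inst/extdata/smppo_table1.tsv`) contains two such rows, which the
acceptance checks deliberately leave flagged.

## Paralog grouping

The classical criteria (E-value <= 1e-40, CIP >= 60%, CALP >= 70%) were
formulated for BLASTP hit lists, where "cumulative" sums over HSPs. This
package computes both percentages on a single deterministic global
alignment (Needleman-Wunsch, BLOSUM62, gap open 10, gap extend 0.5):
CIP = identities / residue-residue columns, CALP = residue-residue
columns / length of the shorter sequence. Rationale: deterministic and
oracle-checkable, and at 60%/70% thresholds within one genome the
E-value filter is vacuous — any pair passing CIP/CALP is far below
1e-40 — so it is recorded in the run configuration but not applied.
Grouping is single-linkage (connected components), the weakest
assumption compatible with "homologous gene groups"; groups require two
or more members and singletons are reported separately.

## Ka/Ks (Nei-Gojobori 1986)

Synonymous site counts per codon are the fraction of the three possible
changes at each position that preserve the amino acid; changes to stop
codons count as nonsynonymous, and site counts are averaged between the
two sequences. Codons differing at 2-3 positions are averaged over all
orderings of the changes, excluding pathways that pass through a stop
codon (if every pathway does, all are used rather than dropping the
codon). Proportions are Jukes-Cantor corrected; `p >= 3/4` is reported
as `NA` (saturation) and such pairs are excluded from group means.
Domain slices keep only codon columns whose codon index falls inside
the region in *both* sequences, so a region annotation never silently
shifts across an indel. The implementation is verified against an
exhaustive pathway-enumeration oracle on all random pairs of <= 5
codons (200 cases in the acceptance suite).

Two choices the source material leaves open: group means average
within-group pairwise estimates (not all pairs family-wide), and the
between-domain t-test treats each within-group pair as the unit of
observation. Both are the finer-grained readings; with 17 genes in 6
groups they are also the only ones that give usable sample sizes.

Default domain coordinates can be derived from motif anchors
(`defaultDomainCoords`): CuA from the first histidine of HxxxC to 30
residues past the third conserved histidine, CuB as HxxxH +/- 30, DWL
and KFDV as windows around their name-giving motifs. These are
heuristics for when no curated annotation exists and are meant to be
overridden by a coordinates table.

## Trees

Distances for NJ and bootstrap are protein p-distances (optionally
Poisson-corrected); the source names only "neighbor joining", and
p-distance is the least parameterized choice. Negative branch lengths —
an artifact NJ produces on non-additive matrices — are clamped to zero
with a warning. Bootstrap resamples alignment columns, rebuilds the NJ
tree per replicate, and reports bipartition frequencies as percentages;
the default of 1000 replicates matches the conventional setting.
On additive matrices topology recovery is exact (tested).

## Expression

RPKM uses the cloned ORF length as the gene length. The Fisher exact
test is applied per gene to the 2x2 table of (gene count, rest of
library) in the two libraries, two-sided by the sum of hypergeometric
outcomes no more probable than the observed one; no multiple-testing
correction is applied by default (an optional Benjamini-Hochberg flag
exists), matching the single-contrast convention of the motivating
analysis. The 2^-ddCt computation pins the control condition to fold 1
by construction. ANOVA is the classical pooled-variance F.
Read mapping is out of scope; a minimal exact-match unique-hit counter
exists solely so synthetic reads can be turned into counts end to end.

## Target scanning

The expectation score is the Allen-style penalty sum: mismatch 1.0, G:U
wobble 0.5, indel 2.0, each doubled at miRNA positions 2-13 from the 5'
end. At most one single-nucleotide bulge is allowed, on either strand;
a target-side bulge between miRNA positions j and j+1 is charged at
position j+1, a miRNA-side bulge at its own position. Sites with
expectation <= 3.0 qualify (the printed cutoff). The expected cleavage
position is the transcript coordinate paired to miRNA nucleotide 10.
The published server this emulates does not document its internals,
so the fully specified scheme above is exposed in configuration and
checked against an exhaustive register-enumeration oracle. One caveat
follows: agreement with the original server's site lists cannot be
guaranteed site-for-site, only the documented semantics.

A target-accessibility filter (maximum energy to unpair the site,
threshold 25.0) is recorded in the configuration for fidelity to the
printed settings, but computed by neither backend: no energy model for
it is specified, and inventing one would change results silently.

Note that the position weighting breaks strict reverse-complement
symmetry of the score (the weighted window follows the miRNA 5' end);
the pairing pattern itself is strand-symmetric, which is what the tests
assert.

## Hairpin extraction, folding and annotation

Around each genomic match the package folds the symmetric window
(flank 300 nt each side) plus three sub-windows (300/60, 60/300,
60/60), keeping the lowest-energy structure per window — the
fixed-window strategy a manual mfold-based analysis approximates. The
folding backend is pluggable: ViennaRNA's `RNAfold` (minimum free
energy, kcal/mol) when the binary is on the PATH, otherwise a built-in
Nussinov base-pair maximization (Rcpp; pair weights G:C 3, A:U 2,
G:U 1, minimum loop 3, energy = negative total weight). The
thermodynamic backend is preferred when available because pure pair
maximization has a known failure mode on windows with long random
flanks: it can trade stem pairs for scattered long-range contacts,
fragmenting a genuine precursor stem in roughly one window in ten.

Annotation evaluates the community structural criteria: mature length
20-22 nt; mature within one arm (no pairing across the terminal loop,
detected as mature self-pairing); at most 4 unpaired mature bases in
the miRNA/miRNA* duplex; at most 2 nt of asymmetric bulge; star read
off the partner arm with a 2-nt 3' overhang. Because a global fold can
assign individual mature bases to spurious distant partners, the duplex
is first identified as the antidiagonal-consistent set of pairs
(partner + position constant within the bulge allowance + 1); pairs
outside it count as unpaired. Read support (> 4 reads) is checked by
the library filter, not the structure.

## Degradome validation

Peak categories follow the established degradome-analysis convention:
0 = the count at the expected cleavage position (+/- 1 nt) is the
unique transcript-wide maximum and exceeds 1; 1 = tied maximum; 2 =
above the median of non-zero positions; 3 = at or below it; 4 = a
single read. "Supported" means category <= 2 (configurable). The
category is invariant to uniform scaling of counts except for the
single-read rule, which is deliberately absolute.

## Synthetic data: what it emulates, and what it does not

The generators define the study conditions and are pure functions of
their seed (byte-identical reruns):

* `simulateGeneFamily` — group sizes default to (3, 3, 2, 3, 4, 2),
  the size spectrum of the motivating 17-genes-in-6-groups family;
  ancestor length 570 codons (the family's typical ORF); 0.25 accepted
  substitutions per codon per branch (placing pairwise Ks near 0.5,
  measurable but unsaturated); dN/dS target 0.3, implemented as the
  acceptance probability of nonsynonymous proposals, with stop-creating
  proposals rejected. A 60-codon "CuA-like" interval evolves at half
  the nonsynonymous acceptance. Group ancestors are independent random
  ORFs, so between-group identity sits at the random-protein baseline
  (about 5%) — far below the grouping threshold.
* `simulateMirLocus` — precursor = mature + 9-nt loop + near-reverse-
  complement star with 1 planted mismatch chosen so it can neither
  Watson-Crick nor wobble pair; 300-nt random flanks; perfect-
  complement target sites planted codon-aligned in the 3' quarter of
  designated CDSs (a "KFDV-region" analogue), shifted if a stop codon
  would arise. The default mature is the RNA form of the documented
  miRNA-specific RT-PCR forward primer of the motivating novel miRNA.
* `simulateSrnaLibrary` — mature at 20% of depth, star binomially at
  ~10% of mature, background counts capped at 4 so the reads-greater-
  than-four filter is exercised exactly at its boundary.
* `simulateDegradome` — Poisson(1) background at every position plus a
  Poisson spike (mean = signal:background) at the true cleavage site.
* `simulateCounts` — Poisson counts around share x library size x fold;
  Poisson rather than negative binomial because the downstream Fisher
  test models no overdispersion, which keeps the type-I calibration
  interpretable (an NB option would be the first extension for real
  data). Lengths 900-1900 bp, the typical plant ORF range.
* `simulateQpcr` — Ct = baseline - log2(fold) + N(0, sigma), reference
  gene constant across conditions (internal-control analogue).

What passing on these data shows: the statistics recover planted
signal at realistic effect sizes, every boundary rule (strict RPKM
threshold, reads > 4, expectation <= 3, category cutoffs) operates as
specified, and the pipeline is deterministic. What it does not show:
robustness to overdispersed counts, sequencing error, adapter
artifacts, paralog alignment ambiguity from indels (simulated families
are indel-free, which is also why the tree stage can use the proteins
unaligned), or real secondary-structure thermodynamics beyond the
backends used.

## Problem sizes and reproducibility

The test-suite and acceptance-script replicate counts (20 seeded runs
per recovery experiment, 300-codon families, 200-gene null count
tables, 100 degradome transcripts) were chosen as the smallest sizes at
which the binomial noise on the reported rates is comfortably below the
acceptance bands. All randomness flows from a single seed argument;
stage outputs carry a manifest with the configuration hash so reruns
are verifiable.

## Known limitations

* CIP/CALP on a global alignment is a deliberate reinterpretation of a
  BLASTP-based protocol; on families with long non-homologous
  extensions the global CALP denominator is conservative.
* The NG86 estimator saturates (`NA`) near p = 3/4; deeply diverged
  pairs need a codon-model method, which is out of scope.
* The built-in folder maximizes weighted pairs and has no loop/stack
  thermodynamics; it is a fallback, not a substitute for an energy
  model.
* The expectation scorer reproduces documented semantics, not any
  specific server's undocumented tie-breaks.
* The absence check is evidence of absence only at the stated mismatch
  allowances (library <= 1, genome exact by default).
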