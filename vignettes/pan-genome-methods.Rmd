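---
title: "Pan-genome analysis with panGenomics: models, parameters and design choices"
author: "panGenomics authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pan-genome analysis with panGenomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

panGenomics is a desk-scale comparative pan-genomics toolkit for small
panels of bacterial strains. It covers the canonical chain of analyses:
all-vs-all protein similarity, ortholog family clustering, the
core/dispensable/strain-specific partition, permutation-median pan- and
core-genome curves with Heaps-law and exponential regression and an
open/closed verdict, fragment-based average nucleotide identity (ANI) with
species grouping, single-copy-core neighbor-joining phylogenies with
family bootstrap, and a two-pronged horizontal gene transfer (HGT) screen.
Because public genome panels cannot be redistributed or downloaded in every
environment, the package ships a synthetic multi-strain generator whose
gene-family history, tree, pairwise identities and planted HGT cluster are
known exactly; every downstream stage is validated against that ground
truth.

# The similarity layer

Proteins are compared by Smith-Waterman local alignment under BLOSUM62 with
affine gaps (open 11, extend 1, a gap of length $L$ costing $11 + L$).
These are the conventional defaults of the protein-BLAST ecosystem. The
unknown residue X is tolerated and scores 0 against everything. Raw scores
$S$ become bit scores through the standard Karlin–Altschul transformation
$S' = (\lambda S - \ln K)/\ln 2$ with the gapped BLOSUM62 constants
$\lambda = 0.267$, $K = 0.041$, and expectations follow the bit-score
identity $E = m\,n\,2^{-S'}$ on the per-pair search space $m \times n$. No
edge corrections are applied; the formula is chosen for being exactly
testable against an independent re-derivation.

Three filters decide whether a pair of genes is "similar": identity at
least 50% of alignment columns (gap columns count in the denominator,
never the numerator — the stricter of the two common conventions, chosen
for determinism), coverage of at least 50% of the *longer* sequence, and
$E \le 10^{-5}$. Coverage uses the longer of the two aligned spans so that
the pass/fail status is invariant under swapping query and subject; with a
single-sided span the statistic would be asymmetric whenever the alignment
is gapped.

Because panels are desk-scale (hundreds of genes), the search is
exhaustive full dynamic programming — there is no heuristic seeding to
audit. The test suite holds the optimized aligner to exact score equality
with a naive full-matrix dynamic program on hundreds of random instances.

# Ortholog families and the presence–absence matrix

Families are the connected components of the undirected pass-graph;
genes with no passing edge are singleton families. Components are the
deterministic, auditable choice; transitive closure also answers the
question of genes that pass thresholds to two otherwise-disconnected
groups (they merge). An MCL-style alternative (expansion/inflation
iterations at inflation 1.5, clusters read off the limit matrix's support)
is available behind `method = "mcl"` in `clusterFamilies()` for
sensitivity analysis. Paralogs stay in one family and simply disqualify it
from single-copy-core status.

The family-by-strain copy-count matrix is the pivot of everything
downstream. Its contract — every gene in exactly one family, column sums
equal per-strain gene counts, no all-zero rows — is enforced by an S4
validity method and fuzz-tested.

# Pan-genome curves and openness

For each sampled ordering of the strains, the pan curve records cumulative
distinct families at each prefix depth, the core curve the families
present in all strains so far, and the new-gene curve the families first
seen at each step. By default `min(1000, n!)` orderings are used; panels
small enough are enumerated exhaustively, which keeps tests exact. Medians
across orderings (not the full sample cloud) are what the regressions are
fitted to, matching the median-connecting presentation conventional for
these curves.

The pan curve is fitted with the Heaps-law form $y = A x^B + C$ and the
core curve with $y = A e^{Bx} + C$, both by Levenberg–Marquardt nonlinear
least squares with multi-start initialization: for growing curves $A$
starts at the observed range with $B \in \{0.1, 0.5, 0.9\}$ and $C$ at the
minimum; additional negative-$A$/negative-$B$ starts cover saturating
curves, for which the best power-law description is $y = C - |A| x^{-|B|}$.
The lowest-residual converged fit wins. Two numerical edge cases are
handled explicitly: an exactly constant curve short-circuits to the
degenerate fit $A = 0$, $C = \bar y$, and a fitted exponent within $10^{-6}$
of 0 or 1 is snapped onto the boundary so that data generated from an
exactly linear or constant law classify deterministically.

The openness verdict follows the strict-interval criterion: the pan-genome
is open exactly when $0 < B < 1$; $B \le 0$ or $B \ge 1$ — including both
boundaries — is closed. The expected new-gene yield of an additional
genome is the first difference of the fitted pan model,
$A\,((n{+}1)^B - n^B)$; a separate published new-gene law is not assumed
because its functional form is not recoverable, so the package exposes the
pan-fit difference only and the new-gene curve itself.

# ANI and species grouping

ANI uses the classical fragment recipe: the query genome is cut into
consecutive 1,020-bp fragments, each is locally aligned (+1/−1, gap open
4, extend 1) against the whole subject genome, and a fragment is retained
if its identity is at least 30% and at least 70% of it aligns. ANI is the
mean identity of retained fragments, in percent; a pair with no surviving
fragment is *undefined* (NA), never 0. These fragment parameters are the
published defaults of the fragment-based ANI tools this module stands in
for. Because fragmenting is directional the two directions differ
slightly; the reported pair value is the mean of the two, which restores
symmetry. Species groups are connected components of the graph with edges
where ANI exceeds 95%, the conventional same-species boundary; raising the
threshold can only refine the grouping, never merge it.

# Core phylogeny

Families that are single-copy in every strain are concatenated: within
each family every strain pair is globally aligned, aligned columns are
pooled across families, and the distance is the p-distance (proportion of
differing columns among columns where neither sequence is gapped). Global
alignment is appropriate because orthologs in these panels are full-length.

The neighbor-joining implementation is the canonical Q-criterion
agglomeration with deterministic tie-breaking (the lexicographically
lowest pair of node labels, a merged node carrying its smallest member's
label) and negative branch lengths clamped to zero. On additive matrices
it recovers the generating tree exactly; the suite verifies this against
an exhaustive three-topology least-squares oracle for four taxa and
against an independent NJ implementation for larger random additive
matrices. Trees are written unrooted; rooting at an outgroup leaf is a
one-call operation downstream (`ape::root`, exposed as `--root` in the
CLI).

Bootstrap support resamples *families* (not alignment columns) with
replacement, which is the standard unit for concatenated gene sets and
reuses cached per-family difference counts, making 500 replicates cheap.
Supports are the percentage of replicates containing each original
bipartition.

# The HGT screen

The screen formalizes a contrast that is usually shown graphically: the
GC content of a candidate cluster against its genome. The statistic is a
sliding-window z-score — the cluster's GC compared with the mean and
standard deviation of all same-length windows (default step: one tenth of
the cluster length) — flagged at $|z| \ge 2$. Both the window-based
background and the plain whole-genome GC are reported, since either
reference is defensible. GC itself excludes ambiguous bases from numerator
and denominator and is reverse-complement invariant.

The placement test builds an NJ gene tree over the query plus a reference
panel labeled by genus and asks for the genus of the query's nearest leaf
by patristic distance — the simplest testable reading of a gene "falling
into" a foreign lineage. Exact ties resolve to the lexicographically first
genus and are marked as ties. A gene whose nearest lineage is not its own
genus is flagged.

# The synthetic generator

`simulateStrains()` produces a panel whose every property is known:

* **Tree**: a random coalescent topology over the strains (the shape of a
  neutral panel); every branch applies the same per-site substitution
  probability `perBranchDivergence`, and the recorded branch lengths equal
  that probability. Equal per-branch divergence keeps true identities
  analytic: orthologs separated by $k$ branches have expected identity
  $(1-p)^k$, which is exactly what the recorded true-ANI matrix contains
  (substitutions always change the base, and back-mutation terms are
  $O(p^2)$).
* **Families**: `nCore` single-copy core families born at the root;
  dispensable families gained on branches (Poisson `dispensableRate` per
  branch) and inherited by all descendant tips; strain-specific families
  drawn per tip (Poisson `uniquePerStrain`). The model is gain-only — no
  loss after gain, no recombination — so occupancy bookkeeping is exact.
* **Sequences**: genes are whole codons, start with ATG, and never contain
  an internal stop (a substitution that would create one is repaired at
  the third codon position); translation uses the bacterial genetic code
  (table 11), standard for *Bacillus*. Genes receive no indels, so true
  identities stay analytic; short indels are allowed only in the
  intergenic spacers that separate genes. Nucleotide sampling weights are
  set so expected GC equals `backgroundGC` (41.5% by default, a
  *Bacillus*-like composition).
* **HGT cluster**: optionally, a contiguous block of donor-lineage genes
  with GC shifted by `gc_shift` is inserted at a random position of one
  strain's genome; coordinates, gene ids and the ancestral donor sequences
  are recorded so both halves of the screen can be scored against truth.

Defaults (8 strains, 20 core families, 2 dispensable gains per branch, 2
unique families per tip, 1% divergence per branch, genes 120–300 bp,
spacers 80–150 bp) give panels of roughly 25–35 families per strain and
6–12 kb genomes — large enough for every statistic to be well-defined,
small enough that the whole suite runs in minutes. What the generator does
*not* emulate: realistic codon usage, rearrangement, gene loss,
recombination, and genome-scale gene counts; conclusions from passing
tests are therefore about the correctness of the algorithms under the
stated model, not about performance on real assemblies.

Two deliberate departures from the defaults are used where a statistic
needs different geometry:

* ANI calibration uses direct genome pairs (`evolveSequence()`, expected
  identity exactly $1-r$) of about 20 kb, giving ~19 fragments so that the
  fragment-mean's sampling error is well inside ±0.3 percentage points,
  and `simulateCladePanel()` for block-structured panels (within-clade
  divergence 1% per lineage, between-clade 10%), which places within-clade
  ANI near 98 and between-clade ANI near 79.
* The GC screen is exercised with a six-gene planted cluster (mirroring
  the six-gene nonribosomal peptide synthetase cluster that motivates the
  screen) inside a ~20 kb genome. A cluster that occupies a large fraction
  of a tiny genome contaminates its own background window distribution and
  weakens the z-score — real clusters are a fraction of a percent of their
  genome, and the screen's operating conditions should reflect that.

# Problem sizes and reproducibility

The test suite and the acceptance script regenerate every input
programmatically. Stochastic claims are evaluated over explicit seed sets
(100 seeds for openness recovery and GC flag power, 50 for placement, 200
alignment-oracle trials), with panel sizes chosen as above. Every random
step is seeded: identical configuration and seed reproduce simulated
panels byte-for-byte, and the acceptance script derives all its
sub-seeds from one `--seed` argument.

# Known limitations

* Alignment is exhaustive dynamic programming; the package is not meant
  for genome-scale proteomes or megabase ANI panels.
* The e-value lacks finite-size corrections; it is calibrated for
  filtering, not for reporting database-style significance.
* Connected-component clustering is single-linkage: one spurious hit can
  merge two families (the MCL option exists precisely to probe this).
* The placement test reads a single nearest leaf; it does not attempt
  reconciliation-based HGT inference, and composition-based screening is
  limited to GC (no codon-usage or k-mer tests).
* The generator's gain-only accessory model cannot produce convergent
  family loss; a closed pan-genome is represented by a finite family
  universe rather than by saturating gene pools.
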