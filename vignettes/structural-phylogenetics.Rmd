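---
title: "Assembling structural phylogenetics datasets with strucphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling structural phylogenetics datasets with strucphylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strucphylo)
```

## The problem

Protein structure diverges more slowly than sequence, so structural
similarity can recover evolutionary relationships that sequence searches
miss. Building a dataset for structure-based phylogenetics from an archive
of deposited structures involves a standard funnel: split entries into
chains, discard short peptides, collapse near-identical sequences into
clusters represented by a centroid structure, verify that each centroid is
structurally analysable, compare all centroids pairwise with a structural
similarity score, and convert those scores into a distance matrix from which
a neighbour-joining tree can be built. `strucphylo` implements that funnel
as a set of composable functions plus a thin command-line wrapper, with a
deterministic synthetic-structure generator so that every stage can be
exercised and tested without any external download.

## The similarity model

Pairwise structural similarity is the SSM/GESAMT-family superposition
quality score

$$Q = \frac{N_{\mathrm{align}}^2}{\bigl(1 + (\mathrm{RMSD}/R_0)^2\bigr)\,N_1 N_2},$$

where $N_{\mathrm{align}}$ is the number of aligned residue pairs,
$\mathrm{RMSD}$ their C$\alpha$ root-mean-square deviation after optimal
rigid superposition, $N_1$, $N_2$ the resolved residue counts of the two
chains, and $R_0$ a scaling factor (default 3.0&nbsp;&#8491;,
configurable). $Q = 1$ for identical structures; $Q$ near 0 for unrelated
ones. $Q$ rewards both fit quality and coverage of *both* structures, so a
small fragment fitting part of a large protein scores low.

Two readings of $N_1$, $N_2$ are conceivable: residues with coordinates, or
the full deposited sequence length. We use resolved residue counts. With
deposited lengths the published reference comparison (72 aligned residues
between a 115- and a 135-residue histone pair giving $Q = 0.409$) is
algebraically unreachable — $72^2/(115 \cdot 135) = 0.334$ is the ceiling
before the RMSD term — whereas with resolved counts it is attainable.

When an aligner finds no detectable similarity it reports not 0 but a
*sentinel* $-1$; downstream, the distance transform
$d = 1 - \max(Q, 0)$ maps the sentinel to the maximal distance 1.

### The alignment procedure

The aligner is C$\alpha$-only and proceeds in three stages:

1. **Secondary-structure assignment.** Residue $i$ is a helix candidate when
   $d(i,i+3) \in [4.5, 6.0]$ and $d(i,i+4) \in [5.7, 7.0]$&nbsp;&#8491;, and
   a strand candidate when $d(i,i+2) \in [6.2, 7.2]$ and
   $d(i,i+3) \in [9.3, 10.8]$&nbsp;&#8491; — distance-mask criteria in the
   P-SEA tradition. Runs of at least 5 (helix) or 3 (strand) consecutive
   candidates become elements, extended to the last residue their final
   candidate probes; overlaps from this extension are trimmed
   deterministically. Each element's axis is the principal axis of its
   C$\alpha$ trace, oriented N- to C-terminally.

2. **Seeding.** For every ordered pair of distinct elements in one chain and
   every same-kind ordered pair in the other whose inter-element angle
   (within 30°) and midpoint separation (within 5&nbsp;&#8491;) are
   compatible, a candidate rigid transform is fitted by the Kabsch algorithm
   on the four axis endpoints. Because detected element boundaries can
   shrink differently in the two chains (which shifts midpoints and can
   starve the pair filter), the same-kind element pairs also contribute
   *per-element correspondence seeds*: one Kabsch fit per relative offset of
   the shorter element slid along the longer. When either chain has exactly
   one element, exhaustive gapless sliding-window seeding (15-residue
   window, one fit per relative offset) is used instead. A chain with *no*
   detected element cannot seed a superposition at all: the comparison is
   NO_SIMILARITY. This mirrors the behaviour of SSE-vector-based aligners,
   which fail on structures whose secondary structure they cannot analyse,
   and is what makes the centroid self-check meaningful.

3. **Iterative refinement.** From each seed (best 100 by preliminary fit),
   the aligner alternates: build the order-preserving residue correspondence
   by dynamic programming maximizing $\sum 1/(1+(d_{ij}/R_0)^2)$ with zero
   gap penalty; drop pairs farther than $d_{\mathrm{cut}} = 5$&nbsp;&#8491;;
   re-fit by Kabsch. It stops when the correspondence repeats or after 50
   iterations, keeps the iterate with the highest $Q$, and reports the best
   seed's result. Alignments with fewer than 10 residue pairs are
   NO_SIMILARITY. Results are exactly symmetric because every pair is
   evaluated in canonical lexicographic order and the transform inverted on
   reversed queries; ties between seeds resolve to the first in
   deterministic seed order.

The dynamic-programming kernel is the only compiled code in the package; it
is quadratic in chain length and dominates the cost of a comparison.

## Sequence comparison

Two different sequence comparisons serve two different purposes:

* **Clustering identity** is a semi-global (glocal) alignment: the shorter
  sequence aligns globally against the longer, terminal gaps on the longer
  are free (match +1, mismatch −1, gap open −2, extend −1), and identity is
  identical columns over alignment columns, terminal-gap columns excluded.
  The shorter sequence must align over its whole length: a truncated
  construct or tagged variant still matches its parent at high identity,
  but unrelated sequences cannot reach a high identity through a short
  chance overlap (with ends free on both sequences, two random proteins
  regularly "align" at identity 1.0 over a handful of columns — we verified
  this failure mode directly, and it is why both-ends-free alignment is not
  used). The scoring scheme is this package's choice; clustering semantics
  follow the greedy length-sorted first-hit scheme of usearch-style tools.

* **Centroid annotation statistics** use exact Smith–Waterman local
  alignment with BLOSUM62, gap open 11 / extend 1, reporting identity and
  positives (similarity) percentages over the local alignment length, plus
  Karlin–Altschul statistics from the published gapped BLOSUM62/11-1
  constants $\lambda = 0.267$, $K = 0.041$:
  $\mathrm{bits} = (\lambda S - \ln K)/\ln 2$ and
  $E = mn\,2^{-\mathrm{bits}}$. The heuristic word-seeded search that a
  database-scale tool needs exists only for speed; at centroid-pair scale
  exactness is preferable and reproducible across environments. The search
  space $mn$ defaults to the product of the two sequence lengths and is
  configurable to emulate database scale; consequently E-values are not
  comparable to any specific database build's. An alignment with no
  positive-scoring cell carries the sentinel −1 in every score field.

## Clustering, confidence and vetting

Chains pass a deposited-size filter first: a chain's *size* is the amino
acid count of its author-deposited sequence record, not its resolved
residue count, and chains under 50 amino acids are dropped — short peptides
carry too little regular secondary structure to compare meaningfully.

Greedy clustering processes chains in decreasing size order (ties broken
lexicographically by identifier) and joins each chain to the first existing
centroid at $\ge 90\%$ semi-global identity, else founds a new cluster.
First-hit (not best-hit) assignment matches the cited tool family's default
semantics; a best-hit mode is available. Cluster identifiers are zero-padded
5-digit founding ordinals.

Because clustering is identity-based, members of a cluster are expected to
be (nearly) the same size; a strong size deviation signals a clustering
artefact. A member is flagged **low confidence** when its size deviates from
the cluster *median* by more than one *population* standard deviation of the
member sizes (the SD is taken about the mean, the deviation about the
median; the centroid is included in both). Population rather than sample SD
is a deliberate choice — the cluster is the whole population of interest —
and the even-size median is the mean of the two central values.

Centroid vetting compares every centroid with itself: a centroid passes when
at least one secondary-structure element is found and self-alignment yields
$Q \ge 0.99$. Failing centroids are replaced by the largest passing member
(ties lexicographic); clusters with no passing member — including failing
singletons — are removed entirely, and every replacement or removal is
logged.

## Queries and export

`neighbours()` resolves a query chain (any cluster member, `PDB_Chain` form)
to its cluster centroid and ranks all other centroids by $Q$, reporting only
$Q \ge 0.1$: below that floor the score distribution is dominated by the
structural analogue of the sequence "twilight zone", where related and
unrelated pairs mix. The list truncates at the top 50 hits; the query
centroid is excluded from the count and added as an extra taxon in exports
(an `--include-self` style flag flips this). Distances $1 - \max(Q, 0)$ over
the query centroid plus its hits form the exported matrix.

Neighbour joining (Saitou–Nei, via `ape::nj`) builds the tree; negative
branch lengths are clamped to zero (a common convention; nothing downstream
depends on them) and the two-taxon case is a single edge split equally. On
any additive matrix NJ recovers the generating tree's path metric exactly,
which the tests verify against random 4–12-taxon trees. The serialized
newick tree is unrooted; the apparent root is an arbitrary trifurcation
with no evolutionary meaning. The distance matrix is written as a NEXUS
`DISTANCES` block in `TRIANGLE=BOTH DIAGONAL` form (full matrix — the most
widely parsed dialect), labels sanitized to `[A-Za-z0-9_]` identically in
both formats.

Databases persist as a directory of TSV tables plus per-chain C$\alpha$ PDB
files — no binary store — so rebuilds are byte-identical and diffable, and
round-trip through `write_db()`/`load_db()` is tested.

## The synthetic generator and what the tests show

`synth_chain()` concatenates ideal helices (1.5&nbsp;&#8491; rise,
100°/residue, 2.3&nbsp;&#8491; radius), ideal strands (3.3&nbsp;&#8491;
rise, ±25° zig-zag) and 3.8&nbsp;&#8491;-step random-walk coils, with every
stochastic choice drawn from an explicitly seeded generator, so identical
specifications are bit-reproducible. `perturb_chain()` adds isotropic
Gaussian coordinate noise; `mutate_seq()` substitutes positions uniformly.
The shipped study set (`synth_study_set()`) emulates an archive slice: a
10-member 100-residue three-helix family (2% sequence mutation,
0.3&nbsp;&#8491; coordinate noise — typical of redundant depositions of one
protein), an 8-member sequence-divergent structural relative of that fold
(60% mutation: the planted deep-homology neighbour), an 8-member unrelated
strand family, a featureless coil singleton (planted to be removed at
vetting), and a 30-residue chain (planted to fall to the size filter).

These fixtures are C$\alpha$-only with ideal or Gaussian-perturbed geometry
and i.i.d. sequence noise. They contain no side chains, no real loop
conformations, no domain architecture, no compositional bias and no
correlated evolutionary signal, so passing tests demonstrate the pipeline's
mechanics — determinism, the funnel's filtering behaviour, score symmetry,
exactness of the numerics — not retrieval performance on real structures.
The published histone-fold comparisons serve as the real-data check; the
structures themselves are not redistributed and must be placed under
`inst/extdata/worked_example/` (see the README there), and because the
structural engine is a re-implementation of the Qscore aligner family
rather than GESAMT itself, alignment-dependent numbers are checked with a
documented engine tolerance, reported alongside.

## Numerical and degenerate-input choices

* Kabsch superposition uses SVD with reflection correction (determinant
  sign flip), so the rotation is always proper; fewer than 3 point pairs or
  mismatched lengths are errors. It is verified against a brute-force
  Euler-angle minimization oracle.
* Qscore arguments are validated ($0 \le N_{\mathrm{align}} \le
  \min(N_1, N_2)$, RMSD $\ge 0$, $R_0 > 0$); the self-comparison of any
  chain that passes vetting yields $Q \ge 0.99$ by construction of the
  check.
* Residue parsing keeps the first model and first alternate location only,
  maps nonstandard residues with known parents (e.g. selenomethionine to M)
  and everything else to `X`, which *does* count toward chain size; waters
  and nucleic-acid chains are skipped with a warning; unparseable files are
  treated as discardable. Deposited sequences come from a supplied FASTA
  when available, else SEQRES, else the resolved sequence.
* Problem sizes in the shipped tests are deliberately desk-scale — chains
  of 45–100 residues, a 28-chain study set, 4–12-taxon trees — which keeps
  a full build of the study database under a few seconds while exercising
  every stage; the design is the same at archive scale, where all-pairs
  comparison parallelizes trivially (its result is order-independent).

## Known limitations

* The aligner is rigid-body and C$\alpha$-only: no flexible or hinge
  alignment, no quaternary-structure comparison, and no claim of
  reproducing GESAMT's output bit for bit.
* E-values are search-space-dependent and not comparable to any specific
  BLAST build.
* Annotation (SCOP/CATH/PDB descriptors) is a pass-through join from
  user-supplied tables keyed by `entry_chain`; missing entries appear as
  `"N/A"`. No live retrieval is attempted.
* Secondary-structure assignment from C$\alpha$ distance masks is cruder
  than backbone-hydrogen-bond methods; heavily distorted elements can drop
  below detection, which is precisely the failure mode centroid vetting is
  designed to catch.
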