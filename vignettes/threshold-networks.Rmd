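---
title: "Threshold similarity networks for phylogenetic classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold similarity networks for phylogenetic classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigmanet)
```

## The method

`sigmanet` classifies a set of homologous protein sequences by the structure
of a one-parameter family of *threshold similarity networks*. The pipeline
has four stages.

**1. Similarity matrix.** Every pair of sequences is locally aligned
(Smith–Waterman, BLOSUM62, affine gaps 11/1 — the classic protein
local-alignment setup) and converted into a percent similarity
$0 \le s_{ij} \le 100$. The matrix $S$ is symmetric by construction: the
general contract symmetrises directed scores by their mean,
$s_{ij} = (\text{score}_{ij} + \text{score}_{ji})/2$, which matters when
scores come from an external (heuristic, hence asymmetric) aligner. A pair is
*valid* only if its E-value is at most 1.0; invalid pairs are stored as
$s_{ij} = 0$, so they can never produce an edge at a positive threshold.

**2. Network family.** For a threshold $\sigma$ (percent), the network
$M(\sigma)$ has an edge between $i \ne j$ iff the pair is valid and
$s_{ij} \ge \sigma$ (the boundary keeps the edge). Sweeping $\sigma$ over a
grid — default integer percent, 0–100, step $\Delta\sigma = 1$, matching the
integer resolution at which critical thresholds are conventionally reported —
yields a nested family: raising $\sigma$ only removes edges, so components
only break apart.

**3. δ-distance scan.** Adjacent networks are compared with a graph metric:
each network is summarised by its geodesic *neighborhood matrix* (all-pairs
unweighted shortest paths, disconnected pairs capped at $n$), and

$$\delta(A, B) = \frac{1}{n(n-1)} \sum_{i \ne j} \left| D^A_{ij} - D^B_{ij} \right|.$$

With the finite cap this is a true metric on networks over a fixed node set,
and it is zero exactly when the adjacency matrices coincide (an edge is
present iff the geodesic distance is 1). Removing an edge inside a
well-connected cluster changes a few entries by 1; a community breaking off
sends all of its cross-pairs to the cap, so separations produce large,
sharp peaks in the curve of δ against σ. The peaks are the *critical
thresholds* $\sigma_{cst}$.

**4. Communities and dendrogram.** Communities are connected components with
at least two members; singleton components are isolated nodes. The community
structure at each $\sigma_{cst}$ — and recursively, the re-analysis of each
community as an independent network — is the classification. Sweeping the
full grid and recording every component split produces a merge tree whose
internal-node heights are split σ values; it is exported as Newick.

## Conventions that needed fixing

Several details of the procedure are underdetermined and had to be fixed;
each is exposed as a parameter where that makes sense.

**Where a δ value sits on the σ axis.** δ is computed between the networks
at $\sigma - \Delta\sigma$ and $\sigma$, and the curve point is labelled with
the *upper* endpoint $\sigma$. A peak at $\sigma_{cst}$ then means: the
network *at* $\sigma_{cst}$ is the first one in which the changed (typically
split) structure is in force, so reading the community partition at
$\sigma_{cst}$ shows the new communities. The curve has one point fewer than
the grid.

**Peak detection.** Peaks are detected as local maxima of the δ-curve with a
relative-prominence cutoff: a peak must reach at least `min_prominence_frac`
(default 0.1) of the curve maximum, and the global maximum is always
reported. Two refinements handle discreteness of the grid. Runs of equal
values (plateaus) are treated as a single candidate. And each detected peak
is carried to the end of its *significant non-increasing tail*: when two
separations land in adjacent grid steps, the second one lies on the
descending slope of the merged peak and is not itself a local maximum, yet
the structure is only settled after it. Reporting the settled end of the
peak makes $\sigma_{cst}$ the first threshold at which the post-change
partition is stable. For well-separated events (the common case) the tail is
empty and the local maximum itself is reported.

**Boundary conventions.** $s_{ij} = \sigma$ keeps the edge; σ may exceed 100
(the grid runs to 100 by default, and a network at σ = 101 is empty, which
is occasionally useful). Disconnected geodesic pairs are capped at $n$; the
cap is a parameter of `neighborhood_matrix()` and `delta_distance()`.

**Dendrogram heights.** An internal node sits at the first grid σ at which
its member set is no longer connected; simultaneous splits produce a single
multifurcation. Leaves sit at height 100, so branch lengths (child height
minus parent height) make the tree ultrametric in σ. Heights are *similarity
thresholds, not evolutionary distances*: taxa leaving a community at the
same σ need not form a clade in the evolutionary sense. A component that is
still connected at the top of the grid (e.g. identical sequences) is kept
together as an unsplit polytomy at height 100. Cutting the dendrogram at any
grid σ reproduces the connected components of $M(\sigma)$ exactly; the whole
construction coincides with single-linkage agglomerative clustering on the
dissimilarity $100 - s$ at grid resolution, which the test suite asserts
against an independent `hclust` oracle.

## Similarity measures and the E-value model

Three ways of turning a local alignment into a percent similarity are
provided via `scoring_params()`:

- **`"bitscore"` (default):** the alignment bit score divided by the smaller
  of the two self-alignment bit scores, times 100. This is a whole-sequence
  relatedness measure: unrelated random pairs of length ~250 stay in a tight
  band of a few percent, while near-identical pairs approach 100.
- **`"positives"`:** percent of aligned columns with a positive substitution
  score — the "similarity" column of familiar local-alignment reports.
- **`"identity"`:** percent identical aligned columns.

The default deserves a comment, because the choice is consequential for
deeply diverged inputs. A local aligner always finds the *best-scoring
segment*, and for unrelated sequences that segment is short and biased
upward: across random length-250 pairs, best-segment percent positives
centres near 50% with a heavy right tail (the test suite pins these bands).
Consequently, under `"positives"` the between-group similarities of strongly
diverged groups form broad, overlapping bands, the groups separate at widely
staggered thresholds, and no single σ exhibits the full group structure. The
normalised bit score does not have this defect — chance segments carry few
bits relative to a self alignment — so group separations concentrate into
narrow σ bands and the dominant δ-peak recovers the planted partition. Use
`"positives"` when compatibility with BLAST-style similarity columns
matters and divergence is moderate.

E-values come from the Karlin–Altschul formula with the standard gapped
BLOSUM62/11/1 parameters ($\lambda = 0.267$, $K = 0.041$, $H = 0.14$) and
the usual edge-effect length correction. This approximates what a full
search engine reports for a single pairwise comparison; it is used only for
the coarse validity rule $E \le 1.0$, to which the pipeline is insensitive
over a wide range. Note that the *best* local alignment of two unrelated
length-250 sequences typically has $E$ between 0.1 and 1 — the cutoff mostly
removes short-sequence or fragment comparisons, not every chance hit.

## The synthetic generators

Two generators produce inputs with known structure, at the two levels the
pipeline consumes.

`planted_block_similarity()` builds a block similarity matrix directly:
`s_within` on diagonal blocks, `s_between` off (a scalar or a per-group-pair
matrix), one Gaussian noise draw per unordered pair (sd `noise_sd`),
truncation to $[0, 100]$ applied after symmetrisation so the matrix
invariants always hold. It emulates the block structure a family with clean
sub-families induces, and nothing else.

`simulate_protein_family()` is a star-of-stars sequence simulator: a uniform
random root, one ancestor per group at Poisson($d_{between} \cdot L$)
substitutions from the root, leaves at Poisson($d_{within} \cdot L$) from
their ancestor, each substitution replacing a uniform site with one of the
19 other residues. Defaults (3 groups × 4 sequences, $L = 250$,
$d_{between} = 1.5$, $d_{within} = 0.02$) describe strongly separated
sub-families of a protein of apolipoprotein-E-like length: at 1.5 expected
substitutions per site per branch, between-group pairs are essentially
saturated while within-group pairs remain nearly identical.

What the generators deliberately omit: indels, rate heterogeneity across
sites, empirical substitution processes (JTT/WAG), compositional bias, and
non-ultrametric group structure. Passing tests therefore demonstrate that
the *network machinery* recovers planted structure from similarity data of
the assumed shape; they do not validate alignment quality or model adequacy
on real, indel-rich families. Determinism is part of the contract: a design
plus its seed reproduces byte-identical output, and generation never
disturbs the caller's RNG state.

## Pipeline and recursion

`run_pipeline()` ties the stages together: read FASTA (computing $S$) or a
similarity TSV (bypassing alignment), scan the δ-curve, take the community
partition at the *dominant* critical threshold, then re-run the scan inside
every community with at least `min_recurse_size` members (default 3 — a
two-member community separates trivially at its own pairwise similarity).
Recursion stops when no peak passes prominence or a community is too small.
This mirrors how staggered separations are actually analysed: the first
split rarely exhibits all structure, and each community is treated as an
independent network, re-scanned at its own scale. Every level writes its
δ-curve as TSV, the JSON report records thresholds, communities and isolates
per level, and all artifacts round-trip through the package's own readers.

## Numerical and degenerate-input notes

- Similarity matrices must be symmetric within $10^{-9}$; the constructor
  then symmetrises exactly, clamps to $[0, 100]$, forces the diagonal to
  100, and zeroes invalid entries.
- Exact Smith–Waterman scores are direction-symmetric, so each unordered
  pair is aligned once. Co-optimal alignments can differ depending on which
  sequence is the pattern, which would make percent positives depend on
  input order; pairs are therefore aligned in a canonical (content) order,
  making $S$ invariant under permutation of the input.
- A flat δ-curve yields zero critical thresholds, one sequence yields a
  bare-leaf dendrogram, and an input whose pairs are all invalid is refused
  with a named error.
- Test-suite problem sizes: oracle equivalence on 200 random graphs
  ($n \le 10$) against a hand-written Floyd–Warshall, metric properties on
  100 random triples, nestedness on 50 random matrices ($n \le 30$),
  single-linkage equivalence on 50 matrices ($n \le 20$), and 20-seed
  recovery runs for both generators. These sizes exercise every code path
  while keeping the default suite in the minutes range.

## Limitations

- Communities are connected components, as the dendrogram-by-separation
  construction requires; denser notions of modularity (edge-betweenness,
  modularity optimisation) are out of scope.
- δ-curve *peak positions* are the meaningful output; absolute δ magnitudes
  depend on the cap and normalisation conventions and should not be compared
  across node-set sizes.
- The σ-height dendrogram is a similarity-threshold summary, not a
  phylogeny: no rooting, no support values, no branch lengths in
  substitution units.
- The E-value model is an approximation adequate for a coarse validity
  cutoff, not a replacement for a database search engine's statistics.
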