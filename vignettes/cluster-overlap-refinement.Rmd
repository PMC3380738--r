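---
title: "Refining overlapping clusters in protein interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining overlapping clusters in protein interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(overclust)
```

## Motivation and model

Protein complexes appear in a protein–protein interaction (PPI) network as
dense subgraphs, and density-based clustering methods return *overlapping*
clusters because proteins participate in several complexes. The practical
complication this package addresses is the converse effect: one complex
frequently surfaces as several strongly overlapping partial clusters —
each holding a shared core, a private slice of the remaining members, and
some contaminating neighbours. Treating each fragment as a separate
complex prediction depresses accuracy; merging every overlapping pair
indiscriminately depresses it even faster. The package therefore (i)
measures the overlap structure of a cluster collection, (ii) merges only
the strongly overlapping groups, keeping each vertex only if enough of the
merged clusters agree on it, and (iii) scores predictions against a
gold-standard catalog.

All containers are deliberately minimal: a network is a simple undirected
`igraph` with protein identifiers as vertex names, a cluster set is an
ordered list of member-id vectors in which duplicates are legal (the
overlap statistics are defined on a *non-unique* collection), and a
complex catalog is a cluster set with unique names.

## Overlap statistics

For cluster $c_i$ in a collection of $n$ clusters, the overlaps are the
multiset $\{V(c_i)\cap V(c_j) : j\neq i,\ V(c_i)\cap V(c_j)\neq\emptyset\}$.
From it we compute the mean overlap size $S(c_i)$, the overlap rate
$R(c_i)=S(c_i)/|V(c_i)|$, the overlap coverage
$\mathrm{Cov}(c_i)=|\bigcup o|/|V(c_i)|$, and the overlapping consistency
$\mathrm{Cons}(c_i)=R(c_i)/\mathrm{Cov}(c_i)$. Since every overlap is a
subset of $\bigcup o \subseteq V(c_i)$, the rate never exceeds the
coverage and consistency lies in $[0,1]$; both bounds are exercised as
property tests over random cluster collections.

Two conventions are worth stating because the definitions leave them open:

- **Clusters with no overlaps** get $S=R=\mathrm{Cov}=\mathrm{Cons}=0$
  (the mean would otherwise divide by zero). The zero consistency also
  guarantees such clusters pass through refinement untouched whenever a
  positive consistency gate is used, and they can never be merge seeds.
- **Duplicate partners count with multiplicity.** Two identical partners
  contribute two overlaps to the mean, matching the non-unique-collection
  semantics of the container.

```{r}
s3 <- read_cluster_file(system.file("extdata", "set3p_clusters.txt",
                                    package = "overclust"))
overlap_profiles(s3)
```

## The refinement pass

`refine_overlaps(clusters, min_cov, min_cons, min_css)` walks the input
once. Clusters below either gate pass through unchanged. A cluster above
both gates is merged with *all* clusters it overlaps; a per-vertex
consensus counter records how many of the `count` merged clusters contain
each vertex, and vertices with counter $< \text{count}\times$ `min_css`
are removed. The threshold comparison keeps vertices exactly at the
boundary (removal is strictly-below, with a small numeric tolerance so
e.g. $3 \times 0.7$ behaves identically in floating point and exact
arithmetic). Results identical to an already-emitted cluster are dropped
as redundant.

Choices made where the procedure is genuinely open, and why:

- **The consensus threshold scales with the merge count**, not with the
  total number of clusters in the collection: only that reading produces
  the documented limiting behaviour, `min_css = 1` $\Rightarrow$
  intersection of the merged group and `min_css = 0` $\Rightarrow$ union.
- **Partners are found against the original seed cluster and frozen**
  before merging; the merge does not grow transitively as partners are
  absorbed.
- **Every input cluster takes a turn as seed**, including clusters already
  absorbed into an earlier merge; the redundancy check deduplicates
  coinciding outcomes. Redundancy means member-set identity — subset
  containment is *not* redundancy, because containment-dropping would
  silently discard passthrough clusters.
- **Gates are evaluated on the original input profiles**, not recomputed
  as the output grows.
- **Empty merges are discarded.** With `min_css = 1` and three or more
  pairwise-overlapping clusters lacking a common member, the filtered
  merge can be empty; an empty cluster is representable neither in the
  container nor in the output format, so it is dropped and recorded in the
  audit trail as `dropped-empty`.

The audit trail (one record per input cluster: action, partner count,
sizes before/after) plus the per-seed results make the pass fully
inspectable, and the per-seed results are what the monotonicity property
(higher `min_css` $\Rightarrow$ smaller per-seed output) is tested on.

```{r}
prp19 <- read_cluster_file(system.file("extdata", "prp19_clusters.txt",
                                       package = "overclust"))
summary(refine_overlaps(prp19, min_css = 0.7))
```

## Entropy-based clustering

The bundled clusterers minimise the *graph entropy* of a candidate
cluster $C$: every vertex $v$ with degree $d(v)\ge 1$ has inner-neighbour
fraction $p(v)=|N(v)\cap C|/d(v)$ and contributes the binary entropy
$h(p(v))$, summed over the graph (only $C$ and its boundary can contribute,
so the sum is computed there). A cleanly separated module scores 0.
Entropy comparisons use an absolute tolerance of $10^{-12}$, and a greedy
move is accepted only on *strict* decrease — ties are rejected — which is
what guarantees termination of every pass.

The single-seed procedure starts from a random unclustered vertex plus its
neighbourhood, then alternates greedy removal (never the seed) and greedy
boundary-addition passes until neither changes the cluster. Alternating to
a joint fixed point (rather than one removal phase followed by one
addition phase) is deliberate: an addition can re-enable a profitable
removal, and the fixed point is what makes every emitted cluster a strict
single-vertex local minimum — a property the tests assert against an
adjacency-matrix entropy oracle on every run. Candidates are always tried
in ascending lexicographic order, so runs are reproducible given the seed
stream; a seed stripped to a singleton is emitted as a singleton, and the
outer loop continues until every vertex lies in some emitted cluster.

The triangle-seeded variant grows whole neighbourhood shells: from each
3-clique (taken in lexicographic order) it repeatedly adds *all* current
boundary vertices, then greedily removes among the vertices just added,
until a round's additions are entirely removed. Adding the shell as a
whole lets the cluster cross entropy barriers that block one-at-a-time
addition. A triangle already contained in an emitted cluster is not
re-seeded — that containment rule is our reading of "until no seed
candidate remains", and it is what bounds the outer loop. On all small
random graphs the implementation is replayed move-for-move by an
independent transliteration of the procedure in the test suite.

## The synthetic benchmark

`generate_planted()` emulates the shape of a curated interactome with its
complex catalog: complexes drawn uniformly in a size range over disjoint
proteins, a fraction of complexes borrowing 1–2 members from another
complex (genuine membership overlap), within-complex edges at `p_in`,
background edges at `p_out`, plus background proteins in no complex.
`degrade_catalog()` then manufactures a "preliminary clustering" by
splitting each complex, with probability `split_prob`, into 2–3 fragments
that share a core of half the complex (rounded up) and partition the rest,
and by adding up to `noise_per_cluster` extraneous proteins per cluster
(drawn uniformly from 0 to the cap, from a caller-supplied universe, so no
identifier is ever invented). The default parameters — 20 complexes, sizes
4–10, `p_in` 0.9, `p_out` 0.02, sharing 0.3, 20 background proteins,
`split_prob` 0.6, noise cap 1 — are the package's standing study
conditions for the end-to-end recovery experiment; all randomness flows
from one integer seed per call, so every instance is reproducible.

What the generator does *not* emulate: scale-free degree structure,
false-negative-riddled sparse interactomes, and clusterer-specific error
modes. Passing the end-to-end test therefore shows the refinement repairs
the fragmentation/contamination pattern it targets — not that any
particular accuracy level will be reached on a real interactome.

## Threshold selection

`select_refinement_params()` implements the two-stage sweep used in the
accuracy experiments: stage 1 sweeps `min_css` over $\{0,0.1,\dots,1\}$
with `min_cov = min_cons` tied over $\{0.1,\dots,0.6\}$ and fixes
`min_css` at the best mean best-match f; stage 2 sweeps `min_cov` and
`min_cons` *independently* over $[0,1]$ at that `min_css`. The second
stage matters: a single spurious one-protein overlap drags a fragment's
consistency far below its coverage, so tying the two gates together
blocks exactly the sibling-fragment merges the refinement exists for,
while an untied high-coverage/low-consistency (or vice versa) combination
recovers them. Ties in either stage resolve to the first grid point, so
selection is deterministic.

In the end-to-end experiment (10 generator seeds at the default
conditions; problem size chosen to keep the full run in a few minutes on
one CPU) the refined clustering at the selected thresholds beats the
degraded input's mean best-match f-score — the box-plot-style improvement
the refinement is designed to deliver. The test suite asserts the
improvement in at least 9 of the 10 seeds rather than all 10 because the
margin in any single seed is stochastic.

## Evaluation conventions

Best-match f-measure ties are broken by catalog order (first wins); a
cluster intersecting no complex scores 0 with no matched complex. The
five-number summary of `average_f()` uses linear-interpolation quantiles
(`stats::quantile` type 7) by default; the convention is a parameter
because box-plot quartile conventions differ between tools. All clusters
are scored, singletons included — `min_size` filters them out when the
comparison calls for it. Combined catalogs are plain concatenations with
caller-supplied unique names.

## Known limitations

- Edge lists cannot represent isolated proteins, so a network's vertex set
  is exactly the proteins with at least one interaction.
- The refinement is a single pass by design; it is not iterated to a fixed
  point.
- Interaction confidence scores, directed/weighted edges and PSI-MI
  formats are out of scope; only the first two columns of an edge list are
  read.
- The entropy clusterers are reference implementations tuned for clarity
  and reproducibility, not for interactome-scale throughput.
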