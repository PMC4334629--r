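---
title: "Detecting and characterizing nested protein complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterizing nested protein complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(complexnest)
```

## The problem

A protein complex enters an interaction database as a list of copurified
subunits. Consolidated resources therefore contain many *nested* records:
complexes whose subunit set is contained in another complex's subunit
set. Two very different processes produce this pattern. Biologically,
stable modules assemble into larger machines (chaperone modules inside
translocases, shared acetyltransferase cores, replication subcomplexes
assembling into the pre-replication complex). Technically, the same
complex can be reported by two sources with one or a few subunits
dropped, producing a spurious "subcomplex". The package makes nesting a
first-class object so that both signals can be quantified.

Edge-level representations cannot express this distinction. A copurified
group is stored either as a *spoke* model (a star centered on a hub,
canonically the experimental bait) or a *matrix* model (the complete
graph on the members). When a subcomplex is recorded with a different
hub than its maximal complex, its edges are *not* a subset of the
maximal complex's edges even though its nodes are. All definitions here
are therefore set-based.

## Definitions and the detection algorithm

For member sets $C_1, C_2$:

$$\text{meet-min}(C_1, C_2) = \frac{|C_1 \cap C_2|}{\min(|C_1|, |C_2|)},
\qquad
\text{Jaccard}(C_1, C_2) = \frac{|C_1 \cap C_2|}{|C_1 \cup C_2|}.$$

Meet-min is 1 exactly when one set contains the other; Jaccard is 1
exactly when the sets are equal; Jaccard never exceeds meet-min.

Detection proceeds in four steps.

1. **All-pairs similarity** (`all_pairs()`). An inverted index
   protein → complexes touches only co-membered pairs; the result is
   provably identical to the quadratic scan (the test suite checks this
   against a brute-force oracle). Only pairs with nonempty intersection
   are stored; subset status is decided on integer counts
   (intersection = smaller size), never on floating-point values.
2. **Nested pairs** (`find_nested_pairs()`): the stored pairs with
   meet-min = 1, oriented larger → smaller. Equal sets make the
   orientation undefined, so the catalog must first pass
   `dedupe_catalog()`, which merges records with identical member sets
   and concatenates their provenance pairs.
3. **Nested groups** (`nested_groups()`): the oriented pairs form a
   subset DAG; every node with no incoming edge is a maximal complex,
   and one group per maximal complex collects everything reachable by
   depth-first search. Because the subset relation is transitive on
   sets, reachability and direct containment coincide; the
   implementation still re-verifies each member against its root and
   drops duplicate groups, as a guard. A subcomplex contained in two
   maximal complexes appears in both groups — this is what makes the
   histone-acetyltransferase example produce two overlapping groups
   rather than one. An optional `merge_overlapping` mode collapses
   root-sharing groups instead; it is off by default because the
   per-root reading is the one under which overlapping nesting stays
   visible.
4. **Shared partition** (`shared_partition()`): within a group, the
   shared proteins are the union of the subcomplex member sets (each
   such protein is in at least the subcomplex and the root); the
   nonshared proteins are the rest of the root. Pooled counting across
   groups (`classify_proteins()`) is per group instance, because a
   protein can be shared in one group and nonshared in another; for
   per-protein analyses each protein receives a single class with
   "shared anywhere" taking precedence.

### The reliable-set filter

High Jaccard between a maximal complex and a lone subcomplex — sets
differing by one or two subunits — is the signature of a
duplicated-with-dropped-subunit record, and such near-duplicate pairs
turn out to come overwhelmingly from more than one source.
`filter_reliable()` therefore *excludes* size-2 groups whose pair
Jaccard exceeds the threshold (default 0.85) and only flags offending
pairs inside larger groups. The literature that motivates this filter
states the cutoff ambiguously (the same passage argues both that high
Jaccard means artifact and that the reliable set is "Jaccard > 0.85");
we resolve the contradiction in favor of the argument rather than the
parenthesis, and expose `direction = "exclude_below"` for the opposite
convention.

## Representations

`build_view()` expands a catalog under either model into one of four
views: **multiedge** (one node per protein, one parallel edge per
(pair, complex) — the working view for all metrics), **multihub**
(hubs split per complex), **multinode** (every node split per complex;
one component per complex), and **node_attribute** (simple graph,
memberships stored on nodes). The three expanded views carry identical
labeled-edge multisets and their node counts are ordered multiedge ≤
multihub ≤ multinode; collapsing the multinode view reproduces the
node-attribute graph. These invariants are property-tested. The default
hub policy is the recorded bait, falling back to the lexicographically
smallest member — a deterministic stand-in for the common practice of
picking a random member, which remains available as `seeded_random`.

## Node metrics on a multigraph

There is no single canonical contract for centralities on a multiedge
graph, so each metric uses its most standard multigraph reading,
documented and configurable:

- **degree** counts parallel edges — membership in several complexes is
  supposed to inflate it;
- **PageRank** (damping 0.85) runs on the simple projection weighted by
  edge multiplicity: a random walker follows parallel edges
  proportionally;
- **betweenness** runs on the *unweighted* simple projection. igraph
  interprets edge weights as distances, so feeding multiplicities as
  weights would push shortest paths *away* from multi-complex pairs —
  the opposite of the intended emphasis. An `inverse_multiplicity` mode
  makes multi-complex pairs shorter instead. Values are raw,
  unnormalized path counts;
- **local clustering** uses the unweighted projection, with degree-<2
  nodes assigned 0.

Shared and nonshared classes are compared per metric with a two-sided
rank-sum test: exact enumeration when both samples have ≤ 8
observations and no ties, the normal approximation with tie and
continuity corrections otherwise. When every observation ties, the
approximation degenerates (zero variance); the implementation reports
p = 1 — no rank separation is no evidence.

## Enrichment, GO counts, homogeneity

All enrichment is upper-tail hypergeometric (overrepresentation only),
with the catalog's protein universe as the default population — the
network, not the genome; `population` overrides. The subcomplex-richness
comparison between a curated and a consolidated group list uses the
pooled-background convention: population = both lists pooled, sample =
the curated list, successes = pooled groups with ≥ k subcomplexes
(k = 3 by default).

GO-like term counting per class reports the number of *distinct* terms
(the alternative, summing per-protein term counts, is available via
`mode`). Because the nonshared class is typically much larger than the
shared class, the nonshared value is a Monte Carlo baseline: the mean
and sd of distinct-term counts over seeded uniform subsamples of
nonshared proteins of the shared class's size (default 1000 draws).
Term-set homogeneity of a complex is the mean pairwise Jaccard of its
annotated members' term sets; unannotated members are excluded rather
than treated as empty sets (an empty-vs-empty comparison is 0/0), and
the result is absent when fewer than two members are annotated.

## Motifs

`motif_census()` counts connected induced subgraphs on 3, 4 and 5 nodes
of a group's simple projection, classified up to isomorphism (2, 6 and
21 classes; the catalog is built once by exhausting all edge subsets and
canonical labeling, and individual subgraphs are classified by the pair
(sorted degree sequence, triangle count), verified collision-free for
these orders at build time). Enumeration uses the ESU algorithm; the
test suite checks it against exhaustive subset enumeration. Catalogs of
this kind put most complexes at 3–5 subunits, so group subgraphs are
small; a node budget (default 200) skips pathological cases, since the
number of 5-subsets grows as $\binom{n}{5}$.

Significance is assessed against a null of degree-preserving edge
swaps — the original analysis delegated its null model to a package
whose internals it did not describe, so this standard rewiring null is
this package's own, documented choice, not a reimplementation. Each of
`n_random` (default 100) replicas attempts 100·|E| swaps; the degree
sequence is asserted unchanged on every replica. Per class, z-scores
and the empirical upper-tail p-value $(1 + \#\{null \ge obs\})/(n_{random}+1)$
are reported, significant at p ≤ 0.05. Note the granularity: with 100
replicas the smallest attainable p is ~0.0099, and at α = 0.05 up to
four null hits are tolerated; substantially fewer replicas make the
call needlessly fragile.

The 5-node classes are additionally annotated with their number of
missing edges relative to the 5-clique (`imperfect_5clique_summary()`):
a size-5 maximal complex whose subcomplex is spoke-expanded under a
different hub produces precisely these imperfect 5-cliques.

## Modularity and communities as predictors

Three standard algorithms (edge betweenness cut at maximal modularity,
walktrap with step length 4 — its authors' default, and seeded label
propagation) are delegated to igraph; the package's contribution is the
evaluation harness. Newman–Girvan modularity
$Q = \sum_c (e_c/m - (d_c/2m)^2)$ is computed directly from the formula
and cross-checked in the tests against an independent edge-by-edge
accumulation and against igraph.

A community predicts a subcomplex when their node sets match at Jaccard
≥ 0.5 (greedy one-to-one matching by descending Jaccard; exact matching
via `match_threshold = 1`). The 0.5 cutoff is a repository decision —
no published value exists. It has a visible consequence: when a group
is one complex plus a subcomplex spanning most of it, the trivial
single-community partition matches that subcomplex at Jaccard ≥ 0.5 and
counts as a true positive. Per-group precision on synthetic catalogs is
therefore substantially higher than the "mainly low precision" reported
for consolidated data, even though modularity concentrates at zero
exactly as reported (on generator defaults, ~98% of groups have
Q ≤ 0.1 and the pooled FDR is ~0.4). The acceptance test states the
direction accordingly: pooled FDR ≥ 1/3 and pooled precision ≤ 2/3 over
at least 100 groups, rather than a per-group majority.

## The synthetic generator

`generate_catalog(synthetic_spec(...))` emits a catalog, annotations
and ground truth, all reproducible bit-for-bit from the seed. What it
emulates, and what it does not:

- **Sizes.** Maximal complex sizes follow a rounded log-normal
  (meanlog 1.40, sdlog 0.83) truncated to [3, 50]: mode 3, mean ≈ 7.24,
  heavy right tail — matching the published summary statistics of a
  consolidated human complex catalog, which are the only distributional
  facts available. The full catalog's mean size is lower than the
  configured mean because planted subcomplexes are deliberately small
  (2 + Poisson(1.5), capped below the parent), as subcomplexes
  mostly have 3–4 subunits. The distributional check in the tests
  therefore targets the maximal complexes drawn from the distribution.
- **Nesting.** Each maximal complex receives subcomplexes with
  probability `p_nested` (default 0.3), recursively to `depth_max`
  (default 2); sibling subcomplexes overlap with probability
  `p_overlap_sub`. With probability `p_shared_root` a second maximal
  complex is planted over an existing root's subcomplexes — the
  mechanism that reproduces two roots sharing subcomplexes (the
  acetyltransferase topology).
- **Soundness by construction.** Candidate sets that would accidentally
  nest with a complex outside their own planted lineage are rejected
  and resampled. In an artifact-free, noise-free run the only subset
  relations in the catalog are the planted ones, so detection must
  recover the ground truth exactly (precision = recall = 1 for *any*
  seed) — this is an acceptance property, not a tendency.
- **Artifacts and noise.** With probability `artifact_rate` a maximal
  complex is duplicated into a different (publication, database) pair
  with one member dropped (count configurable): Jaccard (s−1)/s,
  always multi-source — the planted integration-error signal that
  concentrates in the top Jaccard bins. `n_noise` complexes overlap
  existing ones without any subset relation.
- **Annotations.** Each complex draws per-ontology seed term sets that
  members inherit with probability `coherence` (default 0.7), plus
  Poisson background terms; planted-shared proteins receive surplus
  random terms for BP and CC only (driving the direction of the
  shared-vs-baseline term-count comparison, which published data shows
  for BP/CC but not MF). Essentiality is `essential_base` (0.15) plus
  `essential_boost` (0.35) for planted-shared proteins; the disease
  flag is uniform at 0.1 — a planted negative control whose enrichment
  must stay at the nominal type-I rate.
- **Not emulated.** Real catalogs have correlated study coverage,
  shared-protein hubs spanning hundreds of complexes, organism-specific
  annotation depth, and identifier noise. Passing tests on synthetic
  catalogs shows the algorithms are correct and the directional
  machinery works; it does not show that effect *sizes* on real data
  will match.

## Numerical and degenerate-input choices

- Subset and equality tests are integer-count comparisons; meet-min and
  Jaccard are reported as doubles but never used for branching.
- Meet-min histograms use right-closed bins so a value of exactly 1
  lands in the top bin; zero-overlap pairs are excluded from histograms
  and reported as a separate count.
- Singleton complexes expand to zero edges (logged); empty graphs yield
  empty metric tables; modularity of an edgeless graph is NA, flagged.
- PageRank tolerance is 1e-9; all stochastic stages (hub sampling,
  Monte Carlo, rewiring, label propagation, generation) consume one
  user-supplied seed.
- Problem sizes in the shipped tests (catalogs of 25–200 complexes,
  oracle graphs of ≤ 15 nodes, 100 Monte Carlo seeds) were chosen so
  each oracle comparison is exhaustive at its scale while the whole
  suite stays inside a coffee break; they are package choices, and all
  scale up through the same interfaces.

## Known limitations

- The nested-group definition is purely set-based; a biologically
  distinct complex that happens to have a subset of another's subunits
  is indistinguishable from a true subcomplex without annotation.
- The motif null model is a standard edge-swap null, not the
  (undocumented) null of the historical package; significant-motif
  fractions are therefore not comparable to previously published
  percentages.
- Multiple testing is reported raw throughout, matching the analysis
  style this package mirrors; users comparing many groups should apply
  their own correction.
- The MITAB-style complex reader handles the dialect described in its
  documentation; real-world exports vary and may need the column
  configuration arguments.
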