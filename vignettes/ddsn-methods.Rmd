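---
title: "Methods: drug-drug similarity networks for repositioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drug-drug similarity networks for repositioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by `ddsnet`, the assumptions
behind it, the parameter defaults, what the synthetic-data generator does
and does not emulate, and the numerical conventions the implementation
commits to. It is the design record for the package; the README shows the
same pipeline as a worked example.

## 1. Model and procedure

The unit of analysis is a **tripartite graph** with disjoint vertex sets
for drugs, genes and diseases, and two edge relations: drug–gene (a drug
targets, is metabolized by, transported by, or carried by a gene product)
and gene–disease (a curated association). `buildTripartite()` validates
disjointness and deduplicates edges; a vertex may not appear in two roles.

**Projection.** `projectDDSN()` collapses the tripartite graph to a
weighted drug–drug similarity network (DDSN). With R(i) the set of
diseases reachable from drug *i* through at least one targeted gene, the
edge weight is

$$w(i,j) = |R(i) \cap R(j)|,$$

the number of *distinct* diseases reachable from both drugs. Path
multiplicity is deliberately ignored: two drugs hitting the same disease
through five genes each are no more similar, under this weight, than two
drugs hitting it through one gene each. The implementation uses a boolean
drug-by-disease reachability matrix and a cross-product; the test suite
certifies it against an independent exhaustive path-enumeration oracle
(`oracleProject()`) on randomized graphs.

**Vertex similarity.** Drugs are compared by the cosine of their weighted
adjacency rows *augmented with a diagonal self-entry equal to the weighted
degree* (the matrix $A + D$). The self-entry makes a vertex similar to its
own neighbors rather than only to vertices sharing neighbors, which keeps
star centers attached to their leaves. A consequence worth stating
plainly: two non-adjacent drugs with identical neighbor sets and weights
do **not** reach similarity 1.0 under this formula — their self-entries
occupy different coordinates, so the cosine is $S/(S+k^2) < 1$ where $S$
is the shared dot product and $k$ the common degree. The implementation
follows the formula; the tests pin its actual values (e.g. $2/3$ for the
interior vertices of a unit-weight 4-path).

**Community detection.** For each connected component,
`hierarchicalCommunities()` runs average-linkage agglomerative clustering
(`stats::hclust`) on the distance $1 - \text{cosine}$, then evaluates
every horizontal dendrogram cut (`cutree` at $k = 1, \dots, n$) by
weighted Newman–Girvan modularity computed against the *global* degree
null. Because modularity is a sum of per-cluster terms sharing the global
$2m$ normalizer, per-component optimization composes into the global
optimum over the family of per-component cuts; the acceptance tests
verify the chosen cut against exhaustive enumeration of that family on
small graphs. Ties between cuts are resolved toward the coarser partition
(a new cut must exceed the incumbent by $10^{-12}$), so the method never
fragments without a modularity reason. The procedure is deterministic —
nodes are processed in lexicographic order and no randomness is used; the
`seed` argument exists only for interface stability.

**Filtering.** `filterCommunities()` applies two exclusions in a fixed
order: first, clusters lying entirely outside the largest connected
component (reason `disconnected_from_main_component`; the largest
component ties broken by lexicographically smallest member); second,
clusters below the minimum size, default 8 (reason `below_min_size`).
Exclusions are recorded, not silently dropped. Survivors are renumbered by
decreasing size, ties by lexicographically smallest member.

**Labeling.** ATC codes follow the WHO positional scheme (legal lengths
1, 3, 4, 5, 7; `validateATC()` is total over character input). For a
cluster, `levelHistogram()` counts each *distinct* prefix once per drug;
the level-1 mode is the cluster label (`dominantCode()`, lexicographic
tie-break with a warning). `classifyCluster()` splits members into
*matched* (at least one code under the label letter) and *candidates*
(everything else, including drugs with no codes — absence of evidence for
the label is treated as a repositioning signal, which is the screen's
purpose). Level-2/3/4 histograms restricted to the label refine the
prediction; `topLevel4()` returns the codes occupying the top $k$
*distinct count values* (dense ranking), so equal counts share a rank and
a tie never silently truncates the list — with counts {8, 5, 5, 3, 3} and
$k = 3$, all five codes are reported, with a message.

**Accuracy arithmetic.** `accuracySummary()` takes per-cluster sizes and
percentages, reconstructs integer counts by nearest-integer rounding of
$\text{size} \times \text{pct} / 100$ (refusing inconsistent rows where
the count would exceed the size), and aggregates size-weighted totals:
matched %, literature-confirmed %, their sum (total accuracy) and the
complement (remaining candidates). Reconstructing counts before summing
keeps the totals exact rather than averaging already-rounded percentages.

**Literature screening.** `buildQuery()` is a pure function producing a
fixed PubMed Boolean template: the drug as a MeSH term, AND a
parenthesized OR-clause of the category MeSH term plus Title/Abstract
synonyms (omitted when only one term exists), AND a publication-type
filter clause. No networking code ships; a fetcher, if any, is passed in
as a plain function so screening can be mocked or done by hand.
`applyValidation()` folds screened evidence back in: a confirmed
candidate needs at least one PMID and is promoted out of the candidate
set.

## 2. Parameters and defaults

| Parameter | Default | Rationale |
|---|---|---|
| `minWeight` (projection) | 1 | keep every shared-disease link; thresholding is a caller decision |
| linkage | average | compromise between single's chaining and complete's fragmentation on cosine distances |
| cut tie epsilon | 1e-12 | numerical guard; prefers coarser partitions on exact ties |
| `minSize` (filter) | 8 | below this, a level-1 histogram over ~14 letters is too sparse to call a dominant class |
| `requireMainComponent` | TRUE | peripheral components lack the shared context that makes neighborhood-based labels meaningful |
| `k` (`topLevel4`) | 3 | enough subgroups to suggest targets without flooding the query log |
| rounding | half away from zero, 1 decimal | see §4 |

Generator defaults (`generatorConfig()`): 4 clusters × 12 drugs, 6
cluster-private genes each with 3 private diseases, within-cluster
drug–gene link probability 0.7, between-cluster 0.02, mislabel fraction
0.1, dominant letters N, C, L, A with three level-4 profiles per cluster
drawn with weights 0.5/0.3/0.2. These defaults are the study conditions
for every statistical claim in the test suite; they were chosen to mimic
the regime of interest — dense private neighborhoods, sparse cross-talk,
a minority of mislabeled drugs — at a size (48 drugs) where tests run in
seconds.

## 3. What the generator emulates — and what it does not

The generator plants a block structure: each cluster owns private genes,
each gene private diseases, and drugs link to genes by independent
Bernoulli draws (`p_within` inside the cluster, `p_between` outside). A
fixed fraction of drugs (nearest integer of fraction × cluster size,
lexicographically first ids for determinism) receive the *next* cluster's
ATC profile; these are the planted repositioning candidates and the
ground truth is returned alongside the tables
(`truth$is_planted_candidate`). `expectedWeightBounds()` gives the
closed-form expected projected weights, and a Monte-Carlo test checks the
empirical means against them within three standard errors.

Real drug–target and disease-association databases differ in ways the
generator does not model: heavy-tailed target degrees (promiscuous
kinases, polypharmacology), genes shared across many disease areas,
hierarchical and overlapping disease vocabularies, annotation bias toward
well-studied drugs, and multi-class ATC assignments. The generator's job
is to make the pipeline's behavior *checkable* — planted truth, known
expectations — not to be a realistic pharmacological simulator.
Conclusions about real data must come from real data.

## 4. Numerical conventions and degenerate inputs

- **Rounding.** Percentages are reported to one decimal, rounding halves
  away from zero (`roundHalfAway()`), the convention of published tables,
  not banker's rounding as in base `round()`. Counts are reconstructed
  before aggregation so totals never compound rounding error.
- **Tie-breaks.** Dominant codes: lexicographic with a warning. Cluster
  ordering: size descending, then lexicographically smallest member.
  Largest component: lexicographically smallest member. Dendrogram cuts:
  coarser wins. All deterministic; two runs on identical inputs produce
  byte-identical outputs (tested).
- **Degenerate inputs.** An empty drug–gene table aborts the pipeline at
  the tripartite stage with a named-stage error. Drugs with no ATC codes
  get empty histograms and fall to the candidate side. A network with no
  edges has undefined modularity (`NA`) and every vertex is its own
  singleton. Isolated drugs survive projection as vertices and are
  removed, with reasons, at the filtering stage.
- **RNG hygiene.** `generateDataset()` saves and restores the caller's
  RNG state; package analysis code draws no random numbers.

## 5. Design rationale for the open choices

The analysis this package reproduces used a proprietary hierarchical
clustering tool whose internals are not published. The open
re-implementation — cosine vertex similarity with degree-augmented
diagonal, average linkage, modularity-optimal cut — was chosen because
each ingredient is standard, each is independently testable, and together
they recover planted structure reliably: the test suite asserts a mean
adjusted Rand index ≥ 0.9 between detected and planted memberships over
20 generator seeds at the default conditions. The mean is the asserted
statistic because individual seeds can legitimately dip: the Bernoulli
scheme occasionally gives a drug as much total edge weight to a foreign
cluster as to its own, an ambiguity in the *data* that no detection
method should be penalized for resolving either way (one such case was
verified by hand: equal weight sums to both clusters).

Similarly, the "no mislabeling ⟹ no candidates" invariant is asserted in
the *separable* regime (`p_between = 0`), the only setting where cluster
membership is unambiguous; there the planted clusters form separate
components, so the main-component filter is switched off for that test —
applying it would reduce the run to a single cluster by construction, not
by evidence.

## 6. Limitations

- The DDSN weight ignores association strength; a weak, speculative
  gene–disease link counts as much as a well-established one (a
  `scoreThreshold` at ingestion is the only lever).
- Modularity optimization over horizontal dendrogram cuts searches a
  restricted partition family; non-nested or unbalanced true structures
  may be missed.
- ATC is a therapeutic-*use* classification, not a mechanism ontology;
  the matched/candidate split inherits its coarseness, and drugs with
  multiple legitimate classes inflate the apparent candidate rate.
- Literature confirmation depends on query recall and screener judgment;
  the package standardizes the query and the bookkeeping, not the
  judgment.
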