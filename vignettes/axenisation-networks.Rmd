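---
title: "Method networks for microalgal axenisation: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Method networks for microalgal axenisation: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axenet)
```

## The problem

Producing an axenic culture — a microalgal culture free of all contaminating
bacteria, fungi and amoebae — is a prerequisite for attributing physiology,
metabolism or omics signals to the alga itself. A century of literature
reports purification workflows as ordered sequences of methods (filtration,
washing, antibiotic cocktails, micropicking, ...) ending in incubation of the
putatively pure culture, with inconsistent outcomes and no consensus
protocol. `axenet` treats this literature as data: each publication × species
attempt becomes a record with an ordered method list and an outcome, and the
corpus becomes a set of weighted directed method networks — one per
microalgal division (diatoms, dinoflagellates, green algae, other) — whose
communities and cliques expose which methods are used together, in what
order, and with what success.

## Data model

The unit record is one *publication × species* attempt (`master_table` rows),
because success rates and networks are species-level quantities; publication
resolution (quality scores, antibiotic cocktails, verification methods,
outcome tallies) is recovered by grouping. Method codes come from a closed
24-entry vocabulary — 3 Biological, 8 Chemical, 13 Physical methods — shipped
as a packaged CSV. The source literature names 23 methods while using flow
cytometry in its cluster tables; the vocabulary therefore carries a
`FlCy` (flow cytometry, Physical) code as the 24th entry. Likewise the
13-entry verification vocabulary includes differential interference contrast
microscopy alongside the twelve methods named in the co-usage figure legend
of the source corpus.

In the CSV serialisation, ordered workflows are `";"`-joined (`Fltr;Wash;Mkpk`
means filtration, then washing, then micropicking), antibiotic cocktails are
`class:compound:concentration` triples (mg/L; class may be left blank and is
then filled from the packaged compound → class lookup, unmapped compounds
falling into *Others*), and the three raters' rubric answers are `"|"`-joined
strings. `read_master_table()` validates every row and names the offending
row and code on failure; an alias table maps free-text method labels onto
codes before validation.

## The quality rubric

Five questions score each publication: organism source reported (yes 1 / no
0); method details reproducible (yes 1 / incompletely 0 / no −1); growth
medium described (yes 1 / referenced 0 / no −1); axenicity verified (multiple
methods 1 / one 0 / none −1); contaminants identified (yes 1 / no 0). Each of
three raters answers independently, so per-rater totals lie in [−3, 5], and
the publication's final score is the rounded mean of the three totals.

The rounding rule is *half away from zero* (mean 0.5 → 1, −0.5 → −1). The
convention matters only for means ending in .5 sitting next to the
below-zero quality threshold; banker's rounding would classify a mean of
−0.5 as 0 or −1 depending on parity, which is surprising in an audit trail.
The below-zero classification applies to the final aggregated score, never
to an individual rater.

## Workflow networks

`build_axenisation_network()` converts each record with methods
$m_1, \dots, m_k$ into directed edges $m_1{\to}m_2, \dots, m_{k-1}{\to}m_k$
plus a terminal edge $m_k{\to}\mathrm{INCB}$ into a dedicated incubation
sink; edge weight counts transitions across all species-level records of the
division. Two invariants pin the construction down: the weight flowing into
`INCB` equals the number of records, and total edge weight equals the summed
workflow lengths. Consecutive repeats of one method become self-loops —
deliberate, since the density convention below counts loops as realisable
connections.

Conventions, chosen once and recorded in every report:

* **Node counts and density exclude the sink.** The incubation hub is a
  bookkeeping device shared by every workflow; including it would inflate
  every division's statistics identically.
* **Degree medians include the sink** (`degree_stats(include_sink = TRUE)`,
  the default for whole networks). Degree is the number of distinct
  incoming plus outgoing connections; a self-loop adds one to each
  direction. With the hub, a network with an odd number of methods has an
  even node count, which is how half-integer medians such as 4.5 arise in
  the reference statistics; without it they could not.
* **Density counts presence, not weight**, against the theoretical maximum
  *including* loops: $n^2$ under the directed convention (default) and
  $n(n+1)/2$ under the undirected one. The source analysis does not state
  its convention, so both are implemented and
  `reproduce_published_analysis()` picks the one minimising the discrepancy
  against the reference densities, recording the choice and both
  discrepancies in the report's config echo.

The undirected projection (`to_undirected()`) collapses $u{\to}v$ and
$v{\to}u$ into one edge with summed weight and drops loops by default; it is
the substrate for community detection and cliques.

## Modularity and community detection

Cluster quality is Newman–Girvan modularity on the weighted loop-free
undirected projection,

$$Q = \sum_c \left[ \frac{e_c}{m} - \left(\frac{d_c}{2m}\right)^2 \right],$$

with $e_c$ the intra-community weight, $d_c$ the community strength sum and
$m$ the total weight. An edgeless graph has $Q = 0$ by convention, and a
single community has $Q = 0$ exactly.

Because the largest division network in this domain has ~19 method nodes,
`optimal_partition()` defaults to a *globally exact* search rather than a
stochastic heuristic: connected components are solved independently (a
community spanning components can always be split without losing edge weight
while strictly shrinking the degree penalty, so component-wise optima
compose), and within a component a branch-and-bound enumerates
restricted-growth assignments over the pairwise gain matrix
$B_{ij} = w_{ij} - k_i k_j / 2m$. The admissible bound adds
$\sum \max(0, B_{ij})$ over all still-open pairs to the incumbent sum —
realisable by leaving every remaining node in its own community — and nodes
are examined in decreasing strength order so strongly positive intra-cluster
pairs are committed early and the bound bites. Components above
`max_exact_n` (default 20) fall back to greedy agglomerative merging of the
best positive ΔQ pair; the partition records which mode produced it.

Tie-breaking between equal-Q optima is deterministic: the first optimum met
in the strength-ordered search is kept and community ids are canonicalised
by first appearance in vertex order, making the result independent of node
insertion order. A globally lexicographic-minimal tie-break was considered
and rejected because it would force searching in original vertex order and
forfeit the pruning that makes the 19-node exact search instant.

`compare_partitions()` implements the adjusted Rand index from the
pair-counting contingency formula; the test suite cross-checks it against an
independent pair-enumeration oracle and `mclust::adjustedRandIndex`, and
cross-checks the exact partitioner against brute-force enumeration over all
set partitions (n ≤ 8) and `igraph::cluster_optimal`.

## Cliques

Cliques — method sets used in immediate succession with one another — are an
unweighted concept, so `maximal_cliques_bk()` operates on the simple
undirected projection, ignoring loops and the sink. The enumerator is
Bron–Kerbosch with greedy pivoting (the pivot maximises candidate
neighbours). Per community, `largest_cliques_in_cluster()` reports *all*
co-maximal cliques of the induced subgraph, ranked lexicographically, since
several equally large cliques are common at these sizes and reporting only
one would hide alternatives.

## Success rates

A method's success rate in a division is (records with outcome *success*
containing the method) / (records containing the method). Two conventions:
a method recurring within one workflow counts once per record, and records
with *partial* outcome contribute uses but no successes — conservative,
since the source corpus divides "successfully achieved" by "used" without
resolving partials. Rates are reported only for methods used in **more
than six** species-level records within the division; below that the entry
carries a below-filter-limit (BFL) flag instead of a number, because a rate
estimated from ≤ 6 attempts is dominated by single-lab idiosyncrasies.
Duplicating every record leaves all rates unchanged but can clear BFL flags
— a scale-freeness property the tests assert.

## Antibiotic summaries

Cocktail statistics are publication-level: a publication reporting the same
compound at several concentrations contributes its median once. Class
tables give median (min–max) in mg/L per class × division; compound
frequencies count publications; cocktail combinations count, per unordered
compound (and class) pair, the publications whose cocktail contains both —
a k-compound cocktail contributes $\binom{k}{2}$ pairs.

## The synthetic generator

`generate_master_table()` exists so every stage is testable without the
third-party corpus file. Its defaults *are* the study conditions: 63
publications weighted across divisions as in the curated corpus (11 : 15 :
33 : 22 publication equivalents), 54% single-species publications and the
rest 2–6 species, workflows of 1–5 methods over the full vocabulary, four
planted clusters of six methods with transition mass p_in = 0.8 inside and
p_out = 0.05 between clusters, and per-method success probabilities by
category (Physical 0.85, Chemical 0.75, Biological 0.70 — chosen once to
bracket the 0.46–0.95 range seen in the literature). Workflow length is
drawn uniformly from its range, which plays the role of a termination
hazard; a workflow succeeds with probability equal to the *product of the
per-method probabilities over its distinct methods*, a declared testing
device (the corpus offers no generative model) with the useful property
that setting all other methods to probability 1 makes a focal method's
expected rate exact. Rubric answers are drawn per question from fixed
categorical distributions skewed toward adequate reporting; antibiotic
cocktails of 1–3 compounds with log-uniform concentrations (≈5–1000 mg/L)
attach to workflows using `AntB`. Randomness is one seeded stream with
per-publication sub-seeds derived as `(seed·1000003 + i) mod 2³¹−1`, so
tables are bitwise reproducible.

What the generator does **not** emulate: real corpora couple method choice
to division and era, share species across publications, leave fields
missing, and contain partial outcomes (the generator emits only
success/failure; the reader and the success-rate logic nevertheless accept
`partial`). Passing recovery tests therefore demonstrates that the
*pipeline* inverts its own generative assumptions — planted clusters
recovered with ARI ≥ 0.9 under strong separation, rates within binomial
error of truth — not that the published corpus satisfies those assumptions.

## Numerical choices and degenerate inputs

Branch-and-bound comparisons use an absolute slack of 1e−12, so among
equal-Q partitions the first in search order wins; empty graphs error;
edgeless graphs yield singleton communities at Q = 0; single-node
components are their own community. Median degrees over an even number of
nodes are half-integers by the usual sample-median rule. Problem sizes in
the tests are chosen to keep exhaustive oracles exact: brute-force
partitions at n ≤ 8 (Bell(8) = 4140), subset-enumeration cliques at
n ≤ 10, and recovery runs at ~300 records on 15-node planted networks.

## Limitations

The pipeline reproduces a corpus analysis; it does not model it. Edge
weights conflate replication with popularity, clusters do not account for
success rates, and the representation filter discards exactly the sparsely
reported methods a meta-analysis would most like to rank. The corpus-level
acceptance path requires the archived master table of the source
meta-analysis, which ships separately from this package (see the README's
reproduction section).
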