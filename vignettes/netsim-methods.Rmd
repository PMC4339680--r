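---
title: "Network-aware GO term similarity: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-aware GO term similarity: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netsim)
```

## The problem

Information-content (IC) measures of GO term similarity — Resnik,
Schlicker, and relatives — see only two things: where two terms sit in
the ontology graph, and how many genes are annotated under them. In most
organisms the experimentally supported annotation is thin, so these
measures miss functional relationships that are real but taxon-specific
(in plants, say, the tight coupling between water-deprivation response
and stomatal closure, which GO rightly does not encode as an edge).
Genome-scale *co-function networks* — weighted gene graphs whose edge
confidences estimate the probability of a true functional linkage —
carry exactly this missing, genome-specific signal. The measure
implemented here injects that signal into an IC-style similarity.

## The model

Let `G_a`, `G_b`, `G_p` be the propagated (true-path) gene sets of the
compared terms and of a common ancestor `p`, and `G` the annotated gene
universe of the namespace.

**Step 1 — gene-set distance.** For genes `i`, `j` the network distance
is `d_ij = 0` if `i = j`, `1 - conf(i, j)` for an edge, and 1 otherwise.
A gene's distance to a set is the *product* of its pairwise distances,
so one shared gene or one strong link suffices for closeness; the
gene-set distance `D` plugs these product distances into a
Czekanovski–Dice form. Consequences we rely on (and test): `D = 0` when
the sets are equal, `D = 1` when they are disjoint and no network is
available, and as all confidences vanish `D` tends to the plain
set-overlap Czekanovski–Dice distance.

**Step 2 — path-constrained annotation.** LCA-style measures charge a
term pair with *every* gene under the common ancestor, including genes
on branches unrelated to either term. The path-constrained set `U`
keeps the two terms' propagated sets plus the *direct* annotations of
terms on the upward paths to `p`. Interior path terms deliberately
contribute direct annotations only: propagating them would re-admit
exactly the off-path descendants the constraint exists to exclude (in
the bundled toy world, the genes of `t_d` and `t_g`).

**Step 3 — similarity.** `D` interpolates between an
annotation-frequency view and a network view through
`f = D^2 |U| + (1 - D^2) sqrt(|G_a||G_b|)` and
`h = D^2 |G| + (1 - D^2) max(|G_a|, |G_b|)`, combined as

```
S = (2 ln|G| - 2 ln f) / (2 ln|G| - (ln|G_a| + ln|G_b|)) * (1 - (h/|G|) (|G_p|/|G|))
```

maximized over common ancestors. Tightly linked gene sets (`D -> 0`)
push `f` to its lower bound and `h` to `max(|G_a|, |G_b|)`, lifting
`S`; unlinked sets (`D -> 1`) reduce the first factor to the Schlicker
log-ratio with `|U|` in place of `|G_p|`. Since
`|U| >= |G_a ∪ G_b| >= sqrt(|G_a||G_b|)` and `h <= |G|`, `S` stays in
[0, 1] by construction.

Gene-level similarity is the best-match average of maximized term
similarities over the two genes' direct term sets, computed under
*leave-one-out*: both genes are removed from every term's gene set —
and from `|G|`, because IC-type quantities depend on it — before any
term similarity is evaluated, so a pair can never certify itself.

## Degenerate inputs and numerical choices

* Natural logarithms everywhere. The leading factor of `S` is a ratio
  of log differences, so the base cancels mathematically; fixing it
  keeps results bit-reproducible.
* If both terms are annotated to all of `G`, the first factor is 0/0;
  `S` is defined as 0, consistent with the Resnik/Schlicker limits for
  zero-IC terms. Likewise Schlicker is defined as 0 for two roots.
* When the network is absent or has no edges, `U` is replaced by `G_p`.
  This is the stated no-network degenerate form of the measure, and it
  makes the reduction to Schlicker exact (to 1e-12 in the tests) rather
  than approximate; the path constraint is an adjustment to how network
  evidence is weighted, and without network evidence the measure *is*
  Schlicker.
* Ties in the maximization over ancestors are value-identical; the
  reported ancestor is the lexicographically smallest maximizer, for
  reproducible logs.
* Ancestor sets are reflexive, so self-similarity is well defined for
  every measure; gene self-similarity `GS(g, g)` is fixed at 1 by
  convention rather than computed (leave-one-out would delete the
  gene's own annotations).
* In the gene-level aggregation, zero best-matches contribute nothing
  to the numerator while the denominator stays `|T_i| + |T_j|`, the
  printed form of the formula; the stricter reading (shrinking the
  denominator as well) is available via `nonzero_denominator = TRUE`.
* Cross-namespace term pairs are errors, not zeros: the measure is
  defined within one GO category.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `exclude_evidence` (`parse_gaf`) | `"IEA"` | evidence codes dropped; electronically inferred annotations are excluded unless the user opts in |
| `exclude_not` (`parse_gaf`) | `TRUE` | NOT-qualified annotations are negative statements, not annotations; dropped by default |
| `relations` (`parse_obo`) | `is_a`, `part_of` | ontology edge types loaded; both participate identically in path enumeration, `regulates` is excluded by default |
| `normalize` (`parse_network`) | `minmax` | published network scores (e.g. log-likelihood) are mapped affinely onto [0, 1], since edge confidences must be probabilities |
| `wang_weights` | 0.8 / 0.6 | Wang semantic-contribution factors per `is_a` / `part_of` edge — the measure's original defaults |
| `c` (`lfc_config`) | 0.001 | smoothing constant in the LFC log-ratio; any small positive value, it guards against zero mean distances |
| `min_genes_per_reaction` | 2 | single-gene reactions carry no within-reaction signal and are skipped |
| `currency` (`build_reaction_map`) | 24 compounds | ubiquitous metabolites (ATP, H2O, ...) whose sharing must not make reactions adjacent; supply the list matching your pathway database's nomenclature |

## The benchmark

There is no gold standard for term-to-term similarity, so evaluation
happens at the gene level: genes catalyzing *adjacent* metabolic
reactions (sharing a non-currency compound) should look more similar
than genes of non-adjacent reactions. For gene `g` in reaction `r`,

```
lfc(g, r) = ln [ mean over non-adjacent genes of (1 - GS + c) ] /
            [ mean over adjacent genes of (1 - GS + c) ]
```

averaged over `G(r)`; larger is better. Genes appearing in both
comparison sets, or overlapping `G(r)`, are removed from the sets
first. "Non-adjacent" means every other reaction in the map, not only
distance-2 neighbours; `reaction_distances()` supports stratifying by
path length instead.

The genome-specificity statistic asks whether adding the network makes
term-pair similarities *more organism-specific*: it sums, over organism
pairs, the change in absolute similarity difference caused by using the
network. Each pair's components are tested against the pooled mean
component by a one-sample t-test with Benjamini–Hochberg correction —
the test construction is an interpretation choice (the statistic's
definition does not pin one down), kept deliberately simple and
documented here.

## What the generators emulate — and what they do not

`random_fixture()` builds layered random DAGs (each non-root term draws
1–3 parents among earlier terms), annotations with at least one term
per gene, and uniform-confidence random networks. It exercises the
algebraic properties of the measures — monotonicity, symmetry, the
reductions — not the statistics of real GO: no realistic depth/branching
distribution, no annotation bias toward shallow terms, no
calibrated confidence distribution.

`signal_fixture()` is the constructed-signal world for the benchmark:
reactions form a chain through shared pathway intermediates (plus ATP
everywhere, which the currency filter must ignore), each reaction's
genes are annotated to a reaction-specific term placed *randomly* under
mid-level terms, and co-function edges (confidence 0.9) connect genes
within and between adjacent reactions only. By construction the network
is the sole carrier of adjacency information, so an annotation-only
measure hovers near LFC 0 while the network-aware measure scores
highly; degree-preserving rewiring (50% / 100%) destroys the signal
monotonically. The default problem size — 12 reactions of 3 genes,
4 mid-level terms — keeps a full benchmark run (four gene-similarity
matrices over 36 genes) in the tens of seconds while leaving the
observed margins (median LFC ≈ 2.9 vs ≈ 0, and ≈ 2.9 → ≈ 2.1 → ≈ 0.3
under rewiring) far wider than their seed-to-seed variability.

Passing these tests shows the implementation computes the intended
quantities and that the network channel works end to end; it does not
show that the measure improves biology on any particular real organism,
which depends on annotation coverage and network quality there.

## Other design decisions

* **Leave-one-out removes the pair from the universe too.** `|G|`
  enters every IC-type quantity; leaving the evaluated genes in the
  universe would let the pair influence its own score through the
  denominator.
* **Genes absent from the network are unconnected nodes**, not errors,
  so partial network coverage degrades the measure gracefully toward
  its annotation-only reduction.
* **Duplicate network edges keep the maximum score**; published edge
  lists occasionally repeat pairs with scores from different evidence
  lines, and confidence semantics favour the strongest.
* **Full rewiring on dense graphs retains a chance-level residue of
  original edges** — a degree-matched random graph already shares edges
  with the original. The rewiring loop runs until no original edge
  remains or its attempt budget ends; on sparse, realistic networks it
  reaches zero.
* **The exact layout of the toy world is a choice.** Only its
  documented constraints (ancestor structure, path sets, the
  path-constrained gene set, the leave-one-out sets, the worked
  network distances) are asserted anywhere; the particular edge list
  satisfying them is not load-bearing.

## Known limitations

* The ancestor maximization enumerates all common ancestors with
  memoized ancestor closures; no sub-quadratic scheme is attempted.
  For genome-scale all-vs-all term matrices, expect the dominant cost
  in `gene_similarity_matrix()`, which re-propagates removals per gene
  pair.
* OBO parsing covers the tags the measures need (`id`, `namespace`,
  `is_a`, `relationship`, `alt_id`, `is_obsolete`); it is not a general
  OBO 1.4 reader (no intersection/union axioms, no typedef semantics).
* The Yu measure and disjunctive-common-ancestor variants are out of
  scope, as are ID mapping between gene identifier systems and
  BioCyc flat-file parsing (reaction tables enter as TSV).
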