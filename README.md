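# netsim

Semantic similarity between Gene Ontology (GO) terms that uses more than
the ontology: **netsim** combines the GO graph, gene annotations, and a
weighted **gene co-function network** into one term-to-term similarity
measure (NETSIM), aggregates it to gene-to-gene functional similarity,
and benchmarks similarity measures against metabolic reaction maps.

It is aimed at computational biologists who score functional
relatedness of genes or GO terms — for gene clustering, function
inference, or data quality assessment — in organisms where experimental
GO annotation is sparse but genome-scale functional networks
(YeastNet/AraNet/HumanNet-style weighted edge lists) are available.

## The measure

For two terms `t_a`, `t_b` with propagated gene sets `G_a`, `G_b` and a
common ancestor `p` (propagated set `G_p`, annotation universe `G`):

1. **Gene-set distance** `D(t_a, t_b)` — a modified Czekanovski–Dice
   distance. Each gene's distance to the opposite set is the *product*
   of its pairwise network distances `d_ij` (0 for itself, `1 − conf`
   for an edge, 1 otherwise), so a single strong co-function link pulls
   a gene close to a set:

   `D = (Σ_{i∈G_a} Π_{j∈G_b} d_ij + Σ_{i∈G_b} Π_{j∈G_a} d_ij) / (2|G_a ∪ G_b| − Σ − Σ)`

2. **Path-constrained annotation** `U(t_a, t_b, p)` — the propagated
   sets of `t_a` and `t_b` plus the *direct* annotations of terms on the
   upward paths to `p`; genes hanging off the ancestor's other branches
   are excluded as noise.

3. **Similarity**

   `S(t_a, t_b, p) = [ (2·ln|G| − 2·ln f) / (2·ln|G| − (ln|G_a| + ln|G_b|)) ] · (1 − (h/|G|)·(|G_p|/|G|))`

   with `f = D²·|U| + (1−D²)·√(|G_a||G_b|)` and
   `h = D²·|G| + (1−D²)·max(|G_a|,|G_b|)`. The reported similarity is
   the maximum of `S` over all common ancestors.

Without a network the measure reduces exactly to the Schlicker measure
(for disjoint gene sets), and self-similarity is `1 − (|G_t|/|G|)²`, a
Resnik-style quantity. Baselines (`resnik`, `schlicker`, `wang`) and
ablation variants (`netsim_v1/v2/v3`) are built in. Gene-to-gene
similarity `GS` is the best-match average of term similarities computed
under **leave-one-out**: the evaluated gene pair is removed from every
annotation set (and from `|G|`) first.

## Worked example

The bundled toy world (`figure1_fixture()`) is an eleven-term ontology
with genes g1–g13 and a small co-function network:

```r
library(netsim)
fx <- figure1_fixture()

term_similarity(fx$dag, fx$annots, fx$net, "t_a", "t_b", "t_i")
#> netsim(t_a, t_b | p = t_i): S = 0.814283 (D = 0.141227, |U| = 7, f = 3.53463, h = 4.17951)

as.numeric(schlicker(fx$dag, fx$annots, "t_a", "t_b"))
#> [1] 0.2160388

gene_similarity(fx$dag, fx$annots, fx$net, "g6", "g7")
#> GS(g6, g7) = 0.979339  (|T_i| = 2, |T_j| = 2)
```

Reading: the co-function edges between the two terms' annotated genes
make `D` small (0.14), so the path-constrained set (7 genes) barely
dilutes the information weight `f`, and the pair scores 0.81 where the
annotation-only Schlicker measure sees 0.22. At the gene level, g6 and
g7 share both their terms, and after removing the pair itself the
remaining annotation still supports GS = 0.98.

Reaction-map benchmarking works from any gene-similarity matrices:

```r
sfx <- signal_fixture(seed = 1)   # adjacency signal lives in the network only
genes <- names(sfx$annots$gene_terms)
gs_net <- gene_similarity_matrix(sfx$dag, sfx$annots, sfx$net, genes)
gs_sch <- gene_similarity_matrix(sfx$dag, sfx$annots, NULL, genes,
                                 measure_config("schlicker"))
lfc_benchmark(sfx$reactions, list(netsim = gs_net, schlicker = gs_sch))
```

A command-line interface mirrors these functions
(`inst/scripts/netsim termsim|genesim|lfc-eval|genome-spec|fixture`);
see `?run_cli`.

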