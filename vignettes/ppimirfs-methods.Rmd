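---
title: "Methods: weighted-network microRNA functional similarity"
author: "ppimirfs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted-network microRNA functional similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppimirfs)
```

# The model

`ppimirfs` scores the functional similarity of two plant microRNAs
through the genes they regulate. The pipeline has four layers:

1. **Term-level semantic similarity** over a Gene Ontology aspect,
   using a graph-based contribution measure.
2. **Gene-level similarity**, aggregating the annotation sets of two
   genes.
3. **A weighted protein–protein interaction network (WPPIN)**, whose
   edge weights are gene-level similarities, and a path-based
   association score between any two genes in it.
4. **Set-level similarity** between two microRNAs' target-gene sets,
   aggregated with a modified best-match average, plus the statistical
   machinery to evaluate the scores against family, genomic-cluster and
   stress-response groupings.

# Term and gene similarity

For a focal term $t_0$, every ancestor $t$ receives a semantic
contribution

$$ S_{t_0}(t_0) = 1, \qquad
   S_{t_0}(t) = \max_{c \in \mathrm{children}(t)} w_{c\to t} \, S_{t_0}(c), $$

with relation factors $w = 0.8$ for `is_a` and $0.6$ for `part_of`
(`default_relation_factors()`, overridable everywhere). The similarity
of two terms is the shared-contribution ratio

$$ \mathrm{sim}(a,b) =
   \frac{\sum_{t \in A \cap B} S_a(t) + S_b(t)}
        {\sum_{t \in A} S_a(t) + \sum_{t \in B} S_b(t)}. $$

`term_closure()` computes the contributions by dynamic programming on
the DAG; the test suite checks it bit-for-bit against a brute-force
all-paths oracle on hundreds of random ontologies.

`gene_similarity()` aggregates the term-by-term matrix of two genes'
annotation sets with the best-match average (default) or the maximum.
A design decision worth flagging: a gene with **no annotation** in the
aspect has similarity `NA_real_`, never 0. Zero means "functionally
dissimilar"; `NA` means "no information". The distinction propagates:
edges whose weight is `NA` (or 0) stay in the network but are
**non-traversable** for the path search.

# The weighted network and the path score

`integrate_edge_lists()` merges interaction tables from several
sources (deduplicated, self-loops dropped, gene ids normalized to
uppercase with trailing isoform suffixes removed), and
`weight_network()` attaches a gene-similarity weight per edge.

The association of two genes $i, j$ in the WPPIN is

$$ F(i,j) = \max_{P \in \mathcal{P}_{\min}(i,j)} \prod_{e \in P} w_e, $$

where $\mathcal{P}_{\min}$ is the set of **minimum-hop** paths between
$i$ and $j$ over traversable edges. Semantics fixed by
`shortest_path_best_product()`:

- $F(i,i) = 1$ — the empty product over the zero-hop path. This is the
  anchoring identity of the whole method and the first acceptance
  property of the test suite.
- Disconnected pairs score 0.
- Among equal-scoring minimum-hop paths the lexicographically smallest
  witness path is reported, so results are fully deterministic.
- `path_search_config(score_rule = "geometric_mean")` replaces the raw
  product by its $n$-th root for users who prefer a length-normalized
  score; the raw product is the default because hop count is already
  fixed by the minimum-hop constraint, so within a comparison the
  product and its root are monotonically related.
- `max_hops` optionally caps the search; a capped, unreached pair is
  flagged rather than silently scored 0.

The search is a layered breadth-first traversal keeping, per node and
layer, the best running product. Pruning is sound because every prefix
of a minimum-hop path is itself minimum-hop. Per-source traversals are
cached on the network object, so all-pairs scoring of a target set
reuses each single-source sweep.

# Set-level similarity

For target sets $T_i$ ($m$ genes, $m'$ of them absent from the
network) and $T_j$ ($n$, $n'$ absent), `target_set_similarity()`
computes a modified best-match average over the in-network
("effective") sets:

$$ FS(i,j) = \frac{\sum_{g \in T_i} \max_{h \in T_j} F(g,h)
                 + \sum_{h \in T_j} \max_{g \in T_i} F(g,h)}
                  {(m - m') + (n - n')}. $$

Out-of-network genes therefore neither contribute nor dilute. If both
effective sets are empty the score is undefined (`NA`, status
`"undefined"`); if exactly one is empty the score is 0 with a warning —
an empty-versus-nonempty comparison is evidence of dissimilarity, while
empty-versus-empty is evidence of nothing.

# Evaluation design

`assign_genomic_clusters()` groups microRNAs on the same chromosome
whose gap (end to next start) is at most 10 kb, by single linkage;
singletons are dropped. `partition_pairs()` splits pairs into
intrafamily (or intracluster), interfamily, and random — where random
pairs avoid intra **and** inter pairs of *both* groupings, so the
control class carries no family or cluster signal.
`group_comparison()` runs a Kruskal–Wallis test across the classes and
one-sided rank-sum tests of the reference class against each other
class (exact when both sides have at most 20 observations and no ties).
`roc_prioritization()` ranks each positive pair against 99 sampled
negatives with mid-ranks for ties and reports the trapezoidal AUC over
rank thresholds. `stress_pair_experiment()` builds positive pairs that
share a stress-response label and 50 label-disjoint negative sets.

# Synthetic fixtures and calibration

`generate_fixture()` builds a complete, byte-reproducible study from a
seed: a single-root layered random ontology per aspect, an
Erdős–Rényi interaction core with planted cliques, annotated genes,
microRNA target sets, families, stress groups, and genomic
coordinates. The default sizes — 40 terms, 150 genes, edge probability
0.04, 70 microRNAs, 17 families of 3, 3 stress groups of 4, 5 genomic
clusters, 10% out-of-network targets — were chosen once, before the
statistical experiments were finalized, to give 51 intrafamily pairs
(so 50 are always drawable) at a per-seed runtime near one second, and
were not adjusted afterwards.

`family_effect` and `stress_effect` set the fraction of targets shared
within a family or stress group. One calibration subtlety is important
enough to document: experiments that test the **family** contrast run
with `stress_effect = 0`. The random-pair class excludes family and
cluster pairs but not stress-group pairs, so an active stress effect
would leak real signal into the control class and bias the family
comparison — under a pure null it pushed p-values toward 1. With the
stress effect off, null p-values are uniform (Kolmogorov–Smirnov
check in the test suite) and the empirical false-positive rate matches
the nominal level. The stress-prioritization experiment conversely
runs at the default `stress_effect = 0.75` with family and cluster
pairs excluded from its negative pool via `related_pairs()`.

# Problem sizes and limitations

The shipped experiments run at desk scale: networks of ~150 genes and
~70 microRNAs, hundreds of seeds in a few minutes. At this scale the
package demonstrates the *properties* of the method — identity
anchoring, oracle-exact path and semantic computations, detection of
planted signal, calibrated nulls — rather than genome-scale effect
sizes, which depend on the density and quality of real annotation and
interaction data. The path search is exponential only in the oracle
used for testing; the shipped search is polynomial (layered BFS with
per-layer dominance pruning) and caches per-source sweeps, which is
what makes all-pairs matrices over full fixture networks cheap.

Open choices a user may want to revisit: the best-match-average versus
maximum gene-level combiner (`combine=`), product versus geometric-mean
path scoring, the 10-kb clustering gap, and the relation factors. All
are plain function arguments.
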