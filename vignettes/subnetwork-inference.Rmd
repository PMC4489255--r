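---
title: "Probabilistic sub-network inference: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic sub-network inference: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netsieve)
```

## The model

`netsieve` treats sub-network inference as a probabilistic selection
problem over a mixed interaction graph. The interactome is a graph whose
edges carry an interaction type (protein–DNA `pd`, protein–protein `pp`,
metabolic `met`, small-RNA `srna`, or any user label) and an optional
direction. The biological premise is that edges between strongly
differentially expressed genes are more likely to be part of the mechanism
active in the contrast under study.

**Edge probabilities.** Log fold changes across all measured genes are
modelled as a single normal distribution N(μ, σ), fitted by the sample mean
and sample (n−1) standard deviation. A gene's score is the two-tailed tail
mass of its value,

$$\mathrm{Score}(g) = \left|\,1 - 2\,\Phi_{\mu,\sigma}(D_g)\,\right| \in [0, 1],$$

which is 0 at the mean, approaches 1 in either tail, and — being a function
of the z-transform — is invariant under affine rescaling of the data. Genes
without a measurement receive the uninformative score 0.5. An edge's
presence probability is the product of its endpoint scores, and all edges
are independent Bernoulli variables. No probability floor is applied: a
zero-score endpoint genuinely kills every path through its edges, which is
the intended reading of "this gene shows no evidence of involvement".

**Paths and run modes.** A path is an acyclic sequence of 2–5 consecutive
edges between two list genes, with probability equal to the product of its
edge probabilities. In *downstream* mode every directed edge must be
traversed along its direction. In *upstream* mode the path must decompose
into a nonempty prefix traversed against edge direction followed by a
nonempty suffix traversed along it — the apex is then a common regulator of
both terminal genes — and the first and last edges must be of a regulatory
type (`pd`/`srna` by default, configurable). Undirected edges may serve in
either segment and may be regulatory terminals if their type qualifies.

**Objective.** Over a gene list $L$ the selected sub-network $S$ maximizes

$$O(S) = \sum_{A \in L} P(\mathrm{path}(A,\cdot)\mid S) - x_c\,|S|,$$

where the first term is the probability that $A$ is connected to at least
one other list gene by a surviving path, and $x_c$ penalizes each selected
edge. Computing connectivity exactly over all paths of a network is
NP-hard, so the probability is evaluated over a retained set of paths: the
$k$ most likely mode-valid paths per ordered gene pair, found once in the
full probabilistic network. Restricting $S$ can invalidate retained paths
but paths are never re-enumerated per candidate — matching the view that
the retained set defines the search space.

## Exact union probability

Over the retained paths the connectivity term is computed *exactly*.
Because paths share edges, the events "path i fully present" are positively
correlated and the independent-paths formula would overstate connectivity;
each physical edge is one Bernoulli variable shared across all paths and
all start genes. The implementation splits the path family into
edge-disjoint groups (independent factors) and evaluates each group by
Shannon expansion, conditioning on the edge shared by the most paths, with
closed forms for single paths, pairs, and fully disjoint families. The
kernel is compiled (`src/union_prob.cpp`) because it sits in the inner loop
of the optimizer; it is worst-case exponential in the number of involved
edges but the component split and the small path length bound keep real
instances shallow. A pure-R $2^m$ enumeration (`brute_force_union()`)
serves as an independent oracle in the tests, with agreement required to
1e−9.

## The greedy search

The climber starts from the empty edge set and repeatedly applies the best
strictly improving move. The candidate universe is the union of edges on
retained paths: any other edge adds penalty but no connectivity, so
excluding it is lossless (this is asserted in the tests, not assumed). The
move set contains single-edge additions, single-edge removals, and
whole-path additions (adding all missing edges of one retained path).
Path-level moves are necessary, not cosmetic: the shortest valid path has
two edges, so from the empty set no single-edge addition can complete a
path — every such move has gain $-x_c \le 0$ and a purely edge-level
climber could never leave the start state. Single-edge moves are evaluated
first; path moves are consulted only when no edge move improves, and the
search stops when neither does. Removals let the climber undo additions
made redundant by later ones.

Determinism: ties in gain are broken by move kind (addition, then removal,
then path addition) and then by the lexicographic key of the edge or path;
gains below 1e−12 are treated as zero so floating-point noise cannot cycle
the search. The final sub-network is verified to be a single-edge local
optimum (`is_local_optimum()`), its objective is nonnegative (the empty set
scores zero and is always reachable), and on toy instances with at most a
dozen candidate edges the gap to the exhaustive global optimum over all
$2^{|U|}$ subsets is computed and reported by the test suite. At zero cost
the greedy result provably attains the full-universe objective even when it
selects fewer edges: when no path addition improves, every remaining path
event is almost surely covered by the already-surviving ones.

A cost sweep (`cost_sweep()`) runs independent optimizations for a strictly
decreasing cost series; the expected ordered series of growing sub-networks
is asserted on *mean* sizes across scenarios, not per instance, because
greedy search is not guaranteed monotone case by case.

## Tunable parameters

| Parameter | Default | Range | Meaning |
|---|---|---|---|
| `mode` | — | upstream / downstream | path grammar, see above |
| `cost` (x_c) | — | ≥ 0 | per-edge penalty, in units of summed connectivity probability |
| `path_length` | 4 | 2–5 | maximum edges per path |
| `k` | 10 | 5–50 | retained best paths per ordered gene pair |
| `regulatory_types` | pd, srna | any labels | types allowed as upstream terminal edges |
| `k_scope` | pair | pair / start | whether k bounds paths per (A, Y) pair or per start gene |

The path-length and k ranges are hard bounds reflecting both the biological
reach of regulatory cascades and the combinatorial cost of longer paths;
out-of-range values are rejected rather than clamped. `k_scope = "start"`
is offered because the k-best notion can also be read per start gene; the
per-pair reading is the default as it keeps the support of each union
computation balanced across gene pairs. The cost has no default: it is the
user's sparsity dial, and typical useful values on desk-scale data are
0.001–0.1.

## The synthetic scenario generator

`generate_scenario()` builds fully self-contained inputs with known ground
truth: an Erdős–Rényi-style mixed background graph (defaults: 120 `pd`, 160
`pp`, 60 `met` edges over 200 genes, average degree ≈ 3.8, chosen to
resemble the sparsity of curated microbial interactomes), over which each
planted regulator gains directed `pd` edges to its targets (2 regulators ×
20 targets by default). Target log fold changes are drawn from
Normal(±3, 1) with the sign alternating per regulator; background genes
from Normal(0, 1). The gene list collects genes with |log fold change|
above 1.5, mirroring common practice of thresholding on fold change, so
about 93% of planted targets and about 13% of background genes are listed.
Everything derives from one integer seed and regenerating with the same
spec is byte-identical.

What the generator does *not* emulate: scale-free degree distributions,
replicate-level count noise and P-value-based gene selection,
co-regulation between regulators, or unmeasured genes. Passing the
planted-recovery tests therefore shows that the method recovers hub-shaped
regulatory signal through low-expressed regulators under Gaussian noise —
not that it is robust to the full messiness of real interactomes.

## Numerical choices and degenerate inputs

* σ = 0 (all log fold changes equal) is rejected as a degenerate fit.
* Self-loops are dropped at parse time: paths are acyclic, so they can
  never participate.
* Duplicate (source, target, type) edges collapse to one; parallel edges
  of different type are distinct molecular layers and are kept.
* Gene identifiers are case-sensitive exact strings; no symbol mapping.
* Zero-probability paths are retained by the k-best search (no pruning),
  so rank truncation is well-defined even in degenerate corners.
* Expression statistics are fitted on all genes in the expression file,
  not only network genes.
* The worked-example node scores quoted in the documentation (0.98, 0.9,
  0.88) are reproduced to within ±0.03: the quoted values round the
  intermediate Φ terms, while the package computes the exact normal CDF
  (0.972, 0.882, 0.858).

## Enrichment

The enrichment test is a hypergeometric upper tail per annotation term,
with the full loaded network as the background universe (the sub-network is
drawn from the network, so the network is the sampling frame), GAF 2.x
input with `NOT`-qualified rows skipped, terms without sub-network genes
unreported, and Benjamini–Hochberg q-values alongside raw p-values. No
ontology-graph propagation is performed: annotations are used exactly as
given, which understates enrichment of general terms annotated only at
specific descendants.

## Problem sizes used in the checks

The bundled verification suite runs at desk scale: union-probability oracle
agreement on 200 random instances of up to 15 involved edges; k-best
equivalence with exhaustive enumeration on 50 random mixed graphs of up to
10 nodes in both modes; optimizer property checks on toy and small planted
scenarios; and planted-regulator recovery on 20 seeds of the default
200-gene scenario, requiring at least 16 recoveries. Genome-scale inputs
(tens of thousands of interactions) are supported by the same code paths
but are outside the bundled test envelope.

## Known limitations

* Connectivity is exact only over the retained k-best paths; genuinely
  parallel weak paths beyond the top k are invisible to the objective.
* Greedy hill climbing offers local, not global, optimality; the tests
  measure the gap on toys, where it is typically zero.
* No statistical significance is attached to the selected sub-network;
  enrichment of the result is a descriptive aid, not a selection test.
* Between-list and non-list genes appear in results only as intermediate
  nodes on retained paths.
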