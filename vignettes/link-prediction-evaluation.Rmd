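---
title: "Evaluating link prediction on sliced biomedical graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating link prediction on sliced biomedical graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linksliced)
```

## The problem

Biomedical interaction graphs — drug–target networks, protein–protein
interaction repositories, literature co-occurrence graphs — grow over time,
and a recurring question is whether the links they will gain next can be
predicted from the links they already contain. `linksliced` implements a
complete evaluation methodology for this question: slice a graph into the
part a predictor may see and the part it must predict, score candidate
links with either neighbourhood heuristics or learned node embeddings fed
to a small neural classifier, and measure the resulting rankings with
metrics that are explicit about *what* is being averaged.

Two slicing regimes are supported because they answer different questions:

* **Random slicing** (`random_slice()`) holds out a uniform 40% of links.
  It asks "can hidden links be recovered?" and, following common practice
  for embedding evaluations, keeps every connected component of the graph
  connected in the induction residual — a link is only eligible for removal
  if its endpoints remain mutually reachable without it. The defaults are
  60% induction / 10% train / 40% test, with the training positives drawn
  from *inside* the induction set: there is no reason to withhold the
  predictor's training links from the representation learner, and more
  links give better representations.
* **Time slicing** (`time_slice()`) cuts by the year each link formed and
  asks the harder, more realistic question "can the *future* be
  predicted?". Connectivity cannot be enforced here — history dictates the
  slices — and nodes whose first link falls after the cut have no trained
  representation at all, which is precisely the regime in which embedding
  methods degrade.

Negative examples are sub-sampled uniformly from unlinked node pairs at a
1:1 ratio with the positives (`sample_negatives()`). Within one experiment
a negative must never coincide with *any* positive link of the full graph
— including test positives — otherwise the labels contradict each other;
the sampler therefore excludes the full link set, not just the induction
slice. On bipartite graphs only cross-partition pairs are eligible.

## Scoring methods

### Neighbourhood heuristics

`common_neighbours()`, `adamic_adar()` and `jaccard()` score a pair
$(u, v)$ from the induction-graph neighbour sets $N(u)$, $N(v)$:

$$\mathrm{CN} = |N(u) \cap N(v)|, \qquad
  \mathrm{AA} = \frac{1}{\log |N(u) \cap N(v)|}, \qquad
  \mathrm{JI} = \frac{|N(u) \cap N(v)|}{|N(u) \cup N(v)|}.$$

Note the Adamic–Adar variant used here takes the *count of common
neighbours* as the shared item, so it deliberately ranks pairs with few
common neighbours above pairs with many. Two degenerate cases of that
formula need a convention: at $\mathrm{CN} = 0$ there is no shared
evidence and the score is 0; at $\mathrm{CN} = 1$ the formula divides by
$\log 1 = 0$, and we assign the finite cap $2/\log 2$, chosen to sit
strictly above the $\mathrm{CN}=2$ score so the formula's decreasing
ordering survives without infinities in ranked lists. The logarithm is
natural; the base only rescales scores and cannot change a ranking.

On a bipartite graph $N(u)$ and $N(v)$ live in opposite partitions and
never intersect, so the second argument's neighbourhood is replaced by its
two-hop set $\hat N(v)$ (neighbours of neighbours, deduplicated). The hat
is applied to the second argument and the A-partition node is always
passed first, so scores of unordered pairs are well defined. Whether $v$
itself should be removed from $\hat N(v)$ is a genuinely open choice; the
package keeps it by default (a node is trivially a neighbour of its own
neighbours) and exposes `hat_excludes_self = TRUE` as a sensitivity
switch — on sparse graphs the difference is at most 1 in the count.

### Embeddings and the neural predictor

`generate_walks()` produces a random-walk corpus over the induction graph:
10 walks of length 40 from every node, either first-order uniform walks or
second-order biased walks with unnormalized transition weights $1/p$ back
to the previous node, $1$ to a neighbour of the previous node, and $1/q$
otherwise (defaults $p = 2$, $q = 4$). `train_embeddings()` runs the
package's skip-gram-with-negative-sampling trainer over the corpus
(window 10, 100 dimensions, 5 negative samples, initial learning rate
0.025 with linear decay, 5 passes, single-threaded and deterministic per
seed). The trainer honours a deliberately minimal contract — every node
with at least one co-occurrence receives a vector, and co-occurring nodes
end up closer in cosine than random pairs — so it can be swapped for any
external word2vec-style implementation via the word2vec text format
(`read_embeddings()` / `write_embeddings()`). Five training passes are the
conventional default for this family of trainers; on the reference
synthetic graphs longer training compressed the embedding space and hurt
downstream ranking, so the default is left at 5.

Two post-processing steps mirror common practice:

* `line_postprocess()` concatenates a first- and a second-order proximity
  table of dimension $d/2$ each and L2-normalizes per node, the standard
  recipe for LINE-style embeddings (whose internal optimizer is out of
  scope here — any two half-dimension tables can be combined).
* `complete_table()` assigns seeded random vectors, uniform in
  $[-0.5/d,\, 0.5/d]$ per component, to nodes missing from the trained
  table — isolated induction nodes and nodes first appearing in the test
  slice — and flags them `random-init`. Walks started at isolated nodes
  emit length-1 walks, which carry no co-occurrence; such nodes fall
  through to this same fallback rather than receiving never-updated
  initialization noise labelled as trained.

`train_predictor()` fits the deliberately minimalist link classifier: the
two endpoint vectors are combined with one of five operators
(`average`, `concatenate`, `hadamard`, `weighted_l1`, `weighted_l2`;
element-wise except `concatenate`, which doubles the input), then passed
through a single hidden layer of 100 rectified linear units to a sigmoid
probability, trained on cross-entropy for exactly 7 epochs. The remaining
knobs are unavoidable implementation choices, fixed as defaults and echoed
in every saved model: Adam at its conventional rate $10^{-3}$, mini-batch
32, Glorot-uniform initialization, no early stopping, no dropout, no
validation split, inputs used raw. Batch 32 rather than a larger batch is
a considered choice: with desk-scale training sets of a few hundred
positives, a 7-epoch budget at batch 128 amounts to only ~70 gradient
steps and a visibly under-fitted model (final training loss 0.57 vs 0.37).
Because `concatenate` is order-sensitive, endpoints are always fed in
canonical order (lexicographic; A-side first on bipartite graphs), making
the result independent of how a pair happens to be written.

## Metrics: what gets averaged matters

`evaluate_ranking()` computes five metrics in two families.

**Link-equality** metrics pool all evaluated pairs, so high-degree hub
nodes — whose links are typically the easiest to predict — dominate them:

* `auroc()`: the probability that a random positive outranks a random
  negative, ties counted half. This is the one metric computed on scores
  rather than on the tie-broken order, which makes it invariant under
  strictly monotone score transforms.
* `aupr()`: the area under the precision–recall step curve, accumulated at
  each positive.
* `precision_at_k()`: the paper-trail rule for $k$ is followed — $k$ is
  derived from the number of *positives* ($k = \lceil 0.3 \cdot
  n_{pos}\rceil$ by default), not from the list length, so graphs of
  different sizes are comparable.

**Node-equality** metrics first restrict the global ranking to each node's
incident pairs (`per_node_lists()` — the list is *not* re-scored per node)
and then average per node with equal weight:

* `mean_average_precision()`: mean over nodes of the node's average
  precision.
* `averaged_r_precision()`: mean over nodes of precision within the node's
  top $R$, $R$ being that node's positive count.

Nodes with no positive in the evaluation set are excluded from both
averages — their average precision is undefined — which is the standard
information-retrieval convention. Everywhere except AUROC, ties are broken
lexicographically on the canonical pair *before* metric computation, so
every reported number is reproducible to the last digit.

`aggregate_runs()` implements the reporting protocol: three independent
runs per method (each run re-slices and re-samples negatives under seed
`base + run`), mean and standard deviation per metric, and a two-tailed
pooled-variance t-test of every method against the best one at
$\alpha = 0.05$. Two caveats are deliberate: with $n = 3$ the test has
very little power, so "not-different" verdicts are weak evidence; and
zero-variance groups (identical runs) are handled by an exact-equality
fast path rather than an undefined t statistic.

## The no-common-neighbour diagnostic

Links between nodes that share *no* induction-graph neighbour are exactly
the links CN-family heuristics cannot recall (CN scores them 0), and
arguably the most interesting predictions — the unexpected ones.
`find_no_cn_positives()` identifies them (endpoints absent from the
induction graph count: their neighbourhoods are empty), and
`top_half_fraction()` measures how a method ranks them: with balanced
positives and negatives a good predictor should place most true links
above the midpoint `floor(n/2)` of the full list. Because CN scores these
links 0 and ties are broken lexicographically, the CN fraction is
deterministic but convention-dependent; the report therefore also carries
an `expected` variant giving the expected fraction under random ordering
within tied-score groups.

## The synthetic generator

`generate_graph()` draws a stochastic block model: nodes assigned
contiguously to blocks, within-community pairs linked with `p_intra`,
between-community pairs with `p_inter`. An SBM was chosen over
preferential-attachment models because community structure is the signal
*both* method families exploit — neighbourhood overlap directly, walk
embeddings through walk locality — which is the regime the evaluation
contrasts. In bipartite mode blocks alternate partitions, consecutive
block pairs form drug–target-like communities, and only cross-partition
pairs are eligible, so `p_intra` governs within-community cross-partition
density. Link years are drawn with density proportional to
$\mathrm{rank}^{\,\mathrm{skew}}$ over the year range: skew 0 is uniform
and larger skews concentrate links in late years, reproducing the
late-publication bias of literature-derived graphs, under which
time-slicing strands a sizeable fraction of nodes (about 15% in
literature-scale protein-interaction corpora) outside the induction slice.
Years attach to links, not nodes; a node's first occurrence is derived,
as in co-occurrence corpora. `generate_split_scenario()` returns the
generator's ground truth (first-link year per node, block labels) so
downstream claims — e.g. that the `random-init` fraction of a completed
embedding table equals the true unseen-node fraction — are checked against
construction, not recomputed estimates.

What the generator does **not** emulate: heavy-tailed degree
distributions, degree assortativity, and the sheer scale of real
repositories. Tests passing on SBM graphs therefore demonstrate that the
pipeline's machinery is correct and that its qualitative contrasts
(embeddings recover no-common-neighbour links; baselines hold up on small
graphs) hold under clean community structure — not that any particular
real-world score will be attained.

## Reference conditions and problem sizes

The package's reference study (also run by `scripts/acceptance.R`) uses an
SBM with $n = 400$ nodes, 4 blocks, $p_\mathrm{intra} = 0.25$,
$p_\mathrm{inter} = 0.02$ (~6,000 links), random 60/10/40 slicing, three
runs, CN and Jaccard baselines against uniform-walk embeddings combined by
concatenation. The small-graph regime uses $n = 60$ with
$p_\mathrm{intra} = 0.4$, $p_\mathrm{inter} = 0.01$ — a contrast strong
enough that CN alone reaches AUROC above 0.7, the operational meaning of
"strong community signal" used throughout the tests. Unit tests run the
same machinery at smaller sizes (12–200 nodes) chosen so the full suite
stays comfortably within a coffee break on one CPU.

## Numerical conventions, degenerate inputs, limitations

* Unordered pairs are stored canonically (lexicographically smaller id
  first); all set operations on pairs go through this form.
* Duplicate edge-list observations collapse to one link keeping the
  *earliest* year — a link "forms" at first observation; self-links are
  dropped and counted.
* Jaccard returns 0 on an empty union; AUROC refuses single-class input;
  MAP refuses rankings in which no node has a positive.
* `random_slice()` reports the maximum removable fraction when a request
  is infeasible (a tree admits none; a cycle exactly one).
* The connectivity-preserving removal is greedy over a shuffled candidate
  order; since removing an edge can only create bridges, never destroy
  them, a single pass is exhaustive for that order. Different orders can
  admit slightly different maxima; the split fractions are exact to within
  one link.
* Known limitations: the SGNS trainer is single-threaded (determinism over
  speed); LINE's and SDNE's internal optimizers are intentionally not
  implemented (the former is represented by its post-processing, the
  latter exceeds desk-scale resources by design); significance verdicts at
  $n = 3$ runs are fragile and should be treated as protocol
  reproduction, not inference.
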