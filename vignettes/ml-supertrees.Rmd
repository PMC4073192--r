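---
title: "Approximate maximum-likelihood supertrees: model, search and tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Approximate maximum-likelihood supertrees: model, search and tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlsupertree)
```

## The model

A supertree analysis amalgamates a collection of partially overlapping
phylogenies — typically gene trees, each on a subset of the taxa of
interest — into a single tree on the union of their taxa. `mlsupertree`
treats this as a likelihood problem. Each input tree $T'_i$ with taxon set
$\Upsilon_i$ is modelled as a subsample of the candidate supertree $T$:
restrict $T$ to $\Upsilon_i$, and allow the reconstruction of $T'_i$ to have
been distorted topologically. The probability of observing $T'_i$ is taken
to decay exponentially in the Robinson–Foulds symmetric difference
$d(T'_i, T|_{\Upsilon_i})$:

$$\Pr(T'_i \mid T, \Upsilon_i) \;=\; \alpha\, e^{-\beta\, d(T'_i,\; T|_{\Upsilon_i})},$$

where $\alpha$ is a normalising constant and $\beta$ weights the quantity
and quality of the data behind the input trees. Input trees are
conditionally independent given $T$, so the supertree's log-likelihood is
the sum of the per-tree terms:

$$\ell(T) \;=\; \sum_i \left[\ln \alpha - \beta\, d_i\right]
          \;=\; k \ln \alpha - \beta \sum_i d_i .$$

The likelihood is *approximate* because $\alpha$ is not normalised per input
tree: the exact constant is the (size-dependent) count of trees at each
distance, which is expensive to compute. For small $\beta$ the constants
reduce to a value well approximated by $\alpha = 1$ irrespective of
input-tree size, and — crucially — $\alpha$ enters $\ell$ only through the
additive constant $k\ln\alpha$, so no choice of $\alpha$ can reorder
candidate supertrees. The package's defaults are $\alpha = 1$, $\beta = 1$,
under which $\ell(T) = -\sum_i d_i$ exactly: the ML supertree is the tree
minimising the total symmetric difference to the input set, i.e. a median
tree under the RF metric. Both parameters are exposed in `sr_model()` so the
shift/scaling identities can be exercised programmatically, but the
command-line interface pins $\beta = 1$: per-tree $\beta$ values would
require per-tree reliability estimates that the inputs do not carry.

Two conventions matter and are fixed throughout:

* **Distances are unrooted.** $d$ counts non-trivial splits (bipartitions
  induced by internal edges) of the derooted topologies. Rooted inputs are
  accepted and derooted internally for scoring; explicit `deroot()` /
  `reroot_on()` utilities are provided.
* **The full symmetric difference is counted**, not the halved variant:
  $d = |S_1 \,\Delta\, S_2|$. Using the halved convention would silently
  rescale $\beta$.

Input trees with fewer than 4 taxa in common with the supertree carry no
non-trivial splits; they are scored (contributing $\ln\alpha$) and flagged
with a warning rather than rejected — they are degenerate but harmless.

## Scoring machinery

Splits are encoded canonically: a bipartition is represented by the side
containing the first taxon in sorted label order, so both orientations
compare equal. Internally the scorer assigns each taxon a bit (in 30-bit
words, so taxon sets of any size stay in exact integer arithmetic) and
computes a candidate's distances to all input trees by restricting the
candidate's split masks to each input tree's taxon mask — equivalent to
prune-then-RF but without rebuilding pruned trees. The public
`score_supertree()` path and the brute-force prune/enumerate route are
checked against each other (and against independent split enumeration) in
the test suite.

## Search

Hill climbing operates on binary unrooted trees through subtree
pruning-and-regrafting (SPR) neighborhoods: every edge defines a candidate
subtree, which is detached (suppressing the resulting degree-2 node) and
reattached onto every other edge of the remaining tree; duplicate
topologies and the original are removed. Polytomous starting trees are
resolved randomly (with a warning) — the optimum over resolutions is never
worse than the polytomous tree itself.

Four strategies span the speed/exhaustiveness spectrum; their precise
semantics are this package's own, documented definitions:

1. **Steepest ascent** — evaluate the full neighborhood, move to the best
   strictly improving neighbor (ties broken at random).
2. **First improvement** — scan the neighborhood in random order, accept
   the first strict improvement.
3. **Radius-limited steepest ascent** — as 1, but regraft destinations are
   confined to within 3 edges of the pruning point (edge-to-edge distance
   measured in the pruned tree; adjacent edges are at distance 0).
4. **Greedy subtree sweep** — one pass over the subtrees in random order,
   each immediately regrafted to its best strictly improving destination;
   the fastest and least exhaustive mode, and the default.

An *iteration* is one full neighborhood pass (1–3) or one sweep (4). Only
strict improvements are accepted: the RF-based score is piecewise constant
with large plateaus, and lateral moves would require cycle detection to
guarantee termination. The cost is that plateaus are never crossed, which
is the main reason multiple restarts help. `stepwise_addition_start()`
builds restarts greedily: taxa are shuffled, the first three form the
unique 3-leaf tree, and each further taxon is inserted on the edge
maximising the score against the input trees restricted to the taxa placed
so far. All randomness flows from a single recorded seed;
`bootstrap_support_analysis()` derives replicate seeds as `seed + replicate
index` so replicate streams are independent but reproducible.

`exhaustive_ml_supertree()` enumerates all $(2n-5)!!$ binary unrooted
topologies for up to 8 taxa ($\le 10\,395$), providing an exact optimum
against which the heuristics are validated.

## Bootstrap support and hypothesis tests

Support values follow the tree-resampling protocol: replicates are drawn
from the *input trees* with replacement (not from characters — no sequence
data is involved), the ML search is run on each replicate over the original
union taxon set, and the replicate optima are summarised by a strict
(`> 50%`) majority-rule consensus. The strict threshold makes the retained
splits pairwise compatible by construction; a split occurring in exactly
half the replicate optima is excluded. The ML tree from the original data
is additionally annotated with the percentage of replicate optima
containing each of its splits, and `split_support()` reports the support of
any queried split, present in the consensus or not.

For a-priori hypotheses, `score_hypotheses()` + `rank_hypotheses()` produce
a likelihood ranking, and `winning_sites_test()` implements the classical
sign-test formulation: each input tree is won by the hypothesis fitting it
strictly better (under defaults, the smaller RF distance), ties are
excluded, and the p-value is the exact two-sided binomial tail at
$p = \tfrac12$ (all-ties gives $p = 1$ by convention). The tie handling and
two-sidedness are this package's documented choices; with more than two
hypotheses, `winning_sites_vs_best()` runs all pairs against the rank-1
hypothesis. KH/SH/AU tests are deliberately not reimplemented:
`export_consel_matrix()` writes the per-input-tree log-likelihood matrix in
CONSEL's `.mt` text format (input trees act as sites, so CONSEL's RELL
bootstrap resamples trees), with a sidecar index-to-name map.

## The synthetic generator

`generate_input_trees()` emulates exactly the error process the model
assumes: a known binary supertree is restricted to uniform random taxon
subsets, and each restriction receives $k \sim \text{Poisson}(\lambda)$
random NNI rearrangements. NNI (rather than SPR) edits are used so the
distortion strength maps finely onto RF distance, and the Poisson count
mirrors the exponential decay of tree probability in $d$. The default
subset sizes (4–7 taxa from a 7-taxon truth, 100 trees) reproduce the shape
of a small phylogenomic study of placental mammals: hundreds of gene trees
on 4–7 of 7 taxa. At $\lambda = 0$ the inputs are exact restrictions and the
truth attains the global optimum $\ell = 0$.

What the generator does *not* emulate: correlated error across gene trees
(shared alignment or model artefacts), coalescent gene-tree/species-tree
discordance, biased taxon sampling, or rogue taxa. Recovery results on
these fixtures therefore demonstrate the correctness of the scoring and
search machinery under the model's own assumptions, not robustness to the
violations real data exhibit.

## Numerical and degenerate-case choices

* Ties (equal-scoring placements, neighbors, or sweep destinations) are
  broken uniformly at random from the seeded stream; tied hypothesis ranks
  share the smaller rank and are flagged.
* Consensus supports are reported to one decimal place; `.mt` files use
  fixed 6-decimal formatting so they are diffable.
* Single-leaf and two-leaf trees are legal I/O objects (and legal pruning
  results); scoring treats them as splitless.
* `prune_trees()` drops trees sharing fewer than 2 taxa with the retained
  set (warning); an empty result is an error.
* Reference-guided polytomy resolution adds every reference split (after
  restriction to the tree's taxa) that is compatible with the accumulated
  split set, then resolves residual ambiguity randomly. When the input tree
  is compatible with the reference this recovers the reference's
  restriction exactly, and no split of the output can conflict with it;
  when the input itself contradicts the reference, the input's splits win
  and only then can the (randomly refined) output contain
  reference-incompatible splits.

## Problem sizes and validation

The package is validated on desk-scale simulated instances chosen to make
exact cross-checking feasible: 6–8-taxon supertrees (where exhaustive
enumeration of 105–10,395 topologies provides the true optimum), 10–100
input trees, and 10–20 bootstrap replicates or seeded trials per property.
These sizes exercise every code path at full fidelity — the scorer, not the
problem size, is what the larger analyses reuse. The test suite asserts,
among others: exact agreement of `score_supertree()` with an independent
brute-force oracle on 100 random instances; the RF metric axioms against
set-algebra enumeration; SPR neighborhoods against a brute-force adjacency
oracle; heuristic/exhaustive optimum agreement; exact recovery (total 0,
true topology) on conflict-free fixtures with recovery degrading as
distortion rises; 100% bootstrap support in the conflict-free regime; and
the exact winning-sites binomial tail.

## Known limitations

* Only strict hill climbing is provided — no plateau walks, simulated
  annealing, NNI/TBR neighborhoods, or parallel searches. On large or
  highly conflicting inputs, use several restarts.
* The likelihood is approximate by design (no per-tree normalisation);
  reported values order hypotheses correctly but are not calibrated
  probabilities.
* Consensus requires identical leaf sets (as produced by the bootstrap
  protocol); no majority-rule(−) supertree construction for partially
  overlapping leaf sets is attempted.
* Branch lengths are carried through I/O but never used; there is no
  weighted-RF option.
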