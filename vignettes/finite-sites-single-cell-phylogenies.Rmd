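---
title: "Finite-sites maximum-likelihood phylogenies from single-cell genotype matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finite-sites maximum-likelihood phylogenies from single-cell genotype matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scphylofit)
```

## The model

`scphylofit` infers the genealogy of single tumor cells from an
`n` sites × `m` cells genotype matrix produced by single-cell DNA
sequencing. The observed matrix `D` is modelled as a noisy readout of an
unobserved true matrix `G`, and `G` as the outcome of genotype evolution
along a rooted binary tree whose leaves are the sequenced cells and whose
root carries the homozygous reference genotype (0) at every site. Branch
lengths are expected mutations per site.

**Error model.** Two error rates connect `D` to `G`, applied
independently per entry. For binary data a true 0 is read as 1 with
probability α (false positive) and a true 1 as 0 with probability β
(allelic dropout / false negative). For ternary data (0 homozygous
reference, 1 heterozygous, 2 homozygous non-reference), dropout removes
one allele of a heterozygote so a true 1 is read as 0 or 2 with
probability β/2 each; a true 0 is mis-called 1 with probability α, and,
through an FP followed by dropout, 2 with probability αβ/2; a true 2 is
never altered. The g = 0 row therefore sums to one by construction, and
`error_rates()` rejects parameter pairs with α + αβ/2 > 1 rather than
renormalizing, since such pairs leave no probability for a correct call.
Missing entries have likelihood 1 under every true genotype, which
marginalizes them out exactly; a missing-riddled site simply carries less
information.

**Evolution model.** Sites evolve independently under a continuous-time
Markov chain on {0, 1, 2} (or {0, 1} for binary data). The point-mutation
rate 0→1 is fixed at 1, which fixes the time scale; two free parameters
express everything else relative to it: λd (deletions: 1→0, 1→2, 2→1)
and λl (LOH: 1→0, 1→2). Direct 0→2 transitions are impossible. Because
the scaled rate matrix is linear in the branch length t, transition
matrices satisfy the semigroup property, which the test suite checks to
1e-10. Unlike infinite-sites models, this chain allows back mutation,
parallel gain, and loss of mutations — the events that make real tumor
data violate the four-gamete condition (`four_gamete_test()` quantifies
such violations).

**Likelihood.** The probability of a site column is computed by
Felsenstein's pruning algorithm: partial conditional likelihoods per
genotype state are seeded at the leaves with the error-model observation
probabilities and combined post-order through `P_t = exp(Qt)` for each
branch; the root is conditioned on state 0 with probability 1. The total
log-likelihood is the sum over sites. The engine is written in C++
(RcppArmadillo); the matrix exponential uses dense Padé
scaling-and-squaring rather than an eigendecomposition shortcut so that
it stays exact when Q is defective (e.g. λd = λl = 0, where states 1 and
2 are absorbing). Partial likelihoods are rescaled per site whenever a
column maximum drops below 1e-120, so matrices with hundreds of cells do
not underflow. A likelihood evaluation costs O(m k² n) with k the number
of genotype states.

## Joint stochastic search

`run_search()` explores the joint space of topology, branch lengths,
error rates and (λd, λl). Each iteration draws one move from a fixed
categorical distribution; defaults: error-rate move 0.1, evolution-model
move 0.1, and the remaining 0.8 split over a branch-length multiplier
move (weight 0.4) and five topology proposals (0.12 each): random and
extending subtree-prune-and-regraft, stochastic NNI, and random and
extending subtree swaps. Branch lengths are perturbed by per-branch
multipliers `exp(η (u − 0.5))`, whose exact Hastings ratio (the product
of multipliers) is carried; η defaults to 0.5. Parameter proposals are
normals centred at the current value, reflected into (0, 1) for error
rates (reflection keeps the proposal symmetric) and at 0 for λ.

Acceptance is greedy — a proposal is accepted iff it improves the
likelihood — except that with probability `eps_mh` (default 0.1) a tree
or error-rate proposal is instead judged by its Metropolis ratio, using
Beta priors on the error rates whose means are the user-supplied initial
estimates (total concentration 10, i.e. deliberately wide). This
ε-branch is what lets the search escape local optima. λ moves are always
greedy, since their Beta(1.5, 10) prior only matters in the ε-branch and
their support is the half-line; this asymmetry in the scheme is a
deliberate simplification. The topology proposals are implemented in
their symmetric variants with Hastings ratio 1; the ratio only enters
the ε-branch, so greedy behaviour is unaffected. The search stops at
`max_iterations` or when the best log-likelihood has not improved by
more than 1e-6 within `no_improve_window` iterations (default 20,000 —
the "no improvement" criterion made quantitative). The best state ever
visited is returned with a full per-iteration trace, and a fixed seed
reproduces the run bit for bit.

The starting tree, unless supplied, is a random topology with all branch
lengths 1/n — a deliberately uninformative but correctly scaled
initialization (one expected mutation per branch in total).

## Ancestral reconstruction, placement, clustering

`ancestral_states()` extends joint max-product ancestral reconstruction
to noisy leaves: the bottom-up pass stores, for every node and every
possible parent state g, the child state h maximizing transition ×
subtree score (observation probability at leaves, 1 for missing); the
top-down pass fixes the root at 0 and reads the stored maximizers. Note
the recursion propagates the maximum *value* with the argmax stored as a
pointer. Leaves thus receive error-corrected states rather than raw
observations — mutation placement on a denoised tree — and a flagged
alternative would be to place from raw observations, which we do not do
because FP/FN noise would then appear as spurious terminal-branch
events. Exact score ties are broken toward the lower genotype index,
deterministically. `place_mutations()` lists every branch whose endpoint
states differ (gains and losses), ranked chronologically by edge distance
from the root. `cluster_cells()` runs k-medoids (PAM, via the cluster
package — deterministic build + swap) on the tree path-distance matrix
for k = 2..5 and keeps the k with the best mean silhouette.

## The synthetic-data generator

`simulate_dataset()` emulates the processes the inference model targets.
A random rooted binary tree is grown by recursive uniform splitting of
the cell set; branch lengths are Exponential(rate = m) draws rescaled so
the mean root-to-leaf path equals `tree_height` (default 0.5 — roughly
40% of sites mutated along a lineage, a heavily mutated tumor exome).
On each branch, Poisson(t·n) mutation events strike: fresh sites go
0→1; with probability `recur_prob` (default 0.05) an event is instead
recurrent — a parallel gain at an already-mutated site or a back
mutation — and when no fresh site remains every event is recurrent
(saturation). Heterozygous loci then undergo LOH with per-branch
probability `loh_prob` (0.05) to either homozygote, and with probability
`del_prob` (0.05) one deletion hits a contiguous run of Geometric(0.1)
length (mean 10 loci). Doublets replace a cell's column by an
entrywise merge with a random other cell (identical genotypes preserved,
every mixed pair heterozygous). Noise uses a per-cell dropout rate β_c ~
Normal(β_mean, β_mean/10) truncated to [0, 1] — truncation must be
defined even though at the default (0.2, 0.02) it is never hit — and, in
ternary mode, follows the observation model's conditional exactly
(1→0 and 1→2 each with β_c/2), keeping the simulator and the inference
model mutually consistent. Missing entries are masked i.i.d.

What the generator does *not* emulate: read-level noise (coverage,
allele counts), position-specific error rates, copy-number states, and
chromosomal linkage beyond the contiguous deletion runs. Passing tests
therefore demonstrate correctness of the method under its own generative
assumptions, not performance on any particular real data set.

Note one interaction worth knowing: with `tree_height = 0.5` the total
tree length usually exceeds 1, so the fresh-site pool saturates and the
corner-case rule forces recurrent events even when `recur_prob = 0`.
Property tests of the infinite-sites regime therefore use a lower height
(0.05–0.2) where the premise "every site mutates at most once" actually
holds.

## Numerical and design choices

* Tree comparison treats rooted trees as unrooted (the two root edges
  induce one split), excludes trivial splits, and defines the normalized
  distance as 0 when an encoding is empty (m ≤ 3, where the topology is
  forced). FN and FP distances are reported separately so multifurcating
  trees — e.g. lineage trees projected to leaf phylogenies by
  `lineage_to_phylogeny()`, which attaches internally-placed cells as
  zero-length pendant leaves — can be compared against binary truth.
* `write_newick()` orders children by the lexicographically smallest
  descendant leaf label, giving byte-identical output for topologically
  identical trees; zero branch lengths are printed, never omitted.
* `topology_count()` computes (2m−3)!! exactly with a small base-1e6
  big-integer routine, returning a character string once the value
  exceeds double precision.
* SPR regrafting splits the target branch at a uniform point; the pruned
  edge keeps its length and the dissolved attachment's length is
  absorbed by the sibling branch, so total tree length is conserved up
  to the rearranged edges.
* The search keeps node identities stable across moves (the root never
  changes id), which lets the C++ engine consume the evolving tree
  without re-canonicalization; the final best tree is re-canonicalized
  once on return.

## Validation scale

The test suite validates the likelihood against exhaustive enumeration
(trees to 5 leaves, 50 parameter draws, agreement to 1e-10), checks that
error and evolution models compose to a probability distribution (all 64
observation matrices of a 3-cell, 2-site binary instance sum to 1), and
verifies the ancestral DP against brute-force joint maximization. The
two statistical experiments run at desk scale, chosen by pilot runs as
the smallest sizes at which the effects are clearly measurable: dropout
recovery uses 12 data sets (m = 20, n = 400, β ∈ {0.1..0.4}, 50,000
iterations; Pearson r ≥ 0.9 expected), and site-scaling uses m = 10 with
n ∈ {200, 400, 600}, 10 replicates each at 60,000 iterations. At m = 10
the maximum-likelihood tree genuinely differs from the generating tree
by about one bipartition on average at n = 600 — we verified that the
inferred trees' likelihoods meet or exceed the polished true tree's in
19/20 replicates — so the residual error there reflects the information
content of the data, not search failure.

## Known limitations

Single-chain, single-threaded search: parallelism is left to independent
seeded runs. No posterior uncertainty — this is an ML point estimate; the
trace supports diagnostics but not credible sets. No rate heterogeneity
across sites, no position-specific error rates, no copy-number states,
and doublets are simulated but not modelled during inference. Error-rate
estimates at very small m are weakly identified and can absorb
homoplasy; with 20+ cells the estimates track the truth closely (see the
README example).
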