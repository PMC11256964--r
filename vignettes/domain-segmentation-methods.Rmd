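---
title: "Methods: pairwise co-membership domain segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pairwise co-membership domain segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Protein domains are compact, self-stabilizing structural units; the
empirical regularity the method rests on is that residue–residue contact
density is higher within a domain than between domains. `domseg` turns
domain segmentation into a supervised learning problem at the level of
residue *pairs*: a network predicts, for every pair $(i, j)$ of residues,
the probability $\hat a_{ij}$ that the two residues belong to the same
domain. A domain assignment $D$ of a chain of length $L$ is equivalently a
binary co-membership matrix $A_D = V_D V_D^\top$, where $V_D$ is the
$L \times K$ one-hot assignment matrix (rows of zeros for residues in no
domain). This label representation is permutation-invariant in the domain
ids, has dimension independent of the number of domains, and represents
discontinuous domains as off-diagonal blocks without any special casing.

Given a predicted $\hat A$, segmentation is maximum-likelihood decoding
under an independent-Bernoulli model over pairs:

$$
\mathcal{L}(V, \hat A) \;=\; \sum_{i < j}
  \big[\, a_{ij} \log \hat a_{ij} + (1 - a_{ij}) \log (1 - \hat a_{ij})
  \,\big], \qquad A = V V^\top .
$$

Diagonal terms never enter any sum. Probabilities are clipped to
$[\varepsilon, 1-\varepsilon]$, $\varepsilon = 10^{-4}$, before logs, so a
saturated prediction cannot produce infinities.

## Input features

Five $L \times L$ channels are computed from the C$\alpha$ trace alone:

1. the pairwise C$\alpha$ distance matrix, in Å, divided by
   `dist_scale = 10` (keeping typical values $O(1)$ for optimization
   stability; set `feature_config(dist_scale = 1)` for raw Å);
2. helix segment co-membership (1 when $i$ and $j$ lie in the same helix);
3. strand segment co-membership;
4. helix boundaries: the per-residue vector $b$ with $+1$ at a segment
   start and $-1$ at its end, broadcast along rows
   (channel$[i,j] = b[i]$);
5. strand boundaries, likewise.

Two of these choices are genuinely open and are this package's decisions:
the 2D lift of the 1D boundary vector (row broadcast preserves the
information, and the symmetrized network sees both orientations) and the
distance normalization (none is standard; a fixed global scale preserves
SE(3) invariance exactly).

Secondary structure comes either from a STRIDE/DSSP output file
(`read_ss_file()`; H/G/I map to helix, E/B to strand) or from the built-in
C$\alpha$-only geometric assigner, which keeps the package dependency-free:
helices are called where $d_{i,i+3} \in [4.4, 5.8]$ Å and
$d_{i,i+4} \in [5.5, 6.9]$ Å (the canonical $\alpha$-helical values are
about 5.1 and 6.2 Å), strands where $d_{i,i+2} \in [5.9, 7.8]$ Å with
$d_{i,i+3} \in [8.5, 11.8]$ Å excluding curved turns; helix wins where
both fire, and segments shorter than 4 (helix) or 3 (strand) are
suppressed. This is a coarse three-state assigner in the spirit of P-SEA —
adequate here because the network uses secondary structure only as a
4-channel hint on top of the distance matrix.

Because every channel depends only on pairwise distances and per-residue
labels, the feature stack — and therefore the prediction — is exactly
invariant under rotations, translations and reflections of the input
coordinates (up to floating-point roundoff in the distance computation,
at the $10^{-13}$ relative level).

## Network

A fully convolutional residual network in the trRosetta style maps the
$5 \times L \times L$ stack to an $L \times L$ logit map: an input 3×3
convolution, then `n_blocks` residual blocks
(conv – instance norm – ELU – dropout – conv – instance norm, additive
skip, trailing ELU) with dilation rates cycling through 1, 2, 4, 8, 16,
then a 1×1 convolution to a single channel. The logit map is added to its
transpose *before* the sigmoid — post-hoc symmetrization of probabilities
would not yield a coherent probability, whereas symmetric logits do; the
output is symmetric to the last bit because $z_{ij} + z_{ji}$ sums the
same two numbers on both sides. Nothing in the architecture depends on
$L$, so one weight set serves chains of any length.

The full-scale architecture is 31 blocks of 32 filters. Training minimizes
the mean binary cross-entropy over the $L(L-1)/2$ residue pairs against
the true co-membership matrix. Unstated optimization details are set to
ordinary defaults and are configurable: Adam with learning rate $10^{-3}$,
one chain per step (variable $L$ makes batching across chains awkward),
dropout 0. The output layer is initialized near zero so the untrained
network predicts $\approx 0.5$ everywhere and starts from the $\ln 2$
baseline. At each step a multi-domain chain is drawn with probability
0.65 and a single-domain chain with probability 0.35.

The convolution forward/backward passes are implemented in C++
(im2col + GEMM); instance norm, ELU and Adam are part of the same
self-contained training engine, and the analytic gradients are verified
against finite differences in the test suite.

## Greedy maximum-likelihood assignment

Exact maximization over set partitions is infeasible, so decoding is
greedy coordinate ascent (`assign_domains()`): start with $V = 0$
(`k_init = 4` columns), sweep residues in sequence order, and move each
residue to its best-scoring column whenever that is at least as good as
the null assignment, breaking ties toward the lowest column index. The
change of score for one residue touches only its $L-1$ pair terms, so each
move costs $O(L)$. When the last column is used, a fresh zero column is
appended, so the number of domains is unbounded. Up to `n_iter = 3` sweeps
are made (convergence is typically reached in two on clean inputs), with
early stopping when a sweep changes nothing.

Two details here are deliberate interpretations:

* **Moving on ties.** A literal "strictly better than null" rule can never
  leave the all-null start, because an empty column ties with null at gain
  exactly 0. Accepting ties lets the first residue of a prospective domain
  seed an empty column; its co-members then join at strictly positive
  gain. This is what makes the perfect-predictor recovery guarantee hold:
  for a clipped exact adjacency the sweep provably reconstructs the
  generating assignment, including discontinuous domains and unassigned
  residues.
* **Singleton demotion.** A domain holding a single residue contributes no
  pair terms, so it is an exact likelihood tie with the null assignment;
  terminal singletons are demoted to null, which is also how the
  exhaustive oracle breaks such ties. On a matrix with every
  $\hat a_{ij} < 0.5$ the result is therefore all-null. An optional
  `min_domain_size` filter extends this demotion to small domains
  (off by default).

`brute_force_assign()` is an independent validation oracle: it enumerates
every canonical labelling (restricted-growth order) for $L \le 10$ and
returns the global maximizer, breaking ties toward the lexicographically
smallest labelling. The tests use it to check that the greedy search never
exceeds the optimum and attains it in the large majority of random
$L = 6$ instances (about 85% measured on uniformly random matrices; such
matrices are maximally frustrated, with no consistent block structure —
the remaining cases need coordinated multi-residue rearrangements that
single-residue ascent cannot make. On near-binary matrices, the regime a
trained network produces, recovery is exact).

## Confidence

The soft adjacency is read as a multivariate Bernoulli distribution and
the final assignment's binary matrix is scored as an observation from it.
"Normalized by the number of residues" is interpreted as
$\exp(\mathcal{L}/L)$ — the geometric-mean per-residue likelihood — which
maps realistic predictions into roughly $(0.5, 1]$; per-pair normalization
($\exp(2\mathcal{L}/L(L-1))$) is available via
`confidence_score(..., normalization = "pair")`. The score is 1 exactly in
the saturated perfect-match limit and decreases continuously as the
prediction diverges from the assignment; on the synthetic noise sweep it
correlates positively with the chain IoU.

## Evaluation metrics

* **IoU** (`iou_score`): predicted and reference domains are matched
  one-to-one to maximize the total number of shared residues (exact
  bipartite matching by dynamic programming over subsets — greedy matching
  can be suboptimal and the tests include such a case); each matched pair
  scores intersection-over-union of residue sets, unmatched reference
  domains score 0, and the chain score is the mean over reference domains.
* **Correct-domain fraction** (`domain_correct_fraction`): fraction of
  reference domains, pooled across chains, whose matched IoU is at least
  0.8.
* **Boundary distance score** (`boundary_distance_score`): boundaries are
  positions where the label changes between consecutive residues
  (null transitions included). For each tolerance $t = 1..8$ the harmonic
  mean of (predicted boundaries within $t$ of a true one) and (true
  boundaries within $t$ of a predicted one) is taken, and the score is the
  mean over tolerances. Two boundary-free assignments score 1; if exactly
  one side has no boundaries the score is 0. The exact CASP formulation
  lives behind a reference whose details are not in the main text; this
  tolerance-sweep form is this package's documented interpretation.

## Synthetic chains

`generate_chain()` produces point-cloud C$\alpha$ traces with known
labels: each domain is a 3.8 Å-step random walk confined to a ball of
radius `intra_spread` (8 Å) around its centroid, centroids at least
`centroid_separation` (25 Å) apart — the separation being more than twice
the spread guarantees the within-closer-than-between premise. Linkers are
extended walks between consecutive segments, discontinuous domains revisit
their centroid after an intervening domain, and an optional disordered
tail appends unassigned residues. The generator also emits designed
secondary-structure labels (alternating helix/strand runs inside domains,
coil elsewhere). Default domain sizes are 30–120 residues, typical of
globular domains.

One consistency rule matters in practice: `make_dataset()` featurizes
training chains with the *geometric* secondary-structure assigner — the
same operator applied to a structure file at predict time — rather than
with the generator's designed labels. Training on designed labels but
predicting with geometric ones is a train/test distribution shift in the
SS channels, and it measurably degrades end-to-end segmentation of
structure files (over-splitting); with consistent features the effect
disappears. The designed labels remain available
(`use_designed_ss = TRUE`, and `generate_chain()` returns them) as ground
truth for testing the SS channel construction itself.

What the generator deliberately does not emulate: real backbone
stereochemistry, beta-sheet topology, inter-domain contacts from packed
interfaces, or the long low-confidence tails of predicted models (only
approximated by the null tail). Passing the end-to-end tests on this
geometry therefore demonstrates that the pipeline learns and decodes
contact-density structure, not that the shipped configuration reaches the
accuracy a CATH-trained full-scale model would on experimental structures.

## Study sizes and numerical choices

The test suite and the acceptance script train an 8-block / 16-filter
model for 10 epochs on 200 synthetic chains (50% single-domain; multi
chains have 2 domains with probability 0.8, otherwise 3; domain sizes
20–40 residues) and evaluate on 50 fresh chains — compact chains chosen so
the whole demonstration runs in minutes on one CPU while still exercising
discontinuous domains, null tails and both chain classes. Validation of
the assigner uses 500 random assignments up to $L = 200$ with up to 6
domains of at least 5 residues, and 200 random $L = 6$ matrices against
the exhaustive oracle. Everything is integer-seeded and fully
deterministic given those seeds.

Numerical guards worth knowing: probability clipping at $10^{-4}$
(assigner and confidence), instance-norm variance floor $10^{-5}$,
score-comparison tolerance $10^{-9}$ when checking the greedy bound, and
strict-improvement enumeration in the oracle so that score ties resolve to
the lexicographically smallest labelling.

## Known limitations

* No pretrained full-scale weights ship with the package; training on real
  CATH-annotated structures is the user's task, and headline accuracies on
  CATH/AlphaFold benchmarks are out of scope here.
* One chain at a time; no multi-chain assemblies, no structure repair.
* The geometric secondary-structure assigner is a three-state
  approximation; supply STRIDE/DSSP output where fidelity matters.
* Greedy decoding returns a single assignment; proteins with several
  defensible segmentations get one of them (the confidence score tends to
  be lower in exactly those cases).
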