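---
title: "Disease modules in hyperbolic space: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease modules in hyperbolic space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperdm)
```

## The model

Scale-free, clustered networks admit a geometric description in the
two-dimensional hyperbolic plane (curvature $K = -1$, so the curvature scale
$\zeta$ is fixed to 1 throughout). Each of the $N$ nodes sits at polar
coordinates $(r_i, \theta_i)$ inside a disk of radius $R \sim \ln N$: the
radial coordinate encodes popularity (degree), the angular coordinate
similarity. The exact distance between two nodes is the hyperbolic law of
cosines

$$d_{ij} = \operatorname{acosh}\!\left(\cosh r_i \cosh r_j -
  \sinh r_i \sinh r_j \cos\Delta\theta_{ij}\right),$$

often quoted through its small-angle approximation
$d_{ij} \approx r_i + r_j + 2\ln(\Delta\theta_{ij}/2)$. **We standardise on
the exact form everywhere**: the approximation diverges to $-\infty$ as
$\Delta\theta \to 0$ (where the package falls back to the exact limit
$|r_i - r_j|$), and its error at a fixed angle does not vanish with radius —
it tends to $2\ln\!\big((\Delta\theta/2)/\sin(\Delta\theta/2)\big)$, about
0.9 at $\Delta\theta = \pi$. The approximation is retained only for
teaching and tests (`mode = "approx"`).

Link formation follows the Fermi–Dirac connection probability

$$p(x) = \frac{1}{1 + e^{(x - R)/(2T)}},$$

where the temperature $T$ tunes geometric determinism: $T \to 0$ is a sharp
threshold at $x = R$ (maximal clustering), $T$ near 1 blurs it. Expected
degrees are $\langle k_i \rangle = \sum_{j \neq i} p_{ij}$.

### Choosing the disk radius

The mean of $\langle k_i \rangle$ over fixed coordinates is strictly
increasing in $R$, so `fit_disk_radius()` solves for the target mean degree
by bisection (relative tolerance $10^{-3}$). Inside the *generator* the
situation inverts: radii live on $[0, R]$, so growing $R$ stretches all
distances roughly twice as fast as it relaxes the threshold and the mean
degree *decreases* in $R$. The generator therefore bisects its own monotone
decreasing objective, re-deriving the radii from one fixed set of uniform
quantiles at every candidate $R$ — the stated radial density holds exactly
at the returned radius, and the whole procedure is reproducible from the
seed.

## The synthetic world

Real inputs (a curated interactome, gene–disease associations, protein
class annotations, disease categories) require downloads, so the package
ships a generator for each, with defaults chosen once to mirror the
empirical setting:

* **Network** — the static popularity–similarity model: radii with density
  $\rho(r) \propto \alpha_r e^{\alpha_r (r - R)}$, $\alpha_r = (\gamma-1)/2$
  (this yields degree exponent $\gamma$), uniform angles, Fermi–Dirac
  linking. The static form is used rather than the growing formulation
  because every evaluation formula exercised downstream is static; the two
  are equivalent in distribution for the quantities used here. The
  full-scale acceptance run uses the empirical network's fitted parameters
  ($N = 14788$, $\bar{k} \approx 20.3$, $\gamma = 2.644$, $T = 0.827$);
  tests use $N$ of a few hundred with $T$ 0.1–0.5.
* **Disease modules** — each disease receives 20–40 members (the empirical
  filter keeps diseases with at least 50 genes; we scale down with the
  network) split over 2–6 angular components, mirroring the observed
  fragmentation. Members are drawn degree-proportionally inside narrow
  sectors (hub bias mirrors annotation studies' preference for
  well-studied hubs; configurable off), with 10% uniform background.
  Component centres of a disease share one of `n_categories` angular
  blocks; the block index is the ground-truth category for clustering
  recovery.
* **Class annotations** — six disjoint sectors, one per class; in-sector
  nodes get the sector's class with probability `purity`, out-of-sector
  nodes a uniform class at a background rate.

What a green recovery test establishes is that the statistics detect the
*planted* structure — geometric concentration, hub bias, block categories —
at realistic sizes. It does not establish anything about curation biases,
false-positive interactions, or the non-uniform angular density of real
interactomes, none of which the generator emulates.

## Coordinate inference

Radial coordinates follow the degree ranking: rank $i$ (ties broken by node
id for determinism) receives $r_i = 2\beta\ln i + 2(1-\beta)\ln N$ with
$\beta = 1/(\gamma-1)$. Angular coordinates come from the two eigenvectors
of the symmetric normalised Laplacian with smallest nonzero eigenvalues,
$\theta_i = \operatorname{atan2}(y_i, x_i)$. Likelihood refinement then
sweeps nodes in decreasing-degree order, re-placing each node's angle at
the best of `n_candidate_angles` candidates under the full Fermi–Dirac
graph log-likelihood; the current angle is always a candidate, which makes
every sweep provably non-decreasing in total likelihood (with
`n_candidate_angles = 1` the sweep is the identity). Connection
probabilities are clamped to $[10^{-12}, 1 - 10^{-12}]$ before taking logs.
One sweep of 100 candidates over the full window $w = 2\pi$ is the default;
the exact internals of the reference implementation this emulates are not
published, so the refined objective is simply the model likelihood itself.

Recovery is quantified by the Fisher–Lee circular correlation. The
mean-direction variant is undefined when angles are uniform on the circle —
precisely the case here — so the pairwise T-linear form is used, in absolute
value, since reflections of the disk are immaterial.

## Statistics

* **Fragmentation tests.** Per module: component count, LCC size, and the
  mean distance from each member to its nearest co-member, in hops
  ($\langle d_s\rangle$) and hyperbolically ($\langle d_H\rangle$). Nulls
  are 1000 uniform node samples of matched size; z-tests are one-sided in
  the direction of the empirical claims (LCC larger; both means shorter).
  A null with zero spread is reported as degenerate rather than given a
  p-value.
* **Separation.** $s(A,B) = \langle d(A,B)\rangle - (\langle d(A,A)\rangle
  + \langle d(B,B)\rangle)/2$ with nearest-neighbour means; negative values
  mean overlap. Before MST construction or Ward clustering the matrix is
  shifted by its most negative off-diagonal entry (rank-preserving) and the
  diagonal set to 0.
* **ncMCE.** Minimum spanning tree over the complete module graph, all-pairs
  path lengths along the tree, SVD *without centering*; coordinates are
  singular vectors scaled by root singular values, sign-fixed by the
  largest-magnitude entry. Dimension 2 is the clustering axis.
* **C-score.** The concordance formula is not printed in the source
  literature; the package uses a transition-count reconstruction: order
  samples along the dimension, count label changes $X$ between neighbours,
  and score $(E_{rand} - X)/(E_{rand} - X_{min})$ clamped to $[0,1]$, with
  $X_{min} = k - 1$ and $E_{rand} = (n-1)(1 - \sum_c n_c(n_c-1)/(n(n-1)))$.
  This satisfies both published anchors: exactly 1 for contiguous blocks of
  any sizes, mean $\approx 0$ over random label permutations. Raw
  projection values (not ranks) are used for the ordering.
* **Greedy routing.** Each node forwards to its neighbour hyperbolically
  closest to the target (the adjacent target, at distance 0, always wins;
  ties break to the lowest vertex index). Revisiting a node or hitting a
  faulty relay fails the routing. Efficiency is the success fraction over
  500 pairs, repeated 100 times (50 for impact runs); hop stretch
  (greedy hops / BFS shortest path) is collected over successes only, where
  it is defined. Source–target pairs are drawn uniformly with replacement,
  self-pairs and faulty endpoints resampled. Disease impact injects 20
  freshly drawn faulty members per experiment and subtracts the network's
  own fault-free reference efficiency (recomputed, never hard-coded);
  degree-matched controls use non-members from the same log2-degree bins
  (nearest non-empty bin as fallback), and the two impact samples are
  compared one-sided (module more negative) by Mann–Whitney. Frequent
  faulty proteins are those above the type-7 upper quartile of the fault
  frequencies; this follows the worked convention $Q_3(\{1,1,1,9\}) = 3$.
* **Angular enrichment.** Fifteen equal bins over $[0, 2\pi)$; per bin, six
  one-sided Fisher tests; the bin takes the smallest-p class among those
  with $p < \alpha$ and odds ratio $> 1$. The significance gate is a
  package choice — ungated, every bin would always receive some class; the
  `--no-gate` option restores the ungated reading. No multiple-testing
  correction is applied by default (none is described for the original
  analysis); a Benjamini–Hochberg option exists, and under it the
  uniform-null expectation "no enriched bin in ≥ 90% of runs" holds.
  Adjacent same-class bins merge into sectors with wrap-around at $2\pi$.

## Numerical and degenerate-input choices

* `acosh` arguments are floored at 1 (they can dip below by rounding when
  $\Delta\theta \approx 0$).
* Angles are normalised to $[0, 2\pi)$ on ingestion; all angular
  separations use the minimal arc.
* Modules smaller than the fault count lower the count with a warning;
  members unreachable under the hop metric are dropped from the mean with a
  message (impossible on a connected component — defensive only).
* Degree-rank ties, next-hop ties and SVD signs all break deterministically
  (node id, vertex index, largest-magnitude entry respectively), so a seed
  fixes every output bit-for-bit.

## Known limitations

* The empirical headline numbers (157 modules, C-score 0.758, 89% impactful
  modules) depend on proprietary-scale curated inputs and are out of reach
  of the synthetic world; the package reproduces the *machinery*, with
  oracle-verified behaviour at desk scale.
* The full-scale model stand-in is *more* navigable (median efficiency
  ≈ 0.93) than the empirical network's printed 0.8: ground-truth
  coordinates route better than inferred ones. The acceptance suite
  reports the honestly computed value rather than forcing agreement.
* Embedding reproduces the published method *family* (manifold learning
  plus likelihood maximisation), not any specific implementation
  bit-for-bit.
* Only connected graphs are embeddable; callers extract the largest
  component first (`largest_component()`).
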