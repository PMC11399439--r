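---
title: "Chain-structured colocalization: model, matching and efficiency correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chain-structured colocalization: model, matching and efficiency correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chainmatch)
```

## The problem

Multi-color super-resolution microscopy images several particle species
at nanometer resolution, one color channel per species. When the
biological complex of interest is *chain-like* — exactly one particle of
each type strung together in a fixed order, e.g. adjacent loci on an
mRNA or a DNA-origami nanoruler with fluorophore spots 70 nm apart —
colocalization analysis should count how many such chains are present
and where they sit. Pairwise, geometry-uninformed analyses overcount:
one bright particle can appear in several "colocalized" pairs at once.
`chainmatch` instead searches for the largest set of *disjoint* chains,
so that every particle belongs to at most one structure.

Throughout, channels are labeled A, B, C, ... in chain order. A
*structure* is a contiguous channel span (for three colors: ABC, AB,
BC, A, B, C). A tuple of particles, one per channel of a span, is a
valid chain at colocalization distance `t` when every consecutive pair
is at distance `<= t` (inclusive; coincident points match at any
`t >= 0`).

## Matching as an unbalanced multi-marginal transport problem

Each channel's detected coordinates are support points of mass one. The
matching problem minimizes the summed consecutive-pair distances over
chains, subject to each particle being used at most once, with a reward
`lambda` per matched chain: tuples farther apart than `t` in any link
are inadmissible, and for `lambda` large enough the optimum is a
matching of *maximal cardinality* with minimal summed distance among
the maximal ones. Because the chain cost decomposes over adjacent
channel pairs, the multi-marginal program collapses to a minimum-cost
network flow:

* every particle becomes a split node pair joined by an edge of cost
  `-lambda / k'` and capacity 1 (`k'` = number of channels in the span),
* admissible adjacent-channel pairs become edges carrying the distance
  as cost (inadmissible edges are omitted entirely),
* a source feeds the first layer, the last layer drains into the sink,
  and a direct source–sink edge of cost 0 and unbounded capacity keeps
  any requested flow `m = min_j n_j` feasible.

The constraint matrix is totally unimodular, so an integral optimal
flow exists; the package solves it exactly with successive shortest
paths on integer costs (distances are discretized at `1e-6` of the
distance unit, bounding the total-cost error by `1e-6` per matched
link). Unit flows through the particle layers trace the matched chains.

### Choice of `lambda`

The incentive must be large enough that a larger matching always beats
a smaller one. A per-chain bound (anything above the largest possible
chain cost, `(k'-1) * max(t)`) is *not* sufficient: growing a matching
from `c` to `c + 1` chains can force re-routing every existing chain,
and the swap can add up to `(k'-1) * (c+1) * max(t)` distance. We hit
exactly this with `n = (5, 3)` points and `t = 6.9`: at the per-chain
bound the optimum keeps 2 pairs instead of the maximal 3. Since `c + 1`
is at most the transportable mass `m = min_j n_j`, the package defaults
to

```
lambda = (k' - 1) * m * max(t) + 1,
```

re-derived for every solved sub-problem and every threshold of an
abundance curve. Results are identical for any `lambda` above this
bound (a tested invariant). The contract of a matching is its structure
counts and total cost — individual assignments may differ between
cost-ties; node ordering is fixed (channel-major, index-minor) for
reproducibility.

### Mode I and Mode II

*Mode I* solves the full k-marginal problem first (maximal number of
full chains), removes matched particles, and re-matches the leftovers
per structure in a priority order (default: longest first,
left-to-right). It is the right mode when one chain structure is the
object of interest, and is robust in dense fields.

*Mode II* solves the k−1 adjacent-pair problems independently and
couples pairs sharing a particle (union–find); an AB and a BC pair on
the same B particle become an ABC triplet. It needs no priority order
and does not overemphasize early structures, at the price of sometimes
splitting a chain in dense fields — `nearest_neighbor_matching()` is
the greedy baseline exhibiting the same failure mode more strongly.

Whether Mode I's leftover stage re-optimizes jointly over all leftover
structures or sequentially per type is a genuinely open design choice;
we implement the sequential priority-order semantics, which makes the
priority list an explicit, user-controlled contract.

### Abundance curves

When `t` is unknown, `abundance_curve()` re-runs the matcher over a
threshold grid; Mode I full-chain counts are non-decreasing in `t`
(feasible matchings nest), reaching `min_j n_j` once `t` covers the
point cloud diameter. Relative abundances divide all counts by one
channel's particle count — channel B in the three-color analyses. For
`k >= 4` no convention exists for the scale channel, so it is a
parameter (`scale_channel`).

## Correcting for incomplete labeling efficiencies

A particle of channel `i` is successfully labeled and detected with
probability `s_i` (independent Bernoulli). A true chain is then observed
as whatever its detected subset looks like, and a *non-contiguous*
detected subset decomposes into maximal contiguous runs, each observed
as the corresponding shorter structure: a true ABC triplet whose B went
undetected is counted as an A and a C singlet. Conditional on a true
structure, the detected pattern is a single multinomial draw; with
`S = k(k+1)/2` observable structures and `2^k` patterns, the model
assembles

* `mu` (`2^k x S`): pattern probabilities per true structure,
* `theta` (`S x 2^k`): the run-crediting aggregation matrix,

so that `E[W] = theta mu n` for observed counts `W` and true abundances
`n`. With all `s_i > 0`, `theta mu` is invertible and

```
n_hat = (theta mu)^{-1} W
```

is unbiased. For k = 3 the three matrices equal the classical
three-color forms entrywise (a tested identity). The three-color model
is the canonical case; the maximal-contiguous-run rule is the
generalization consistent with its treatment of the detected-A-and-C
case, e.g. for k = 4 the pattern A·CD yields one A singlet and one CD
pair. Estimates can be negative —
unbiasedness requires reporting them raw; clipping is left to the user.

### Confidence regions

Summing the per-structure multinomial covariances gives
`Sigma(n) = sum_i n_i (diag(p_i) - p_i p_i^T)`; plugging in `n_hat`
(entries floored at zero only inside this plug-in, keeping `Sigma`
positive semidefinite) yields the quadratic statistic

```
Xi(n0) = (n_hat - n0)^T (theta mu)^T (theta Sigma theta^T)^{-1} (theta mu) (n_hat - n0),
```

asymptotically chi-squared with `S` degrees of freedom; if the metric
is singular (singular values below `1e-10` of the largest) its
pseudoinverse is used and the degrees of freedom drop to the rank. The
`1 - alpha` region is `{n0 : Xi(n0) <= chi^2_{df, 1-alpha}}` — the
upper-`alpha` critical value; this is the only quantile convention
under which the nominal 90% region at `alpha = 0.1` covers 90%, which
the tests confirm empirically (89–90% over 10,000 draws at
`n = (500, 50, 50, 50, 50, 50)`, `s = 0.95`). Per-structure intervals
are axis-aligned *slices* of the ellipsoid through the estimate (all
other abundances fixed), with closed-form half-width
`sqrt(chi2_crit / Q_jj)`; slices, not shadows, because the reported
intervals condition on the other estimated abundances. Curve bands from
`corrected_abundance_curve()` are pointwise in `t`; simultaneous bands
are out of scope.

```{r correction-example}
model <- substructure_model(3, s = 0.95)
set.seed(1)
W <- simulate_misdetection_counts(c(ABC = 500, AB = 50, BC = 50,
                                    A = 50, B = 50, C = 50), model)
est <- estimate_true_abundances(W, model)
ci <- confidence_region(est, alpha = 0.1)$intervals
ci[-1] <- round(ci[-1], 1)
ci
```

## What the simulator emulates

`sim_scenario()`/`simulate_chain_points()` mirror the nanoruler imaging
setup: 400 x 400 px frames at 25 nm/px, chain links drawn with mean
70 nm = 2.8 px and sd 0.5 px, anchored at the channel-B particle
(uniform on the frame). `near_linear` geometry puts the outer triplet
partners at angles `alpha` and `alpha + pi + eps`, `eps ~ N(0, 0.2)` —
approximately straight chains; `curled` draws every link angle
uniformly. Coordinates are rounded to the integer pixel grid (an
instance leaving the frame is redrawn whole); rounding alone perturbs
each link by up to `sqrt(2)` px, which is why abundance curves
stabilize around 4–5 px rather than at the true 2.8 px. Rendering gives
every particle an isotropic Gaussian spot with FWHM 40 nm
(`sigma = FWHM / (2 sqrt(2 ln 2))` ≈ 0.68 px) and Poisson pixel noise;
the exact photon-budget parameters of the experimental reference
renderer are not restated anywhere, so peak amplitude (default 100
counts) and background (default 1 count, times `noise_scale`, 10 in the
four-color setting) are package choices exposed in the scenario —
absolute intensities are not reproducible, pattern geometry and
detection statistics are.

The simulator does **not** emulate: fluorophore blinking/photobleaching
dynamics, anisotropic or spatially varying point-spread functions,
chromatic aberration or drift, nanoruler misfolding/clumping, or 3D
structure projected into 2D with out-of-plane rotation. Passing tests
on simulated data therefore demonstrate correctness of the matching and
correction machinery under the stated point-process model, not detector
robustness on degraded experimental images.

## Spot detection

The detector (Gaussian smoothing, default `sigma = 0.7` px to match
the rendered spot width; strict 8-neighborhood maxima above
`median + 8 * mad` of the smoothed image; non-maximum suppression at
2 px; 3 x 3 intensity-weighted centroid refinement) is deliberately
minimal — upstream object detection is a pluggable step, and any
coordinate list or distance matrix can be fed to the matcher directly.
It is 2D, matching the simulator's output; the matcher and the
correction machinery accept 2D or 3D coordinates and per-pair
thresholds throughout.

## Numerical choices and problem sizes

* Distance ties at exactly `d = t` are admissible (inclusive rule).
* Flow costs are integers at scale `1e6` (times `k'`, keeping the
  `-lambda/k'` split costs integral); the induced cost tolerance is
  below `1e-6` per matched link and the matching itself is unaffected
  except between cost-ties closer than the discretization.
* The exhaustive test oracle enumerates endpoint subsets layer by
  layer — exact for the `n_j <= 5` instances used in the equivalence
  tests and independent of the flow solver.
* The shipped test-and-validation runs use 25 images per simulated
  scenario (larger batches add nothing at these tolerances), 200 random oracle
  instances, and 10,000 multinomial draws for unbiasedness and
  coverage; these sizes reproduce the reported summary statistics well
  within their tolerances.

## Known limitations

* Estimated abundances are unbiased but not variance-optimal; for very
  small counts the chi-squared approximation of `Xi` degrades.
* Dense particle fields are fundamentally ambiguous: chance proximity
  is indistinguishable from true assembly at a single `t`. Singlet
  abundances at moderate thresholds systematically absorb a small
  Poisson number of chance matches; abundance curves over `t` are the
  recommended diagnostic.
* Labeling efficiencies are assumed known; estimating them from data is
  out of scope.
* Tree-shaped (non-chain) structures do not reduce to a network flow
  and are not supported.
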