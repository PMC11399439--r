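# chainmatch

Geometry-informed, object-based colocalization analysis for multi-color
super-resolution microscopy. `chainmatch` is for experimentalists and
image analysts who label k particle species (color channels A, B, C,
...) that assemble into **chain-like structures** — one particle of each
type in a fixed order, consecutive neighbors within a colocalization
distance *t* — and who want to count and locate those chains without the
overcounting that pairwise colocalization tools suffer from: here every
particle belongs to at most one structure.

## The method in brief

Given per-channel coordinate lists X⁽¹⁾, ..., X⁽ᵏ⁾ (or user-supplied
distance matrices for adjacent channel pairs), an optimal
**d_t^k-matching** is the largest collection of pairwise-disjoint chains
(x⁽¹⁾, ..., x⁽ᵏ⁾), x⁽ʲ⁾ ∈ X⁽ʲ⁾, with d(x⁽ʲ⁾, x⁽ʲ⁺¹⁾) ≤ t for all j;
ties are broken by minimal summed distance. This is an *unbalanced
multi-marginal optimal transport* problem with chain-structured cost

  c(x₁, ..., x_k) = Σⱼ d(xⱼ, xⱼ₊₁) − λ  (admissible links only),

which the package solves exactly as an **integer minimum-cost network
flow** (split node per particle, admissible links as edges, a zero-cost
source–sink bypass; total unimodularity guarantees integral optima).
Two matching modes are provided: **Mode I** (chain-first multi-marginal
matching, then leftover re-matching in priority order) and **Mode II**
(independent adjacent-pair matchings coupled through shared particles).
Abundances w = (w_ABC, w_AB, w_BC, w_A, w_B, w_C) are reported for a
fixed *t* or as curves w(t) over a threshold range.

For incomplete labeling efficiencies s_i ∈ (0, 1] (independent Bernoulli
detection per particle), observed counts W follow a sum of per-structure
multinomials with E[W] = Θμ n, and

  n̂ = (Θμ)⁻¹ W

is an **unbiased estimator** of the true abundances n, with asymptotic
chi-squared confidence ellipsoids from the plug-in covariance
Σ(n̂) = Σᵢ n̂ᵢ (diag(pᵢ) − pᵢpᵢᵀ) and per-structure interval slices.
A STED-like simulator (400 × 400 px, 25 nm/px, 70 nm chains, 40 nm FWHM
spots, Poisson noise) and a local-maxima spot detector close the loop
from ground truth to intensity images to detected abundances.

See `vignettes/chain-colocalization.Rmd` for the full model account.

## Worked example

Simulate a three-color frame with 100 ABC triplets, 50 AB and 50 BC
pairs and 50 singlets per type, render it, detect spots and match:

```r
library(chainmatch)
set.seed(42)
sc  <- canonical_scenario("3")        # 100 ABC, 50 AB, 50 BC, 50 A/B/C
gt  <- simulate_chain_points(sc)
img <- render_sted_image(gt)
clouds <- detect_spots(img)
clouds
#> point_cloud_set: 3 channels (A,B,C), 2D, unit = px
#>   counts: 199, 244, 197

res <- match_chains(clouds, match_config(t = 5, mode = "I",
                                         scale_channel = 2))
res$abundance
#> ABC  AB  BC   A   B   C
#> 104  47  45  48  48  48
round(res$abundance / clouds$counts[2], 3)
#>   ABC    AB    BC     A     B     C
#> 0.426 0.193 0.184 0.197 0.197 0.197
```

The detected relative abundances (scaled by the channel-B count, true
values 0.4, 0.2, 0.2, 0.2, 0.2, 0.2) recover the simulated mixture; the
small triplet excess comes from chance proximities at t = 5 px.

Correct observed counts for 95% labeling efficiency and attach 90%
confidence intervals:

```r
model <- substructure_model(3, s = 0.95)
set.seed(43)
W <- simulate_misdetection_counts(c(ABC = 500, AB = 50, BC = 50,
                                    A = 50, B = 50, C = 50), model)
W
#> ABC  AB  BC   A   B   C
#> 428  64  74  76  51  76
est <- estimate_true_abundances(W, model)
ci <- confidence_region(est, alpha = 0.1)$intervals
ci[-1] <- round(ci[-1], 1)
ci
#>   structure estimate lower upper
#> 1       ABC    499.2 492.2 506.2
#> 2        AB     46.0  38.8  53.1
#> 3        BC     57.0  49.8  64.2
#> 4         A     52.7  43.8  61.6
#> 5         B     47.3  40.1  54.5
#> 6         C     52.2  43.5  60.9
```

The raw counts underestimate triplets (428 observed of 500 true, since
a triplet survives intact with probability 0.95³) and overestimate
pairs and singlets; the corrected estimates recover the truth within
their intervals.

A thin command line sits over the same functions
(`inst/cli/chainmatch.R`): subcommands `match`, `curve`, `correct`,
`simulate`, `detect`, `evaluate`, each writing CSV outputs plus a
`manifest.json` recording config, seed and versions.

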