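---
title: "Modeling chromatin conformation ensembles from 5C/Hi-C interaction frequencies"
author: "chromconf developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling chromatin conformation ensembles from 5C/Hi-C interaction frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromconf)
```

## The model and its assumptions

Chromosome conformation capture assays (5C, Hi-C) measure pairwise
interaction frequencies between genomic restriction fragments in a
population of cells.  `chromconf` models the fiber as an ordered set of
3D points `S(1..n)` — one per restriction site or bin, connected
conceptually by a piecewise-linear curve — and links geometry to signal
with a power law:

\[ IF(i,j) \;=\; \psi \, D_S(i,j)^{-\alpha}. \]

Assumptions worth stating explicitly:

* **No structural prior.** There are no excluded-volume, fiber-packing
  or polymer-physics constraints; the posterior is the likelihood.
  This keeps the model unbiased but means coincident points are only
  excluded dynamically (a proposal creating a zero distance scores
  `-Inf` and is always rejected).
* **Independent Gaussian noise.** 5C observations are
  `Normal(IF(i,j), sigma(i,j)^2)` with per-pair standard deviations
  supplied by the data (replicate-derived).  Hi-C counts are
  approximated by `Normal(r(i,j), r(i,j) + kappa)`; the variance floor
  `kappa` (default 10 counts) protects near-zero expected counts.
* **Scale handling.** For Hi-C the expected counts are normalized per
  evaluation so the model total equals the sequencing total; as a
  consequence the Hi-C likelihood is invariant under a global rescaling
  of the structure and only relative geometry is identified.  For 5C,
  `psi` fixes an absolute scale.
* **Mirror ambiguity.** Distances cannot distinguish a structure from
  its mirror image; enantiomers have identical likelihood.  All
  ensemble comparisons therefore use the reflection-invariant metric
  `dist(S,T) = sqrt(sum_{i<j} (D_S - D_T)^2)`, and `superpose()` can
  mirror before aligning.

Unmeasured pairs (the 5C even–odd primer mask, Hi-C missing cells) are
excluded from every likelihood sum, never imputed.  Input standard
deviations below `1e-6 * max(IF)` are clamped to that floor so a
degenerate replicate estimate cannot acquire infinite weight.

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `alpha` | 2 | — | distance exponent; 2 is the value retained by cross-validation on real 5C data, and values between 1 and 3 are typically not distinguishable |
| `psi` | 1 | IF·(distance unit)^alpha | power-law scale; `estimate_scale()` calibrates it so short-range pairs sit at the packed-chromatin distance (~50 nm for a typical design) |
| `kappa` | 10 | counts | Hi-C variance floor |
| `radius` | 0.25 | distance units (nm once calibrated) | Metropolis proposal ball radius |
| `mixing_threshold` | 0.10 | fraction | two-chain within/cross agreement declaring mixing |
| `k0` | 1e5 | iterations | first mixing checkpoint; checks at `k0 * 2^j` |
| `n_samples` | 250 | — | ensemble size per chain after mixing |
| profile `r` | 1.0 | distance units | sphere radius for density/compaction/looping |
| profile `step` | 10 | bases | stride between evaluated positions |

The sampler checks mixing at geometrically growing milestones because
the collection schedule is only defined relative to the (unknown)
mixing iteration `k`: at each milestone the 11 snapshots
`R_{k/2}, R_{k/2+k/20}, ..., R_k` per chain are compared — the mean
pairwise structure distance within chain A's snapshots against the mean
over all cross-chain pairs, with chain A's within-run mean as the
denominator and a two-sided, boundary-inclusive 10% band.  Milestone
doubling makes each new check reuse the previous milestone as its
`k/2` snapshot, so no iterations are wasted.  After mixing, samples are
collected every `delta = k/20` iterations, the spacing at which
successive samples are effectively independent.

## What the synthetic generator emulates — and what it does not

`make_structure()` provides gold standards (random walks, helices,
two-domain structures, hairpins); `simulate_5c()` draws
`IF^ ~ Normal(psi * d^-alpha, (cv * IF + sigma0)^2)` truncated at zero,
records the per-pair sigma exactly as the likelihood expects, and can
apply the even–odd measurability mask of real 5C primer designs (a
41-fragment masked dataset, ~420 measured pairs, mirrors the published
data shape).  `simulate_hic()` draws multinomial counts with
proportions `d^-alpha` at a fixed sequencing total.

What it does **not** emulate: microarray intensity preprocessing and
outlier exclusion, gene-desert normalization, genomic-distance-dependent
noise structure beyond the `cv * IF + sigma0` form, mappability/GC
biases of Hi-C, and population heterogeneity (the data are
population-average; an ensemble describes uncertainty about the
*average* conformation, not the cell-to-cell distribution).  A green
recovery test therefore establishes that the sampler inverts its own
forward model at desk scale — not that real chromatin is recovered at
any particular accuracy.

The noise defaults are `cv = 0.1`, `sigma0 = 0.01 * mean(IF)`; real
microarray 5C data is considerably noisier (long-range interaction
frequencies sit near background), which matters for sampling behavior
(below).

## Numerical choices

* All probability math is in log space; per-pair terms are cached so a
  single-point move costs `O(pairs touching the point)` for 5C.  For
  Hi-C the scale normalizer couples all pairs, so the `d^-alpha` cache
  is updated locally but the density sum is recomputed in `O(pairs)`.
* The compiled chain re-sums the cached per-pair terms at every
  snapshot, so reported log posteriors carry no incremental drift
  (verified to 1e-8 relative against full recomputation).
* Proposal displacements are volume-uniform in the closed ball
  (rejection sampling from the cube); the kernel is symmetric, so no
  Hastings correction is needed.
* Property spheres are closed balls (boundary bases count) and the
  center base counts itself: density >= compaction >= 1.  Density and
  compaction are non-decreasing in the radius; **looping is not** — a
  growing sphere can swallow the gap that separated a looping segment
  from the run through the center, converting looping bases into
  compaction.  Only the identity `density = compaction + looping` is
  exact at every radius.
* The base curve maps each restriction site to its fragment start (the
  cut site) and covers the half-open span `[first site, last site)`, so
  base counts equal genomic spans exactly.
* Ward clustering uses `hclust(method = "ward.D2")`: the structure
  metric *is* a Euclidean distance (between flattened upper-triangle
  distance matrices), so this is exact Ward linkage.  k-means operates
  on the same flattened representation, which keeps it
  rotation/reflection-invariant and comparable.
* Ties: the LOOCV argmin takes the smaller exponent; cluster
  representatives take the earliest (chain, iteration) maximum; the
  greedy reliable-subset seed takes the lexicographically smallest pair
  and later additions the smallest fragment index.

## Fitting point estimates (LOOCV internals)

Leave-one-out cross-validation of `alpha` refits a maximum-posterior
structure for every held-out pair.  The fit is a short MCMC run
followed by an accept-only-improvement polish, with two pragmatic
refinements that experience with the plain recipe forced:

1. **Distance-geometry initialization.** From a random start,
   single-point moves frequently lock into misfolded local optima whose
   held-out predictions are bad enough to distort the MSE ordering of
   exponents.  The first start is therefore the classical-MDS embedding
   of the IF-implied distance matrix (shortest-path completion for
   unmeasured pairs); additional restarts are random, and the best
   final log posterior wins.
2. **Annealed polish radius.** An accept-only phase with proposal
   radius `rho` stalls at a geometry error of order `rho`; the polish
   therefore steps the radius down (factor-4 schedule) instead of using
   a single value.

During every fold fit the scale is re-fit per evaluation (model IF
total matched to the observed total), so candidate exponents compete on
geometry rather than on scale.  The prediction for the held-out pair
uses the scale fitted at the final structure.  Folds whose removal
leaves a fragment with fewer than two measured pairs are skipped with a
warning; datasets beyond 200 measured pairs may subsample folds (seeded
and recorded).

## Sampling behavior and a known limitation

Posterior sharpness controls whether the plain single-point sampler can
reach the global basin from a random start.  On a 41-fragment masked
synthetic dataset we measured the fraction of chains reaching the
global basin within 2e7 iterations as a function of the noise scale:
5/8 at `cv = 0.1`, 7/8 at `cv = 0.2`, 8/8 at `cv = 0.3`.  A chain
trapped at `cv = 0.1` stayed trapped out to 1.6e9 iterations (log
posterior ~300 nats below the basin), and the within/cross mixing ratio
plateaued near 0.9 indefinitely; smooth helical gold structures trap
just as often as crumpled random walks.  With realistically noisy data
(`cv = 0.3`, comparable to replicate error in microarray 5C) two chains
mix within ~1e6 iterations and recovery of the gold standard's distance
matrix exceeds Pearson r = 0.95 — the regime the published protocol
reports.  The package therefore runs its desk-scale mixing/recovery
validation at `cv = 0.3` and treats very tight noise as a documented
limitation of the plain Metropolis kernel: richer proposal kernels
(crankshaft moves, tempering) would be required there and are out of
scope.

The initialization cube has side `10 * avg(d)`, with `d` the distances
implied by the observed IFs — for Hi-C, distances relative to the
strongest contact, since the count normalization makes absolute scale
unidentifiable.

## Design choices where the design was open

* **Forward-model parameterization.** Source descriptions of the
  IF–distance transform are mutually inconsistent (`IF ∝ d^-alpha`
  versus `d = C / IF^alpha`); this package uses `IF = psi * d^-alpha`
  everywhere with its exact inverse, which is the form the published
  cross-validation criterion actually evaluates, and lets `psi` play
  the role of the scale constant `C` after calibration.
* **Mixing reference.** "Within 10% of each other" does not name a
  reference; chain A's within-run mean is the denominator, and the
  band is two-sided and boundary-inclusive.
* **Scale calibration.** `psi = mean(short-range IF) * L^alpha`, where
  `L` is the mean genomic separation of pairs closer than 5 kb divided
  by the packing ratio (default 130 bp/nm, configurable within the
  plausible 110–150 range).
* **Greedy subset definition.** "Greedy" is pinned down as: seed with
  the pair of smallest distance-sd, then repeatedly add the fragment
  minimizing the subset's total pairwise sd, ties to the lowest index.
  On n = 7, k = 3 ensembles the greedy solution matched the exhaustive
  optimum in 23/30 random cases (and never beat it, as it cannot).
* **PDB export.** One CA pseudo-atom per fragment, residue number =
  fragment index, coordinates scaled nm→Å (further shrunk if they would
  overflow the fixed 8.3 field), scale factor and log posterior in
  REMARK records so original coordinates round-trip to field precision.

## Known limitations

* Whole-genome Hi-C scale is out of scope (the protocol is reported not
  to mix there), as are torsion/crankshaft proposals, parallel
  tempering and polymer-physics priors.
* The per-pair Gaussian is a convenience model: it admits negative IFs
  (the simulator truncates at zero and logs the rate) and treats pairs
  as independent.
* Hi-C reconstruction identifies shape only, not size; physical scale
  must come from external calibration.
* Cluster count selection is manual (inspect the merge heights), by
  design.
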