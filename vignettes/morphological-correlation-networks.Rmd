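---
title: "Detecting variational modules with morphological correlation networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting variational modules with morphological correlation networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcnet)
```

## The problem

Landmark-based morphometrics asks how the parts of a morphological
structure covary across individuals. A *variational module* is a set of
landmarks whose positions are tightly correlated with one another and only
weakly correlated with the rest of the configuration — the quantitative
face of the idea that functionally or developmentally related parts are
coupled while unrelated parts vary independently. `mcnet` detects such
modules in 2-D landmark data (the motivating application is moth wing
patterns, where pattern–vein intersections are measured against a scaffold
of stable wing-vein landmarks) by building a *morphological correlation
network* and extracting its communities.

The pipeline has four stages, each exposed as a function and composed by
`mcn()`:

1. **Superimposition** (`gpa()`, `transfer()`). Generalized Procrustes
   analysis on the *reference* landmarks only, then the fitted similarity
   transform of each specimen is applied to its *measurement points*.
2. **Correlation** (`rv_matrix()`). Pairwise Escoufier Rv coefficients
   between the 2-D coordinate blocks of every pair of measurement points.
3. **Network construction** (`threshold_network()`). Correlations strictly
   above a threshold `tau` become weighted edges.
4. **Module extraction** (`frequency_solutions()`). Repeated simulated
   annealing of a Potts spin glass whose ground state is the modular
   partition; distinct solutions are reported with occurrence frequencies.

## Superimposition and the two-step transfer

The Procrustes fit scales every configuration to unit centroid size,
translates its centroid to the origin, and rotates it to minimize the
summed squared distance to the consensus, with the consensus re-estimated
(and rescaled to unit centroid size, which fixes the scale gauge) until
the total Procrustes sum of squares changes by less than `1e-10`. Only
proper rotations are allowed (`det = +1`): the data are same-side
structures, so reflections are anatomically meaningless. Convergence is
typically reached in a handful of iterations; failure to converge within
200 iterations is reported as an error rather than silently accepted.

The measurement points never enter the fit. They are carried along by each
specimen's reference transform (`transfer()`). Fitting on the stable
reference scaffold and transferring avoids the spurious covariance that a
joint superimposition induces among the points of interest: in a joint
fit, every landmark's residual is contaminated by every other landmark
through the rotation estimate, which biases downstream correlations.
Replicate digitizations enter the fit as separate configurations, so
digitization error passes through exactly the same alignment as the
biological signal; `procrustes_anova()` then certifies whether that error
is negligible (individual mean squares ≫ error mean squares). Degrees of
freedom use the similarity-shape-space convention `d = 2k − 4` for `k`
2-D landmarks; the value is recorded in the output so an alternative
convention can be audited.

## The Rv coefficient

For two measurement points, each an `N × 2` block of aligned coordinates
across `N` specimens, the association is Escoufier's Rv: with
column-centered blocks `X`, `Y` and cross-products `S_xy = X'Y`,

$$\mathrm{Rv} = \frac{\mathrm{tr}(S_{xy}S_{yx})}
{\sqrt{\mathrm{tr}(S_{xx}^2)\,\mathrm{tr}(S_{yy}^2)}} \in [0, 1],$$

a squared cosine between positive semi-definite matrices and the
matrix-level generalization of a squared Pearson correlation. It is
invariant to rotation, translation and positive scaling of either block,
which makes it the natural statistic after a Procrustes superimposition
(whose gauge choices are exactly such similarity transforms). Blocks are
always column-centered before the cross-products, because Rv is defined on
covariance structure. When replicates exist they are averaged per specimen
first (the default `use = "specimen_means"`): the ANOVA certifies the
digitization error negligible, and the target of inference is
between-individual covariation.

## Thresholding

`threshold_network()` keeps edge `(i, j)` with weight `Rv_ij` iff
`Rv_ij > tau`, strictly. The working default is `tau = 0.2`, with
`tau = 0.4` and no threshold used as sensitivity levels
(`threshold_sweep()`). A significance-level threshold is deliberately not
the default: with `k(k−1)/2` simultaneous tests the familywise type-I
error is uncontrolled, and the network topology would depend on `N`
rather than on effect size. Isolated nodes are retained — a measurement
point with no strong correlate is itself a finding.

## Spin-glass module extraction

Modules are the ground state of the Reichardt–Bornholdt Hamiltonian over
spin assignments $\sigma$ (one spin state per node allowed, so the module
count is free up to `k`):

$$H(\sigma) = -\sum_{i<j}\,(W_{ij} - \gamma\,p)\,
\delta_{\sigma_i\sigma_j},$$

with the weighted Erdős–Rényi null `p = (total weight)/(pair count)`. The
sum runs over unordered pairs — half the ordered-pair convention, a global
factor that cannot move any argmin. Conserving total weight in the null
gives two useful identities used as tests: the all-singleton partition has
`H = 0`, and at `γ = 1` the all-in-one partition also has `H = 0`, so any
reported architecture with negative energy beats both trivial extremes.
The resolution `γ` defaults to 1, the standard choice; it is exposed for
exploration but no result in the package depends on moving it.

Minimization uses single-spin Metropolis simulated annealing (compiled
code), with:

* geometric cooling, factor `0.99` per temperature step;
* starting temperature auto-calibrated so that roughly 90% of uphill
  moves from the initial random state would be accepted;
* 50 sweeps (one attempted update per node each) per temperature;
* stop at temperature `1e-3`, or earlier once the chain is *frozen* —
  100 consecutive temperature steps with neither a best-energy improvement
  nor appreciable move acceptance (below 1% of attempts). Freezing alone
  is required: stopping merely on "no recent improvement" would abort
  during the high-temperature random walk;
* the best-visited state (not the final one) is returned, then polished by
  a zero-temperature greedy descent.

Exact ties in the greedy descent are broken toward splitting: an
energy-neutral move of a node out of a multi-member group into an empty
spin state is taken. This resolves degenerate inputs deterministically —
on an empty network (`p = 0`, every partition at `H = 0`) the result is
all singletons, matching the convention that isolated nodes resolve to
singleton modules — and can never raise the energy.

Each trial is deterministic given its seed; `frequency_solutions()` spawns
per-trial seeds from one master seed, so whole frequency tables are
reproducible. Repeated trials matter because the spin glass typically has
several near-minimal states: the frequency with which each distinct
(canonicalized) partition recurs across trials measures the ambiguity of
the covariance architecture, and `module_reproducibility()` reports, for
one module, the fraction of trials containing exactly that node set. On
every small network where exhaustive enumeration is feasible
(`brute_force_min()`, ≤ 12 nodes), the annealer's best-of-trials energy is
tested to match the exhaustive global minimum.

## The synthetic generator

`generate_landmarks()` plants a known modular architecture so every stage
is testable without real data. The template places `k_ref` reference
landmarks on a ring of radius 100 pixel units and `k_mp` measurement
points on an inner ring of radius 60 (mimicking a digitizer's pixel
scale). Per specimen, each planted module draws one shared 2-D Gaussian
displacement (`module_effect_sd`, default 5 px) added to all its members —
the simplest common-factor construction that realizes "tightly correlated
units" measurable by Rv — plus independent Gaussian noise per landmark
(`noise_sd`, default 1 px, so the default effect-to-noise ratio is 5).
The whole configuration then receives a random similarity nuisance
(rotation uniform on the circle, translation ±50 px, scale 0.8–1.25), and
each of the `replicates` (default 2) digitizations adds post-nuisance
error (`digitization_sd`, default 0.2 px). The presets
`paper_shaped_spec("oexcavata_like")` (21 reference + 19 measurement
points, n = 24, modules of sizes 2/5/7/5) and `"tjuno_like"` (18 + 16,
n = 16, sizes 3/4/5/4) match the two study designs the method was
developed on.

What the generator does *not* emulate: non-Gaussian variation, spatially
graded covariance (nearby landmarks more correlated), allometry,
asymmetry, or digitizer drift. Passing the recovery tests therefore shows
that the pipeline correctly inverts its own generative assumptions at
realistic sizes — not that real wing data satisfy those assumptions.

## Known limitations

* At study-sized samples the latent module displacements are 2-D vectors
  observed `n` times; two *independent* modules' vectors can correlate by
  chance above `tau = 0.2` at `n = 24`, in which case the merged
  architecture genuinely minimizes the energy and the planted partition
  is unrecoverable from that draw by any method. This occurs in a small
  minority of generator draws and is the same finite-sample ambiguity the
  frequency tables are designed to surface; the leave-one-out analysis
  (`leave_one_out()`) is the practical guard, since such chance edges sit
  near the threshold and flip under single-specimen removal.
* The annealing schedule is a heuristic: optimality is *verified* only at
  oracle-checkable sizes (≤ 12 nodes) and supported by solution-frequency
  concentration at larger ones.
* Procrustes ANOVA assumes a balanced replicate design and reports the
  `2k − 4` dimensionality convention; unbalanced designs are refused
  rather than approximated.
* Rv between single landmarks uses 2-variable blocks; the package does not
  offer multi-landmark-block Rv or partial correlations.

## Problem sizes in the test suite

The shipped tests run the full pipeline at the study-sized presets
(19-node networks, 1,000 annealing trials for the recovery check), verify
the annealer against exhaustive enumeration on twenty 5–9-node random
networks at 100 trials each, and use 500 simulation seeds for the
measurement-error null; these sizes make the whole suite complete in a few
minutes on one CPU while keeping every check at full strength.

## A worked run

```{r example, eval = FALSE}
sim <- generate_landmarks(paper_shaped_spec("oexcavata_like", seed = 1))
m <- mcn(sim$dataset, tau = 0.2, trials = 1000, seed = 1)
summary(m)
identical(m$modules, sim$planted)
plot(m)
```
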