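---
title: "SigPolytope methods: latent encoding, dual polytopes, and the geometry of discordance"
author: "SigPolytope authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SigPolytope methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SigPolytope)
```

## The representation

A regulatory circuitry pairs an upstream signature ("sig") with its
experimentally supported interaction target ("int"). Each side is summarized
by an 18-dimensional latent vector whose coordinates, in fixed order
(`latentCoordinateNames()`), aggregate:

* the Spearman correlation `rho` of the side with its phenotypic attribute
  and a `rho_strength` derived from the multiple-testing-adjusted P;
* the tumor-versus-normal direction (`+1` up, `-1` down, `0` not
  significant) and a strength from the Wilcoxon P;
* for each of four survival endpoints (OS, DSS, DFI, PFI) a signed Cox
  direction (`+1` risk, `-1` protective, `0` ns), a strength from the
  endpoint P, and the raw log-rank chi-squared statistic;
* the continuous microenvironment score and a signed immune code.

Two conventions deserve comment because the encoding contract leaves them
open:

**Strength transform.** The tumor-normal axis is defined via
`-log10(P)`; the adjusted correlation P and the survival P values admit
either a raw or a transformed reading. We apply `-log10` uniformly
(`pvalueTransform = "neglog10"`) so that "strength" has the same units and
the same monotonicity on every axis, capping at 300 to keep coordinates
finite when P underflows double precision; `"raw"` is a configuration
switch, not a code change.

**Immune map.** Four immune classes must land on the signed codomain
\{-1, 0, +1\}. Hot and cold are the polar states, so `hot = +1`,
`cold = -1`, and both non-polar states (`excluded`, `intermediate`) map to
0. The map is a parameter (`immuneMap`) because the assignment of
`excluded` is a genuine modelling choice, not a fact.

**Survival zeroing.** When an endpoint is flagged non-significant, its
direction, strength and chi-squared coordinates are set exactly to
`(0, 0, 0)`, so uninformative endpoints cannot deform the geometry. A
missing annotation is only interpreted as non-significant when the explicit
significance flag says so; genuinely absent cells are a validation error,
because silently fabricating zeros would manufacture concordance.

## The shared embedding

All `2N` side vectors are pooled into one tensor, globally centered and
scaled per coordinate, and decomposed by PCA. Conventions:

* **Standard deviation denominator** is `n - 1` (the sample convention of
  mainstream statistics stacks); the centering-only variant
  (`scaleColumns = FALSE`) reproduces the no-scaling robustness check.
* **Zero-variance coordinates** are centered and divided by a scale of 1:
  they become exactly zero, contribute no variance, and cannot produce
  divide-by-zero artifacts.
* **Sign convention**: the largest-magnitude entry of every loading column
  is made positive. PCA signs are otherwise arbitrary; pinning them makes
  barycenter coordinates bit-stable across runs (distances are
  sign-invariant regardless).
* The full 18-component decomposition is retained; distances and hulls use
  the leading `nComponents = 3` by default. Full-dimensional scores are an
  isometry of the standardized space; truncated distances are lower bounds.

## Dual polytopes and descriptors

Each side's latent vector `x` is expanded into 36 vertices
`x ± max(alpha * |x_i|, epsilon) * e_i`, two per axis: a cross-polytope
whose semi-axes grow with how strongly the side engages each coordinate,
with a floor `epsilon` that keeps silent axes from collapsing the shape.
The proportionality constant is not dictated by the construction --- only
proportionality and the safeguard are --- so we fix `alpha = 1`,
`epsilon = 0.05`. `alpha` rescales every hull volume by `alpha^3`
(verified as a test invariant) and leaves barycenter distances and regime
ordering untouched, so its exact value is immaterial to classification;
`epsilon` only matters for near-neutral circuitries.

Descriptors per circuitry:

* **dbary**: Euclidean distance between the two projected barycenters.
  Projection is linear, so the barycenter of projected vertices equals the
  projected latent point; the pipeline exploits this for fast paths
  (permutation, ablation) and the equality is asserted to `1e-10` in tests.
* **Hull volumes**: two volume definitions coexist naturally for this
  construction. The operational default measures the 3-D convex hull of
  the projected vertices (`volumeSpace = "projected3d"`); the alternative
  measures the full 18-dimensional cross-polytope in the standardized
  latent space, which has the closed form `2^d / d! * prod(delta_i / s_i)`
  (`volumeSpace = "latent18"`). Both are exposed; neither is asserted to be
  "the" published convention, and the volume classes are data-driven
  quantiles either way.
* **Asymmetry**: `vol_sig / vol_int`, symmetrized as `max(r, 1/r)` for
  classification.
* **Anisotropy**: the ratio of extreme principal semi-axes of the
  projected vertex cloud (square root of the covariance eigenvalue ratio).

The 3-D convex hull is computed by an incremental insertion algorithm
implemented in the package (visible-facet deletion and horizon
re-triangulation, outward-oriented facets, volume by signed tetrahedra
against an interior point). It is validated against the analytic
cross-polytope volume, cube/octahedron combinatorics, Monte-Carlo rejection
sampling (agreement within 3 standard errors), and subset monotonicity.
Because the loading matrix is orthonormal, the projection of a
full-dimensional cross-polytope always has rank 3, so degenerate hulls
cannot arise from the standard pipeline; the degeneracy path (flag, zero
volume, export refusal) exists for externally supplied geometry.

## Classification

* **Distance regimes** bin dbary at fixed thresholds 0.5 / 1.5 / 2.5,
  half-open with boundary values assigned upward (a dbary of exactly 2.5 is
  extreme discordance).
* **Volume tiers** (Low / Intermediate / High) cut a scalar size summary
  --- the geometric mean of the two side volumes, symmetric in the sides
  and scale-covariant --- at data-driven quantiles (defaults 1/3 and 2/3,
  type-7 interpolation, pinned for reproducibility; degenerate volumes are
  excluded from quantile fitting).
* **Symmetry states** cut the symmetrized ratio at bands 1.5 and 3.0.
  The bands are configuration, reported in the output sidecar, because no
  canonical values exist for them; tiers crossed with symmetry give the
  nine mutually exclusive volume classes.
* **Joint phenotypes**: concordant means the high-concordance regime;
  the dimensionality arm is the Low or High tier, with Intermediate mapped
  to the high-dimensional arm when asymmetric and to the low-dimensional
  arm otherwise (a documented tie-break, configurable in principle).
* **Concordance summary** compares the signs of the two sides over the
  annotated axis families: correlation sign, tumor-normal direction, every
  survival endpoint significant on both sides, microenvironment sign, and
  immune polarity. Axes neutral on either side are excluded. All-agree is
  Only Convergent, all-disagree Only Divergent, otherwise Mixed, and a
  circuitry with no comparable axis gets the explicit Indeterminate label.
  Geometric separation and sign convergence are independent readouts:
  a circuitry can be extremely discordant in latent position yet Only
  Convergent in sign structure (separation-with-convergence), and the test
  suite constructs such fixtures.

## Entropy, baselines, ablations, and the permutation null

**Entropy.** Heterogeneity of a class across the four regimes is the
Shannon entropy of its regime-proportion vector, in natural log units by
default: 4-class profiles then live in `[0, ln 4 ~ 1.386]`, which matches
the magnitudes the framework reports for concordance classes; base-2 is a
switch. Classes are ranked by decreasing entropy with lexicographic
tie-breaks.

**Baselines.** Per circuitry: Euclidean and cosine distance between the
two standardized latent vectors (standardized, so that the Euclidean
baseline coincides with the full-PC-space distance --- an identity the
suite checks), survival-direction mismatch counts over endpoints with
defined directions on both sides, immune-class mismatch, tumor-normal
mismatch, and the absolute microenvironment difference. A zero vector makes
the cosine undefined; it is set to 1 (orthogonal-equivalent) and flagged.
The Spearman matrix across metrics uses average ranks; constant columns
yield flagged `NA`s, never a silent 0.

**Ablations** re-run the standardize + PCA + project + dbary + regime chain
after deleting the 12 survival coordinates or the immune code, or after
switching off variance scaling, and report the Spearman correlation of
dbary against the reference plus the fraction of retained regime labels.
On synthetic atlases the survival axes carry most inter-side signal, so
dropping them degrades the ranking far more than dropping the immune code
--- the qualitative ordering the robustness analysis is designed to expose.

**Permutation null.** Interaction sides are re-assigned uniformly at
random within cancer-type strata (strata of size one stay fixed); for every
replicate the embedding is refit from the permuted tensor and all
distances and regimes recomputed. Three global statistics are tracked
(mean dbary, proportion extreme, proportion high concordance), compared
upper-tailed, with the bias-corrected estimator `p = (k+1)/(B+1)` whose
minimum is `1/(B+1)`. Replicate seeds are derived from the base seed by a
counter, so enlarging B never reshuffles earlier replicates. Calibration is
verified empirically: on atlases whose sides are drawn independently
within strata, the rejection rate at `alpha = 0.05` sits inside the 99%
binomial band over 200 repeats at B = 99 (B scaled down from the
production 500 to keep the check affordable; the estimator is
B-independent in distribution under exchangeability).

## The synthetic atlas generator

`simulateAtlas()` emulates the statistical structure the pipeline assumes,
not any particular dataset. Three design features matter:

1. **Coherent sides.** Each side draws a latent orientation (pro-tumoral
   vs anti-tumoral) and a significance depth; all signed axes align with
   the orientation with high probability and all strengths share the depth.
   Without this coupling the standardized tensor has a nearly flat
   eigen-spectrum, and which directions land in PC1-3 becomes unstable
   across realizations --- distances then fluctuate wildly between runs.
2. **Stratum profiles.** Every cancer-type stratum has a dominant
   orientation, a depth baseline, and endpoint-specific significance rates,
   mimicking cohort-level coherence (different cancer types differ in which
   endpoints are informative). This places meaningful variance between
   strata, which is what makes within-stratum permutation a sharp null.
3. **Alignment-aware discordance.** The interaction side of a discordant
   circuitry flips a controlled set of signed axes --- a graded number of
   weak axes (correlation, tumor-normal, microenvironment, immune) and
   survival-endpoint directions --- chosen preferentially among axes
   currently aligned with the side's dominant orientation, so the flip
   displacements add coherently instead of cancelling. The extreme
   component additionally re-draws its survival strengths independently
   and opposes the signature's orientation outright.

The default effect scales were calibrated once, during generator design,
so that the four components land in the four distance regimes under the
fixed thresholds; with the default mixture (5% concordant, 20% moderately,
20% strongly, 55% extremely discordant) a 2,000-circuitry atlas recovers
the generating proportions within about 2-4 percentage points, and the
median dbary comes out near 3.

What the generator does **not** emulate: the empirical marginal
distributions of any real supplementary dataset, shared molecular
identities across circuitries (every circuitry is drawn independently given
its stratum), pathway or superfamily structure beyond opaque labels, and
annotation noise or missingness. Passing tests therefore demonstrate that
the pipeline's geometry, classification and statistics behave as specified
under controlled conditions --- not that any biological conclusion about
real atlases is reproduced.

One consequence of the generator's design is worth stating explicitly:
because the majority of interaction sides oppose their stratum's dominant
orientation by construction, a within-stratum permutation hands most
signatures another opposing interaction side, so the proportion of extreme
discordance is *not* enriched relative to the null on synthetic data.
The non-random pairing signal appears instead as a strong enrichment of
high concordance (typical empirical p of about 0.002-0.01 at B = 500),
since permutation destroys the deliberately concordant pairs. On real
atlases the direction of enrichment is a property of the data, not of the
method; both tails are available from the same `PermutationResult`.

## Numerical conventions and problem sizes

* Tables are serialized as UTF-8 TSV at 17 significant digits, so
  write-read round trips are bit-exact; a JSON sidecar stores the fitted
  tier thresholds and classification parameters.
* Orthonormality is enforced to `1e-8`; isometry checks run at `1e-8`;
  barycenter/projection commutation at `1e-10`; hull-vs-closed-form volume
  agreement at `1e-6` relative.
* The checks that ship with the package use: 2,000-circuitry atlases for
  mixture recovery and benchmarking; 200 repeats at B = 99 (n = 60, 4
  strata) for permutation calibration; 20 random polytopes with 20,000
  rejection samples each for Monte-Carlo volume validation. These sizes
  were chosen to make the statistical assertions sharp at interactive
  runtimes.

## Known limitations

* The latent encoding fixes 18 coordinates; additional annotation layers
  require extending the coordinate map, not just the table schema.
* Hull descriptors are computed on the 3-D projection by default; the
  full-dimensional closed form is exact for the cross-polytope but does not
  generalize to arbitrary vertex sets.
* The concordance summary treats axes symmetrically; weighting axes by
  reliability is out of scope.
* The permutation null permutes whole interaction sides; nulls that
  permute individual axes, or that resample rather than permute, are not
  implemented.
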