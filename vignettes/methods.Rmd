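---
title: "Methods: from comb silhouettes to QTL, eQTL and colocalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from comb silhouettes to QTL, eQTL and colocalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combqtl)
```

# The problem

The chicken comb is a sexual ornament whose size and shape vary strongly
between wild Red Junglefowl and domestic White Leghorn. combqtl implements
the full analysis chain that links comb morphology to genotype and to
comb-tissue gene expression in an F8 advanced intercross line (AIL) between
such lines: outline morphometrics to phenotype shape, Haley-Knott interval
mapping for QTL and eQTL, and interval colocalization with a random-region
permutation null. Because the original study's individual-level data live in
external repositories, the package also ships a seeded simulator of the
entire design with known ground truth; every downstream stage is exercised
and calibrated against planted effects rather than against downloads.

# The simulator

## Genetic map and meiosis

`simulate_map()` places markers on a regular cM grid. The study-scale
design (`sim_config_full()`) mirrors the real marker panel: 10 chromosomes
of 920 cM at 16 cM spacing (580 markers over 9,200 cM) and 326 F8
individuals. The default `sim_config()` is a scaled-down version used for
simulation studies -- 5 chromosomes x 200 cM at 10 cM spacing, n = 300 --
chosen so a full scan with 1,000 permutations runs in well under a second
while retaining a realistic genome-wide multiple-testing burden
(105 markers over 1,000 cM).

`simulate_ail_genotypes()` breeds the AIL forward from founder lines that
are differentially fixed at every marker (`R` vs `W` alleles), so F1 is
exactly heterozygous everywhere. Meiosis assumes no crossover interference
(Haldane). Under that assumption crossover counts in disjoint intervals are
independent, so the allele-origin process along a marker grid is an exact
Markov chain whose switch probability between adjacent markers is the
Haldane recombination fraction of their distance; gametes are therefore
simulated directly at the markers, with no loss relative to a
continuous-crossover simulation. Mating from F2 on is random between
distinct dams and sires (no selfing), with uniform litter contributions;
the breeding design beyond "F8" is not specified by the study, so these are
the package's choices. Intermediate generation size is a knob
(`n_per_generation`, default equal to the mapped sample size); at the
default sizes drift keeps F8 allele frequencies within 0.35-0.65 at
essentially all markers. The dam of each final individual defines a
`family` factor used as the population-structure covariate, realising the
study's "population structure" fixed effect as F7 family identity.

## Phenotypes, outlines, expression

`simulate_quantitative_trait()` realises exactly the model the scan fits:
`y = mu + covariates + a*x_a + d*x_d + e` with `x_a` in {-1, 0, +1} and
`x_d` the heterozygote indicator at the marker nearest each planted QTL.
Sex and batch are balanced categorical covariates, weight a Gaussian
continuous covariate, family a random per-family shift. The helper
`noise_sd_for_pve()` converts a target proportion of variance explained
into a residual SD using the realised genotype variance, so "a QTL with
PVE 10%" is a well-defined simulation condition.

`simulate_outline_population()` is the generative inverse of the
morphometrics chain: each individual's elliptic Fourier coefficient vector
is a mean shape plus allele dose times an effect vector plus coefficient
noise, reconstructed into an outline. A planted shape QTL is therefore
recoverable by trace -> interpolate -> align -> EFA -> PCA -> scan, and the
recovered PC1 is collinear with allele dose when noise is absent.

`simulate_expression_matrix()` plants cis effects (acting through the
marker nearest the probe) and trans effects (through a regulator position
elsewhere), plus per-probe baselines, per-batch shifts and Gaussian noise,
and returns the ground-truth labels. Batches are assigned by the same
deterministic rule as in the trait simulator so expression and phenotype
covariates agree. What the simulator does *not* emulate: linkage
disequilibrium beyond map-distance recombination, selection during
breeding, array-normalisation artefacts, probe cross-hybridisation, or
non-Gaussian measurement error. Passing tests therefore demonstrate
correctness and calibration of the *methods* under the stated generative
model, not robustness to every pathology of real array data.

# Morphometrics

## Outline extraction and interpolation

`trace_outline()` performs Moore-neighbour boundary tracing (with Jacob's
stopping criterion) on the largest 8-connected foreground component of a
binary silhouette, the digital analogue of outlining a comb photographed as
a black object on white. `interpolate_outline()` resamples the closed
polyline at equal arc-length steps; Procrustes alignment and Fourier
analysis need equal point counts, and the original analysis interpolated
all outlines to 16,570 coordinates (the largest observed outline). The
package default for simulation studies is a few hundred points, which is
past the point of diminishing returns for the smooth shapes the generator
produces; 16,570 remains available.

## Procrustes alignment

`align_outlines()` centres each outline, scales it to unit centroid size,
and iteratively rotates each to the current mean shape (closed-form 2D
rotation), re-estimating the mean until it changes by less than 1e-8 or
100 iterations. Rotations and the new mean each minimise the same summed
squared deviation, so the objective is non-increasing -- a property the
test suite monitors. Correspondence is by point index; outlines should be
interpolated to a common count first. The mean is centred but not
re-scaled, which keeps the alternating minimisation monotone.

## Elliptic Fourier analysis

`efa_decompose()` returns, per harmonic `n`, the quadruple
`(a_n, b_n, c_n, d_n)` of the Fourier series of `x(t)`, `y(t)` over the
closed outline, plus offsets `A0`, `C0`. The parameterisation is uniform
per vertex: each polyline segment advances the parameter by one step. This
was a genuine design choice. The classical chord-length (Kuhl-Giardina)
parameterisation weights the parameter by segment length; the two coincide
exactly once outlines are interpolated to equal arc-length spacing -- which
this pipeline always does before EFA -- but they differ on non-uniformly
sampled curves. The uniform convention was chosen because it makes
`efa_decompose()` and `efa_reconstruct()` exact inverse pairs on sampled
curves (up to the `sinc^2` attenuation of linear interpolation, below 0.1%
for 500 points and 10 harmonics), which in turn makes the outline
generator's planted coefficients recoverable and gives the analytic
ellipse its textbook coefficients (`|a1|` = semi-major, `|d1|` =
semi-minor, all power in harmonic 1).

Orientation is normalised to counterclockwise before decomposition so
coefficients are deterministic; no first-harmonic size/phase normalisation
is applied because outlines are pre-aligned (mirroring the original
workflow, which needed no further normalisation after alignment). Harmonic
power is `P_n = (a_n^2 + b_n^2 + c_n^2 + d_n^2)/2`; `harmonic_power()`
reports the smallest harmonic count reaching a cumulative power threshold
(0.99 by default), the rule by which 26 harmonics were judged sufficient
for combs. With 4 coefficients per harmonic, 26 harmonics give 104 PCA
columns; the offsets `A0`, `C0` are excluded from PCA since outlines are
centred. (The source analysis reports "200 coefficients" for 26 harmonics,
which no 4-per-harmonic bookkeeping reproduces; the package keeps 4H.)

`shape_pca()` runs column-centred, unscaled PCA (coefficients share units)
via an eigendecomposition of the covariance; tests cross-check scores and
loadings against an explicit `eigen(cov(X))` oracle.

# Interval mapping

## Model and LOD

`hk_scan()` implements Haley-Knott regression: at each position the trait
is regressed on expected additive and dominance dosages
`x_a = P(WW) - P(RR)`, `x_d = P(RW)` given the observed markers, and

LOD = (n/2) log10(RSS0 / RSS1),

where the null model holds the intercept and any additive covariates (plus
the interacting covariate's main effect when one is given) and the full
model adds `x_a`, `x_d` and, for interacting-covariate scans, their
products with that covariate. Regression on expected dosages (rather than
an EM mixture likelihood) was chosen because the study's model statement is
regression-like and because the estimator is deterministic and directly
checkable against an ordinary least-squares oracle -- which the tests do,
to 1e-8 at every marker. Small LOD differences from mixture-based engines
are expected at positions with substantial genotype uncertainty.

Dosages come from `genotype_probabilities()`, a three-state
forward-backward pass per chromosome with F2-type transition matrices built
from the Haldane fraction, a genotyping-error emission allowance (1e-4 by
default) and the stationary prior (1/4, 1/2, 1/4). Missing genotypes are
marginalised by the HMM; missing phenotypes or covariates are dropped
listwise per trait. The default evaluation grid is the markers themselves
(`step = 0`), matching marker-level scans; a pseudomarker grid is
available. The F8 is scanned with the F2-type three-genotype model on the
supplied map, without an AIL map-expansion correction: the simulated map is
generated by the same process that is scanned, and the real cross file is
expressed the same way.

## Permutation thresholds

`perm_thresholds()` shuffles individual labels -- trait and covariate rows
jointly against genotypes, preserving trait-covariate association under
the null of no genotype effect -- and records the genome-wide maximum LOD,
1,000 times by default, reporting the empirical 0.95 (significant) and
0.80 (suggestive) quantiles with the linear-interpolation quantile rule.
The genome-wide p of a peak is the fraction of permutation maxima at or
above it (ties exceed). The permutation loop exploits two invariances:
under a joint shuffle of (y, covariates) against genotypes, the null RSS
and the dosage cross products are unchanged, so each permutation costs one
projection of the dosage matrix onto the permuted null-space basis rather
than a full re-fit. The result is bit-identical to re-scanning the permuted
data (a test asserts this) at roughly 50x the speed, which is what makes
200-replicate calibration studies with 1,000 permutations each feasible on
one CPU in minutes.

## Support intervals and effects

`lod_drop_interval()` walks outward from a peak until the curve first
drops more than 1.8 LOD (comparable to a 95% CI in intercrosses) and snaps
the outermost still-qualifying positions to the closest markers,
equidistant ties to the lower position. `qtl_fit()` reports additive and
dominance estimates with standard errors from the least-squares fit at the
peak, and percent variance explained as the partial R-squared of the
genotype dosages given the covariates (x100). That definition is stated
deliberately: the source study's "%Var" column is inconsistent with the
usual `1 - 10^(-2 LOD / n)` identity and its formula is unstated, so no
attempt is made to reproduce that column's numbers.

# eQTL mapping

`scan_expression()` treats each probe as a phenotype (batch as the default
fixed covariate), applies permutation thresholds, and emits one record per
probe whose genome-wide best LOD reaches the suggestive threshold,
recording the tier, a 1.8-LOD-drop interval, and the cis/trans label. One
seeded set of permutation index vectors is shared across probes: every
probe's null is built from the same label shufflings, which is valid
per-probe and removes the dominant cost of per-probe permutation draws.
`classify_cis_trans()` calls a peak cis when the probe lies on the peak
chromosome within 50 cM of the peak marker (boundary inclusive -- a
distance of exactly 50 cM is cis); all other placed probes are trans, and
probes off the map are flagged unclassifiable rather than erroring.
Distance is measured in cM on the scan map, as the rule is stated in map
units, and cis additionally requires the same chromosome (the alternative,
50 cM across a concatenated map, is not meaningful between chromosomes).
Only each probe's single best peak is recorded, matching reported eQTL
counts that approximate counts of probes passing threshold.

# Colocalization

`map_ci_to_physical()` converts a cM confidence interval to physical
coordinates by taking the closest marker to each endpoint (ties to the
lower position). `find_overlaps()` reports all same-chromosome pairs of
closed intervals that intersect -- touching endpoints count, since
marker-snapped intervals are closed by construction; the implementation is
a per-chromosome sweep over start-sorted intervals, verified in tests
against both a brute-force all-pairs oracle and GenomicRanges.

`enrichment_permutation()` implements the random-region null: each
iteration places the two region sets uniformly on the genome and counts,
by default, how many B regions overlap at least one A region -- the
resolution of "number of overlapping regions" that matches summaries of
the form "98 (out of 1,184) eQTL". The count rule is pluggable and recorded
in the result. Placement draws a start uniform on the concatenated
chromosomes and shifts a region back when it would run off its chromosome
end; treating the genome as per-chromosome segments (rather than one
unstructured range) avoids regions spanning chromosome joins. The
one-tailed p uses the +1 correction, `(1 + #{null >= obs}) / (1 + iters)`,
so it is never zero. Pearson correlations between eQTL expression and QTL
phenotypes go through `stats::cor.test` (t distribution, n-2 df) with
pairs at p < 0.05 flagged, and no multiple-testing correction, mirroring
how the study reported raw per-pair correlations.

# Numerical choices and degenerate inputs

* Near-collinear dosage pairs (e.g. monomorphic or fully heterozygous
  positions) fall back from the 2x2 normal equations to the better single
  regressor; a full-model RSS is floored at 1e-12 of the null RSS, capping
  LOD at 6n rather than producing infinities.
* Collinear covariate designs error, naming the offending column; traits
  with zero variance error rather than scanning.
* Quantiles use R's default linear interpolation (type 7); permutation
  p-values count ties as exceeding.
* Outline constructors drop consecutive duplicate points and require 3
  distinct points; zero-area outlines cannot be rasterised; empty masks
  cannot be traced; a foreground touching all four image borders warns of
  possible cropping.
* All stochastic functions take explicit seeds and restore the caller's
  RNG state; the pipeline derives per-stage seeds from one master seed, so
  a configuration reproduces its outputs exactly.

# Problem sizes used in the verification suite

The test-suite and acceptance-script experiments run at the scaled-down
design (5 x 200 cM, 10 cM spacing): 200 replicates with 1,000 permutations
each for threshold calibration and for support-interval coverage
(n = 300); 7 replicates of a 6-probe planted cis/trans panel plus one
100-probe null panel (n = 200, 400-1,000 permutations); 1,000 random
interval instances against the brute-force overlap oracle; 500 null draws
at 2,000 iterations for enrichment-p uniformity (10 vs 1,184 regions,
matching the study's region counts) and 100 planted-colocalization
replicates. These sizes give binomial error bands tight enough to detect
miscalibration of a 5% test while keeping the whole suite comfortably
runnable on a laptop core.

# Known limitations

* The F2-type scan model ignores AIL map expansion; LOD decays faster
  between markers than an AIL-aware model would predict, so support
  intervals on sparse maps are conservative near peaks.
* Only single-QTL models are fitted: no composite interval mapping,
  epistasis, or X-chromosome dosage handling.
* The cis/trans rule is positional, not mechanistic; a trans-acting
  variant within 50 cM of its target is labelled cis.
* Outline correspondence is by index after common-count interpolation, not
  by landmarks; strongly rotated starting points degrade alignment of very
  asymmetric shapes (the generator's outlines share a parameterisation, so
  this does not arise in simulation studies).
* The enrichment null treats regions as independently placed; clustered
  real features (gene deserts, recombination coldspots) would need a
  structured null.
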