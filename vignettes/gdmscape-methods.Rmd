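---
title: "Methods: landscape genomic dissimilarity modelling with gdmscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landscape genomic dissimilarity modelling with gdmscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdmscape)
```

## The problem

Restoration projects for widespread foundation trees need to decide where
to source seed. Two population-genetic signals inform that decision:
isolation by distance (IBD), the decay of genomic similarity with
geographic separation, and isolation by environment (IBE), the additional
differentiation associated with environmental contrasts once geography is
accounted for. `gdmscape` implements the full analysis chain from a SNP
genotype matrix and per-site environmental values to a fitted generalized
dissimilarity model (GDM), its projection onto raster landscapes (genomic
composition maps, genomic vulnerability under a future climate scenario,
seed-source matching for a restoration site), and a Qst–Fst comparison for
maternal half-sib seedling trials.

## Population-genomic inputs

Genotypes are biallelic SNPs coded as alternate-allele counts (0/1/2,
missing allowed). `filter_and_thin()` applies, in order: removal of samples
with more than 60% missing calls, removal of loci with more than 60%
missing calls, and greedy left-to-right thinning per chromosome so that
retained loci are more than 300 bp apart. Both missingness cutoffs are
strict-greater rules, and thinning keeps a locus only when it lies more
than the minimum spacing beyond the last *kept* locus, matching the
semantics of the common VCF thinning tools.

Individual genomic distances are Euclidean over shared (pairwise-complete)
loci, rescaled by `sqrt(L / L_shared)` so pairs with different missingness
stay on one scale; no imputation is performed. Geographic distances are
great-circle (haversine) on a sphere of authalic radius 6371.0087714 km.
`pcoa()` is classical scaling (double-centre −½D², eigendecompose), with
percent variance computed over positive eigenvalues only. `mantel_test()`
correlates lower triangles and computes a one-sided permutation p-value
`(1 + #{r* ≥ r}) / (n_perm + 1)`; by default the second matrix is
natural-log transformed, with co-located pairs set to 1 m beforehand (the
count of such pairs is reported). An exhaustive mode enumerates all n!
permutations for small matrices.

Site differentiation uses the Weir–Cockerham (1984) estimator: per-locus
variance components a (among populations), b (among individuals within
populations) and c (within individuals), combined across loci polymorphic
in the pair as `sum(a) / sum(a + b + c)` (ratio of sums). Slightly negative
estimates are retained until `scale_unit_interval()`, which maps
off-diagonal values affinely so the minimum becomes 0 and the maximum 1.
The verbal rule "subtract the minimum, divide by the maximum" is ambiguous
about whether the divisor is the original or the shifted maximum; only the
shifted-max reading guarantees a [0, 1] response, so that is implemented.

## The dissimilarity model

The GDM regresses the scaled Fst response d for every unordered site pair
on monotone transforms of predictor differences:

  mu = 1 − exp(−eta),  eta = beta0 + sum_p sum_k beta_pk |I_pk(x_i) − I_pk(x_j)|

with every beta non-negative. Each predictor gets K = 3 monotone I-splines
(integrated quadratic M-splines) with knots at the 0/50/100-percentiles of
the observed site values, normalized so I(min) = 0 and I(max) = 1.
Geography enters as one additional predictor: the same basis evaluated at
pairwise great-circle distance, with the lower knot anchored at 0 km so
the basis vanishes for co-located sites.

Fitting minimizes the squared-error deviance `D = sum((d − mu)^2)` by
Gauss–Newton iteration; each step solves a non-negative least-squares
subproblem (Lawson–Hanson, via `pracma::lsqnonneg`) on the linearized
model, with step-halving if a step would increase D. The fit is
zero-initialized and fully deterministic; convergence is declared when D
improves by less than 1e-10 (at most 100 iterations). Deviance explained
is `1 − D_model / D_null` with D_null the best intercept-only fit of the
same family. The reference GDM literature defines its own deviance; the
squared-error form used here is monotone-equivalent for ranking fits but
not numerically identical, so deviance-explained values are comparable in
kind, not digit for digit.

At prediction time, inputs outside the training range are clamped to the
range and counted: extrapolating a monotone quadratic spline beyond its
knots is undefined, and projection rasters routinely exceed training
ranges.

### Variable selection and validation

`select_variables()` applies three stages in order: (1) drop candidates
whose single-variable model (the candidate plus geography) explains less
than 5% of the deviance; (2) among survivors, repeatedly find the pair of
site-value vectors with |Pearson r| above 0.60 and drop the member with the
lower single-variable deviance; (3) permutation importance on the joint
model (values permuted across sites, pairs rebuilt, model refitted;
importance is the mean percent drop in deviance explained, p the
+1-corrected exceedance probability). Stage 3 flags weak variables for
review rather than removing them, because the analogous step in practice
involves analyst judgment; automatic removal is available behind a flag.

Because stage 1 includes geography, a predictor with no effect of its own
can survive it whenever geography alone clears the floor; such predictors
are caught by the stage-3 flags. Note also that two independently
generated landscape layers can be strongly correlated *at the sampled
sites* by chance; when that happens to two genuine drivers the correlation
screen keeps the stronger one, which is the intended behaviour of the
rule, not a selection failure.

`cross_validate()` holds out a random 30% of sites per iteration, fits on
the training pairs, predicts dissimilarities among held-out sites only,
and reports the Pearson correlation with the observed values (1000
iterations by default). Iterations with a constant held-out response are
counted and excluded from the mean: with few sites a 30% holdout can be
degenerate.

## Landscape projection

`transform_environment()` maps each raster layer cellwise through its
fitted partial spline. Two geographic layers are added by evaluating the
geographic spline on each cell's easting/northing offsets (in km) from the
mask's west/south edges; this coordinate-transform approximation of a
distance-based term mirrors common practice and is documented as such.
`pca_rgb()` runs a centred PCA over in-mask cells and rescales the first
three components to [0, 255] as red/green/blue: similar colours mean
similar predicted genomic composition. Whether the geographic layers
belong in that PCA is not settled; they are included by default with
`include_geography = FALSE` available.

Genomic vulnerability is the predicted dissimilarity between a cell's
current and future environments at zero geographic distance:
`1 − exp(−sum_p |f_p(x_cur) − f_p(x_fut)|)`. The seed-source map compares a
restoration target under its future environment with every cell under its
current environment, including the geographic spline at the
target-to-cell distance; low values mark good sources. Both maps exclude
the intercept by default: beta0 encodes the baseline dissimilarity of
distinct samples and would put a constant floor under same-place
comparisons (`include_intercept = TRUE` restores it). Nodata propagates
through any predictor, and cells outside the mask are nodata in every
output.

With no dedicated raster package among the dependencies, the raster
container is a plain list of co-registered matrices with a geotransform;
I/O uses ESRI ASCII grids (and optional PNG export for RGB maps), and the
region mask is a GeoJSON polygon rasterized by point-in-polygon on cell
centres.

## Qst–Fst for maternal half-sib designs

Growth-trait metrics: relative height increment is
`(ln h2 − ln h1)/(t2 − t1)` per day, with values above 0.035/day flagged
as outliers but never removed; specific leaf area is area/mass.
`variance_partition()` gives a sequential (type I) percent-of-sum-of-squares
decomposition over condition, site and line-within-site — a deterministic
fixed-effects approximation of a mixed-model partition, with the order part
of the contract.

`nested_variance_components()` estimates among-site, among-line and
residual variance by method of moments from the nested ANOVA mean squares,
using the unbalanced-design expected-mean-square coefficients; negative
estimates are truncated at zero and flagged. For offspring related as
maternal half-sibs the additive variance is four times the line variance,
so `Qst = s_site / (s_site + 8 s_fam)`.

`qst_fst_test()` compares Qst with the multilocus Weir–Cockerham Fst of
the phenotyped sites. The null distribution of `delta = Qst − Fst` is
simulated: each replicate bootstraps loci to draw F*, sets the neutral
among-site variance `sigma_B* = [2F*/(1 − F*)]·(4 sigma_fam)`, draws the
three ANOVA *mean squares* from scaled chi-squared distributions with their
degrees of freedom, and pushes them through the same method-of-moments
(including truncation) as the observed estimate. Drawing mean squares
rather than components matters: the components themselves are differences
of scaled chi-squares and simulating them directly as chi-squares badly
inflates the type-I error. The family variance entering the null centres
is a df-weighted pool of the line-stratum estimate and the site-stratum
estimate implied by the neutral relation, which stabilizes the null when
the line degrees of freedom are small. The p-value is two-tailed on |delta|
with the +1 correction (one-tailed available); locus bootstrap is the
resampling unit for F*. Qst is computed per trait and per condition.

## The synthetic world

Every stage is testable without downloads through `world_config()` and the
`generate_*()` functions. Defaults emulate the study design this package
targets: a roughly 1000 × 1200 km landscape (40 × 48 cells of 0.25°), 36
sampling sites of 3–10 trees, 9,378 biallelic SNPs, four environmental
drivers, and a geographic effect that is flat to 500 km.

* Environmental layers are Gaussian random fields: seeded white noise
  smoothed with a Gaussian kernel (correlation length 6 cells ≈ 150 km),
  standardized to mean 0, sd 1. The future scenario adds a uniform shift
  (+1 sd) and a north–south gradient (0.5 sd).
* Genotypes: per locus an ancestral frequency p0 ~ U(0.1, 0.9); site
  deviations on the logit scale are multivariate normal with covariance
  `s² exp(−eta_ij)`, where eta is the generating linear predictor — so
  differentiation grows monotonically with eta. Site frequencies are
  logistic-transformed and genotypes drawn Binomial(2, p). Since
  `exp(−eta)` need not be positive definite, small negative eigenvalues
  are clipped (floor 1e-6 of the leading eigenvalue) before Cholesky;
  generation errors out if the matrix is far from PD. The scale s = 0.8
  was calibrated empirically, once, so the realized pairwise Fst
  distribution matches the intended study conditions (mean ≈ 0.04,
  sd ≈ 0.02, maximum ≈ 0.09); a logit-normal model was chosen over a
  Balding–Nichols construction because only a normal model expresses an
  arbitrary pairwise covariance keyed to eta.
* The flat-to-rising geographic effect is a smooth quadratic:
  zero value and slope at the 500 km threshold, rising to its maximum at
  1200 km. A kinked linear ramp is *not* representable by the monotone
  quadratic spline family — its best noiseless approximation already
  leaks about 10% of the spline maximum below the threshold — so the
  smooth form is the right truth for recovery checks of the flat region.
* Phenotypes follow `y = mu + condition + site + line + residual` with
  configurable components; in the neutral setting the site variance is
  derived from the realized genomic Fst through the same half-sib
  relation used by the test, optionally inflated to emulate divergent
  selection.
* A truth record (per-pair eta and mu, driver identities, bases,
  sub-seeds) accompanies every dataset and suffices to recompute expected
  values without regeneration.

What the generator does not emulate: linkage disequilibrium, individual
loci under selection, coalescent noise structure, non-Gaussian
environmental fields, and climate-model spatial structure in the future
scenario. Passing tests therefore demonstrate the estimators' behaviour
under the stated statistical structure, not performance on any particular
empirical dataset.

## Reproducibility and problem sizes

Every stochastic operation takes a seed; pipeline stages derive their own
seeds deterministically from one master seed (`derive_seed()`), and two
runs with the same configuration produce byte-identical numeric outputs.
The test suite exercises the estimator oracles at hand-traceable sizes,
statistical calibration at 500 simulated datasets (null replicates scaled
to 1000 per dataset) and 1000 Mantel null simulations of 12 samples with
999 permutations, and driver recovery over 20 seeded worlds at the full
36-site, 9,378-locus preset — sizes chosen to give stable Monte Carlo
estimates while keeping a complete run of the suite on one CPU
comfortable.

## Known limitations

* The squared-error GDM deviance is not numerically the reference
  implementation's deviance; percent-deviance figures are therefore not
  directly transferable.
* The geographic layers in `transform_environment()` approximate a
  distance-based model term with two coordinate-based terms.
* The method-of-moments variance partition replaces REML mixed models by
  design; with strongly unbalanced phenotype tables its site stratum is
  noisy, and Qst inherits that noise.
* Masks are rasterized by cell-centre membership; cells straddling the
  polygon boundary are all-in or all-out.
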