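---
title: "Methods: harmonized diversity meta-regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: harmonized diversity meta-regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popgendiv)
```

## The problem

Published estimates of within-population genetic diversity -- expected
heterozygosity ($H_E$) from nuclear markers -- accumulate across
thousands of studies, but they are not directly comparable: marker
systems bound $H_E$ differently (dominant AFLP-type markers at 0.5,
codominant microsatellites at 1, allozymes lower still), sampling effort
varies by orders of magnitude, and populations of one species share
history and methodology. `popgendiv` implements a complete meta-regression
pipeline that harmonizes such records, attaches life-history, climate and
biogeographic covariates, and asks which of these factors structure
diversity worldwide -- with a synthetic-data generator providing known
ground truth so every stage can be verified quantitatively.

## Response harmonization

Raw $H_E$ is transformed in two affine stages:

1. z-score within each marker type, using the sample ($n-1$) standard
   deviation, so each marker system contributes on a common scale;
2. min-max rescale of the pooled standardized values to $[0, 1]$.

Stage 2 pools both kingdoms by default so that cross-kingdom contrasts
are made on one scale; `harmonize_gdp(pool = "kingdom")` switches to a
per-kingdom rescale. Whether the original analysis pooled or rescaled per
group is not derivable from the harmonized values alone; pooling is our
default and we flag it as an assumption. Rank order within a marker type
is preserved by construction, and re-harmonizing the harmonized response
is rank-stable.

Each record also receives a meta-regression precision weight

$$w_i = \frac{1}{\sqrt{\ln(\mathrm{loci}_i \times n_i)}},$$

which enters every model as a residual precision multiplier,
$\mathrm{Var}(\varepsilon_i) = \sigma^2 / w_i$. The natural logarithm is
the default; `precision_weight(base = )` exposes the base because the
formula is sometimes written with log10. The weight is undefined when
$\mathrm{loci} \times n \le$ the log base's unit, which the function
treats as a domain error.

Inclusion screening (`apply_inclusion_filters()`) drops populations with
fewer than 10 genotyped individuals (inclusive at 10), marine
populations, records flagged as introduced / invasive / cultivated
material, and records without coordinates, logging one reason code per
dropped row.

## Covariates

**Life-history principal components (animals).** Lifetime fecundity,
body size and maximum longevity are log10-transformed, standardized and
reduced by PCA. Signs are fixed so the first component loads positively
on size and longevity (a slow--fast continuum) and the second positively
on fecundity. Scores are zero-mean; the full loading matrix is kept so
the standardized traits can be reconstructed exactly from all
components.

**Climate axes.** Site-level climate variables are standardized and
reduced by PCA; the three retained orthogonal components are labeled
temperature / precipitation / humidity by the variable family of each
component's dominant loading (families inferred from column-name
prefixes, or supplied explicitly). Each component's sign is set so its
dominant loading is positive.

**Past-temperature stability.** For each reference epoch (Mid-Holocene,
~6 kyr BP; Last Glacial Maximum, ~22 kyr BP) the raw score is
$-|t_{\mathrm{now}} - t_{\mathrm{past}}|$, z-standardized across the
dataset. The negated absolute difference makes "more stable" read as
"larger", so positive model coefficients mean diversity increases with
stability; the literal phrase "standardized difference" leaves the sign
convention open, and ours is configurable by negating the input. Scores
are invariant to common additive shifts of both epochs.

**Biogeographic position.** Species confined to less than 10,000 km²
are `endemic` wherever sampled; populations on insular landmasses are
`island` or `isle` depending on the same 10,000-km² threshold applied to
the landmass; mainland populations are `core`, `subedge` or `edge`
according to whether they fall inside the inner region holding 50% of
the range area, between 50% and 75%, or in the outer 25%. Two genuinely
open design points are resolved as follows and kept configurable:

* *Area vs distance banding.* We band by **area share**, realized as
  inward erosion: the inner region at erosion distance $d$ is the set of
  in-range points at least $d$ from the boundary, and $d$ is found by
  binary search until the eroded area matches the target share. Bands
  defined by distance-to-boundary quantiles would differ on elongated
  ranges.
* *Numerics.* Geometry is evaluated in a spherical Lambert azimuthal
  equal-area projection centered on the range's vertex centroid; area is
  sampled on a 400x400 grid over the range bounding box (the binary
  search stops at 0.05% of the target share, well inside the 0.5%
  guarantee we document); points up to 1 km outside the polygon are
  snapped to `edge`, farther points are an error. On a circular range
  the recovered core radius matches the analytic $R/\sqrt{2}$ to
  ~0.05% in area.

Populations may alternatively carry a precomputed position label
(pass-through), since published labels are generally not re-derivable
without the original range maps.

## The weighted mixed model

All models are Gaussian linear mixed models fitted by `lme4`, with
independent random intercepts and the precision weights above. The two
descriptive gradient models are

* kingdom level: `gdp ~ |latitude| * kingdom + (1|species) + (1|marker)`;
* phylum level: `gdp ~ |latitude| * phylum + (1|species) + (1|marker) +
  (1|kingdom)`,

and the per-kingdom "full" models add position, life-history descriptors
(trait PCs for animals; pollen, seed, mating and lifeform classes for
plants), range size, elevation, the climate axes and both stability
scores, plus position x life-history and phylum x predictor pairwise
interactions.

Choices that the original description leaves open, fixed here:

* **ML vs REML.** Maximum likelihood for every fit that participates in
  model comparison (AICc is not comparable across fixed structures under
  REML); the reported final model is refit by REML. Both are available
  on any `model_spec`.
* **Parameter count for AICc.** $k$ = fixed coefficients + one per
  random-intercept variance + 1 for the residual variance.
* **Marker as a random term.** Marker type enters as a random intercept
  despite having only three levels. When its variance estimate hits the
  zero boundary the fit is flagged, and `boundary_fallback = TRUE`
  refits with marker type as a fixed effect. The fallback is *not*
  applied inside an enumerated model set -- switching the random
  structure mid-enumeration would break AICc comparability -- only for
  standalone/final fits.
* **$R^2$ for weighted fits.** Marginal and conditional $R^2$ follow the
  variance-partition decomposition
  $R^2_m = \mathrm{var}(X\hat\beta) / (\mathrm{var}(X\hat\beta) +
  \sum\tau^2 + \bar\sigma^2)$, with $\bar\sigma^2$ taken as the residual
  variance parameter at unit weight. With heteroscedastic residuals
  there is no single residual variance; using the unit-weight parameter
  is an explicit assumption, documented here.
* **Wald inference.** Coefficient p-values and CIs are normal-based;
  per-group slopes from an interaction fit are contrasts $c'\hat\beta$
  with $\mathrm{SE} = \sqrt{c'\hat\Sigma c}$ from the full fixed-effect
  covariance.

A useful identity for testing: with no random terms and equal weights
the fit equals closed-form OLS (verified to 1e-8). Duplicating every row
while halving its weight leaves the weighted least-squares coefficients
exactly unchanged; in the mixed model the variance components are
re-estimated under the doubled nominal $n$, so the identity holds only
to $O(1/n)$ -- an inherent property of ML variance estimation, not a
numerical defect.

## Model selection and relative importance

`enumerate_submodels()` generates every subset of the full fixed terms
in which an interaction is always accompanied by both parent mains
(marginality), from the intercept-only model upward; random structure
and weights are held fixed across the space. Enumeration is capped
(default 1e5) with an explicit error advising term reduction -- the
complete kingdom models are deliberately above the cap, and desk-scale
analyses dredge a reduced space.

Each submodel is fitted by ML and scored by AICc
($\mathrm{AIC} + 2k(k+1)/(n-k-1)$; we standardize on AICc throughout).
The candidate set keeps models within $\Delta\mathrm{AICc} < 4$ of the
best and renormalizes Akaike weights over that set, so the relative
importance of a term -- the summed weight of candidate models containing
it -- is 100% exactly when the term is in every candidate model.
Categorical terms are selected whole (all levels in or out). Final-model
terms are those with RI **strictly** above 50%, closed under marginality
(a selected interaction pulls in its mains); the final model is refit by
REML. Continuous AICc values make tie-breaking unnecessary; exact ties
share weight naturally.

### What RI discrimination can and cannot promise

For a zero-effect term with $p$ parameters, its models beat the AICc
penalty when the null chi-square improvement exceeds $\approx 2p$. For
multi-parameter terms (the 6-level position class, phylum, their
interactions) that probability is small ($P(\chi^2_5 > 10) \approx
0.075$), so RI falls below 50% in well over 90% of replicates. For a
**single-df** zero-effect covariate the same event has probability
$P(\chi^2_1 > 2) \approx 0.157$: about one replicate in six will put a
pure-noise 1-df term above 50% RI. This is a property of AIC-type
selection itself, not of the implementation; our recovery tests
therefore hold the >=90% discrimination guarantee for multi-parameter
terms and a correspondingly weaker (~84%, tested at its 3-sigma lower
bound) guarantee for 1-df noise terms. Interpretations of RI for
single-df predictors should bear this false-selection rate in mind.

## Spatial and robustness diagnostics

**Correlograms.** Moran's I is computed per great-circle distance class
(haversine, 6371-km sphere) with binary membership weights; the
one-sided permutation p-value per class is
$(1 + \#\{I_{\mathrm{perm}} \ge I_{\mathrm{obs}}\})/(B+1)$ under joint
relabelling of values across sites. Since the original distance classes
are unstated, the function defaults to 100-km classes to 5000 km with
$B = 999$ (the pipeline's desk-scale defaults are 250-km classes to
3000 km, $B = 199$); classes with fewer than two pairs are flagged empty
and carry no statistic. The expectation under no autocorrelation,
$-1/(n-1)$, is attached to every correlogram. Internally the per-class
statistic uses a pair-list formulation (identical to the weight-matrix
form, which the tests verify) so that permutations cost $O(\text{pairs})$
rather than $O(n^2)$ per class.

**Jackknife.** Units are either species or occupied 3-degree cells
(half-open intervals anchored at (-180, -90); longitude 180 folds into
the westernmost adjacent cell). The model is refit once per left-out
unit; the delete-group SE is $\sqrt{\frac{m-1}{m}\sum_i(\hat\theta_{-i} -
\bar\theta)^2}$ with group-count scaling and unequal group sizes accepted
as-is, and the 95% CI is SE-based around the full-data estimate (whether
the original CIs were percentile- or SE-based is unstated; SE-based is
our choice). Failed refits -- typically a leave-out that empties a factor
level -- are logged, warned about and skipped.

## The synthetic generator

`synthetic_config()` encodes the reference study conditions used by all
recovery tests: 250 species allocated over nine phyla in two kingdoms,
2--50 populations per species with mean 6 (about 1500 populations),
marker mixture 60/25/15 codominant/dominant/enzyme, position frequencies
35/20/20/10/10/5 for core/subedge/edge/endemic/island/isle, species
range centers across -55..70 degrees latitude with 1.5-degree population
scatter, and a response simulated **directly on the harmonized scale**:
$y = X\beta + u_{\mathrm{species}} + u_{\mathrm{marker}} + \varepsilon$
with $\tau^2_{\mathrm{species}} = 0.01$, $\tau^2_{\mathrm{marker}} =
0.002$, $\sigma^2 = 0.02$ (species variance deliberately half the
residual variance) and $\mathrm{Var}(\varepsilon_i) = \sigma^2/w_i$.
The default fixed effects are an intercept of 0.55, a plant deficit of
-0.15 and a slope of -0.05 on the *standardized* distance from the
equator; continuous covariates enter the generating design z-scored, so
"slope" is per SD of |latitude| (about 25 degrees under the default
spatial model), which keeps the response inside a realistic 0--1 band
without clipping (a clipped variant exists and is off by default).
Site temperatures are latitude-driven with epoch-specific drift, giving
the stability scores realistic structure; a raw-He column is provided
through a marker-specific affine back-transform for I/O realism only.

One root seed drives named sub-streams (species, populations, climate,
response), so components can be regenerated in isolation and every table
is byte-reproducible. Dataset bundles serialize doubles at `%.17g`, so
CSV round-trips recover exact binary values.

What the generator does **not** emulate -- and hence what passing
recovery tests do not establish about real compilations: phylogenetic
covariance beyond species identity, spatial clustering of sampling
effort (synthetic ranges scatter nearly uniformly, so occupied 3-degree
cells are more numerous than in real data), publication bias, and any
mechanistic link between $H_E$ and the covariates (the response is
phenomenological, not coalescent-based).

## Problem sizes and runtime choices

The test suite verifies oracle equivalences on small instances
($n \le 30$ Moran matrices, <=6-term model spaces), geometry on 70x70
classification grids, and the recovery study at the full reference
conditions (100 seeds x ~1500 populations; the dredge replicates use a
20-model space spanning active, multi-parameter-noise and 1-df-noise
terms). The pipeline's default dredge space is a reduced 5--7 main
space for the same reason. These sizes are the package's choices for a
reproducible desk-scale study; all are configurable upward.

## Known limitations

* Random-intercept structures only: no random slopes, no phylogenetic
  or spatial covariance matrices, Gaussian responses only.
* The position classifier assumes reasonably well-conditioned polygons;
  bands on strongly non-convex ranges follow the erosion definition,
  which may differ from intuitive "distance from edge" bands.
* Coefficients are not model-averaged; the workflow refits a single
  final model from the RI-selected terms.
* The climate axes here are synthetic site-level covariates; raster
  extraction and the exact composition of real climate PCAs are out of
  scope.
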