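---
title: "Ensemble null models for gene category enrichment on spatial transcriptomic atlases"
author: "ensembleGCEA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble null models for spatial GCEA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensembleGCEA)
```

## The problem

Gene category enrichment analysis (GCEA) on spatially resolved
transcriptomic atlases asks whether genes annotated to a functional
category (a Gene Ontology biological process, say) are preferentially
correlated with a spatial brain phenotype (SBP) — a map assigning one value
to each brain region, such as a cell density or a connectome nodal degree.
The workhorse procedure is gene-score resampling: each gene receives a
score, the spatial correlation between its expression profile and the
phenotype; category scores are the mean score over member genes; and
significance is assessed against a *random-gene* null in which category
scores are recomputed for randomly resampled gene sets of the same size.

Two generic properties of atlas data violate the exchangeability this null
assumes. First, genes annotated to the same category tend to be
*coexpressed*: their spatial profiles are correlated, so the category mean
score has a much larger sampling variance across phenotypes than the mean
of an equally sized random gene set. Second, expression profiles and many
phenotypes are *spatially autocorrelated*, which further widens the
distribution of observed spatial correlations. Both effects let entirely
uninformative phenotypes produce "significant" categories at rates far
above the nominal level — and they do so reproducibly, for the same
categories, because coexpression and autocorrelation are properties of the
expression atlas, not of any particular phenotype.

This package implements the conventional pipeline, two *ensemble* null
models that repair it, and the auditing machinery to measure how badly a
given configuration misbehaves.

## Null models

Let $x_g \in [-1, 1]$ be gene $g$'s score (Pearson by default, Spearman
optional), and $S_C = \frac{1}{s}\sum_{g \in C} x_g$ the score of category
$C$ with $s$ measured member genes.

**Random-gene null.** For each size $s$, the null is the distribution of
the mean of $s$ scores drawn uniformly without replacement from the scored
gene pool. The default fits a Gaussian to 40,000 resampled means. Because
those moments converge to the closed-form finite-population values
$\mu = \bar{x}$ and $\sigma^2 = \frac{S^2}{s}(1 - s/N)$ (pool size $N$,
sample variance $S^2$), `buildRandomGeneNull(exact = TRUE)` computes them
directly; the resampled and closed-form fits agree to within Monte-Carlo
error (this is asserted in the test suite) and the exact mode is what makes
multi-thousand-phenotype audits tractable.

**Ensemble nulls.** `buildEnsembleNull()` scores every gene against each
of $n_{null}$ surrogate phenotypes and aggregates per category, giving each
category its own null that inherits the atlas's coexpression structure.
Surrogates come in two flavours:

* *SBP-random* (`generateRandomMaps()`): independent standard-normal
  values per region.
* *SBP-spatial* (`generateSpatialLagMaps()`): draws from the spatial-lag
  model $u = (I - \rho W)^{-1}\varepsilon$ with
  $W_{ij} = \exp(-d_{ij}/d_0)$ for $i \ne j$, zero diagonal and rows
  normalized to unit sum. $\rho \in [0, 1)$ sets the autocorrelation
  strength relative to noise (default 0.8) and $d_0$ (mm) the
  characteristic length. Row normalization is an implementation choice the
  model statement leaves open; it guarantees $(I - \rho W)$ is invertible
  for every $\rho < 1$ and is recorded in the ensemble spec. The analytic
  covariance $(I-\rho W)^{-1}(I-\rho W^{\top})^{-1}$ is exposed as
  `spatialLagCovariance()` and used as an independent oracle in the tests.

$d_0$ is estimated from the data by `fitSpatialScale()`: correlated gene
expression (CGE) across all genes is computed for every region pair and
fitted with the three-parameter exponential
$\mathrm{CGE}(d) = A e^{-d/\lambda} + B$; $d_0 := \lambda$.

Ensemble null banks are phenotype independent: building one is a one-off
cost, after which any number of phenotypes can be evaluated against it.
Banks record the scoring configuration (correlation method and raw vs
absolute transform) and refuse evaluation under a different configuration.

**p-values and FDR.** The default $p_Z$ comes from a Gaussian fitted to
the null samples (right tail by default; two-sided doubles the smaller
tail; values are floored at the smallest positive double). The Gaussian
fit systematically underestimates small $p$ relative to a full permutation
test, so an empirical mode (`pMode = "empirical"`,
$p = (1 + \#\{x_{null} \ge x\})/(n+1)$) is available whenever raw null
samples are retained; under a matched generating process its p-values are
uniform (tested). Multiple-testing correction is Benjamini–Hochberg
(`bhFDR()`). BH was chosen over Storey's pFDR because it is deterministic
and conservative; the original analyses used a MATLAB `mafdr` call whose
variant is ambiguous, so exact significant-category counts can differ
slightly from analyses using pFDR.

## CFPR auditing

`computeCFPR()` runs GCEA once per surrogate phenotype and reports each
category's false-positive rate, the percentage of phenotypes with
$q_{FDR} < \alpha$ (default 0.05). Three conditions matter:

* **reference** — expression randomized per gene
  (`referenceRandomize()`, which permutes each gene's observed values
  independently while preserving missingness) with random phenotypes:
  the floor any unbiased procedure should sit at;
* **sbp_random** — real (structured) expression, random phenotypes;
* **sbp_spatial** — structured expression, spatially autocorrelated
  phenotypes.

The audit fixes the inner GCEA to the random-gene null because the CFPR is
defined as the conventional method's false-positive rate; passing an
ensemble bank instead audits the corrected procedure, which should stay at
the nominal level. The vectorized audit path is verified in the tests
against a literal phenotype-by-phenotype `runGCEA()` loop.
`summarizeCFPR()` relates CFPRs to category properties through equiprobable
bins and computes fold changes between conditions and per-category changes
between the two ensembles.

Two category-level diagnostics explain *which* categories inflate:
$\langle r \rangle$ (`withinCategoryCoexpression()`), the mean pairwise
Spearman coexpression of member genes, drives inflation under random
phenotypes; $R^2_{exp}$ (`categoryCGE()` + `fitExpDecay()`), the goodness
of the exponential distance-CGE fit, indexes the spatial autocorrelation
that interacts with SBP-spatial ensembles. The fit-free alternative
statistic $-\rho_{Spearman}(\mathrm{CGE}, d)$ is reported alongside.

## Ontology handling

`parseOBO()` reads OBO 1.2 structure; only `is_a` edges define the
hierarchy (a `part_of` capture flag exists, off by default, because
annotation propagation is specified along `is_a` alone). `parseGAF()`
reads 17-column GAF 2.x annotations and always excludes NOT-qualified and
ND-evidence records. `propagateAnnotations()` adds every transitive
ancestor (obsolete terms never participate), and `buildCategoryTable()`
optionally maps gene identifiers through a static join table, intersects
with the measured-gene universe, and filters sizes to $[10, 200]$ by
default. Sizes are computed *after* universe intersection, so $s$ always
equals the size of the pool the null models resample — a category with 250
annotations but 150 measured genes enters at $s = 150$.

## The synthetic atlas generator

`makeSyntheticAtlas()` emulates the statistical structure the analyses
depend on, not any particular organism. Member genes of an engineered
category mix a latent map with idiosyncratic noise,
$g = wL + \sqrt{1 - w^2}\,\sigma z$, so the population pairwise
within-category correlation is $w^2$ at the default $\sigma = 1$ — an
analytic handle used to validate $\langle r \rangle$ (via the Gaussian
Spearman correspondence $\rho_S = \frac{6}{\pi}\arcsin(\rho/2)$). When an
autocorrelation length $\ell$ is set, both the latent and each gene's
idiosyncratic component are Gaussian random fields with inter-region
correlation $e^{-d/\ell}$. Two points deserve emphasis:

* The spatial fields use the exponential-kernel random field directly
  rather than the spatial-lag generator. A single shared spatially smooth
  latent would *not* produce distance-dependent CGE — the across-gene
  correlation in CGE removes any component shared by all member genes — so
  gene-level heterogeneity must carry the structure, as it does in real
  transcriptomes. And the spatial-lag model's realized correlation length
  is a multiple (roughly 2.5–3x under row normalization) of its $d_0$
  parameter, whereas the generator's $\ell$ is, by construction, the
  correlation length itself; this is what makes "recover $\ell$ within
  25%" a well-posed parameter-recovery statement for `fitSpatialScale()`.
  Recovery is cleanest when $\ell$ is well below the domain size (the test
  fixtures use $\ell = 5$ mm in a 40 mm box, mirroring the mm-scale
  correlation lengths of real brains); per-gene standardization removes
  each gene's spatial mean and biases $\hat\lambda$ downward as
  $\ell$ approaches the domain size.
* A shared smooth gradient (linear in a random direction, strength
  configurable) can be added to every gene to emulate a dominant
  expression gradient; `makeGradientAlignedPhenotype()` extracts the
  leading spatial principal component as a phenotype aligned with it. This
  reproduces the mechanism by which the random-gene null becomes
  *conservative*: when every gene scores highly, the resampling null
  inherits the shifted mean and the phenotype-specific signal disappears
  into it, while ensemble nulls keep the per-category reference at zero.

What the generator does **not** emulate: donor-level structure, probe- or
section-level measurement noise, normalization artifacts, realistic GO
topology (engineered categories are disjoint; `makeRandomCategories()`
produces overlapping random sets), or non-Gaussian marginals. Passing
tests therefore demonstrate the statistical mechanisms and the correctness
of the machinery, not that any particular real dataset is well calibrated.

## Numerical choices

* **Correlations** use pairwise-complete observations throughout, matching
  incomplete atlases after the 50% quality filter (`applyQualityFilter()`
  removes under-sampled genes first, then regions — the order changes the
  result and is fixed). Spearman ties get average ranks.
* **Exponential fits** run Levenberg–Marquardt from
  $A_0 = \max y - \min y$, $\lambda_0 = \mathrm{median}(d)$,
  $B_0 = \min y$, with $\lambda$ bounded positive. Because fast decays are
  easily missed from a long-length start, additional starts over distance
  quantiles are tried and the best sum of squares kept; non-convergence is
  flagged on the returned object rather than raised.
* **Audit problem sizes.** The package's own validation runs at
  deliberately modest scales chosen for seconds-to-minutes turnaround:
  the bundled reference-calibration script uses a 213-region x
  19,417-gene i.i.d. atlas, 6,000 random categories and 2,000 random
  phenotypes (full-scale audits use 10,000); mechanism fixtures use
  ~100 regions and 1,000–1,200 genes. At these ensemble sizes the mean
  reference CFPR is estimated from order-100 significance events, i.e. to
  ~10% relative Monte-Carlo error.
* **Determinism.** Every stochastic function takes a seed; ensembles carry
  a spec sufficient for bit-identical regeneration
  (`regenerateEnsemble()`), and result tables carry a JSON run record that
  reproduces them byte for byte. A single master seed per generator call
  is used (rather than per-map substreams); regeneration is all-or-nothing
  but exactly reproducible.

## Limitations

The Gaussian $p_Z$ approximation is anti-conservative in the extreme tail;
for reporting a specific analysis at small $p$, use the empirical mode with
a large bank. Ensemble banks scale as categories x maps in memory when raw
samples are retained. Variogram-matching surrogates and spin tests are
out of scope, as are GSEA-style rank statistics, hierarchical GO testing,
and atlas preprocessing (probe selection, normalization, sample-to-region
assignment); expression matrices are expected pre-normalized.
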