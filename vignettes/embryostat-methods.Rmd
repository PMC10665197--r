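---
title: "Statistical methods for hashed whole-embryo single-cell experiments"
author: "embryostat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for hashed whole-embryo single-cell experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryostat)
```

## The setting

In a hashed whole-embryo experiment, every embryo is labelled with its own
hash oligonucleotide before nuclei are pooled, so each sequenced cell carries
a count vector over hash barcodes that identifies its animal of origin. With
many replicate embryos per genotype and stage, questions shift from "which
cells exist" to "how reproducible is the cellular composition of an embryo,
and which cell types change abundance when a gene is knocked out". This
package implements that statistical layer: demultiplexing and QC, the
embryo-by-cell-type composition matrix, beta-binomial differential
cell-type-abundance (DACT) testing, mean-variability trend modelling,
reference projection with label transfer, and local Getis-Ord hot/cold-spot
detection - together with a generative simulator that serves as the test
bed for all of it.

## The abundance model

For a focal cell type in embryo $e$, let $k_e$ be its cell count and $n_e$
the embryo's total. The count is modelled as beta-binomial,

$$k_e \sim \mathrm{BeBin}(n_e,\ \mu,\ \rho), \qquad
\mathrm{logit}(\mu) = \beta_0 + \beta_g x_e,\qquad
\mathrm{logit}(\rho) = \chi_0 + \chi_g x_e,$$

where $x_e$ indicates the knockout genotype. $\mu$ is the expected
proportion and $\rho$ the *litter effect*: the intra-class correlation of
cells within an embryo, i.e. overdispersion relative to binomial sampling
caused by genuine embryo-to-embryo variability. In shape terms the mixing
density is $\mathrm{Beta}(\mu(1-\rho)/\rho,\ (1-\mu)(1-\rho)/\rho)$, giving
$E[k] = n\mu$ and $\mathrm{Var}[k] = n\mu(1-\mu)(1+(n-1)\rho)$. Both
parameters carry a genotype term because perturbed embryos can be more
variable, not just shifted. An optional nuisance covariate (standardized
$\log(1+\text{periderm count})$, a proxy for animal size) can enter the
mean predictor.

The genotype effect $\beta_g$ is tested by a Wald test, and p-values are
Benjamini-Hochberg corrected across cell types within each
genotype-by-timepoint contrast; a cell type is called a DACT at $q < 0.01$
by default.

### Response scale

The likelihood needs integer successes and trials, so the response is the
raw count $k_e$ with the embryo total $n_e$ as denominator: recovery-depth
differences between embryos are absorbed by the binomial denominator.
Size-factor-normalized counts are used for visualization, embedding and the
variance module. A `rounded_normalized` compatibility mode feeds rounded
normalized counts instead; it is provided for comparison and not
recommended, since rounding breaks the count likelihood's variance
structure.

### Estimation details

Fitting is quasi-Newton (BFGS) on the joint log-likelihood with an analytic
gradient, started from the null model (pooled proportion; $\rho = 0.01$)
plus two deterministically jittered restarts, gradient tolerance relative
to the objective, standard errors from the inverse observed information
(numeric Hessian). Two small-sample safeguards matter in practice with
eight replicates per condition:

* **Dispersion boundary.** With few embryos the genotype-specific $\rho$
  frequently collapses to the $\rho = 0$ boundary, where the model deems
  that group binomially precise and the Wald standard error becomes
  spuriously small (|z| > 5 from a handful of cells). When one genotype's
  $\hat\rho$ hits the boundary while the other's does not, the dispersion
  predictor is reduced to a shared intercept for inference and the entry is
  flagged `dispersion_boundary`.
* **t reference.** Wald p-values use a Student-t reference with residual
  degrees of freedom (embryos minus parameters) rather than a normal; with
  ~34 embryos the normal reference is measurably anticonservative in the
  far tail that $q < 0.01$ calling probes.

Complete separation (the focal type absent from one group) is flagged and
inference suppressed; a Jeffreys-style half-count augmentation can rescue
such fits behind an explicit flag. Cell types absent everywhere are
reported, not tested. The exact denominator is the embryo total including
the focal type.

## Cell-count variability

Across replicate wild-type embryos of one stage, each cell type's
coefficient of variation $c_j = s_j/m_j$ of size-factor-normalized counts
is regressed on its mean with a gamma GLM (identity link) of the
dispersion-trend form

$$E[c] = a_0 + a_1 / m,$$

so rare types are dominated by counting noise ($a_1/m$) while abundant
types approach an asymptotic biological floor $a_0$. The gamma shape is
estimated from Pearson residuals; each type's one-sided upper-tail
probability under the fitted gamma law flags types significantly *more*
variable than the trend ($P < 0.05$, uncorrected by default, matching the
convention of flagging raw P in this analysis; an FDR option exists).
CoV is the primary response; squared-CoV/variance is available as an
alternative response flag. The sample (n-1) standard deviation is used.

## Size factors and composition preprocessing

An embryo's size factor is its total recovered cells divided by the
geometric mean of totals across embryos *of the same timepoint* - embryos
grow, so depth correction must not mix stages. Within every timepoint the
size factors therefore have geometric mean one, and normalized counts are
invariant to rescaling all of a timepoint's embryos. For embedding,
normalized counts are `log1p`-transformed (variance stabilization chosen
here; raw normalized counts are available via a flag), centered, and
reduced by PCA; any nonlinear embedding of those loadings is a pluggable
external step, not part of the statistical contract.

## Demultiplexing and QC

Cell filters run in a fixed order: lower UMI threshold (experiment-specific,
typically 100-250; default 250), then removal of cells more than four
standard deviations above the mean UMI of the surviving cells (the upper
rule is strict, so a zero-variance UMI distribution removes nothing), then
removal of cells above 25% mitochondrial reads. A cell is then assigned to
the embryo of its most abundant hash oligo when that count is at least
`min_top` (10) and the enrichment ratio top/max(second, 1) is at least
`min_ratio` (2.5); the `max(second, 1)` guard avoids division by zero, and
exact ties are never assigned. Doublets carry two embryos' hash signal at
roughly half rate each, so their enrichment ratios concentrate near one and
a strict ratio cutoff removes most of them.

## Projection and label transfer

A frozen reference transform stores per-gene centering/scaling constants on
`log1p` size-factor-normalized expression (size factors taken against the
*reference* geometric-mean UMI), the PCA rotation, per-component linear
coefficients of the loadings on $\log_{10}$ UMI, and the residualized
labelled reference loadings. Queries are normalized identically, rotated by
the stored matrix, and depth-corrected by subtracting the stored linear
effect - nothing is refit on the query, so projection is a fixed affine
map. Genes missing from a query are treated as zero counts (reported); an
overlap under 50% errors as a guard against mismatched annotations.
Labels transfer by majority vote among the k = 10 nearest reference cells
(exact Euclidean k-NN by default; an inverted-file approximate backend over
a coarse k-means partition is provided and is required to agree with exact
search on simulated data). Ties break by inverse-distance-weighted vote,
then by smaller mean neighbour distance - deterministic by construction.
Hierarchical transfer assigns a major group in the global space first, then
finer labels in the matching sub-model's space.

## Hot and cold spots

For a binary perturbation indicator $x$ over cells embedded in 2-3
dimensions, the local Getis-Ord statistic with binary weights over each
cell's k = 15 nearest neighbours (self excluded) is standardized
conditionally on the cell's own value:

$$z_i = \frac{\sum_{j} w_{ij} x_j - k\,\bar x_{(i)}}
{s_{(i)}\sqrt{\left[(n-1)k - k^2\right]/(n-2)}}.$$

This z has exactly mean zero and unit variance under random labelling (the
neighbourhood sum is hypergeometric). Two-sided p-values are Bonferroni
corrected over all defined cells; hot means enriched ($z > 0$) and cold
depleted ($z < 0$) at adjusted $p < 0.05$. A conditional-permutation
p-value (redrawing the k neighbour labels from the remaining cells) is
bundled as an internal oracle. A $G_i^*$ variant including the focal cell
is available. One caveat documented deliberately: with a binary indicator
the z-scores live on a lattice of $k+1$ neighbourhood sums, so although
their mean and standard deviation are calibrated, a Kolmogorov-Smirnov
distance to the continuous normal below ~0.06 is unattainable at k = 15;
inference relies on the exact conditional moments, not on continuity.

## Pseudo-cells

Expression is aggregated by summing raw counts over all cells of one type
in one embryo (sums, not means, preserving the count nature for downstream
GLMs); groups under `min_cells = 5` members are dropped and reported. The
per-gene differential-expression model downstream of this aggregation is
outside this package's scope.

## The simulator

`sim_config()` / `simulate_experiment()` generate a complete experiment
with known ground truth. Compositions are drawn per embryo from a
Dirichlet-multinomial with total concentration $\alpha_0 = (1-\rho)/\rho$,
so counts sum to the embryo total while each single type's marginal is
exactly $\mathrm{BeBin}(n, \mu_j, \rho)$ - the generative twin of the
abundance model. Perturbation effects add deltas to baseline log-odds
before softmax renormalization; because the softmax denominator excluding
the focal type is unchanged, a delta of $\delta$ shifts exactly that type's
log-odds by $\delta$, which is what parameter-recovery checks compare
against. Defaults mirror a heavily replicated crispant screen: 8 perturbed
vs 26 control embryos per timepoint, $\rho = 0.02$, ~1,800 cells per
embryo (lognormal, CV 0.4, floored at 50), and a deterministic abundance
ladder spanning common (~9%) to rare (<0.3%) among 40 types.

Expression is Poisson-lognormal around cell-type centroids separated by a
configurable multiple of the within-type standard deviation of
log-expression per gene; depth factors are lognormal. Hash counts are
Poisson signal (default 40) on the true embryo's oligo over Poisson
background (default 2) elsewhere; doublets merge two cells' expression and
split the hash signal at half rate. Mitochondrial fractions come from a
healthy beta population (mean 0.05) with a small failing spike (mean 0.4,
2% of cells). The per-embryo yield and hash-rate defaults are stated
modelling choices, not estimates of any particular dataset.

What the simulator does *not* emulate - and hence what passing tests do not
certify about real data - includes gene-gene correlation beyond cell-type
structure, ambient RNA and ambient hash contamination, batch effects, and
doublets between stages. Its role is to make every pipeline stage testable
against known truth, not to be a digital twin of a sequencing run.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on simulated data at
deliberately compact scales: composition-level checks use the full 8-vs-26
design (34 embryos, 40 types; 100 replicates for power, 1,000 fits for
calibration), while cell-level checks (demultiplexing, projection,
hot-spots) use a few thousand cells with tens of genes, which is ample to
exercise every code path and statistical property. Optimization tolerances,
restart jitter, and the k-NN tie-breaks are fixed constants documented
above; all randomness flows from explicit seeds, and identical seeds give
byte-identical outputs end to end, including through the command-line
pipeline.

## Known limitations

* Wald-only inference (no likelihood-ratio or score tests), matching the
  analysis convention this package encodes.
* The dispersion-boundary reduction is a pragmatic identifiability
  safeguard, not a shrinkage estimator; hierarchical sharing of dispersion
  across cell types is deliberately out of scope.
* Hot/cold-spot detection tests each perturbation label against all
  co-embedded cells; density-based neighbourhood tests are out of scope.
* Model-based hash demultiplexing (mixture models, ambient estimation) is
  out of scope; the enrichment-ratio rule is the documented contract.
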