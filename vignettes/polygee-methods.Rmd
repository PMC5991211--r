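---
title: "Estimating polygenic effects and confounding from summary statistics: model, estimation and design choices"
author: "polygee authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating polygenic effects and confounding from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polygee)
```

## The marginal model

Genome-wide association studies report a chi-squared statistic
$\chi^2_l$ per variant $l$.  Two mechanisms inflate these statistics
above their null expectation of 1: confounding (population
stratification), which lifts every statistic by roughly the same
amount, and polygenic signal, which lifts a variant in proportion to
how much causal variation it tags.  The amount of tagging is measured
by the LD score $\ell_l = \sum_v r^2_{lv}$, the sum of squared
correlations between variant $l$ and every variant within 1 cM
(including itself, so $\ell_l \ge 1$).  The package fits the marginal
model
$$
\mathrm{E}[\chi^2_l] \;=\; \beta_1 + C_{\text{study}}\,\ell_l\,\beta_2,
\qquad
\mathrm{Var}(\chi^2_l) \;=\; \phi\,\bigl(\mathrm{E}[\chi^2_l]\bigr)^2 .
$$
$\beta_1$ houses the confounding term $1 + Na$; $\beta_2$ houses the
heritability $h^2$ on the observed scale (the polygenic term).  The
quadratic variance is the gamma-type mean--variance relation of a
squared statistic; if genetic effects are normally distributed it
holds with $\phi = 2$ (the variance-to-squared-mean ratio of a scaled
$\chi^2_1$ variable), but $\phi$ is treated throughout as a free
nuisance parameter and estimated post hoc by the Pearson moment
estimator.

### Design constants

$C_{\text{study}}$ converts per-SNP heritability into statistic
inflation and depends only on a-priori known study parameters
(`study_design()`, `c_study()`):

* quantitative traits, unrelated individuals: $N/M$;
* case-control: $n_{\text{cases}} n_{\text{controls}} c^2 /
  ((1-K)^2 N M)$, where $K$ is the prevalence and $c = t/K$ the
  liability-scale factor ($t$ = standard normal density at the $1-K$
  quantile, `liability_context()`);
* family-based designs tested with the FBAT statistic (offset $z$,
  $n_a$ affected and $n_u$ unaffected offspring per family, $N$
  families):
  $c^2 \tfrac{N}{2}\,\bigl((1-z) n_a + z \tfrac{K}{1-K} n_u\bigr)^2 /
  \bigl(((1-z)^2 n_a + z^2 n_u)\,M\bigr)$.
  For affected-offspring trios ($z = 0$, $n_a = 1$) this collapses to
  $c^2 N / (2M)$;
* mixtures of designs: the weighted sum of the component constants.
  The weighting convention is not canonical; the package defaults to
  weights proportional to the component sample sizes (the natural
  choice when the per-study statistics are comparably scaled, as in a
  sample-size-weighted meta-analysis) and accepts explicit weights
  (`mixture_design()`).

$M$ is the number of common SNPs (MAF $\ge 5\%$) used to define
per-SNP heritability; it can be supplied or counted from the panel
(`count_common_variants()`).  The liability relation
$q^2 = 2p(1-p)(\lambda-1)^2/c^2$ (`explained_variance()`) links a
relative risk $\lambda$ at MAF $p$ to explained liability variance.
Estimated heritability is reported on the observed scale; conversion
to the liability scale is a constant factor and is left to the user.

## Estimation

Statistics are grouped into clusters along the genome: consecutive
half-open blocks of 1 cM of genetic distance, anchored at cM 0 on
each chromosome (`partition_blocks()`).  Since LD — and hence the
correlation between statistics — is negligible beyond 1 cM, blocks two
or more intervals apart are treated as independent, while genetically
adjacent blocks are allowed to be correlated.

Within cluster $i$, the working covariance is
$V_i = A_i^{1/2} R_i A_i^{1/2}$ with $A_i =
\operatorname{diag}(\mu_{ij}^2)$ and working correlation $R_i$ given by
the reference-panel $r^2$ between the member variants
(`working_correlations()`); $r^2$ is the correlation of *squared*
statistics implied by the classical result that association z-scores
of variants in LD $r$ correlate like $r$.  The estimating equation is
$$
g_n(\beta) \;=\; \sum_i X_i^\top V_i^{-1}(\beta)\,\bigl(y_i - X_i\beta\bigr)
\;=\; 0,
$$
with $X_i = [\,1,\; C_{\text{study}}\ell\,]$.  Under the identity mean
link the derivative matrix $D_i = \partial\mu_i/\partial\beta$ equals
$X_i$ (in the exponential-family notation, the product of the variance
diagonal and the link-derivative diagonal is the identity), and the
dispersion $\phi$ scales $g_n$ by a constant, so it cancels at the
root and is dropped during estimation.

`gee_solve()` runs Fisher scoring,
$\beta \leftarrow \beta + H_n^{-1} g_n$ with
$H_n = \sum_i X_i^\top V_i^{-1} X_i$, with step halving (up to 30
halvings) whenever a step would make some fitted mean non-positive —
the identity link does not keep the mean positive along the path — or
fail to decrease $\lVert g_n\rVert_\infty$.  Convergence is declared
at `tol = 1e-8` on the step size or on
$\lVert g_n \rVert_\infty / n$; non-convergence is flagged, never
silent.  The default start is $\beta_1 = \bar y$, $\beta_2 = 0$, which
is always admissible for non-negative statistics.

### Sandwich variance with correlated clusters

The covariance of $\hat\beta$ is estimated by
$\hat\Sigma = H_n^{-1} \hat M_n H_n^{-1}$ with
$$
\hat M_n \;=\; \sum_i g_{ni} g_{ni}^\top \;+\;
\sum_{\{i,j\}\ \text{adjacent}} \bigl(g_{ni} g_{nj}^\top +
g_{nj} g_{ni}^\top\bigr),
$$
where the second sum runs over unordered pairs of genetically adjacent
blocks (`block_adjacency()`), making $\hat M_n$ symmetric by
construction.  With the 1 cM band and 1 cM blocks, adjacency is
exactly the set of cluster pairs that can share correlated statistics.
In finite samples the cross-terms can make $\hat M_n$ indefinite; its
negative eigenvalues are clipped to zero, the standard remedy for
indefinite HAC-type covariance estimators.  Per-coordinate hypotheses
are tested by the Wald statistic
$W_b = \hat\beta_b^2 / \hat\Sigma_{bb}$ against $\chi^2(1)$
(`wald_test()`).

### Numerical choices

* **$r^2$ estimator** — raw squared Pearson correlation of phased
  allele indicators.  The bias-adjusted estimator used by some LD-score
  software is available behind `adjusted = TRUE`, but a working
  *correlation* matrix requires the raw quantity.
* **PSD repair** — estimated LD submatrices can be rank-deficient;
  `psd_repair()` clips eigenvalues at $10^{-6}$ and rescales the
  diagonal back to 1.  Perfect-LD pruning (`filter_perfect_ld()`,
  threshold $r^2 > 0.999$, keeping the first variant of each group in
  position order) removes the worst degeneracies before repair.
* **Shrinkage** — the misspecification experiment multiplies
  off-diagonal entries by $s$ (`shrink_correlation()`), i.e.
  $R' = sR + (1-s)I$, a convex combination with the identity that
  preserves positive semi-definiteness for $s \in [0,1]$.
* **Genetic coordinates** — 1-based bp positions; cM positions of
  variants absent from the map are linearly interpolated in bp between
  flanking map points, and variants outside the map span are dropped.
* **Degenerate blocks** — single-variant clusters are handled as
  scalars with no special-casing.
* **LD scores** — always taken from the reference panel (computed via
  `ld_scores()` or read from pre-computed files), never re-estimated
  from the study statistics.

## The explicit WLS comparator

LD Score regression fits the same mean model by weighted linear
regression.  For benchmarking, `wls_fit()` implements the explicit
closed-form estimator $(X^\top W X)^{-1} X^\top W y$ with the product
weights $w_l = \ell_l^{-1} \cdot \bigl(2\mu_l^2\bigr)^{-1}$: an
overcounting part (reciprocal LD score over the regression SNP set)
and a heteroscedasticity part evaluated at supplied parameter values —
in simulations the true ones, so the comparator is, if anything,
favoured.  Standard errors for the comparator come from empirical
replication, deliberately avoiding the delete-block jackknife whose
block-count choice would confound the comparison.
`relative_efficiency()` reports $100 \cdot
\mathrm{Var}(\hat\beta_{\text{GEE}}) /
\mathrm{Var}(\hat\beta_{\text{WLS}})$; values below 100 favour the
GEE.  When true parameters are unavailable, `wls_fit_feasible()`
iterates weights from fitted values; the estimate moves by far less
than a standard error between iterations.

## The synthetic reference panel

Real evaluations of this model family lean on phased reference panels
(e.g. European-ancestry panel haplotypes for chromosome 2).  To keep
the package self-contained, `synthetic_haplotypes()` builds a
copying-mosaic stand-in: founder haplotypes carry independent
Bernoulli alleles with variant-specific frequencies drawn uniformly on
$(0.1, 0.9)$; each output haplotype copies founder segments whose
breakpoints follow a Poisson process on the genetic map; sites then
flip with a small probability; variants with realised MAF below the
floor are rejected.  Defaults — 200 haplotypes, 6 founders, 0.5 cM
mean segment length, 3% flip rate, 100 variants per cM, MAF floor 5% —
were chosen once so that

* mean $r^2$ between close variants ($< 0.1$ cM) is about 0.2 and
  decays to below 0.05 near 1 cM, the magnitude and range seen between
  nearby common variants in European panels;
* the per-site flip noise keeps block correlation matrices away from
  exact low-rank degeneracy, as finite real panels are;
* LD scores fall in the tens, consistent with the variant density.

What the generator does *not* emulate: MAF-dependent LD, variable
recombination intensity, natural allele-frequency spectra, population
structure or admixture, and genome-scale LD score ranges (real
panels with ten times the variant density have proportionally larger
$\ell$).  Passing simulation-based tests therefore demonstrates the
statistical machinery — unbiasedness, variance calibration, relative
efficiency, test size — under a realistic band-LD correlation
structure, not concordance with any particular real panel.

## The replication harness

`replication_study()` generates one LD landscape and then repeatedly
draws mean-zero z-scores whose correlation matrix is the PSD-repaired,
band-truncated signed-$r$ matrix of each region and whose marginal
variances are $\beta_1 + \ell_l\beta_2$; squared, these follow the
marginal model exactly, with dispersion 2 and squared-statistic
correlation equal to the elementwise square of the generation
correlation.  That elementwise square is therefore also the source of
the working matrices for the full-information scenario ($s = 1$) and
of the LD scores, so generation and fitting see a single
self-consistent model; misspecification is introduced explicitly by
shrinking the working matrices ($s < 1$), never incidentally.
Generation matrices and working matrices remain distinct objects.
Each replication is fitted by the GEE under every requested shrinkage
factor and by the WLS comparator with true-parameter weights, on the
same draws, so scenario and estimator comparisons are paired.

The default truth is $(\beta_1, \beta_2) = (1.02, 5\times10^{-4})$,
one point of the evaluated parameter grid.  Three geometries are
shipped (`simulation_preset()`):

* `desk` — 5 regions of 5 cM at 100 variants/cM (about 2,200 variants
  after MAF rejection, 25 clusters), 500 replications; runs in
  seconds and is the default for parameter-recovery checks.
* `null` — $\beta_2 = 0$ with sixteen independent draws of the desk
  region set (400 clusters), 1,000 replications, for the size of the
  Wald test.  The $\chi^2(1)$ reference is an asymptotic-in-$n$
  statement; at a few dozen clusters even the infeasible test that
  standardizes by the true empirical spread over-rejects, so the size
  check must use a cluster count where the limit is a usable
  approximation (size measured at 0.050 over 2,000 replications at 400
  clusters, against 0.0625 at 200; see Limitations).
* `genome` — the genome-scale geometry of the original evaluation
  design (11 regions of 25 cM, roughly 62,500 variants, 13 independent
  draws, about 812,500 statistics, 1,000 replications), intended for
  cluster-scale hardware and not exercised by the test suite.

Calibration and efficiency checks use the desk region set with four
independent draws (100 clusters): at 25 clusters the sandwich shows
the generic small-sample downward bias of cluster-robust variance
estimators (roughly $1/n$, here about 8%), which is a property of the
cluster count rather than of the estimator.  All replication studies
are deterministic given their seed.

## Limitations

* The sandwich variance is anticonservative at small cluster counts
  (as all cluster-robust estimators are); genome-wide applications
  have thousands of 1 cM clusters, but results from small targeted
  regions should not rely on the asymptotic standard errors.
* The Wald test inherits this: its size is accurate at hundreds of
  clusters and inflated below that.
* Heritability estimates are on the observed scale; liability-scale
  conversion is a constant factor applied downstream.
* LD is estimated from phased haplotypes only (or read from files);
  unphased dosage data are out of scope.
* The comparator is the explicit weighted regression form of LD Score
  regression, not a reimplementation of the two-step jackknifed
  software pipeline.
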