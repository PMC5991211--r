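# polygee

Genome-wide association statistics are inflated both by confounding
(population stratification) and by many true polygenic effects too
small to reach significance individually.  `polygee` separates and
quantifies the two from summary statistics alone.  It fits the
marginal model

    E[χ²_l]  = β₁ + C_study · ℓ_l · β₂
    Var(χ²_l) = φ · (E[χ²_l])²

where `ℓ_l` is the LD score of variant *l* (the sum of `r²` with every
variant within 1 cM, including itself), `β₁` houses the confounding
term `1 + Na`, `β₂` the heritability `h²` on the observed scale, and
`C_study` is a design constant known a priori for case-control,
quantitative, family-based (FBAT) and mixed designs.

Estimation is by generalized estimating equations: statistics are
clustered into 1 cM LD blocks, reference-panel `r²` matrices serve as
working correlations, and standard errors come from a sandwich
estimator `H⁻¹ M̂ H⁻¹` whose middle matrix carries cross-terms for
genetically adjacent blocks (clusters are only *sparsely*
independent).  Exploiting the local LD structure makes the estimator
substantially more precise than the weighted-regression estimator of
LD Score regression, while remaining robust when the reference-panel
LD deviates from the study's true correlation structure.  An explicit
weighted-least-squares LD Score regression comparator, the standard
summary-statistic quality filters (strand-ambiguous variants, low
imputation info, extreme p-values, perfect LD), LD-score computation
from phased haplotypes, and a full simulation harness with a
synthetic banded-LD haplotype generator are included.

Intended users: statistical geneticists working with GWAS or
family-based association summary statistics who want heritability /
inflation decompositions with asymptotically valid standard errors,
and methodologists benchmarking summary-statistic estimators.

## Worked example

A self-contained run on a synthetic 25 cM region: build a reference
panel, compute band LD and LD scores, simulate statistics under the
model with truth `(β₁, β₂) = (1.02, 0.05)`, and fit.

```r
library(polygee)

panel <- synthetic_haplotypes(synthetic_ld_params(), region_cm = 25, seed = 42)
r2 <- band_ld_matrix(panel$haplotypes, panel$cm)            # working r²
rs <- band_ld_matrix(panel$haplotypes, panel$cm, stat = "r") # generation r
l2 <- ld_scores_from_band(r2)

z   <- simulate_zscores(rs, l2, beta1 = 1.02, beta2 = 0.05, seed = 43)
fit <- polygee(z$chisq, l2, ld = r2)
summary(fit)
```

```
Polygenic-effect GEE fit

2112 variants in 25 LD blocks; dispersion phi = 1.902

      Estimate Std. Error      W   Pr(>W)
beta1  0.92719    0.21939 17.861 2.38e-05 ***
beta2  0.08652    0.03455  6.272   0.0123 *
```

Both coefficients land within about one standard error of the truth
on this single small region; the Wald test (`W`, referred to χ²(1))
rejects `β₂ = 0` at the 5% level, i.e. the region shows detectable
polygenic inflation beyond the intercept, and the dispersion estimate
is close to the theoretical value 2 for squared normal scores.  For a
real study, `β₂` is put on the heritability scale via the design
constant, e.g.

```r
design <- study_design("case_control", N = 20000, n_cases = 10000,
                       n_controls = 10000, K = 0.01, M = 1e6)
fit <- polygee(chisq, ldscores, ld = panel_r2, design = design)
```

and `coef(fit)["beta2"]` is then the observed-scale `h²` directly.
Replication experiments (parameter recovery, standard-error
calibration, relative efficiency against the WLS comparator under
correct and deliberately shrunk working correlations) are run with
`replication_study(sim_config(...))`; see the methods vignette.

A thin command-line wrapper ships in `inst/cli/polygee` with
`estimate`, `simulate`, `ldscore` and `ldsc-wls` subcommands over the
same functions.

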