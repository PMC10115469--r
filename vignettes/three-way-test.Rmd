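---
title: "The Three-Way Test: model, calibration, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Three-Way Test: model, calibration, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twtest)
```

## The testing problem

A gene-based multi-trait GWAS analysis asks whether any of $m$ SNPs in a
gene window is associated with any of $q$ traits, using only the publicly
shared summary Wald statistics $Z_{jk}$ ($j$ indexes traits, $k$ SNPs) and
a reference genotype panel from the target population. Under the global
null, the column-stacked vector $\mathrm{vec}(Z)$ is asymptotically
multivariate normal with mean zero and correlation
$\Delta_\theta \otimes \Delta_\rho$, where $\Delta_\rho$ is the $q \times
q$ trait correlation and $\Delta_\theta$ the $m \times m$ SNP correlation:
$\mathrm{corr}(Z_{jk}, Z_{j'k'}) = \rho_{jj'}\,\theta_{kk'}$. The product
form holds for Wald statistics from per-trait, per-SNP linear regressions
*with covariates*, provided $\theta_{kk'}$ is read as the partial
correlation of the two genotypes given the covariates.

## Estimating the two correlation matrices

**Trait correlation** $\hat\rho_{jj'}$ is the sample Pearson correlation
of the two traits' Z-score columns over $L$ independent null SNPs
(`estimateTraitCorrelation()`). Null SNPs are chosen by per-trait
two-sided $p > 0.05$ for every trait followed by greedy LD pruning at
$r^2 < 0.1$ against the panel (`selectNullSnps()`); both thresholds are
arguments because practice varies. $L$ matters: the entrywise noise is
$O(1/\sqrt{L})$, and because the test inverts $\Delta_\rho$ inside
quadratic forms, noise at the percent level visibly inflates tail
rejection rates. Genome-wide studies typically leave on the order of $10^5$ SNPs after
filtering and pruning, and the simulation engine defaults to
$L = 100{,}000$ for that reason — large enough that the estimation noise
contributes negligibly to the test's tail behaviour.

**SNP correlation** $\hat\theta_{kk'}$ comes from the reference panel
under three covariate cases (`partialGenotypeCorrelation()`):
environment-only covariates are independent of genotype, so the plain
Pearson dosage correlation applies; population-stratification covariates
are projected out of each dosage column with
$I - C(C^\top C)^{-1}C^\top$ before correlating; the mixed case ignores
the environmental columns and reduces to the stratification case.
Stratification axes can be built from the panel itself by classical
multidimensional scaling of Euclidean distances between mean-imputed
dosage vectors (`principalCoordinates()`); Euclidean classical scaling is
the standard reading of "principal coordinates", and each axis is
oriented so its largest-magnitude loading is positive, making results
reproducible (eigenvector sign is otherwise arbitrary).

Estimated matrices are regularized by eigenvalue clipping at
$\varepsilon_{pd} = 10^{-6}$ with rescaling to unit diagonal
(`regularizeCorrelation()`). This guarantees an invertible matrix for
the quadratic forms without materially perturbing well-conditioned
estimates; inputs already meeting the floor pass through unchanged.

## The three components and their combination

1. **Rows (intrinsic genetic structure).** LD spreads a causal variant
   over the Z-scores of a whole region, so
   $Z_{\{j\}}^\top \Delta_\theta^{-1} Z_{\{j\}} \sim \chi^2_m$ aggregates
   trait $j$'s signal; the $q$ p-values are combined by the Cauchy
   combination test with uniform weights, giving $P_1$.
2. **Columns (pleiotropy).**
   $Z_{[k]}^\top \Delta_\rho^{-1} Z_{[k]} \sim \chi^2_q$ aggregates SNP
   $k$ across traits; the $m$ p-values combine into $P_2$.
3. **Truncated scan (irregular patterns).** For each
   $\eta \in \{0.1, \dots, 0.9, 1\}$ the statistic
   $\tilde T_\eta = Z_\eta^\top \Delta_\eta^{-1} Z_\eta$ keeps the
   $\lceil \eta M \rceil$ largest $|Z|$ entries ($M = qm$) and the
   matching principal submatrix of $\Delta_\theta \otimes \Delta_\rho$.
   $\tilde T_1$ has an exact $\chi^2_M$ reference; the others are
   calibrated as below. The per-$\eta$ p-values combine into $P_3$.

The final p-value combines $(P_1, P_2, P_3)$ with weights $1/3$ through
the same Cauchy transform. The Cauchy combination's guarantee is a
*tail* property: under arbitrary dependence the combined statistic's
upper tail is standard Cauchy, so small p-values are trustworthy, but
the bulk distribution of the combined p-value deviates from uniform when
the inputs are strongly dependent (the three components share the same
Z matrix). The package's probability-integral checks therefore assert
exact uniformity only for the component references and verify the
combination via tail rejection rates.

## Numerical choices

* **Kept counts.** $\lceil \eta M \rceil$ is computed as
  `ceiling(eta * M - 1e-9)`: in double precision $0.1 \times 60$ lands
  just above 6 and a naive ceiling would keep 7 entries.
* **Ties in $|Z|$** are broken by ascending vector index, so results are
  deterministic.
* **Quadratic forms** are evaluated by Cholesky factor-and-solve, never
  by explicit inversion; the grid of truncated statistics reuses a
  single factorization of the permuted Kronecker matrix because the kept
  sets are nested across $\eta$.
* **p-value floor.** The tan/arctan pair cannot represent p-values below
  about $10^{-14}$; all reported p-values are clipped to
  $[10^{-14}, 1]$.
* **p-values at 1.** A component p-value of exactly 1 (an all-zero row
  or column) maps to $-\infty$ under the tan transform and would veto a
  genuine signal elsewhere. Inputs to the transform are therefore capped
  at $1 - 10^{-6}$, bounding such contributions at about
  $-3.2 \times 10^5$ while leaving the significance tail untouched.
* **Degenerate dimensions** $q = 1$ or $m = 1$ are allowed; the
  component statistics collapse to single quadratic forms.

## Calibrating the truncated statistics

The kept set of $\tilde T_\eta$ is data-dependent, so no classical null
law applies. Following the parametric-bootstrap recipe, $B$ draws of
$\mathrm{vec}(Z) \sim N(0, \Delta_\theta \otimes \Delta_\rho)$ are
reduced to truncated statistics, and the first three cumulants (sample
mean $K_\eta$, variance $L_\eta$, third central moment $M_\eta$, all
$1/B$-normalized) are matched to a generalized chi-square surrogate
$a\chi^2_d + b$:
$a_\eta = M_\eta / 4L_\eta$, $b_\eta = K_\eta - 2L_\eta^2/M_\eta$,
$d_\eta = 8L_\eta^3/M_\eta^2$. The default $B = 10^5$ keeps the cumulant
noise well below the 20% relative tail accuracy the package verifies
down to tail probability $10^{-3}$. The matching assumes right skew
($M_\eta > 0$), which holds for these chi-square-like statistics; a
non-positive third moment raises an error by default, with an optional
moment-matched normal surrogate behind a flag for exotic inputs.

The calibration depends only on $(\Delta_\theta, \Delta_\rho)$, so one
table (`calibrateTruncated()`) is reused across all tests and all
simulation replications sharing those matrices — this is what makes
$10^5$-replication studies feasible. Tables serialize to JSON with their
bootstrap size and seed (`writeCalibration()` / `readCalibration()`).

## What the simulation engine emulates

`scenarioConfig()` + `runScenario()` reproduce a type-I-error / power
study at desk scale. Phenotypes follow
$y_{ij} = \alpha_j + \sum_k g_{ik}\beta_{jk} + c_i\gamma_j +
\epsilon_{ij}$ with per-individual error vectors drawn jointly with
correlation $\Delta_\rho$ and a one-dimensional covariate $c_i$. Signal
allocations NONE / SINGLE / ROW / COLUMN place the nonzero entries of
the coefficient matrix $B$. Wald statistics are recomputed from the
individual-level data of every replication, adjusted for the covariate.

Choices the engine fixes (and why):

* **Genotypes** come from a latent-Gaussian threshold generator: two
  independent haplotype draws from $N(0, \text{LD})$, allele carried
  when the latent value falls below $\Phi^{-1}(\mathrm{MAF})$. This
  replaces the fixed real reference genotypes of a population panel
  while preserving the LD structure class; a real panel can be supplied
  instead wherever a dosage matrix is accepted. Genotypes and the
  covariate are held fixed within a scenario (errors are redrawn each
  replication), mirroring analyses built on a fixed genotype panel; the
  product-correlation identity is conditional on them anyway.
* **Default conditions** for the null study: $n = 2504$ individuals (the
  size of a standard public reference panel), MAF drawn once from
  $U(0.05, 0.5)$, AR(1) latent LD 0.8, covariate effect $\gamma_j = 0.5$,
  intercepts 0. For $q = 6$ the default trait correlation is a fixed
  two-block matrix (`defaultTraitCorrelation6()`) emulating a trait
  panel that splits into two metabolic families (within-block 0.3–0.6,
  cross-block 0.15), the structure typical of fatty-acid-like phenotype
  panels; for other $q$ the default is AR(1) with parameter 0.5.
* **Estimation is part of the pipeline.** Each scenario estimates
  $\Delta_\rho$ from a null-SNP pre-pass ($L = 100{,}000$ independent
  SNPs in blocks of 1000, each block with a fresh phenotype
  realization — a single shared realization would bias the estimate
  toward that realization's sample correlation, which is the wrong
  target when replications redraw errors) and $\Delta_\theta$ from the
  genotype panel itself, then calibrates once and reuses the table.
* **Rejections** are counted with strict inequality $p < \alpha$, and
  batching derives sub-seeds from the master seed (pre-pass: seed;
  calibration: seed + 1; replication loop: seed + 2).

Problem sizes used by the packaged checks: the two null studies run
$10^5$ replications each at $(q, m) = (6, 9)$ and $(10, 6)$ with
$B = 10^5$ calibration; the surrogate-accuracy check compares against an
independent $10^6$-draw Monte Carlo; the product-correlation and
uniformity checks use $2 \times 10^4$ replications.

What passing these simulations does *not* show about real data: the
generator draws Hardy–Weinberg genotypes from a stationary LD class and
normal errors, so it says nothing about model misspecification
(non-normal traits, binary traits, dosage uncertainty), imputation
artifacts, or SNP-to-gene assignment error; allele harmonization is
exercised on clean synthetic labels rather than messy real ones.

## Worked example

```{r example}
summaryPath <- system.file("extdata", "example_summary.tsv",
                           package = "twtest")
panelPath <- system.file("extdata", "example_panel.vcf",
                         package = "twtest")
genesPath <- system.file("extdata", "example_genes.bed",
                         package = "twtest")

summary <- readSummaryStats(summaryPath)
panel <- readPanelVcf(panelPath)
summary <- harmonizeAlleles(summary, panel$info)

regions <- readGeneRegions(genesPath)
geneSnps <- assignSnpsToGenes(panel$info, regions)
units <- buildGeneUnits(summary, panel$dosage, geneSnps)

wide <- with(summary, tapply(z, list(snp, trait), mean))
nullSnps <- selectNullSnps(wide, panel$dosage)
rho <- estimateTraitCorrelation(wide[nullSnps, ])

twtGenes(units, rho, B = 2e4, seed = 7)
```

The example data are synthetic: GENEB carries a pleiotropic signal at
one SNP (every trait shifted at that column) and GENEA is null.

## Known limitations

* Binary traits / logistic Wald statistics are out of scope; the product
  correlation identity is derived for linear-model Wald statistics.
* The Cauchy combination inherits mild tail inflation under strong
  dependence (empirically $\approx 1.1$–$1.3 \times 10^{-3}$ at nominal
  $10^{-3}$ in the packaged null studies), shrinking at stricter levels.
* Very small p-values are reported as $10^{-14}$, a floor imposed by the
  tan/arctan transforms in double precision.
* Gene windows use fixed ±5 kb flanks and SNP-count limits
  ($m \in [2, 500]$ by default); regulatory SNP-to-gene mappings are not
  implemented.
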