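---
title: "Validating a proxy lipid phenotype: models, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a proxy lipid phenotype: models, simulation design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Breeding programs often cannot record the trait they actually want to
improve. Fillet lipid percentage in farmed fish is the canonical example:
the reference measurement (solvent extraction from the homogenised fillet)
is accurate but destructive and expensive, while a handheld microwave
dielectric spectrometer ("fat meter") gives a rapid, non-destructive proxy
reading at a chosen body site. Before the proxy can drive selection
decisions, two different questions must be answered:

1. **Phenotypic agreement** — do the two instruments give the same number
   on the same fish? This is a measurement-error question, answered with
   paired tests, coefficients of variation, the root mean square error of
   prediction (RMSEP) and Lin's concordance correlation coefficient (CCC).
2. **Genetic agreement** — do the two traits rank *families* the same way?
   Selection acts on breeding values, so a proxy that is biased or noisy at
   the phenotypic level can still be nearly perfect genetically if its
   genetic correlation with the reference trait approaches one.

`proxyval` implements both analyses and a synthetic-data generator that
reproduces the statistical structure of a typical two-cohort aquaculture
study: roughly 750 fish from 37 sires and 33 dams in full- and half-sib
families, genotyped at a few thousand SNPs, all measured four times with
the proxy (left/right x anterior/posterior sites) and a random subset of
about 313 additionally measured with the reference method.

# Models

## Genomic relationships

Relationships are computed from SNP dosages with the VanRaden method-1
matrix
$$G = \frac{ZZ'}{2\sum_j p_j(1-p_j)}, \qquad Z = M - 2P,$$
where $M$ is the dosage matrix and $P$ the allele-frequency matrix. SNPs
pass quality control on per-SNP call rate (default $\ge 0.93$), minor
allele frequency (default $\ge 0.01$) and a one-degree-of-freedom
chi-square test of Hardy–Weinberg equilibrium (default $p \ge 10^{-7}$).
Missing dosages are mean-imputed ($2p_j$) before centring. A small ridge
("bending", default $10^{-6}$) is added to the diagonal so downstream
factorizations always succeed.

Two choices here were genuinely open. The array-quality threshold could be
a per-sample or per-SNP call rate; we apply it per SNP, which is the choice
that affects the marker panel rather than the animal set. The HWE test
could be exact or asymptotic; the chi-square approximation is the common
default, is analytically testable (a panel in exact HWE proportions gives a
statistic of exactly zero), and the filtering threshold operates at
p-values where the two tests agree for the sample sizes involved.

## Variance components

Three animal models are fitted by restricted maximum likelihood:

* **Univariate** (single-record traits):
  $y = \mu + C + S + a + e$, with cohort $C$ and sex $S$ fixed,
  $a \sim N(0, G\sigma^2_a)$ and $e \sim N(0, I\sigma^2_e)$.
  Heritability is $h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_e)$.
* **Repeatability** (site-indexed repeated records):
  $y = \mu + C + B + S + a + pe + e$ with body site $B$ fixed and a
  permanent-environment effect $pe \sim N(0, I\sigma^2_{pe})$ shared by an
  individual's records. Here
  $h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_{pe} + \sigma^2_e)$ and the
  repeatability
  $t^2 = (\sigma^2_a + \sigma^2_{pe}) / (\sigma^2_a + \sigma^2_{pe} + \sigma^2_e)$
  bounds $h^2$ from above.
* **Bivariate** (reference x proxy): the joint covariance structure
  carries $\sigma^2_{a1}, \sigma^2_{a2}, \sigma_{a12}$ on the genetic side
  (through $G$), a permanent-environment term for the repeated trait only
  — a single-record trait cannot separate $pe$ from $e$ — and residual
  variances with an optional residual covariance $\sigma_{e12}$.
  The genetic correlation is
  $r_g = \sigma_{a12} / \sqrt{\sigma^2_{a1}\sigma^2_{a2}}$ and the
  phenotypic correlation
  $r_p = (\sigma_{a12} + \sigma_{e12}) / \sqrt{(\sigma^2_{a1}+\sigma^2_{e1})(\sigma^2_{a2}+\sigma^2_{pe2}+\sigma^2_{e2})}$.

Individuals lacking the reference record enter the bivariate model with
proxy records only; their information flows through the genetic covariance.
This is what makes the genetic comparison possible on all ~750 fish even
though only ~313 carry both traits.

The residual covariance of a single-record trait with a repeated-record
trait is not uniquely defined by the model statement alone. We link the
reference residual *equally* to each of the individual's proxy records
(an identity-indicator cross block), the simplest structure consistent with
an `I`-type residual covariance; positive-semidefiniteness of the
per-individual residual block then requires
$m\,\sigma_{e12}^2 \le \sigma^2_{e1}\sigma^2_{e2}$ for $m$ repeated
records, which the optimiser enforces. Because the two instruments need not
be operated simultaneously, `res_cov = FALSE` fixes $\sigma_{e12} = 0$
instead.

Standard errors of all ratio parameters use the first-order Taylor (delta)
method with the inverse average-information matrix as the component
covariance.

## Agreement statistics

Lin's CCC is computed with n-denominator moment estimators, following its
original definition,
$$\mathrm{CCC} = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2},$$
with the standard asymptotic variance for its uncertainty. Descriptive
standard deviations and CVs elsewhere use the conventional $n-1$
denominator; the report states both conventions so the mixed usage is
explicit. The paired t-test reports the relative bias
$100(\bar x - \bar y)/\bar x$. Tests of a correlation against a
hypothesised value use the Fisher z-transformation; the value 1 is a
boundary where any sample correlation below one is categorical evidence
against the hypothesis, and the p-value degenerates to zero by convention.
The benefit of averaging $n$ repeated records of a trait with
repeatability $t^2$ is quantified by the proportional reduction in total
variance, $100 - 100(1 + t^2(n-1))/n$ percent.

# The synthetic-data generator

The generator is first-class, tested code: every downstream stage is
exercised against populations whose true parameters are known.

**Pedigree and genotypes.** Families are formed by repeatedly pairing a
random sire (of 37) with a random dam (of 33); family sizes follow a
truncated geometric distribution with configurable median (default 5,
truncated to [2, 150]), so a few parents accumulate many offspring, as in
real mass-spawning data. Founder genotypes are binomial draws at allele
frequencies uniform in [0.05, 0.5]; offspring genotypes follow Mendelian
gamete sampling. Broodstock are treated as unsampled: only offspring are
genotyped, and relationships are estimated from markers, not the pedigree.

**Breeding values.** Per-SNP effect pairs are drawn bivariate-normal and
then recoloured so their sample covariance equals the target genetic
covariance divided by the VanRaden denominator. This makes the genetic
(co)variance *in the relationship-matrix metric* — the quantity REML
estimates — equal the configured components exactly. The realized sample
variance of breeding values across the (related) individuals then sits a
few percent below the nominal component and fluctuates by 10–15% between
replicates; that is a property of real family data, not an artefact.
An earlier design that rescaled the realized breeding-value sample to the
target variance was abandoned because it made the REML estimand
systematically ~3% larger than the configured value, which would have
contaminated the parameter-recovery checks.

**Phenotypes.** The reference trait is one record on a random fraction
(default 313/749); the proxy is four site-indexed records on every fish
with a shared permanent-environment deviation. Default components are the
published combined-cohort estimates: reference 4.15/2.89 ($h^2 = 0.59$),
proxy per record 5.44/2.16/6.00 ($h^2 = 0.40$, $t^2 = 0.56$), genetic
correlation 0.96, means 9.0 and 7.1 lipid percent. Cohort, sex and
body-site fixed effects default to small values consistent with the
published cohort tables (the proxy's cohort gap of 1 lipid point, a
0.1-point reference gap). The residual correlation between the reference
record and each single proxy record is not identifiable from published
tables; its default 0.17 is back-solved so that the phenotypic correlation
between the reference trait and the four-record mean is about 0.66, the
published value. It must satisfy $|r_e| \le 0.5$ for the five-record
residual covariance of one fish to be positive semidefinite. Body weight is
simulated per cohort (means 376 g and 279 g, SD 60 g) independent of the
lipid architecture, so the size-independence diagnostic is null-calibrated
by construction.

**What the generator does not emulate.** No linkage disequilibrium beyond
family co-segregation; no device physics (the proxy is modelled directly at
the phenotype level, so calibration-curve artefacts such as nonlinearity in
the lipid range are absent); no selection or non-random mating; genotyping
error only as random missingness. Passing the recovery tests therefore
demonstrates correctness of the estimation machinery under the stated
model, not robustness to model misspecification in real data.

# Numerical choices

The REML engine maximises the restricted likelihood of
$y = X\beta + u$, $\mathrm{Var}(y) = \sum_k \theta_k V_k$, with
average-information (quasi-Newton) updates and step halving. Specifics:

* **Representations.** For the univariate model the GRM is eigendecomposed
  once and the problem rotated so both structures are diagonal; for the
  repeatability model with balanced records the GRM rotation combines with
  an orthogonal within-individual transform (record means carry the genetic
  and permanent-environment signal, contrasts carry pure residual), again
  fully diagonal. Iterations then cost O(n p^2). Bivariate and unbalanced
  models run on dense covariance matrices, which is comfortable at a few
  thousand records. The two representations are verified against each
  other in the tests.
* **Constraints.** Variances are floored at $10^{-8}\times$ the phenotypic
  variance (with an absolute floor of $10^{-12}$ so degenerate zero-variance
  inputs remain factorizable); covariances are kept strictly inside the cone
  implied by their parent variances. Parameters pinned at a bound with an
  outward-pointing score form an active set excluded from the AI system.
* **Fallbacks.** If no damped AI step improves the likelihood, an
  EM-flavoured step is tried: classic $\sigma^4$-scaled score updates for
  variances, parent-variance-scaled score updates for covariances. If the
  AI matrix is singular — as it is, structurally, when genetic and
  permanent-environment terms coincide under an identity relationship
  matrix — its pseudoinverse is used and the fit is flagged
  non-identifiable; the identifiable sums still converge (and match the
  balanced-ANOVA estimator exactly in that case).
* **Convergence.** Relative restricted-log-likelihood change below
  $10^{-9}$ together with a squared score norm below $10^{-8}$; a flat
  likelihood over three consecutive iterations is also accepted (this is
  what terminates fits whose optimum lies on a constraint). Iteration cap
  200. Starting values split the phenotypic variance (half genetic;
  the non-genetic half split equally between permanent environment and
  residual where both exist); covariances start at one quarter of the
  geometric mean of their parent variances, and residual covariances at 0.
* **Fixed effects.** Treatment coding with the first level constrained to
  zero; factors with a single observed level (e.g. cohort in a
  within-cohort analysis) are dropped automatically, and any remaining
  aliased columns are removed by QR. Derived ratios are invariant to the
  constraint choice.

# Problem sizes and what the tests compute

Unit tests run on small populations (tens to a few hundred fish, a few
hundred SNPs) chosen so each property is sharp: exact Mendelian forcing,
analytic HWE statistics, hand-evaluated GRM entries, closed-form CCC/RMSEP
identities, grid-search and ANOVA oracles for REML, and equivariance
properties. The recovery checks simulate the full study design — 749 fish,
2,000 SNPs (a scaled-down marker panel; relationship estimates at 2,000
markers are accurate to ~1/45, ample for these family sizes) — for 50
replicates and compare replicate-mean estimates of $h^2$, $t^2$ and $r_g$
with the configured truths within two Monte-Carlo standard errors. The
left/right repeatability check simulates per-record components whose side
means carry the published left/right-model estimates (5.32/2.85/1.87),
because the published all-records and left/right rows are not mutually
consistent under exact halving of the residual; the generator's defaults
follow the all-records row, and the left/right condition is set explicitly
where it is the target.

# Known limitations

* The published per-cohort RMSEP values (1.9–2.1) cannot be reproduced
  from the published summary statistics under the stated definition
  (which yields ~2.9–3.1), and the 2016-cohort CCC of 0.36 likewise
  differs from the value implied by its printed moments (~0.42). The
  implementation follows the stated definitions and makes no attempt to
  match those two printed numbers.
* $\sigma^2_a$ and $\sigma^2_{pe}$ are reported separately but are only
  jointly identifiable when the relationship matrix is (near) identity;
  the fit flags this.
* The bivariate model supports exactly two traits; multi-trait extensions
  and pedigree-based (A-matrix) or single-step relationship matrices are
  out of scope.
* The CCC asymptotic SD assumes bivariate normality, as does REML.
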