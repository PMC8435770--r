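# proxyval

Validation of an indirect (proxy) phenotype against a reference
measurement for selective breeding, with the two analyses that question
requires:

* **Phenotypic agreement** — does the proxy instrument reproduce the
  reference value on the same individual? Quantified with paired t-tests,
  coefficients of variation, the root mean square error of prediction
  (RMSEP) and Lin's concordance correlation coefficient
  (CCC = 2s\_xy / (s\_x² + s\_y² + (x̄ − ȳ)²)).
* **Genetic agreement** — does the proxy rank families like the reference
  trait? Quantified with variance components estimated by
  average-information REML under genomic animal models, using the VanRaden
  method-1 relationship matrix G = ZZ′ / (2Σ p_j(1−p_j)):
  univariate (y = μ + C + S + a + e, a ~ N(0, Gσ²\_a)), repeatability
  (adds body site B and a permanent-environment effect pe for repeated
  records; t² = (σ²\_a + σ²\_pe)/σ²\_p) and bivariate
  (r\_g = σ\_a12 / √(σ²\_a1 σ²\_a2)), with first-order Taylor-series
  standard errors for all ratios.

The motivating application is fillet lipid percentage in farmed fish,
where the reference method (solvent extraction) is destructive and a
handheld microwave dielectric spectrometer provides four spatially
repeated proxy records per fish. The package is aimed at breeding-program
analysts deciding whether such a proxy can replace the reference trait in
genetic evaluation, and at methodologists who need a fully synthetic but
realistically structured test bed: the built-in generator simulates
full/half-sib families from mass spawning, Mendelian SNP segregation, and
the two-method recording scheme (reference on a subset, four proxy records
on everyone), all with known true parameters.

## Worked example

Simulate a study population at its default conditions (749 fish, 37 sires
x 33 dams, 2,000 SNPs, reference trait on 313 fish, four proxy records on
all), run SNP QC, build the GRM, derive the proxy trait views and fit the
central comparison:

```r
library(proxyval)

cfg   <- sim_config(seed = 2024)
sim   <- simulate_population(cfg)
grm   <- vanraden_grm(qc_filter(sim$genotypes))
views <- make_trait_views(sim$phenotypes)

agreement_report(views, "lipid_ref", "lipid_ds_mean")
#> Method agreement (reference vs proxy)
#>   C1 (n=132): ref 9.3 +/- 2.7 (CV 28.6%), proxy 6.8 +/- 2.7 (CV 39.0%)
#>       R=0.60 +/- 0.07, CCC=0.41 +/- 0.05, RMSEP=3.46, bias=27.1% (p=2.2e-23)
#>   C2 (n=181): ref 9.1 +/- 2.4 (CV 26.3%), proxy 7.5 +/- 2.6 (CV 34.3%)
#>       R=0.62 +/- 0.06, CCC=0.51 +/- 0.05, RMSEP=2.71, bias=17.7% (p=5.6e-19)
#>   pooled (n=313): ref 9.2 +/- 2.5 (CV 27.3%), proxy 7.2 +/- 2.6 (CV 36.4%)
#>       R=0.60 +/- 0.05, CCC=0.46 +/- 0.03, RMSEP=3.05, bias=21.7% (p=4.6e-40)

fit_bivariate(views, grm, "lipid_ref", "lipid_ds_mean")
#> bivariate animal model: lipid_ref x lipid_ds_mean (1062 records, 749 individuals)
#>   sigma2_a1     3.5227 +/- 0.9106
#>   sigma2_a2     4.4789 +/- 0.8133
#>   sigma_a12     3.3716 +/- 0.7264
#>   sigma2_e1     3.6586 +/- 0.6119
#>   sigma2_e2     3.9828 +/- 0.4452
#>   sigma_e12     1.7577 +/- 0.4404
#>   r_g           0.8488 +/- 0.0674
#>   r_p           0.6580 +/- 0.0344
#>   h2_1          0.4905 +/- 0.0984
#>   h2_2          0.5293 +/- 0.0680
#>   logL -1466.9036, 10 iterations, converged
```

Reading the output: the proxy *underestimates* the reference by ~22%
pooled and is noticeably noisier (CV 36% vs 27%), so phenotypic agreement
is only moderate (CCC ≈ 0.46). The genetic correlation from the bivariate
animal model is nevertheless high (here 0.85 ± 0.07 in a single simulated
replicate whose true value is 0.96 — single-replicate estimates scatter
this much at 749 fish), which is the quantity that decides whether the
proxy is usable for selection. `run_full_analysis(run_config(sim = cfg))`
chains all stages — QC, GRM, per-site/averaged trait views, agreement and
the full set of univariate, repeatability and bivariate fits — into the
two study-style tables plus CSV/JSON outputs.

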