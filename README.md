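# codecomp

Doubly multivariate ("codecomposition") analysis of structural
covariation between hippocampal subfields and default-network parcels,
with a bootstrap group-difference test and a genetics arm linking
polygenic risk to individual mode expressions.

## Who this is for

Population-neuroimaging analysts who want to ask: *which patterns of
volume variation inside one brain system travel together with patterns
inside another, and do those patterns differ between two groups of
people (here, lonely versus nonlonely)?* The same machinery applies to
any pair of z-scorable feature blocks measured on the same
participants. Because cohorts of this kind are typically
access-restricted, the package also ships a synthetic cohort generator
with planted ground truth, so every stage of the pipeline can be
verified end to end on data whose answers are known.

## The model at the core

Given deconfounded, z-scored blocks $X \in \mathbb{R}^{n \times p}$
(91 default-network parcel volumes) and $Y \in \mathbb{R}^{n \times q}$
(38 hippocampal subfield volumes), canonical correlation analysis finds
weight pairs $(v_l, u_l)$ maximizing

$$\rho_l = \mathrm{corr}(X v_l,\; Y u_l), \qquad l = 1, \dots, K,$$

subject to uncorrelatedness with earlier modes. Group differences are
assessed with a bootstrap contrast: resample each group, fit one CCA
per group, align modes (order and sign) to the full-cohort reference,
subtract matched canonical vectors elementwise, and flag a subregion as
a **hit** when the 10/90% percentile interval of its difference
distribution excludes zero. A quality-controlled additive polygenic
score $prs_j = \sum_i g_{ij}\hat\beta_i$ identifies top/bottom 5%
scorers, and a Bayesian logistic regression with $N(0,1)$ priors asks
which mode expressions separate those genetic extremes (a mode is
*robust* when ≥ 95% of its coefficient's posterior mass shares one
sign).

## Worked example

```r
library(codecomp)

spec <- simSpec(2000, pDN = 10, qHC = 6,
                plantedRhos = c(0.6, 0.4), lonelyFraction = 0.4,
                seed = 7)
cohort  <- deconfound(generateCohort(spec))
solution <- fitCCA(volumeMatrix(cohort, "DN", "cleaned"),
                   volumeMatrix(cohort, "HC", "cleaned"), K = 2)
canonicalCorrelations(solution)
#> [1] 0.5633913 0.4207145

contrast <- bootstrapContrast(cohort, K = 2, nBoot = 100, seed = 1)
contrast
#> ContrastResult: 100 bootstrap iterations, 2 modes x 16 subregions
#> interval: 10/90 % percentiles; hits: 4 HC, 6 DN
```

The two recovered canonical correlations sit within sampling error of
the planted population values 0.6 and 0.4 — the generator's closed
form guarantees the population CCA equals the requested values. The
contrast on this cohort (the generator planted no group effect, so the
labels are uninformative) flags 10 of the 32 mode-by-subregion
coefficients, consistent with the roughly 20% two-sided exclusion
level a 10/90% percentile interval implies under the null.

`runPipeline(runConfig(spec, ...), outDir = "run1")` chains all stages
(simulate → deconfound → CCA → contrast → PRS → Bayesian regression)
and writes TSV artifacts plus a provenance stamp.

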