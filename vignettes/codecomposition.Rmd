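---
title: "Codecomposition of hippocampus-default-network covariation: methods"
author: "codecomp package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codecomposition methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis this package implements

Structural covariation analysis asks how volume variation inside one
brain system tracks volume variation inside another, across a
population. Here the two systems are the hippocampal formation,
measured as 38 subfield volumes (19 FreeSurfer-style head/body
subsegmentation labels per hemisphere), and the default network,
measured as 91 cortical parcel volumes. The pipeline has five stages:

1. **Deconfounding** — each volume column is residualized on a nuisance
   design (age, age², sex, sex×age, sex×age², body-mass index, head
   size, two head-motion summaries, head position x/y/z, scanner table
   position, acquisition site) and then z-scored.
2. **Canonical correlation analysis (CCA)** — paired weight vectors
   $(v_l, u_l)$ maximize $\mathrm{corr}(X v_l, Y u_l)$ over modes
   $l = 1,\dots,K$ (default $K = 25$), producing canonical correlations
   $\rho_l$ and per-participant mode expressions $L_X = XV$, $L_Y = YU$.
3. **Bootstrap group contrast** — in each of 100 bootstrap iterations
   both label groups (lonely / nonlonely) are resampled with
   replacement at their own sizes, one CCA is fitted per group, both
   solutions are aligned in mode order and sign to the full-cohort
   reference fit, and the aligned canonical vectors are subtracted
   elementwise. A subregion is a **hit** for a mode when the 10/90%
   percentile interval of its difference distribution excludes zero.
4. **Polygenic scoring** — GWAS summary statistics are quality
   controlled (MAF < 1%, INFO < 0.8, duplicates, strand-ambiguous A/T
   and C/G pairs, panel allele mismatches), additive scores
   $prs_j = \sum_i g_{ij}\hat\beta_i$ are computed over SNPs passing a
   p-value threshold chosen on training data, and the top and bottom 5%
   scorers are extracted.
5. **Bayesian mode-heritability regression** — extreme-tail membership
   is regressed on the 25 mode expressions of one side with
   sex-specific intercepts and sex-specific (z-scored) age slopes, all
   coefficients under standard-normal priors, sampled by MCMC with at
   least three chains; a mode is *robust* when ≥ 95% of its
   coefficient's posterior mass shares one sign.

Because the cohort this design targets is access-restricted, the
package ships a synthetic cohort generator whose planted ground truth
makes every stage verifiable.

## The generative model and its closed form

The generator is a shared-latent linear factor model, the only
generative family whose population CCA is available in closed form and
can therefore certify the planted values. For mode $l$ with target
canonical correlation $\rho_l$:

* latent scores $z_{x,l} \sim N(0,1)$ and
  $z_{y,l} = \rho^*_l z_{x,l} + \sqrt{1-\rho^{*2}_l}\,\varepsilon_l$;
* $X = Z_x A^\top + \sigma E_x$ and $Y = Z_y B^\top + \sigma E_y$ with
  orthonormal loading matrices $A$ ($p \times K$), $B$ ($q \times K$)
  and isotropic noise sd $\sigma$ (`noiseSd`, default 0.5).

With this structure $\Sigma_{xx} = AA^\top + \sigma^2 I$ and
$\Sigma_{xy} = A\,\mathrm{diag}(\rho^*)\,B^\top$, so the population
canonical correlation of mode $l$ is $\rho^*_l/(1+\sigma^2)$. The
generator therefore plants $\rho^*_l = \rho_l (1+\sigma^2)$ and refuses
specifications where that compensation would reach 1. Deconfounding and
z-scoring are invertible column-wise transforms of each block, so the
planted population correlations survive the preprocessing.

Group effects live in the loadings, not in mean volumes: the contrast
procedure compares canonical vectors, so a detectable group difference
must alter the covariance structure. Lonely participants receive
additive shifts on selected loading entries (`effectMap`). Confounds
enter as linear contributions of the full 13-term nuisance expansion
with per-term coupling strengths chosen to mimic a population-imaging
cohort (head size and age strongest, scanner-geometry terms weakest);
they are free parameters of the generator, not calibrated estimates,
because the source cohort's empirical confound correlations are not
public.

What the generator deliberately omits: spatial autocorrelation between
neighbouring parcels, non-Gaussian volume distributions, linkage
disequilibrium between SNPs, missing data, and site-by-covariate
interactions. Passing recovery tests therefore certify the *procedures*
under the stated model, not robustness to those real-data features.

## Numerical choices

* **CCA algorithm**: each block is whitened by the inverse symmetric
  square root of its covariance; the SVD of the whitened
  cross-covariance gives correlations (singular values) and weights.
  Rank deficiency is an error reporting the effective rank.
* **Sign convention**: CCA signs are arbitrary, so each mode is
  reflected to make the largest-magnitude entry of the concatenated
  vector $[v_l; u_l]$ positive. The reflection is applied jointly to
  both sides, which keeps every $\rho_l \ge 0$ and makes refits on
  identical data bitwise-identical.
* **Variate normalization**: unit variance on the fitting sample
  (population $1/n$ denominator throughout the package, so z-scoring
  is idempotent). This choice does not affect correlations or hit
  decisions.
* **Mode matching**: the $K \times K$ matrix of Pearson correlations
  between concatenated reference and candidate weight vectors is passed
  to an optimal linear-assignment solver (shortest augmenting path,
  $O(K^3)$); matched signs come from the matched correlations, an exact
  zero correlation defaulting to $+1$. Both group solutions are aligned
  to the full-cohort reference — the common reference keeps mode
  identity stable across the 100 iterations so differences can be
  aggregated; aligning the two group fits only to each other would not.
* **Percentiles**: linear-interpolation empirical quantiles (type 7).
* **Deconfounding order**: residualize, then z-score, computed once on
  the full cohort (not per bootstrap resample, and not per analysis
  subgroup; subgroup-wise cleaning can be had by subsetting first).
  Age is z-scored before squaring; one site level is the reference.
* **Bayesian sampler**: JAGS with the GLM module, ≥ 3 chains, 1000
  post-warmup draws per chain by default, per-chain seeded RNGs.
  Sampling extends automatically up to two rounds if any potential
  scale reduction exceeds 1.01; persistent non-convergence is an
  error. With zero observations the exact prior is returned without
  invoking the sampler. The likelihood is logistic because the
  response (top-vs-bottom PRS tail) is binary; a linear-likelihood
  variant is exposed but not default.

## What the verification experiments do — and what we learned

The acceptance suite (also re-runnable via `scripts/acceptance.R`)
fixes these problem sizes:

* oracle equivalence on 20 instances at $n=60$, $p=4$, $q=3$ against an
  independently coded generalized-eigenproblem solution;
* recovery of planted mode strengths 0.51/0.42/0.39/0.31/0.27/0.23 at
  $n = 20{,}000$ with the full 91 + 38 feature blocks, within ±0.03;
* exact inversion of 100 random permutation/sign patterns at $K=10$;
* null calibration of the hit test over 200 replicate cohorts at
  $n = 2000$, $K = 5$, 100 bootstrap iterations;
* power over 50 replicate cohorts at $n = 4000$ with 0.5 loading-unit
  shifts on three hippocampal subregions;
* elementwise-loop equivalence of the scoring engine and a six-SNP QC
  enumeration;
* recovery of a planted logistic coefficient of 0.8 at $n = 2000$ with
  25 modes, plus the null flag rate of the posterior-mass rule;
* the percentage arithmetic of hit summaries on fixed flag patterns.

Two design points deserve emphasis. First, the null calibration uses
scaled-down blocks ($p=8$, $q=6$) whose ratio $n/(p+q)$ matches the
regime the full-scale analysis operates in ($\approx 300$ participants
per feature), with planted correlations separated by 0.15. Piloting
showed why this matters: when per-group sample sizes are small relative
to the feature count, or when neighbouring canonical correlations are
closely spaced, the sampling noise of canonical vectors includes
rotations between modes; mode matching then partially symmetrizes the
bootstrap difference distributions, the percentile intervals widen
relative to the centre displacement, and the empirical hit rate falls
below the nominal 20% level. The procedure is conservative — not
anticonservative — in weakly identified regimes, which is the right
failure direction for a screening test, but calibration claims should
only be read in the identifiable regime.

Second, the power experiment uses the full 91 + 38 blocks: a loading
shift spreads into other modes' weights in proportion to its overlap
with their loading vectors, which scales like $1/\sqrt{q}$ for random
loadings. At $q = 6$ the overlap is large and group differences
delocalize across modes and subregions; at $q = 38$ the planted
subregions dominate their block. This is a property of weight-space
contrasts generally: a localized change in how a subregion loads on a
mode is detected as a localized weight difference only when the blocks
are wide enough for loading directions to be mutually incoherent.

## Tunable parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `K` | 25 | modes examined |
| `nBoot` | 100 | bootstrap iterations of the contrast |
| `probs` | 0.1, 0.9 | percentile interval for hit detection |
| `noiseSd` | 0.5 | feature-noise sd in latent-score units |
| `lonelyFraction` | 0.2 | labelled prevalence in generated cohorts |
| `prsGrid` | 5e-8 … 1 | candidate p-value inclusion thresholds |
| `extremeFraction` | 0.05 | PRS tail fraction per side |
| `mass` | 0.95 | posterior-mass threshold for robust modes |
| `chains` / draws | 4 × 1000 | MCMC configuration (≥ 3 chains enforced) |

## Known limitations

* The PRS engine uses plain p-value thresholding; it does not clump or
  prune against an LD reference panel. For the simulated independent
  loci this is exact; for real summary statistics it would overcount
  correlated signals. Outputs are labelled accordingly.
* Summary statistics are emulated (effect estimate = true effect plus
  its sampling error at the discovery-cohort size), not estimated by a
  per-SNP regression.
* The DN parcel-to-grouping table is a reconstruction: the parcellation
  fixes 91 default-network parcels, but the four-way lobe grouping used
  in hit tallies is assigned from parcel-name subtypes and is editable
  (`inst/extdata/atlas_dn.tsv`).
* No family-wise or false-discovery correction is applied across the
  $K \times (p+q)$ interval tests; per-coefficient intervals are
  reported exactly as specified, and summaries always recompute
  percentages from their own counts.
* Hit counts depend on the bootstrap seed; intervals from 100 resamples
  have non-negligible quantile noise, which is why the calibration and
  power claims are stated over replicate cohorts rather than single
  runs.
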