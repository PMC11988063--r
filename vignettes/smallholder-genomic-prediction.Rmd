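---
title: "Genomic prediction of test-day milk fat percentage in smallholder herds: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction of test-day milk fat percentage in smallholder herds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smallgp)
```

## The problem

Smallholder dairy systems record milk traits under conditions that make
classical genetic evaluation hard: herds of one or two crossbred cows,
heterogeneous management, sparse monthly test-day recording, and no usable
pedigree. `smallgp` implements a two-stage genomic evaluation of test-day
milk fat percentage for exactly this setting:

1. **Quality control** of phenotypes and SNP genotypes, with an audit
   ledger for every filter.
2. **Stage 1** — a repeatability animal model that strips fixed effects
   from the raw records and emits *adjusted* test-day records.
3. **Genomic relationships** — the VanRaden genomic relationship matrix
   (GRM) built from QC-passed genotypes.
4. **Stage 2** — Bayesian inference by Gibbs sampling of a random
   regression model on the adjusted records, yielding variance components,
   heritability, and genomic-estimated breeding values (GEBV).

A synthetic-data module generates populations with this exact structure
and known ground truth, so every stage of the pipeline is testable without
access to any proprietary recording database.

## Stage 1: the repeatability animal model

Raw test-day records are modelled as

$$\mathbf{y} = \mathbf{X b} + \mathbf{Z}_1 \mathbf{a} + \mathbf{Z}_2 \mathbf{h} + \mathbf{e},$$

with fixed effects **b** for lactation number, community development
centre (CDC — the administrative grouping of farms), and the
year-month-by-CDC interaction; random animal effects **a** and herd
effects **h**, both with identity covariance (animals are deliberately
treated as unrelated at this stage), and residuals **e**.

Variance components are estimated by EM-REML on Henderson's mixed-model
equations (`estimate_variances_em_reml()`); the equations are then solved
once at the estimates (`solve_mme()`) to give BLUE(**b**) and BLUPs. The
*adjusted* record is

$$y^{*} = y - \mathbf{x}'\hat{\mathbf{b}} = \hat{a} + \hat{h} + \hat{e},$$

reported per record as its three components (animal effect, herd effect,
record-level residual) plus their sum, the adjusted fat percentage. The
decomposition is exactly additive in this implementation; published
component tables can disagree with their printed sum by ±0.01 through
rounding of the printed components. Whether the record-level component is
labelled a "fixed-effect residual" or simply the residual is a naming
choice; its value is $\hat e$, and the adjusted record is invariant to
adding a constant to all levels of one fixed-effect factor
(identifiability contract, tested).

**A caution on fixed-effect absorption.** The year-month-by-CDC
interaction can easily approach one parameter per handful of records
(in a population of a few hundred cows it reaches 10–15% of the record
count). Estimating that many cell means absorbs a corresponding share of
residual variance into $\mathbf{X}\hat{\mathbf{b}}$ and leaves
animal-level estimation noise in the adjusted records, which a
downstream model with only a genomic and a residual term will attribute
partly to genetics. Variance components estimated from heavily adjusted
records should therefore be read with this in mind; the package's
parameter-recovery checks simulate records whose variance is exactly the
nominal components so that the sampler itself is what is being measured.

## Stage 2: random regression with a genomic covariance

Adjusted records enter

$$\mathbf{y}^{*} = \mathbf{Z}_1 \mathbf{a} + \mathbf{Z}_2 \mathbf{p} + \mathbf{Z}_3 \mathbf{h} + \mathbf{e},$$

where each animal's additive genetic (**a**) and permanent environmental
(**p**) terms, and each herd's term (**h**), are coefficient vectors of
order-$m$ normalized Legendre polynomials of days in milk (DIM). DIM $t$
in the closed window $[8, 340]$ maps to $x = 2(t-8)/(340-8) - 1$, and
$\phi_k(x) = \sqrt{(2k+1)/2}\, P_k(x)$. The covariance structure is

$$\mathrm{var}(\mathbf{a}) = \mathbf{G} \otimes \mathbf{K}_a,\quad
  \mathrm{var}(\mathbf{p}) = \mathbf{I} \otimes \mathbf{K}_p,\quad
  \mathrm{var}(\mathbf{h}) = \mathbf{I} \otimes \mathbf{K}_h,$$

with **G** the genomic relationship matrix and $\mathbf{K}_a$,
$\mathbf{K}_p$, $\mathbf{K}_h$ the $(m+1)\times(m+1)$ coefficient
covariance matrices. Residual variances are homogeneous within and
heterogeneous between lactation-period classes; the default classes are
the DIM bands 8–45, 46–115, 116–225 and 226–340 (the band boundaries are
a package choice — the class concept requires a partition and none is
canonical).

`gibbs_rr_gblup()` samples all blocks from their conjugate full
conditionals: coefficient blocks from multivariate normals, coefficient
covariances from inverse-Wishart (scaled inverse-$\chi^2$ when $m=0$),
residual class variances from scaled inverse-$\chi^2$, and an overall
mean with a flat prior. When the model reduces to order-0
additive-plus-residual with the same record layout for every animal, the
sampler works in the eigenbasis of **G**, where every full conditional is
diagonal — iterations are then $O(n^2)$ instead of $O(n^3)$, which is
what makes long chains on hundreds of animals cheap.

Reported quantities are phenotype-scale: per draw, the genetic variance
is the trajectory variance $\phi(x(t))' \mathbf{K}_a \phi(x(t))$ averaged
over the integer DIM grid of the window (for $m=0$ this is
$\mathbf{K}_a/2$), the residual variance is the record-weighted mean of
the class variances, and $h^2 = V_a / (V_a + V_e)$ — the denominator
deliberately excludes permanent-environment and herd variance, matching
the convention in which total phenotypic variance is reported as
$V_a + V_e$. The GEBV of an animal is its posterior-mean genetic
trajectory averaged over the DIM window (for $m=0$, the intercept
coefficient rescaled by $1/\sqrt 2$).

### Two engines, one interface

The analysis this package reimplements describes simultaneously an
animal-level random-regression model with $\mathbf{G} \otimes \mathbf{K}_a$
and a BayesR-type SNP-effect method; the exact hybrid used is not
recoverable from a methods section alone. `smallgp` therefore ships both:

* `gibbs_rr_gblup()` — the full animal-level model above; and
* `bayesr_snp_engine()` — a BayesR-style sampler for SNP effects on one
  aggregated record per animal (the per-animal mean adjusted record),
  with the four-component mixture prior: effect variances
  $(0, 10^{-4}, 10^{-3}, 10^{-2}) \times \sigma_g^2$, the first class
  exactly zero, mixture proportions under a flat Dirichlet, and
  $\sigma_g^2$, $\sigma_e^2$ under scaled inverse-$\chi^2$ priors. The
  mixture variance scales are the BayesR literature's convention (the
  method name alone does not fix them) and are configurable.

The two engines answer the same questions (variance components, $h^2$,
GEBV) from different parameterizations; the GBLUP engine is the default
because the animal-level covariance structure is the one written out
explicitly in the model equations.

**Behaviour on null data.** A property worth knowing: on pure-noise
phenotypes the BayesR mixture does *not* concentrate its proportions on
the null class. The two smallest non-null classes are
likelihood-indistinguishable from the exact null on noise, so the
proportions stay near their flat Dirichlet prior, while the genomic
variance attributed to SNPs — the scientifically meaningful output —
stays negligible and no SNP reaches a confident inclusion probability.
The tests assert the latter, not a null-class share.

### MCMC protocol and reproducibility

The default protocol is three parallel chains of 25,000 iterations, the
first 5,000 discarded and the rest thinned by 10 —
`floor((25000-5000)/10) = 2000` retained draws per chain, and the package
always reports the arithmetic count. The master seed spawns one
sub-stream per chain; identical configuration and seed reproduce results
bit-for-bit. `convergence_diagnostics()` reports split-chain potential
scale reduction factors and autocorrelation-based effective sample sizes
per variance parameter.

## Quality control conventions

All thresholds default to the recording protocol this pipeline targets
and all "higher than" rules are strict inequalities for retention:

| Filter | Default | Convention |
|---|---|---|
| records per cow-lactation | ≥ 4 in DIM [8, 340] | window closed; whole lactation dropped |
| cow-mean fat outliers | mean > pop. mean + 3 SD | one-sided above, strict; two-sided by flag |
| standardized residuals | outside [−2, +2] | closed band, removal strictly outside; OLS on fixed effects only, internally studentized |
| GenCall score | calls ≤ 0.15 → missing | no-op with warning when scores absent |
| duplicate animals | genotype r > 0.98 | keep the higher call rate, ties by id |
| animal call rate | > 0.90 | |
| SNP call rate / MAF | > 0.95 / > 0.01 | screened together, one ledger row |
| chromosomes | autosomes 1–29 | species count configurable |

Stages run in a fixed order (duplicates → animal call rate → SNP
call rate/MAF → autosomes; phenotype steps 1 → 2 → 3), each stage
recomputing its statistics on the survivors of the previous one — the
defensible reading when the source protocol is silent — and the ledger
(screened / retained / dropped per stage, conservation enforced) makes
the effect of the ordering auditable. `qc_ledger_compose()` also accepts
ledgers whose SNP rows are marginal screens from a common base, as
published QC summaries are often printed, and returns the cumulative
retained counts.

The step-3 regression excludes DIM covariates by default (a flag adds
Legendre terms), and "monthly" recording is enforced only through record
counts and the DIM window, not calendar spacing.

## The synthetic-data generator

`simulate_population()` emulates the study conditions:

* **Herd structure** — herd sizes i.i.d. from the observed composition
  of a 1,260-herd smallholder population (sizes 1–7+, two-thirds
  single-cow herds); herds partitioned among CDCs at ~22 herds per CDC.
* **Genotypes** — 50K-style biallelic SNPs, allele frequencies uniform
  on a configurable MAF range, Hardy–Weinberg genotypes, chromosomes
  cycled over autosomes 1–29. Missingness, duplicates, sex-chromosome
  markers and other defects are injected separately by
  `inject_defects()`, which returns an exact manifest of what each QC
  filter must remove.
* **SNP effects** — the four-component mixture with proportions
  defaulting to (0.95, 0.03, 0.015, 0.005), a once-chosen BayesR-style
  sparsity; effects are rescaled so the realized variance of true
  breeding values equals the nominal $V_a$ exactly (standard simulation
  calibration, so recovery checks measure the estimator, not the
  simulation's sampling noise).
* **Phenotypes** — population mean 4 fat%, variance components
  defaulting to $V_a = 0.012$, $V_e = 0.106$ fat%² with zero
  permanent-environment and herd variance (the totals published for this
  trait leave no room for more), fixed effects drawn i.i.d. normal with
  SD 0.1 fat% (no magnitudes are published; this puts them on the order
  of the residual SD), eight equally spaced test days per lactation in
  [8, 340] with optional jitter.

What the generator does **not** emulate: linkage disequilibrium (SNPs
are independent), breed admixture and its allele-frequency structure,
selection, non-additive genetic effects, calendar seasonality of test
days, and informative missingness. Passing recovery tests on this
generator therefore demonstrates correctness of the estimators under the
stated model, not robustness to the full messiness of field data.

## Numerical choices

* EM-REML iterates to a componentwise change below `tolerance`
  (default 10⁻⁶ fat%²), with variance components clamped at a floor of
  10⁻⁸ × var(y) so boundary components (e.g. a true zero herd variance)
  terminate cleanly rather than stalling convergence.
* Rank-deficient fixed-effect designs (confounded year-month × CDC
  cells, single-level factors) are reduced to full rank by a
  rank-revealing QR before the MME are formed.
* The GRM is positive semi-definite by construction;
  `stabilize_grm()` blends $G^{*} = (1-w)G + wI$ (default $w = 0.01$)
  before inversion, and refuses to proceed if the result is still not
  positive definite.
* Mean imputation of missing calls precedes GRM centering (QC caps
  missingness at 5–10%, so the distortion is bounded); masking
  concordance rounds imputed dosages to the nearest genotype class with
  ties away from zero.
* The Gibbs samplers guard degenerate inputs (constant response) by
  flooring the variance used for prior auto-scaling.

## Problem sizes

The shipped tests exercise the samplers at a few dozen to a few hundred
animals with chains of a few hundred to a few thousand iterations, and
the parameter-recovery checks use 500 animals × 8 records with reduced
chains — sizes chosen so the whole suite reflects the models' behaviour
while remaining quick to run routinely. The same recovery computation at
3 × 5,000 iterations is what `scripts/acceptance.R` performs. All
reported numbers in the package documentation are produced by these
computations at run time.

## Known limitations

* Stage 1 treats animals as unrelated (by design); the genomic
  information enters only in stage 2.
* The BayesR engine works on per-animal aggregated records (an
  intercept-level reduction), not on the full random-regression
  structure; the GBLUP engine carries the full structure.
* No single-step (pedigree + genomic) evaluation, no dominance or
  epistasis, no haplotype-based imputation — `mean_imputer()` is a
  baseline, and imputation quality metrics (`allele_freq_r2()`,
  `masking_concordance()`) evaluate imputers rather than replace them.
* GEBVs for non-genotyped animals are out of scope.
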