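---
title: "Single-step genomic evaluation for growth under thermal stress: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step genomic evaluation for growth under thermal stress: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(troutgp)
library(dplyr)
```

## The problem

Aquaculture breeding nuclei select on growth traits that, under chronic
thermal stress, can only be measured on sibs of the selection candidates.
Genomic evaluation — single-step GBLUP over genotyped and ungenotyped
relatives, GWAS to locate trait-associated variants, and genomic prediction
under different marker densities — is the standard toolkit. `troutgp`
implements that pipeline end to end for a rainbow trout-like nucleus
population (full-sib families reared in tanks, low/mid/high marker-density
tiers) and couples it to a synthetic-population generator so every stage is
testable without external data.

## The animal model

All evaluation runs through the univariate animal model

$$ y = X\beta + Za + e, \qquad
   a \sim N(0,\, K\sigma^2_a), \quad e \sim N(0,\, I\sigma^2_e), $$

where $y$ are phenotypes (e.g. average daily gain in g/day, body length in
cm, body weight in g), $\beta$ holds the tank fixed effect and an
initial-body-size covariate, and $K$ is one of:

* **A** — pedigree expected relationships (tabular method; `build_A()`),
  giving pedigree BLUP (PBLUP);
* **G** — VanRaden's realized genomic relationships from centered allele
  counts, $G = M_c D M_c' / (2\sum_j p_j(1-p_j)w_j)$ with optional marker
  weights $D$ (`build_G()`), giving GBLUP;
* **H** — the single-step combination, used through its inverse
  $$ H^{-1} = A^{-1} +
     \begin{pmatrix} 0 & 0 \\ 0 & G^{-1} - A_{22}^{-1} \end{pmatrix}, $$
  which lets genotyped and ungenotyped animals be evaluated jointly
  (`build_H_inverse()`).

Heritability is $h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_e)$
(`heritability()`), and prediction accuracy in cross-validation is
$r(\hat{a}, y^{adj}) / h$ (`accuracy()`), the validation-set correlation
between predicted breeding values and fixed-effect-adjusted phenotypes,
rescaled by the square root of heritability.

### Numerical choices

* **Allele frequencies** for centering and scaling G are the observed
  frequencies of the genotyped set; missing genotypes are mean-imputed per
  marker (this preserves the frequency). With observed-frequency centering
  the columns of $M_c$ sum to zero, so **G is always singular** (the vector
  of ones is a null direction). The model therefore uses
  $G_b = (1-\alpha)G + \alpha A_{22}$ with $\alpha = 0.05$ by default —
  the standard blending of ssGBLUP software — which restores positive
  definiteness.
* **A-inverse** is built directly by Henderson's rules with inbreeding from
  the Meuwissen–Luo algorithm; dense storage throughout, adequate for the
  few-thousand-animal scale this package targets.
* **REML** (`reml_estimate()`) uses average-information updates with an
  EM-style multiplicative fallback whenever an AI step leaves the parameter
  space, plus step-halving so the restricted likelihood never decreases.
  Internally $ZKZ'$ is eigendecomposed once, making every iteration
  $O(np^2)$; the result is numerically identical to the dense formulation
  (it agrees with `lme4` to machine precision on designs both can fit, and
  with brute-force maximization of the dense restricted likelihood).
  Convergence is a relative parameter change below $10^{-8}$, capped at 200
  iterations; the residual variance is floored at $10^{-6}\,\mathrm{var}(y)$
  so the mixed-model equations stay solvable when a cross-validation split
  drives it toward the boundary (such fits are flagged unconverged). The
  standard error of $h^2$ comes from the inverse AI matrix by the delta
  method.
* **Mixed-model equations** (`solve_mme()`) are Henderson's; animals
  without records receive breeding values through kinship.

## Weighted single-step GWAS

`run_wssgblup()` iterates: (1) fit the model with all marker weights 1 —
plain ssGBLUP; (2) back-solve marker effects from the genotyped animals'
GEBV, $\hat{a}_{snp} = k^{-1} D M_c' G^{-1} \hat{u}$; (3) convert each
marker's effect to its share of additive genetic variance,
$100 \cdot 2p_j(1-p_j)\hat{a}_j^2 / \hat\sigma^2_a$; (4) use those variances
as next-iteration weights (floored at $10^{-8}$ of their mean, normalized to
mean 1 so the interpretation of $\sigma^2_a$ is stable). Two iterations are
the default; the final SNP table is the second iteration's.

Two asymmetries are deliberate. The model fit uses the **blended** G (it
must be invertible inside $H^{-1}$), while the back-solve uses the
**unblended** weighted G, so the round trip $M_c\hat{a}_{snp} = \hat{u}$ is
exact for any $\hat u$ in the column space of G; when that G is singular
(it always is, see above) a pseudo-inverse is used and the identity holds in
the projected space. The variance-percentage denominator is the current
iteration's REML $\hat\sigma^2_a$.

Lead SNPs are the top $k$ by variance explained, ordered with ties broken by
chromosome and position (`select_lead_snps()`), and candidate genes are any
annotation intervals intersecting the ±100 kb window around each lead
(closed-interval overlap; a gene containing the SNP is flagged, but
exon/intron resolution is out of scope).

## Genotype QC

`apply_qc()` removes samples below the sample call-rate threshold first
(so marker statistics reflect the retained cohort), then markers in the
fixed order **MAF → call rate → HWE**: a marker failing several filters is
counted once, at the first failing filter, which makes the removal counts a
deterministic partition. Tools with a different internal order will
attribute the same removals differently. The HWE test is the exact
(enumeration) test — the same family of test PLINK applies — computed on all
samples. Presets `qc_preset("wgs")` (MAF < 0.01, call rate < 0.80,
HWE < 1e-8), `"imputed_wgs"` (MAF < 0.05, HWE < 1e-8) and `"panel"`
(MAF < 0.01, call rate < 0.70, HWE < 1e-6) mirror the thresholds used for
the three genotype tiers this pipeline is designed around.

## Genomic-prediction experiment

`run_prediction_cv()` runs repeated k-fold cross-validation (5×5 by
default; folds differ by at most one animal; per-repetition seeds derive
from the master seed by fixed offsets) over marker scenarios:

* `wgs` — all markers;
* `pruned` — an LD-pruned subset (sliding 40 kb window, step one marker,
  greedy removal of the lower-MAF member of any pair with $r^2$ above the
  threshold, default 0.5, overridable per chromosome);
* `top_k` — GWAS-preselected subsets: within **every** training fold, the
  wssGBLUP GWAS is re-run with validation phenotypes masked and the top-k
  markers by variance explained are selected. The preselection GWAS is
  single-step, so it uses every phenotyped animal (genotyped or not); the
  prediction models themselves are fitted and validated on the genotyped
  cohort. Selected subsets are stored per split for audit.

Validation correlations are computed against phenotypes adjusted by the
training-estimated fixed effects (avoiding fixed-effect leakage). The Eq-4
denominator is one heritability per method, estimated once on the full
data: the pedigree $h^2$ for PBLUP and the full-density genomic $h^2$ for
every GBLUP scenario. Re-estimating $h^2$ from a preselected subset would
inflate the denominator with the selection itself and make scenarios
incomparable. Summaries report means over all splits and means of
within-repetition fold averages, plus the relative gain
$100(\mathrm{acc} - \mathrm{acc}_{PBLUP})/\mathrm{acc}_{PBLUP}$.

## Imputation harness

The imputation-accuracy design is masking cross-validation
(`run_imputation_cv()`): the panel animals are split into folds; validation
animals keep only the low-density markers; accuracy is the per-marker
squared correlation between true and imputed allele counts over masked
entries (zero-variance markers score 0 by convention; the retention filter
is strictly greater-than, default $r^2 > 0.8$). The imputer is a pluggable
function. The shipped `naive_impute()` is a deliberately simple baseline —
Mendelian-certain fills (0×0, 2×2, 0×2 parent pairs) and otherwise the
reference mean dosage $2p$ — because the contribution here is the
evaluation design, not the imputation algorithm; haplotype-library methods
can be dropped in behind the same interface. Non-integer dosages are
permitted downstream (G construction accepts them). `stepwise_impute()`
chains low→mid→high density steps, each step's output feeding the next.

## The synthetic-population generator

`sim_config()` defaults describe the study conditions the package is built
around: 36 sires × 66 dams producing 119 full-sib families averaging 15
offspring (range 12–16, sizes drawn uniformly then trimmed to the exact
total), offspring split evenly into 3 tanks within family, and a single
growth trait with target $h^2 = 0.4$ (the 0.33–0.55 range typical of growth
under thermal stress) on a unit-phenotypic-variance scale; the intercept
defaults to 3.4, an average-daily-gain-like scale. The genome is 30
chromosomes of 50 Mb / 1 Morgan with 5000 markers by default — a desk-scale
stand-in for the real 0.37 K/10 K/1.4 M tiers; `degrade_to_panel()` thins
to lower densities.

Genotypes are gene-dropped: founder haplotypes drawn independently per locus
at frequencies uniform in (0.05, 0.5), gametes formed with Haldane
(no-interference) recombination — crossover counts Poisson with the
chromosome's genetic length — and Mendelian transmission. Phenotypes are
intercept + tank effect + covariate slope × a standard-normal initial-size
covariate + TBV + normal residual. TBV comes from additive effects at
`n_qtl` sampled markers, rescaled so the **phenotyped cohort's** realized
genetic variance is exactly $h^2$ (residual variance $1-h^2$): the
generating-model heritability equals the target to machine precision, which
makes parameter-recovery tests sharp. The initial-size covariate is
simulated independent of TBV — the adjustment is what is being tested, not
a genetic correlation model. Genotyping error exists as a rate parameter
but defaults to 0. Tanks get effects 0.25 trait-SD apart by default.

What the generator does **not** emulate: selection across generations,
genotype-by-environment interaction, dominance or epistasis, sequence-level
LD structure from deep founder histories, and correlated initial-size
covariates. Tests passing on this generator therefore demonstrate the
algebra and the experimental design, not robustness to those features of
real data.

## Problem sizes used in the shipped checks

The package's deeper checks run at sizes chosen to exercise the designs
faithfully while staying desk-scale:

* heritability recovery: 134 full-sib families × 15 (2010 phenotyped
  fish), 600 markers / 200 QTL, pedigree REML, 10 seeds;
* the marker-density experiment: the study-structured population (119
  families × 15 = 1785 phenotyped, 540 genotyped), 3000 markers / 20 QTL,
  top-k = 675, 2 repetitions × 5-fold cross-validation, 5 seeds;
* algebraic identities on random pedigrees up to 500 animals and 100 random
  back-solve instances.

## Known limitations

* With ~130 large full-sib families, REML $\hat h^2$ has a finite-sample
  spread of about ±0.04–0.06 and a small negative drift; single-seed
  recovery within ±0.06 of the target is therefore not guaranteed even
  though the estimator is exact (it agrees with `lme4` and with brute-force
  likelihood maximization to machine precision). Designs with many smaller
  families recover the target without drift.
* GWAS-based preselection reliably **matches** the all-marker scenario at
  desk scale but does not reliably beat it: with a few hundred training
  animals the within-fold GWAS ranking captures only part of the causal
  variance, and the mis-ranked markers degrade the subset G. Panels built
  from windows around the true QTL (an oracle unavailable in practice) do
  beat the all-marker scenario decisively, so the limitation is GWAS power
  at this population size, not the evaluation machinery. At the real
  study's scale (hundreds of thousands of imputed markers, selection
  backed by all phenotyped relatives) the published gains are larger.
* The naive imputer is a baseline: its mean masked-genotype $r^2$ is far
  below what haplotype-library imputation achieves, so the $r^2 > 0.8$
  retention filter typically retains few or no markers under it. The
  harness, not the imputer, is the deliverable.
* Dense matrix algebra throughout: comfortable to a few thousand animals
  and a few tens of thousands of markers; beyond that, sparse/APY methods
  (out of scope) are needed.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_markers = 2000, n_qtl = 50, seed = 1)
ped  <- simulate_pedigree(cfg)
map  <- simulate_marker_map(cfg)
geno <- gene_drop_genotypes(ped, map, cfg)
sim  <- simulate_phenotypes(geno, ped, cfg)

offspring <- as.character(ped$id[ped$generation == 1])
geno_off  <- subset_genotypes(geno, ids = offspring)

qc <- apply_qc(geno_off, qc_preset("panel"))
fit <- run_wssgblup(qc$genotypes, sim$phenotypes, ped, n_iterations = 2)
glance(fit)
select_lead_snps(fit$effects, k = 5)
plot_manhattan(fit$effects)

cv <- run_prediction_cv(
  qc$genotypes, sim$phenotypes, ped,
  scenarios = list(list(name = "wgs"),
                   list(name = "pruned"),
                   list(name = "top_k", k = 500)),
  n_folds = 5, n_repetitions = 2, seed = 7)
compare_scenarios(cv)
autoplot(cv, gain = TRUE)
```
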