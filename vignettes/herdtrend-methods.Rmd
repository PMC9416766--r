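---
title: "Models and methods behind herdtrend"
author: "herdtrend maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind herdtrend}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdtrend)
```

herdtrend implements a complete quantitative-genetic analysis chain for
dairy-cattle breeding data on synthetic populations: pedigree algebra,
multi-trait animal-model BLUP, multi-trait REML variance components,
selection-index theory, and mixed-model genome-wide association. This
vignette explains each model, the tunable parameters and their defaults,
the numerical choices, and what the simulation-based checks do and do
not demonstrate.

## The trait set and reference parameters

The package is organized around the nine traits of the Israeli Holstein
breeding index PD19: milk, fat and protein yield (kg), somatic cell
score, conception status (CS, the inverse of the number of
inseminations to conception in percent), herd-life (days), persistency
(%), dystocia (%) and stillbirth (%). Two bundled parameter sets anchor
every default:

* `pd19IndexWeights()` — the index coefficients of each revision of the
  national index since 1985; the 2019 column defines PD19.
* `ilTraitCovariances()` — the published 9×9 genetic (**G**) and
  environmental (**E**) covariance matrices estimated from first-parity
  records of cows born 2008–2016. The phenotypic covariance is
  **P** = **G** + **E**.

Derived parameters follow the usual definitions: heritability
$h^2_t = G_{tt}/(G_{tt}+E_{tt})$, genetic correlation
$r_g = G_{ab}/\sqrt{G_{aa}G_{bb}}$, and the analogous phenotypic and
environmental correlations. `parameterMatrix()` reproduces the
conventional reporting layout (heritabilities on the diagonal, genetic
correlations above it). The published parameter table prints
phenotypic-scale correlations below the diagonal; the package therefore
exposes both `environmentalCorrelation()` and
`phenotypicCorrelation()`, and the cross-checks in the test suite use
the quantity that reconciles (milk–protein 0.90 is the phenotypic
value; the environmental-only value is ≈0.96).

## The individual animal model

All evaluation machinery assumes the multi-trait individual animal
model

$$y = Xb + Zu + e, \qquad u \sim N(0,\, A \otimes G), \qquad
  e \sim N(0,\, R),$$

where $A$ is the numerator relationship matrix over the pedigree,
fixed effects are herd-year-season (HYS) classes and parity shifts, and
each animal-parity record may observe any subset of traits: the
residual block of a record is the observed submatrix of **E**, and its
inverse enters Henderson's mixed-model equations (no imputation of
missing traits). Unknown-parent groups are supported as phantom-parent
columns (Westell/Quaas–Pollak): `assignGroups()` maps every unknown
parent slot to a group (`by_sex` mirrors the two-group national
convention for the variance-component data sets;
`by_sex_and_birth_year` the finer grouping of the full evaluation data
sets), and `aInverse()` appends the group columns with the standard
contribution rules. Because the group block receives no data and is
structurally singular, `buildMME()` adds a relative ridge of $10^{-8}$
to the group equations only.

Pedigree algebra is exact: inbreeding by the Meuwissen–Luo
gene-contribution algorithm, a dense tabular $A$ reserved for oracle
use at desk scale (guarded at 2,000 animals by default), and a sparse
$A^{-1}$ built directly from Henderson's rules with
Mendelian-sampling variances $d_i = \tfrac12 - \tfrac14(F_s+F_d)$,
adjusted when parents are unknown. The test suite verifies
$A A^{-1} = I$ on random pedigrees and that each animal contributes at
most a 3×3 block (≤ 9n nonzeros).

Reliabilities are exact at desk scale: $r^2 = 1 - \mathrm{PEV}/G_{tt}$
with the prediction-error variance read off the dense inverse of the
coefficient matrix (guarded at 4,000 equations). This replaces the
approximation used in national systems, which is not published; at the
scales this package targets, exactness is affordable and makes the
dense-oracle tests sharp.

EBVs are reported against a genetic base — the mean EBV of a chosen
birth cohort is subtracted per trait (`rebase()`, idempotent).
Realized genetic trends are ordinary least-squares regressions of EBV
on birth date in decimal years. Multi-parity evaluations are combined
as a normalized weighted sum; the national weights are unpublished, so
the default (0.5, 0.3, 0.2) favors early parities and is configurable.

## REML variance components

`remlFit()` estimates **G** and **E** by restricted maximum likelihood
for the same model. Rather than factorizing the mixed-model equations
at every iterate, the likelihood is evaluated in the eigenbasis of the
relationship matrix among the *phenotyped* animals: unphenotyped
relatives integrate out of the marginal likelihood exactly, and with
complete trait records and a shared fixed-effect design the rotated
observations decompose into independent $J \times J$ blocks
$\tilde y_k \sim N(\tilde x_k' B,\, d_k G + E)$ per eigenvalue $d_k$.
Connected components of the relationship matrix are detected first, so
family-structured data cost one small eigendecomposition per family.
This form is algebraically identical to the MME-based restricted
likelihood but is much faster at desk scale; it does require
complete-case records across the analyzed traits, which mirrors the
national variance-component analyses (cows with missing index traits
were deleted there too). With several parities requested, each
trait–parity combination becomes a separate trait, reproducing the
parity-as-trait convention.

Two update rules are implemented:

* **EM**: $G \leftarrow G + G(S_1 - T_1)G/n$ and
  $E \leftarrow E + E(S_0 - T_0)E/n$, where $S$ are the quadratic
  forms in $Py$ and $T$ the corresponding trace terms from the
  block-diagonal of $P$. EM is monotone in the restricted likelihood
  (asserted in the tests on every fit) but slow near a variance
  boundary.
* **AI**: average-information quasi-Newton steps with step-halving
  whenever a proposal would decrease the likelihood, and a fallback EM
  step if halving stalls. Approximate standard errors come from the
  inverse AI matrix at convergence.

The default `em-then-ai` runs 10 EM warm-up rounds (5 in the heavier
simulations) before switching — the standard remedy for AI divergence
far from the optimum. Positive semi-definiteness is enforced at every
iterate by eigenvalue flooring at $10^{-8}$ times the trace; derived
correlations are clamped to $[-1, 1]$. Convergence is declared when
the largest relative parameter change drops below `tol`
($10^{-6}$ by default). Non-convergence is flagged on the returned
object, with the last iterate preserved.

On balanced paternal half-sib data the animal-model REML estimate
coincides with the closed-form ANOVA estimator (a smooth
reparameterization maps one parameter space onto the other), which the
suite checks to $10^{-6}$. A zero-variance truth is checked on family
data rather than on unrelated animals: with $A = I$ the genetic and
residual variances enter the likelihood only through their sum, so a
boundary check on unrelated animals would be vacuous.

## Selection-index engine

For index weights $b$ and genetic SDs $g_j = \sqrt{G_{jj}}$:

* fraction of the index: $c_j = |b_j g_j| / \sum_j |b_j g_j|$;
* expected genetic gains under truncation selection on the index:
  $\Phi = i\, b'G / \sqrt{b'Pb}$, with selection intensity $i$;
* total expected economic gain: $\mathrm{TEG} = \Phi'b$;
* intensity calibration:
  $i = \mathrm{TEG}_{\text{realized}} \sqrt{b'Pb} / (b'Gb)$, so the
  calibrated expected total equals the realized total exactly (a round
  trip the tests verify to $10^{-10}$).

The intensity is interpreted as cumulated over the planning horizon of
the gain report (ten years in the national analysis); the module never
hard-codes a value — 3.02 enters only as an argument, because the
intensity across the four selection pathways is only known
approximately and was calibrated nationally against the realized total
gain. Traits with zero weight stay in all vectors: milk carries no
weight in PD19 yet shows the largest expected gain through its genetic
covariances with fat and protein — the correlated-response structure
the engine must preserve. Standardized discrepancies
$d_j = s_j(\text{realized}_j - \Phi_j)/g_j$ reverse the sign
($s_j = -1$) for the traits whose favorable direction is negative, so
a positive value always means faster-than-expected progress in the
desired direction.

The expected-gain formula is validated against an independent
truncation-selection Monte-Carlo oracle: 200,000 animals, top 5%
selected on the phenotypic index, matching intensity
$\varphi(z_\alpha)/\alpha$, with agreement within 2%. One published
asymmetry is reproduced as configured rather than resolved: expected
gains use first-parity parameters while realized trends average all
parities.

## Derived fertility and longevity traits

Conception status is $100/n$ for a cow conceiving at service $n$. For
censored sequences the number of further services is imputed from the
geometric model at the empirical per-service conception rate of the
cow's herd-year: $CS = 100/(n + 1/\hat p)$. The geometric model is the
minimal process consistent with a per-service rate; the national
imputation procedure is unpublished. A herd-year without any observed
conception falls back to the global rate, with a log message; if no
conception is observed anywhere the trait is undefined and the
function stops. Whether the national imputation conditions on parity
or cow covariates is unknown; the herd-year rate is used and the
choice is logged, not hidden.

Herd-life is days from first calving to culling. Live cows are
projected with a Kaplan–Meier curve fitted to the same data: observed
days plus the restricted mean residual lifetime
$\int_t S(u)\,du / S(t)$ (survival beyond the last observed event is
truncated, a conservative choice). Projection never alters
already-culled cows.

Herd-year-season classes split each herd-year at the April and October
freshening months. The year of season 2 is the year of the October
that starts it, so January–March belongs to the previous year's season
2; the convention keeps every class a contiguous six-month block (the
source convention is not stated, so contiguity decided the tie).

Pre-adjustment removes least-squares covariate-class effects (birth
month, calving month, 30-day days-open bins) estimated within the data
set and restores the overall mean, pooling classes under five records
with their nearest neighbor. National adjustment factors are
unpublished; within-data least squares is the transparent stand-in.

## Mixed-model GWAS

The scan is two-stage in the EMMAX style. SNPs are first filtered on
call rate (> 0.90, strict, matching the national ">90% of the tested
cohort" rule). The kinship is the identity-by-state mean
$K_{ij} = \overline{1 - |d_i - d_j|/2}$ over shared called SNPs. A
single-component genomic REML of $y = \mu + g + e$ with
$\mathrm{cov}(g) = \sigma^2_g K$ (the same spectral iterator, $J = 1$)
yields the pseudo-heritability $\sigma^2_g/(\sigma^2_g + \sigma^2_e)$;
per-SNP effects are then generalized least squares with the covariance
fixed at the null estimates. Missing dosages are mean-imputed per SNP
after QC (standard for this scan type; the source does not state its
handling). Test statistics use the t distribution with $n - 2$ degrees
of freedom with a per-SNP residual variance, so the scan collapses
*exactly* to the per-SNP OLS t-test when $K = I$ — the reduction the
tests check to $10^{-8}$. Monomorphic SNPs are flagged and excluded
from the p-value set. The experiment-wise correction is Bonferroni
over the tested SNP count. The response variable is intended to be
sire EBVs with reliabilities above a floor (no deregression or
weighting, as none is described for the source analysis); an optional
covariate matrix (e.g. birth year) is accepted and off by default.
`crossTraitEffects()` restricts two scans to shared SNPs with
MAF > 0.10 (optionally the top-k by p-value) and reports the
$R^2$ and slope of one trait's allele-substitution effects on the
other's — the single-marker view of a genetic correlation.

## The synthetic-data generator

`simConfig()` fixes the study conditions; the defaults are chosen once
and the analyses are tested against them:

* **Population structure**: discrete generations of random mating,
  founders half of each sex, offspring inheriting the dam's herd; 10
  herds; generation interval `yearsSpanned/nGenerations` with
  within-cohort birth-date jitter. A configurable fraction (5%) of
  non-founders loses the sire, the dam or both; unknown parents are
  simulated as phantom founders drawn from the founder distribution,
  matching the genetic-group modelling downstream.
* **Breeding values** by gene dropping: founders $N(0, G)$,
  non-founders mid-parent mean plus a Mendelian deviation with
  covariance $(\tfrac12 - \tfrac14(F_s+F_d))G$.
* **Phenotypes**: record = parity shift + HYS effect + breeding value
  + residual ($N(0, E)$, independent across parities). HYS SDs default
  to $\sqrt{0.1\,\mathrm{diag}(P)}$ — management groups explaining a
  tenth of phenotypic variance, a realistic magnitude for dairy herds.
  Parity shifts default to 0, 0.3 and 0.4 phenotypic SD for parities
  1–3 (the usual maturity gain). Sequential culling with per-parity
  hazards 0.25/0.30/0.35 (typical annual turnover) enforces monotone
  missingness: a parity-3 record exists only if parities 1 and 2 do.
* **Inseminations**: per-service Bernoulli trials at
  $p = \mathrm{logit}^{-1}(\mathrm{logit}(p_0) + s\,u_{CS} + h)$ with
  baseline $p_0 = 0.45$ (near the national per-service mean), herd
  effects $h \sim N(0, 0.15^2)$ on the logit, and the slope $s$
  calibrated by quadrature so the population SD of the expected CS
  matches the genetic SD of the CS trait. The trait model gives a
  variance on the percent scale, not a service-level process, so this
  logistic model is an explicit stand-in. Sequences stop at
  conception, at `maxServices` (8, censored) or at a mid-sequence
  culling (2% per failed service).
* **Genotypes**: founder allele frequencies uniform on the MAF range,
  Mendelian transmission of one random allele per parent per SNP
  (unlinked loci — no linkage map is simulated), optional per-SNP
  missingness for QC tests, and an optional causal architecture whose
  bivariate effects are scaled so the expected causal genetic
  covariance matches the protein/CS block of **G**.

A single master seed drives everything through named child streams
(`childSeed()`), so each operation is independently reproducible and
whole runs are byte-identical — the pipeline tests compare emitted
files line for line.

What the generator does **not** emulate: linkage and LD (SNPs are
independent), selection (matings are random by default; genetic trends
in simulated data are therefore null), age structure within herds,
genotype-by-environment interaction, maternal effects, and the
threshold nature of the calving traits (dystocia and stillbirth are
simulated and analyzed as ordinary linear traits, consistent with the
published linear-scale variance components). Passing parameter-recovery
tests therefore show that the estimators are correct for the stated
model, not that the model captures every feature of national data.

## Problem sizes used by the checks

The heavier checks run at sizes chosen to make Monte-Carlo error small
while staying comfortably interactive: BLUP/GLS equivalence on 50
random instances of up to 300 equations and 50 random pedigrees of up
to 300 animals; REML recovery on 30 replicates of 3,000 first-parity
cows in 50 independent paternal families (one sire, 20 dams, two
full-sib daughters per dam — a family design that identifies the
low-heritability fertility variance much better than pure half-sib
panels and keeps the relationship matrix block-diagonal); GWAS
calibration on 400 related individuals × 2,000 SNPs with ten
permutations, and genomic-REML recovery at n = 1,000. The nine-trait
REML path is supported but the stochastic checks use two traits
(protein and CS), the pair the published analysis emphasizes.

## Known limitations

* The REML engine requires complete trait records and a fixed-effect
  design shared across traits (per-trait designs and unequal record
  sets would need the general MME path, which `buildMME()` provides
  for BLUP but not for variance-component estimation).
* Exact reliabilities and the dense tabular $A$ are desk-scale tools;
  national-scale data would need iterative approximations that are out
  of scope.
* Expected gains computed from the *printed* covariance tables differ
  from the published expected-gain column by a few percent for the
  smallest-magnitude traits (SCS, CS, dystocia, stillbirth): the
  published column was computed from unrounded REML output, and
  one-decimal rounding of small covariance entries propagates several
  percent of relative error through $b'G$. The large-magnitude gains
  and the total economic gain agree well inside 1%.
* Genomic prediction, single-step blending of pedigree and genomic
  relationships, threshold models and multi-trait genomic evaluation
  are deliberately not implemented.
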