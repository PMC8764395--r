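---
title: "Single-step GWAS for herd data: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step GWAS for herd data: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssgwasr)
```

## The problem this package addresses

In performance-tested livestock populations, growth and carcass traits are
recorded on a limited set of animals (often males only), while genotypes are
available for a partially overlapping set that includes non-phenotyped
relatives. Single-step genomic BLUP (ssGBLUP) handles this unbalanced design
by combining the pedigree relationship matrix **A** and the genomic
relationship matrix **G** into one matrix **H**, so that every animal —
genotyped or not, phenotyped or not — contributes to one mixed-model
evaluation. A genome-wide association study is then obtained *post hoc* by
linearly transforming the genomic breeding values of the genotyped animals
into per-SNP allele substitution effects with prediction-error variances
(ssGWAS). This avoids the de-regressed-proof pseudo-phenotypes of two-step
GWAS, which behave poorly exactly in the sex-limited, partially genotyped
situation this package targets.

## Model

The animal model is

$$\begin{bmatrix} X'X & X'Z \\ Z'X & Z'Z + H^{-1}\frac{\sigma_e^2}{\sigma_a^2}
\end{bmatrix}\begin{bmatrix} \hat b \\ \hat a \end{bmatrix} =
\begin{bmatrix} X'y \\ Z'y\end{bmatrix},$$

with fixed effects (contemporary group, dam parity class, birth month) in
$X$ and additive genetic effects $a \sim N(0, H\sigma_a^2)$. The inverse of
the combined relationship matrix is

$$H^{-1} = A^{-1} + \begin{bmatrix} 0 & 0 \\ 0 & G^{-1} - A_{22}^{-1}
\end{bmatrix},$$

where $A_{22}$ is the pedigree relationship block of the genotyped animals.
`build_a()` uses the tabular recursion, `build_a_inverse()` Henderson's
rules with inbreeding (verified against each other and against a
path-counting oracle in the test suite). The raw genomic matrix is
$G_0 = MM'/(2\sum_i p_i(1-p_i))$ with $M$ centred by twice the allele
frequencies of the current genotyped set (`build_g()`); it is blended as
$G = 0.99\,G_0 + 0.01\,I$ to guarantee invertibility (`blend_g()`), and its
mean diagonal and off-diagonal are matched to those of $A_{22}$ to put the
two matrices on one genetic base (`tune_g_to_a22()`).

Two distinct "tuning" outputs coexist in the literature, and the printed
sources are ambiguous about which enters where. We apply the mean-matching
adjustment $G_\text{adj} = \alpha + \gamma G$ to the matrix used in $H$, and
additionally report the scalar
$\delta = 1 - \tfrac{0.5}{n^2}\bigl(\textstyle\sum_{ij} A_{22,ij} -
\sum_{ij} G_{ij}\bigr)$, which enters the SNP-effect back-solve below as a
multiplier. Both are returned so either convention can be audited; $\delta$
enters linearly (the alternative $\sqrt\delta$ reading is obtained by
passing `delta = sqrt(delta)`).

## SNP effects, their variances and p-values

After solving the MME, SNP allele-substitution effects are

$$\hat g = \lambda\,\delta\,\frac{1}{2\sum p_i q_i} M' G^{-1} \hat a_{22},$$

with sampling variance

$$\mathrm{Var}(\hat g) = \left(\lambda\delta\frac{1}{2\sum p_i q_i}\right)^2
M' G^{-1}\bigl(G\hat\sigma_a^2 - C^{22}\bigr) G^{-1} M,$$

where $C^{22}$ is the block of the inverted MME coefficient matrix belonging
to the genotyped animals, scaled by $\sigma_e^2$ so that it is directly the
prediction-error covariance of $\hat a_{22}$ (`solve_mme()` returns it on
this scale). Two-sided normal p-values follow as
$p_i = 2(1 - \Phi(|\hat g_i / \mathrm{sd}(\hat g_i)|))$. The test suite
checks the whole transformation against an independent SNP-BLUP fit (exact
equivalence on fully genotyped data) and the variance against a Monte-Carlo
sampling oracle. SNPs with zero prediction-error variance are excluded from
testing rather than given $p = 0$; the percentage of additive variance
explained is reported as the genic share $100\cdot 2p_iq_i\hat g_i^2 /
\sigma_a^2$ (the column is standard in GWAS reports but rarely defined; the
formula is stated in the output documentation).

Significance thresholds divide $\alpha$ by the *effective* number of
independent tests, computed from the eigenvalues of the SNP correlation
matrix: each eigenvalue contributes its integral part capped at one plus its
fractional part, summed per chromosome (whole-genome correlation matrices
are not desk-scale; per-chromosome blocks change the estimate only
marginally because between-chromosome correlation is negligible under
linkage equilibrium). The suggestive threshold is $1/m_\text{eff}$ — one
expected false positive per genome scan; boundary hits count as significant.
Calibration is summarised by the median-based inflation factor
$\lambda_{GC} = \mathrm{median}(\chi^2_\text{obs}) / 0.45494$.

## Variance components

`ai_reml()` estimates $(\sigma_a^2, \sigma_e^2)$ by average-information
REML. Internally the relationship matrix among recorded animals is
eigendecomposed once, after which every iteration costs $O(n)$; this is an
implementation device only — the estimates equal those of the naive dense
formulation (cross-checked in the tests) and of the balanced half-sib ANOVA
estimator. When an AI step proposes a non-positive variance the update
falls back to the EM fixed-point, and a component collapsing below
$10^{-6}$ of the total variance is snapped to that boundary so the
iteration can terminate; convergence is declared at a relative parameter
change below `tol` (default 1e-8, at most 200 iterations unless raised).

The bivariate model shares one relationship matrix with a 2x2 genetic and a
2x2 residual covariance; residual covariance applies only to animals
recorded in both traits. When both traits are recorded on the same animals
the same rotation trick applies (per-animal 2x2 blocks); otherwise a dense
general path handles unequal record sets. Non-positive-definite updates are
bent to the nearest positive-definite pair. Phenotypic (co)variances are
defined as genetic plus residual.

Standard errors of derived parameters (heritability, correlations) are
obtained by Monte-Carlo: parameter vectors are drawn from a multivariate
normal centred at the estimates with covariance equal to the inverse AI
matrix; draws violating positivity/positive-definiteness are rejected (an
error is raised if more than half are, since the sampling normal is then a
poor local approximation). Intervals are the shortest 95% highest-density
intervals of the draws, and a correlation is declared significant when its
interval excludes zero.

## The synthetic herd generator

Because no real herd data ship with the package, `simulate_herd()` builds
populations with known truth that emulate a small performance-tested
dual-purpose herd:

* **Pedigree** — discrete generations of random mating from a founder set;
  sexes alternate and are then shuffled so tiny pedigrees still contain both.
* **Genotypes** — founder haplotypes come from a latent AR(1) Gaussian
  process thresholded at each SNP's allele frequency (drawn uniform on
  [0.1, 0.5], giving a minor-allele-frequency spectrum centred near 0.3);
  descendants are gene-dropped with Poisson crossovers. The correlation
  scale `ld_decay_bp = 1e6` was chosen so that the mean $r^2$ of SNP pairs
  under 1 Mb is roughly 0.17–0.19, decaying to below 0.05 beyond 1 Mb —
  the LD regime typical of a local cattle breed with moderate effective
  population size. This first-order Markov model is *not* a coalescent: it
  reproduces the monotone distance decay of LD, but not long-range
  admixture LD, allele-frequency/LD correlations, or realistic haplotype
  block structure. Passing calibration tests on these data therefore shows
  correctness of the algorithms under a plausible LD regime, not robustness
  to every real-data pathology.
* **Phenotypes** — $y = \mu + Xb + Mq + e$ with a sparse-to-polygenic QTL
  vector $q$ (Gaussian, default 300 causal SNPs) rescaled so the *founder*
  breeding-value variance equals $h^2\sigma_p^2$ exactly. Founders are the
  natural base population: pedigree-based REML estimates base-generation
  variance, so scaling on all generations would bias recovery checks
  through the drift and linkage-disequilibrium variance that accumulates in
  descendants. Phenotypes are male-only by default (`sex_limited`),
  mirroring station-tested bull traits.
* **Weight series** — per-animal linear growth with Gaussian noise and a
  configurable fraction of erratic series, which is what the R² < 0.9
  cleaning rule is meant to catch.
* **Panels** — `split_panels()` reproduces a two-platform design (HD and
  LD chips with ~60% overlap) for the masking cross-validation harness.

Every simulator function is a pure function of its inputs and seed.

## Quality control

`run_geno_qc()` applies, in order: MAF < 0.01 and SNP call rate < 0.90
(pre-imputation), Mendelian-conflict blanking, imputation, then MAF < 0.05,
|observed heterozygosity − 2pq| > 0.15, SNP call rate < 0.90 and animal
call rate < 0.95. The heterozygosity filter is deliberately formulated on
the proportion scale: 0.15 is meaningless as a count, and the proportion
reading matches the intent of flagging departure from Hardy–Weinberg
heterozygosity. A Mendelian conflict is an opposite-homozygote
parent–offspring pair, or a heterozygous offspring of two identical
homozygotes; resolution blanks the offspring call, as the offspring
genotype is the observation with least corroboration. The imputation
cross-validation harness hides the between-panel overlap SNPs in a rotating
animal subset and scores any pluggable imputer by the correlation between
true and imputed dosages; the shipped baseline (parental average with
per-SNP-mean fallback) is intentionally simple — it provides a floor that a
real population/pedigree imputation algorithm should beat, and the harness
is the deliverable, not the imputer.

## Problem sizes and numerical choices

The test-suite and acceptance experiments use herds of 800 animals with
2,000 SNPs for calibration/localization and 2,000 animals with 1,000 SNPs
for variance-component recovery, ten seeds per condition — sizes at which
the dense algebra (relationship matrices, one MME inverse per evaluation)
runs in seconds while leaving the statistical targets well-determined.
Dense inversion is used up to a few thousand animals; $A^{-1}$ is always
assembled sparse. Blending defaults ($\lambda = 0.99$, $\beta = 0.01$)
follow common ssGBLUP practice. Degenerate inputs have defined behaviour
throughout: monomorphic SNPs are excluded from the G scaling, constant
weight series get slope 0 with R² = 1, a single genotyped animal drops the
off-diagonal tuning constraint, and an empty genotyped set collapses
$H^{-1}$ to $A^{-1}$ exactly.

## Post-GWAS interpretation

SNPs are mapped to every annotated gene interval within 15 kb (gene spans,
not CDS sub-features — the mapping a gene-level annotation service
provides). The enrichment background is every gene with at least one mapped
SNP; hits are genes containing at least one SNP with nominal $p < 0.01$,
counted once. Enrichment uses the one-sided hypergeometric tail with
Benjamini–Hochberg adjustment across all tested terms jointly (per-source
adjustment is an option), and a term must additionally cover at least 3 hit
genes and 4% of its background members. Candidate regions (top SNP ± flank)
are intersected with user-supplied QTL interval tables on 1-based inclusive
coordinates, reporting the category share of overlapping intervals;
`localized_ld()` reproduces the five-class $r^2$ colour binning used in
regional association plots, assigning boundary values to the lower class.

## Known limitations

* The generator's LD model is Markovian; see above for what that does and
  does not emulate.
* The baseline imputer ignores linkage and population haplotype structure;
  its accuracy is a lower bound, not a benchmark.
* Multi-trait models beyond two traits, permanent-environment/maternal
  effects, metafounders, unknown-parent groups and large-scale sparse
  $G^{-1}$ approximations are out of scope.
* Dense solves bound the practical size to a few thousand genotyped
  animals.
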