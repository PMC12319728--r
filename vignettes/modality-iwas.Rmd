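---
title: "Modality-level imaging-wide association testing: model, design and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modality-level imaging-wide association testing: model, design and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Two-stage instrumental-variable designs (TWAS/IWAS) test whether the
genetically regulated component of an intermediate phenotype — here an
imaging-derived phenotype (IDP) from brain MRI — carries a causal pathway
from a gene to a disease trait. The SNPs of a gene act as composite
instruments; validity requires that they affect the trait only through the
tested exposure. Brain imaging breaks the one-exposure picture twice over:
a modality (sMRI, dMRI, fMRI) contains dozens to hundreds of IDPs with high
within-modality and appreciable cross-modality genetic correlation, and genes
can retain direct effects on the trait that bypass imaging altogether.
Testing IDPs one at a time therefore either inflates Type-I error (no
pleiotropy adjustment) or, in a joint multivariate regression, loses power to
multicollinearity and multiplicity.

`miwas` tests one modality as a unit. For a gene with J SNPs, Stage 1
produces per-modality weight matrices Â⁽q⁾ (J × K_q) so that GÂ⁽q⁾ are the
genetically imputed IDPs. Stage 2 considers

y = G Â⁽¹⁾ β⁽¹⁾ + G Â⁽²⁾ β⁽²⁾ + ε,

where modality 1 is under test and Â⁽²⁾ stacks the other modalities' columns
and an all-ones burden column whose coefficient absorbs residual direct
genetic effects (the Egger-style device). The null H₀: β⁽¹⁾ = 0 is tested
with a variance-component score statistic in the SKAT mold: with the
adjustment coefficients estimated under the null, the score vector of the
tested columns has the summary-statistics form

S = Â⁽¹⁾ᵀz − Â⁽¹⁾ᵀRÂ⁽²⁾(Â⁽²⁾ᵀRÂ⁽²⁾)⁻¹Â⁽²⁾ᵀz,

Cov(S) = Â⁽¹⁾ᵀRÂ⁽¹⁾ − Â⁽¹⁾ᵀRÂ⁽²⁾(Â⁽²⁾ᵀRÂ⁽²⁾)⁻¹Â⁽²⁾ᵀRÂ⁽¹⁾,

with z the disease GWAS z-scores and R the SNP correlation (LD) matrix,
estimable from a reference panel. T = SᵀS is asymptotically a positively
weighted mixture of 1-df chi-squares with weights the eigenvalues of Cov(S).
A quadratic form is the right shape here because individual IDP effects are
expected to be small and of mixed sign, exactly the regime where SKAT-type
tests dominate burden-type linear combinations.

Two comparators are built in: `idp_specific_test(adjusted = TRUE)` tests each
tested-modality IDP separately with the same adjustment (Bonferroni over the
K₁ tests), and `adjusted = FALSE` gives classic univariate IWAS with no
adjustment. When the tested modality has exactly one IDP the modality test
coincides with the adjusted univariate test, and — with adjustment switched
off — with univariate IWAS.

**Scaling conventions.** Published formulations of the statistic carry
mutually inconsistent O(1) normalizing constants (1/N versus 1/(N−1) versus
split √N factors). The package computes S and Cov(S) purely in the summary
form above, with z and R as given. Because the p-value depends only on T
relative to the eigenvalues of Cov(S), any scaling common to S and the
implied covariance cancels; the test suite asserts this scale invariance to
1e-10. What does *not* cancel is the calibration of z itself: the inputs must
be genuine z-scores (unit variance under the null), which per-SNP GWAS Wald
statistics are.

**Binary traits.** The summary path treats the disease trait as continuous
(linearization). This is standard for small per-instrument effects; the
Type-I error experiments below run the binary generative model through
logistic GWAS summaries and confirm calibration.

## Stage-1 choices

- **z → marginal beta**: b = z/√(n − 2 + z²), the sample correlation implied
  by the Wald statistic of a univariate regression on a standardized dosage.
- **Joint weights**: Â columns solve R w = b. When the condition number of R
  exceeds 1e8 a ridge of 0.001 × mean(diag R) is added (`default_ridge()`);
  reference-panel LD for high-LD genes is otherwise not reliably invertible.
- **Clumping**: greedy, most significant first (two-sided normal p from z;
  ties broken by smaller genomic position for determinism), removing SNPs
  within 1 Mb at r² > 0.5. Per-IDP retained sets are merged (set union in
  genomic order) into one gene-level SNP set; SNPs absent from a particular
  IDP's GWAS receive weight 0 in its column.
- **Instrument screen**: the joint-model R² is reconstructed from summaries
  as bᵀR⁻¹b (clipped to [0, 0.999999]), converted to the overall
  F statistic on (J, n − J − 1) degrees of freedom, and the gene–IDP pair is
  kept when p < 5 × 10⁻⁵. Screening is applied after clumping on the merged
  set — the natural order when only summary statistics exist, since the
  merged set defines the weight support. Individual-level data, when
  available (the simulator), give the same F test through the standard
  joint regression; the suite checks the single-SNP case against the
  F-distribution tail directly.
- **Allele harmonization**: target tables are aligned to a reference
  orientation; swapped alleles negate z, strand-ambiguous pairs (A/T, C/G)
  are dropped (no allele frequencies are guaranteed in the inputs, so
  frequency-based resolution is not attempted), irreconcilable pairs are
  dropped, and within-file duplicate SNP ids are an error rather than being
  silently deduplicated (duplicates corrupt LD indexing).

## Mixture chi-square p-values

`mixture_chisq_pvalue()` computes Pr(Σ λ_k χ²₁ > T) after discarding
eigenvalues below 1e-12 × λ₁ (numerical noise otherwise inflates the mixture
dimension). Four routes:

- **Davies-type inversion** (`imhof_pvalue()`): the characteristic-function
  inversion integral evaluated as adaptive quadrature up to the first zero of
  sin θ(u) past θ's maximum, then as an alternating series of half-cycle
  segments between successive zeros; when the polynomially decaying envelope
  has not died out after 120 segments the alternating tail is summed by
  iterated Euler averaging. Against exact chi-square references the route is
  accurate to ~1e-10 across K = 1…10 and tail probabilities down to 1e-8.
- **Liu moment matching**: a noncentral chi-square matched to the first four
  cumulants; used automatically whenever the inversion fails or leaves
  (0, 1].
- **Monte Carlo**: (1 + #{draws ≥ T})/(1 + draws) over `mc_draws` mixture
  samples, so the p-value is never exactly 0; a seed is mandatory on this
  path.
- **Exact**: when all retained eigenvalues are equal (relative spread
  ≤ 1e-9) the mixture *is* λχ²_K and the survival function is evaluated
  exactly. This matters for K₁ = 1 — the modality test then reproduces the
  two-sided Gaussian score test to machine precision rather than to Monte
  Carlo error.

The `auto` policy uses the exact route when eigenvalues are equal, the
inversion when more than 5 eigenvalues remain, and Monte Carlo otherwise,
with Liu as fallback. Monte Carlo and the inversion are cross-checked against
each other in the suite within Monte Carlo sampling error.

Collinear adjustment columns (singular Â⁽²⁾ᵀRÂ⁽²⁾) are dropped by
rank-revealing QR pivoting, with the dropped IDP ids recorded in the result;
multicollinearity among imputed IDPs is common and exact singularity (e.g.
duplicated IDPs) should not abort a genome-wide run. Bonferroni significance
is strict (p < α/m) throughout.

## The simulation framework

`simulate_dataset()` implements the generative model used to validate the
test. One gene of J = 58 SNPs is drawn as correlated binary variables:
a latent multivariate normal is dichotomized at the allele-frequency
quantile, with latent correlations solved numerically (bivariate-normal
quadrature + root finding) so the *binary* correlations hit the AR(1) target
corr(gⱼ, gⱼ′) = ρ^|j−j′|. Infeasible targets are clipped to the attainable
bound. Q = 2 modalities of K = 10 IDPs follow

m_k⁽q⁾ = Σⱼ gⱼ α_jk⁽q⁾ + u γ_k⁽q⁾ + δ_k⁽q⁾,

with an unobserved confounder u ~ N(0,1) feeding both the IDPs and the
trait; the trait is

y = burden·μ + Σ_q Σ_k m_k⁽q⁾ β_k⁽q⁾ + u·θ + ε (continuous), or
logit E[y] = −2 + the same linear predictor (binary).

Defaults: α ~ N(0, 0.3²), γ ~ N(0, 1), β⁽²⁾ ~ N(0, 0.05²), μ = θ = 1,
sd(δ) = 5, sd(ε) = 4, allele frequency 0.3, LD base 0.5, n = 2000. The
tested modality's effects β⁽¹⁾ follow the scenario: all zero (null), all
N(0, τ²) (dense signal), or only the first IDP N(0, τ²) (sparse signal);
τ > 0 exactly when a signal scenario is requested. All effect vectors are
redrawn per replicate (random-effects reading of the design).

**Genotype scale and the burden term.** The design was calibrated so that,
under the null, the binary-trait prevalence is ≈ 18% and the average
genotype-to-trait and genotype-to-IDP R² stay below 0.10. These targets pin
down two otherwise open conventions, and they are mutually incompatible with
both of the "obvious" uniform choices: with column-standardized genotypes in
the structural equations the genotype-to-IDP multiple R² is ≈ 0.17 (the
gene's per-IDP heritability becomes implausibly large), while a raw-dosage
burden Σgⱼ·μ has variance ≈ 1ᵀΣ1 ≈ 36, driving prevalence to ≈ 0.42 and the
genotype-to-trait R² to ≈ 0.9. The package therefore uses allele-count (0/1)
dosages in the structural equations — the scale on which real SNP effects
act, giving a per-gene per-IDP heritability of ≈ 4% — and standardizes the
burden to unit variance before applying μ, giving a direct-effect
contribution of one logit unit. Under these defaults the realized design
hits all three stated calibrations (prevalence ≈ 0.20, R² ≈ 0.08 and 0.07).
Both conventions are exposed (`genotype_scale`, `standardize_burden`) for
sensitivity analyses.

**Derived summaries.** `individual_to_sumstats()` computes per-SNP Wald z
from univariate linear regressions (continuous outcomes) or univariate
logistic regressions (binary traits; a vectorized IRLS checked against
`glm()`; separation yields a dropped SNP), and R = GᵀG/(n−1) from the
standardized genotypes. A `z_method = "score"` variant returns the score-form
z = Gᵀy_c/(sd(y)·√(n−1)) with a common variance plug-in: with those inputs
the summary-path statistic equals the individual-level statistic
(`individual_level_test()`, computed entirely from raw matrices) up to one
global scale factor, hence identical p-values — the suite asserts agreement
below 1e-8. Per-SNP Wald z-scores carry per-SNP residual-variance factors,
so for them the equality is asymptotic rather than exact; they remain the
default because they are what real GWAS provide.

**Experiments.** `run_null_experiment()` and `run_power_experiment()` run the
four methods per replicate — (1) the proposed adjusted modality test, (2)
per-IDP adjusted tests with Bonferroni, (3) the unadjusted modality test, (4)
univariate IWAS with Bonferroni — on summary statistics derived from each
simulated dataset, with Stage-1 clumping and screening disabled (the
experiments probe the test, not the filtering; at the default AR(0.5) LD
clumping would be a no-op anyway since adjacent r² = 0.25). Method 3 is fully
unadjusted (no burden column) — the harsher comparator; the burden column can
be re-enabled through `modality_test(adjust_direct = TRUE)`. Methods 2 and 4
are reported as Bonferroni-adjusted minimum p-values so rejection is p < α
uniformly.

At the default conditions the suite reproduces the validation study's
findings: the adjusted tests hold the nominal 5% and 1% levels (slightly
conservatively, Method 2 more so than Method 1), the unadjusted methods
reject the null in the vast majority of replicates, dense-signal power of the
modality test increases with τ and exceeds the per-IDP comparator, and
sparse-signal power of the two adjusted methods is similar. The power grid
τ ∈ {0.05, 0.1, 0.2} was chosen from a variance budget: at τ = 0.1 the
detectable (genetic) signal variance is roughly 0.1 against a trait variance
near 21 at n = 2000 — the middle of the power curve — with the two
neighbors a factor of four in signal variance to either side.

**Problem sizes.** The acceptance-level checks use 1000 null replicates per
trait type for Type-I error, 500 replicates per (scenario, τ) cell for
power, and 200–250 replicates for the design-calibration quantities; at
these sizes a 3-standard-error bound on a 5% rejection rate is ±2.1
percentage points, tight enough to separate calibrated (≈ 0.03–0.05) from
inflated (> 0.9) methods unambiguously. The experiment drivers accept any
`n_reps` for larger runs (5000 replicates is a common choice at this design).

## What the simulations do and do not show

The generator emulates: LD-correlated biallelic genotypes, many-IDP
modalities with shared genetic architecture, an unobserved confounder acting
on both IDPs and trait, direct (pleiotropic) genetic effects, and both trait
types with GWAS summaries derived exactly as a practitioner would compute
them. It does not emulate: the empirical LD of any real gene (an AR(1)-decay
binary-correlation family with configurable base `ld_rho` stands in for real
haplotype structure, so comparisons against results computed on real gene LD
are qualitative, not numerical), allele-frequency
spectra across SNPs (one shared frequency), imputation uncertainty, sample
overlap structures between IDP and disease GWAS other than complete overlap,
or fMRI-style low-heritability regimes. Passing tests certify the statistic's
calibration and ordering under the stated design, not performance on any
particular real cohort.

## Known limitations

- No summary-level binary-link variant exists: the linearization is the only
  summary path for binary traits.
- Effect-size estimation and modality-level variance explained are out of
  scope; the package tests, it does not estimate β.
- Stage-1 penalized-regression training on individual-level imaging data
  (TWAS-style elastic net) is not implemented; the summary path plus the
  simulator's OLS path are.
- Harmonization does not attempt strand-flip rescue of ambiguous SNPs and no
  genome-build liftover is provided.
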