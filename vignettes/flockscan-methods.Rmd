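---
title: "flockscan: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{flockscan: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette describes the statistical models implemented in flockscan,
the choices made where the methodology left room, and what the synthetic
data generator does and does not emulate. It is the package's own account
of its methods; every empirical claim about behaviour is one the test suite
or `scripts/acceptance.R` actually computes.

## Data model

Genotypes are diploid biallelic SNP-array calls on autosomes, held as a
sample x marker matrix of counted-allele dosages {0, 1, 2} with `NA` for
missing calls, a marker map (chromosome, 1-based inclusive bp position,
alleles) sorted by position, and a sample table with farm labels. The
counted allele is always the minor allele observed in the retained samples
(lexicographic tie-break), which makes SNP substitution effects directly
comparable with MAF. Missing genotypes stay missing through run detection;
mean imputation happens only inside the GRM and the association scan.

Quality control filters in the conventional order — samples by call rate,
markers by call rate, autosome restriction, then MAF — with 90% call-rate
defaults and an optional MAF >= 0.01 cut used before the genomic analyses.
QC is idempotent; the report records removals per step.

## Runs of homozygosity and heterozygosity-rich regions

**ROH (sliding window).** A window of `window_snp` SNPs (default 50) slides
one SNP at a time within each chromosome; a window is homozygous when it
has at most `max_opposite` heterozygous (1) and `max_missing` missing (1)
calls. Each SNP receives the proportion of its overlapping windows that are
homozygous; SNPs at or above `window_hom_prop` (0.05) are candidates.
Maximal candidate stretches are split at inter-SNP gaps above `max_gap_bp`
(250 kb), trimmed to homozygous non-missing endpoints, and kept when they
have at least `min_snp` SNPs (20), `min_length_bp` bp (250 kb), and satisfy
the heterozygote/missing caps **again at run level**. Applying the caps at
both window and run level is deliberate: it honours the parameter
description ("allowed in a ROH") literally while keeping the standard
window mechanics; both levels share the same exposed parameters. A
consequence, verified by the brute-force oracle tests, is that a candidate
stretch that drifts across more opposite calls than the cap is dropped
whole rather than shrunk.

**ROHet (consecutive).** A candidate grows SNP by SNP and stops just before
the SNP whose inclusion would exceed `max_opposite` homozygotes (3) or
`max_missing` missing calls (2), or when the next gap exceeds 250 kb; it is
trimmed to heterozygous endpoints and emitted when it reaches 15 SNPs and
250 kb. After an emitted run the scan resumes at the SNP following the run
(greedy, non-overlapping). After a *rejected* candidate the scan resumes
one SNP right of the candidate's origin rather than after its end: the
end-resume rule can step over a passing interval that starts inside a
failed candidate, and the origin-advance rule provably cannot. The
exhaustive-subinterval oracle in the tests recomputes every constraint from
scratch and agrees run-for-run.

Run length is `last bp - first bp + 1`; the `+1` is a fixed convention,
immaterial at 250-kb scales but pinned for bit-exact tests. F_ROH divides
each individual's summed run lengths by `L_aut`, the summed per-chromosome
map extents (first to last mapped SNP) — the array's view of the autosomal
genome, not assembly lengths. Size-class tables and class-restricted F_ROH
use left-closed right-open bins ([2,4), [4,8), [8,16), [16,Inf) Mb by
default).

**Islands.** Per-SNP run frequency is the fraction of samples whose runs
cover the SNP's position. The island threshold is the empirical quantile
(default 0.999) of the genome-wide frequency vector, computed with R's
default interpolating quantile (type 7) — tie and interpolation handling
changes thresholds on small data, so the choice is documented and fixed.
SNPs at or **above** the threshold are members (the threshold value itself
qualifies); consecutive members with gaps at most `max_gap_bp` (default:
the run-level 250 kb) merge into one island. No merge rule is canonical in
the field; ours is parameterized rather than inferred.

## Reaction-norm resilience phenotypes

Test-day milk yield is modelled as

  milk = farm + lactation + year of lambing + month of lambing +
         days-in-milk class + sum_k beta_k phi_k(t*) +
         sum_k a_ik phi_k(t*) + e,

where phi_k are Legendre polynomials (order 0..2 by default) of the
temperature standardized to [-1, 1] over the observed range, a_i ~ MVN(0,
unstructured 3x3) are per-animal random regression coefficients, and the
model is fitted by REML via `lme4::lmer`. lme4 is used deliberately: a
random regression with an unstructured per-animal covariance on ~10^4
records is exactly its domain, whereas the package's dense AI-REML engine
is built around an n x n genomic covariance. Days-in-milk enters as
30-day classes to avoid confounding the lactation curve with the
temperature curve; the quadratic order is a parameter (`order`), since
with order 1 the slope is constant over temperature and with order 2 the
slope varies linearly — both interpretations of "slope of the reaction
norm" are available.

An animal's resilience phenotype at temperature T is the analytical
derivative of its *individual* curve (population curve plus predicted
deviation), including the standardization Jacobian 2/(t_max - t_min);
10 °C and 25 °C are the cold- and heat-stress evaluation points. Because
the per-animal curves are BLUPs, they are shrunken: the regression of
*true* slopes on *fitted* slopes has coefficient 1 (calibration), while
the reverse regression equals the reliability and is below 1 by
construction. The tests and the acceptance script therefore check the
calibration direction.

Lifetime milk yield uses the Fleischmann test-interval method per
lactation (first-test yield x its days-in-milk, then mean of adjacent
yields x the interval, summed over lactations; a single-record lactation
with no usable days-in-milk falls back to a 30-day interval). Length of
productive life is the number of calendar days from an animal's first to
last milk record, inclusive. Both are simple conventions standing in for
formulas the methodology leaves unspecified; nothing downstream depends on
their exact form.

## Genomic variance components, GEBV, GWAS, RHM

**GRM.** VanRaden method 1: G = ZZ'/(2 sum p_j(1-p_j)) with missing
dosages mean-imputed and columns centred at 2p_j; monomorphic markers are
excluded. PCA of G supplies the leading components (scores scaled by the
square root of their eigenvalues) as structure covariates; variance
proportions are eigenvalues over the trace.

**REML.** The engine maximizes the restricted likelihood of V = sum_k
theta_k K_k + theta_e I by average-information iteration with: clamped AI
steps with step-halving, an EM fallback step, a boundary probe that pins a
small component to its floor when doing so does not lower the likelihood
(the surface can be extremely flat near a zero variance), and an
active-set freeze for components that sit at the floor with negative
score. Convergence is a log-likelihood change below 1e-8 (or a stalled
parameter vector) within 200 iterations; variances are floored at 1e-10 x
the phenotypic variance. Standard errors come from the inverse AI matrix;
h2 = Vg/(Vg + Ve) and its SE by the delta method. A fit is flagged "at the
boundary" when a variance is pinned or h2 is within 1e-3 of 0 or 1. The
grid-search oracle test confirms the optimizer lands on the
likelihood-surface maximum.

**Bivariate REML** rotates both traits by the eigenvectors of G, turning
the stacked covariance G0 x G + R0 x I into n independent 2x2 blocks, and
maximizes the exact restricted likelihood over Cholesky factors of G0 and
R0 (so both stay positive semi-definite) by Nelder-Mead. The genetic
correlation's SE uses the observed information at the optimum (central
differences) and the delta method; significance is a two-tailed t with
n - rank(W) - 1 degrees of freedom. At the +/-1 boundary the Wald SE does
not exist; `profile_rg` evaluates the profile likelihood at chosen
correlation values, whose LRT remains valid there.

**GEBV.** BLUP solutions u_hat = Vg G P y at the REML estimates, with
PEV from Vg G - Vg G P G Vg (equivalent to the inverse mixed-model-equation
block, verified against a dense MME oracle); accuracy = sqrt(1 - PEV /
Vg), with PEV clamped to [0, Vg] and clamped animals flagged. The trait
additive variance (not Vg G_ii) is used in the denominator, following the
accuracy definition adopted here.

**GWAS.** For each SNP, y = Wa + xb + u + e is fitted by GLS after
eigendecomposition of G. Fast mode fixes the variance components at the
null-model REML estimates (one weighted least squares per SNP); exact mode
re-optimizes the variance ratio per SNP on the profiled restricted
likelihood. The Wald t uses n - rank(W) - 1 degrees of freedom (normal
approximation by flag). SNPs below MAF 0.01 after imputation are skipped;
SNPs collinear with the fixed effects return NA with a reason. Thresholds:
genome-wide alpha/n and suggestive 1/n (one false positive per scan);
genomic control reports lambda = median(chi2)/0.4549 always and rescales
only when lambda > 1. Raw and corrected columns are both kept, since
whether correction preceded thresholding is left open in the field.

**RHM.** Windows of 100 consecutive SNPs with 30-SNP overlap per
chromosome; the final window is anchored to the chromosome's last SNP
(possibly overlapping more than 30), and short chromosomes give one
whole-chromosome window. Each window's model carries two genomic
components — G_(i) from the window's SNPs and G_(-i) from all others, each
VanRaden-scaled on its own SNP set so both variances are on the phenotypic
scale — and the LRT compares against the model without the regional term.
The null is the 50:50 mixture of chi2(0) and chi2(1) (one variance tested
on its boundary), with plain chi2(1) available as a conservative option.
Small negative LRTs (within 0.01) are numerical and clamped; larger ones
raise an error. The degenerate all-SNP window reproduces the univariate
genomic model exactly, which the tests assert to 1e-6.

## The synthetic generator

`simulate_genotypes()` draws two independent Bernoulli(p) haplotypes per
SNP with farm-specific frequencies from the Balding-Nichols construction
(ancestral p ~ U(maf_range), divergence `farm_divergence` = 0.05 by
default across 3 farms), which yields PCA-visible farm structure. Defaults
mirror the emulation targets: 538 individuals, 47,600 SNPs on 26
autosomes, 0.2% missing calls. Planted ROH copy one haplotype over the
other inside the region and force the two flanking markers on each side
heterozygous — under the default one-het cap no window or run can cross
two consecutive heterozygotes, so the homozygous tract is exactly the
planted interval and the planted-recovery invariant is well-posed. Planted
ROHet force heterozygote calls. Missingness is sprinkled before planting,
so carriers are complete inside their region.

`simulate_phenotypes()` gives each animal a milk level and a
reaction-norm slope at 25 °C whose genetic parts are drawn as MVN with
covariance implied by (h2_milk = 0.26, h2_resilience = 0.20,
rg = -0.94) and the dataset's own GRM; permanent-environment parts fill
the phenotypic variances (level SD 0.5 kg, slope SD 0.015 kg/°C). Animals
also get a small quadratic (curvature) coefficient (SD 5e-4 kg/°C^2,
permanent-environment only) with the linear term anchored at 25 °C: the
truth then lives in the same quadratic basis the fitted model uses —
making BLUP calibration well-posed — without disturbing the configured
genetic parameters of the 25 °C slope. The population mean curve is the
quadratic whose slope is 0.003 kg/°C at 10 °C and -0.006 at 25 °C;
temperatures are i.i.d. N(15.51, 8.45^2) °C; ~19 records per ewe arrive in
8-test lactations with fixed farm/lactation/year/month/days-in-milk
effects and residual SD 0.3 kg.

What the generator does **not** emulate: linkage disequilibrium and its
decay (so no background ROH arise and island calling on unplanted data is
degenerate by design), pedigree/family relatedness (the GRM's information
about h2 comes only from marker-sampling and farm structure, making
heritability SEs larger than in a real flock with sires), seasonal
temperature autocorrelation, and selection or drift. Passing tests
therefore demonstrate correctness of the estimators under the stated
model, not real-data effect sizes; the study-specific quantities that are
reproduced exactly are the deterministic ones (threshold arithmetic,
detector definitions).

## Problem sizes and numerical choices in the checks

The test suite runs detector-oracle equivalence on 100 random 200-SNP
datasets; heritability recovery on 30 simulations of n = 500 ewes x 2,000
SNPs (true h2 = 0.20) plus 50 null phenotypes; one bivariate recovery at
n = 500 with true rg = -0.9 checked by Wald and profile likelihood;
GWAS calibration on one structured null of n = 500 x 2,000 plus a 30-sample
identity-kinship OLS oracle; reaction norms on n = 500 ewes x ~20 records;
and RHM power on 20 simulations over two 170-SNP chromosomes, so every
window overlaps its neighbour by exactly the standard 30 SNPs (an
end-anchored final window on a single short chromosome would overlap by
more and blur localization — an artifact of a toy genome, not of the
method). These sizes keep the whole suite in a few minutes while leaving
the Monte-Carlo error well inside the asserted bounds.

Known limitations: single-residual models only (no heterogeneous residual
variances per farm or stage of lactation); bivariate REML assumes both
traits measured on the same animals; no pedigree (A-matrix) alternative;
exact-mode GWAS re-optimizes one variance ratio, not both components; and
the run detectors are hard-threshold methods — no model-based (HMM)
calling.
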