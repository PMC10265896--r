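---
title: "Evaluating cross-population transferability of GWAS index SNPs"
author: "crosspop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating cross-population transferability of GWAS index SNPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosspop)
```

# The problem

Most genome-wide association studies (GWAS) are performed in European-ancestry
(EUR) cohorts, and their genome-wide significant index SNPs are routinely
carried over to other populations — for polygenic scores, drug-target
prioritization, or replication. Whether that transfer is justified for a given
SNP depends on two nuisance processes that have nothing to do with biology:

1. **Winner's curse.** An index SNP is selected *because* its estimated effect
   cleared $P < 5\times10^{-8}$ in the same data that estimated it, so its
   effect estimate is inflated away from zero.
2. **Sample-size imbalance.** Target-population studies (here, East Asian,
   EAS) are typically several-fold smaller, so a SNP can fail to replicate
   simply for lack of power.

crosspop implements a summary-statistics-only pipeline that removes both
nuisances and then asks, SNP by SNP, whether a discovery index SNP is also
significant in the target population, using the **trans-ethnic false
discovery rate (transFDR)** — the posterior probability that the SNP is null
for the phenotype in the target population, conditional on its observed
significance in both studies. The two resulting SNP groups
(population-common vs discovery-specific) are then characterized by effect
heterogeneity, direction concordance, and population-genetic differentiation.

# The model and procedure

## Harmonization and index-SNP selection

Per-population summary statistics are quality-controlled in five ordered
steps (duplicate ids, non-biallelic variants, missing rs labels, absence
from or allele mismatch with the reference panel, MAF $\le$ 0.01), restricted
to a common SNP set, and aligned to a shared effect allele (`qc_filter()`,
`harmonize_pair()`). Index SNPs are selected in the discovery population by
greedy P-value-ordered clumping (`clump()`): a significant SNP
($P < 5\times10^{-8}$) is kept unless it lies within 1 Mb of an
already-selected index SNP with panel $r^2 > 0.01$ — the PLINK `--clump`
convention, re-implemented on reference-panel dosages.

## Winner's-curse correction

For a selected SNP with observed effect $\hat\beta$ and truncation point
$c = \Phi^{-1}(1-\alpha/2) \approx 5.4513$ at $\alpha = 5\times10^{-8}$, the
corrected effect is the $\beta$ solving the conditional-mean identity

$$\hat\beta = \beta + s\,
  \frac{\phi(\beta/s - c) - \phi(-\beta/s - c)}
       {\Phi(\beta/s - c) + \Phi(-\beta/s - c)},$$

where $s$ is the per-phenotype pooled SE (mean discovery SE over the index
set). `winners_curse_correct()` solves this by a dense grid search
(10,001 points) over $\hat\beta \pm 1.96\,s$, the 95% confidence interval of
the observed effect, with ties broken toward smaller $|\beta|$. The SE is
then recomputed holding the Z score fixed, $se(\beta) = \beta/Z$.

Two properties of this estimator are worth knowing. First, the right-hand
side above is nearly flat in $\beta$ just above $c\,s$, so the inversion is
ill-conditioned near the threshold; the confidence-interval window acts as a
regularizer, and observations whose solution lies below the window are
corrected to the window boundary (a maximum shrinkage of $1.96\,s$). Second,
like all conditional-mean inversions, the estimator under-corrects right at
the threshold and over-corrects at moderate true effects; in our simulations
(true $z$ uniform on $[4, 8]$, per-SNP conditioning on selection) the signed
mean bias falls from about $+0.66\,s$ (raw) to about $-0.17\,s$
(corrected), a three-to-five-fold reduction rather than an elimination.
`scripts/acceptance.R` recomputes both numbers on every run.

## Sample-size standardization

Target-population SEs are replaced by the value implied by the *discovery*
sample size at the SNP's target allele frequency
(`standardize_se()`, `rescale_target_stats()`):
$se = \sqrt{1/(N f (1-f))}$ for continuous phenotypes and
$se = \sqrt{(N_1+N_0) / (2 N_1 N_0 f (1-f))}$ for binary ones, keeping the
effect fixed and recomputing $z = \beta/se$ and the two-sided P value. After
this step, a small target z-score can no longer be blamed on the target
study being smaller.

## transFDR via an empirical-Bayes two-group model

On the standardized target z-scores of the index set, `transfdr()` fits
Efron's two-group local false discovery rate with a theoretical
standard-normal null:

$$\mathrm{fdr}(z) = \hat\pi_0\, f_0(z) / \hat f(z),$$

with $\hat f$ estimated by Poisson-regression natural-spline smoothing of
histogram counts (120 equal-width bins, 7 spline df by default), $\hat\pi_0$
by Storey's estimator at $\lambda = 0.5$ (capped at 1), values clipped to
$[0,1]$ and made monotone non-increasing in $|z|$ on each side of zero by
isotonic regression. Conditioning on discovery significance is realized by
restriction: the two-group model is fit on exactly the discovery-significant
index set, so $\hat f$ is the conditional marginal density and the local fdr
is the conditional posterior null probability — the transFDR. SNPs with
transFDR < 0.05 form the significant (population-common) group.

Sets smaller than 30 SNPs skip density estimation and fall back to
Benjamini–Hochberg adjusted target P values, a conservative surrogate. MHC
SNPs (chr6:28.5–33.5 Mb) are excluded before fitting because their long-range
LD violates the approximate-independence assumption of the index set.

## Group characterization

* **Effect heterogeneity** (`heterogeneity_test()`):
  $u = (\hat\beta_{1} - \hat\beta_{2}) / \sqrt{s_1^2 + s_2^2 - 2 \hat r_m s_1 s_2}$,
  comparing the unadjusted target effect with the bias-reduced discovery
  effect, with BH adjustment per group. $\hat r_m$ is the **disattenuated
  marginal effect correlation** of the SNP's group
  (`marginal_correlation()`): sample covariance over noise-corrected sample
  standard deviations, $S_{12}/\sqrt{(S_1^2 - \overline{se_1^2})(S_2^2 -
  \overline{se_2^2})}$, clipped to $[-1,1]$, falling back to raw Pearson when
  a noise-corrected variance is non-positive.
* **Direction concordance** (`direction_concordance()`): sign-pair classes
  $++, +-, -+, --$ (target sign first) and the discordance share.
* **Population-genetic metrics** (`ld_scores()`, `hudson_fst()`,
  `pair_cv()`): LD scores as windowed sums of bias-adjusted squared dosage
  correlations $r^2 - (1-r^2)/(n-2)$ over a 10 Mb window with MAF > 0.01 and
  HWE $P > 10^{-5}$ flanking filters; Hudson's Fst with sampling correction;
  and the two-population coefficient of variation
  $(|a-b|/\sqrt2)/\bar{x}$ for MAF (folded) and LD scores. Groups are
  compared per phenotype by a two-sided Mann–Whitney U test (normal
  approximation, tie-corrected, no continuity correction) and across
  phenotypes by an exact sign test on the direction of per-phenotype group
  means.
* **Phenotype-level tests** (`h2_difference_test()`, `rho_tests()`): the
  heritability-difference statistic
  $u = (\hat h^2_1 - \hat h^2_2)/\sqrt{se_1^2 + se_2^2 - 2\hat\rho_g se_1 se_2}$
  and normal tests of the trans-ethnic genetic correlation against 0 and 1,
  consumed from an external LDSC/popcorn-style estimate table
  (estimation of $h^2$ and $\rho_g$ themselves is out of scope).

# Design choices where the method was open

* **Sidedness of the $\rho_g$ tests.** Implemented two-sided. On the bundled
  31-phenotype table, two-sided tests with BH at 0.05 reject $H_0:\rho_g=1$
  for exactly 16 of 30 phenotypes (53.3%), which matches the published
  share; one-sided tests would give 19.
* **Conditioning in transFDR.** The conditional two-group model is fit on
  the discovery-significant index set itself; no attempt is made to model
  the joint density over both populations' P values, since the analysis set
  already realizes the discovery conditioning event.
* **$\pi_0$.** Storey at $\lambda = 0.5$, capped at 1 — robust at index-set
  sizes of 50–1300. A central-matching empirical null is deliberately *not*
  used: index sets are small and strongly enriched, which breaks the
  "null majority near zero" assumption central matching needs.
* **Palindromic SNPs.** A/T and C/G variants are strand-ambiguous; they are
  kept only when MAF < 0.4 in both populations (configurable), the
  conventional safeguard.
* **Duplicates.** All copies of a duplicated id are dropped, not
  "keep first": conflicting duplicates are unresolvable from summary data.
* **Clumping ties.** Equal P values break toward lower (chrom, bp), making
  the output platform-deterministic; distance is measured
  index-to-candidate.
* **Fst estimator.** Hudson's, with the finite-sample correction in the
  numerator (reported unclamped, so slightly negative values occur at
  undifferentiated SNPs). It is nearly unbiased and does not depend on the
  relative sample sizes of the two panels.
* **"Paired McNemar" across phenotypes.** Reducing each phenotype to the
  binary indicator "significant-group mean < non-significant-group mean" and
  testing against 0.5 is implemented as the exact binomial sign test; a
  literal McNemar chi-squared on the discordant-pair construction is
  available behind `literal_mcnemar = TRUE`. A textbook McNemar needs paired
  binary outcomes that the averaged-metric design does not define.
* **Heritability CV.** The two-value coefficient of variation uses the
  $n-1$ sample standard deviation, $(|h^2_1 - h^2_2|/\sqrt2)/\text{mean}$.
  Other conventions rescale all CVs by a constant and cannot change the sign
  of its correlation with $\rho_g$, which is the quantity of interest.

# The synthetic-data generator

`generate_panels()` draws ancestral allele frequencies from
Uniform(0.05, 0.5) and diverges them with the Balding–Nichols model, whose
parameter is the expected Fst — measured per-SNP Hudson Fst tracks the
requested level across 0–0.1. LD blocks share a latent Gaussian factor per
haplotype; liability thresholding attenuates the latent correlation, so
realized dosage $r^2$ sits somewhat below the nominal `within_block_r2`.
Analyses only ever use realized panel $r^2$, so this affects no downstream
contract.

`generate_paired_sumstats()` draws causal standardized effects from a
bivariate normal with correlation $\rho_g$ and variance $h^2_k/m_c$,
converts to the per-allele scale by $1/\sqrt{2f(1-f)}$, and adds sampling
noise with $se = 1/\sqrt{2 N f (1-f)}$ (effective sample size
$4 N_1 N_0/(N_1+N_0)$ for binary phenotypes). This scale convention makes
the mean association chi-square equal $1 + N h^2/m$, the standard polygenic
expectation, which the tests verify by simulation. Note the deliberate
contrast with the SE-standardization step, which implements the published
approximation $se = \sqrt{1/(N f(1-f))}$ (no factor 2) exactly as stated;
the generator needs internal consistency, the standardization step needs
fidelity to the published formula, and no computation mixes the two roles.

What the generator does *not* emulate: realistic genome-wide LD maps,
population stratification within a population, imputation error,
liability-scale case–control effects (binary phenotypes are emulated at the
summary level only), and correlated estimation noise between populations.
Passing tests therefore demonstrate the statistical machinery under the
stated model, not robustness to these real-data complications.

# Numerical choices

* Deep-tail evaluation of the shrinkage identity switches to log-domain
  normal tails when both $\Phi$ arguments fall below $-30$, avoiding 0/0.
* `local_fdr()` guards degenerate inputs (all-identical z, fewer than 30
  values) by returning the conservative value 1 with a warning; empty
  histogram bins are expected and harmless in the Poisson fit.
* Exact-zero P values (underflow of `pnorm` at $|z| \gtrsim 38$) are
  accepted by `bh_adjust()`.
* All pipeline randomness flows from one seed through per-stage substreams
  (`run_pipeline()`), so reruns are bit-identical; the test suite checks
  output-file hashes.

# Problem sizes used in the tests

The suite exercises: panels of 50–2,000 SNPs with 80–200 individuals;
paired summary statistics of 1,000–10,000 SNPs; transFDR calibration on 50
replicate index sets of 400 SNPs (half shared at essentially full power,
half target-null) plus 50 pure-null sets; winner's-curse bias reduction on
2,000 selected SNPs; and disattenuation recovery on 5,000 SNPs with noise
at half the signal variance — a regime typical of borderline GWAS hits.
These sizes give Monte-Carlo error well below every asserted tolerance
while keeping the default run in the tens of seconds.

# Known limitations

* The conditional-mean winner's-curse inversion over-corrects moderately
  strong effects (see above); bootstrap or empirical-Bayes (FIQT-style)
  alternatives are out of scope.
* Local-fdr estimates are pointwise-accurate away from the fdr transition
  but can err substantially *in* the steep transition region at realistic
  set sizes; group classification (the actual decision) is calibrated, as
  the FDR-control tests verify.
* The per-SNP heterogeneity test plugs the group's effect correlation
  $\hat r_m$ into the variance of the estimate difference, which is
  anti-conservative when estimation errors are independent across
  populations; with $r_m = 0$ it reduces to the standard two-sample z test,
  and the type-I-control test uses that configuration.
* transFDR assumes approximately independent SNPs; clumping plus MHC
  exclusion enforces this only approximately in regions of unusual LD.
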