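---
title: "Methods: multitrait association testing, imputation and profile clustering from GWAS summary statistics"
author: "mtgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multitrait association from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtgwas)
```

# The model

For one SNP observed in $K$ univariate GWAS, collect the per-trait Z-scores
into $z = (z_1,\dots,z_K)^\top$. Under the complete null of no association,
$z \sim N(0, \Sigma_r)$: the off-diagonal structure of the *residual
covariance* $\Sigma_r$ is created entirely by sample overlap combined with
phenotypic correlation. For two studies of sizes $n_1$, $n_2$ sharing $n_s$
individuals whose phenotypes correlate at $\rho$,
$$(\Sigma_r)_{12} = \rho\, n_s / \sqrt{n_1 n_2},$$
so $\Sigma_r$ interpolates between the identity (disjoint studies) and the
phenotypic correlation matrix (complete overlap). Under the alternative,
$z$ gains additional covariance through shared genetics, summarized by the
genetic covariance $\Sigma_g$ of standardized effects.

Two test families are built on this null:

* the **omnibus** Wald statistic $T_{omni} = z^\top \Sigma_r^{-} z$,
  chi-square with $K'$ degrees of freedom where $K'$ is the rank retained by
  the pseudo-inverse $\Sigma_r^-$. It spends power uniformly in all
  directions of trait space;
* the **sumZ** statistic
  $T_{sumZ} = (w^\top z)^2 / (w^\top \Sigma_r w)$, chi-square with one
  degree of freedom for any fixed weight vector $w$, scale-invariant in $w$.
  It concentrates power along $w$.

Writing $\Sigma_r = P D P^\top$, the omnibus statistic is exactly the sum of
the sumZ statistics over the eigenvectors of $\Sigma_r$
($T_{omni} = \sum_i T_{sumZ}|_{w=v_i}$), which the suite fuzz-tests to
$10^{-8}$ relative error. With a single predictor and complete sample
overlap the omnibus test is equivalent to an individual-level MANOVA; the
verification engine measures a $>0.99$ correlation of $-\log_{10} p$ between
the two on simulated genotype data (and $>0.95$ when the phenotypes are
made non-normal), which justifies treating the summary-statistic test as a
stand-in for the individual-level analysis.

Four weightings are provided: all-ones (`sumz_1`, a fixed-effect
meta-analysis flavour), the first eigenvector of $\Sigma_r$ (`sumz_r`,
dominant axis of phenotypic correlation), the first eigenvector of
$\Sigma_g$ (`sumz_g`, dominant axis of genetic correlation), and an
independent component of the genome-wide Z matrix (`sumz_ica`). For the ICA
weighting, components are extracted by a deflation FastICA with the logcosh
contrast, and the component retained is the one yielding the most regions
significant for its sumZ test at $10^{-8}$ while univariately
non-significant (ties: total significant regions, then component index).
Because a direction estimated from $10^5$ SNPs is essentially independent of
any single SNP, this selection does not inflate the null — the calibration
study checks all five tests at $\alpha = 0.05$ and $10^{-3}$ within three
binomial standard deviations.

## Rank deficiency

When traits are numerous or nearly collinear, $\Sigma_r$ is rank-deficient.
Three inversion strategies are exposed, with `truncate` the default
(eigenvalues $> \varepsilon$ retained, $df = K'$), plus `floor` (eigenvalues
clamped to $\varepsilon$, $df = K$) and `ridge`
($(\Sigma_r + \varepsilon I)^{-1}$, $df = K$). The default
$\varepsilon = 10^{-6}$ keeps the omnibus calibrated on rank-deficient null
panels (tested at rank 6 of 12); `floor` and `ridge` are retained for users
who prefer full degrees of freedom at the price of conservativeness.

# Estimating $\Sigma_r$

Obtaining $(\rho, n_s, n_1, n_2)$ for every pair of consortium GWAS is
impractical, so $\Sigma_r$ is estimated from the data:

* **naive**: pairwise-complete covariance of all Z columns. Biased when
  causal SNPs with correlated effects contaminate the genome-wide pool (the
  verification engine plants 10% causal SNPs and measures the inflation);
* **trimmed**: same after removing SNPs with any per-trait
  $p < 5\times10^{-8}$; strictly smaller bias in the contamination study;
* **pruned**: a random SNP subset (a stand-in for LD pruning; with the
  block-LD model used here, random thinning is the operative part);
* **LD-score regression**: for each trait pair, regress $z_j z_k$ on the LD
  score $\ell$ with weights $1/\ell$; the intercept estimates
  $(\Sigma_r)_{jk}$ free of polygenic contamination, and the slope times
  $M/\sqrt{n_j n_k}$ estimates $(\Sigma_g)_{jk}$. Standard errors come from
  a delete-block jackknife over 200 contiguous blocks. The weights are the
  simplest choice that preserves the intercept target at these problem
  sizes; the full heteroskedasticity-aware weighting of dedicated
  heritability software is out of scope and the jackknife makes the
  uncertainty explicit.

$\Sigma_r$ is estimated *before* imputation, since imputation reuses LD and
would otherwise correlate the errors. A deliberately downscaled $\Sigma_r$
(80%) inflates the genomic inflation factor of the omnibus above 1.05 on
null data, while the correct matrix stays in $[0.95, 1.05]$ — the
misspecification study keeps this visible.

# Preprocessing

The pipeline follows six steps: extract and validate columns; restrict to a
strand-unambiguous reference (A/T and C/G SNPs are excluded when the
reference is built, and the harmonizer refuses ambiguous references rather
than guessing strand); derive $z = \mathrm{sign}(\hat\beta)\,
\Phi^{-1}(1-p/2)$ from the signed statistic and p-value; infer missing
sample sizes; filter entries with $n$ below 70% of the per-trait maximum;
impute missing Z-scores.

Choices worth stating:

* p-values of exactly 0 are clamped to $10^{-300}$ (far beyond any decision
  threshold, which is $10^{-8}$) rather than producing infinite Z;
* when a file carries both $z$ and $(\hat\beta, se)$ and they disagree by
  more than 0.1, the p-derived value wins and the conflict is logged — the
  p-value is the canonical source;
* the per-trait maximum used by the 70% filter is by default the 99.9th
  percentile of observed $n$, which resists single-row typos; the literal
  maximum is available via `robust = FALSE`. Observed $n$ takes precedence
  over inferred $n$ when both exist;
* the sample-size proxy is $\hat n = 1/(se^2 \cdot 2f(1-f))$. For a linear
  model on a standardized outcome it targets $N\sigma_e^2$; for logistic
  GWAS it is proportional to $Np(1-p)$, assuming the case fraction is
  stable across SNPs. The verification engine recovers the true $N$ within
  5% at $N = 20{,}000$ and measures $<5\%$ coefficient of variation of the
  proportionality slope across case fractions.

The low-sample-size filter is not cosmetic: SNPs assayed on fewer samples
than the bulk of a trait's panel have *less* cross-trait overlap than the
global $\Sigma_r$ assumes, and testing them against it inflates the omnibus
(the heterogeneous-overlap study shows $\lambda_{GC} > 1.05$ in the
low-overlap stratum and monotone decline of the median statistic with
per-SNP overlap). Filtering restores calibration.

# Imputation

Within an LD block with correlation matrix $R$, missing Z-scores are
imputed by their Gaussian conditional expectation given the observed ones,
$\hat z_t = R_{t,obs}(R_{obs,obs} + \lambda I)^{-1} z_{obs}$, with quality
$q_t = R_{t,obs}(R_{obs,obs}+\lambda I)^{-1}R_{obs,t}$. Defaults
$\lambda = 0.1$ and quality threshold $0.6$ are conservative: poorly tagged
SNPs stay missing rather than being filled with near-zero conditional
means. At $\lambda = 0$ the implementation matches the closed-form
conditional expectation to $10^{-10}$, and on a 20,000-SNP blockwise null
panel the omnibus p-value distribution moves by less than 0.02 in
Kolmogorov–Smirnov distance after imputing 30% of one trait's entries.

Imputation can still produce isolated artifacts, so a post-imputation QC
rule removes genome-wide-significant SNPs with no LD neighbor
($r^2 \ge 0.2$) at $p < 10^{-6}$.

# Locus discovery

Analysis regions are LD blocks (half-open `[start, end)` intervals).
Per region, the minimum multitrait and minimum univariate p-values are
extracted; a region is a *new multitrait association* when the joint
p-value is below $10^{-8}$ while the univariate one is not. Within
significant regions, lead SNPs are selected by greedy PLINK-style clumping
(`p1 = 1e-8`, `r2 = 0.2`; smallest p first, ties broken by position then
id; cross-region LD treated as zero). The SNPs fed into clustering are the
union of the three tracks (minimum univariate, ICA sumZ, omnibus) at
$10^{-8}$, one representative per clump — the member with the smallest
p-value across the three tests among those with at least 60% of their
profile observed. The sign-test track of the profile analysis uses the
stricter `r2 = 0.05` thinning, as two different questions (representative
selection vs strict independence) warrant two radii.

# Profile clustering

Selected SNPs are clustered on their Z profiles with a $k$-component
Gaussian mixture fitted by EM in the presence of missing coordinates: the
E-step evaluates each component's marginal density on the observed
sub-vector and the conditional moments of the missing block; the M-step
updates $(\pi, \mu_j, \Sigma_j)$ from completed sufficient statistics. The
log-likelihood is asserted non-decreasing at every iteration.

Numerical choices: initialization is k-means++ on the column-mean-completed
matrix with 5 restarts of 10 burn-in EM iterations, best likelihood
continued to convergence (relative tolerance $10^{-6}$); component
covariance eigenvalues are floored at $10^{-6}$; an effectively empty
component is re-seeded once and the fit fails on a second collapse —
deliberately, since it signals $k$ above the support of the data; labels
are canonicalized by the first coordinate of the means; subsampling keys on
sorted SNP ids, so row order is irrelevant end to end.

Assignment ambiguity is measured by the entropy
$S_i = -\sum_j p_{ij}\ln p_{ij}$ of the posterior memberships; SNPs with
$S_i > 0.75$ are excluded from downstream cluster summaries. Two caveats
are intentional and documented: the entropy here uses the conventional
minus sign (a sign-free variant would order ambiguity backwards), and with
natural logarithms the 0.75 threshold exceeds $\ln 2 \approx 0.693$, so no
filtering can occur for 2-cluster models — the threshold is configurable.

The number of clusters is chosen by fitting each candidate $k$ on random
80% subsets, recording BIC and the mean silhouette (Euclidean distance on
conditional-expectation-completed data, hard assignments), and applying a
compound rule: start from the silhouette optimum and, while the BIC optimum
is larger, step upward until a one-sided Welch test on the replicate
silhouettes detects a significant decrease ($\alpha = 0.05$, a declared
quantification of "significantly decrease") or the BIC optimum is reached.
Silhouette alone is conservative and BIC alone anticonservative on these
panels; the rule splits the difference reproducibly.

Arbitrary allele coding can split one biological cluster into two
sign-mirrored ones. Candidate mirror pairs
($\mu_a \approx -\mu_b$ within half the mean norm) are detected and
reported (`detect_mirror_clusters()`), never merged automatically.

# Cluster profiles

With standardized effects $\hat\beta = z/\sqrt{N}$, the cross-product of
two traits' effects at a null SNP has expectation $n_s\rho_Y/(n_1 n_2)$
under sample overlap, so the per-SNP contribution to a cluster's genetic
covariance is corrected as
$X_j = \hat\beta_{j1}\hat\beta_{j2} - n_s\rho_Y/(n_1 n_2)$, the cluster
estimate being $\bar X$ over its LD-thinned SNPs with a two-sided t-test.
The genetic correlation divides by per-trait variances corrected the same
way, $v_\ell = \overline{\hat\beta_\ell^2 - 1/n_\ell}$ (since
$E[\hat\beta^2] = \beta^2 + 1/n$ under the same model), reported missing if
a corrected variance is non-positive. Bonferroni correction is applied
across clusters × trait pairs. The verification engine confirms the
corrected estimator is less biased than the naive one, lands within two
Monte-Carlo standard errors of the design value, and that the t-test holds
its 5% level on null clusters.

Cluster direction summaries use a PC1 made free of allele-coding
arbitrariness by averaging over 20 random per-SNP sign shuffles (each PC1
sign-aligned to the first replicate); profiles are then sign-aligned to
that PC1, and concordance with an external disease's Z-scores is assessed
by an exact two-sided binomial sign test (two-sided as the neutral default;
the direction is reported alongside). Per-SNP variance explained uses
$z^2/n$, the squared standardized effect.

# What the simulation engine does and does not emulate

The generators produce: null Z panels with arbitrary $\Sigma_r$; causal
panels $Z = Z_g + Z_{res}$ under five effect scenarios (per-trait uniform
$[-6, 6]$ effects; correlated normal effects; effects along one direction
blurred with unit noise; independent high-heritability traits, SD 4; a
single high-heritability trait, SD 4 — the "high" scale is a free parameter
where no canonical value exists, and the residual correlation can be drawn
at random or aligned as $0.4\rho_g + 0.6E$ projected back to a correlation
matrix); LD-score panels whose covariance follows the polygenic regression
model with a causal fraction; blockwise-LD null panels; mixture-distributed
profile panels with MCAR missingness; individual-level binomial genotypes
with correlated (optionally non-normal) phenotypes; heterogeneous-overlap
panels; and null logistic GWAS. Random correlation matrices come from an
onion-method sampler, uniform over the space of valid correlation matrices.

Not emulated: LD-aware genotype simulation (predictors are independent;
LD lives only in the block-LD Z panels), genomic-control-deflated input
GWAS, non-MCAR missingness (real missingness tracks genotyping arrays),
indels and multi-allelic records (rejected at parse time), and
ancestry-mismatched LD references. Passing tests therefore certify the
statistical machinery under the stated models, not robustness to those
real-data complications.

# Verification problem sizes

The acceptance studies run at: $10^5$ SNPs for calibration (K = 5 and 20)
and for the estimator-contamination study; $10^4$ fuzzed pairs for the
eigen identity; 5,000 individuals × 2,000 SNPs × 5 traits for the MANOVA
equivalence; $5\times10^4$ SNPs for misspecification inflation; 500 causal
SNPs × 50 replicates × 10 traits for the power ordering; 200 LD blocks of
100 SNPs for imputation; 20 seeds × 2,000 SNPs (20% missing, candidate
$k \in 2..5$, 5 bootstrap replicates) for mixture recovery; 300 estimation
and 1,000 calibration replicates for the cluster covariance; and
$N = 20{,}000$ for the sample-size proxy. These sizes give Monte-Carlo
error comfortably below every decision margin used.

# Known limitations

* The ICA weighting needs a mostly complete Z matrix (≤ 20% missing after
  imputation) and its component selection is only as good as the novelty
  count driving it.
* LD is modeled blockwise; long-range LD across block boundaries is
  ignored everywhere (imputation, clumping, QC).
* The LDSC weights are $1/\ell$, adequate at these scales but not the
  variance-optimal weighting; jackknife intervals should be consulted.
* The mixture model assumes SNPs belong to exactly one cluster; posterior
  probabilities are exposed for soft interpretations, but overlapping
  memberships are not modeled.
* With natural-log entropy and the default 0.75 threshold, 2-cluster
  models are never filtered (see above).
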