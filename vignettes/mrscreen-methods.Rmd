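---
title: "Methods: two-sample MR screening of metabolite panels"
author: "mrscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR screening of metabolite panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrscreen)
```

## The causal model

mrscreen estimates the causal effect of each exposure in a panel (typically
blood metabolites) on a binary outcome from two independent GWAS: one for the
exposure, one for the outcome. For SNP $j$, let $\gamma_j$ be the true
per-allele effect on the exposure and $\Gamma_j$ the per-allele log-odds
effect on the outcome. Under the instrumental-variable assumptions —
(1) the SNP is robustly associated with the exposure, (2) it is independent
of exposure–outcome confounders, and (3) it affects the outcome only through
the exposure — each SNP supplies a Wald ratio estimate
$\hat\beta_j = \hat\Gamma_j / \hat\gamma_j$ of the causal log-odds effect
$\theta$, and the inverse-variance-weighted (IVW) estimator pools them with
first-order weights $w_j = \hat\gamma_j^2 / \mathrm{se}(\hat\Gamma_j)^2$.
IVW is exactly weighted least squares of $\hat\Gamma$ on $\hat\gamma$
through the origin, which the test suite checks against `lm()` to $10^{-10}$.

Violations of assumption (3) — horizontal pleiotropy, a direct SNP→outcome
effect $\alpha_j$ — are the screening pipeline's central concern. The four
ancillary estimators trade efficiency for robustness to different violation
patterns:

* **MR-Egger**: weighted regression with a free intercept; the slope is
  consistent under InSIDE (pleiotropy independent of instrument strength) and
  the intercept estimates the mean directional pleiotropy. Instruments are
  oriented to $\hat\gamma_j \ge 0$ first, and standard errors use the
  estimated residual dispersion floored at 1 (multiplicative random effects
  that never claim less than fixed-effect precision). Because of that floor,
  an exactly affine configuration yields the exact intercept but not a
  vanishing p-value; p-values are two-sided t with $n-2$ df.
* **Weighted median**: the weighted 50th percentile of the ratios (linear
  interpolation across cumulative-weight midpoints); consistent while valid
  instruments hold more than half the weight.
* **Simple and weighted mode**: the kernel-density mode of the ratios
  (normal kernel, bandwidth $\phi \times$ a modified Silverman rule with a
  fallback from MAD to SD when the ratios cluster); consistent when the
  largest group of instruments sharing one ratio value is valid.

Median and mode standard errors come from a parametric bootstrap (each ratio
resampled from its normal sampling distribution), with an explicit seed —
no function touches the global RNG state without restoring it.

## The screening pipeline

`run_screen()` executes, in order: per-exposure instrument selection →
harmonization → all five estimators → sensitivity diagnostics →
Benjamini–Hochberg tiering over the panel → confounder-exclusion rerun of
the non-null exposures → replication in a second outcome cohort → direction
consistency and fixed-effect meta-analysis → cross-trait LD score regression
on candidates → reverse MR on candidates → pathway over-representation. The
run log records this stage order, and a test asserts it.

**Instrument selection** applies four stages in a fixed order, each drop
logged with exactly one (first-failing) reason: exposure association
p < 1e-5; greedy LD clumping at $r^2 \le 0.01$ within 100 kb (best p first;
ties broken by position then SNP id, a rule the source conventions leave
open but determinism requires); per-SNP F ≥ 10; annotation-based confounder
exclusion (case-insensitive trait-label match, emulating a PhenoScanner-style
lookup from a local table). Exposures retaining fewer than 3 instruments are
marked excluded from analysis. Variance explained uses
$R^2 = 2\,\mathrm{MAF}(1-\mathrm{MAF})\beta_{std}^2$ and
$F = R^2 (N - 1 - K)/((1 - R^2) K)$ with $K = 1$ per SNP. The published
rendering of the $R^2$ formula conflates the allele effect and its standard
deviation; we read it as the standard variance-explained formula with
$\beta$ on the standardized-trait scale ($\beta_{std} = \beta/\mathrm{SD}$
when a trait SD is supplied) and otherwise fall back to the z-score
approximation $R^2 = F_0/(F_0 + N - 2)$, $F_0 = (\beta/\mathrm{se})^2$;
both paths are logged and agree closely for strong instruments.

**Harmonization** aligns the outcome to the exposure's effect allele:
swapped labels negate the outcome beta and reflect its allele frequency,
strand complements are complemented first, and palindromic (A/T, C/G) SNPs
are kept only when both allele frequencies fall outside 0.5 ± 0.08 and imply
the same orientation — otherwise dropped, the conservative default since the
original analysis' handling is unstated. Matching is by rsID; the two real
repositories share an rsID namespace, and position matching is out of scope.

**Sensitivity diagnostics** are Cochran's Q (first-order weights, chi-square
upper tail, heterogeneity flagged at p < 0.05), the Egger intercept t-test,
MR-PRESSO, and leave-one-out IVW. MR-PRESSO is restated operationally, since
the citation gives no algorithmic detail: the observed statistic is the
weighted residual sum of squares around leave-one-out IVW predictions; its
null distribution is simulated parametrically (exposure effects from
$N(\hat\gamma_j, \mathrm{se}_j)$, outcome effects from
$N(\hat\theta_{-j}\,\gamma^{\ast}_j, \mathrm{se}_j)$); per-SNP contributions
give Bonferroni-corrected outlier p-values at $\alpha = 0.05$; the
distortion test compares the outlier-removed estimate against random
same-size removals; empirical p-values are floored at $1/(n_{sim}+1)$.
Simulation counts (1000 by default) and thresholds are recorded assumptions,
and the implementation is validated by calibration (null p-values uniform
within the DKW band) rather than against a reference implementation.

**Aggregation** applies step-up Benjamini–Hochberg over the primary IVW
p-values of every analyzed exposure (the FDR family is the panel surviving
selection). Tiers: *significant* if FDR < 0.05, *suggestive* if FDR ≥ 0.05
but p < 0.05, else *null*. Replication is gate-kept rather than re-FDR'd: a
candidate must be non-null, direction-consistent with the replication
estimate (same nonzero sign), and significant in the fixed-effect
inverse-variance meta-analysis of the two cohorts. With two strata the
fixed-effect model is the natural default; DerSimonian–Laird is out of scope
here. After tiering, non-null exposures are re-screened with the confounder
annotation table applied and the panel re-tiered — mirroring the post-hoc
confounder audit of the original workflow.

**LD score regression (simplified)** guards candidates against shared
genetic architecture: per-trait heritability slopes from regressing $z^2$ on
the LD score, co-heritability from $z_1 z_2$, genetic correlation
$r_g = \widehat{\mathrm{cov}}_g / \sqrt{\hat h_1^2 \hat h_2^2}$ soft-clipped
to $[-1, 1]$, with a delete-one-block jackknife (20 contiguous blocks;
remainder SNPs join the last block) for the standard error. There is no
reference-panel download, no heteroskedasticity weighting, and intercepts
are unconstrained and reported; non-positive heritability slopes flag the
estimate as undefined, as real LDSC does. This is calibration-grade: the
pipeline uses it as a yes/no co-inheritance check, not for publication-grade
$h^2$.

**Reverse MR** swaps the roles, selecting disease instruments at the
genome-wide 5e-8 threshold (stricter than the metabolite threshold because
disease GWAS conventionally use it; separately configurable). A rare
outcome, such as a 234-case cohort, typically has no genome-wide hits: the
pair is then flagged `reverse_untestable` rather than failing — which is
the expected, honest result in the demo.

**Pathway over-representation** is a hypergeometric upper-tail test of the
nominally associated metabolites (raw p < 0.05, the set the original
workflow fed to pathway analysis) against a local pathway membership table,
with the analyzed panel as the universe; it equals the one-sided Fisher
exact test, which the suite checks to $10^{-12}$. The hosted pathway-library
version behind the original printed pathway p-value is unidentifiable, so
the library ships as an editable TSV and no attempt is made to reproduce
that exact number.

## The synthetic GWAS generator

Every stage is testable without downloads because `simulate_gwas_panel()`
generates two-sample summary statistics with known ground truth:

* Minor-allele frequencies uniform on [0.05, 0.5]; standardized-trait
  standard errors $1/\sqrt{2p(1-p)N}$; p-values from the normal
  approximation.
* True exposure effects $\gamma_j = |N(0, \sigma_\gamma)|$ — half-normal,
  i.e. effect alleles aligned to the exposure-increasing allele. This is the
  frame in which directional pleiotropy is defined: MR-Egger orients
  instruments to $\hat\gamma_j \ge 0$, and with sign-symmetric effects that
  orientation would flip half the direct effects, silently converting any
  directional scenario into a balanced one. $\sigma_\gamma$ defaults to the
  value making the median per-SNP F ≈ 30 at the exposure sample size (the
  half-normal preserves the $\chi^2_1$ magnitude law used in that
  calibration).
* Outcome associations simulated directly on the log-odds summary-statistic
  scale, $\hat\Gamma_j = \theta\gamma_j + \alpha_j + \epsilon_j$, rather
  than via individual-level case–control sampling — the pipeline only ever
  touches summary statistics, and this keeps full calibration runs in
  seconds. $\alpha_j$ is zero for valid instruments and
  $N(\mu_\alpha, \sigma_\alpha)$ for the invalid fraction (balanced:
  $\mu_\alpha = 0$; directional: $\mu_\alpha \ne 0$); InSIDE holds by
  construction. Distinct cohort labels give independent noise with the same
  expectations, providing a replication cohort.
* Defaults emulate the study conditions: exposure GWAS of 7,824 individuals;
  outcome cohorts entered via the case-control effective sample size
  $4/(1/\mathrm{cases}+1/\mathrm{controls})$ — 935.1 for a 234/265,626
  cohort and 395.9 for a 99/456,249 cohort.
* LD is block-diagonal AR(1): $r^2 = \rho^{2|i-j|}$ within blocks, LD scores
  are row sums, and blocks sit 1 Mb apart so the clumping window and the LD
  blocks agree.

What the generator does **not** emulate: genotype-level sampling noise and
case-control ascertainment, allele-frequency mismatch between cohorts,
strand errors and palindromic ambiguity (synthetic panels use non-palindromic
alleles; harmonization corner cases are built explicitly in tests), sample
overlap between exposure and outcome GWAS, and population stratification.
Passing tests therefore validate the estimators and pipeline logic under the
stated model, not robustness to those real-data pathologies.

## Problem sizes and numerical choices

The suite's simulation studies use: 1000 null replicates for IVW type-I
error (observed within [0.035, 0.065]; the multiplicative random-effects
default is slightly conservative because its dispersion floor only ever
widens intervals); 500 replicates for Egger intercept calibration under
balanced pleiotropy; 200 replicates for recovery at $\theta = 0.3$ (mean
IVW bias below 0.02); 500 replicates for MR-PRESSO null calibration
(uniformity within the DKW 95% band, plus the 1/(n+1) discreteness step);
100 replicates per setting for LDSC recovery at $r_g \in \{0, 0.5\}$ on
2000-SNP panels with 20 jackknife blocks; and a 50-exposure demo screen
with 3 planted causal metabolites at $\theta = 0.5$.

The contamination-robustness scenario (40% invalid instruments with
directional pleiotropy, where the weighted median stays near $\theta$ while
IVW is visibly biased) is defined at a biobank-scale outcome (effective
n = 200,000) with strong instruments (median F ≈ 100). This is a property
of estimator geometry: the median can only resist contamination when the
valid and invalid ratio clusters are separated relative to per-SNP ratio
noise. At a rare-disease cohort scale (effective n ≈ 936) that noise is
roughly 0.4 per SNP — larger than the separation — and no estimator can
recover $\theta$ to 0.05 there; the scenario conditions follow from that
separation argument.

Other numerical decisions: 1.96 for 95% intervals (normal quantile,
matching the odds-ratio reporting convention); p-values floored at the
smallest positive double so they stay in (0, 1]; Wald-ratio standard errors
include the exposure-uncertainty delta-method term for single-SNP use but
IVW uses conventional first-order weights (which is what makes it equal
origin-WLS); kernel-mode bandwidth falls back from MAD to SD to a degenerate
point mass as ratio spread collapses; clumping distance is $|\Delta pos|
\le 100{,}000$ bp on the same chromosome; genome positions are treated as
build-consistent across cohorts (neither source states its build); and a
"Fixed-effects Direction" LD step named in the source methods has no
definition or citation anywhere we could find, so it is deliberately not
implemented.

## Worked example

```{r example}
truth <- simulation_truth(theta = 0.3, seed = 7)
panel <- simulate_gwas_panel(truth)
insts <- harmonize(panel$exposure, panel$outcomes$primary)$instruments
run_all_methods(insts, seed = 1, n_boot = 200)[,
  c("method", "n_snp", "beta", "se", "pvalue", "or_value")]
```

A full screen with all stages, written to disk:

```{r screen, eval = FALSE}
res <- run_screen(pipeline_config(mode = "demo", seed = 42),
                  out_dir = "mrscreen_demo")
subset(res$panel, candidate,
       select = c(exposure_id, or_value, pvalue, fdr_value, tier,
                  pvalue_meta, true_theta))
```

## Known limitations

Single-pass MR-PRESSO (no iterative outlier re-detection); no multivariable
MR, Steiger filtering, winner's-curse correction, or contamination-mixture
estimators; LDSC without reference-panel weights is not comparable to
published $h^2$ estimates; reverse MR shares the forward pipeline's
assumptions and is only as good as the disease GWAS's instrument supply;
and the synthetic generator's omissions listed above bound what the green
test suite demonstrates about real data.
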