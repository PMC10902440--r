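---
title: "Models and methods behind mrpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
```

mrpipe implements two-sample Mendelian randomization (MR) from GWAS
summary statistics: genetic variants robustly associated with an exposure
(gut-microbiome taxon abundances and serum metabolite levels are the
motivating use case) serve as instrumental variables for estimating the
causal effect of that exposure on a binary disease outcome such as
psoriatic arthritis. This vignette describes the statistical models, the
package's default parameters and why they hold their values, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices a maintainer should know about.

## The causal model and its assumptions

For SNP $j$, let $\hat\gamma_j$ (SE $\sigma_{Xj}$) be its estimated
per-allele effect on the exposure and $\hat\Gamma_j$ (SE $\sigma_{Yj}$)
its estimated effect on the outcome, on the log-odds scale, from two
non-overlapping GWAS. If SNP $j$ is a valid instrument — associated with
the exposure, independent of confounders, and affecting the outcome only
through the exposure — then $\Gamma_j = \theta\,\gamma_j$ where $\theta$
is the causal log odds ratio per SD of exposure, and the per-SNP Wald
ratio $\hat\Gamma_j/\hat\gamma_j$ estimates $\theta$.

The five estimators combine Wald ratios with different robustness
trade-offs:

* **IVW** — weighted mean of ratios with weights
  $w_j = \hat\gamma_j^2/\sigma_{Yj}^2$, equivalent to weighted regression
  of $\hat\Gamma$ on $\hat\gamma$ through the origin. Efficient when all
  instruments are valid; biased by any net directional pleiotropy.
  Heterogeneity is measured by Cochran's
  $Q = \sum_j w_j (r_j - \hat\theta)^2$ with $k-1$ df.
* **MR-Egger** — the same regression with a free intercept, after
  orienting all $\hat\gamma_j \ge 0$. The intercept estimates the average
  direct effect (the pleiotropy test); the slope is consistent under the
  InSIDE assumption (instrument strength independent of direct effects)
  even when every instrument is invalid, at a substantial cost in power.
* **Weighted median** — the weighted 50% quantile of ratios
  (cumulative-weight midpoint interpolation); consistent while valid
  instruments carry more than half the weight.
* **Weighted and simple mode** — the maximizer of a normal-kernel
  smoothed density of ratios (inverse-variance or uniform weights);
  consistent when the largest cluster of instruments is valid.

Inconsistencies among methods are resolved in favour of IVW, which is the
estimate the pipeline carries into FDR correction and reporting.

## The analysis cascade and its parameters

`run_pipeline()` strings the stages together per exposure. The defaults,
all overridable in `pipeline_config()`:

| parameter | default | rationale |
|---|---|---|
| instrument p-threshold | 1e-5 | locus-wide threshold conventional for microbiome/metabolite GWAS, where genome-wide significant hits are too few to instrument most taxa |
| clumping | r² 0.001 / 10,000 kb | near-independence of retained instruments; supplied LD tags or pair tables stand in for reference-panel LD |
| MAF filter | 0.01 | removes rare variants with unstable effect estimates |
| F-statistic gate | ≥ 10 | conventional weak-instrument bound; `F = (R²/(1−R²))·((N−K−1)/K)` |
| variance-explained gate | ≥ 0.5% | excludes exposures too weakly instrumented for meaningful inference |
| instrument-count gate | ≥ 3 | minimum for sensitivity analyses and for the relative-bias approximation behind the F gate |
| palindrome band | 0.08 | A/T and C/G SNPs with EAF in (0.42, 0.58) cannot be strand-resolved; band follows common harmonization practice and is configurable |
| test size / FDR | 0.05 | standard |
| reverse-MR threshold | 5e-8 | disease outcomes have well-powered GWAS, so the conventional genome-wide threshold applies to reverse instruments |

Per-SNP variance explained uses the summary-statistic approximation
$r^2_j = \hat\gamma_j^2 2p_j(1-p_j) / (\hat\gamma_j^2 2p_j(1-p_j) +
\sigma_{Xj}^2 2p_j(1-p_j) N)$ (equivalently $F_j/(F_j+N-2)$); a
standardized-trait alternative $2p(1-p)\hat\gamma^2$ is available.
Statistical power for a binary outcome uses the normal-approximation
non-centrality $\lambda = N r^2 \log(\mathrm{OR})^2\,\phi(1-\phi)$ with
case fraction $\phi$; because closed-form power approximations deserve
suspicion, the test suite validates it against a Monte-Carlo
rejection-rate oracle (agreement within 0.05 at a representative design).

Duplicate SNPs keep the record with the smallest exposure p-value.
Proxy substitution is a lookup in a user-supplied two-column table of
pre-computed LD proxies (r² > 0.8); the package never computes LD from
genotypes.

## Sensitivity machinery

**MR-PRESSO.** The observed statistic is the sum of leave-one-out
weighted squared residuals about the IVW fit. Outcome betas are redrawn
from $N(\hat\theta_{(-j)}\hat\gamma_j, \sigma_{Yj})$ `n_sim` times
(default 1000) and the global p is the add-one rank of the observed
statistic, so the smallest attainable p is $1/(n_\text{sim}+1)$ and an
exact-fit dataset returns p = 1. Per-SNP outlier p-values are Bonferroni
corrected across SNPs. Because the observed leave-one-out fits of clean
SNPs are contaminated by any true outlier while the simulated ones are
not, neighbours of a gross outlier are co-flagged somewhat above the
nominal family-wise rate (measured ~12% at 20 SNPs with a 10-SE
outlier); the planted outlier itself is flagged essentially always. The
distortion test (change in slope after outlier removal, compared against
removing equally many random clean SNPs) is reported as informational,
and outlier-corrected estimates are reported alongside, never silently
substituted.

**Steiger directionality.** The instruments' summed variance explained in
exposure versus outcome decides the causal orientation; the p-value is an
asymptotic two-sample z-test on Fisher-z-transformed $\sqrt{r^2}$
(non-overlapping cohorts; overlap correction is out of scope). Per-SNP
Steiger filtering is offered in addition to the whole-set test.

**Multivariable MR.** Weighted least squares of outcome betas on the
matrix of exposure betas without intercept, over the instrument union;
every exposure's beta must be observed at every SNP (missing values are
an error — imputation is out of scope; the synthetic panel generator
guarantees completeness). Entry into the pipeline's MVMR stage requires
forward FDR < 0.05, mirroring the candidate-set logic of a two-stage
screen. The same PRESSO machinery applies to the multivariable fit.

**Meta-analysis.** Replication cohorts are pooled on the log-OR scale
with fixed-effect weights $1/\mathrm{se}^2$ or DerSimonian–Laird
random-effects weights $1/(\mathrm{se}^2+\hat\tau^2)$,
$\hat\tau^2 = \max(0, (Q-\mathrm{df})/C)$. Published tables print OR and
95% CI but no SE, so `ci_to_se()` recovers
$\mathrm{se} = (\log \mathrm{CI_{hi}} - \log \mathrm{CI_{lo}})/(2\cdot1.96)$
and warns when the printed CI is asymmetric on the log scale by more than
10% — a symptom of rounding too coarse to invert reliably, which bounds
the fidelity of any pooling computed from printed values.

**LD-score regression** (deliberately minimal). Heritability is the slope
of $\chi^2$ on $N\ell/M$; genetic covariance the slope of $z_1 z_2$ on
$\sqrt{N_1 N_2}\,\ell/M$; $r_g$ is the ratio, clipped to $[-1.25, 1.25]$
with a flag outside $[-1,1]$. Unit regression weights by default and no
sample-overlap intercept — documented divergences from production
LD-score software, adequate for the synthetic-recovery validation this
module is scoped to. Standard errors are a 200-block delete-one
jackknife of the full functional.

**Pathway over-representation.** One-sided upper-tail hypergeometric
$P(X \ge k)$ for $k$ hit compounds in a pathway of size $S$ drawn from a
background universe (default: the full library universe), with Holm and
Benjamini–Hochberg adjustments across pathways. No topology scores and
no compound-ID resolution; names are opaque strings.

## The synthetic-data generator

`simulate_pair()` draws LD-free SNPs with MAF uniform on (0.05, 0.5),
per-allele exposure effects rescaled so the planted variance explained is
hit exactly, observed betas with
$\sigma_{Xj} = 1/\sqrt{2p_j(1-p_j)N_X}$, and binary-outcome betas around
$\theta\gamma_j + \alpha_j$ with the logistic approximation
$\sigma_{Yj} = 1/\sqrt{2p_j(1-p_j)N_Y\phi(1-\phi)}$. The defaults are the
study conditions the package targets: exposure n = 18,340 (a
microbiome-consortium scale), outcome n = 347,125 with 8,075 cases (a
national-biobank psoriatic-arthritis scale, case fraction 2.3%), 200
candidate instruments, and total variance explained 1.5% — the value
implied by a median instrument F near 21 with ~13 instruments at that
exposure sample size.

Direct (pleiotropic) effects $\alpha_j$ are drawn for a configurable
fraction of SNPs and oriented relative to the exposure-increasing allele,
so a non-zero mean is *directional* after the conventional MR
re-orientation of instruments (with symmetric allele coding, a constant
added to raw outcome effects would cancel in ratio space and bias
nothing). A correlation knob ties $\alpha$ to instrument strength to
violate InSIDE on demand. Generated variants are strand-unambiguous by
construction; palindromic behaviour is exercised through hand-built
fixtures instead. What the generator does **not** emulate: real LD
(clumping is exercised via explicit cluster tags), population
stratification, sample overlap between the two GWAS, winner's-curse
selection of instruments, and allele-frequency differences between
cohorts. Passing tests therefore demonstrate correctness of the
estimators and pipeline logic under the stated sampling model, not
robustness to those real-data pathologies.

`simulate_panel()` extends this to multiple exposures over one SNP panel
(block-diagonal true effects, complete observed beta matrices) for MVMR
and pipeline tests; `simulate_ld_scores()` draws z-scores with the exact
LD-score-regression moment structure; `simulate_pathway_library()`
samples pathway memberships without replacement.

## Validation design and problem sizes

The test suite separates *calibration* from *recovery*. Calibration
(type-I error of the IVW test in [0.03, 0.07]; Egger-intercept rejection
near 0.05 under balanced pleiotropy) runs at the study-condition
defaults over 1000 replicates of 200 SNPs, since test size is unaffected
by instrument strength. Recovery (all five estimators' mean within 3
Monte-Carlo SEs of a planted θ = 0.5 over 500 replicates of 100 SNPs;
MVMR recovering (0.5, 0) over 300 panels) uses a strong-instrument
validation configuration — exposure n = 5×10⁵ with 5% variance explained,
per-SNP F ≈ 250 — because consistency is a strong-instrument property:
at the microbiome-scale defaults (per-SNP F ≈ 2–3) two-sample estimators
are attenuated by weak-instrument regression dilution toward the null by
design, and a recovery test there would measure that dilution, not
implementation correctness.

Under 30% one-sided gross contamination the weighted median carries a
deterministic trimming bias — the weighted mixture median sits at the
0.5/0.7 quantile of the valid ratios, roughly 2.7 bootstrap SEs at 50
SNPs in the large-displacement limit — so robustness is validated
comparatively: the weighted median stays within 2 bootstrap SEs of the
truth in most panels with median absolute error below half of IVW's,
while fixed-effect IVW essentially never covers. Other stochastic checks:
planted MR-PRESSO outliers at 10 SE detected in ≥ 90% of 50 panels and
null global p uniform by Kolmogorov–Smirnov over 500 panels of 20 SNPs
with 1000 simulations each; Steiger direction correct in ≥ 95% of 200
forward panels; LD-score recovery of (h² = 0.2, r_g = 0.5) within 2
jackknife SEs at 50,000 SNPs. Exact checks (hypergeometric tails up to
background 60, BH-FDR, DL τ², the F formula) compare against brute-force
enumerations or independent transcriptions. `scripts/acceptance.R`
recomputes all of these from scratch under a caller-supplied seed.

## Numerical choices, tie-breaks and degenerate inputs

* Random-effects IVW uses the *multiplicative* over-dispersion model
  (SE inflated by $\max(1, \sqrt{Q/\mathrm{df}})$); the additive variant
  is not implemented, but the `model` argument isolates the choice.
  `model = "auto"` selects random effects when the Q p-value < 0.05.
* Weighted-median interpolation follows the cumulative-weight midpoint
  convention; ties break at the first crossing; a single dominant weight
  returns that ratio.
* Mode bandwidth is the modified Silverman rule
  $0.9\min(\mathrm{sd},\mathrm{mad})\,k^{-1/5}$ scaled by
  `bandwidth_factor`; when sd or mad is zero (point-mass ratios) the
  highest-weight ratio is returned directly. The kernel maximizer is read
  off a 1024-point density grid.
* Bootstrap SEs for median/mode are parametric (betas redrawn from their
  sampling distributions), `n_boot` configurable, `n_boot = 0` giving
  point estimates only; all seeds flow from a single integer through a
  hash-based splitter, so results are independent of exposure ordering
  and bit-reproducible.
* Single-SNP sets: `mr_ivw(model = "fixed")` relaxes its precondition and
  degenerates to the Wald ratio; one-study meta-analysis returns the
  study with a warning; `k = 0` instrument selection returns an empty
  result with a complete filter report, not an error.
* Monomorphic SNPs (EAF 0 or 1) get r² = 0 with a warning; an exact
  variance tie in the Steiger test returns p = 1 and direction FALSE.
* Harmonization drops what it cannot reconcile rather than guessing, and
  every drop carries a reason code; `exclusions()` exposes the log.

## Known limitations

Clumping and proxy lookup require user-supplied LD information; there is
no reference-panel computation. The LDSC module is didactic and is never
claimed to reproduce production LD-score estimates on real data. Pooling
from printed OR/CI pairs inherits the print's rounding: a replication
cohort printed as 0.01 (0.01, 0.72) cannot be inverted to a meaningful
log-OR standard error, and `ci_to_se()`'s asymmetry warning flags exactly
this. Binary-outcome SEs use the logistic approximation, adequate at
biobank case counts but optimistic for very rare outcomes. No correction
for sample overlap, winner's curse, or population stratification is
attempted anywhere.
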