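---
title: "Methods: two-sample Mendelian randomization with mrflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization with mrflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrflow)
library(dplyr)
```

## The estimation problem

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure on an outcome using genetic variants as instrumental variables, with
association summary statistics drawn from two non-overlapping GWAS. For each
candidate SNP $j$ we observe the exposure association $\hat\gamma_j$ with
standard error $\sigma_{\gamma j}$ and the outcome association $\hat\Gamma_j$
with standard error $\sigma_{\Gamma j}$ (log-odds scale for binary traits).
Under the instrumental-variable assumptions — the SNP is associated with the
exposure, independent of confounders, and affects the outcome only through the
exposure — each instrument supplies a Wald ratio
$\hat\beta_j = \hat\Gamma_j / \hat\gamma_j$ estimating the same causal effect
$\beta$.

`mrflow` was designed around psychiatric-epidemiology applications of this
design, in particular bidirectional analyses between mental disorders (such as
anorexia nervosa) and sepsis, where the headline effect sizes sit near an odds
ratio of 1.08 ($\beta \approx 0.077$) and where inference leans heavily on the
downstream sensitivity battery. Nothing in the implementation is specific to
those traits.

## Instrument selection

Instruments pass a cascade in the conventional order:

1. **Association threshold.** `pval < p_threshold`, with 5e-8 the default and
   5e-6 / 1e-5 the relaxed settings commonly used when a trait yields few
   genome-wide-significant, independent hits.
2. **Greedy LD clumping.** Candidates are ranked by p-value (ties broken by
   chromosome, position, then SNP id, so results cannot depend on row order or
   platform sort stability). The best remaining SNP is retained and every
   unselected SNP on the same chromosome within `clump_kb` kilobases (default
   10,000) with $r^2 \ge$ `clump_r2` (default 0.001) against it is discarded.
   The LD matrix is an explicit input; no reference-panel lookup or proxy
   search is attempted.
3. **Instrument strength.** $F_j = \hat\gamma_j^2/\sigma_{\gamma j}^2$ must
   reach 10 (boundary inclusive); weaker instruments amplify regression
   dilution.
4. **Outcome-association exclusion** (optional). Instruments with outcome
   p-value below `outcome_p_exclusion` (default 5e-8; `NA` disables) are
   removed, on the reasoning that a variant with a primary outcome
   association is a poor exposure instrument. One caveat the pipeline makes
   explicit rather than hiding: when the true causal effect is substantial
   and the outcome GWAS very large, *valid* instruments inherit genome-wide
   significant outcome associations and this filter removes exactly the SNPs
   one wants to keep. The filter is therefore configurable, reported in the
   audit trail, and disabled in the package's own large-sample demonstration
   scenarios.

Every stage logs a removal count; the counts always sum to input minus
retained, and each clumped SNP records the index SNP that removed it.

## Harmonization

Exposure and outcome records are matched by SNP id and the outcome record is
re-expressed on the exposure's effect allele: swapped allele labels flip the
sign of $\hat\Gamma_j$ and mirror the effect-allele frequency (EAF); alleles
reported on the opposite strand are complemented before matching. Palindromic
SNPs (A/T, C/G) cannot be strand-resolved from labels, so orientation is
inferred from EAF agreement when both frequencies are informative — outside
$0.5 \pm$ `eaf_ambiguity_band` (default 0.08, i.e. drop when either EAF lies
in [0.42, 0.58]) — and the SNP is dropped otherwise, including when either
EAF is missing. Indel alleles are matched directly or swapped but never
complemented (allele columns are not oriented sequences). Irreconcilable
allele sets are dropped with an explicit action tag; nothing is dropped
silently, and retained plus dropped rows always account for every input
instrument. Harmonizing an already-harmonized pair is a no-op, and all
downstream estimators are invariant to mirrored allele encodings of either
dataset.

## Estimators

All estimators consume the harmonized table. P-values are two-sided; 95%
intervals use the fixed constant 1.959964 so that reports are reproducible to
the byte across numerics libraries.

**IVW.** Weighted least squares of $\hat\Gamma$ on $\hat\gamma$ through the
origin with weights $1/\sigma_{\Gamma j}^2$ — equivalently the
inverse-variance-weighted mean of Wald ratios with first-order weights:

$$\hat\beta_{IVW} = \frac{\sum_j \hat\gamma_j \hat\Gamma_j / \sigma_{\Gamma j}^2}
{\sum_j \hat\gamma_j^2/\sigma_{\Gamma j}^2},\qquad
SE_{fixed} = \Big(\sum_j \hat\gamma_j^2/\sigma_{\Gamma j}^2\Big)^{-1/2}.$$

Heterogeneity is measured by Cochran's
$Q = \sum_j w_j (\hat\beta_j - \hat\beta_{IVW})^2$ with first-order ratio
weights $w_j = \hat\gamma_j^2/\sigma_{\Gamma j}^2$, referred to
$\chi^2_{J-1}$. The random-effects variant inflates the fixed SE
multiplicatively by $\sqrt{\max(Q/(J-1), 1)}$ — an overdispersion model with
the floor guaranteeing the random-effects SE never undercuts the
fixed-effects SE. In `mode = "auto"` the heterogeneity p-value gates the
choice at 0.05: random effects when $p < 0.05$, fixed otherwise, with the
gate decision recorded in `model_note`.

**MR-Egger.** After orienting every SNP to $\hat\gamma_j > 0$, a weighted
regression $\hat\Gamma_j = \beta_0 + \beta\,\hat\gamma_j$ with weights
$1/\sigma_{\Gamma j}^2$. The intercept estimates the mean directional
pleiotropic effect; the slope is the causal estimate under the InSIDE
assumption. Coefficient SEs use the weighted residual dispersion
$\hat\sigma^2 = Q_{egger}/(J-2)$ *without* a floor, and p-values use a t
reference on $J-2$ degrees of freedom. This is the conventional weighted
least-squares treatment; flooring the dispersion at 1 here would make the
intercept test conservative (null rejection near 3% rather than the nominal
5% in our calibration simulations), which matters because the intercept test
is the pleiotropy alarm the workflow relies on.

**Weighted median.** Per-SNP ratios with first-order weights
$w_j = \hat\gamma_j^2/\sigma_{\Gamma j}^2$; the estimate interpolates the
weighted empirical ratio distribution at cumulative standardized weight 0.5,
and is consistent while invalid instruments carry under half the total
weight. The SE comes from a parametric bootstrap (default 1000 replicates)
that resamples $\hat\gamma_j$ and $\hat\Gamma_j$ from normal distributions
centred at the observed values with the reported SEs; the bootstrap seed is a
required input and is recorded in `model_note`. `n_boot = 0` returns the
point estimate alone, which keeps large simulation studies affordable.

**Maximum likelihood.** The bivariate-normal model
$(\hat\gamma_j, \hat\Gamma_j) \sim N\big((g_j, \beta g_j),
\mathrm{diag}(\sigma_{\gamma j}^2, \sigma_{\Gamma j}^2)\big)$ with the true
instrument effects $g_j$ profiled out in closed form, leaving the
one-dimensional objective
$\tfrac12\sum_j (\hat\Gamma_j - \beta\hat\gamma_j)^2 /
(\sigma_{\Gamma j}^2 + \beta^2 \sigma_{\gamma j}^2)$. This is minimized by
Brent search on an interval centred at the IVW estimate with half-width
$\max(1, 100\,SE_{IVW})$; the SE comes from the observed information via a
central second difference with step $10^{-5}(1+|\hat\beta|)$. Non-positive
curvature raises an error rather than returning a bogus SE. In the limit of
exactly measured exposure effects the estimator coincides with IVW, a
property the tests verify numerically.

## Sensitivity battery

Beyond Q and the Egger intercept, `leave_one_out()` recomputes IVW excluding
each SNP in turn (the fixed/random gate re-evaluated per subset and logged),
and `funnel_data()`/`scatter_data()` emit plot-ready tables — ratio versus
precision, and effect pairs with one fitted line per method — leaving
rendering to the `plot_mr_*()` helpers or the caller.

## Multivariable MR and meta-analysis

`mvmr_ivw()` regresses harmonized outcome effects on several exposures'
effect columns jointly (no intercept, weights $1/\sigma_{\Gamma j}^2$),
giving direct effects conditional on the co-exposures; SEs use the same
multiplicative overdispersion floor as random-effects IVW, so the single
exposure case reduces exactly to univariable IVW. Rank-deficient designs
raise a collinearity error naming the offending columns. `mvmr_assemble()`
builds the input table: per-exposure selection, joint re-clumping of the
union using the smallest cross-exposure p-value, alignment of every dataset
to a common reference allele, and complete-case filtering.

`meta_pool()` pools cohort estimates with fixed-effect weights $1/se_k^2$
and DerSimonian–Laird random effects,
$\hat\tau^2 = \max\big(0, (Q-(k-1))/(\sum w_k - \sum w_k^2/\sum w_k)\big)$,
reporting $Q$, $I^2 = \max(0, (Q-(k-1))/Q) \cdot 100$, and both pooled
models; `model = "auto"` mirrors the IVW gate (fixed when the heterogeneity
p exceeds 0.05). OR-with-CI manifests are converted through
$\log$ and $(\ln hi - \ln lo)/(2 \times 1.959964)$.

## Two-step mediation

For a mediator $M$, the exposure→mediator effect $a$ (instrumenting the
exposure), the mediator→outcome effect $b$ (instrumenting the mediator,
default threshold 1e-5), and the total effect $c$ combine into the indirect
effect $ab$ and mediated proportion $ab/c$, with first-order delta-method
SEs:

$$SE_{ab} = \sqrt{a^2 se_b^2 + b^2 se_a^2},\qquad
SE_{prop} = \sqrt{SE_{ab}^2/c^2 + (ab)^2 se_c^2 / c^4}.$$

The total effect is the univariable exposure→outcome IVW, and the
mediator→outcome step is unadjusted for the exposure (two-step, not network
MR); an MVMR-adjusted second step can be run by hand with `mvmr_ivw()`. The
proportion SE treats the indirect and total estimates as independent even
though both derive from partially shared data — a stated approximation of
the delta approach, adequate when the exposure GWAS is large relative to the
effects. The proportion is undefined (an error, not an `NA`) when the total
effect is numerically zero. `mediated_proportion_from_ors()` applies the
same arithmetic to printed odds-ratio triplets,
$\ln(OR_{EM})\ln(OR_{MO})/\ln(OR_{total})$; note that two-decimal OR
rounding limits the reproducibility of published proportions to roughly
$\pm 0.8$ percentage points at these effect sizes. `screen_mediators()`
applies the two-step screen across a panel, retaining mediators with both
step p-values below 0.05 and an indirect effect direction-concordant with
the total; no multiplicity correction is applied by default (matching
raw-p screening practice), with Bonferroni/BH available.

## The synthetic generator

`simulate_two_sample()` realizes exactly the model the estimators assume:
$g_j \sim N(0, \texttt{gamma\_sd}^2)$,
$\hat\gamma_j \sim N(g_j, \sigma_{\gamma j}^2)$,
$\hat\Gamma_j \sim N(\beta\,g_j + \alpha_j, \sigma_{\Gamma j}^2)$, with SEs
from the standard $1/\sqrt{2\,maf(1-maf)\,n}$ approximation and LD emitted
only at the $r^2$ summary level (block-constant matrices; clumping consumes
$r^2$ directly, so no haplotype simulation is needed). Defaults encode the
motivating study conditions: $\beta = 0.077$ (OR 1.08), an exposure GWAS of
72,500 and an outcome GWAS of 462,918.

Pleiotropy models: *balanced* draws $\alpha_j \sim N(0, sd^2)$ on the
invalid fraction; *directional* applies $mean + N(0, sd^2)$ in each SNP's
exposure-increasing orientation, i.e. the effective direct effect is
$\mathrm{sign}(g_j)(mean + \epsilon_j)$. The orientation matters: with
$g_j$ symmetric about zero and $\alpha_j$ independent of $\mathrm{sign}(g_j)$,
a constant-mean $\alpha$ would cancel in the IVW numerator in expectation
and "directional" pleiotropy would bias nothing — whereas a pathway shared
by the exposure-increasing alleles, which is what directional pleiotropy
means after harmonization orients instruments, produces the textbook
hierarchy: IVW biased, weighted median consistent below 50% invalid weight,
Egger intercept powered.

What the generator does **not** emulate — and therefore what passing tests
cannot certify on real data: case-control ascertainment and attenuation in
effective sample size, realistic allele-frequency spectra, cross-dataset
sample overlap, population stratification, and LD beyond block-constant
$r^2$. Instrument-selection effects (winner's curse) *are* reproduced when
you run selection on simulated data, which is why calibration studies below
skip selection and feed all instruments to the estimators.

## Validation study sizes

The packaged acceptance checks run, and the numbers they assert are produced
by, the following simulation designs (chosen once as the package's standard
verification conditions):

- **Null calibration**: $\beta = 0$, $J = 20$, `gamma_sd` 0.15,
  $n_{exp} = 2\times10^5$, $n_{out} = 10^6$, MAF 0.1–0.4, 2000 replicates.
  IVW (auto gate) and Egger-intercept rejection rates are checked against
  5% ± 1%, and the Q sample against $\chi^2_{19}$ at Kolmogorov distance
  0.035.
- **Recovery**: $\beta = 0.077$, $J = 50$, same sample sizes, 500
  replicates, clean and with 30% directional pleiotropy
  (mean 0.02, sd 0.01). These sizes put the mean instrument F in the
  hundreds — the "strong instrument" regime where first-order weights are
  trustworthy.
- **Mediation**: $a = 0.2$, $b = 0.077$, $c_{direct} = 0.0616$ (true
  proportion exactly 0.20), $30+30$ instruments, 2000 replicates; mean
  recovery within 0.02 and delta-method CI coverage within [93%, 97%].

## Numerical and degenerate-input policy

- LD matrices must be symmetric within $10^{-8}$ (then symmetrized exactly),
  with unit diagonal and entries in [0, 1].
- Wald ratios are undefined at $\hat\gamma_j = 0$ (error, not `Inf`).
- A single instrument yields the Wald ratio from IVW with
  `model_note = "fixed-effects (single SNP)"`; Egger and the weighted median
  require 3 SNPs and the full pipeline degrades to IVW/ML with a warning
  below that.
- P-values are clamped into $(0, 1]$; they never underflow to exactly 0.
- Clumping tie-breaks, the fixed 1.959964 quantile, seeded bootstraps, and
  `readr`'s shortest-round-trip numeric formatting together make report
  files byte-identical across repeated runs of one configuration.

## Known limitations

Steiger direction filtering, MR-PRESSO outlier correction, mode-based
estimators, robust/penalized IVW, conditional F-statistics for MVMR, and
proxy-SNP substitution are deliberately out of scope. The LD model is an
explicit input; users clumping against a reference panel must compute the
$r^2$ matrix upstream. Sample overlap between the two GWAS biases estimates
toward the confounded association and is neither detected nor corrected.
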