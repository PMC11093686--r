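---
title: "Methods: two-sample Mendelian randomization of homocysteine on PCOS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization of homocysteine on PCOS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcymr)
```

## The question and the design

Observational studies disagree on whether elevated plasma homocysteine
(Hcy) raises the risk of polycystic ovary syndrome (PCOS); both quantities
are entangled with BMI, insulin resistance and diet, and reverse causation
is plausible. Two-sample Mendelian randomization (MR) sidesteps these
problems by using genetic variants as instrumental variables: alleles are
assigned at conception, so a variant that raises Hcy can only associate
with PCOS through pathways downstream of that assignment. `hcymr`
implements the full workflow on GWAS summary statistics — no individual
genotypes are needed — for one continuous exposure (Hcy, SD units) against
any number of binary-outcome cohorts (PCOS, log-odds units).

The packaged instrument table (`hcy_pcos_table1()`) holds 14 SNPs
associated with plasma Hcy at $p < 5\times10^{-8}$ in a meta-GWAS of
44,147 Europeans, with their PCOS associations in three cohorts: Day et
al. (4,138 cases / 20,129 controls), Tyrmi et al. (3,609 / 229,788) and
FinnGen R7 (994 / 165,817, where three of the SNPs are unavailable and no
proxy at $r^2 > 0.8$ exists). FinnGen R6 contributes to the Tyrmi et al.
sample, so those two cohorts partially overlap; `meta_fixed()` warns about
this and deliberately applies no covariance correction, reporting the
naive pooled estimate with the overlap as a stated caveat.

## Instrument qualification

`select_instruments()` encodes the selection logic against caller-supplied
tables rather than live services: a genome-wide significance filter, an
explicit drop list, removal of variants annotated to secondary traits
(horizontal pleiotropy, e.g. a BMI association), and greedy LD pruning
that walks candidates in order of increasing p-value and keeps a variant
only if its $r^2$ with every already-kept variant is below the threshold
(default 0.05). Ties in p are broken by rsID so the result is
deterministic and order-invariant. The package never downloads reference
panels; the $r^2$ table is an input.

`harmonize()` aligns outcome effects to the exposure's coded allele. With
only one allele recorded per study, a non-complementary allele mismatch is
an unambiguous allele swap (sign flip), while a complementary one (A/T or
C/G pair) cannot be told apart from a strand flip; such
palindromic-ambiguous variants are excluded by default with a warning,
the conservative standard choice. Every removal — missing in outcome,
palindromic, sign-flipped — lands in a reason-coded audit log.

Instrument strength is summarized by $F_j = (\beta_{Xj}/se_{Xj})^2$; all
14 packaged instruments have $F > 30$, far above the conventional weak
instrument bound of 10, which also justifies first-order Wald weights
below.

## Estimators

Per variant, the Wald ratio $\hat\theta_j = \beta_{Yj}/\beta_{Xj}$
estimates the causal effect, with first-order delta-method standard error
$|se_{Yj}/\beta_{Xj}|$ (the second-order form that propagates exposure
uncertainty is available via `second_order = TRUE`; at the packaged F
statistics the difference is negligible).

**IVW.** `mr_ivw()` pools Wald ratios with weights $w_j =
\beta_{Xj}^2/se_{Yj}^2$. The fixed-effect standard error is
$1/\sqrt{\sum w_j}$; the multiplicative random-effects model inflates it
by $\max(1, \sqrt{Q/(J-1)})$ with $Q$ Cochran's heterogeneity statistic,
and never deflates it. The default `model = "auto"` uses multiplicative
random effects from $J \ge 4$ instruments, the behaviour of the standard
reference implementation; on the packaged data this is the uncertainty
model that reproduces all three published confidence intervals (for Tyrmi
et al. $Q < J-1$, so both models coincide). One instrument degenerates
exactly to the Wald ratio.

**MR-Egger.** `mr_egger()` regresses $\beta_{Yj}$ on $\beta_{Xj}$ by
weighted least squares (weights $1/se_{Yj}^2$) with a free intercept,
after orienting exposure betas non-negative so the intercept is
identified. The slope is the pleiotropy-adjusted causal estimate; the
intercept estimates the average directional pleiotropic effect, and its
test is the package's primary pleiotropy diagnostic. Standard errors use
the same truncated multiplicative dispersion $\max(1, \hat\sigma)$, and
p-values use the normal reference by default (Student's t with $J-2$ df
is available; with the truncation it is conservative — in a 2000-replicate
null simulation at $J = 14$ the normal reference rejected at 0.040, the t
reference at 0.024).

**Weighted median.** `mr_weighted_median()` sorts Wald ratios, forms
standardized mid-cumulative weights $s_j = (\sum_{i\le j} w_i -
w_j/2)/\sum w$, and linearly interpolates the ratio at $s = 0.5$; the
estimate is consistent while instruments carrying at least half the
weight are valid. Its SE is a parametric bootstrap (default `n_boot =
10000`, fixed seed): betas are resampled from their sampling
distributions and the SD of the replicated medians reported.

## Diagnostics

**MR-PRESSO** (`mr_presso()`). For each variant the residual from the
leave-one-out IVW prediction is squared and weighted by $1/se_{Yj}^2$;
the global statistic is the sum. The null is simulated parametrically
(default 5,000 draws, fixed seed; empirical p-values use $(r+1)/(n+1)$ so
they are never zero), and each variant's residual is tested against its
own simulated distribution with Bonferroni adjustment at $0.05/J$. A
gross outlier biases the leave-one-out estimates used to test every
*other* variant, which the plain test occasionally converts into false
flags on strong instruments; `mr_presso()` therefore iterates — re-testing
all variants against estimates computed with the flagged set excluded
until the flag set stabilizes. Clean data never enter that loop. In
calibration runs a single variant displaced by 10 outcome SEs among 20 is
recovered exactly (no misses, false-flag runs reduced from ~11% to ~3%),
and under the null the global test rejects at the nominal rate. The
distortion test compares the estimate with and without outliers against a
resampling distribution and is reported only when outliers exist,
otherwise as not applicable.

**Steiger directionality** (`mr_steiger()`). Per variant the explained
variance is approximated from the squared z-score, $r^2_j = F_j/(F_j + N
- 2)$, with the case-control outcome using the effective size
$4/(1/n_\text{cases} + 1/n_\text{controls})$ (overridable). Summed over
instruments, the causal direction exposure → outcome is supported when
the exposure $r^2$ exceeds the outcome $r^2$; the difference is tested
via Fisher's z-transform. Note $r^2_\text{outcome}$ *grows* as the
outcome sample shrinks at fixed F, so on an ascending grid of sample
sizes the direction flag can only switch from FALSE to TRUE — the
monotonicity the tests assert. Steiger output is a reported diagnostic,
not a filter, since every packaged cohort supports the forward direction.
The published per-cohort Steiger p-values cannot be reproduced because
the formula and sample sizes behind them are unstated; only the direction
is checked.

**Leave-one-out** (`mr_leave_one_out()`) refits the IVW estimate omitting
each variant in turn; on the packaged data no single SNP moves any
cohort's estimate across zero in a way that changes the conclusion.

## Meta-analysis

`meta_fixed()` pools per-cohort log-odds estimates with inverse-variance
weights; fixed-effect pooling is the default because it exactly closes
the published arithmetic — pooling standard errors back-computed from the
printed per-cohort confidence intervals reproduces the printed combined
odds ratio and CI to three decimals, which is also an independent oracle
in the test suite. DerSimonian–Laird random effects is available
(`model = "random"`, cross-checked against `metafor::rma`). The pooled
result on the packaged data is OR 1.032 (95% CI 0.885–1.204, p = 0.686):
no evidence that genetically elevated Hcy changes PCOS risk.

## The synthetic-data generator

`simulate_instrument_set()` draws true exposure effects uniformly over
0.04–0.16 in magnitude with random signs, exposure SE 0.008 and outcome
SE 0.035 — calibrated so simulated F statistics span roughly 25–400, the
range of the packaged instruments — and builds outcome effects
$\beta_{Yj} = \theta\,\beta_{Xj} + s_j\alpha_j$, where $s_j$ orients the
direct effect $\alpha_j$ to the exposure-increasing allele (otherwise
random allele coding would average directional pleiotropy to zero).
Regimes: `none`, `balanced` (zero-mean, InSIDE holds), `directional`
(non-zero mean), and `inside_violated` (direct effects proportional to
instrument strength, breaking MR-Egger's key assumption). Planted
outliers displace observed outcome betas by a stated number of SEs.
`replicate_study_trio()` reuses one exposure draw across three outcome
draws with per-study SE scales and availability masks, mimicking the
11-versus-14 SNP asymmetry. Ground truth travels in a `"truth"`
attribute, and generation is bit-reproducible from the seed.

What the generator does *not* emulate: LD between instruments (the pruned
real set is treated as independent, and simulated variants are
independent by construction), sample overlap between the exposure and
outcome studies, winner's curse in instrument discovery, and non-normal
sampling error. Passing calibration tests therefore demonstrate
correctness of the estimators under the assumed two-sample linear IV
model, not robustness to those real-data complications.

## Numerical choices and problem sizes

95% intervals use the normal quantile 1.959964 throughout. Degenerate
inputs fail loudly: zero exposure betas (Wald), fewer than 3 instruments
(Egger, median, leave-one-out), fewer than 4 (PRESSO), constant exposure
betas (Egger design), non-positive SEs anywhere. Test-suite simulation
sizes — 500 replicates for coverage, bias and type-I error, 200 for
PRESSO null calibration, 100 seeds for planted-outlier recovery, 1,000
null draws per PRESSO run — keep the default suite to a couple of minutes
while leaving Monte-Carlo error well inside the asserted binomial bounds;
the analysis scripts use 5,000 PRESSO draws, matching the package
default.

## Known limitations

- The harmonizer works from a single coded allele per study; without the
  non-effect allele it must treat complementary matches as ambiguous
  rather than resolving strand by frequency.
- Fixed-effect pooling ignores the Tyrmi/FinnGen sample overlap (warned,
  not corrected), so the pooled CI is slightly narrower than an
  overlap-aware one would be.
- Steiger's $r^2$ from summary z-scores is an approximation; its p-value
  depends on effective-sample-size conventions for case-control data.
- No mode-based, multivariable or contamination-mixture estimators are
  provided; the workflow covers the estimator set used in the packaged
  analysis.
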