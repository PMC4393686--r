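---
title: "Twin ACE modelling with twinace: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Twin ACE modelling with twinace: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinace)
```

## The model

`twinace` implements the classical twin design for quantitative traits. A
trait measured on both members of monozygotic (MZ) and dizygotic (DZ) twin
pairs is decomposed into additive genetic (A), common/shared environment (C)
and unique environment (E) contributions,

$$ y = a\,A + c\,C + e\,E, $$

where the latent factors are standard normal, $C$ is shared within a pair,
$E$ is independent across twins, and the additive factors of co-twins
correlate 1 for MZ pairs (who share all segregating variants) and 0.5 for DZ
pairs (who share half on average). The implied pair covariance is

$$ \Sigma_{\mathrm{zyg}} = \begin{pmatrix} a^2+c^2+e^2 & \alpha a^2 + c^2 \\
\alpha a^2 + c^2 & a^2+c^2+e^2 \end{pmatrix}, \qquad
\alpha = \begin{cases}1 & \text{MZ}\\ 0.5 & \text{DZ}\end{cases} $$

and the reported quantities are the standardized components
$a^2/(a^2+c^2+e^2)$ etc. (heritability, shared- and unique-environment
proportions).

The bivariate extension is the correlated-factors solution: each of two
traits has its own A/C/E paths, and factor correlations $r_a$, $r_c$, $r_e$
link the traits' factors. The within-person cross-trait covariance is
$a_x a_y r_a + c_x c_y r_c + e_x e_y r_e$; the cross-twin cross-trait
covariance replaces $r_a$'s weight by $\alpha$. From a fitted solution,
`derived_bivariate()` reports the share of the implied phenotypic
correlation routed through each factor — the *bivariate heritability*
$\mathrm{biv}a^2 = a_x a_y r_a / r_{\mathrm{implied}}$ and its C/E
analogues — which is distinct from $r_a$ itself (the overlap of the two
traits' gene sets).

## Likelihood and fitting

All models are fit by full-information maximum likelihood
(`fiml_neg2ll()`): each pair contributes the multivariate-normal
$-2\log L$ of its *observed* subvector under the matching rows and columns
of the zygosity-specific implied covariance, so partially observed pairs
stay in the analysis. Internally the likelihood is accumulated from
per-missingness-pattern sufficient statistics (count, mean, scatter), which
makes an evaluation $O(\text{patterns})$ rather than $O(n)$; the two forms
are algebraically identical and the test suite checks them against a
row-wise density sum.

Parameterization choices:

* **Paths are sign-unconstrained reals**; squared-and-standardized
  components are reported. This avoids boundary pathologies at $c \to 0$
  during optimization. Because jointly negating one trait's path and its
  factor correlation leaves the likelihood unchanged, bivariate solutions
  are canonicalized to non-negative paths with the correlation sign carried
  by the path products.
* **Factor correlations** are optimized through $\tanh$, keeping them
  inside $(-1, 1)$; solutions with $|r| > 0.995$ or a standardized
  component at (numerical) zero are flagged as boundary solutions.
* **Means** in the ACE families are one grand mean per trait, equated
  across twins and zygosities. The saturated reference frees means,
  variances and covariances per zygosity (10 parameters univariately, 28
  bivariately), which reproduces the conventional degree-of-freedom deltas:
  6 (univariate ACE), 17 (bivariate full ACE), 18 (one correlation
  dropped), 20 (AE/CE).
* **Optimization** is quasi-Newton (BFGS) with a relative tolerance of
  1e-12 and multiple starts: the first start is moment-informed (Falconer
  components from double-entry twin correlations; cross-twin cross-trait
  arithmetic for the factor correlations) and the rest are jittered.
  Univariate families default to 8 starts; bivariate families to 4, which
  in every fixture we examined reach the same optimum as 12+ starts while
  keeping the repeated-fit suites fast. Degrees of freedom are observed
  data points minus free parameters.

Model comparison (`compare_models()`) uses the likelihood-ratio test
against the saturated model and the Mx-convention
$\mathrm{BIC} = -2LL - \mathrm{df}\,\ln N$ with $N$ defaulting to the
number of contributing pairs. Only BIC *differences* and orderings are
meaningful under this convention, and `select_best_model()` applies the
rule: lowest BIC among models not rejected by the LRT at $\alpha = .05$,
ties resolved toward fewer parameters.

Confidence intervals (`profile_ci()`) are profile-likelihood intervals: a
bound is where the $-2LL$, re-minimized over all other parameters, rises by
$\chi^2_1(.95) = 3.84$. Standardized components are profiled through a
constrained reparameterization (total variance, the fixed component share,
and a logistic split of the remainder), so bounds respect $[0, 1]$; factor
correlations are profiled directly on $[-1, 1]$. A profile that never
crosses the threshold before the domain edge reports the edge, flagged —
the analogue of printed interval ends like 0.00 or 1.00. Falconer's
closed forms ($a^2 = 2(r_{MZ} - r_{DZ})$, $c^2 = 2r_{DZ} - r_{MZ}$,
$e^2 = 1 - r_{MZ}$) are kept un-truncated and serve as the analytic oracle:
on moment-matched, just-identified data the FIML solution must equal them,
and the tests enforce this to 1e-4.

## Preprocessing

The preprocessing mirrors standard behavioural-genetic practice for
bounded, positively skewed questionnaire scales: item totals
(`score_scale()`, with a conservative any-missing-item rule by default and
an optional prorated alternative), a square-root transform to reduce
skewness and kurtosis, then OLS residualization on sex (male = 1) and age
with standardization of the residuals (`residualize()`). The square root is
applied *before* residualization: residuals are centred and partly
negative, so the reverse order would be ill-defined. Residualization is a
single regression over all persons (both twins stacked); clustering within
pairs affects standard errors of the regression, not the residuals
themselves, and the twin models consume only the residuals. Zygosity-group
mean differences are deliberately not removed — they are reported in the
descriptives instead.

Descriptives reproduce the usual reporting surface: raw-scale means/SDs
overall and by sex and zygosity, skewness and non-excess kurtosis
(Gaussian = 3) of the transformed scores, Cronbach's alpha from item-level
data, and a two-way type-II ANOVA (sex, zygosity, interaction) on one
random member per pair. Twin similarity uses double-entry Pearson
correlations for the intraclass (ICC) and cross-twin cross-trait (CTCT)
correlations; the Fisher-z interval uses the number of *pairs* as the
effective n, since double entry duplicates rather than adds information.
The exact ICC estimator and CI method used in classical reports are rarely
stated; double entry is the conventional choice in twin descriptives and is
configurable in principle, but published two-decimal tables cannot
distinguish it from ANOVA-based variants. Bivariate modelling is gated on
the phenotypic correlation: only exposure–outcome pairs with $r$ strictly
above the threshold (default .25) are modelled.

## The synthetic cohort generator

No individual-level data accompany the analyses this package operationalizes
(twin-register data are not public), so the generator is a first-class
module: every downstream stage is exercised on cohorts whose true structure
is known. `simulate_univariate()` builds the latent trait from explicit
A/C/E factor draws — for DZ pairs the additive factor is
$\sqrt{.5}\,A_{\mathrm{family}} + \sqrt{.5}\,A_{\mathrm{individual}}$,
giving an exact 0.5 cross-twin additive correlation without rejection
sampling — and `simulate_bivariate()` draws the factor pairs jointly with
correlations $r_a, r_c, r_e$, keeping the generator's algebra independent
of the engine's `expected_cov_*` functions so that moment-convergence tests
are genuine cross-checks.

Defaults encode the study conditions the package targets: sample sizes
mirror the published pair counts (1719/1551 MZ/DZ for paranoia-like runs,
1418/1258 for bullying-like runs; `default_study_spec()` carries the
best-fitting published bivariate solution). Small linear sex and age
effects (0.1 SD per sex contrast, 0.05 SD per year over ages 15.5–17.5)
are added so the residualization stage has real signal to remove — the
combined effect is small, matching the reported $R^2$ of .00–.06 for
sex/zygosity on the means. MCAR missingness defaults to 0 for unit-level
fixtures and 0.15 for pipeline fixtures (real attrition is larger, but
informative missingness is out of scope); a pair never loses both of its
values. `apply_raw_scale()` maps latent values monotonically onto bounded
integer ranges with positive skew so the transform path sees realistic
input — the generator is calibrated only to range/skew/kurtosis, not to any
specific item-generating process, and `simulate_items()` provides parallel
equicorrelated items for reliability computations.

What passing tests on these cohorts do *not* show: robustness to
informative missingness, assortative mating, sibling interaction or rater
contrast, selection/ascertainment, sex-limitation structure, or ordinal
measurement — all outside the generative model (and the scope of the
engine).

## The pipeline

`run_pipeline()` executes preprocessing, descriptives, the correlation
gate, the univariate suites, the bivariate suites for gated outcomes, and
covariate-adjusted bivariate refits, logging the n retained at every stage
and writing a deterministic JSON/TSV report (rerunning a configuration
reproduces it byte for byte). Covariate adjustment residualizes both
analysis traits on the covariates and re-standardizes before refitting —
the simplest mechanism consistent with reporting an unchanged model
structure afterwards; modelling covariates inside the SEM means model is a
printed-result-indistinguishable alternative we did not take. If
adjustment removes (nearly) all cross-trait covariance the derived shares
become ratios of vanishing quantities; the suite then flags the result
degenerate rather than reporting unstable numbers.

One behaviour worth knowing: under the package's own default generating
values the implied phenotypic correlation is $\sqrt{.35 \cdot .52}\,.55 +
\sqrt{.39 \cdot .48}\,.04 \approx .252$ — essentially *on* the default gate
threshold of .25. Whether a particular simulated cohort passes the gate is
therefore sample-dependent at realistic n; the pipeline records the gate
decision and proceeds accordingly, and a report with only univariate blocks
is a valid outcome, not an error.

## Numerical choices and problem sizes

Tolerances: optimizer relative tolerance 1e-12 on $-2LL$; nesting
monotonicity asserted to 1e-6; standardized components sum to 1 within
1e-10; profile bounds located by `uniroot` to 1e-6. Ties in model selection
go to the more parsimonious model. Degenerate inputs (all-missing traits,
zero-variance variables, singular selected covariances, non-positive-
semidefinite implied covariances) raise errors naming the offending
field or pattern.

The test suite and the bundled recovery script run simulations at the
published sample sizes; replicate counts (20–120 per condition) were chosen
so that Monte-Carlo standard errors sit well inside the assertion bands.
One estimator property surfaced by these runs is worth recording: the
fitted genetic correlation in the dropped-$r_c$ bivariate model is a ratio
estimator and carries a small positive finite-sample bias (about +0.02 at
the study's sample sizes, with a heavy right tail in replicates where the
sampled exposure heritability is low). This is a property of maximum
likelihood in this parameterization, not of the implementation; the
recovery assertions average over enough replicates that the bias plus
Monte-Carlo noise stays inside their bands.

## Limitations

The engine covers the saturated, ACE/AE/CE/E univariate families and the
correlated-factors bivariate families (full, either correlation dropped,
AE, CE). ADE models, sex-limitation/scalar-sex models, ordinal/threshold
liability models, >2-trait Cholesky decompositions and
direction-of-causation models are out of scope. Absolute BIC values depend
on the $N$ convention and should never be compared across software; only
differences within a comparison table are meaningful. Item-level
psychometrics (IRT) and multiple imputation are not provided; FIML under
MCAR/MAR is the missing-data mechanism.
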