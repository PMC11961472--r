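---
title: "Tailored fit-index cutoffs by simulation and ROC analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tailored fit-index cutoffs by simulation and ROC analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the method

Fixed cutoff conventions for SEM fit indices (CFI ≥ .95, RMSEA ≤ .06,
SRMR ≤ .08, ...) were derived in particular simulation settings and do not
transfer to an arbitrary model, sample size, estimator and response
distribution. `tailorcut` replaces them with cutoffs *tailored* to the
study at hand, cast as a Neyman–Pearson decision between two explicit
hypotheses about the data-generating process:

* **H0**: the population model is (nearly) identical to the analysis model —
  the analysis model is correctly specified;
* **H1**: the population model differs from the analysis model in a way the
  researcher declares *intolerable* — the analysis model is misspecified.

Both population models are covariance structures
$\Sigma = \Lambda \Psi \Lambda^\top + \Theta$ stated by the user (H0 is
typically the fitted analysis model itself). The pipeline:

1. **Simulate and fit.** Draw `n_reps` datasets of size $N$ from each
   population, matched to the study's marginal skewness and excess
   kurtosis, fit the analysis model to every replicate by (robust) maximum
   likelihood, and record χ², CFI, RMSEA and SRMR. This yields each index's
   sampling distribution under correct specification and under the declared
   misspecification.
2. **Rank indices by ROC/AUC.** Treating "misspecified" as the positive
   class and every observed index value as a candidate cutoff, the ROC
   curve traces sensitivity against 1 − specificity; its area (AUC) is the
   probability that a random H1 fit looks worse than a random H0 fit.
   Indices with AUC below a threshold (default .80) are screened out — they
   cannot see this particular misspecification at this $N$.
3. **Generate cutoffs.** For each retained index the cutoff maximizing the
   Youden index (sensitivity + specificity − 1) is reported with its
   accuracy and type I/II error rates.

An empirical model is then **accepted** if its fit-index values pass all
retained cutoffs, **rejected** if they fail all of them; when indices
disagree, the best-performing (highest-AUC) index decides. If no index
survives screening the verdict is *indeterminate*: the declared
misspecification is too mild to be detectable in this setting.

## Estimation details

The fitter minimizes the normal-theory discrepancy
$F_{ML} = \log|\Sigma(\theta)| - \log|S| + \mathrm{tr}(S\Sigma^{-1}(\theta)) - p$
by BFGS with an analytic gradient
($\partial F = \mathrm{tr}[(\Sigma^{-1} - \Sigma^{-1}S\Sigma^{-1})\,
\partial\Sigma]$), starting from loadings $0.7\,\mathrm{sd}$ and residual
variances $0.5\,\mathrm{var}$, with one deterministic perturbed restart on
failure. Convergence requires a gradient max-norm below $10^{-6}$ (cap 500
iterations). The test statistic uses the normal-likelihood multiplier
$T = n F_{min}$ (sample covariance with divisor $n$); an $(n-1)$ Wishart
option exists and RMSEA's denominator follows the same convention for
internal consistency. Means are centred out everywhere: all models are
covariance structures only.

Under `estimator = "MLR"` the statistic is mean-scaled:
$c = \mathrm{tr}(U\hat\Gamma)/df$ with $\hat\Gamma$ the empirical
fourth-moment (ADF) covariance of $\mathrm{vech}(S)$ and
$U = V - V\Delta(\Delta^\top V\Delta)^{-1}\Delta^\top V$ the normal-theory
residual projection at the estimate; $T/c$ restores the statistic's mean
under non-normal data. This is a Satorra–Bentler-type mean scaling; we do
not claim exact equality with any particular software's robust variant, and
the scaled CFI/RMSEA are the plug-in versions computed from the scaled
statistics (not later robust-formula refinements). The baseline
(independence) model has the closed-form solution $\mathrm{diag}(S)$, hence
$F_b = \log|\mathrm{diag}(S)| - \log|S|$; its scaling factor is computed
analogously. Because the baseline is misspecified by construction, its
scaling factor converges to a pseudo-true value, not to 1, even under
normality.

Improper solutions (negative residual variances, out-of-range factor
correlations) are flagged and *retained* in the distributions by default,
with the propriety rate reported; `drop_improper = TRUE` excludes them.
Silently dropping them would condition the cutoff distributions on
propriety and bias them. Replicates that fail to converge are excluded and
counted; more than 20% nonconvergence aborts the study.

## The synthetic-data generator

Non-normal data use Fleishman's cubic transform
$Y = a + bZ + cZ^2 + dZ^3$ of standard normals, with coefficients solved by
damped Newton iteration (tolerance $10^{-10}$ on the moment equations) for
each item's target skewness and excess kurtosis (feasible when
excess kurtosis ≥ skew² − 2), combined with Vale–Maurelli intermediate
correlations: for each item pair the cubic
$r = \rho k_1 + \rho^2 k_2 + \rho^3 k_3$ is solved so that the transformed
pair attains the target correlation. With normal margins the transform is
the identity, so the non-normal path reproduces the plain normal draw
bit-for-bit. Each replicate's stream is seeded deterministically from
(master seed, population label, replicate index), making runs reproducible
and order-independent.

When empirical data are supplied, the default margins are the data's
per-item moment estimates of skewness and excess kurtosis, so the
simulation mimics the study's response distribution. The generator is
continuous: Likert-type data are emulated only through their first four
marginal moments and the correlation structure, not through discreteness,
floor/ceiling effects, or item-level dependence beyond second order.
Passing tests therefore demonstrate calibration for continuous non-normal
data; categorical coarseness is a documented limitation (ordinal
estimators are out of scope).

## ROC conventions and numerical choices

* Candidate cutoffs are the *observed* pooled values (no interpolation);
  the reported cutoff is always an observed value.
* A value exactly at the cutoff counts as passing, so accept rules read
  "χ² ≤ cutoff", "CFI ≥ cutoff".
* The trapezoidal AUC over these candidates equals the Mann–Whitney
  pairwise-concordance probability with ties counted 0.5 — this identity is
  enforced by tests against an independent pairwise oracle and
  cross-checked against `pROC`.
* Youden ties are broken toward higher specificity, then toward the more
  conservative (more accepting) cutoff: when several cutoffs classify
  equally well, the one that preserves H0 acceptance is preferred.
* An AUC below .5 means the index orders the hypotheses *backwards*; the
  report flags this pathology instead of silently re-orienting the
  classifier.
* Degenerate CFI baselines ($T_b \le df_b$) return 1; RMSEA is undefined at
  $df = 0$ and the robust correction refuses saturated models
  ($T_{scaled} = T = 0$).

## Identification and syntax choices

Model strings use a minimal dialect of the de-facto SEM syntax (`=~`,
`~~`, numeric `*` premultipliers; `~` reserved). Marker-loading
identification (first listed item fixed to 1) is the default because
unstandardized solutions are the natural scale for population models
derived from a fitted solution; unit-factor-variance identification is
selectable, and the test statistic is identical under both (a tested
property), so the choice only affects parameter reporting. When a user
fixes any loading on a factor, that fixed loading already sets the
factor's scale and no marker is imposed. Degrees of freedom count
covariance moments only: $df = p(p+1)/2 - q$.

`split_factor()` generalizes slightly beyond unit-variance populations: the
input's factor variance is preserved on both diagonal entries of the new
2×2 factor covariance (off-diagonal $r\,\phi$), so a correlation of 1
reproduces the one-factor population exactly for any $\phi$.

## Misspecification effect sizes and robustness

`quantify_misspecification()` fits the analysis model directly to a
population covariance (no sampling) and reports the population discrepancy
$F_0$, the population RMSEA $\sqrt{F_0/df}$, and the
noncentrality-per-df analogue $1 + nF_0/df$. These make H1 choices
comparable across forms. `robustness_check()` reruns screening and cutoff
generation for each of several H1 forms (sharing the H0 simulations) and
reports whether the verdict agrees; it warns when the forms' $F_0$ values
differ by more than a factor of two, since cutoffs for unequal degrees of
misspecification are not comparable.

## Built-in scenarios and problem sizes

The packaged scenarios use *synthetic stand-in* coefficients chosen as
typical for short Likert-type scales (standardized loadings .55–.80, unit
item variances, modest factor correlation .30 in the two-factor scenario,
mild negative skew); they are not transcribed from any fitted empirical
solution, and exact reproduction of a published analysis routes through
`transcribe_paper_models()` with user-supplied coefficients. Defaults
follow the method's canonical operating conditions: 500 replications per
population, N = 468 (one-factor split scenario, factor correlation .70)
and N = 474 (residual-correlation scenario, r = .50 on two pairs), MLR.
The calibration scenarios use 1000 replications at N = 500 with a 6-item,
loadings-.7 one-factor population — enough for Monte Carlo standard errors
of ~0.13 on the mean statistic and ~0.7 points on rejection rates, while a
full scenario completes in well under a minute on one CPU.

## Known limitations

* Continuous simulation only (no ordinal discretization, no missing data).
* CFA measurement models only: no structural regressions, multi-group
  models or mean structures.
* The robust statistic is a mean-scaled (not mean-and-variance-adjusted)
  correction; cross-software agreement is expected to be close but not
  exact.
* Youden weighting treats type I and type II errors as equally costly;
  alternative utility weightings are not implemented.
* AUC screening uses a point estimate; no confidence intervals or partial
  AUC.
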