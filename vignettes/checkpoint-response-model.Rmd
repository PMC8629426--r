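---
title: "Modeling solid-tumor response to PD-1/PD-L1 checkpoint inhibition"
author: "icikin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling solid-tumor response to PD-1/PD-L1 checkpoint inhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icikin)
```

## The model

Checkpoint inhibitors (anti-PD-1/PD-L1 antibodies) restore T-cell
killing of tumor cells, but only a minority of patients respond. This
package implements a mechanistic, closed-form model of the normalized
tumor burden $\rho'(t)$ — total indexed-lesion volume divided by its
value at the first dose, so $\rho'(0) = 1$ — governed by three
patient-level parameters:

* $\alpha$ (1/day): intrinsic tumor proliferation rate. Doubling time
  is $\ln 2/\alpha$.
* $\Lambda$ (dimensionless, $\ge 0$): the anti-tumor immune state,
  combining intratumoral effector-cell abundance with per-cell kill
  ability.
* $\mu$ (1/day): the immunotherapy-mediated amplification of immune
  kill. Negative values describe tumors that accelerate on treatment.

The burden follows a logistic-type trajectory

$$\rho'(t) = \frac{\rho_\infty}{1 - (1-\rho_\infty)\,e^{-k t}},
\qquad k = \alpha - \mu + \mu\Lambda,
\qquad \rho_\infty = 1 + \frac{\alpha - \mu}{\mu\Lambda},$$

equivalently the solution of
$d\rho/dt = k\,\rho\,(1 - \rho/\rho_\infty)$ from $\rho(0)=1$. The sign
of $\alpha - \mu$ sets the direction of response (progression when
$\alpha > \mu$), scaled by $\mu\Lambda$. Useful identities:
$k = \mu\Lambda\rho_\infty$, so $k$ and $\rho_\infty$ share a sign
whenever $\mu\Lambda > 0$.

Regimes:

* $k > 0$, $\rho_\infty > 1$: progressive growth saturating at
  $\rho_\infty$.
* $k > 0$, $0 < \rho_\infty < 1$: partial regression to a positive
  plateau.
* $k < 0$ (then $\rho_\infty < 0$): complete regression, $\rho' \to 0$.
* $\mu\Lambda < 0$ (possible with $\mu < 0$): hyperprogression with a
  finite-time vertical asymptote at $t^* = \log(1-\rho_\infty)/k$;
  projections at or past $t^*$ are reported as $+\infty$.

```{r trajectory}
m <- trajectory_model(model_parameters(alpha = 0.02, lam = 1, mu = 0.01))
predict_burden(m, c(0, 50, 200, 700))
```

### Numerical choices

* Exponential-limit threshold: when $|\mu\Lambda| \le 10^{-12}$ the
  asymptote is a removable singularity and `predict_burden()` switches
  to the analytic limit. The true pointwise limit of the closed form is
  $e^{kt}$ (not $e^{\alpha t}$, except along the physically meaningful
  path $\mu \to 0$ where the two coincide), so the limit branch uses
  $e^{kt}$; this keeps the prediction continuous in every direction of
  parameter space, which the test suite asserts across the switch.
* Singularity tolerance: a trajectory denominator within $10^{-9}$ of
  zero raises an error rather than returning huge nonphysical values.
* Burden is clamped at zero only in classification and projection
  outputs; the analytic layer never clamps.

## The estimation pipeline

Estimation is two-step, mirroring the two clinical data situations:

1. **Fix $\alpha$.** With no pretreatment imaging (literature-style
   cohorts) the fastest-progressing patient per histology is fit to a
   pure exponential and that rate is shared by the histology group
   (`resolve_alpha(..., "fastest-progressor")`). With a pretreatment
   scan, each patient gets
   $\alpha = \log(1/\rho_{pre})/(-t_{pre})$
   (`"pretreatment"`; negative values mean the tumor was already
   shrinking). The exponential fit minimizes squared error in
   log-burden — exact, convex, and unique for positive data.
2. **Fit $(\Lambda, \mu)$** per patient by nonlinear least squares
   against the closed form, $\alpha$ fixed, baseline $(0, 1)$ included
   in the residual sum (it contributes exactly zero).

The least-squares step uses box-constrained L-BFGS-B over
$(\Lambda, \mu) \in [0, 100] \times [-1, 1]$ (bounds span the
plausible clinical range with wide margin) with an analytic gradient,
restarted from a deterministic $4 \times 5$ grid of initial guesses
plus data-driven starts obtained by inverting rough $(k, \rho_\infty)$
estimates. Two refinements matter in hard corners of parameter space:

* **$(k, s)$ polish.** With $s = 1/\rho_\infty$ the trajectory is
  $\rho'(t) = 1/(s + (1-s)e^{-kt})$, which is smooth through the
  exponential limit ($s = 0$) and well-conditioned along the
  near-exponential ridge where $\Lambda$ and $\mu$ are nearly
  collinear. The best solution is re-polished in this space and mapped
  back, accepted only when it respects the bounds and lowers the SSR.
* **Exact interpolation candidates.** Noise-free data are an
  interpolation problem: equating the model through two observations
  gives a one-dimensional root problem in $k$ whose solution
  reproduces generating parameters to machine precision even where the
  SSR surface is flat below double precision (for example burdens that
  have collapsed to $10^{-20}$, which contribute nothing to a residual
  sum). These candidates only replace the optimized solution when they
  genuinely lower the SSR, so noisy fits are unaffected.

Convergence uses an L-BFGS-B relative-SSR factor of $10^{2}$ machine
epsilons (relative change $\sim 2\times 10^{-14}$) and at most 500
iterations per start; ties across starts resolve to the first start in
grid order, making every fit bit-reproducible.

```{r fit}
tt <- seq(0, 560, by = 80)
s <- patient_series("p1", tt,
                    predict_burden(trajectory_model(
                      model_parameters(0.02, 1, 0.01)), tt))
fit_patient(s, alpha = 0.02)
```

## Response classification and projection

RECIST v1.1 reduces to a binary outcome: *favorable* (partial/complete
response, a $\ge$30% reduction) versus *unfavorable* (stable or
progressive disease), taken from the last recorded point. Because the
30% rule is stated on diameters while the model works in volumes, two
conventions are implemented and recorded with every label: the literal
volume reading (threshold 0.70 on normalized burden, the default) and
the diameter-equivalent reading ($0.7^3 = 0.343$). Long-term outcome
is projected by evaluating the fitted trajectory at a 700-day horizon
(beyond the last follow-up of typical trials), clamped at zero, with
divergent (hyperprogressing) fits projecting to $+\infty$.

Stability is probed three ways, as in the source analyses:

* **Truncation:** refit on data restricted to $t <$ 30/60/120/200 days
  and compare, via Spearman rank correlation, windowed versus
  full-data $\Lambda$ and $\mu$; misclassification is the fraction of
  patients whose projected-horizon label from the windowed fit differs
  from the full-data-fit label (both labels are model projections —
  the observed-last-point alternative is recorded as metadata).
  Patients without a post-baseline scan inside a window are excluded
  from that window and counted.
* **Parameter perturbation:** $\Lambda$ and $\mu$ are varied $\pm$10%
  one at a time ($\alpha$ is not perturbed) and the change in
  $\rho'(200\,\mathrm{d})$ recorded.
* **Data perturbation:** uniform $\pm 0.1$ noise is added to every
  post-baseline burden (the baseline stays exactly 1, since burden is
  defined relative to it), the cohort refit, and rank stability
  reported.

## Biomarker mapping

$\Lambda$ maps linearly to an intratumoral CD8+ T-cell density,
$\Lambda \times 5558$ cells/mm$^2$, assuming one tumor cell killed per
CD8+ T cell and the melanoma-measured microenvironment density of 5558
cells/mm$^2$. $\mu$ maps to a PD-L1-positivity-scale percentage as
$\mu \times 100$; the raw (possibly negative) value is preserved, and
stratification at the standard 1% and 5% cutoffs clamps at zero
because a staining percentage cannot be negative.

```{r biomarker}
lambda_to_cd8(0.0995)
mu_to_pdl1_percent(0.054)
```

## The virtual-cohort generator

No per-patient data from the source trials are public, so the
generator is a first-class module that emulates their statistical
structure with known ground truth:

* **Growth rates.** Calibration style samples one of six histologies
  with its published rate ($\alpha \in [0.0034, 0.0622]$/d); validation
  style draws per-patient $\alpha \sim U(-0.0129, 0.0602)$/d and adds a
  pretreatment scan at $-(17\text{–}91)$ d consistent with that rate.
* **$(\Lambda, \mu)$ families.** Class-conditional draws anchored at
  the published cohort means (responders: $\Lambda$ 0.714, $\mu$ 0.054
  calibration; 0.876, 0.0529 validation; nonresponders: 0.0995, 0.013
  and 0.0297, $-0.0064$), with spread $\mathrm{SEM}\sqrt{n}$ from the
  published standard errors. Positive-support quantities use
  lognormals; nonresponder $\mu$ is normal, allowing the negative
  values the validation cohort exhibits. The published summaries pin
  only means and SEMs, so the distributional forms are this package's
  own commitment; one published SEM (validation nonresponder
  $\Lambda$: 0.469 about a mean of 0.0297) implies a coefficient of
  variation near 99 and is treated as anomalous — the lognormal CV is
  capped at 3 throughout. Draws are redrawn (up to a fixed cap) until
  the model-projected outcome at the horizon matches the drawn class,
  so the realized responder fraction is binomial at the configured
  rate (default 0.29) and truth labels are internally consistent.
* **Visits.** Baseline at $t=0$, follow-ups every $42 \pm 10$ d
  (uniform jitter) to a 700-day horizon — inside the published 17–91 d
  inter-scan range. A trajectory that diverges mid-schedule
  (hyperprogression) is truncated at its last valid scan, a simple
  last-visit dropout.
* **Noise.** Uniform $\pm 0.1$ (configurable) added to post-baseline
  burdens, clamped at zero; the baseline stays exactly 1.
* **Lesions.** Optionally each burden series is decomposed into 1–12
  indexed lesions (truncated-geometric, median 3) by per-patient
  Dirichlet proportions, with long/short axes back-solved from sphere
  volumes at a fixed per-lesion axis ratio in $[1, 2.5]$, so
  aggregation inverts the decomposition exactly.

Reproducibility: one master seed; each patient gets a derived 31-bit
subseed, so regeneration is bit-for-bit identical and partial
regeneration reproduces individual patients.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: pseudoprogression (transient growth
before response), inter-lesion differential response, informative
dropout and censoring, scan-to-scan correlated measurement error, and
any bound on how large a progressing burden may grow before follow-up
stops. Because nonresponder asymptotes are drawn unbounded, some
synthetic trajectories reach burdens far beyond what a clinical cohort
would observe; this stresses the optimizer usefully but inflates
absolute residual summaries relative to published fits on real trial
measurements.

## Statistical components

Group comparisons use a two-tailed Wilcoxon rank-sum test computed on
mid-ranks: exact by full enumeration of rank assignments when
$n_x + n_y \le 12$ (valid under ties, where classical null tables are
not), otherwise the tie-corrected normal approximation with continuity
correction; the two branches agree closely at the crossover size.
Spearman correlation delegates to `stats::cor`. ROC analysis scans
thresholds at midpoints between distinct scores plus $\pm\infty$ with
the fixed orientation "higher score predicts response" (no automatic
sign flipping), picks the threshold maximizing Youden's
$J = \mathrm{sens} + \mathrm{spec} - 1$ with ties resolved toward the
smallest threshold (favoring sensitivity, the clinically relevant
direction for early triage), and reports AUC as the tie-adjusted
Mann–Whitney statistic. Ratios with zero denominators (e.g. NPV when
no patient is predicted negative) are signaled as undefined, never
silently zeroed.

## Problem sizes and runtime

The shipped analyses use a 189-patient calibration-style cohort and a
64-patient validation-style cohort (matching the published cohort
sizes), 100-patient noise-free and 200-patient noisy cohorts for
recovery studies, and 100 random parameter triplets for the
ODE-equivalence check; each full cohort fit takes well under a minute
on one core.

## Known limitations

* $\Lambda$ is weakly identified from early or near-exponential data;
  its rank stability under truncation is correspondingly poor. This is
  a property of the model geometry, visible in the $(k, s)$
  parameterization, and matches the behavior reported for the original
  cohorts. $\mu$ is the robust early biomarker.
* The fastest-progressor $\alpha$ is an extreme-value estimate taken
  on treated patients; with measurement noise it drifts from the true
  growth rate (stage 2 of the analysis quantifies this on synthetic
  data). Pretreatment scans, where available, are preferable.
* The binary RECIST reduction ignores nadir tracking, new-lesion
  rules, confirmation scans and iRECIST; the two threshold conventions
  bracket the volume/diameter ambiguity but neither is full RECIST.
* The CD8 and PD-L1 conversions are deliberate order-of-magnitude
  bridges (linear, with literature-fixed constants), not calibrated
  immunohistochemistry predictions.
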