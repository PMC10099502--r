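---
title: "Modelling outlet choice for family planning: methods and design"
author: "fpchoice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling outlet choice for family planning: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

In urban East African settings a woman seeking contraception usually has
many service delivery points — public clinics, private clinics, pharmacies
— within walking distance, and she frequently bypasses the nearest one.
Which structural-quality attributes (method range, stockouts, opening
hours, trained providers, signage, sector) justify the extra travel?
`fpchoice` estimates that trade-off from linked household–outlet data:
each surveyed woman is geolocated, every outlet in her area is audited,
and users of modern methods are (where possible) linked to the specific
outlet where they obtained their method.

Two statistical obstacles shape the design:

1. **Selection.** Outlet choice can only be modelled for women who use a
   modern method *and* were successfully linked to their outlet.  Linked
   users differ systematically from other women (education, marriage,
   parity), so an uncorrected choice model estimates preferences of a
   selected subpopulation.
2. **Preference heterogeneity.** A single coefficient per attribute
   (conditional logit) imposes the independence-of-irrelevant-alternatives
   substitution pattern and hides variation in, say, distance aversion.

# The model

## Selection stage: six-category multinomial logit

Every respondent falls in one of six categories: (1) no method — the
reference, (2) traditional method, (3) long-acting method not linked to an
outlet, (4) short-acting method not linked, (5) long-acting method linked,
(6) short-acting method linked.  With respondent covariates $x_i$
(education, marriage, parity, wealth, supply-environment summaries),

$$\log \frac{p(y_i = n \mid x_i)}{p(y_i = 1 \mid x_i)} = x_i' \beta_n,
  \qquad n = 2, \dots, 6 .$$

`mnl()` fits this by maximum likelihood (globally concave; quasi-Newton
from a zero start on internally standardised covariates, followed by
Newton polishing so the gradient max-norm at the optimum is below
$10^{-5}$).  `compute_ipw()` then weights each linked respondent by the
reciprocal of the fitted probability of her *own observed* linked category
(5 or 6), rescaled to mean one over the estimation sample.  Under
selection on observables (linkage ignorable given the covariates), the
weighted linked sample reproduces population moments — a property the test
suite checks directly on synthetic data.

## Choice stage: conditional and mixed logit

Chooser $i$ receives utility from outlet $m$ in her choice set

$$U_{im} = z_{im}' \beta_i + \varepsilon_{im},$$

with outlet attributes $z_{im}$ (distance in km plus the structural-quality
attributes), independent standard Gumbel errors, and random coefficients
$\beta_i \sim N(\beta, \Sigma_\beta)$ with **diagonal** $\Sigma_\beta$ —
the restriction stabilises estimation at the sample sizes linked designs
deliver while still breaking independence of irrelevant alternatives.

The choice set is every outlet within a fixed Euclidean radius of the
respondent's residence (3 km in the Kenya-like design, 2 km in the
Uganda-like design, where the outlet density is much higher), plus her
chosen outlet if it lies beyond the radius (kept and flagged
`out_of_radius` — dropping it would discard the dependent variable).
Euclidean rather than network distance is a deliberate simplification: in
dense urban settings with good road networks the two are close, and the
straight-line metric is simple and measured without error.

`cond_logit()` maximises the IPW-weighted conditional log-likelihood.
`mixed_logit()` maximises the simulated version

$$\mathcal{L}(\beta, s) = \sum_i w_i \log \frac{1}{R} \sum_{r=1}^{R}
  \frac{\exp\!\big(z_{i,c_i}'(\beta + s \odot \eta_{ir})\big)}
       {\sum_m \exp\!\big(z_{im}'(\beta + s \odot \eta_{ir})\big)},$$

where $\eta_{ir}$ are standard-normal draws and $s$ holds the
random-coefficient scales.  The log-likelihood, analytic gradient and
per-chooser scores are computed in compiled code; the nesting identity —
with $s = 0$ the objective *equals* the conditional logit exactly — is a
unit test, not an approximation.

Numerical choices that matter:

* **Draws.** Shuffled Halton sequences (one prime base per dimension,
  first 10 points discarded, a seeded permutation breaking cross-dimension
  correlation) mapped through the normal quantile function.  Default
  $R = 500$ per chooser; estimates on the bundled presets move by well
  under one standard error when $R$ doubles.
* **Parameterisation.** $s$ enters unconstrained and is reported as
  $|s|$: the likelihood is symmetric in the sign of $s$, and the absolute
  value avoids a boundary at zero during optimisation.
* **Start.** Conditional-logit estimates for $\beta$ (that likelihood is
  globally concave, so the warm start is reliable) and $0.1$ for each
  scale.
* **Standard errors.** Sandwich (robust) by default: IPW weighting breaks
  the information equality.  The bread is a central-difference Hessian of
  the analytic gradient.
* **Screening.** `screen_attributes()` implements overfit-then-prune
  backward elimination: drop the attribute with the largest Wald p-value
  above `p_drop` (default 0.3), refit, repeat; distance is never dropped,
  and within-choice-set collinear attributes are removed up front and
  logged.  The default threshold is intentionally permissive — omitting a
  relevant attribute is a worse specification error than keeping an
  irrelevant one.  Note that a threshold of 0.3 retains a pure-noise
  attribute about 30% of the time (its null p-value is uniform); that is
  the price of the asymmetry, not a defect.
* **Model comparison.** `lr_test()` uses the standard chi-square reference
  with degrees of freedom equal to the number of random coefficients.
  Under the null the scales sit on the boundary of the parameter space, so
  the test is conservative (the asymptotic null is a chi-bar-square
  mixture); the type-I simulation in the test suite confirms rejection
  below nominal level.

## Willingness to travel

Choice-model coefficients are scale dependent; ratios are not.  For each
non-distance attribute $k$,

$$\mathrm{wtt}_k = -\frac{\beta_k}{\beta_d} \quad \text{km per unit of } k,$$

with $\beta_d$ the mean distance coefficient — positive for valued
attributes when $\beta_d < 0$.  Ratios use coefficient means only, so one
willingness-to-travel figure is reported per attribute per sample.
Confidence intervals come from the delta method by default
($\operatorname{var}(r) \approx v_k/\beta_d^2 + \beta_k^2 v_d/\beta_d^4 -
2\beta_k c_{kd}/\beta_d^3$), which is deterministic and auditable; a
simulation method (draw coefficient vectors from the normal approximation,
take empirical ratio quantiles) is available as an option and agrees with
the delta intervals on well-conditioned fits.  The ratio is refused when
$|\beta_d| < 10^{-8}$.

# The synthetic-data generator

Real linked household–outlet microdata cannot ship with a package, so
`simulate_study()` generates a complete study under known truth; every
estimation stage is validated by parameter recovery against that truth.

* **Geometry.** Outlets uniform in an outer-ring disc (5 km radius in the
  Kenya-like preset), households uniform in a nested inner ring (2 km), so
  every household's full choice set is observed — mirroring designs whose
  outlet census extends beyond the household frame.
* **Outlet mix and attributes.** `site_preset()` scales down the two
  study mixes (pharmacy-heavy 921:614:233 for Kenya-like; private-heavy
  826:56:18 for Uganda-like).  `attribute_preset()` draws binary
  attributes at type-specific prevalences shaped like the corresponding
  outlet audits; methods offered is a shifted binomial on 1–12 matched to
  the type means; prices are log-normal matched to the type medians
  (log-scale SD 0.5 — the audits publish only medians, so the spread is a
  modelling choice).
* **Selection.** Categories are sampled from a multinomial logit on
  observables; the preset makes marriage and parity raise the odds of the
  linked categories and college education the odds of the unlinked-user
  categories, with intercepts placed to give roughly 30% non-use and a
  30–45% linkage rate among users — the orders of magnitude seen in urban
  surveys of this kind.  Missingness depends *only* on observables: that
  is the identifying assumption of the IPW correction, and the generator
  realises it exactly.
* **Choice.** $\beta_i$ is drawn from the truth's normal law
  (`truth_preset()`: distance $-1$/km with SD 0.5; public $+2.0$ with SD
  0.8; methods $+0.15$ per method with SD 0.08; the remaining attributes
  fixed), Gumbel noise is added per alternative, and the utility-maximal
  outlet is chosen.  Realised $\beta_i$ draws are stored so oracle tests
  can condition on them.
* **Heterogeneous means.** `truth_preset(heterogeneous = TRUE)` is a
  selection-stress scenario: married women put an extra +2.0 on the
  public-sector indicator while their distance weight is unchanged, and
  linkage depends strongly on marriage (coefficient 2.5 on the linked
  categories).  Both choices are deliberate.  The shift must act on the
  numerator of the willingness-to-travel ratio *only* — a proportional
  shift of the public and distance coefficients would cancel in the ratio
  and leave selection with nothing to distort — and the selection effect
  must be large enough that the bias it induces exceeds the variance cost
  of inverse weighting (the rarer linked category draws weights of an
  order of magnitude, so weak selection would be drowned by weighting
  noise).  If preferences were independent of the observables that drive
  linkage, the linked sample would be effectively random and IPW would
  have nothing to correct.  The population-average coefficient vector,
  computed analytically by `population_beta()`, is the estimand the
  IPW-weighted model targets.

What the generator does **not** emulate: road networks and travel time
(straight-line geometry is exact here by construction), spatial clustering
of outlets and households, survey nonresponse, repeated survey rounds, or
outlet-side causes of failed linkage.  Passing recovery tests therefore
demonstrates correctness of the estimators under the stated model, not
robustness to those real-data complications.

# Reproducibility and problem sizes

Every stochastic step takes an explicit seed; `run_pipeline()` spawns
per-stage seeds deterministically from one master seed (a seeded
`sample.int()`), so identical configuration and seed give byte-identical
artifacts.  All artifacts are delimited or structured text.

The validation suite works at deliberately desk-sized scales, chosen so
the full suite runs in minutes while leaving the Monte-Carlo checks
well-powered: recovery of the mixed logit uses 20 replicates of 1,500
choosers × 30 outlets with $R = 200$ draws; interval coverage uses 300
replicates of 400 choosers × 30 outlets with $R = 100$ and one random
coefficient; the IPW bias-reduction comparison uses 50 replicates of
6,000 respondents; the likelihood-ratio calibration uses 200 replicates
of 150 choosers.

Two details of the reduced designs are worth recording.  They use a
balanced outlet-type mix (rather than the pharmacy-heavy study mix) so
that every attribute varies within choice sets even when the outlet
universe is small, and the interval-coverage study omits the stockout
attribute: at 5–20% prevalence it is constant across a small outlet
census in a non-negligible fraction of draws, which would make the model
unidentified in those replicates rather than telling us anything about
interval calibration.  With several random-coefficient scales at this
reduced scale the weakest of them is barely identified and its
near-singular information contaminates the covariance, so the reduced
design randomises the distance coefficient only; the full three-scale
model is exercised at the recovery scale above.

# Known limitations

* Diagonal $\Sigma_\beta$ only; no correlated random coefficients, and no
  non-normal mixing distributions.
* One choice per respondent (no panel structure).
* The IPW correction assumes linkage is ignorable given the covariates in
  the selection model; outlet-side causes of failed matching are out of
  scope.
* The delta-method interval for a coefficient ratio degrades when the
  distance coefficient is imprecise; the simulation (Krinsky–Robb-style)
  method is the fallback in that regime.
* The chi-square reference for the LR test is conservative at the
  boundary; a chi-bar-square mixture would be exact but is deliberately
  not implemented.
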