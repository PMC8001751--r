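---
title: "Growth-curve methods: models, selection criteria, and derived quantities"
author: "capricurve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-curve methods: models, selection criteria, and derived quantities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capricurve)
```

## The problem

In staged-slaughter studies of young ruminants, a cohort of animals is
distributed over a grid of ages (here 1, 7, 14, 28, 42, 56, 70 and 84 days,
six animals per age) and each animal is measured once — body weight and size
on the live animal, then organ weights, stomach-compartment proportions and
ruminal pH at slaughter. The scientific questions are: which growth function
best describes each trait's trajectory over age; when does each trait grow
fastest (the inflection point); and how much cumulative "growth exposure"
accrues per rearing stage (area under the fitted curve). Around weaning
(60 d here) the forestomach compartments — rumen, reticulum, omasum — expand
dramatically while the abomasum's relative share collapses, so these derived
quantities have direct husbandry meaning.

`capricurve` implements that analysis end to end: fit eight candidate model
families per trait, pick the best by information criteria, derive inflection
points and stage AUCs, and tabulate Pearson correlations of every trait
against age and body weight.

## The model families

Six sigmoidal families and two polynomial baselines. With response $y$, age
$x$ (days), and parameters $a, b, c$ (plus shape $d$ for four-parameter
families):

| Family | Equation | $IP_y$ | $IP_x$ |
|---|---|---|---|
| Logistic | $a/(1+b e^{-cx})$ | $a/2$ | $\ln(b)/c$ |
| Gompertz | $a\exp(-\exp(b-cx))$ | $a/e$ | $b/c$ |
| Ratkowsky | $a/(1+e^{b-cx})$ | $a/2$ | $b/c$ |
| MMF | $(ab+cx^d)/(b+x^d)$ | $\frac{d(c+a)+(a-c)}{2d}$ | $\left(\frac{b(d-1)}{d+1}\right)^{1/d}$ |
| Weibull | $a-b\exp(-cx^d)$ | $a-b e^{(1-d)/d}$ | $\left(\frac{d-1}{cd}\right)^{1/d}$ |
| Richards | $a/(1+e^{b-cx})^{1/d}$ | $a(1+d)^{-1/d}$ | $(b-\ln d)/c$ |
| Quadratic | $a+bx+cx^2$ | — | — |
| Cubic | $a+bx+cx^2+dx^3$ | — | $-c/(3d)$ |

For every family except the MMF, $a$ is the upper asymptote in the
response's units and $c$ a maturing rate per day. Three conventions deserve
comment, each adopted here deliberately:

* **MMF roles.** In the MMF equation the value at age 0 is $a$ and the
  $x\to\infty$ limit is $c$: $a$ is the *intercept* and $c$ the *asymptote*,
  even though in the other families $a$ plays the asymptote role. The
  summaries report both and label $c$ the asymptote for MMF. This matters
  for decreasing traits (the abomasum's relative share starts near 60% and
  falls towards 18%): the same equation fits with $a > c$.
* **Weibull inflection ordinate.** The closed form used is
  $IP_y = a - b\,e^{(1-d)/d}$, i.e. the exponent is $(1-d)/d$. Evaluating
  the curve at the closed-form $IP_x$ confirms it, and the package's
  property tests assert $y(IP_x) = IP_y$ to relative $10^{-8}$ for every
  family.
* **Ratkowsky inflection.** The Ratkowsky is an exact reparameterization of
  the Logistic ($b_{\mathrm{logis}} = e^{b}$), so although it is
  conventionally tabulated without an inflection formula, the package
  derives one through that equivalence and flags it
  (`method = "logistic_equivalence"`). Both families are kept in the
  candidate set because both are conventional; their fits are identical up
  to the reparameterization and the tie-break rule resolves them
  deterministically.

A negative $IP_x$ means the fitted curve's fastest-growth age precedes
birth; for traits already decelerating at birth this is the correct reading
of the fit and is reported as-is, never clipped to the observed age range.

## Fitting

Sigmoidal families are fitted by damped least squares (Levenberg–Marquardt)
with analytic parameter gradients: solve
$(J^\top J + \lambda\,\mathrm{diag}(J^\top J))\,\delta = J^\top r$, accept
only SSR-decreasing steps, $\lambda_0 = 10^{-3}$, $\times 10$ on rejection,
$\div 10$ on acceptance. Convergence is declared when the relative SSR drop
or relative parameter step falls below $10^{-10}$, with a 500-iteration cap.
Because only improving steps are accepted the SSR path is monotone — the
returned fit is never worse than its start point, and non-convergence
returns the best-so-far parameters flagged `converged = FALSE` rather than
an error. Polynomial families skip iteration entirely and solve the normal
equations exactly.

Start values come from family-specific linearizations (e.g.
$\log(a_0/y - 1)$ regressed on $x$ for the Logistic, with
$a_0 = 1.05\max y$), shape $d$ defaulting to 1.5. If the first attempt fails
to converge or is beaten by the polynomial baseline of equal parameter
count, five seeded $\pm 20\%$ perturbations of the start are tried and the
best kept; the perturbation seed is fixed so fits are bit-reproducible.

Standard errors come from the usual linearized covariance
$s^2 (J^\top J)^{-1}$, $s^2 = SSR/(n-p)$. No bounds are imposed by default
(fitted tables legitimately contain negative $b$ and $c$); box constraints
can be passed through `fit_options()`.

Fitting uses individual-animal observations ($n = 48$ in the default
design), not age-group means. The spacing of information criteria among
families is consistent with $n$ near the animal count, and individual-level
residuals are what the noise model below emulates; `use_means = TRUE` is
available for the group-mean alternative.

## Model selection

Four criteria per family, all "lower is better":

$$MSE = \frac{SSR}{n-2},\qquad AIC = n\ln\frac{SSR}{n} + 2k,$$
$$AICc = n\ln\frac{SSR}{n} + \frac{2kn}{n-k-1},\qquad BIC = n\ln\frac{SSR}{n} + k\ln n.$$

The MSE denominator is $n-2$ for *every* family, including four-parameter
ones. That convention is unusual but is kept verbatim under its own name;
the residual standard error $\sqrt{SSR/(n-p)}$ is reported separately as
`SEM`, which is what the criteria tables of this study design actually
print.

Two counting conventions are exposed side by side:

* `mode = "standard"`: $n$ = fitted observations, $k$ = the family's
  parameter count.
* `mode = "published"`: $k$ = parameter count minus one and a fixed effective
  $n = 47$. Under this convention — and only under it — the within-variable
  criterion gaps are constants: $BIC - AIC = k(\ln n - 2)$ equals 3.70 for
  three-parameter and 5.55 for four-parameter families, and
  $AICc - AIC = 2k(k+1)/(n-k-1)$ equals 0.27 / 0.56. Published criteria
  tables for this design show exactly that gap structure, so the convention
  is provided for comparability; neither convention is asserted as uniquely
  correct, and selection can be driven by either.

Default selection criterion is AICc (the small-sample-safe choice at
$n \approx 47$, $k \in \{2,3,4\}$); AIC, BIC or MSE are configurable.
Ties within 0.01 — the resolution of two-decimal criteria tables — break
toward fewer parameters, then a fixed family order (Logistic, Gompertz,
Ratkowsky, Quadratic, Cubic, MMF, Weibull, Richards). The window is strict:
a gap of exactly 0.01 at printed resolution is a win, not a tie, which is
what makes near-tied published rows resolve to their printed winner.
Non-converged fits stay visible in the criteria table, flagged, but are
never selected.

## Derived quantities

Inflection points use the closed forms above. Stage AUCs integrate the
fitted curve over the three rearing-stage windows $[1,28]$, $[29,56]$,
$[57,84]$ days — milk feeding, transition, post-weaning. The windows
deliberately leave the one-day gaps $(28,29)$ and $(56,57)$, mirroring the
reporting convention of staged designs; additivity is therefore checked on
contiguous windows instead. Polynomials integrate in closed form;
sigmoids use adaptive Gauss–Kronrod quadrature (`stats::integrate`) at
relative tolerance $10^{-8}$ with absolute floor $10^{-12}$, which the test
suite pins against a $10^5$-panel trapezoid oracle at relative $10^{-6}$.

Report tables round to two decimals, half away from zero — the convention
of the printed tables this analysis style produces — while a full-precision
copy is always written alongside. (Binary floating point makes naive
rounding of, say, $54.57/2 = 27.285$ land on 27.28; the rounding helper
resolves decimal ties away from zero.)

## Correlations

Pearson $r$ per trait against age and against each animal's own body weight
(joined on animal id — the design is cross-sectional, so there is exactly
one body weight per animal), with two-sided $p$ from the $t$ transform
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom, starred at
$p < 0.01$. No multiple-testing correction is applied, matching the
presentation conventions of this literature; a Bonferroni option exists but
defaults off.

## The synthetic-data generator

The raw animal data behind this study design are not publicly deposited, so
the package ships a generator that emulates the design: 8 ages × 6
replicates (48 animals), shared animal ids across traits (each animal is
"measured" for everything at its slaughter age), and per trait
$y = f(x) + \varepsilon$, $\varepsilon \sim N(0, \sigma)$ homoscedastic.
The packaged default configuration (`inst/extdata/study_config.csv`,
editable) carries all eighteen published trait models with their printed
parameter estimates, and sets each $\sigma$ to the printed residual
standard error of the corresponding criteria table — e.g. body weight:
Gompertz, $\sigma = 1.22$ kg; chest depth: MMF, $\sigma = 3.05$ cm. Setting
`drop_count = 1` mimics the effective $n = 47$ implied by the criterion
arithmetic. Every trait consumes an RNG substream derived from the master
seed and the trait name, so a trait generated alone is byte-identical to
its slice of the full study.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: longitudinal correlation (every animal appears
once, so there are no repeated measures to model), heteroscedastic or
age-dependent noise, litter/dam effects, non-Gaussian residuals, and
truncation at zero (values are deliberately not truncated; at the shipped
parameter/noise combinations negative draws are vanishingly rare, and
truncation would bias recovery checks).

## Numerical choices and degenerate inputs

* $x^d$ in the MMF/Weibull evaluates in log space for stability at large
  $d$; negative ages with fractional $d$ raise a classed domain error.
* Constant-response data: $R^2$ is defined as 0 with a warning; initial
  guesses degrade to a flat-curve start instead of failing.
* A perfect fit ($SSR = 0$) reports $-\infty$ criteria with a
  `perfect_fit` flag so noiseless recovery runs can still rank models.
* Undefined closed forms (Weibull/MMF with $d \le 1$, $c = 0$ rate, zero
  cubic coefficient) raise classed invalid-parameter errors; the Quadratic
  simply has no inflection and returns `NULL`.
* Collinear polynomial designs raise a degenerate-design error rather than
  returning pseudo-inverse coefficients.

## Problem sizes used by the test suite

Unit tests run the full 8 × 6 design. The parameter-recovery suite refits
each published generator over 200 seeded replicates in the acceptance
tests and a 40-replicate smoke version in the unit tests; the correlation
type-I check uses 200 replicates; the law-of-large-numbers check uses
10^4 replicates per age for a single trait. These sizes keep the whole
suite in the low minutes on one core while leaving Monte-Carlo error well
below the asserted margins.

## Known limitations

* **Wald intervals for the MMF's $b$.** The MMF scaling parameter enters as
  $b \approx x_{half}^d$ and ranges over orders of magnitude; at the noise
  levels of this design its natural-scale standard error from
  $s^2(J^\top J)^{-1}$ is badly miscalibrated whenever $\hat b$ lands low.
  The package's own recovery simulations show roughly 76–80% of
  200 replicates landing within 3 SE of truth for the MMF generators
  (against ~87–100% for every other family), and refitting from the true
  parameters confirms these misses are global minima, not optimizer
  failures. Profile-likelihood or log-scale intervals would fix this but
  are out of scope; treat MMF $b$ standard errors as descriptive only.
* Criteria and $R^2$ from refits of *synthetic* data are not expected to
  reproduce published fitted-from-data values — the raw data are
  unavailable; only closed-form derived quantities recomputed from printed
  parameters are reproducible exactly, and those are what the acceptance
  script checks.
* No weighted or robust loss, no autocorrelated residuals, no mixed-effects
  growth models (the design is cross-sectional), and no delta-method or
  bootstrap intervals on inflection points and AUCs (extension hooks only).

## A minimal run

```{r example, eval = FALSE}
cfg <- synthetic_config(seed = 7)
kids <- generate_study(cfg)

res <- run_pipeline(run_config(input = kids, seed = 7, outdir = "kid_run"))
res$best                       # winning family per trait
res$summaries$body_weight_kg   # parameters, inflection, stage AUCs
head(res$correlations)
```

The same pipeline is scriptable from a shell through
`inst/cli/capricurve.R` (`simulate`, `fit`, `run`, `report` verbs).
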