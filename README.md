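# capricurve

Growth-curve modelling of body and digestive-tract development in goat
kids — and, more generally, of any cross-sectional age-series trait
measured on a staged-slaughter design.

In such studies a cohort of young animals is spread over a grid of ages
(here 1, 7, 14, 28, 42, 56, 70, 84 days, six animals per age) and each
animal is measured once: live body weight and size, then organ weights,
stomach-compartment proportions and ruminal pH at slaughter. `capricurve`
answers the three questions this design is run for:

1. **Which growth function describes each trait?** Eight candidate
   families are fitted per trait — Logistic, Gompertz, Ratkowsky, MMF
   (Morgan–Mercer–Flodin), Weibull, Richards, Quadratic, Cubic — by damped
   (Levenberg–Marquardt) least squares with analytic Jacobians, or exact
   normal equations for the polynomials. The best family is selected by
   small-sample information criteria, all in their least-squares forms
   (lower is better):

   ```
   MSE  = SSR/(n-2)
   AIC  = n ln(SSR/n) + 2k
   AICc = n ln(SSR/n) + 2kn/(n-k-1)
   BIC  = n ln(SSR/n) + k ln(n)
   ```

2. **When does each trait grow fastest?** Closed-form inflection points
   per family, e.g. Logistic `IPy = a/2, IPx = ln(b)/c`; Gompertz
   `IPy = a/e, IPx = b/c`; Weibull `IPy = a − b·exp((1−d)/d)`,
   `IPx = ((d−1)/(cd))^(1/d)`; MMF `IPy = (d(c+a)+(a−c))/(2d)`.

3. **How much growth accrues per rearing stage?** Areas under the fitted
   curve over the milk ([1, 28] d), transition ([29, 56] d) and
   post-weaning ([57, 84] d) windows — closed-form antiderivatives for
   polynomials, adaptive Gauss–Kronrod quadrature for sigmoids.

A Pearson-correlation module tabulates every trait against age and against
each animal's own body weight (starred at p < 0.01), and a seeded
synthetic-data generator reproduces the whole study design — including all
eighteen published trait models and their residual scales — so the entire
pipeline is testable without animal data.

## Worked example

Simulate a study (body weight + carcass weight), fit all eight families to
body weight, select, and derive:

```r
library(capricurve)

vars <- default_study_config()
cfg  <- synthetic_config(seed = 7,
          variables = vars[vars$variable %in% c("body_weight_kg", "carcass_kg"), ])
kids <- generate_study(cfg)          # 96 rows: 2 traits x 8 ages x 6 animals

fits <- fit_all_families(kids, "body_weight_kg")
tab  <- criteria_table(fits, "body_weight_kg", mode = "published")
print(tab, digits = 4)
#>         variable    family k   SEM   MSE  AICc   AIC   BIC converged
#> 1 body_weight_kg  Logistic 3 1.206 1.455 19.84 19.57 23.27      TRUE
#> 2 body_weight_kg  Gompertz 3 1.213 1.471 20.36 20.09 23.79      TRUE
#> 3 body_weight_kg Ratkowsky 3 1.206 1.455 19.84 19.57 23.27      TRUE
#> 4 body_weight_kg Quadratic 3 1.218 1.484 20.77 20.50 24.20      TRUE
#> 5 body_weight_kg     Cubic 4 1.175 1.351 18.64 18.08 23.63      TRUE
#> 6 body_weight_kg       MMF 4 1.169 1.335 18.10 17.54 23.09      TRUE
#> 7 body_weight_kg   Weibull 4 1.176 1.352 18.70 18.14 23.69      TRUE
#> 8 body_weight_kg  Richards 4 1.207 1.425 21.18 20.62 26.17      TRUE

best <- select_best(tab, "AICc")
stage_summary(fits[[best]], variable = "body_weight_kg")
#> <derived_summary> body_weight_kg ~ MMF, R2 = 0.787
#>   inflection: IPy = 5.042 at IPx = 39.71 d
#>   AUC_1_28 = 82.85, AUC_29_56 = 144.52, AUC_57_84 = 208.41
```

Reading the output: `SEM` is the residual standard error `sqrt(SSR/(n−p))`,
the criteria columns are the formulas above under the published counting
convention (`mode = "published"`: k = parameters − 1, effective n = 47; note
the constant gaps BIC − AIC = 3.70 / 5.55 for 3- / 4-parameter rows), and
the winner at this noise level is nearly tied across several families —
exactly the situation the criteria tables of such studies print. The
derived summary then reports the fastest-growth point (here 5.04 kg at
39.7 d for this replicate) and the per-stage cumulative growth in kg·days.

A one-shot pipeline over every configured trait, with a report bundle
(criteria tables, best-model summary, per-family fitted curves at ages
1–84, correlation table, JSON fit store + manifest, run log):

```r
res <- run_pipeline(run_config(seed = 7, outdir = "kid_run"))
res$best
```

The same pipeline is available from a shell via the thin CLI:

```sh
Rscript inst/cli/capricurve.R run --outdir kid_run --seed 7
Rscript inst/cli/capricurve.R simulate --outdir out --seed 1
```

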