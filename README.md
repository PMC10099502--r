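# fpchoice

Where do women obtain contraception when several service delivery points
compete within walking distance — and which aspects of outlet quality are
worth extra travel?  `fpchoice` implements a selection-corrected
discrete-choice workflow for linked household–outlet family-planning data:
each surveyed woman is geolocated, every outlet offering contraception in
her area is audited, and users of modern methods are linked (where
possible) to the outlet where they obtained their method.

The package is aimed at biostatisticians and health-systems researchers
working with outlet-census designs, and at methodologists who want a
tested, fully synthetic-data-driven reference implementation of the
estimation chain.

## The method in brief

1. **Choice sets** — all outlets within a Euclidean radius of the
   residence (3 km in the Kenya-like design, 2 km in the Uganda-like one),
   plus the chosen outlet if it lies beyond the radius (flagged, never
   dropped): `build_choice_sets()`.
2. **Selection correction** — a six-category multinomial logit
   (no method / traditional / long- or short-acting unlinked / long- or
   short-acting linked) over the full surveyed population:

   ln[p(y=n|x)/p(y=1|x)] = x'β_n,

   from which inverse-probability weights 1/p̂(own linked category) correct
   the linked subsample for selection on observables: `mnl()`,
   `compute_ipw()`.
3. **Outlet choice** — random-coefficient (mixed) logit estimated by
   maximum simulated likelihood with shuffled Halton draws,

   U_im = z_im' β_i + ε_im,  β_i ~ N(β, Σ_β) with diagonal Σ_β,

   with a weighted conditional logit as the screening/reference model and
   a likelihood-ratio test between them: `cond_logit()`, `mixed_logit()`,
   `lr_test()`, `screen_attributes()`.
4. **Willingness to travel** — coefficients re-expressed on a common scale
   as wtt_k = −β_k/β_d km per unit of attribute k, with delta-method or
   simulation confidence intervals: `willingness_to_travel()`,
   `wtt_confidence_interval()`.

A synthetic-study generator (`simulate_study()` and presets) emulates the
whole design — outlet census in an outer ring, households in an inner
ring, observable-driven linkage, random-coefficient utilities — under
known truth, so every stage is validated by parameter recovery.
`run_pipeline()` chains all stages reproducibly from one master seed.

## Worked example

```r
library(fpchoice)

site  <- site_preset("kenya", n_outlets_total = 30, n_respondents = 1500)
study <- simulate_study(site, seed = 7, all_linked = TRUE)
cs <- build_choice_sets(study$respondents, study$outlets,
                        choice_radius = 3, links = study$links)

fit <- mixed_logit(cs,
  attributes = c("distance_km", "methods_offered", "open7",
                 "stockout_injectables", "provider_trained", "fp_signage",
                 "public", "pharmacy"),
  random_attributes = c("distance_km", "methods_offered", "public"),
  draws = halton_config(n_draws = 200, seed = 3))
fit
#> Mixed logit, MSL with 200 Halton draws (1500 choosers, unweighted)
#>                      estimate std_error        z p_value
#> distance_km           -0.9851    0.0534 -18.4540  0.0000
#> methods_offered        0.1255    0.0279   4.5035  0.0000
#> open7                  0.1537    0.0992   1.5484  0.1215
#> stockout_injectables   0.0229    0.0937   0.2444  0.8069
#> provider_trained       0.3684    0.0850   4.3355  0.0000
#> fp_signage             0.4988    0.1003   4.9724  0.0000
#> public                 1.9413    0.2005   9.6842  0.0000
#> pharmacy               0.2298    0.1043   2.2030  0.0276
#> sd_distance_km         0.5174    0.1864   2.7755  0.0055
#> sd_methods_offered     0.2931    0.1111   2.6390  0.0083
#> sd_public              1.0535    0.5557   1.8957  0.0580
#> Simulated log-likelihood: -2854.421
```

The generating truth here was distance −1.0/km (SD 0.5), methods +0.15
(SD 0.08), public +2.0 (SD 0.8): means and scales are recovered within
sampling error.  Dividing through by the distance coefficient,

```r
head(wtt_confidence_interval(fit), 3)
#>              attribute     wtt_km      ci_low   ci_high method
#> 1      methods_offered 0.12743698  0.06947185 0.1854021  delta
#> 2                open7 0.15599302 -0.04433216 0.3563182  delta
#> 3 stockout_injectables 0.02325306 -0.16351490 0.2100210  delta
```

a chooser accepts about 0.13 km of extra travel per additional method
offered, and (further down the table) about 2 km for a public outlet —
the willingness-to-travel scale on which attribute preferences become
comparable across samples.

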