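# thermoperf

Thermal performance curves and metabolic thermal sensitivity for
ectotherms.

`thermoperf` is an R package for labs that quantify how body temperature
shapes ectotherm physiology along the two classic axes:

* **Locomotor performance.** Maximum locomotion speeds measured across a
  set of thermal treatments are turned into a thermal performance curve
  (TPC): a unimodal function *P(T)* anchored to zero at the species'
  critical thermal limits (CTmin, CTmax), fitted by nonlinear least
  squares over a catalog of skewable peak families (exponentially
  modified Gaussian, asymmetric logistic, extreme-value/Gumbel) and
  selected by small-sample AICc after an R² ≥ 0.9 screen. From the
  selected curve the package extracts the standard metrics:

  | metric | definition |
  |---|---|
  | V<sub>max</sub> | maximum performance, max *P(T)* |
  | T<sub>o</sub> | optimal temperature, argmax *P(T)* |
  | B<sub>80</sub> | performance breadth, {*T* : *P(T)* ≥ 0.8 V<sub>max</sub>} |
  | TSM | thermal safety margin, CT<sub>max</sub> − T<sub>o</sub> |
  | TTB | thermal tolerance breadth, CT<sub>max</sub> − CT<sub>min</sub> |

* **Resting metabolism.** Open-flow respirometry traces are reduced by
  the lowest-stable-window rule (minimum 100 s running mean of the
  excurrent CO₂ fraction) and converted to rates of CO₂ production,
  VCO₂ = FR·(F<sub>e</sub>CO₂ − F<sub>i</sub>CO₂) in ml CO₂/min. Thermal
  sensitivity is summarised by Q₁₀ = (RMR₂/RMR₁)^(10/(T₂−T₁)) between
  consecutive treatments and across the whole span, and resting
  metabolic rate is modelled on the log10 scale with linear mixed models
  (`log10 RMR ~ treatment + log10 mass + sex` candidates, individual
  random intercept, ML fits, AICc selection, conditional R²),
  mass-adjusted marginal means between species, and tie-corrected
  Kruskal–Wallis/Dunn rank tests.

A first-class synthetic-data generator (`make_default_profiles()`,
`simulate_study()`) reproduces the full trial design of a three-species
comparative study — five treatments (15/25/30/33/36 °C), realistic
sample sizes, individual random effects, measurement noise, and a late
cohort lacking the 33 °C respirometry treatment — so the entire pipeline
is testable without any raw data.

## Worked example

```r
library(thermoperf)

# simulate one species' swimming trials and fit its TPC
prof <- make_default_profiles()$thamnophis_melanogaster
sp   <- simulate_speeds(prof, seed = 1)                  # 38 snakes x 5 treatments
mu   <- tapply(sp$max_speed_cm_s, sp$treatment_c, mean)  # treatment means
anch <- tolerance_summary(prof$species, 8.5, 41.6, n = 38)
res  <- fit_tpc(as.numeric(names(mu)), as.numeric(mu), anch, seed = 1)
derive_metrics(res$best)
#> <thermal_metrics> Thamnophis melanogaster (asym_logistic_peak)
#>   Vmax = 73.2 cm/s at To = 28.6 C
#>   B80 = [25.6, 31.1] C, TSM = 13.0 C, TTB = 33.1 C
```

The garter snake's optimum sits at 28.6 °C with a 13 °C safety margin
below its critical maximum; it maintains ≥ 80 % of its 73 cm/s top speed
between 25.6 and 31.1 °C. (With noisy data the AICc winner need not be
the generating family — here the 4-parameter asymmetric logistic edges
out the generating Gumbel.)

The full pipeline over all three synthetic species:

```r
sim <- simulate_study(seed = 1)
res <- run_all(speeds = sim$speeds, tolerance = sim$tolerance,
               rmr = sim$rmr, seed = 1, verbose = FALSE)
res$q10
#>                   species q10_15_25 q10_25_30 q10_30_33 q10_33_36 q10_overall
#> 1        Conopsis lineata      2.43      2.21      1.30      2.29        2.15
#> 2    Crotalus polystictus      1.51      1.29      2.28      1.66        1.57
#> 3 Thamnophis melanogaster      2.26      2.42      2.93      1.80        2.31
res$adjusted_means
#>                   species adjusted_mean     se
#> 1        Conopsis lineata         0.358 0.0268
#> 2    Crotalus polystictus         0.381 0.0184
#> 3 Thamnophis melanogaster         0.453 0.0203
```

The rattlesnake shows the weakest metabolic thermal sensitivity (overall
Q₁₀ 1.57 vs ≈ 2.2 for the other two), and after adjusting for body mass
the semiaquatic active forager has the highest marginal mean log10 RMR —
the orderings the comparative study reports.

A command-line interface wraps the same steps
(`inst/cli/thermoperf simulate|tpc|rmr|models|report|validate`).

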