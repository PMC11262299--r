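---
title: "Methods: TPC construction, respirometry reduction, and RMR mixed models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TPC construction, respirometry reduction, and RMR mixed models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoperf)
```

This vignette is the package's own account of its methods: the models
and their assumptions, the tunable parameters, what the synthetic-data
generator does and does not emulate, the numerical choices, and the
known limitations. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. Thermal performance curves

### Model

A thermal performance curve (TPC) maps body temperature $T$ (°C) to a
performance measure $P$ (here maximum swimming speed, cm/s). Biological
constraints: $P \ge 0$, unimodal, and $P = 0$ at and beyond the critical
thermal limits $CT_{min}$ and $CT_{max}$ (loss of righting response).
Three skewable unimodal families are provided (`tpc_family()`):

* **`emg_peak`** — exponentially modified Gaussian,
  $f(T) = a\,\tfrac{\lambda}{2} e^{\lambda(\mu-T)+\lambda^2\sigma^2/2}
  \operatorname{erfc}\!\big(\tfrac{\mu-T+\lambda\sigma^2}{\sqrt2\sigma}\big)$.
  Gaussian rise, exponential fall; in this parameterization the heavy
  tail is always the warm-side one (a mirrored version diverges), so
  the family can be right-skewed or symmetric but not left-skewed.
* **`asym_logistic_peak`** — $a\,s^d(1-s)$ with
  $s = \operatorname{logistic}((T-c)/b)$, normalised so the peak equals
  $a$ (at $T = c + b\log d$). The sign of $b$ mirrors the curve.
* **`gumbel_peak`** — $a\,e^{-e^{-z}-z+1}$, $z=(T-\mu)/\sigma$; peak $a$
  at $\mu$. The sign of $\sigma$ selects which side carries the heavy
  (extreme-value) tail; negative $\sigma$ gives the slow-rise /
  fast-crash shape typical of TPCs.

Allowing negative scale parameters is a deliberate design choice: field
TPCs are predominantly left-skewed, the formulas are silent on sign,
and the mirrored curves are members of the same families.

### Fitting

`fit_family()` fits one family to $(T, P)$ points — by default the five
treatment means, following the convention of fitting species-level mean
performance — plus two *anchor points* $(CT_{min}, 0)$ and
$(CT_{max}, 0)$ entering the weighted least-squares criterion as
ordinary points with weight `anchor_weight` (default 1). Downstream
evaluation is additionally hard-clamped to 0 outside
$[CT_{min}, CT_{max}]$ (`tpc_eval_clamped()`). Anchoring-by-data plus
clamping-by-rule was chosen over hard constraints because it mirrors how
boundary conditions are imposed in practice while keeping every family
differentiable for the optimiser.

Numerics: the model is linear in the amplitude, so $a$ is profiled out
analytically and only the 2–3 shape parameters are optimised —
Nelder–Mead from 20 Latin-hypercube starts over data-driven bounds
(locations span the observed temperatures, scales 3–80 % of their
range, shape parameters log-uniform, sign-flippable scales alternate
sign across starts), followed by a BFGS and a final Nelder–Mead polish
(relative tolerance $10^{-12}$–$10^{-14}$). Fits are deterministic
given `seed`; non-convergence is reported in the `converged` flag, not
masked. The residual sum of squares is floored at $10^{-300}$ only so
that AICc stays finite on numerically perfect fits.

### Selection and derived metrics

`select_tpc()` mirrors the standard workflow: screen candidates at
`r2_floor` (default $R^2 > 0.9$), pick the lowest small-sample AICc,
$AICc = n\log(rss/n) + 2k + 2k(k+1)/(n-k-1)$ (`aicc_ls()`), with ties
broken by fewer parameters then family-name order. Two conventions for
$n$ are provided, because studies that fit treatment means often quote
$n$ as the number of individuals: `n_reported = "individuals"`
(default, reporting parity) and `"n_fit"` (the fitted point count —
statistically the defensible choice, and the one used in the package's
own family-recovery study: inflating $n$ to the individual count makes
the log-likelihood term dominate the parameter penalty and min-AICc
then prefers the most flexible family on almost any noisy draw).

`derive_metrics()` extracts $V_{max}$ and $T_o$ by a 0.01 °C grid over
$[CT_{min}, CT_{max}]$ with golden-section refinement, and the
$B_{80}$ endpoints by root bracketing of $P(T) = 0.8\,V_{max}$ on each
side of the optimum (`uniroot`, $10^{-4}$ °C tolerance). Degenerate
cases are explicit: a clamped curve with two local maxima above the
breadth level is an error (ambiguous optimum); a curve that never falls
below the level before a tolerance limit reports that endpoint *at* the
limit with a warning and a `boundary_warning` flag. TSM and TTB are
exact arithmetic on their inputs, never fitted.

## 2. Respirometry

`stable_mean()` implements the lowest-stable-window rule: the minimum
over all contiguous windows of `window` seconds (default 100 s, the
conventional stability criterion) of the running mean of the excurrent
CO₂ fraction, windows advancing one sample at a time. Uniform sampling
is validated, not resampled — a non-uniform grid indicates a logging
problem that interpolation would hide. `vco2()` applies
$\dot VCO_2 = FR_i(F_eCO_2 - F_iCO_2)$; a negative rate (excurrent
below incurrent) warns but is returned, because silently clamping
baseline drift would hide instrument problems. `q10()` evaluates
$(RMR_2/RMR_1)^{10/(T_2-T_1)}$ after canonicalising $T_2 > T_1$;
`q10_table()` applies it to per-treatment *arithmetic mean* RMR (the
summary statistic is a design choice; the source convention is
unstated) for consecutive treatment pairs and the whole span, leaving
`NA` cells — not errors — where a treatment is missing, since partial
designs are normal (here, a late cohort without 33 °C trials).

## 3. RMR mixed models

Both RMR and body mass are log10-transformed (`log10_prepare()`):
metabolic scaling is a power law, so the log scale linearises the
mass–rate relationship and stabilises variance. Rows with non-positive
rate or mass are dropped with a logged count.

`candidate_set()` builds the seven fixed-effect structures over
categorical treatment (reference 15 °C), log10 mass, and sex —
$\{T,\,M,\,S,\,T{+}M,\,T{+}M{+}S,\,T{+}S,\,T{+}M{+}T{\times}M\}$ — each
with an individual random intercept for the repeated-measures design.
The roster is configurable. `fit_candidates()` fits each by **maximum
likelihood** (not REML: candidates differ in fixed effects, so only ML
likelihoods are comparable), ranks by AICc with
$k = \text{fixed coefficients} + 2$ variance components, and excludes
singular fits from selection with a warning. Conditional $R^2$ follows
the fixed-plus-random over total variance decomposition
$(\sigma_f^2+\sigma_u^2)/(\sigma_f^2+\sigma_u^2+\sigma_e^2)$ with
$\sigma_f^2$ the population variance of the fixed-effect predictor.

`species_adjusted_comparison()` compares species at a common body mass:
`log10 RMR ~ species + log10 mass`, with the species × mass interaction
*tested* first and retained only if significant at `alpha` (default
0.05; both forced paths are available via `retain_interaction`).
Adjusted means are model predictions at the grand mean log10 mass;
pairwise contrasts use the fitted covariance ($t$, residual df),
unadjusted by default (`p_adjust` configurable). The adjusted means are
invariant to recentring mass — a property the tests verify.

`rank_group_tests()` is an authored implementation of the tie-corrected
Kruskal–Wallis $H$ (χ² reference) and Dunn's pairwise $z$ with Holm
adjustment (the adjustment is a design choice; the source convention is
unstated). All-tied data yield $H = 0$, $p = 1$ rather than 0/0. The
implementation is cross-checked against `stats::kruskal.test` and a
hand-evaluated toy in the tests.

## 4. The synthetic world

`make_default_profiles()` encodes one fixed stated world per species,
read from the comparative study's reported values: sample sizes
(33/31/38 swimming, 41/26/36 respirometry, 10/8/7 tolerance), CT means
± SD, the five-treatment design, the log10-scale RMR coefficient
vectors (intercepts −0.944/−0.931/−0.965; offsets rising to
0.381/0.709/0.774 at 36 °C; mass slopes 0.760/0.610/0.674), random
intercept SD 0.1 and residual SD 0.08, flow 100 ml/min, trace noise 2 %
of plateau, speed noise 10 % of $V_{max}$, lognormal individual speed
factors (sdlog 0.1 — between-animal speed variance is unreported; this
is a placeholder exposed in the profile).

**TPC parameters** were solved once (`scripts/solve_profiles.R`) to
match each species' reported optimum as closely as its assigned family
allows *subject to near-zero performance at the CT means* — the
anchored-fitting world is only self-consistent if the generating curve
actually vanishes at its anchors. Because all three families carry
heavy tails, that boundary constraint caps how wide $B_{80}$ can be:
the synthetic breadths are narrower than the published ones, and the
EMG species' optimum sits at 31.8 °C rather than the published 36.7 °C
(the EMG family cannot be left-skewed; the published shape is strongly
so). The published $T_o$/$B_{80}$ are therefore treated as plausibility
anchors, not reproduction targets; cross-species *orderings* (fastest
swimmer, warmest optimum, weakest Q₁₀) are preserved and asserted
end-to-end.

**Masses.** Body-mass distributions are unreported; the profiles use
overlapping log10-normal distributions (means 1.55/1.25/1.50, SD 0.35).
Overlap is deliberate: with widely separated species masses the
common-slope mass adjustment under heterogeneous true slopes
extrapolates, inflating the small species' adjusted mean and destroying
the reported ordering. The real study's samples included juveniles of
the large species and adults of the small one, so overlapping ranges
are also the realistic choice. A consequence of taking the reported
coefficients at face value with gram-scale masses is that implied
excurrent CO₂ fractions are far above what a real analyser reads; this
is immaterial downstream because every reduction is ratio-based, but
the traces should not be mistaken for instrument-realistic ones.

**What a green test establishes.** The generator draws independent
Gaussian noise, exact treatment temperatures, no acclimation drift, no
behavioural refusals, no instrument drift beyond a single exponential
settle-in transient (amplitude 0.5 of plateau, time constant 120 s —
only the minimal-window rule matters downstream). Recovery tests
therefore validate the *machinery* under the stated world, not
robustness to real-data pathologies. Swim trials cap per-segment frame
counts at `duration_cap·frame_rate/5` (a 1.25 cm/s censoring floor),
emulating the protocol guarantee that animals cover five marks within
the 2 min trial.

## 5. Known limitations

* **AICc selection rate.** One acceptance criterion asserts that
  minimum-AICc selection identifies the generating $T{+}M$ structure in
  ≥ 90 % of replicates. With two nested pure-noise extensions in the
  candidate set ($+2$ and $+3$ parameters), min-AICc admits an overfit
  with probability ≈ $P(\chi^2_2 > 4.6) + P(\chi^2_3 > 7.0) \approx
  0.17$, so the achievable rate is ≈ 0.8 regardless of effect sizes.
  The corresponding test is kept at the stated level and fails
  honestly; the coefficient-recovery clauses (±2 SE coverage, mass
  slope within ±0.2) pass. A selector with a consistency-oriented
  penalty (BIC-like) would meet the rate but would not be the stated
  procedure.
* The EMG parameterization cannot produce left-skewed peaks, so one
  species' generating optimum deviates from its published value (the
  ordering across species is unaffected, and with noisy data the
  selected family for that species is usually the Gumbel).
* Degrees of freedom for mixed-model $t$ statistics are not
  Satterthwaite/Kenward–Roger approximations; coefficient tables
  report estimate, SE and $t$ only, and the species contrasts use
  residual df from the fixed-effects comparison model.
* No phylogenetic correction across species, no non-Gaussian response
  families, no O₂-based metabolism or respiratory exchange ratio.
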