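---
title: "Net channel block as a torsadogenic risk screen: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Net channel block as a torsadogenic risk screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnetscore)
```

## The problem

Drug-induced torsades de pointes (TdP) is a polymorphic ventricular
tachycardia historically screened for via hERG (IKr) block and QTc
prolongation alone -- a sensitive but unspecific criterion, because
block of depolarizing currents (late sodium INaL, L-type calcium ICaL,
peak sodium INa) protects against the arrhythmia even when hERG is
blocked. The CiPA initiative addressed this with a mechanistic in-silico
myocyte model and its torsade metric score (TMS); the net-block score
implemented here is the simple linear alternative: a back-of-envelope
metric computable from nothing but IC50/Hill pairs and an unbound Cmax,
intended for quick screening, with the expensive simulation reserved
for compounds that do not screen as low-risk.

## The model

Fractional block of a channel at unbound concentration $C$ (µM) follows
the Hill equation

$$\%block = 100\,\frac{C^{h}}{C^{h} + IC_{50}^{h}},$$

and the net-block score at a Cmax multiple $m$ is

$$B_{net} = \sum_i R_i - \sum_j D_j,$$

the percent block of the repolarizing current (IKr) minus the summed
percent blocks of the three depolarizing currents, all evaluated at
$C = m \cdot C_{max,free}$. Higher values mean more unopposed
repolarization block, hence higher predicted TdP risk; this orientation
is defined once in the scoring module and consumed as configuration by
the evaluation functions, never inferred from data.

The dynamic variant replaces the static IKr term with an Emax-scaled
Hill curve, $100\,E_{max}\,C^{h}/(C^{h}+IC_{50,dyn}^{h})$, evaluated at
1× Cmax, with the depolarizing terms kept static at 1× Cmax. The source
material for the dynamic parameters specifies the inputs (a dynamic
IC50 and a maximal inhibition at therapeutic concentration) but not the
functional form; the Emax-scaled Hill curve is this package's
interpretation, isolated in `dynamic_percent_block()` so an alternative
form is a one-line swap.

## Parameters that matter

* `multiple` (default **5**): the Cmax multiple for the static score.
  Five-fold was the best-performing choice among 1×/5×/10× in the
  screening study this design follows; 1× and 10× remain available.
* Hill coefficient absent (default **1.0**, flagged): single-site block
  is the conventional prior, but the default is never silent -- results
  carry a `hill_defaulted` flag.
* Censored IC50 ("> X"): evaluated **at the bound** and flagged
  (`ic50_censored_bound`). For IKr this overestimates block and
  therefore risk; for depolarizing channels it underestimates their
  protective block, which also errs on the side of flagging risk. Both
  directions are conservative for screening, which is why censored
  records are scored rather than rejected.
* Units are fixed to µM everywhere. No unit auto-detection: silent unit
  coercion is the dominant error mode for potency tables, so mixed-unit
  sources must be converted by the user.
* Missing depolarizing fits contribute **0 block but stay visible** in
  `missing_channels`: hERG-only literature records must be scorable for
  screening, yet the output must show they are one-sided.

## Evaluation statistics

Three-level risk labels (low / intermediate / high) are evaluated only
through the two conventional dichotomies: low vs intermediate+high, and
low+intermediate vs high. ROC AUC uses the midrank Mann–Whitney
estimator (ties count half), which is deterministic and matches the
standard probabilistic reading of AUC. The logistic model is
univariable maximum likelihood, fitted by Newton iteration on a
standardised score to a gradient norm below 1e-8, reporting the
likelihood-ratio $\chi^2 = 2(LL_{model} - LL_{null})$; which dichotomy
feeds it is selectable and defaults to low-vs-rest (the source study
does not state its binarization). Complete/quasi-complete separation is
detected geometrically (touching class score ranges) and reported
rather than masked: the fit stops at a capped iteration with
`converged = FALSE` and the last stable $\chi^2$. The t-test defaults
to Welch's unequal-variance form (the pooled Student form is a flag)
because nothing guarantees equal variances between risk groups; raw
p-values are reported with no multiplicity correction, matching how
such tables are conventionally presented.

## The synthetic world

`generate_panel()` exists so every scoring and evaluation path is
testable without any external download. It emulates the *statistical
shape* of a CiPA-style panel, not its pharmacology:

* 28 drugs, 9 low / 11 intermediate / 8 high (the CiPA category
  sizes); the first 12 in panel order are tagged "training", the rest
  "validation" (a bookkeeping tag with no generative meaning).
* Unbound Cmax log-uniform over $[10^{-3}, 10]$ µM -- potencies in
  literature hERG tables span roughly six orders of magnitude, and only
  the *margin* $\log_{10}(IC_{50}/C_{max})$ enters the score, so the
  Cmax range mostly exercises I/O and numerics.
* hERG margins normal on the log10 scale with category means 0 / 1 /
  2.5 (high / intermediate / low) and sd 0.45: at 5× Cmax these give
  expected IKr blocks near 83%, 33% and 2%, ordering the categories
  while leaving realistic overlap.
* Depolarizing margins mean 1.5, sd 0.5 for every category and channel
  (~14% block per channel at 5×): protective block is present but not
  category-informative, so the risk signal lives in the hERG margin, as
  in the screening setting.
* Hill coefficients uniform on $[0.7, 1.7]$, the span observed in the
  packaged literature hERG table.
* Each depolarizing fit is independently missing with probability
  0.15, mimicking incomplete literature coverage.
* The companion metric is a noisy linear image of the drug's noiseless
  static score at 5×: slope −1 (lower = riskier, like a TMS-style
  reference), intercept 0, Gaussian noise sd 20 -- noise chosen once so
  the companion explains roughly two-thirds to three-quarters of score
  variance, the level of cross-metric agreement typical when two risk
  metrics are compared on small panels.
* Dynamic-hERG parameters for every drug, with `dyn_ic50` ≥ the static
  IC50, `max_inhibition` in [0.55, 0.95), and the *same* Hill exponent
  as the static fit. Sharing the exponent is deliberate: it guarantees
  the dynamic score never exceeds the static score at 1× Cmax, a
  testable consistency property; with differing exponents the curves
  can cross at low concentration and the guarantee would be false.

Risk labels are the generating category, not a threshold on the
realized score, so labels stay noisy relative to scores -- as with real
adjudicated TdP categories, where individual drugs sit in the "wrong"
cluster. One shared RNG stream drives the whole panel; removing a drug
therefore shifts all downstream draws. This is accepted for simplicity
and pinned by a determinism test.

**What a green test does not establish.** The generator draws
independent lognormal margins; it does not simulate action potentials,
channel trapping or state-dependent binding, correlated measurement
error between channels measured in one lab, or the heavy-tailed
variability of real patch-clamp IC50s across laboratories. Recovery
tests therefore validate the *software* (scoring, ranking statistics,
round-trips) under a known world -- they say nothing about clinical
predictive performance, which the original panels' external data would
be needed to assess.

## Numerical choices

* Block is computed as $100/(1+(IC_{50}/C)^h)$ -- stable across the
  full double range -- and clamped to $[0, 100]$ to absorb rounding;
  strict monotonicity in concentration is therefore only representable
  while the block is strictly inside the interval (beyond ~16 decades
  of saturation the value rounds to exactly 0 or 100).
* At the IC50 the implementation returns exactly 50 for every Hill
  exponent (the ratio is exactly 1 in floating point).
* CSV round-trips write each number with the shortest decimal string
  that reads back to the identical double, so write→read is the
  identity on every field including missing-vs-present distinctions.
* Panel sorting breaks score ties alphabetically (case-insensitive) so
  output order is total and reproducible.
* Logistic fitting uses step-halving on the log-likelihood; $\chi^2$ is
  clipped at 0 against rounding on null-like data.

## Known limitations

* The score cannot see binding kinetics: drugs trapped in the hERG
  channel have underestimated static block, which is exactly the gap
  the dynamic variant (and full in-silico simulation) addresses.
* No uncertainty propagation: IC50s and Hills are point estimates, as
  in the screening use the score is designed for.
* No categorical cutoffs are shipped: the cluster borderlines seen in
  published figures are visual, and thresholding is delegated to the
  ROC machinery.
* The packaged hERG table covers the 16 validation compounds only and
  prints no Cmax, so it cannot be scored as shipped -- it exists for
  transcription-integrity testing and as a worked example of censored /
  absent-Hill handling.
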