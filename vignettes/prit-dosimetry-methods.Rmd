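---
title: "Methods: alpha-particle PRIT dosimetry and response analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alpha-particle PRIT dosimetry and response analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pritdose)
```

This vignette documents the models, conventions and numerical choices
behind `pritdose`, in the spirit of a statistical-methods appendix: what
is computed, under which assumptions, which knobs matter, and what the
synthetic-data tests do and do not demonstrate.

## The dosimetric model

### Decay-chain energetics

²²⁵Ac (half-life 9.92 d) heads a chain of four α-emissions
(²²⁵Ac → ²²¹Fr → ²¹⁷At → ²¹³Bi, the last branching 97.8 % through the
²¹³Po α at 8.376 MeV and 2.2 % through its own α at 5.87 MeV). Dosimetry
here assumes **secular equilibrium with total local absorption**: every
daughter decays where the parent decayed, instantaneously on the
dosimetric timescale, and only α-energy counts (β/γ contributions are
excluded). The energy per parent decay is then the branching-weighted
sum of the chain's mean α-energies,

$$E = \sum_i b_i \, \bar E_{\alpha,i} \approx 27.48\ \mathrm{MeV},$$

shipped as a human-readable JSON data file
(`inst/extdata/ac225_chain.json`) compiled from standard evaluated
nuclear data, rather than hard-coded, so the constants are auditable and
replaceable. This is a deliberate simplification: in reality a fraction
of ²¹³Bi formed in blood or tumor redistributes before decaying. The
package offers no daughter-migration model; coefficients should be read
as local-absorption estimates.

### Time-integrated activity

Biodistribution tables carry %IA/g with a mandatory `decay_corrected`
flag, because the correction convention is often unstated in practice
and the two conventions differ by up to 2× over a 240-h study.
Integration always runs on the *physical* (decay-inclusive) curve;
decay-corrected input must pass through `undecay_correct()` first, which
makes the convention explicit and testable.

`integrate_tac()` uses trapezoids over the observed span plus two
extrapolations:

* **Leading segment** — the first observed value is held constant back
  to $t = 0$. Blood activity is maximal immediately post-injection, so
  assuming zero at $t=0$ would bias blood TIA low; for 2-h first samples
  the bias either way is small and holding the value is conservative for
  dose.
* **Tail** — beyond the last sample, the default `physical-decay` model
  contributes $A_\mathrm{last}/\lambda$ (no biological clearance
  assumed), `fitted-monoexponential` fits the last three points for an
  effective rate $\lambda_\mathrm{eff} \ge \lambda$ and contributes
  $A_\mathrm{last}/\lambda_\mathrm{eff}$, and `none` contributes 0. A
  fitted rate slower than physical decay is impossible for a decaying
  tracer and signals a rising (noise-dominated) tail; the integrator
  then falls back to physical decay with a warning.

The physical-decay default is intentionally conservative: it never
understates normal-tissue dose. It also means that for a tissue with
genuine biological clearance the default *overestimates* TIA — for the
synthetic tumor curve below, by about 20 %. Parameter-recovery checks
therefore use the fitted-monoexponential tail, which is exact when the
true tail is monoexponential; the difference between the two is a
modelling choice, not an error, and both are reported with the
`tail_fraction` diagnostic.

### From TIA to dose

With TIA in %IA·h/g (per administered kBq, since %IA is already a
fraction of the injection), the RBE-weighted coefficient is

$$D = \tilde A \times 10 \times 3600 \times E \times
      1.602\,176\,634\times10^{-13} \times 1000 \times \mathrm{RBE}
      \quad [\mathrm{Gy/kBq}],$$

the factors being Bq/g per %IA/g per kBq administered, s/h, MeV per
decay, J/MeV, and g/kg. Dose is per gram of tissue throughout, so organ
masses cancel and no organ-mass table is needed. RBE defaults to 5, the
standard weighting for α-radiation in this setting; every coefficient
records whether it is RBE-weighted, and therapeutic indices refuse to
mix weighted with unweighted values (the RBE cancels in the quotient,
which the tests assert numerically).

Absorbed doses are linear in administered activity, and multi-cycle
doses add with no repair or fractionation correction — appropriate for
ledger-style bookkeeping of cycle doses, not for biologically effective
dose modelling, which is out of scope.

Coefficients are **extrapolated across mass regimens** by scaling with
the ratio of 24-h uptakes, assuming the curve *shape* is unaffected by
receptor saturation at the tumor. For the kidney — where saturation is
not expected — this reproduces the independently integrated value to
within about 1.3 %. For the tumor the same scaling applied to the
printed group means gives 0.206 Gy/kBq where the published table prints
0.170; the published value was presumably derived from unrounded or
absolute (per-tumor) uptake. The package reports its own full-precision
arithmetic and does not force agreement with rounded printed values; the
same policy applies to therapeutic-index quotients (59.7 and 2.43 from
the printed coefficients, where the table prints 60.0 and 2.5).

## Receptor saturation

Tumor capture of the radiohapten is limited by pretargeted antigen
sites. The minimal model reproducing the observed mass dependence is a
single-site Langmuir form with the administered amount $m$ as
free-ligand proxy:

$$\mathrm{uptake}(m) = \frac{100\,B_\mathrm{max}}{K_m + m}
  \ [\%\mathrm{IA/g}],$$

so fractional uptake falls monotonically with mass while the absolute
bound amount $m \cdot \mathrm{uptake}/100$ rises toward $B_\mathrm{max}$.
Two observations determine the model exactly (the package solves the
ratio equation algebraically); more are fitted by least squares on
log-uptake, reflecting multiplicative errors. Calibrating on the two
regimens (0.60 nmol → 10.48 %IA/g; 26.9 nmol → 0.38 %IA/g) gives
$B_\mathrm{max} = 0.1037$ nmol/g and $K_m = 0.3895$ nmol. Data in which
uptake *increases* with mass contradict the model; the fit warns and
returns the best (nearly flat) constrained least-squares curve rather
than a negative capacity.

## Internalization kinetics

The assay summaries are deliberately non-mechanistic: the per-time-point
internalized fraction internalized/(membrane + internalized) — fractions
of *total cell-bound*, not of added activity — and an overall percentage
as the ratio of trapezoidal AUCs of the internalized and total channels
over the observed span, with no extrapolation beyond the assay's 24 h.
Zero-total time points yield a flagged `NA`, never 0. Both summaries are
invariant to uniform rescaling of the two channels, so the activity unit
is immaterial.

## Therapy endpoints and survival statistics

Complete response is a **final-measurement** rule: last recorded volume
at or below 4.2 mm³ (inclusive). An any-time-minimum rule would
misclassify tumors that regress transiently and regrow.

Endpoint times (volume doubling relative to the day-0 baseline, or a
10-mm diameter) are located by linear interpolation between the
bracketing caliper days — the least-surprising convention for
twice-weekly measurements; first-measurement-past-threshold is available
as an option. Animals never reaching the endpoint are censored at last
observation; deaths from other causes count as events at the death time,
with the cause kept as an annotation for sensitivity analyses.

Kaplan–Meier estimation, median survival (smallest $t$ with
$S(t) \le 0.5$, undefined with the last follow-up reported when the
curve stays above 0.5) and the Mantel–Cox log-rank test are implemented
natively — they are core outputs here, not incidental — and are verified
in the tests against hand-computed product-limit and
observed-minus-expected tables and against the independent `survival`
package on censored data. P-values use the 1-df chi-square reference; no
multiple-testing correction is applied.

## The synthetic-data generator

`generator_config()` fixes the emulated study conditions once:

* **Arms**: 37 kBq / 0.60 nmol (low mass) and 296 kBq / 26.9 nmol
  (high mass); sampling at 2, 24, 72, 192, 240 h.
* **Curves**: $A(t) = S\,(e^{-k_c t} - e^{-k_u t})\,e^{-\lambda t}$ with
  $k_u > k_c$, scaled so the 24-h value equals the saturation-model
  prediction (tumor) or the arm's anchor (blood 0.68/0.03, kidney
  0.63/0.47 %IA/g). Defaults: tumor $k_u = 0.2$, $k_c = 0.002$ h⁻¹
  (peak near 23 h, slow retention — the behaviour that makes PRIT
  dosimetrically attractive); blood $k_u = 2$, $k_c = 0.02$; kidney
  $k_u = 1$, $k_c = 0.005$. Only the 24-h values are observationally
  anchored; the shapes are plausible, not fitted to unpublished serial
  tables, and this anchoring is approximate by construction.
* **Noise**: multiplicative lognormal, mean-preserving, CV 0.30 for
  biodistribution (matching the observed SD/mean ≈ 3.66/10.48) — chosen
  over Gaussian because CVs this large would otherwise produce negative
  %IA/g. Group size n = 5 per time point.
* **Internalization**: total binding plateaus after ~1 h (19.0 → 16.4 %
  added activity per 10⁶ cells between 1 and 24 h); the internalized
  share follows $f(t) = c\,(1 - e^{-k_i t})$ with $(c, k_i)$ solved so
  $f(1\,\mathrm h) = 0.09$ and $f(24\,\mathrm h) = 0.28$. The resulting
  AUC-based overall internalized percentage is ≈ 24.7 %; the assay's
  two printed anchors do not pin the early-time shape, so this figure is
  a shape consequence, not a calibration target.
* **Therapy cohorts**: baseline 100 mm³ (CV 0.2); exponential growth at
  $g = \ln 2 / 25$ d⁻¹ with per-animal CV 0.15; measurement CV 0.10
  every 3.5 d over 140 d. Treatment multiplies volume by a single-hit
  surviving fraction $e^{-\mathrm{dose}/D_0}$ with $D_0 = 20$ Gy
  (RBE-weighted), resorbed at 0.1 d⁻¹, after which the survivors regrow.
  Single-hit kill with one parameter is the classical α-particle model
  and suffices for shape emulation: 210 Gy is curative (all volumes far
  below 4.2 mm³ at 140 d) while ~50 Gy gives only transient control.
  The noise CVs matter for the *observed* doubling median: detection of
  a threshold crossing in noisy series is biased early, and at the
  chosen CVs the observed control median stays centred on 25 d.

All generators are pure functions of (config, seed); identical seeds
give bit-identical outputs.

### What passing tests show — and do not

Parameter-recovery tests confirm that the integration and unit chain
recover a *known* generating coefficient (to 1 % noise-free; the median
over 200 noisy replicates at CV 0.30, n = 5, to well under 10 %). They
run on the tumor curve, whose slow kinetics are well resolved by the
2–240 h schedule. They do **not** validate the schedule for fast-peaking
tissues (the blood curve peaks near 2 h, and a 5-point trapezoid
genuinely misses part of that peak — as it would in a real study), nor
the local-absorption assumption, nor the generator's unanchored curve
shapes against real serial data. Therapy-cohort tests mirror the
qualitative anchors (control doubling median in 20–30 d; ≥ 90 % complete
responses at 210 Gy; log-rank p < 10⁻⁴ for well-separated arms) and are
not equality claims about in vivo response rates.

## Numerical conventions

* Internal time unit is hours; public interfaces take d/h/s with
  explicit tags. Half-life unit round-trips are exact to 1e-12.
* All arithmetic is full precision; rounding (coefficients to 3
  decimals, doses to 2–3 significant figures, ratios to 1 decimal) is
  presentation-layer only.
* Degenerate inputs fail loudly: negative times/uptakes, mismatched
  ratio time points, empty chains or cycle lists, fitted tails with < 2
  points, zero-total internalization points, non-positive survival
  times.
* Problem sizes in the tests (200 recovery replicates; cohorts of 10;
  400 draws for the noise-CV check) were chosen as the smallest sizes at
  which the Monte-Carlo error is comfortably inside the asserted
  tolerances.

## Known limitations

* No daughter-migration or microdosimetric model; no β/γ dose; no
  organ-mass–based cross-dose. Human extrapolation is out of scope.
* No fractionation/repair (BED) modelling across cycles.
* The saturation model treats the administered amount as the free-ligand
  concentration proxy and ignores BsAb crosslinking kinetics.
* The generator's curve shapes are anchored only at 24 h; serial-shape
  realism is unverifiable from the available summary values.
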