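# pritdose

Biodistribution-driven α-particle dosimetry and response analysis for
preclinical **pretargeted radioimmunotherapy (PRIT)** with actinium-225.

In three-step PRIT, a bispecific antibody is given first, a clearing agent
removes its circulating fraction, and a small radiolabelled DOTA-hapten is
given last and captured at the tumor. Assessing such a regimen requires
turning serial ex vivo biodistribution data (percent injected activity per
gram, %IA/g) into absorbed doses, and relating those doses to tumor
response and normal-tissue toxicity. `pritdose` implements that chain for
²²⁵Ac and its α-emitting decay chain, for investigators running or
modelling preclinical targeted-α-therapy studies.

## What it computes

**Dosimetry.** Under secular equilibrium and total local absorption of
α-emissions, the energy deposited per parent decay is the
branching-weighted sum of the chain's mean α-energies,
E = Σᵢ bᵢ Eᵢ ≈ 27.5 MeV for ²²⁵Ac. A tissue's time-integrated activity
(TIA, Ã) is the integral of its physical activity–time curve — trapezoids
over the observed span, the first observed value held constant back to
t = 0, and a tail model beyond the last sample (pure physical decay
A_last/λ by default, or a fitted monoexponential A_last/λ_eff). The
RBE-weighted dose coefficient is then

    D [Gy/kBq] = Ã [%IA·h/g] × 10 × 3600 × E × 1.602·10⁻¹³ × 1000 × RBE

with RBE = 5 for α-radiation by default. Absorbed doses scale linearly
with administered activity; multi-cycle doses add; therapeutic indices
are tumor-to-organ coefficient quotients; coefficients are extrapolated
across mass regimens by scaling with the 24-h uptake ratio.

**Binding.** Fractional tumor uptake falls with administered hapten mass
because antigen sites are saturable: uptake(m) = 100·Bmax/(Km + m), with
an exact two-point calibration and least-squares fitting for richer data.
Internalization assays are summarised per time point
(internalized / total cell-bound) and overall (AUC ratio).

**Therapy.** Tumor-volume series are classified for complete response
(final volume ≤ 4.2 mm³), converted to endpoint times (volume doubling or
10-mm diameter, linear interpolation between caliper days), and analysed
with natively implemented Kaplan–Meier product-limit curves, median
survival, and the Mantel–Cox log-rank test.

**Synthetic data.** A seeded generator emulates every input: saturable
uptake-and-clearance tissue curves anchored to 24-h values, lognormal
measurement noise, internalization time courses, and therapy cohorts with
single-hit exponential tumor kill — so the whole pipeline is testable
without animal data.

## Worked example

```r
library(pritdose)

## dose coefficients from a (synthetic) serial biodistribution study
cfg <- generator_config(seed = 42)
bd  <- gen_biodist_study(cfg, arm = "low", cv = 0, n = 1)
fit <- dosimetry(bd, rbe = 5, tail_model = "fitted-monoexponential")
round(coef(fit), 3)
#>  blood kidney  tumor
#>  0.047  0.078  1.855

predict(fit, administered_kbq = 37)[["tumor"]]
#> [1] 68.62711     # Gy to tumor for one 37-kBq cycle of this synthetic arm

## the published dose ledger: 5.670 / 0.095 Gy/kBq at 37 kBq per cycle
tum <- dose_coefficient_value("tumor", 5.670)
kid <- dose_coefficient_value("kidney", 0.095)
signif(absorbed_dose(tum, 37), 2);  round(absorbed_dose(kid, 37), 1)
#> [1] 210
#> [1] 3.5
round(therapeutic_index(tum, kid), 1)
#> [1] 59.7

## receptor saturation from two mass regimens
sat <- fit_saturation(c(0.60, 26.9), c(10.48, 0.38))
round(coef(sat), 4)
#>   bmax     km
#> 0.1037 0.3895   # nmol/g bindable capacity; nmol half-saturation mass

## survival: control cohort vs a 210-Gy arm
ctrl <- gen_therapy_cohort(cfg, 0,   n = 10, group = "control")
trt  <- gen_therapy_cohort(cfg, 210, n = 10, group = "treated", seed = 43)
median_survival(km_fit(ctrl$survival$time_d, ctrl$survival$event))
#> [1] 28.64222    # days to tumor doubling, untreated
sv <- rbind(ctrl$survival, trt$survival)
logrank_test(sv$time_d, sv$event, sv$group)$p.value
#> [1] 2.968367e-06
```

The tumor coefficient of the synthetic arm (1.855 Gy/kBq) is the value
implied by the generator's curve shape anchored at the observed 24-h
uptake of 10.48 %IA/g; the published-coefficient ledger reproduces the
printed 210 / 3.5 Gy doses and the 59.7 kidney therapeutic index.

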