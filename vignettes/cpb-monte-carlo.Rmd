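---
title: "Monte Carlo clinically preventable burden and clinic impact"
author: "cpbsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo clinically preventable burden and clinic impact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpbsim)
```

## The model

The clinically preventable burden (CPB) of a preventive intervention is the
number of quality-adjusted life-years (QALYs) it would save if offered to a
whole target population. `cpbsim` computes CPB for a hypothetical birth cohort
(4,000,000 persons by default) followed over its lifetime, and reports it on
the scale of QALYs saved per 10^3 interventions — a magnitude suited to a small
provider such as a student-run clinic rather than a national program.

For one set of parameter values the deterministic chain is, per age stratum
and event channel (mortality, hospitalization, illness):

1. **Attributable events.** An incidence rate $r$ per 100,000 person-years
   applied to the stratum's person-years $T$ gives the current burden
   $E = rT/10^5$.
2. **Counterfactual burden.** With pre-existing coverage $p$ and per-recipient
   efficacy $e$, the burden that would occur if no one received the
   intervention is $E_0 = E/(1 - pe)$: the observed burden is what remains
   after a fraction $pe$ of $E_0$ has already been averted, and the division
   inverts that.
3. **Effectiveness.** Offering the intervention to everyone only reaches
   those who accept it, so the realised effect is $a \cdot e$ for adherence
   $a$.
4. **Prevented events.** $E_0 \cdot a e$.
5. **QALYs.** Each prevented death counts a full 1 QALY; prevented morbidity
   events carry fractional per-event weights. Channel contributions are
   summed.
6. **Normalisation.** Total QALYs are divided by the number of interventions
   delivered and multiplied by 1,000.

Strata are independent and additive: no transmission dynamics (e.g. indirect
protection of seniors by vaccinating adults) and no discounting of future
QALYs are modelled.

**The intervention denominator.** Published per-intervention rates rarely
state whether "an intervention" is an offer or a delivery. `cpbsim` defaults
to interventions *delivered*, $\sum_s T_s \cdot a$, because an intervention is
most naturally a service actually rendered; with this choice adherence cancels
from the per-intervention rate (both the QALYs saved and the deliveries scale
with $a$). `cohort_model(denominator = "person_years")` or `"cohort"` switch
to offers or to the cohort size. At exactly $a = 0$ the delivered denominator
is 0 with 0 QALYs saved; the rate is defined as 0 in that degenerate case.

## Uncertainty propagation

Each input parameter is known only as a literature range $[\ell, u]$, which
parametrizes a uniform distribution. A simulation draws all parameters
independently, runs the chain, and repeats; the sample of per-intervention
rates is summarised by its mean, sample standard deviation ($n-1$
denominator) and the 0.025/0.975 empirical quantiles (the 95% quantile
interval, computed with the standard linear-interpolation rule so results are
bit-reproducible). The default is $10^6$ iterations; estimates are close to
converged by $10^4$ (see `convergence_trace()`), and the test suite runs at
$10^4$–$10^5$ iterations, a deliberate package choice that keeps the full
suite under a minute while leaving Monte Carlo error an order of magnitude
below every tolerance tested.

As a distributional sensitivity analysis, `input_distribution =
"normal_matched"` replaces each uniform by the normal with identical mean and
variance ($\mu = (\ell+u)/2$, $\sigma = (u-\ell)/\sqrt{12}$). Normal draws can
leave the physical domain, so they are clamped — probabilities to $[0,1]$,
rates, counts and weights to $\ge 0$. Clamping (rather than rejection
sampling) keeps the RNG stream aligned with the draw index, so a seed fully
determines every draw; the resulting point mass at the boundary is negligible
for the bundled ranges, which sit many standard deviations from their
boundaries. Means under the two input families agree within Monte Carlo error
for the bundled models.

Sampling order is the parameter-set order, fixed at construction, which is
what makes `sim_config(seed = )` reproduce samples bit-for-bit.

## The influenza model and its placeholders

The bundled two-stratum (50–64, 65+) influenza-vaccination model carries the
literature ranges that are available: senior influenza-mortality rate
9.4–15.6 per 100,000/yr, mortality efficacy 0.35–0.55, senior coverage
0.43–0.72, adherence 0.75–0.95, illness efficacy 0.10–0.30, and a 0.20–0.40
QALY decrement for the time a patient is seriously sick (applied to the
hospitalization channel). Every other range — the 50–64 stratum's rates and
coverage, hospitalization and illness incidence, hospitalization efficacy,
and the per-illness weight — has no published range and ships as a flagged
placeholder (`note` field) chosen from general influenza epidemiology. The
per-illness weight in particular is small (0.004–0.012), a sick-time utility
decrement of about 0.3 scaled by an illness duration of one to two weeks: a
weight of 0.3 *per illness-event* applied to millions of mild illnesses would
dwarf the mortality contribution and is not credible. Quantities that depend
on placeholders are illustrative only, and no test or reported result treats
them as literature estimates.

## Literature-only rates: the fixed coefficient of variation

Interventions whose published CPB calculations are not detailed enough to
simulate enter with a published mean only. Their standard deviation is
approximated as one third of the mean — a coefficient of variation inside the
~15–40% band observed across the simulated interventions (`cv_estimate()`,
`to_rate_estimate()`). Stored values are exact (`17/3`, not `5.7`); rendered
values truncate to two significant figures, because truncation — not rounding
— is the convention the bundled published table follows (`5.667` prints as
`5.6`, `0.1667` as `0.16`), and truncation reproduces all nine published SDs
exactly. Downstream clinic-impact arithmetic uses the *printed* table values
as inputs, so the bundled `ucc_rates.csv` stores them as printed.

## Clinic impact: products of independent variables

Annual impact multiplies a per-thousand rate $R$ (mean $m_R$, sd $s_R$) by an
annual volume $V$ with year-to-year fluctuation expressed as a standard
deviation $s_V = \mathrm{cv}_V \cdot V$ (default 20%). Rate, volume and the
dollar value of a QALY are treated as independent, so the exact
product-variance identity applies:

$$\mathrm{Var}(RV) = m_R^2 s_V^2 + V^2 s_R^2 + s_R^2 s_V^2.$$

The identity is distribution-free for independent factors, which is why the
test suite can check it against a Monte Carlo oracle with normal draws.
Dollar conversion multiplies by \$132,200/QALY (a conservative 2003 \$100,000
valuation inflated to 2017) and reports thousands of dollars per year. Two SD
conventions exist for the dollar columns: the default `"row"` mode scales the
QALY SD by the cost mean, which is the convention the bundled published
tables follow; `"with_cost_variance"` additionally folds a 20% cost
fluctuation into the product formula (for the obesity row this gives an SD of
about 178 rather than 156 thousand dollars — materially different, which is
how one can tell the published tables did not include it despite a footnote
suggesting otherwise). Totals sum means exactly and sum variances exactly
under independence.

Volume "fluctuation" is interpreted as a standard deviation, not as the
half-width of a uniform; the SD interpretation reproduces the published
per-row SDs.

### Rounding and the published cells

Rendered tables use two significant figures for QALY columns (ties away from
zero) and integers for dollar columns at or above 10 (two significant figures
below). The published table this machinery reproduces is itself internally
inconsistent at the final printed digit: its dollar total equals the sum of
its *rounded* rows while its QALY-SD total uses unrounded rows, and a few
cells (e.g. the obesity dollar mean, 396 vs an exact 396.6) disagree with
exact arithmetic by about one unit in the last digit. The acceptance tests
therefore compare every computed cell to its printed counterpart within one
unit of the last printed digit (or 1% for the handful of dollar cells where
the published rounding drifted slightly further); most cells agree to within
half a digit. Exact values, not rendered ones, flow through all downstream
computation.

## Synthetic fixtures and what passing tests show

`make_product_chain()` builds models whose output is a product of independent
uniforms, with closed-form mean and SD
($E[\prod X_i] = \prod \frac{\ell_i+u_i}{2}$,
$E[X_i^2] = (\ell_i^2 + \ell_i u_i + u_i^2)/3$). These are exact oracles for
the sampler, the summaries and the convergence behaviour, and they exercise
the same code paths as the epidemiological models. They do not emulate real
data: real parameter ranges are correlated in the literature (the same
studies inform several parameters), incidences drift over calendar time, and
the uniform-range representation itself discards any information about
central tendency. Passing the oracle tests shows the propagation machinery is
correct, not that the input ranges faithfully describe any particular
disease.

## Known limitations

* Independence everywhere: between parameters, between services in a menu,
  and between rate, volume and cost. Correlated inputs would require a joint
  sampling model the range format cannot express.
* No referral-attribution model: QALYs from services completed elsewhere
  after a referral are fully credited to the referring clinic.
* The counterfactual inversion assumes homogeneous coverage and efficacy
  within a stratum.
* Cost per QALY is a single 2017 constant; no inflation machinery is
  included.
* The influenza model's placeholder ranges bound what its simulated totals
  can mean (see above).

## Reproducing the bundled analyses

```{r, eval = FALSE}
rates <- ucc_rate_table()
impact <- scenario_impact(services_from_menu(ucc_service_menu("current"),
                                             rates))
print(impact)
roi(impact$total$dollars_mean, economic_assumptions()$annual_budget)

flu <- make_influenza_like(seniors_only = TRUE)
simulate_rate(flu$model, flu$ranges, sim_config(1e5, seed = 1))
```

`scripts/acceptance.R` in the source repository recomputes all headline
quantities from scratch and writes them as JSON.
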