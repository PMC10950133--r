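---
title: "A Markov cohort model for the cost-utility of hearing-aid provision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model for the cost-utility of hearing-aid provision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The decision problem

Age-related hearing loss is progressive, irreversible and common: roughly a
quarter of people in their sixties and seventies and half of those over 80
live with some degree of it. Hearing aids are the main rehabilitation
instrument, but uptake is leaky at every step: many people never seek care,
some who do are not prescribed a device, some do not buy the prescribed
device, and some buy it and stop using it. `hearcue` implements a
decision-analytic model that prices this leaky pathway: it compares, over a
lifetime, the discounted costs and quality-adjusted life years (QALYs) of
three strategies — no treatment, hearing-aid provision alone, and
hearing-aid provision bundled with a post-purchase support service that
raises long-run compliance — and summarises each pairwise comparison with
the incremental cost-utility ratio (ICUR, incremental euro per QALY) and
the incremental net monetary benefit (INMB, incremental QALYs valued at a
willingness-to-pay threshold net of incremental cost).

```{r}
library(hearcue)
```

## Model structure

The cohort enters at age 55 with normal hearing and is followed in annual
cycles to age 110, so every relevant difference between strategies is
captured over the remaining lifetime. Hearing is classified by the
better-ear threshold into four states — normal (<25 dB), mild (25–44 dB),
moderate (45–64 dB) and severe-to-profound (≥65 dB) — plus death.
Progression is *gradual*: within each row of the transition matrix a
one-step worsening is at least as probable as a two-step jump, which is at
least as probable as a three-step jump, and there is no recovery.

Two structural assumptions keep the model identifiable from the available
inputs:

* **Mortality is state-independent.** Death claims the same gender- and
  age-specific annual probability `q(age)` from every alive state, and the
  surviving mass is split between staying and progressing using
  conditional-on-survival probabilities scaled by `1 - q(age)`. Rows
  therefore sum to one by construction, treatment cannot alter survival,
  and mean life years are identical across arms — a property the test
  suite asserts to 1e-10. Neither hearing loss nor hearing-aid use carries
  an excess-mortality input.
* **Treatment affects quality of life only.** The same progression
  probabilities drive all three arms; compliant aid use changes the
  utility attached to a state (and some cost flows), never the state
  dynamics.

### The uptake journey

In the treatment arms, mass that progresses into a (more severe)
hearing-loss state faces four sequential hurdles: completing the
care-seeking journey up to the ENT specialist, receiving a prescription,
purchasing the device, and using it as prescribed. `uptake_split()` turns
the four stage probabilities into the four terminal outcomes of that
journey. The aid status dimension of the state space records where each
slice of the cohort got stuck:

* `USER_COMPLIANT` — bought the device and uses it; *absorbing*: compliant
  users stay compliant for life, carrying the device across later severity
  progressions without re-entering the journey.
* `OWNER_NONCOMPLIANT` — bought the device but does not use it. They keep
  the sunk purchase cost, accrue unaided utility, no follow-up visits and
  no replacements, and do not re-enter the journey on progression (they
  already own a device). This is the conservative reading of an
  under-specified corner: it neither grants them aided benefits nor
  charges them usage costs.
* `DECLINED` / `NAIVE` — completed the journey without a device, or never
  started it. Both re-enter the journey exactly once per severity, in the
  cycle they progress, at the new severity's probabilities.

The two treatment arms differ in a single number: the compliance
probability. With the post-purchase service it is the surveyed 0.94;
without it the configured decrement (0.36) applies — multiplicatively by
default (`0.94 × (1 − 0.36) = 0.6016`), because the source reports
proportions and relative scaling keeps the result a valid probability for
any baseline; an `absolute` mode (`0.94 − 0.36 = 0.58`) is switchable in
the configuration.

```{r}
p <- default_parameters("male")
uptake_split(p$pathway, "severe", "ha_plus_pps")
compliance_for_arm(p$pathway, "ha_alone")
```

### Cycle order and discounting

Each cycle applies, in order: (1) mortality and hearing transitions; (2)
the uptake journey for newly progressed untreated mass; (3) utility
accrual on the post-transition occupancy; (4) cost accrual; (5)
discounting of both streams by `(1 + r)^(-t)` with `t` completed years
since model start (first cycle undiscounted) and `r = 0.03` per year. No
half-cycle correction is applied — events are valued at cycle end — which
slightly understates accruals relative to a mid-cycle convention but does
so identically in every arm, leaving the incremental results essentially
untouched.

## Valuation rules

**Utilities.** Normal hearing is anchored at 1.0 — the upper bound of the
utility scale — so hearing-loss states are the only quality-of-life
decrements in the model; no anchor below 1 is available from the input
sources, and because every arm shares the anchor it cancels from all
incremental results. Hearing-loss states carry unaided weights, replaced
by aided weights only for compliant users. Two published weight sets are
packaged (`utility_set("base_case")`, `utility_set("alternative")`);
swapping them changes utilities only, never costs, which the tests assert
bit-for-bit.

**Costs** accrue in seven components: the first-visit bundle whenever a
journey is completed (charged even if no prescription follows — the
specialist visit has happened); an annual follow-up bundle per compliant
user; the device at purchase and, while compliant, every 5 years
thereafter (replacement is tracked per purchase *vintage* — an exact
expected-value bookkeeping, since replacement timing depends only on time
since purchase, survival and compliance, all already traced — rather than
as extra Markov states); expected injurious falls priced at the femur
fracture DRG tariff; transport per visit of either kind; and two
productivity components restricted to working age (≤ 64): an annual
excess occupational cost for unaided moderate/severe loss (mitigated for
compliant users by the relative reduction in unemployment between unaided
and aided hearing-impaired workers) and one day of per-capita GDP per
specialist visit.

**Falls.** Baseline incidence is age-banded from 60; below 60 no incidence
estimate exists and the probability is set to 0 rather than extrapolated.
The unaided excess risk is published as an odds ratio and is applied on
the odds scale, `p' = OR·o/(1 + OR·o)` with `o = p/(1-p)`; the aided
mitigation is a hazard ratio applied on the complement scale,
`p' = 1 − (1−p)^HR`. Each conversion is faithful to the measure the
source estimated; with `OR = HR = 1` both collapse to the baseline, and
for `HR ≤ 1 ≤ OR` the aided risk never exceeds the baseline nor the
baseline the unaided risk. Non-compliant owners count as unaided.

```{r}
falls_probability(p$falls, age = 80, aided = FALSE, hearing_impaired = TRUE)
falls_probability(p$falls, age = 80, aided = TRUE, hearing_impaired = TRUE)
```

**Supply mixes.** Visits and devices can be priced through four modes:
the base 50/50 public/private visit mix with the private device price
(which bundles the post-purchase service), private-only, public-tariff
only, and public supply at the private price. The *mercato sociale* and
*mercato riconducibile* market shares are stored and exposed but drive no
default cost formula: no published combination rule exists for them, so
they are left to explicit user-defined mixes rather than guessed.

## Parameters

All inputs live in one validated object (`default_parameters()`,
`load_parameters()` for flat YAML overrides, `validate_parameters()` for
machine-readable violations). The headline settings: willingness-to-pay
16,265 €/QALY (a published marginal-productivity estimate for the Italian
health service; the net-benefit arithmetic of the reference results is
internally consistent at exactly this value), discount rate 0.03/year,
horizon 55–110 years, cycle length 1 year. `param_keys()` lists every
overridable key with its type.

## Synthetic inputs and what they do (not) show

Two inputs are external to any parameter table: the life table and the
hearing-loss progression probabilities. The package generates both
synthetically, and the generators are first-class, tested code:

* `synth_life_table()` builds annual death probabilities from a
  Gompertz–Makeham hazard `h(x) = a + b·e^{c(x−55)}`, the standard
  adult-mortality law, with gender presets shaped to plausible high-income
  mortality (undiscounted cohort life expectancy from 55 of about 30 years
  for men and 34 for women, the female preset living longer); `q(110)` is
  forced to 1 so the horizon closes.
* `synth_transition_model()` builds a gradual-ordered progression matrix
  from adjacent-step rates with skip fractions (defaults 0.25), a faster
  band from age 70 (multiplier 1.40, reflecting the steeper onset of
  hearing loss at older ages), and then calibrates a single global scale
  factor so that the prevalence of any hearing loss among survivors
  matches 25% at age 70 and 50% at age 85 — single representative ages
  inside the ranges reported for the Italian population. The base rates
  are chosen so the calibrated scale lands near 1.

Calibration is one-dimensional on purpose: the reference analyses report
only that a correction was applied to match real-world prevalence, and a
single multiplicative factor is the minimal choice identifiable from
any-hearing-loss targets (per-severity targets would require more
structure than the targets can pin down). Any-hearing-loss prevalence is
monotone in the factor, so golden-section search on the squared error has
a unique optimum; rows are capped at total probability 1 with the capping
reported, and jointly infeasible targets produce a diagnostic carrying the
best achievable prevalence.

What passing tests on this fixture demonstrate is *structural*: occupancy
conservation, life-year invariance, QALY ordering with treatment
intensity, net-benefit identities, calibration recovery of known scale
factors, reproducibility. What they cannot demonstrate is numerical
agreement with analyses built on the real national life tables and the
literature transition probabilities, which are not published at usable
granularity; absolute costs and QALYs on the synthetic fixture are
indicative only. The loaders (`read_life_table()`,
`read_transition_model()`) accept the same CSV formats the generators
emit, so real data can replace the synthetic inputs with no code change.

## Sensitivity analysis defaults

* **One-way (tornado).** Every probability, utility, unit cost and effect
  ratio is varied ±20% of base — ranges are package defaults, overridable
  per parameter — clipped first to its scale and then to joint validity
  (e.g. an aided utility cannot drop below its unaided counterpart; the
  binding bound is found by bisection toward the base value). Bars are
  ordered by INMB width with alphabetical tie-breaks. On the default
  fixture the utility weights produce the widest bars by a clear margin.
* **Probabilistic.** Independent draws per iteration: Beta for
  probabilities and utilities, moment-matched to the mean with SE = 10% of
  the mean; Gamma for unit costs with SE = 20%; log-normal around the
  point estimate (sdlog 0.1) for the falls odds/hazard ratios. No
  correlation structure is imposed — none is documented. Joint validity
  (ordering constraints across parameters) is enforced by redrawing the
  whole set, i.e. truncation to the valid region; draws are sequential
  from one seeded stream, so results are bit-reproducible per seed. The
  conventional 1000 iterations run in about a minute on one CPU.
* **Scenarios.** `run_scenarios()` crosses the four supply modes with
  three uptake assumptions: current dropout, no dropout with current
  compliance (journey stages set to 1), and no dropout with full
  compliance (compliance also 1, in both treatment arms — the decrement is
  zeroed, since the scenario posits full adherence regardless of
  service).

## Numerical choices and problem sizes

Occupancy conservation holds to 1e-10 per cycle; net-benefit identities
to 1e-9; calibration converges to 1e-10 on the scale factor. The unit
test suite runs the full 55-cycle model throughout but keeps Monte-Carlo
sizes small (10–100 iterations), which is ample for the exact-count and
reproducibility properties it checks; the packaged analysis scripts use
1000 iterations. Ties in the tornado ordering break alphabetically so the
output is a deterministic function of the input set.

## Known limitations

* Expected-value cohort only; no individual-level heterogeneity or
  microsimulation mode.
* Mortality independent of hearing state and treatment; if hearing loss
  carries excess mortality the model understates treatment benefit.
* Transition probabilities are age-banded, not continuously age-specific,
  and identical across genders before calibration.
* Dementia, depression and social isolation enter only through the
  utility weights, not as explicit cost streams; battery replacement is
  subsumed in the 5-year device replacement.
* The uptake journey is re-entered only on severity progression; a
  declined patient cannot change their mind within a severity state.
* PSA draws are independent; correlated uncertainty (e.g. between the
  stage probabilities) is not modelled.
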