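---
title: "A decision-tree cost-effectiveness model for insomnia pharmacotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A decision-tree cost-effectiveness model for insomnia pharmacotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insomniaCEA)
```

## The decision problem

Chronic insomnia is common, reduces quality of life, and raises the risk of
three costly adverse events: falls, motor vehicle collisions (MVCs) and
workplace accidents (WPAs). Hypnotic drugs relieve insomnia but can
themselves modify those risks -- classical GABAergic agents such as zolpidem
raise fall and collision risk, while dual orexin receptor antagonists
(lemborexant, suvorexant) appear to lower fall risk relative to untreated
insomnia. `insomniaCEA` implements a decision-tree cost-effectiveness model
that weighs these effects from the perspective of the Japanese healthcare
payer: four strategies (lemborexant, suvorexant, zolpidem immediate release,
untreated insomnia), a six-month horizon with no discounting, outcomes in
quality-adjusted life years (QALYs), and direct medical costs in JPY.

## Model structure

Each strategy is evaluated in two age strata (18--64 and 65+ years, differing
only in baseline event risks) and mixed by population weights. For strategy
$s$ and stratum $a$, with horizon $T = 0.5$ years:

* **Event risks.** Each event's annual probability is the stratum's baseline
  annual risk in good sleepers times a strategy-specific relative effect,
  converted to the horizon by the constant-hazard transform
  $p_T = 1 - (1 - p_{\text{annual}})^{T}$. The relative effects are composed
  exactly as the source literature derives them:
  * *Falls*: a drug's hazard ratio versus untreated insomnia is chained with
    the relative risk of untreated insomnia versus the general population
    (1.48), e.g. $0.68 \times 1.48 = 1.0064$ for lemborexant and
    $0.85 \times 1.48 = 1.258$ for suvorexant. The fall effect applies to all
    patients on a strategy, without response weighting.
  * *MVCs*: untreated insomnia carries an odds ratio of 2.7; the
    zolpidem-derived effect is applied to all three drugs because no
    drug-specific collision data exist for the orexin antagonists.
  * *WPAs*: treatment responders revert to baseline risk, so the strategy
    effect is the response-weighted mixture
    $r \cdot 1 + (1-r) \cdot \text{OR}$ with OR = 1.79
    ($0.207 \times 1.0 + 0.793 \times 1.79 = 1.63$ at the base-case response
    rate). The older stratum's baseline WPA rate is the younger rate scaled
    by the 24.3% employment ratio of the 65+ population.
* **Re-falls.** Groups with more fallers have more falls per faller: a
  linear relationship anchored at 1.957 falls per faller (0.957 extra falls)
  at the survey's faller proportion, with a positive slope, floored at one
  fall per faller. Expected falls per capita are
  $p_{\text{faller}} \times \text{falls-per-faller}(p_{\text{faller}})$.
* **Fall cascade.** Conditional on a fall: 44% receive no care, 48%
  outpatient care only, and 8% are admitted; admissions split 32%
  non-fracture / 68% fracture, fractures split 47% non-hip / 53% hip, giving
  the 2.56% / 2.56% / 2.88% admission cells. Only admissions carry fatality
  risk (6% non-fracture, 0.1% non-hip fracture, 20% hip fracture, implemented
  exactly as printed in the source; the first two labels look transposed, and
  both are plain parameters that a configuration file can swap). Outpatient
  and unattended falls are minor injuries with no death risk.
* **QALYs.** Responders regain the general-population utility norm;
  non-responders lose the chronic-insomnia decrement (0.026 on the EQ-5D-3L
  scale) for the whole horizon. Each expected event subtracts a one-off,
  duration-integrated disutility; non-fracture admissions conservatively
  reuse the plain fall disutility and WPAs carry none. Deaths forfeit half a
  horizon of norm utility (midpoint timing).
* **Costs.** Drug cost per day over $365.25 \times T$ days (six months =
  182.625 days) plus 1.3 physician visits per month over $12 \times T$
  months -- both zero for untreated insomnia, and both pro-rated by
  $1 - p_{\text{death}}/2$ so decedents accrue time-based costs to the
  horizon midpoint -- plus per-event treatment costs over the fall cascade
  and flat unit costs per MVC/WPA.

Events are independent across types and expectations additive; this is a
single-period decision tree, not a state-transition model, so no
competing-risk adjustment is applied within the horizon.

Pairwise comparisons report incremental cost $\Delta C$, incremental effect
$\Delta E$, and either a dominance label or the incremental
cost-effectiveness ratio $\text{ICER} = \Delta C / \Delta E$, computed from
full-precision model outputs (reporting rounds afterwards, because an ICER
recomputed from rounded table entries visibly disagrees with the
full-precision quotient). Weak dominance -- one margin strict, the other zero
-- is labelled dominant/dominated, the standard convention. Net monetary
benefit is $\text{NMB} = \lambda \Delta E - \Delta C$ at willingness-to-pay
$\lambda$ (JPY 5 million/QALY).

## Parameters and uncertainty

Every input is a `parameter_spec`: value, semantic role (which fixes its
admissible domain), optional 95% CI and/or standard error, a distribution
family for probabilistic analysis, and a provenance flag. The reference set
(`reference_parameters()`, also shipped as
`inst/extdata/reference_parameters.yaml`) carries 33 values printed in the
source literature with `provenance = "printed"`. The remaining cells are not
reproduced in the available text; they are realistic placeholder
calibrations flagged `provenance = "placeholder"`, chosen once from Japanese
fee-schedule and epidemiology conventions: baseline annual faller
proportions 0.10 (18--64) and 0.25 (65+) among good sleepers, driver
collision risks 0.4%/0.3%, workplace-accident risk 0.3% among the employed
young, a zolpidem fall hazard ratio of 1.6 versus untreated insomnia, a
collision odds ratio of 2.2 for hypnotic users, a 730 JPY follow-up
consultation fee, a population utility norm of 0.86, fall-cascade unit costs
from 30 000 JPY (outpatient) to 1.5 million JPY (hip fracture), one-off
disutilities of 0.01 (fall), 0.09 (non-hip fracture), 0.27 (hip fracture)
and 0.02 (MVC), a re-fall anchor rate of 0.25 with slope 2.7, equal age
weights, and WASO/LPS scenario response rates with matched decrements.
Because of these placeholders the package reproduces the *qualitative*
published pattern -- lemborexant dominant over both active comparators and
cost-effective against untreated insomnia -- and all of the printed
worked-example arithmetic, but not the published base-case totals, one-way
thresholds or PSA percentages, which depend on the unpublished cells.

* **One-way analysis** (`one_way_analysis()`) varies each eligible parameter
  over its 95% CI when recorded, otherwise $\pm 20\%$ of the base value,
  clipped to the role's domain (probabilities to $[0,1]$, costs to
  non-negative values, relative effects to positive values). The tornado
  outcome is NMB when the base case is dominant (the ICER is undefined or
  unstable near $\Delta E = 0$) and the ICER for genuine trade-offs. A
  perturbation that violates a cross-parameter invariant (the re-fall
  anchor's printed CI dips below one fall per faller) is skipped with a
  logged reason rather than silently clamped.
* **Threshold search** (`threshold_search()`) bisects a user-supplied
  bracket to a relative tolerance of $10^{-6}$ for criteria
  $\Delta C = 0$, $\text{ICER} = \lambda$ or $\text{NMB} = 0$, returning
  "no crossing" when the criterion has one sign across the bracket.
* **Probabilistic analysis** (`run_psa()`) samples every non-degenerate
  parameter independently -- beta for probabilities/fractions/utilities,
  gamma for costs, lognormal for relative effects, normal otherwise, each
  moment-matched to the base value as mean and to the recorded standard
  error (or $(CI_{high}-CI_{low})/3.92$ from a CI, or the conventional 10%
  of the mean) -- and re-runs the full tree per draw, 2000 draws by default.
  Sampling is inverse-CDF with one stream per parameter, seeded from the
  master seed plus a hash of the parameter id, so fixed seeds reproduce
  results bitwise and adding a parameter leaves other streams untouched.
  A value on a support boundary (probability exactly 0 or 1 under a beta)
  degrades to a point mass with a warning. Draws violating cross-parameter
  invariants are resampled with a logged count. No correlation structure is
  imposed: the source describes per-parameter dispersion only.

## Numerical choices and degenerate inputs

* Six months is 0.5 years = 182.625 days for per-day drug costs; visits are
  billed as six whole months. The source gives per-day and per-month unit
  costs but never a day count.
* Odds and hazard ratios are applied multiplicatively to baseline
  probabilities as if they were risk ratios; baseline risks are small and the
  source itself mixes HR/OR/RR multiplicatively.
* A composite annual risk exceeding 1 (possible at extreme one-way or PSA
  values) is clipped to 1 with a warning rather than failing; an annual
  probability of exactly 1 is a degenerate (infinite) hazard and converts to
  a period probability of 1 with a warning.
* A negative expected QALY (possible only under extreme synthetic inputs) is
  floored at zero with a warning.
* The re-fall slope is taken as positive -- falls per faller increase with
  the faller proportion, as the anchoring survey implies. The source
  contains one prose sentence implying the opposite sign that is internally
  inconsistent with its own anchor and is not used.
* The 2.5 (CI 2.0--3.0) mean annual falls per faller that weighted the
  source's regression is carried as a parameter for completeness but has no
  model influence; its tornado span is zero by construction.
* Whether the base case mixes ages by population weights or models one
  averaged cohort is not stated in the source; the package weights
  per-stratum results (a convex combination, exact for a linear aggregate)
  and exposes the pure strata through the scenario runner.
* The WPA response weighting is recomputed from each strategy's own response
  rate; at the printed 0.207 this reproduces the printed 1.63 exactly, and
  scenario response definitions propagate consistently.

## What the synthetic generator emulates

`random_parameters(seed)` draws a complete, always-valid input set from wide
ranges: probabilities and fractions uniform on $[0, 0.5]$ (hospital
admission bounded by the any-care fraction), relative effects log-uniform on
$[0.25, 4]$, costs log-uniform over plausible JPY ranges, the utility norm
uniform on $[0.6, 1]$, and a non-negative re-fall slope. Across seeds the
generated models exercise dominant, dominated and trade-off comparisons,
which is what the property tests need (monotonicity, partition and
death-bound invariants, label classification against a sign-case oracle).
The generator emulates the *structure* of real inputs -- domains, units and
cross-parameter constraints -- not their joint distribution: real parameters
are correlated (costs track severity; risks track age), real response rates
and baseline risks are far better localized, and no placeholder draw claims
clinical realism. Passing property tests therefore demonstrate internal
consistency of the machinery over the whole valid input space, not agreement
with any particular published cohort.

Problem sizes used by the test suite were chosen to keep the full run
desk-scale while leaving Monte-Carlo error negligible: 2000-draw PSA for
end-to-end checks, a 20 000-draw PSA for the law-of-large-numbers check
(under a symmetric, small-dispersion configuration where the model is
locally linear), 1000 random fixtures for the generator census, and 100 for
the monotonicity and partition sweeps.

## Known limitations

* Placeholder inputs make absolute outputs calibration-dependent; only the
  printed worked-example arithmetic and the qualitative comparison pattern
  are anchored to the literature.
* The single-period tree ignores competing risks within the horizon, event
  recurrence (beyond the fall inflation), treatment discontinuation, and
  adverse-event disutilities of the drugs themselves.
* Fatality labels for non-fracture versus non-hip-fracture admissions are
  implemented exactly as printed even though they look transposed; both are
  single configuration entries.
* The PSA samples parameters independently; correlated uncertainty (e.g.
  between response rates of the two orexin antagonists) is out of scope.
* Indirect costs, productivity losses, carer costs and lifetime
  extrapolation are deliberately excluded, matching the payer perspective.

## A worked run

```{r example, eval = FALSE}
ref <- reference_parameters()
results <- evaluate_all(ref)
comparisons <- compare_all(results)
base_case_table(results, comparisons, profile = "paper")

tornado <- one_way_analysis(ref, "lemborexant", "suvorexant")
head(tornado)

psa <- run_psa(ref, seed = 1)
psa_summary(psa)
```
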