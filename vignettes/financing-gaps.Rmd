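---
title: "The financing-gaps framework: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The financing-gaps framework: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fingaps)
```

## The allocation problem

Donors of development assistance for health (DAH) have traditionally
anchored allocation on national income, which penalises economic growth and
ignores how far a country already is from its health goals. The
financing-gaps framework instead allocates against three country-level
financing trajectories, cumulated over a goal horizon:

* **Need (N)** — the cost, in USD, of moving a country from its *expected*
  mortality trend onto the trajectory that reaches an international target;
* **Expected spending (ES)** — the domestic government spending on the
  focus area projected under current behaviour;
* **Potential spending (PS)** — what the country *could* spend, benchmarked
  against the best-performing peers at its income level.

Funds are then allocated by

$$\mathrm{DAH}_i \;=\; \alpha\,\bigl[(N_i - PS_i) \;+\; \beta\,(PS_i - ES_i)\bigr],$$

where $N - PS$ is **Gap A** (the shortfall beyond the country's own
capacity) and $PS - ES$ is **Gap B** (unrealised domestic potential, which
may be negative when a country already outspends its peers). Setting
$\beta = 1$ collapses the rule to $\alpha(N - ES)$, funding the total gap
and thereby penalising domestic spending; $\beta = 0$ gives
$\alpha(N - PS)$, making allocations independent of expected spending;
$\beta < 0$ actively rewards domestic investment. Both weights are donor
choices; the package treats them strictly as inputs, and can instead derive
$\alpha$ from a fixed budget $B$ as
$\alpha = B / \sum_i \max\{0, (N_i - PS_i) + \beta (PS_i - ES_i)\}$, so
allocations exhaust the budget. Negative per-country terms are floored at
zero — an allocation cannot be negative — while Gap B itself is never
clipped.

The package implements the framework end to end for the child-health case:
the goal is an under-five mortality rate (U5MR) of at most 25 deaths per
1000 live births by 2030, and need is costed with a published schedule of
incremental cost per child life saved: \$4205 in low-income, \$6496 in
lower-middle-income and \$10,016 in upper-middle-income countries. No cost
is defined for high-income countries, so they are excluded from the
need/gap/allocation stages (they may still serve as spending-frontier
reference points).

## Stage models

### Expected mortality trend

`fit_mortality_model()` fits pooled OLS of $\ln(\mathrm{U5MR})$ on
$\ln(\mathrm{GDP})$, $\ln(\mathrm{GDP\ pc})$, maternal education (years),
$\ln(1 + \mathrm{DAH\ pc})$, $\ln(1 + \mathrm{GHE\text{-}S\ pc})$ and a
linear time trend centred at the base year (a technology proxy), over the
observed country-years. Design choices, each of which was genuinely open:

* **Shifted logs on the financing regressors.** Many country-years have
  zero DAH per capita; $\ln(1+x)$ keeps them in the sample while matching
  the log transforms used elsewhere in the pipeline. The transform record
  travels with the fitted object.
* **Pooled OLS without country effects.** The canonical model has six
  regressors plus a trend; a `country_effects = TRUE` option exists but is
  off by default, and projection is only supported for the pooled fit.
* **Plain exponentiation for the back-transform.** No smearing or
  half-variance correction is applied; with log-scale residual sd
  $\sigma \approx 0.05$ the implied retransformation bias is
  $\approx \sigma^2/2 \approx 0.1\%$, far below the other uncertainties in
  the exercise. The bias is therefore documented rather than corrected.

`project_expected_trend()` predicts U5MR from the base year + 1 through the
target year using forecast GDP, GDP per capita and education (inputs — the
package never produces macro forecasts), the advancing trend, and **DAH and
GHE-S frozen at base-year values**: the expected trend is the
"no change in donor or government spending" counterfactual. Perturbing
post-base-year financing columns in the panel provably does not move the
projection; the test suite asserts this invariance.

### Required trajectory and need

`required_trajectory()` builds the goal-compliant path as a constant annual
rate of reduction (ARR),

$$\mathrm{ARR} = 1 - \left(\frac{\text{target}}{\text{baseline}}\right)^{1/(T - t_0)},$$

a geometric decline that lands on the target **exactly** at the target year
(verified to $10^{-9}$ relative error). "Annual percent reduction" is read
as a constant proportional step; a continuous-time exponential variant is
selectable (`arr_method`) and produces the identical path. A country whose
baseline is already at or below the target needs no reduction: its required
path is the expected path capped at the target, so it generates no need.

`lives_to_save()` converts rate gaps to deaths:
$\max\{0, \mathrm{U5MR}_{\mathrm{exp}}(t) - \mathrm{U5MR}_{\mathrm{req}}(t)\}/1000
\times \mathrm{births}(t)$. Because 5q0 is a probability per live birth,
live births is the default denominator; total population is available via
`denominator = "population"` for users who prefer the coarser convention.
`compute_need()` multiplies cumulative lives by the income-group unit cost.
Need is reported cumulatively over base year + 1 … target year; per-year
columns are retained. Income group is frozen at the base year so the unit
cost is stable over the horizon.

### Expected spending

`fit_fraction_model()` regresses the child-health fraction of government
health spending on $\ln(\mathrm{GHE\text{-}S\ pc})$ and
$\ln(\mathrm{GDP\ pc})$, pooled over the sub-account country-years. The
fraction is fitted on the raw scale and clipped to $[0,1]$ at prediction
time; a logit link is available (`fraction_link = "logit"`) for users
worried about boundary behaviour. `forecast_expected_spend()` applies the
share to each country's GHE-S path:
$ES = \sum_t \hat f(t)\, \mathrm{GHE\text{-}S\ pc}(t)\, \mathrm{pop}(t)$.
GHE-S forecasts are an *input column*; when absent, a per-country
log-linear trend extrapolation of the observed series can be enabled
explicitly (`extrapolate_ghe = TRUE`) so the tool stays runnable
standalone, with the substitution visible in the configuration.

### Potential spending

`fit_frontier()` stores the base-year cross-section of (GDP per capita,
GHE-S per capita); `evaluate_frontier()` solves the output-oriented,
variable-returns-to-scale data envelopment analysis program

$$\max_{\varphi, \lambda}\ \varphi
\quad\text{s.t.}\quad \textstyle\sum_j \lambda_j y_j \ge \varphi y,\
\sum_j \lambda_j x_j \le x,\ \sum_j \lambda_j = 1,\ \lambda \ge 0,$$

with one input (GDP pc) and one output (GHE-S pc). This is the minimal
faithful reading of a frontier "as a function of GDP per capita"; no
bootstrap bias correction and no multi-input extensions (tax capacity,
governance) are attempted. The program is solved by the simplex LP solver
in `pracma`; the test suite cross-checks it against an independent
brute-force concave-envelope oracle (all pairwise convex combinations) to
$10^{-6}$ relative error on hundreds of random instances.

Numerical niceties that matter in practice:

* the simplex implementation randomises pivot tie-breaks, so the solver is
  wrapped in a locally pinned RNG (caller state untouched) with a fixed
  ladder of pivot seeds and iteration caps — evaluations are
  bit-reproducible and degenerate bases cannot stall a run;
* peer weights below $10^{-9}$ are dropped and peers are reported in
  country-id order;
* for evaluation points below the smallest reference input the VRS program
  is infeasible; the documented fallback returns the best reference output
  at no more input, or the observed output if none exists, flagged
  `feasible = FALSE`;
* the frontier is **never extrapolated**: forecast GDP outside the
  reference range is clamped to the nearest reference point, so potential
  spending for fast-growing countries flattens at the frontier's top — one
  honest route by which expected spending can overtake potential spending
  (a negative Gap B).

The frontier is fitted on a single base-year cross-section rather than the
pooled panel: forecasting then evaluates one fixed frontier at future GDP,
and pooling would mix price levels and trends. Conversion to child health
applies the share model at the *potential* spending level
(counterfactual-consistent); evaluating it at the expected level instead is
available via `ps_fraction_basis = "expected"`.

### Gaps, allocation and rankings

`compute_gaps()` assembles the cumulative totals. `gap_total` is computed
as `gap_a + gap_b` so the decomposition identity holds bitwise, not merely
to rounding. `allocate()` / `allocate_budget()` implement the formula and
its budget-normalised form; `rank_countries()` reproduces the comparison
orderings (GDP per capita ascending; total gap, Gap A, or U5MR descending)
with lexicographic country-id tie-breaks so rankings are deterministic.

## The synthetic panel generator

`generate_panel()` draws country panels with exactly the statistical
structure the estimators assume, so every stage is testable by parameter
recovery without any external data:

* log U5MR is linear in the model's transformed covariates with known
  coefficients and Gaussian log-scale noise (default sd 0.05, a typical
  measurement-error scale for mortality series);
* government health spending per capita is `a * gdp_pc^b` (default
  `a = 0.015`, `b = 0.95`: concave, increasing, and spanning roughly \$6
  per capita at \$1000 GDP pc to \$300 at \$40,000) times a per-country
  efficiency drawn from (0.4, 1];
* the child-health share is linear in log spending and log income
  (defaults give shares of roughly 5–15%, declining with income);
* GDP per capita follows country-specific geometric growth
  (mean 3%/yr, sd 1%); education grows 0.1 years/yr capped at 15; DAH per
  capita is a decreasing function of income, floored at zero and constant
  over time; crude birth rates decline with log income from ~4% to ~1%.

Defaults were chosen once to give a case-study-like cross-section — U5MR
from single digits (high income) to above 100 per 1000 (low income), a
mixture of countries above and below the 25-target, needy countries whose
need exceeds potential spending, and occasional countries whose expected
spending exceeds potential spending. Magnitudes are plausible rather than
calibrated to any real country, and the generator deliberately omits
features of real data: no measurement error in covariates, no spending
shocks or aid volatility, no income-group transitions, no demographic
projection model, and efficiency constant over time. Passing recovery
tests therefore demonstrates internal correctness of the estimators under
their own assumptions, not robustness to real-world misspecification.

Everything is driven by a single integer seed; identical specifications
generate identical panels, and the truth record (coefficients, frontier
parameters, per-country efficiencies) is returned alongside the data for
use as a test oracle.

## Worked example

```{r example, eval = FALSE}
g <- generate_panel(synthetic_spec(n_countries = 30, seed = 7))
cfg <- run_config(alpha = 0.05, beta = 0)
res <- run_all(cfg, g$panel, g$subaccounts)
res$top_need
res$allocation[order(-res$allocation$dah_usd), ][1:5, ]
```

Gap percentages in the top-need table are reported as Gap A over need,
$100\,(N - PS)/N$, and Gap B over potential spending, $100\,(PS - ES)/PS$;
both denominators are a documented convention and recoverable from the raw
columns.

## Test design and problem sizes

The suite verifies each stage against an independent oracle: closed-form
geometric paths against iterated multiplication; lives-to-save against a
year-by-year brute-force evaluation; the DEA LP against the pairwise
concave-envelope enumeration (200 random instances of up to 12 points);
zero-noise exact recovery (to $10^{-8}$) and 200-replicate unbiasedness
screens for both regressions (50 countries × 16 years for mortality; ~300
sub-account rows for the share model); frontier recovery within 5% at
interior GDP for 100 countries placed on a smooth concave curve (the band
covers the piecewise-linear chord error of the convex hull); budget
conservation to $10^{-6}$ relative; and byte-identical end-to-end reruns
of a 30-country pipeline. These sizes keep the whole suite under a minute
on a single core while leaving each check's Monte-Carlo error well inside
its tolerance.

## Known limitations

* Pooled OLS with a common time trend ignores country-level heterogeneity
  in mortality decline; the fixed-effects option exists but cannot be used
  for out-of-sample projection.
* The DEA frontier is a biased (inward) estimator of a smooth frontier at
  finite samples and is sensitive to outliers in the reference set; the
  bootstrap bias corrections from the DEA literature are out of scope.
* Uncertainty is not propagated: no intervals on trends, need, or
  allocations.
* Prepaid private spending is not modelled; the data model leaves the hook
  (the share regression and spending columns would accept it) but no
  estimator is provided.
* All monetary columns must arrive in constant USD of a common base year;
  the package performs no deflation or currency conversion.
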