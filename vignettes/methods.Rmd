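---
title: "Methods: GHGE-minimizing diet optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GHGE-minimizing diet optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the model, its assumptions, the tunable
parameters, the design of the synthetic-data generator, and the
numerical choices made where the design was genuinely open. It states
no empirical result that the package's tests and acceptance script do
not themselves compute.

## The model and its assumptions

A diet is a non-negative vector `x` of mean daily amounts (g/day) over
a fixed taxonomy of 55 food subcategories nested in 15 categories.
The optimizer minimizes total diet-related greenhouse-gas emissions,
`GHGE(x) = sum_k c_k x_k`, over all diets satisfying a set of labeled
linear constraints `lb_j <= a_j' x <= ub_j`.

Assumptions inherited from this modeling tradition:

* **Linearity.** Emissions and nutrient supplies scale linearly with
  amounts. Nutrient interactions (e.g. absorption enhancers) are out
  of scope.
* **Subcategory resolution.** The decision variables are subcategory
  amounts, not individual foods. Each subcategory is represented by
  its consumption-weighted mean nutrient content per 100 g, computed
  from the survey stratum being modeled. Items never consumed can
  enter the optimum only through their subcategory aggregate.
* **As-consumed basis.** Emission coefficients and diary amounts are
  taken to be on the same (as-consumed) weight basis; the literature
  source does not state a raw/cooked convention, so none is imposed.
* **Independent strata.** Males and females are solved as independent
  problems with their own statistics, contents and bounds.
* **System boundary.** Emission coefficients cover production through
  retail; post-retail emissions (transport home, cooking, waste) are
  excluded by construction of the coefficient database.

## Emission database

Literature LCA data points (kg CO2e per kg food) attach to *indicator
products*; an indicator's value is the arithmetic mean of its points,
and a subcategory's coefficient is the unweighted mean of its
indicators, divided by 1,000 to give kg CO2e per gram. Indicator
means are unweighted by study quality because the methodology being
reproduced averages them plainly.

Descriptive uncertainty ranges accompany every indicator:
lower/upper quartiles with four or more points, min–max with two or
three, ±50 % with a single point (±25 % when the single point is a
reliable national estimate). Two choices were open:

* **Quartile convention.** Unstated in the source; linear
  interpolation between order statistics (`stats::quantile` type 7)
  is the default, configurable via `qtype`.
* **Containment.** With skewed samples the mean can fall outside the
  quartile band (e.g. points 0.2, 8, 8, 8, 8 have mean 6.44 but lower
  quartile 8). Because the range is documented as bracketing the mean
  and is purely descriptive — the test suite verifies that altering
  ranges never changes any optimum — the band is widened to contain
  the mean whenever necessary.

Raw gas inventories can be converted with 100-year Global Warming
Potential factors (CH4 = 25, N2O = 298, configurable); literature
values already in CO2e are never converted twice.

## Survey processing

Diary records aggregate to per-subject mean daily subcategory intakes
(sum over the diary divided by the number of distinct diary days; the
design length is 3 days but the code is data-driven). Population
statistics are computed per sex with non-consumers included, because
the acceptability envelope is meant to describe the whole population,
not just consumers.

The percentile definition was unstated (a statistics-package default
was used upstream); this package defaults to the empirical
distribution function with averaging at discontinuities
(`stats::quantile` type 2, the default of the statistical software
used for the original descriptive analysis), configurable via `qtype`.
The choice matters: it moves the `[p5, p90]` box bounds and therefore
the feasible set, which is why it is fixed and documented.

## Constraints

**Nutritional.** Per-day bounds (energy kcal; protein, fiber, alcohol
g; cholesterol, calcium, iron, zinc mg; vitamin B12 µg) become
content-weighted rows. Percent-of-energy bounds (total fat, SFA,
PUFA, carbohydrate, total sugar, free sugar) are linearized exactly
and homogeneously with energy factors of 9/4/4/7 kcal per g of
fat/protein/carbohydrate/alcohol — conventional values supplied as
configuration because the source omits them. The homogeneous form was
chosen over fixing energy at a point because energy itself has a band
(e.g. 2,400–2,460 kcal/day); scaling any diet by λ > 0 preserves
satisfaction of every %-energy row, a property the tests assert.

Free versus intrinsic sugar is classified at the subcategory level
(the source lists food groups, not a formula): sugars of biscuits,
cakes, sweet snacks, milk-based desserts, ice cream, chocolate,
sugar/honey, candies, preserved fruit, juices, soft drinks and
alcoholic beverages count as free; sugars of fruit, vegetables, milk
and plain yogurt — and of any unflagged food — as intrinsic. The
partition always sums to total sugar.

The strict female iron range (17–19 mg/day) ships disabled: the
observed female intake distribution cannot support it (that is the
point of the infeasibility diagnostic), so it is included only on
request (`include_female_iron = TRUE`). Alcohol is bounded to zero as
a male nutrient row and for both sexes through the zero bound on
alcoholic-beverage subcategories.

**Acceptability.** One total-weight band (80–140 % of the observed
mean — full precision internally; the printed 1,825/3,193-style
figures are rounded only for display), 55 subcategory boxes
`[p5, p90]`, and category-level sum constraints. Whether the
category-level constraints applied in addition to subcategory boxes
was ambiguous in the source ("category and subcategory quantities");
both are emitted by default with a switch
(`include_category_sums`), and the subcategory boxes dominate in
practice.

**Healthy.** Policy bounds over registry-flag membership. Healthy
lower bounds deliberately override percentile lower bounds when boxes
are intersected at assembly (pulses observed at `[0, 36.9]` with the
>= 20 g/day rule become `[20, 36.9]`). A syntactically empty box —
for example a subcategory fixed to zero by the percentiles but
required positive by policy — aborts assembly with an error naming
the subcategory.

## Solver

No linear-programming library is available in the supported
environment, so the package ships a deterministic dense two-phase
primal simplex: rows are equilibrated by their largest coefficient,
Dantzig's rule selects the entering column with a permanent switch to
Bland's rule after 200 degenerate pivots (guaranteeing termination),
and ratio-test ties break toward the lowest basis index. Phase-1
feasibility uses a tolerance of `1e-7` scaled by the right-hand side;
pivot tolerance is `1e-9`.

The solver is validated rather than trusted: the suite compares it to
exhaustive vertex enumeration on every <=3-variable fixture (to 1e-9)
and to `boot::simplex` on random programs, and every optimal solution
is re-verified arithmetically against all constraints
(`check_feasible`, normalized tolerance 1e-8). During development the
full-scale problems were additionally cross-checked against an
independent interior-point/dual-simplex implementation and agreed to
machine precision, including on infeasibility calls.

Degenerate optima are real: multiple optimal vertices can exist, so
tests and reports assert on objective values and binding patterns,
never on the full amount vector. Binding is declared at relative
tolerance 1e-6 with an absolute floor of 1e-9, both configurable.

The infeasibility diagnostic removes one suspect constraint at a
time, re-solves, and computes the achievable `[min, max]` of the
suspect quantity by optimizing it in both directions over the
remaining feasible set. Consistency is tested: re-adding a lower
bound anywhere at or below the achievable maximum is feasible, above
it infeasible. When the female iron range is diagnosed as the cause,
the default is to drop the constraint entirely (matching the
published procedure); clamping at the diagnosed maximum is possible
through a custom bounds table.

## Synthetic data: what it emulates and what it does not

The generator produces the three inputs at survey scale: a catalog
(1,119 items, 198 flagged as infant formula, so filtering retains
921), GHGE data points (102 indicators whose point counts cycle
through 1–6, exercising every uncertainty rule), and 3-day diaries
for 2,098 adults aged 18–60 with balanced sexes.

Consumption is zero-inflated log-normal: each subject is a consumer
of a subcategory with a per-subcategory propensity, consumers eat on
a given day with a per-subcategory frequency, and amounts are
log-normal calibrated so that mean intakes match published national
consumption means, which are used as the generator's targets. Seven
staple subcategories are universal (nonzero 5th percentile); a
per-sex list of rare subcategories has a zero 90th percentile; most
subcategories have a zero 5th percentile, as in the real survey.

**Feasibility by construction (plant-then-perturb).** After the
background population is drawn, the shipped constraint set is
assembled from its own statistics and solved; the resulting diet is
planted into 15 % of each sex stratum (as diaries of representative,
noise-free items). Planting pins the percentile boxes around the
planted diet — with more than 10 % of subjects at exactly `x*_k`, the
90th percentile cannot fall below it, and the many zero intakes keep
the 5th percentile below it — so the full problem is feasible by
construction. Because planting itself shifts the consumption-weighted
nutrient contents, the plant is computed on a slightly *tightened*
problem (two-sided bands pulled inward by 0.4 % of their scale, zero
bounds untouched) and the solve–plant cycle is iterated to a fixed
point, verified arithmetically. At very small population sizes
(tens of subjects per sex) the percentile envelope becomes too noisy
for planting and the generator raises an error rather than silently
degrading.

Per-subcategory base compositions and emission levels are fixed
package constants chosen once from food-composition and LCA
literature ranges (red meat rich in iron/zinc/B12 and carrying the
highest per-kg emissions, beef above pork; dairy rich in calcium;
cereals in carbohydrate and fiber; tap water near zero emissions,
bottled water above fresh produce). They were calibrated, before the
acceptance tests were written, so that the default scenario
reproduces the qualitative binding pattern of the study this package
operationalizes — red meat at its policy floor in the
emission-dominated scenario, fruit & vegetables at their 500 g/day
ceiling — which the tests then assert as properties, not as exact
values.

What the generator does **not** emulate: true within-person
day-to-day correlation, under-reporting, seasonal structure, item
substitution patterns, or the real survey's empirical distributions.
A green end-to-end test therefore establishes that the pipeline's
logic is correct on data with the right structure, not that the
published optimized amounts are reproduced — those depend on the
unavailable survey and emission databases.

Scenario dials: `iron_scarce` scales catalog iron by 0.75 so the
achievable female iron maximum sits well below the 17 mg/day bound,
mirroring the published diagnosis (achievable maximum 11.8 mg/day)
without reproducing its exact value; `red_meat_dominated` multiplies
red-meat emission levels by 1.5 to make the ordering unambiguous.
All randomness flows from one scenario seed through deterministic
per-stage sub-seeds; identical scenario and seed give byte-identical
outputs.

## Reporting conventions

Percent changes are rounded half away from zero to integers (matching
the apparent convention of the printed tables: 36.9 → 37, 68.5 → 69);
they are undefined (NA) for a zero baseline, and only the sign
relation `sign(change) = sign(optimized − observed)` is asserted as a
property, since relative changes are base-dependent. Category
contribution shares always sum to 100 % (within 1e-9) when the
nutrient total is positive. Bound annotations follow the published
footnote style: `b` at the 90th percentile, `c` at a nonzero 5th
percentile, `d` fixed to zero by the percentiles, `e` set to zero by
policy.

## Known limitations

* The solver is dense and intended for this problem's scale
  (55 variables, a few hundred rows); it is not a general-purpose LP
  code.
* Uncertainty ranges are descriptive only; no propagation of emission
  uncertainty into the optimum is attempted (by design — the source
  methodology does likewise).
* The free/intrinsic sugar split is a subcategory-level
  approximation; mixed foods inherit their subcategory's class.
* Percentile and quartile conventions are configurable but default to
  single fixed choices; results are only comparable across runs using
  the same conventions.
* The published headline values (optimized GHGE of 1.9/1.6 kg
  CO2e/day, iron maximum 11.8 mg/day) are not reproducible without
  the restricted survey and emission databases; the package
  reproduces the *procedure* and its qualitative outcomes on
  synthetic data.
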