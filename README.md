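# ghgediet

Diet optimization by linear programming: find the food consumption
pattern with the lowest greenhouse-gas emissions (GHGE) that is still
nutritionally adequate, culturally acceptable, and compliant with
food-based dietary guidelines.

## Who this is for

Nutritional epidemiologists and sustainability researchers who have
(1) a food-consumption survey with short-term diaries, (2) a food
composition database, and (3) per-kg emission estimates for foods from
life-cycle-assessment (LCA) literature, and who want to translate
nutrient-based recommendations into concrete, climate-friendly food
patterns for a population.

## The model

Diets are vectors `x = (x_1, ..., x_55)` of daily amounts (g/day) over
55 food subcategories (grouped into 15 categories). The optimizer
solves

```
minimize    GHGE(x) = sum_k c_k x_k
subject to  lb_j <= sum_k a_jk x_k <= ub_j     for every constraint j
            x_k >= 0
```

where `c_k` is the emission coefficient of subcategory `k`
(kg CO2e per g, built from literature data points via "indicator
products") and the constraints come in three families:

* **Nutritional** — dietary-reference-intake bounds for energy and 13
  nutrients. Percent-of-energy bounds (e.g. total fat 24.5–30.8 %E)
  are linearized exactly and homogeneously:
  `p_lb <= 100·E_j·N_j/E_tot <= p_ub` becomes the row pair
  `sum_k (E_j f_jk − p_lb/100 · e_k) x_k >= 0` and
  `sum_k (E_j f_jk − p_ub/100 · e_k) x_k <= 0`,
  valid whatever the total energy.
* **Acceptability** — total diet weight within 80–140 % of the
  observed mean; each subcategory (and category) within the 5th–90th
  percentile of observed consumption, non-consumers included;
  subcategories with both percentiles zero are fixed to zero.
* **Healthy** — red meat 10–30 g/day, processed meat 0, alcoholic
  beverages 0, fruit & vegetables 400–500 g/day, pulses and fish
  >= 20 g/day.

Both sexes are solved as independent problems. When a problem is
infeasible (typically the female iron requirement), the package
reproduces the published diagnostic: drop the suspect constraint,
re-solve, and maximize the suspect nutrient over the remaining
feasible set to report the achievable range.

The LP is solved by a deterministic two-phase primal simplex built
into the package (no LP library is required); it is verified in the
test suite against exhaustive vertex enumeration on small fixtures and
against `boot::simplex`.

## Worked example

All inputs are synthetic (the original survey is not public); the
generator emulates its structure: 2,098 adults aged 18–60, 3-day
diaries, a 1,119-item catalog, and 102 GHGE indicator products.

```r
library(ghgediet)

scenario <- diet_scenario("default_feasible", seed = 1)
art      <- generate_scenario(scenario)
catalog  <- filter_catalog(art$catalog)
#> filter_catalog: retained 921 items, excluded 198

stats    <- survey_stats(art$diary, catalog, sex = "F")
problem  <- build_problem(stats, art$ghge)
solution <- solve_min_ghge(problem)
print(solution)
#> <diet_solution> status=optimal, GHGE=1.748 kg CO2e/day,
#>   total weight=1611.3 g/day, 58 binding constraints

obs <- observed_summary(stats, art$ghge)
cat(sprintf("observed GHGE %.1f vs optimized %.1f kg CO2e/day (%d%%)\n",
            obs$ghge, solution$objective,
            percent_change(obs$ghge, solution$objective)))
#> observed GHGE 3.0 vs optimized 1.7 kg CO2e/day (-41%)
```

The binding report shows which recommendations actually shape the
optimum — cholesterol, fiber and calcium pinned at their lower bounds,
red meat at its 10 g/day floor, fruit & vegetables at the 500 g/day
ceiling:

```r
b <- solution$binding
b[b$kind %in% c("nutritional", "healthy") & !grepl("%E|alcohol", b$label), ]
#>                 label        kind value  lb   ub  side
#>  nutrient:cholesterol nutritional   250 250  300 lower
#>        nutrient:fiber nutritional    24  24   26 lower
#>      nutrient:calcium nutritional   900 900 1100 lower
#>      healthy:red_meat     healthy    10  10   30 lower
#>     healthy:fruit_veg     healthy   500 400  500 upper
#>          healthy:fish     healthy    20  20  Inf lower
```

The infeasibility diagnostic, on a scenario where iron is scarce and
the strict female iron range (17–19 mg/day) is enabled:

```r
art     <- generate_scenario(diet_scenario("iron_scarce", seed = 1))
catalog <- filter_catalog(art$catalog)
stats   <- survey_stats(art$diary, catalog, "F")
problem <- build_problem(stats, art$ghge, include_female_iron = TRUE)
solve_min_ghge(problem)
#> <diet_solution> status=infeasible

diagnose_infeasibility(problem, suspects = "nutrient:iron")
#>           label restores_feasibility achievable_min achievable_max lb ub  gap
#> 1 nutrient:iron                 TRUE           7.36           9.92 17 19 7.08
```

No diet within the acceptability envelope can reach 17 mg/day of iron
(the achievable maximum is 9.9), so the constraint — not the solver —
is the reason no solution exists.

## Command-line entry points

Thin wrappers live in `inst/cli/`:

```sh
Rscript inst/cli/synth.R      --scenario default_feasible --seed 1 --out data/
Rscript inst/cli/build_ghge.R --points data/ghge_points.csv --mapping data/mapping.csv --out data/ghge.csv
Rscript inst/cli/optimize.R   --sex F --catalog data/catalog.csv --diary data/diary.csv --ghge data/ghge.csv --out results/
```

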