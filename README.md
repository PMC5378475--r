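# androdyn

Sex-ratio dynamics and survival statistics for androdioecious nematode
populations.

## The problem

*Caenorhabditis elegans* and its androdioecious relatives consist of
self-fertile hermaphrodites plus rare males: selfing produces males only
through spontaneous X-chromosome nondisjunction (~0.2% in the N2 strain),
whereas outcrossing produces 50% males. A male-secreted ascaroside pheromone
shortens male lifespan and depresses male fertility, which raises a
population-level question: how fast would pheromone exposure alone drive a
population back to a primarily hermaphroditic state?

`androdyn` is for quantitative biologists working on this system. It
implements:

* **Progeny bookkeeping and the relative progeny factor** — over a mating
  window of days 1–6 of adulthood, a fixed pool of N₀ males with per-day
  fertile fractions f_d and progeny-per-mating k_d yields expected total
  progeny Σ_d N₀ f_d k_d per condition; the treated/control ratio is the
  relative progeny factor *r* (the measured value for lifelong exposure is
  r = 0.768).
* **The geometric male-frequency recursion** m_X = m₀ · r^X, with the
  generation count to a "primarily hermaphroditic" threshold (default 1%
  males) and its conversion to days (3 d/generation).
* **A stochastic discrete-generation mating-system simulator** with
  male-limited mating probability min(1, c·M/H)·r, selfing at 0.002,
  outcrossing at 0.5, fixed hermaphrodite broods and a population cap —
  plus its exact mean-field recursion.
* **Survival statistics written from scratch** — Kaplan-Meier product-limit
  estimation, the log-rank (Mantel-Cox) test with full hypergeometric
  covariance, mean ± SE lifespan summaries and percent lifespan reduction —
  cross-checked in the tests against the `survival` package.
* **The chemotaxis index** (n_super − n_ctrl)/(n_total − n_origin) with
  mean ± SEM aggregation and t or exact/sampled permutation comparisons.
* **A hypergeometric gene-list overlap test.**
* **A seeded synthetic-data module** (Gompertz lifespans calibrated to
  target means, interpolated fertility schedules, multinomial chemotaxis
  plates, offspring-sex draws) so the whole pipeline is testable without
  animal data, and a JSON-configured `run_pipeline()` with provenance.

## Worked example

How many generations of pheromone exposure until males are effectively gone?

```r
library(androdyn)

male_fraction_trajectory(r = 0.768, generations = 15) |> head(4)
#> # A tibble: 4 × 2
#>   generation male_fraction
#>        <int>         <dbl>
#> 1          0         0.5
#> 2          1         0.384
#> 3          2         0.295
#> 4          3         0.226

generations_to_threshold(r = 0.768, threshold = 0.01, m0 = 0.5)
#> [1] 15

compare_to_benchmark(male_fraction_trajectory(0.768, 20))
#> # A tibble: 1 × 3
#>   reached generation  days
#>   <lgl>        <int> <dbl>
#> 1 TRUE            15    45
```

Starting from the cross-progeny ratio of 50% males, each generation of
exposure multiplies the male fraction by r = 0.768 (50% → 38.4% → 29.5% …),
first dropping below 1% at generation 15 — about 45 days at 3
days/generation, slower than the 12–20 days observed for male disappearance
in wild-type populations, consistent with pheromone killing acting in
tandem with other male-culling forces.

Synthetic survival cohorts calibrated to printed group means reproduce the
lifespan analysis end to end:

```r
rec <- dplyr::bind_rows(
  gen_survival_cohort(40, calibrate_hazard(12.0, aging_rate = 0.25),
                      group = "solitary", seed = 101),
  gen_survival_cohort(80, calibrate_hazard(7.7, aging_rate = 0.25),
                      group = "grouped8", seed = 102)
)
mean_lifespan(rec)
#> # A tibble: 2 × 6
#>   group     mean    se     n n_event method
#>   <chr>    <dbl> <dbl> <int>   <int> <chr>
#> 1 grouped8  7.14 0.401    80      80 arithmetic
#> 2 solitary 11.9  0.647    40      40 arithmetic

glance(logrank_test(rec))
#> # A tibble: 1 × 4
#>   statistic    df       p.value method
#>       <dbl> <int>         <dbl> <chr>
#> 1      37.3     1 0.00000000102 log-rank (Mantel-Cox)

percent_reduction(mean_lifespan(rec), "grouped8", ctrl_group = "solitary")
#> [1] 40.06264
```

The grouped cohort lives 40% shorter than the solitary one in this draw
(the calibration targets imply 35.8% in expectation), and the log-rank test
separates the curves decisively. `autoplot()` methods plot `km_estimate()`
curves and male-fraction trajectories; `vignettes/male-pheromone-demography.Rmd`
documents the models, assumptions and numerical choices in full.

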