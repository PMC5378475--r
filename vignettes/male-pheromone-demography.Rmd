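---
title: "Modelling male-pheromone demography in androdioecious Caenorhabditis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling male-pheromone demography in androdioecious Caenorhabditis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, message=FALSE}
library(androdyn)
library(dplyr)
```

## The biological question

Androdioecious *Caenorhabditis* species consist of self-fertile
hermaphrodites plus rare males. Selfing yields males only through
spontaneous X-chromosome nondisjunction (about 0.2% in the N2 lab strain),
while outcrossing yields 50% males, so any force that suppresses male mating
success pushes a population back towards hermaphroditism. A male-secreted
ascaroside pheromone is such a force: lifelong exposure shortens male
lifespan and depresses male fertility. `androdyn` packages the quantitative
machinery needed to reason about this system: the generational sex-ratio
model, the survival statistics behind the lifespan claims, the chemotaxis
index used to characterise the attractant, and a hypergeometric gene-list
overlap test — all fed, for testing, by a seeded synthetic-data generator.

## The generational model

### Progeny bookkeeping and the relative progeny factor

The bookkeeping treats a fixed pool of $N_0$ males (default 60) that each
have an equal chance of mating on every day $d$ of the mating window
(days 1–6 of adulthood). With $f_d$ the fraction of males fertile on day $d$
and $k_d$ the expected progeny per successful mating, the expected total
progeny of a condition is

$$T = \sum_{d} N_0 \, f_d \, k_d,$$

and the **relative progeny factor** is $r = T_{\text{treated}} /
T_{\text{control}}$. There is no male attrition inside the window: the
printed calculation treats the pool as fixed, and male death over six days
would confound the fertility effect being isolated. $r$ is invariant to
rescaling $N_0$ or multiplying every $k_d$ by a constant, which the tests
verify.

Only two fertility fractions per condition are printed (Day 4: 82% vs 69%;
Day 6: 69% vs 29%), so `gen_fertility_schedules()` fills the window by
linear interpolation, with Day 1 defaulting to fully fertile — an assumption,
exposed as an overridable anchor. Per-day progeny counts were published only
as a bar chart, so the default `progeny_anchors` are illustrative
placeholders; consequently the shipped schedules do **not** reproduce the
published factor, and all downstream work consumes the printed value
$r = 0.768$ directly. `relative_progeny_factor()` exists so users with real
schedules can recompute it.

### The geometric recursion

Treating $r$ as the per-generation multiplier of male production gives

$$m_X = m_0 \, r^X, \qquad m_0 = 0.5,$$

the male fraction after $X$ generations of exposure (the control curve,
$r = 1$, stays at 50%). `generations_to_threshold()` finds the first
generation at which $m_X$ drops below a "primarily hermaphroditic"
threshold. The threshold is a convention, not a published number: we default
to 1% males, which with $r = 0.768$ gives 15 generations — the value quoted
for this model — and expose the 0.2% spontaneous-male baseline as a stricter
alternative. `compare_to_benchmark()` converts generations to days at 3
days/generation, the equivalence implied by the benchmark that males
disappear from wild-type populations in 12–20 days, i.e. 4–7 generations;
the pheromone-only model's 15 generations ≈ 45 days, slower than the
benchmark, consistent with pheromone killing being one of several male-culling
forces acting in tandem.

```{r recursion}
male_fraction_trajectory(0.768, 15) |> tail(3)
generations_to_threshold(0.768, threshold = 0.01, m0 = 0.5)
compare_to_benchmark(male_fraction_trajectory(0.768, 20))
```

### The stochastic extension

`simulate_sex_ratio()` embodies the same biology as an explicit
discrete-generation population. Each generation with $H$ hermaphrodites and
$M$ males, every hermaphrodite independently mates with probability

$$q = \min(1,\, c\,M/H) \cdot r,$$

mated hermaphrodites produce brood-size cross offspring (male w.p. 0.5),
unmated ones self (male w.p. 0.002), and the next generation is
down-sampled without replacement to a cap. Design choices worth making
explicit:

* **Encounter model.** No encounter model was measured; $\min(1, cM/H)$ is
  the simplest male-limited saturating form. The default $c = 10$ is
  near-saturating at balanced sex ratios and male-limited when males are
  scarce. $c$ is a free parameter, and $c = 0$ disables mating entirely.
* **Brood size.** Hermaphrodites contribute a fixed brood of 238 offspring
  regardless of treatment, matching the finding that pheromone leaves the
  self brood unchanged (238.2 ± 5 control vs 240.5 ± 5 treated).
* **Relation to the recursion.** `expected_sex_ratio()` iterates the exact
  conditional expectation of the simulator, $m' = q(m)\cdot 0.5 +
  (1-q(m))\cdot p_{\text{self}}$. In the scarce-male linearisation — small
  $m$, $c = 2$, no selfing males — this is exactly $m' = r\,m$, i.e. the
  geometric recursion; at balanced sex ratios the two models deliberately
  differ, because saturated mating decouples the sex ratio from male
  scarcity. Tests therefore compare the 200-seed mean trajectory against
  `expected_sex_ratio()` (the matched deterministic recursion) in the
  scarce-male regime, at three Monte-Carlo standard errors per generation.
* **Degenerate states.** A generation without hermaphrodites cannot
  reproduce: the trajectory is truncated and flagged `extinct` rather than
  padded or errored.

With mating disabled the male fraction settles at the selfing rate, and
with saturated mating at $r = 1$ it fluctuates around the Mendelian 50%
with variance shrinking as $1/N$ — both are property tests.

## Survival statistics

Lifespan claims rest on per-worm event records (`group`, `day`, `event`;
Day 1 is the first day of adulthood, fractional days allowed).
`km_estimate()` is a from-scratch product-limit estimator with the standard
deaths-before-censorings tie convention; `logrank_test()` implements the
Mantel-Cox test with the full hypergeometric variance–covariance at each
distinct death time and a chi-square reference on $k-1$ degrees of freedom.
Both are cross-checked in the test suite against the `survival` package
(agreement to at least six significant digits on random data) and against
hand-enumerated 2×2 tables; the estimator is also required to reproduce the
empirical survival function exactly on uncensored data.

`mean_lifespan()` reports the figure-legend presentation (mean ± SE, n).
The assays it emulates follow every animal to death, so the arithmetic mean
applies; for censored inputs it switches to the Kaplan-Meier restricted mean
up to the last death, with a Greenwood-type standard error — a documented
behaviour switch recorded in the `method` column. Restricting to the last
death (rather than the last observation) makes the uncensored case collapse
exactly to the arithmetic mean.

`percent_reduction()` is the effect size quoted in the legends,
$100\,(1 - \bar t_{\text{trt}}/\bar t_{\text{ctrl}})$: the printed group
means 12.0 vs 7.7 d (solitary vs eight grouped males) give 35.8%, and
10.9 vs 6.8 d (unmated vs six-days-mated males) give 37.6% — both "more
than 35%".

```{r effect}
percent_reduction(12.0, 7.7)
percent_reduction(10.9, 6.8)
```

`hypergeometric_overlap()` is the upper-tail test for shared membership of
two gene lists in a common universe. The list sizes behind the published
overlap p-value are not printed, so the implementation is validated by
exhaustive enumeration over small universes rather than by reproducing that
number. Two-sided p-values are used throughout and no multiple-testing
correction is applied, matching the per-comparison reporting style; the
t-test is pooled-variance by default with Welch available for
unequal-variance replicate comparisons, and zero-variance inputs follow a
documented total convention (p = 1 for equal means) rather than erroring.

## Chemotaxis

The chemotaxis index is
$(n_{\text{super}} - n_{\text{ctrl}})/(n_{\text{total}} - n_{\text{origin}})$:
worms at the test spot minus worms at the control spot over all worms that
left the origin; worms elsewhere on the plate count only in the denominator,
exactly as the formula's terms dictate. Plates are replicates:
`aggregate_ci()` reports an unweighted mean ± SEM (a single plate gets
SEM 0 with a warning so pipelines stay total), and `compare_ci()` offers
the unpaired t-test or a label-permutation test on the difference of group
means — enumerated exactly whenever the two groups total at most 12 plates
(at most $\binom{12}{6} = 924$ relabellings), sampled with 10,000 resamples
and an add-one estimator otherwise.

## Synthetic data: what it does and does not emulate

The generator exists so every downstream statistic is testable end to end
without animal data. It emulates the *statistical structure* the analyses
assume:

* **Mortality** is Gompertz, $h(t) = a e^{bt}$ — the field-standard ageing
  hazard. Only group means ± SE were printed, so the shape is a modelling
  choice; `calibrate_hazard()` root-finds $a$ (quadrature mean, tolerance
  well under $10^{-6}$ d) so a cohort's expected mean matches any printed
  group mean, and $b = 0$ recovers the exponential for analytic checks.
  Cohorts default to no censoring, as in the assays.
* **Fertility schedules** interpolate the printed Day 4/Day 6 anchors.
* **Chemotaxis plates** are multinomial over
  {supernatant, control, origin, elsewhere}.
* **Offspring sexes** are Bernoulli draws at 0.002 (selfing) or 0.5 (cross).

It does not emulate inter-plate overdispersion, day-resolution scoring,
worm-to-worm frailty, or any physiology (body size, fat staining,
transcriptomes, developmental staging). Passing tests therefore certify the
statistical machinery under the stated models, not the biology of any real
cohort.

Every generator takes a mandatory integer seed and uses one private RNG
stream per call (the caller's RNG state is untouched), so identical inputs
give bit-identical outputs.

## Pipeline and reproducibility

`run_pipeline()` executes configured stages — synthetic cohorts through
KM/log-rank/summaries, deterministic trajectories with threshold crossing,
chemotaxis generation and comparison — from a versioned JSON configuration
(see `inst/extdata/default_config.json`), validated by `validate_config()`
which returns every violation rather than failing on the first. Reports
embed the configuration, a content hash, the seed and the package version;
identical configurations reproduce identical reports, and no record is
dropped between generation and analysis (tested). The default demography
stage emits both the control ($r = 1$) and treated ($r = 0.768$) curves.

## Problem sizes and numerical choices

Monte-Carlo checks in the test suite use sizes chosen to make the relevant
standard errors decisively small while keeping the suite quick: $10^5$
lifespans for calibration recovery, $10^6$ offspring draws (3 binomial SEs
≈ 0.013 percentage points at 0.2%), 1000 null replicates for type-I-error
rates (nominal 0.05 within [0.03, 0.07]), 50 random datasets for
reference agreement, and 200 seeds for the stochastic-demography mean
trajectory at populations capped at 20,000. Threshold crossing uses strict
inequality ($m_X <$ threshold); interpolation clips to [0, 1]; permutation
p-values use a $10^{-12}$ relative tolerance when comparing resampled to
observed statistics so ties are not lost to floating-point noise.

## Known limitations

* The recursion treats $r$ as generation-invariant; any interaction between
  mating-induced male death and pheromone exposure is excluded by design.
* The encounter model, generation time (3 d) and hermaphroditic threshold
  (1%) are conventions; conclusions that depend on them should be swept.
* The bookkeeping is a deterministic expectation, matching how the printed
  calculation reads; sampled-mating variability enters only through the
  stochastic simulator.
* No genetics beyond sex determination: no genotypes, linkage, inbreeding
  or spatial structure.
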