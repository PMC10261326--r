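---
title: "Diet models behind complementary feeding recommendations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diet models behind complementary feeding recommendations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfrlp)
library(dplyr)
```

## The problem

Breast-fed infants and young children (6--23 months) in food-insecure
settings often cannot reach recommended micronutrient intakes from the
foods their communities actually eat. cfrlp asks three questions about a
target group (an age band crossed with a livelihood or community
stratum), using nothing but that group's 24-hour dietary recalls, a food
composition table and a set of Recommended Nutrient Intakes (RNI):

1. Which of the eleven target micronutrients (calcium, iron, zinc,
   vitamin A, riboflavin, thiamin, niacin, vitamin B6, folate, vitamin
   B12, vitamin C) are *problem nutrients* -- unreachable, or reachable
   only at the expense of other nutrients, within observed dietary
   patterns?
2. Which food subgroups are the best locally available sources of
   multiple nutrients?
3. Which small set of complementary feeding recommendations (CFR) --
   promoted weekly consumption levels of food groups or subgroups, on
   top of breast-feeding on demand -- best protects nutrient adequacy at
   the *population* level, and can one consolidated set serve all three
   age bands?

## From recalls to a weekly diet model

All modelling is at the 7-day scale. For one target group, a single 24-h
recall per child is expanded to a week (multiplied by 7), and three
families of constraints define the space of "realistic" diets:

* **Energy equality.** The modelled diet's energy equals the group's
  average requirement, `7 E` kcal per week. Breast milk is a fixed term,
  never a decision variable: the default assumption is an intake of
  570/520/420 g/day at 6--8/9--11/12--23 months with an energy density
  of 0.66 kcal/g (2.76 kJ/g), contributing 67/55/39 % of the median
  energy requirement. Complementary foods must supply exactly the rest.
* **Food group and subgroup serving bounds.** Per child, daily servings
  of a group are summed grams over member foods divided by each food's
  portion size; weekly bounds are the 10th and 90th percentiles of 7
  times that per-child distribution.
* **Item gram bounds.** Weekly grams per food are bounded by the
  10th/90th percentiles of the per-child weekly-gram distribution.

Portion sizes are *median consumer portions*: the median daily grams
among the children who actually ate the food. Percentiles use linear
interpolation between order statistics (R's default type 7); the
convention is configurable and logged. Bound distributions include
non-consumers as zeros by default, so rarely eaten foods get a genuinely
attainable zero lower bound; a consumers-only switch exists because
survey practice varies. Foods consumed by fewer than two children keep
bounds `(0, 7 x observed grams)` so every reported food stays
modellable. Condiments, foods of no nutritional value, therapeutic
foods and foods deemed uncommon are excluded upstream, with a logged
provenance count.

Energy is stored internally in kcal; kilojoules appear only at
presentation, converted with the exact factor 4.184.

## The linear programs

Decision variables are continuous weekly servings per food
(fractional servings are meaningful weekly frequencies; an
integer-presentation mode exists for reporting). Three objectives are
solved over the same constraint polytope:

* **Nutritionally best diet.** The published description of this
  analysis names the optimization but not its algebra, so the objective
  here is the package's own documented choice: maximize
  $\sum_n z_n$ with auxiliary adequacy scores
  $z_n \le \min(1, \text{intake}_n / \text{RNI}_n)$ per target
  micronutrient. Capping at 1 rewards adequacy across all eleven
  nutrients without over-crediting surpluses. The downstream decision
  rules (problem-nutrient classification, candidate generation) depend
  only on which nutrients fall short, not on the weighting, and the
  property suite verifies the orderings that matter are insensitive to
  this choice. Among alternate optima a second lexicographic pass
  minimizes total absolute deviation of food-group servings from their
  observed medians, making the reported diet deterministic and
  observed-pattern-like.
* **Per-nutrient extremes ("worst case").** For each nutrient, the
  feasible diet minimizing (or maximizing) that nutrient. The minimized
  value is the population-level guarantee: if even the worst feasible
  diet supplies at least 65 % of the RNI, nearly everyone following the
  recommendations is protected.

CFR enter the program as lower bounds (at least `r` servings per week
summed over the targeted group's foods), not equalities: a minimized
diet sits on the bound anyway, so worst-case results are identical
while feasibility is maximal.

### Numerical choices

The solver is the two-phase simplex from the recommended `boot` package
behind a single wrapper, so another backend can be substituted in one
place; instances export to a plain-text LP format for debugging. A
presolve fixes foods with zero gram capacity at zero servings, merges
group rows with identical member sets, drops rows that can never bind
and detects structural infeasibility before solving. A CFR bound that
sits exactly on the matching upper serving bound is emitted as one
equality row rather than a degenerate pair of inequalities -- the
textbook simplex pivot fails on such ties. Energy equality is exact by
default; a configurable relative slack exists for coarse data but
infeasibility is always reported, never silently relaxed. Feasibility
tolerances are 1e-9 on constraint rows; degenerate tableaus are retried
across pivot tolerances (1e-10, 1e-7, 1e-5).

## Decision rules

* **Problem nutrients.** *Absolute*: below 100 % RNI in the best diet
  and in the nutrient's own maximized diet (the requirement cannot be
  met within observed patterns). *Partial*: below 100 % in the best
  diet but reachable in the maximized diet. The comparison is strict:
  exactly 100.0 % is not a problem. Maximized diets are solved one
  nutrient at a time, eleven programs without CFR constraints. Niacin is
  classified like the others; a report note records that
  tryptophan-to-niacin conversion is not modelled, which may overstate
  niacin gaps.
* **Best food sources.** In the best diet, a subgroup (breast milk
  counted as its own subgroup) contributing at least 5 % of a
  nutrient's total for at least five micronutrients. Shares are computed
  on raw diet content, not capped at the RNI, and column-normalize to
  100 % per nutrient.
* **Candidate CFR.** (i) food groups served more in the best diet than
  the observed median (strictly); (ii) best-source subgroups. A
  subgroup replaces its parent group when both fire. The recommended
  frequency is the best-diet servings rounded half-up, clamped to
  `[1, floor(upper bound)]` so printed frequencies are integral;
  frequencies are frozen at generation and never re-optimized per
  subset, keeping the search space finite. Breast milk is never a
  candidate.
* **Screening.** Each candidate alone is evaluated in the eleven
  minimized diets; per nutrient the top two candidates are retained and
  the union truncated to eight by total minimized adequacy. Candidates
  infeasible alone are dropped with a log entry.
* **Systematic search.** Every subset of the screened candidates up to
  size five is evaluated (the cap reflects the practical range of three
  to five recommendations per set; configurable). Ranking: adequate
  nutrients (minimized %RNI at or above 65) descending, then set size
  ascending, then summed minimized %RNI descending, then diet cost
  ascending when a price table is supplied (the tie-break order past
  adequacy and cost is a repository decision), then label order.
  Infeasible subsets stay in the table flagged NF.
* **Consolidation.** Identities -- (level, target label) pairs, so
  "dairy products" matches across bands even when member foods differ
  -- proposed for at least two of the three age bands are retained and
  applied to all bands; singletons are eliminated. Age-specific portion
  sizes and frequencies are maintained; an identity a band never
  proposed gets a frequency derived from that band's best diet by the
  same rounding rule (the published procedure is silent here; the
  choice is flagged per band in the output). Bands where the
  consolidated set cannot satisfy the energy equality report NF. No
  consolidation is attempted across livelihood groups.

## The synthetic study

No recall data are distributed with this package, so a generator
produces complete studies with known ground truth. Its defaults emulate
the survey conditions the pipeline is designed for: 95 children per age
band in each of three livelihood groups (settled, pastoralist,
agro-pastoralist), a 27-food catalog in eight groups, and complementary
diets dominated by dairy, grains, added fats and added sugar (at least
75 % of complementary energy). Energy requirements are set consistent
with the breast-milk assumptions (E = breast-milk energy / energy
fraction: about 561, 624 and 711 kcal/day), so complementary budgets are
about 185, 281 and 434 kcal/day. Portions are lognormal (dispersion
0.4 on the log scale) around age-scaled medians calibrated so expected
complementary energy matches the band budget; each child's grams are
then rescaled to land near the budget with 10 % lognormal noise. Food
choice is independent Bernoulli per (child, food) with skewed
probabilities -- staples near 0.9, rare foods near 0.1.

Because the RNI table and the breast-milk nutrient composition are not
reproduced from any source, the generator ships clearly labelled
synthetic placeholder vectors with plausible magnitudes; real analyses
must supply their own in the study config.

### Planted ground truth, and why it is shaped this way

* **Gaps.** Iron and zinc densities are clamped below an analytically
  derived ceiling: even if the entire complementary energy budget came
  from the least energy-dense food, intake would stay below 90 % of the
  RNI in every band. This guarantees, by construction, that both
  nutrients classify as absolute problem nutrients everywhere --
  mirroring the situation the method is designed to detect.
* **Fixes.** Beans are planted rich in folate (700 µg/100 g) plus
  thiamin, riboflavin, niacin and B6; animal milk in vitamin B12. The
  folate floor is set so that the worst-case adequacy threshold is
  clearable at every band's portion scale with a handful of weekly
  servings, and the four secondary enrichments ensure beans carry at
  least 5 % of at least five micronutrients even when the best diet
  takes only a few dozen grams of them per week.
* **Unique winner.** Bean consumption probabilities are low enough that
  the observed median is zero servings/week while the 90th-percentile
  bound still admits several servings. An under-consumed,
  uniquely-folate-rich subgroup is exactly the situation in which both
  candidate rules fire and no other candidate can deliver folate
  adequacy (every other subgroup's minimized-folate contribution stays
  below the cutoff), so every top-ranked CFR set must contain the
  beans/legumes identity. The recovery of all three plants across all
  nine target groups is asserted in the acceptance suite.

### What passing tests do and do not show

The generator reproduces the *statistical shape* the pipeline assumes:
skewed consumption, lognormal portions, energy-calibrated totals,
age-banded strata. It does not reproduce real food lists, true nutrient
correlation structure (densities are jittered independently),
within-child day-to-day variation (a single recall per child, as in the
survey design), seasonality, or recipe disaggregation. Passing the
planted-truth suite therefore demonstrates that the pipeline's
*inference machinery* recovers known structure from data of this shape
-- not that any particular real population has these nutrient gaps.

## Problem sizes and defaults

| Parameter | Default | Meaning |
|---|---|---|
| `adequacy_cutoff` | 65 (% RNI) | minimized-diet adequacy criterion |
| `rni_cutoff` | 100 (% RNI) | problem-nutrient cutoff (strict `<`) |
| `source_share_pct` / `source_min_nutrients` | 5 / 5 | best-source rule |
| `p_lo` / `p_hi` | 10 / 90 | bound percentiles |
| `keep_k` | 8 | screened candidates entering the search |
| `max_set_size` | 5 | largest CFR combination tested |
| `energy_tolerance` | 0 | relative slack on the energy equality |
| `n_children` | 95 | per age band per livelihood (generator) |

The full default study (9 target groups, 855 simulated children, about
4,000 linear programs) runs in roughly a minute on one core; the unit
and property tests use 10--25 children per band so the whole suite
stays fast. Those sizes are the package's own test-design choice: the
planted effects are strong enough to be recovered at survey scale, and
the properties under test (orderings, completeness, determinism) are
size-invariant.

## Known limitations

* The best-diet objective is a documented stand-in for an unpublished
  optimization; absolute best-diet %RNI values depend on it mildly,
  classifications and CFR selection depend only on threshold crossings.
* Bioavailability enters solely through the choice of RNI column
  (15 % zinc, 5 % iron by default); no phytate or absorption modelling.
* Tryptophan-to-niacin conversion is not computed; niacin problem
  calls may be conservative.
* Usual-intake modelling (within-person variance) is out of scope: one
  recall per child defines the empirical distributions.
* Diet cost participates only as a linear tie-break when a price table
  is supplied; no affordability modelling.

## A worked mini-example

```{r example, message = FALSE}
spec <- synthetic_spec(seed = 7, n_children = 20, livelihoods = "settled")
report <- run_pipeline(simulate = spec)
glance(report)
tidy(report) |>
  filter(target_group == "settled_m6_8", class != "none")
```

The `glance()` row per target group reports the number of problem
nutrients, candidates and the adequate-nutrient count under the
selected recommendations; `tidy()` exposes the per-nutrient
classifications and worst-case %RNI values that the rendered tables
print.
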