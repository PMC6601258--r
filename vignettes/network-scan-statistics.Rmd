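---
title: "Network scan statistics for county-level prescription surveillance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network scan statistics for county-level prescription surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Public claims data report, per county and year, how many prescription
claims and beneficiaries there are in total and how many of them involve
opioids. Surveillance asks: which *connected* groups of counties have
opioid rates that are too high to be chance fluctuations, have those
regions changed over time, and what distinguishes the counties and
prescribers involved? Classical scan software restricts candidate regions
to circles or ellipses around grid points; `netscan` scans over all
connected subgraphs of the county contiguity graph instead, so elongated
corridors (for example along a river valley or interstate) are first-class
candidates.

## Model and statistics

Let each county $i$ have a baseline count $b_i$ (total claims or total
beneficiaries) and an event count $c_i$ (the opioid subset), and let
$C = \sum_i c_i$, $B = \sum_i b_i$ over the whole study area.

**Kulldorff Poisson statistic.** Under the null, $c_i \sim
\mathrm{Poisson}(\mu b_i)$ with a single statewide rate $\mu = C/B$.
Under the alternative for a cluster $Z$, counties inside $Z$ have rate
$\eta$ and counties outside have rate $\mu < \eta$. Writing $c = \sum_{i
\in Z} c_i$, $b = \sum_{i \in Z} b_i$ and $E = C b / B$, the generalized
log likelihood ratio profiles out $(\eta, \mu)$ with $\hat\eta = c/b$,
$\hat\mu = (C-c)/(B-b)$ and equals

$$\log F(Z) = c \log\frac{c}{E} + (C - c) \log\frac{C - c}{C - E}$$

when $c > E$, and $0$ otherwise. The scan is one-sided by construction:
both hypotheses of interest posit an *elevated* rate inside the cluster.
Scores are kept in nats on the log scale; the raw ratio overflows double
precision for realistic county counts.

**Expectation-based Poisson statistic.** To detect change over time
rather than excess over the rest of the state, each county's current
count is compared with an expectation $b_i$ built from its own history —
by default the arithmetic mean of the supplied history years (for a 2015
analysis, the mean of 2013 and 2014). Under the alternative the mean is
inflated by a fold-change $\mu > 1$; profiling over $\mu \ge 1$ gives the
per-cluster log score $c \log (c/b) + b - c$ for $c > b$, else $0$. The
two statistics deliberately answer different questions, and on data with
a persistent hot spot plus a newly changing region they return different
clusters: the Kulldorff scan locks onto the persistently elevated region,
the expectation-based scan onto the region whose rate moved.

**Monte Carlo significance.** The maximum of a scan over thousands of
candidate regions has no usable closed-form null distribution, so
significance is assessed by replication: the year's total event count is
redistributed across counties by a single multinomial draw with
probabilities $b_i / B$ (i.i.d. Poisson counts conditioned on their
total), the full search is re-run on each replicate, and the observed
score is ranked among the replicate maxima,
$p = (1 + \#\{r : S_r \ge S_{obs}\})/(R+1)$. For the expectation-based
statistic the null fixes each county's mean at its history expectation,
so replicates draw independent Poisson counts without conditioning on the
total. Clusters with $p \le \alpha$ (default $0.05$) are flagged
significant. Secondary clusters (found by removing the counties of
higher-ranked clusters and re-searching) are compared against the *same*
null distribution of maxima — a conservative, standard convention.

## The search

Maximizing a scan statistic over connected subgraphs with a size bound is
computationally hard, so the package provides two searches with an
explicit contract between them:

* `exact_best_cluster()` enumerates every connected subset up to
  `max_size` (reverse-search extension, each subset generated exactly
  once) and takes the argmax. It refuses instances whose enumeration
  would exceed a subset budget.
* `search_best_cluster()` grows a cluster greedily from *every* county as
  a seed (repeatedly adding the adjacent county that maximizes the
  statistic, keeping the best prefix), then applies best-improvement
  1-swap local search — add a neighbor, drop a member, or swap, keeping
  the set connected — to the strongest eight seed candidates, and returns
  the best result over all seeds. Eight polish candidates keep the
  replicate loop tractable; on every exhaustively checkable instance
  tried in the test suite the heuristic attains the exact optimum, and
  that equivalence is enforced as an acceptance property rather than
  assumed.

Ties anywhere (equal scores) break toward the lexicographically smallest
sorted member list, so results are deterministic. Disconnected study
areas need no special handling: greedy growth cannot cross components.
`circular_scan()` implements the classical circular-window baseline
(zones = a center county plus its $k$ nearest counties by great-circle
centroid distance, while zone baseline stays within
`max_baseline_fraction` — default 0.5 — of the total); it is included for
comparison and its zones are exempt from the connectivity contract.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `max_size` | 30 | counties | the largest cluster scale of interest in state-level county analyses; configurable |
| `replicates` | 999 | replicates | p-values then have resolution 1/1000 with the add-one estimator; 1000 is available |
| `alpha` | 0.05 | — | conventional significance level for flagging clusters |
| `continuity` | 0.5 | events | floors zero history expectations; an all-zero history would otherwise give unbounded scores, which are artifacts |
| `max_baseline_fraction` | 0.5 | fraction of B | common circular-scan convention |
| `contiguity` | rook | — | "share a boundary" read as a shared border segment; queen (corner contact) available by flag |
| pruning threshold | 0.6 | \|Pearson r\| | multicollinearity cutoff for the characterization covariates |

## Characterizing significant clusters

Counties are labeled 1 when they belong to any significant cluster of the
configured statistic/count kind/year and 0 otherwise. Eight candidate
demographic covariates (percentages of African Americans, American
Indians, males; housing units; Medicaid, Medicare and direct-purchase
insurance access; extreme poverty) are first pruned greedily in that
declared order, dropping any column whose absolute Pearson correlation
with an already-kept column reaches 0.6 — the declared order makes the
"keep one of each correlated group" rule deterministic. A binomial
logistic regression is then reduced by stepwise AIC selection in both
directions from the full model (`MASS::stepAIC`), and coefficients are
reported as odds ratios per covariate unit with Wald p-values; variables
with $p < 0.1$ are flagged. Regressions are intended to be run separately
per year and count kind. Within the top cluster, providers at or above
the 90th-percentile cutoff of *both* opioid beneficiary and opioid claim
counts (nearest rank, ties inclusive — so exactly the top 10% qualify
under distinct values) are profiled per medical specialty.

## The synthetic-data generator

Real claims extracts cannot be redistributed, so every stage is validated
against `simulate_scenario()`, which generates: a grid contiguity graph;
log-normal county baselines (county sizes are right-skewed) with one size
drawn per county and a small log-normal year-to-year jitter (sd 0.05 on
the log scale) — independent per-year redraws would make exposures swing
~50% between years and confound the temporal statistic with baseline
noise, which real county exposures do not exhibit; Poisson events at
background rate $\mu$ outside and $\eta \ge \mu$ inside a connected
injected cluster (grown by random walk when set to `"auto"`); an optional
single-year rate multiplier for a region; normal covariates with
inside/outside means (defaults: Medicaid access 20 vs 15 (sd 4),
African-American percentage 12 vs 18 (sd 7), all others no shift — gaps
sized to the modest odds ratios typical of county characterization);
and a provider layer that splits county totals by a symmetric
Dirichlet-multinomial with opioid counts allocated by multivariate
hypergeometric draws, so provider sums reproduce county totals exactly.

What the generator does *not* emulate: small-cell suppression in public
claims files, survey margins of error, spatially autocorrelated
covariates, provider-level specialty/volume dependence, and real
coastline/island geography. Passing tests therefore demonstrate
statistical correctness of the machinery under the stated generative
model, not robustness to those artifacts.

## Reference validation conditions

The acceptance checks (in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`) run at fixed, pre-declared problem sizes chosen
as the package's reference conditions: 100 random count tuples for
closed-form vs numeric-likelihood agreement (1e-8); 50 random graphs with
at most 12 nodes and size bound at most 6 for heuristic/exact
equivalence; 200 null datasets on a 6×6 grid ($\mu = 0.1$, mean baseline
2000, `max_size` 8, $R = 199$) for type-I calibration against the exact
binomial band around 0.05; 50 datasets on a 10×10 grid with a 6-county
cluster at $\eta = 2\mu$ and mean baseline 5000 (`max_size` 10) for power
and Jaccard recovery; one 3-year study with a persistent cluster
($\eta = 3\mu$) and a region doubling only in the final year for the
temporal contrast; and 100 logistic simulations at $n = 500$ counties
with a single true log-odds slope of 0.7 on the Medicaid covariate (unit
sd, so the effect is per standard deviation) for selection and odds-ratio
recovery, cross-checked against exhaustive $2^8$ AIC enumeration.

## Numerical and degenerate-input choices

* $0 \log 0 = 0$ throughout; with $c = C$ the second Kulldorff term
  vanishes.
* A cluster with zero baseline and positive events is rejected as invalid
  input (it would imply an infinite score); it cannot arise from a valid
  count table, where opioid counts are bounded by totals.
* Nonpositive expectations in the temporal statistic are floored at the
  continuity constant with a logged warning, never silently infinite.
* Score comparisons in the search use an absolute tolerance of 1e-9
  before falling back to the lexicographic tie-break.
* Null multinomial replicates may, with small probability, place more
  events than baseline in a county; this is inherent to conditioning on
  the total and replicates are therefore exempt from the
  `opioid <= total` table validator. Conservation of the total is exact.
* Replicate $r$ draws its seed from a deterministic stream keyed by the
  root seed, so results do not depend on evaluation order.
* Counties present in the graph but missing from the count table are an
  error by default; `allow_missing` zero-fills them with a logged
  warning, matching the convention for suppressed small counts in public
  claims files.

## Known limitations

* The characterization regression ignores spatial correlation between
  neighboring counties, which can understate standard errors.
* The heuristic search carries no optimality guarantee beyond the
  exact-oracle equivalence demonstrated at small scale.
* Boundary-based contiguity uses shared snapped boundary *points* (queen:
  at least one, rook: at least two); exact shared-segment geometry can
  differ on pathological polygon layers.
* The circular baseline uses centroid great-circle distance only;
  elliptical and space-time cylindrical windows are out of scope, as are
  Bernoulli and negative-binomial count models.
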