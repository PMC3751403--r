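---
title: "Models and methods behind rangediv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rangediv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`rangediv` asks whether speciation and extinction rates differ between
geographic regions — hotspot versus the rest of a continent, and
bioclimatic zones within the hotspot — using dated phylogenies of
extant species. This vignette documents the models, the tunable
parameters, the numerical choices, and what the synthetic-data
generators do and do not emulate. Everything here describes what the
code computes; no empirical claim is made that the tests and
`scripts/acceptance.R` do not themselves reproduce.

## From occurrence records to geographic states

Species are assigned states in two steps. First, hotspot membership:
a species is a hotspot (SWBP) species if the majority of its
occurrence records fall inside the union of the zone polygons or
within a buffer of it (default 50 km, great-circle distance to the
polygon boundary via `geosphere`). The buffer exists because a few
species sit slightly outside a formally drawn boundary while being
clearly disjunct from everything else; the original assignments were
made by eye, so a single configurable distance is our reproducible
stand-in for that judgement. Second, zone state within the hotspot: a
species belongs to a single zone if **strictly more than 90%** of its
in-zone records fall there, otherwise to `"both"`. The comparison is
strict because the rule is stated as ">90%"; `assign_zone(c(90, 10))`
is therefore `"both"`.

Point-in-polygon tests treat boundary points as inside (herbarium
coordinates are coarse); a point on the shared edge of two adjacent
zones is assigned to the first zone in map order, a deterministic
tie-break, while a point in the *interior* of two zones is an error
because it means the polygons genuinely overlap. Containment is
evaluated in plain lon/lat (containment needs no projection); only
the buffer involves real distances.

Record filtering is rule-based: per-species bounding boxes and
source-id blacklists, with a removal log so that
`filtered + removed = input` always holds. Which records the original
curation removed is not recoverable; the rule set is a transparent
replacement, not a re-creation.

## Ancestral range: the Mk2 model

The hotspot/non-hotspot character evolves under a two-state
continuous-time Markov model with rates `q01` and `q10`
(events/Myr). Transition probabilities are closed-form —

P00(t) = π₀ + π₁ e^(−st), s = q01 + q10, π = (q10, q01)/s

— rather than matrix exponentials, for exactness and speed; `s = 0`
uses the identity-matrix limit, never an epsilon. The likelihood is
Felsenstein pruning with per-node renormalisation; marginal
ancestral probabilities combine the postorder pass with a preorder
"rest-of-tree" pass, so every row of the output sums to one exactly
and tips sit at probability 1 on their observed state.

The root is weighted by the stationary frequencies by default. The
sources we reproduce do not state their root treatment, so `"equal"`,
`"obs"` (weights proportional to the root partial likelihoods, the
default of the software family this analysis descends from) and
`"given"` are options. The stationary default is the natural choice
for a time-reversible equilibrium reading of the model, but note its
behaviour on effectively irreversible data (one rate fitted near 0):
the stationary prior then concentrates on the absorbing state, which
is usually also what the tip data support.

Fitting maximises the likelihood over `(log q01, log q10)` with
`nlminb` from five deterministic starts at 10⁻⁴…1 events/Myr,
tolerance 1e-8 on the log-likelihood. Mk2 cannot account for
incomplete taxon sampling; the SSE models below can, which is one
reason to treat the two analyses as complementary.

## State-dependent diversification: BiSSE and GeoSSE

Both models track, along each branch, E_i(t) — the probability that a
lineage in state i at time t leaves no sampled descendants — and
D_i(t), the likelihood density of the observed subtree. For BiSSE
(states 0/1; rates λ₀, λ₁, μ₀, μ₁, m01, m10):

dE_i/dt = μ_i − (μ_i + λ_i + m_ij) E_i + λ_i E_i² + m_ij E_j

dD_i/dt = −(μ_i + λ_i + m_ij) D_i + m_ij D_j + 2 λ_i E_i D_i

GeoSSE adds a third, widespread state AB with between-region
speciation sAB (an AB lineage splits into A and B daughters),
within-region speciation sA/sB (daughters AB + A or AB + B), region
loss xA (AB→B) and xB (AB→A), and range expansion dA (A→AB), dB
(B→AB). At internal nodes daughters combine with the model's
cladogenetic rule; the widespread-parent term enumerates the allowed
ordered daughter pairs with a factor ½.

Implementation choices:

- **Integration.** Adaptive Cash–Karp Runge–Kutta 4(5) in C++,
  absolute tolerance 1e-10, relative 1e-8, with D renormalised at the
  start of every branch (log factors accumulated), so 40-Myr branches
  never underflow. A fixed-step RK4 oracle in plain R checks the
  solver in the test suite.
- **Sampling fractions.** Tips are initialised D_i = f_i·1[state = i],
  E_i = 1 − f_i, where f_i is the fraction of extant species of state
  i present in the tree, computed from present/absent counts by
  `sampling_fractions()`. The closed-form single-state birth-death
  likelihood (logistic solution of the E Riccati equation) provides an
  independent analytic route used to verify the sampling correction.
- **Root.** D values are combined with weights proportional to the
  root D values themselves ("obs"); `"flat"` and `"given"` are
  options. No conditioning on survival by default (an option): it
  shifts absolute log-likelihoods but not, at a fixed scheme, the
  model rankings we reproduce.
- **Optimisation.** Log-parameterised, rates bounded internally to
  [1e-8, 10] events/Myr, five deterministic starts (a Yule-moment /
  Mk2 heuristic, scaled variants, and two flat starts). Estimates
  below 1e-6 are reported as 0 and flagged as boundary hits — never
  rejected, because extinction genuinely fits at zero on many
  extant-only trees. Negative net diversification (λ − μ < 0) is
  reported as estimated, not clipped.
- **Model ladders.** BiSSE: full (k = 6), equal-rates (k = 3),
  equal-speciation (λ and m tied, k = 4), equal-extinction (μ and m
  tied, k = 4). GeoSSE: full (k = 7), equal-rates (sA = sB, xA = xB,
  dA = dB; k = 4), equal-speciation (sA = sB only, k = 6),
  equal-extinction (xA = xB, k = 6), equal-migration (dA = dB,
  k = 6). The GeoSSE "equal-speciation" constraint leaves sAB free —
  the minimal reading of the model's name; tying sAB as well is a
  defensible alternative the sources do not disambiguate.
- **Comparison.** AIC = 2k − 2 ln L (not AICc, matching the analysis
  being reproduced), ΔAIC relative to the minimum, with ΔAIC > 2
  flagged as the conventional "substantial" difference. AIC ties
  within 1e-9 break towards fewer parameters and are counted.

GeoSSE requires all three states occupied by at least one tip
(`require_all_states = FALSE` exists for reduction tests); that
restriction is why a hotspot boundary that no species spans must be
analysed with BiSSE instead.

## Temporal diagnostics

The LTT curve lists node ages in descending order with lineage counts
2…n. The gamma statistic is computed from internode intervals by the
Pybus–Harvey formula and compared to the standard normal; the default
test is two-tailed at α = 0.05 (the source analysis says only
"significantly", so a one-tailed slowdown option is provided).
Incomplete sampling inflates apparently-negative gamma; a Monte-Carlo
(MCCR) correction is deliberately out of scope, and the per-state
sampling fractions can instead correct clade richness in the
age-richness analysis (option, off by default).

Independent clades are the nodes exactly k parent-to-child steps from
the root (default k = 6), plus any tips reached sooner as singletons,
which makes the clades a disjoint cover of the tips regardless of
tree shape. The regression is ordinary least squares of crown age on
log richness (raw-richness option available); singletons carry no
crown age and are excluded.

## Posterior replication

`replicate_analysis()` runs one analysis per tree with per-tree seeds
drawn deterministically from the master seed, so runs are
reproducible bit-for-bit and the per-tree pruning of subspecies to
one random tip is a fresh draw per tree, as it should be. Per-tree
failures (boundary ML fits occasionally fail on single posterior
trees) are recorded and excluded from aggregates, with the count
always reported; more than 50% failures aborts. Aggregates are the
median and the central 2.5–97.5% percentile interval — labelled as a
percentile interval, not an HPD. "Sampled evenly" from a posterior is
interpreted as evenly spaced indices (first tree included), not
random thinning: deterministic, and faithful to the phrase.

## What the simulators emulate — and what they do not

`simulate_tree()` is an exact continuous-time Gillespie simulation
from a crown of two lineages: exponential waiting times, no time
discretisation. Stopping is either at a crown age or at a tip count;
in the latter case the final internode interval is completed with a
fresh exponential draw so the interval distribution follows the
process exactly (the gamma null calibration depends on this).
Conditioning on survival is by bounded retry with the retry count
reported, so tests can bound the survivorship bias — the test suite
checks extant richness against the *conditional* branching-process
expectation E[N | N ≥ 2], not the unconditional 2e^(rT).

Default study conditions mirror the design being reproduced: trees of
~150–200 tips over ~40 Myr; a strongly asymmetric binary state (~10%
in the rare state, as in 15/158); per-state sampling fractions from
the printed present/absent counts (non-hotspot 15/16, hotspot
143/155, and the three-state 11/11, 78/87, 54/57); occurrence records
drawn with purity 0.95, 100 per species, inside toy rectangular
zones.

What the generators do **not** emulate: phylogenetic uncertainty that
is correlated across posterior trees (our "posterior-like" samples
are independent simulations), rate heterogeneity through time or
among lineages beyond the state dependence itself, spatially
autocorrelated or biased occurrence sampling, and real zone geometry.
Passing tests therefore demonstrate that the estimators are correct
and calibrated under their own model assumptions — not that those
assumptions hold for any particular empirical system.

## Problem sizes

The test suite and `scripts/acceptance.R` use problem sizes chosen to
give stable statistical checks at interactive runtimes: 100
random instances for the Mk2 enumeration oracle; 20 ten-tip trees for
the BiSSE factorization; 500 Yule trees of 158 tips for the gamma
null; 50 BiSSE trees of 200 tips for rate recovery (median fitted
λ₁/λ₀ against a true ratio of 2); 25 (tests) or 12 (script) ladders
on equal-rate data; 200 species × 100 records for the zone-rule
calibration against the binomial-tail oracle
P[Binomial(100, 0.95) > 90]. Medians over replicates, rather than
single runs, are reported wherever an estimator is stochastic.

## Known limitations

- BiSSE has limited power below ~300 tips with strongly asymmetric
  tip states; on 158-tip data a negative result is inconclusive, and
  the package reports effect sizes (rate ratios, ΔAIC distributions)
  rather than verdicts.
- Extinction rates on extant-only trees are weakly identified;
  boundary fits at zero and occasional negative net diversification
  estimates are reported as such.
- Mk2 reconstruction ignores incomplete sampling entirely.
- No HiSSE-style hidden states, no MuSSE/ClaSSE generalisation, no
  MCMC over SSE parameters, and no diversification-shift detection;
  the scope is the fixed model set described above, replicated over
  posterior samples.
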