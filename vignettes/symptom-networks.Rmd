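---
title: "Symptom networks: architecture, nulls, and activation dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symptom networks: architecture, nulls, and activation dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symptomnet)
```

## The model

`symptomnet` implements the network view of psychopathology. Its starting
point is a *symptom--disorder incidence table*: a bipartite structure
recording which symptoms serve as diagnostic criteria for which disorders.
Projecting that table onto the symptom mode joins two symptoms by an edge
whenever they are criteria for at least one common disorder, so every
disorder's symptom set induces a clique, and disorders become connected
through *bridge symptoms* -- symptoms shared between their criterion sets.
The package then asks three questions of the projected graph:

1. **Architecture.** Is the connected core of the symptom space a *small
   world* -- strongly clustered yet traversable in few steps -- and is that
   structure attributable to how symptoms are assorted into disorders,
   rather than to the margins alone?
2. **Geometry and comorbidity.** Do graph distances between disorders
   (average shortest path length between their symptom sets) predict how
   strongly the disorders co-occur empirically?
3. **Dynamics.** Can a minimal stochastic activation process on the
   two-disorder depression/anxiety network reproduce realistic yearly
   prevalences, diagnostic comorbidity (odds ratio) and internal
   consistency (Cronbach's alpha)?

## Graph statistics and baselines

All Table-style statistics live in `summarize_network()`: node and edge
counts, mean degree, density, the *transitivity* clustering coefficient
(3 x triangles / paths of length two -- the global, triple-based
definition, not the mean local coefficient), the average shortest path
length `L` over unordered pairs, and the mean number of distinct geodesics
per pair. Geodesic counting uses the breadth-first path-count recursion and
is validated in the test suite against an exhaustive depth-first
enumeration oracle on all small graphs.

The random baseline is an Erdos--Renyi graph with the same `n` and `m`:
`C_rnd = <k>/n` and `L_rnd = (ln n - gamma)/ln <k> + 1/2` (Euler's
constant `gamma`). These closed forms were selected because they reproduce
the conventional printed baselines at `n = 208`, `m = 1949` (0.09 and
2.12). The *small-world-ness index*

$$\mathrm{SWI} = \frac{C/C_\mathrm{rnd}}{L/L_\mathrm{rnd}}$$

uses them directly; values above 3 are conventionally called small-world.
A caveat documented here because the tests rely on it: the `L_rnd` closed
form is asymptotic. At `(208, 1949)` (a dense graph with `L` close to 2)
it overestimates the sampled `G(n, m)` mean path length by a systematic
~2.3%, so sampled ensembles are compared against the closed forms at
`(1000, 5000)`, where the bias is ~0.2%; at `(208, 1949)` the sampled
clustering is checked within 3 standard errors and the mean ensemble SWI
within an absolute 0.05 of 1.

Degree-distribution tails are classified by fitting the log survival
function linearly against `k` (exponential) and against `log k` (power
law), without binning; the larger coefficient of determination wins and
differences under 0.01 are reported as indeterminate. Node centrality
ships in two forms: the exact current-flow (random-walk) betweenness,
computed from the Laplacian pseudoinverse, and a Monte-Carlo walker
estimate that averages the *net* number of times consecutive absorbed
random walks cross each edge, per source--target pair, and sums the
current magnitudes per node. Net crossings matter: raw visit counts
over-weight high-degree nodes that walks revisit idly and do not converge
in rank to the exact measure, whereas the net-crossing estimate does; the
exact measure is the one reported in outputs.

## The permutation null

`randomize_bipartite()` re-assorts symptoms with disorders while holding
every symptom's bipartite degree and every disorder's criterion count
exactly fixed, via a chain of checkerboard (2x2 submatrix) swaps, with
10 accepted swaps per membership as burn-in. Margins that admit only one
matrix (as in the 14-symptom fixture) are detected and returned unchanged,
which makes the fixture's permutation ensemble exactly degenerate -- a
property the tests assert. `permutation_swi_distribution()` projects each
replicate, restricts to its own giant component by default (configurable
to the full graph), and reports the observed SWI's percentile.

What separates observed taxonomies from their margin-preserving
re-assortments is *membership redundancy*: real criterion sets recur in
blocks across disorders, so the same symptom pairs are re-used and the
projected graph is sparser and more clustered than a random assortment of
identical margins. The block-structured generator `generate_dsm_like()`
(20 five-symptom blocks, 30 disorders of one block plus two idiosyncratic
symptoms) reproduces exactly this signature: observed SWI above the
ensemble mean, permuted density above observed density. A plain chain of
cliques lacks redundancy and does *not* show the SWI separation, which is
why the directional tests use the block generator.

## Disorder distances and comorbidity

The distance between disorders A and B is the mean shortest path length
over all ordered symptom pairs (s in A, t in B); a shared symptom
contributes distance-0 self pairs, which is forced by the "randomly chosen
symptom from each" definition and makes within-disorder distances smaller
than 1. `distance_comorbidity_correlation()` correlates these distances
with a supplied comorbidity matrix across disorder pairs (Pearson by
default, Spearman as an option), with a subset switch that drops pairs
sharing symptoms. Estimating tetrachoric correlations from raw interview
data is out of scope: the comorbidity matrix is consumed as input, and the
simulation-backed scenario generator uses the phi coefficient between
simulated diagnoses as its association measure, which is sufficient for
sign and ordering.

Because the published correlation values depend on an external incidence
file and a published tetrachoric table, the package tests a substituted,
fully internal property: on `generate_comorbidity_scenario()` output (a
six-disorder chain whose comorbidity truly arises from activation spreading
on the projected graph), the distance--comorbidity correlation is strongly
negative and the matrix forms a positive manifold.

## Activation dynamics

On any symptom graph, each symptom `i` on day `t` turns on with
probability

$$p_{it} = a + (1-a)\left[\sigma(b_i A_i(t-1) - c_i) - a\right]$$

where `sigma` is the standard logistic, `A_i(t-1)` counts i's active
neighbors the previous day, `b_i >= 0` is sensitivity, `c_i` a threshold,
and `a` (0.22 throughout, the single global parameter) sets both the
spontaneous-activation floor `a^2 = 0.0484` and the ceiling
`a + (1-a)^2 = 0.8284`. The ceiling's complement `a(1-a) = 0.1716` is the
probability of recovering under full neighbor pressure; note that rounding
the floor gives 0.05 while the exact recovery complement rounds to 0.17,
not 0.18 -- the package reports the analytic value. Updates are
synchronous, ignore the symptom's own previous state (the formula has no
self term; "turning off" is failing to turn on), and start from an all-off
state with no burn-in -- the conservative choice for yearly prevalence
reconstruction, configurable via `init`.

Persons are independent. `simulate_population()` advances everyone in one
matrix recursion but draws each person's uniforms from a seed derived from
the master seed, so the panel is bit-identical to stacking
`simulate_person()` calls and person-level results are schedule-invariant.

### Parameter estimation and calibration

`estimate_symptom_params()` emulates deriving `(b_i, c_i)` from
cross-sectional survey data: logistic regression of each symptom's
endorsement on the number of the disorder's *other* endorsed symptoms.
The self-excluded count deviates from the literal "total number endorsed"
deliberately -- including the symptom itself puts it on both sides of the
regression -- and `include_self = TRUE` restores the literal reading.
Symptoms belonging to two disorders are fitted once per disorder and
averaged. Because the regression conditions on a same-day sum score while
the dynamics respond to lagged neighbor counts, absolute recovery is
attenuated (roughly a factor two in the regimes used here); rank recovery
is what the model supports, and in a weakly coupled ten-symptom clique
with sensitivities spread over 0.2--1.3 the Spearman correlation between
true and re-estimated `b` is essentially 1. In the strongly bistable
fixture regime, attenuation differs by activity level and rank recovery
degrades -- a documented limitation of sum-score regression on episodic
dynamics, not of the estimator's implementation.

The exact survey-derived parameter values are not public, so the package
ships a calibration recipe instead of claiming them:
`calibrate_thresholds()` tunes each `c_i` (holding `b_i` and `a` fixed) so
simulated marginal daily activation rates hit targets, via simultaneous
per-symptom bisection followed by a damped stochastic-approximation
refinement (decaying gain, steps clipped to 0.5) that corrects the
interaction bias bisection leaves behind in near-bistable regimes;
convergence within 0.02 of every target is enforced.

### The bundled fixture parameterization

`mde_gad_fixture()` carries the package's own calibrated defaults, chosen
once from a regime analysis and then frozen:

| group | b | c | target daily rate |
|---|---|---|---|
| 5 core MDE symptoms | 1.3 | 6.5 | 0.077 |
| 4 bridge symptoms | 0.8 | 4.2 | 0.149 |
| 5 core GAD symptoms | 1.4 | 4.2 | 0.192 |

The logic of the regime: GAD cores form a strongly self-sustaining
cluster with chronic, moderate-duty episodes; MDE cores are sluggish at
low neighbor counts but ignite in intense episodes when the bridges are
up; bridges sit in between, at roughly half duty during one-sided
episodes. That separation is what lets anxiety-side episodes persist for
months without automatically handing the depression side a 14-day run --
the structural requirement for a finite diagnostic odds ratio -- while
anxiety symptoms remain *more* prevalent than depression symptoms even
though GAD (182-day criterion) stays rarer than MDE (14-day criterion),
the duration-asymmetry phenomenon the dynamics are meant to exhibit.

### Diagnosis rules

MDE: some run of at least 14 consecutive days, on each of which at least
5 of the 9 symptoms are active including at least one of depressed
mood/loss of interest; symptom identity may vary across days (a
`fixed-set` reading is not implemented; the count-based reading follows
the rule's "five out of nine" phrasing), and the core requirement is
evaluated per day. GAD: some 182-day window in which each of the three
core symptoms is active on a strict majority of days and a strict majority
of the nine symptoms each reaches a strict majority duty cycle
(`window_mode = "per-symptom"`, the literal reading of "most of the
symptoms present for most of the days"; cores count inside the majority).
The alternative simultaneous reading -- a majority of symptoms active at
once on a majority of days -- ships as `window_mode = "simultaneous"`; it
couples GAD diagnosis tightly to bridge activation and, on this fixture,
forces every GAD case to carry MDE as well, which is why it is not the
default. Windows lie within the simulated year; both majority thresholds
are configurable and 0.5-exclusive. Boundary conventions: plausibility
ranges are closed intervals; the odds ratio uses the Haldane 0.5
correction only when a cell is empty, with a logged message.

## Replication studies and the specificity control

`replication_study()` repeats simulate--diagnose--summarise, either with
the spec's own parameters or with the `(b, c)` pairs re-assigned to
symptoms anew each replicate (pairs intact). Shuffling is the specificity
control: the network architecture alone, with the same multiset of
parameters in the wrong places, should not produce jointly plausible
statistics. With the bundled fixture parameters at 50 replicates of 2000
persons x 365 days (the problem size the package's own checks use), the
original parameterization lands all four statistics in their plausible
ranges in the large majority of replicates while the shuffled control
essentially never does, and MDE prevalence alone is in range in every
original replicate.

## What the generators do and do not emulate

The synthetic generators reproduce the *structural* features the analyses
need -- clique projection, bridge overlap, block redundancy, margins,
graph-driven comorbidity -- under fixed seeds, so every pipeline stage is
testable without external data. They do not emulate: editorial
symptom-equivalence coding (that judgment lives in the input table),
individual differences in network parameters (explicitly absent from the
dynamics), item-level response structure of real interviews, or negative
(protective) connections. Passing tests therefore demonstrate internal
coherence of the method on data whose generating mechanism is known, not
agreement with any particular empirical taxonomy.

## Numerical choices

- Ties for the giant component break toward the component holding the
  lexicographically smallest vertex name.
- Transitivity errors (rather than returning 0) on graphs with no paths of
  length two; the ratio is undefined there.
- Unreachable pairs are `NA` in every output, never numeric infinity.
- `sample_er_graphs()` computes each replicate's statistics on that
  replicate's own giant component.
- Seed derivation for persons and replicates uses R's generator as the
  mixing function; nested linear congruential derivations are avoided
  because two masters differing by the increment share shifted streams.
- All simulation sizes in the tests (bisection at 1200--1500 persons,
  replication at 50 x 2000 x 365) were chosen as the smallest sizes at
  which the checked contrasts are stable across seeds.

## Known limitations

- The closed-form `L_rnd` is asymptotic and biased high for dense graphs
  with `L` near 2 (see above).
- The swap-chain sampler is exact only in distribution; extremely
  constrained margins mix slowly (degenerate margins are detected and
  short-circuited).
- The phi coefficient understates the tetrachoric correlation it proxies;
  only signs and orderings of comorbidity are interpreted.
- Cross-sectional sum-score regression cannot recover absolute dynamic
  sensitivities; calibration targets marginal rates instead.
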