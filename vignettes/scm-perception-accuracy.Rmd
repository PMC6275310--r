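---
title: "Measuring perception accuracy of classroom affiliative networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring perception accuracy of classroom affiliative networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

In a Social Cognitive Map (SCM) survey each classroom member lists the groups
of classmates who "hang around together a lot" and names the classmates who
belong to no group. Every respondent therefore supplies a *perceived*
affiliative network for the whole classroom, and the collection of reports
supports two derived quantities:

* a consensus ("true") affiliative network, and
* a score for how accurately each respondent perceives it.

`scmnet` implements this measurement chain together with a longitudinal model
that asks whether classroom structure — specifically transitivity, the
tendency of one's affiliates to be affiliated with each other — predicts how
accurately members perceive the network.

## From group listings to networks

A listed group is read as a clique: it implies a tie between *every* pair of
its members, including pairs involving the reporter. Overlapping groups are
unioned at the dyad level (a pair mentioned twice counts once), isolates
contribute no ties, and a singleton "group" is rejected at validation time
with instructions to record it as an isolate. Only members who completed an
SCM carry relational information, so perceived networks are defined over the
participant set and pairs involving non-participants are dropped before any
downstream computation.

The reverse encoding, used by the synthetic-data generator to emit SCM-format
files, lists the maximal cliques (size two or more) of a network as its
groups and the degree-zero nodes as isolates. Maximal cliques cover every
edge, so decode(encode(g)) = g exactly; the generator-to-reader path is
lossless and downstream tests are isolated from encoding noise. An
alternative — partitioning nodes into disjoint groups — would be closer to how
children typically fill in the form but is lossy; we chose exactness.

## The consensus network

A dyad {i, j} is a true tie if and only if **both** i's own map and j's own
map depict it (the locally-aggregated-structures intersection rule).
Third-party depictions never create a true tie. Two consequences are worth
keeping in mind:

* the true network is always contained in the intersection of each dyad's
  two self-reports, and removing an edge from any single perceiver's map can
  only shrink it; and
* the true network is *estimated from the same reports it is used to score* —
  see the calibration section for what this implies.

Classroom-waves enter the analysis only when their participation rate
(participants / members) strictly exceeds 0.60; a classroom at exactly the
threshold is excluded. The strictness mirrors the inclusion rule of the data
the package is designed for.

## Accuracy and transitivity

With `D` the dyads a perceiver depicted, `T` the true dyads and
`C = |D ∩ T|`:

* precision `= C / |D|`,
* coverage `= C / |T|`,
* accuracy `= precision × coverage`.

Accuracy equals 1 exactly when a perceiver depicts all true ties and nothing
else. Two degenerate cases have documented conventions. A perceiver who
depicted nothing has 0/0 precision; we score accuracy 0 (they identified no
true relationship) and flag the record rather than erroring, which would
silently drop participants. A classroom-wave whose true network has no edges
offers no target at all: coverage is undefined, a classed error
(`scmnet_undefined_coverage`) is raised at the single-pair level, and the
pipeline excludes the classroom-wave with a logged warning. Accuracy is
always computed on unrounded components; two-decimal rounding is applied
only for display.

Classroom transitivity is `3T / (3T + P)` with `T` the number of triangles
and `P` the number of open two-paths: the probability that a connected
triple is closed. A network with no connected triples (e.g. a perfect
matching) gets a *missing* index, not 0 — a 0 would assert maximal
intransitivity where there is no information. Counts are computed from the
adjacency matrix (`tr(A³)/6` and `Σ deg(deg−1)/2 − 3T`), and the test suite
checks them against brute-force triple enumeration and against igraph's
global clustering coefficient.

## The longitudinal model

Accuracy scores are repeated measures nested in participants. The package
fits, by restricted maximum likelihood with `lmerTest`:

```
accuracy_it = β0 + β1·time_it + β2·t0_i + β3·change_it + u_i + ε_it
u_i ~ N(0, σ²_intercept),  ε_it ~ N(0, σ²_residual)
```

Transitivity is time-varying, so it is disaggregated: `t0_i` is the
classroom transitivity at participant *i*'s **first observed wave** (not
calendar wave 0), and `change_it` is the deviation of the current wave's
classroom transitivity from `t0_i` (zero at the first observed wave, and
`t0 + change` always reproduces the wave's transitivity exactly). `β2` is
the between-person effect, `β3` the within-person effect. Time is coded as
the integer wave index 0, 1, 2, assuming equal spacing; the assumption is
documented rather than configurable per row. Participants who change
classrooms take each wave's transitivity from the classroom they belong to
at that wave. Participants contribute only if they have at least two usable
waves (rows with a missing transitivity index are dropped first and
counted).

P-values use Satterthwaite degrees of freedom, recorded in the fit's
`df_method` field. A singular design — constant `transitivity_change`,
constant accuracy (e.g. noiseless reports), collinear predictors — raises a
classed error naming the culprit instead of returning a misleading fit, and
optimiser non-convergence is an error, never a partial result. A boundary
estimate `σ²_intercept = 0` is legitimate (balanced designs then reproduce
ordinary least squares, which the tests verify to 4 decimals). Because the
coefficients act on the proportion scale, effect translation is linear:
a coefficient of 0.67 on `t0` means a 0.10 transitivity difference
corresponds to an expected 0.067 accuracy difference.

## The synthetic-data generator

The generator is first-class, tested code; every stage of the pipeline is
exercisable without any external data. Its defaults describe the study
conditions the package targets:

| parameter | default | meaning |
|---|---|---|
| `n_classrooms` | 10 | classrooms per study |
| `class_size` | 20 | members (15–30 realistic) |
| `n_waves` | 3 | observation waves |
| `edge_density` | 0.18 | true-network density (≈ 3–4 affiliates each) |
| `target_transitivity` | U(0.35, 0.75) | per classroom-wave target |
| `transitivity_tolerance` | 0.02 | targeting tolerance |
| `p_hit_own` | 0.95 | P(report an own true tie) |
| `p_hit_other` | 0.50 | P(report another's true tie), uncoupled case |
| `p_false` | 0.03 | P(report a non-tie) |
| `coupling` | a = −1.6, b = 3.2 | `p_hit_other = plogis(a + b·t)` |
| `rewire_fraction` | 0.3 | edges rewired per wave |

With these values classroom transitivity spans roughly 0.3–0.8 and mean
accuracy lands around 0.4 (roughly 0.2–0.6 across classrooms), matching the
descriptive ranges the package is meant to emulate; the coupling slope
translates into a within-person effect of roughly 0.4–0.6 on the accuracy
scale. The coupling acts only on `p_hit_other`, never on `p_hit_own`, so the
planted true network is unaffected and truth recovery stays separable from
perception effects: with `p_hit_own = 1` and `p_false = 0` the intersection
rule returns the planted network *exactly*, whatever `p_hit_other` does.

True networks are drawn at a fixed edge count `round(density·n(n−1)/2)` and
hill-climbed to the target transitivity: to raise it, add an edge closing a
random two-path and delete a random edge; to lower it, the reverse; keep a
swap only if it shrinks the distance to the target. Greedy swaps can stall
in a local optimum of this coarse landscape, so after 150 consecutive
rejections the climber accepts a burst of random rewires (about 10% of
edges) and descends again, returning the best state seen. Wave-to-wave
evolution rewires `⌈rewire_fraction·m⌉` edges and re-targets. Two numerical
caveats are deliberate contracts: targeting failure after `max_iter`
proposals raises a classed error reporting the best achieved value, and very
small sparse networks (say 10 nodes, 8 edges) support only a coarse grid of
transitivity values, so targets near the extremes may be genuinely
unreachable at tolerance 0.02 — choose mid-range targets or a higher density
for miniature examples.

All randomness flows from the single config seed; equal configurations
produce byte-identical roster/report/truth files (canonical orderings use C
collation so the output is locale-independent).

What the generator does **not** emulate: non-participation (every simulated
member reports; participation filtering is exercised by editing rosters in
tests), attrition and classroom reshuffling, ego-biased perception styles
(expansiveness, reciprocity bias), rank-ordered or directed nominations, and
any dependence of report quality on the perceiver's own network position.
Passing tests therefore show the pipeline is correct and well-calibrated
under clique-structured truths with independent Bernoulli report noise; they
do not certify the behaviour of the accuracy index under richer response
biases found in real children's reports.

## Calibration results and a measurement caveat

The test suite computes, from the measurement-level generator (data drawn
directly from the random-intercept model, 150 participants × 3 waves):

* parameter recovery: over 200 replicates, each fixed effect's absolute bias
  stays below 0.05 and the 95% Wald–Satterthwaite intervals for the two
  transitivity effects cover their true values at rates within [0.90, 0.99];
* type-I control: with the within-person coefficient set to zero, the β3
  test at α = 0.05 rejects at the nominal rate (within [0.02, 0.09] over 500
  replicates).

A separate experiment keeps the full report-level generator but switches the
coupling off, so report quality is independent of transitivity. The
within-person test then rejects *well above* the nominal 5% (the suite
asserts the inflation direction over 40 replicates). The mechanism is
instructive: classmates share the realised consensus network, so their
accuracy scores carry a common classroom-wave shock that a participant-only
random intercept does not absorb, and the measured transitivity is itself
computed from the same reports, making the covariate endogenous to the
outcome's noise. Any analysis that regresses report-derived accuracy on
report-derived classroom structure without a classroom-wave variance
component inherits this anticonservativeness; we mirror the single-level
specification deliberately (the analysis this package reproduces fits no
classroom effect) and flag it here as the main caveat for interpreting
small within-person p-values on real data.

## Problem sizes

The shipped tests run the oracle battery on 10,000 random graphs with up to
8 nodes, the round-trip property on every one of them, recovery/calibration
at 150 participants × 3 waves (200 and 500 replicates), and full-pipeline
studies of 6–10 classrooms × 16–20 members × 2–3 waves — sizes chosen to
match the scale of the motivating studies while keeping the whole suite
comfortably reproducible on a laptop.

## A worked example

```{r, eval = FALSE}
library(scmnet)

cfg <- simulation_config(seed = 7)
study <- simulate_study(cfg)
res <- run_pipeline(rosters = study$rosters, reports = study$reports)
res$summary   # accuracy / transitivity means and SDs per wave
res$fit       # fixed effects, Satterthwaite p-values, variance components

# translate the within-person coefficient into an accuracy difference
predicted_accuracy_difference(res$fit, "transitivity_change", delta = 0.10)
```
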