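---
title: "Cross-modal systems alignment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modal systems alignment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alignsim)
```

## The problem

A *system* is the set of similarity relations among items in one
representational space — here a visual embedding (objects positioned by
scene co-occurrence) and a linguistic embedding (words positioned by text
co-occurrence). Items that occur in similar visual contexts also tend to
occur in similar linguistic contexts, so the two systems carry mirrored
similarity structure. *Systems alignment* exploits this: an agent that
knows some word–object mappings (its *knowledge state*) can infer the
mapping for unfamiliar items by asking which assignment makes the
cross-modal similarity patterns line up, with no co-occurring
labeling event at all.

`alignsim` implements the full simulation pipeline around this idea:
scoring candidate mappings, growing knowledge states month by month from
age-of-acquisition (AoA) schedules, characterizing knowledge states with
structural features, training generative agents that select concepts by
optimizing those features, and generating synthetic paired-embedding
worlds so that every stage can be exercised and tested without external
downloads.

## Alignment scoring

The alignment score between two systems under a candidate item mapping is
the Spearman rank correlation between the upper triangles of their pairwise
distance matrices, with the second matrix reordered by the mapping
(`alignment_score()`). Spearman uses average ranks for ties; the score is
therefore invariant under any monotone transform of either distance matrix,
which the test suite checks directly.

For a two-alternative forced choice, only two probe items move between the
candidate mappings, so `probe_alignment_score()` correlates the
concatenated probe distance columns (distances from each probe item to
every knowledge-state concept, concatenated in candidate order) across
modalities. This shortcut is the scoring rule used throughout the
simulations. It is *not* exactly equivalent to ranking full-matrix
alignment scores: the full upper triangle also contains state–state and
probe–probe entries whose ranks interleave with the probe columns. The
acceptance suite measures the decision agreement between the two rules on
hundreds of small synthetic worlds and reports the disagreement rate rather
than assuming equivalence.

Numerical choices:

* distance metric: the default is euclidean distance on raw embedding
  coordinates, with cosine distance
  available via the `metric` argument everywhere distances are built.
  The rank-based score makes many monotone metric changes irrelevant,
  but the switch is exposed so sensitivity can be checked.
* forced-choice ties (scores equal within `1e-12`) are broken uniformly at
  random and flagged in the result, so they are auditable.
* degenerate constant vectors raise errors instead of returning 0; a
  constant probe column in a synthetic world is a bug worth surfacing.
* knowledge states must have at least 2 concepts before probing (shorter
  concatenations make rank correlation fragile); real schedules start at
  17 concepts, so this floor only binds on deliberately tiny tests.

## Acquisition schedules and agent populations

`load_acquisition_table()` reads MB-CDI style item trajectories (one row
per word, one column per month, cells are cumulative production
proportions), restricted by default to months 16–24, where such inventories
track the true vocabulary closely. Monotonicity over months is enforced
with a running maximum and a warning. Multiword items are dropped with a
warning unless an alias map is supplied, since their tokenization in
embedding vocabularies is not well defined.

Cumulative monthly counts are the rounded sums of cumulative acquisition
probabilities, `N_m = round(sum_i p_im)` (half away from zero, so the tie
behaviour is reproducible); per-month counts are obtained by differencing.
`cdi_month_schedule()` ships the WordBank English (American) cumulative
counts for the 138-word reference concept set — (17, 21, 36, 45, 49, 55,
68, 77, 83) — and derives the per-month counts from them. The cumulative
row is the authoritative one: published per-month and cumulative figures
for this schedule disagree by one concept in two months (rounding each
month independently does not commute with differencing), and downstream
checks (21 concepts after month 17, 83 after month 24) are stated on the
cumulative scale.

AoA agents grow their knowledge state one concept at a time, sampling from
the acquisition probabilities of the current month renormalized over
unacquired concepts (`acquisition_distribution()`); control agents sample
uniformly from concepts outside the AoA set (a flag switches to the
whole-vocabulary variant). `run_experiment()` evaluates every agent each
month with freshly drawn probe pairs under the AoA probe condition
(unacquired AoA concepts) and/or the unconstrained condition (all
unacquired concepts), and aggregates per-agent accuracies into means with
95% CIs across agents (normal approximation by default, percentile CIs by
config). Defaults: 100 agents, and 50 probe pairs per month per condition
— a pair count that keeps per-agent accuracy stable while staying cheap. All sampling is reproducible: per-agent RNG streams are derived
from one master seed, and identical seeds give bitwise-identical result
tables.

## Structural features of knowledge states

Neighborhood graphs keep an edge only where the interconcept distance is
strictly below the 10th percentile (linear interpolation) of all
upper-triangle distances (`build_neighbor_graph()`); graphs may be
disconnected. Feature definitions (`state_features()`):

| feature | definition |
|---|---|
| `degree_knowledge` | mean, over state members, of sub-threshold neighbors *within the state* |
| `degree_full` | mean degree in the full-system graph |
| `mean_dist_knowledge` | mean, over state members, of mean distance to other state members |
| `min_dist_knowledge` | mean, over state members, of distance to the nearest other state member |
| `min_dist_full` | mean, over state members, of distance to the nearest concept in the full system |
| `coverage` | per-dimension span of the state divided by the full-system span, averaged over dimensions |
| `skew_degree_knowledge` | adjusted Fisher–Pearson sample skewness of within-state degrees (0 for constant vectors) |

Interpretation choices fixed here: the graph threshold is always computed on the full system, with
"knowledge" degrees counted on the induced subgraph; features are computed
per modality and averaged by default (`modality = "mean"`), with
single-modality and both-as-separate-features options; "mean dimension
coverage" is the span-ratio definition above, which is invariant to affine
rescaling of any dimension. Clustering and betweenness features exist in
the graph machinery but are excluded from classifier selection by default
because of their cost.

`classify_states()` is the AoA-vs-control knowledge-state classifier:
min-max normalization fitted on the 80% training split only, L2-penalized
(ridge) logistic regression with up to 10,000 iterations, and recursive
feature elimination by smallest absolute coefficient, scoring each feature
count k by training AIC (deviance + 2(k+1)) and keeping the AIC-minimizing
k. Held-out accuracy, precision, recall and F1 are reported.

## Generative agents

A generative agent's *internal model* is a pair of vectors over the
structural features: target values `x_hat` and importance weights `w`.
For each candidate concept, the features of the hypothetically augmented
state form a row of the matrix `A` (normalized by a min-max normalizer
fitted once per world on random states spanning the schedule sizes, then
frozen); the generative score is `s = -|A - x_hat| %*% w`. The deviation
enters through its absolute value: a signed deviation would contribute the
same additive term `x_hat . w` to every candidate's score and cancel out
of the shift-invariant softmax, leaving the targets unlearnable — the
absolute form is the minimal reading under which "distance from target"
is meaningful and the targets are identifiable. Scores are standardized
within the candidate set (so the temperature acts on a fixed scale across
worlds) and converted to a selection distribution by a softmax at
T = 5e-2. Acquired concepts carry inclusion probability 1; unacquired
candidates carry their softmax mass.

Two agents differ only in the loss backpropagated at each month's end:

* **AoA-Matched** — mean squared error between the inclusion-probability
  vector and a bootstrapped acquisition table (`bootstrap_distributions()`
  resamples full AoA trajectories and records per-concept, per-month
  inclusion proportions; 70/30 train/validation split over tables).
  Candidate concepts absent from the table get target 0.
* **Task-Optimized** — the *soft alignment loss*: the mean, over a slate
  of probe pairs from held-out concepts, of the margin
  `s_incorrect - s_correct`, where each probe-column entry is weighted by
  the corresponding candidate's inclusion probability (weighted Pearson on
  rank-transformed concatenated columns). The non-candidate concepts are
  re-segmented into disjoint train and validation slates at every loss
  evaluation, so every concept eventually serves as a probe.

Both losses are z-scored per month against Monte-Carlo samples of the loss
under random concept selection (`calibrate_normalizers()`), then shifted by
the z-score of the loss's theoretical floor (0 for the MSE; -2 for the
margin, since each alignment score lies in [-1, 1]), making every loss
nonnegative. The pseudo probability vector used in calibration gives
selected concepts probability 1 and spreads a uniform distribution over
the rest of the candidate set; the same construction is used for both loss
kinds.

Training (`train_agent()`) runs R restarts of an epoch loop: each epoch
simulates the monthly schedule by sampling concepts from the current
selection distribution (the first two concepts uniformly — structural
features need at least three members), computes the loss at each month's
end and performs an Adam update (learning rate 0.003 for AoA-Matched, 0.01
for Task-Optimized; 150 epochs and 5 restarts by default). The restart
with the lowest validation loss averaged over the final 5 epochs wins.
Gradients are analytic: the losses are smooth in the inclusion
probabilities once ranks are held fixed (the loss is linear in the
probability weights, so gradients flow through the weights, not through
the discontinuous ranks; a soft-rank variant was considered and rejected
as it changes the estimator the margin is defined on). The full chain —
weighted-Pearson entries, softmax, score standardization, absolute
deviation — is differentiated by hand and verified against central finite
differences to relative tolerance 1e-4 (with absolute agreement required
where saturated softmax draws make the true gradient numerically zero).

`generate_sequence()` freezes a trained model and samples trajectories
from its selection distribution, refilling the candidate set to its
configured size after each acquisition; the trajectories plug directly
into `run_experiment()` via the `"generative"` agent condition.

For vocabularies smaller than the 418-concept reference scale, the
candidate set (300), held-out slates (59 + 59) and slate size (750 pairs)
scale proportionally with vocabulary, except that a slate uses all
available held-out pairs whenever these are fewer than 750 — subsampling a
28-pair universe would only add variance.

## The synthetic world generator

`generate_paired_systems()` places concepts in a latent space as a mixture
of Gaussian clusters and observes them through two independent random
*orthonormal* maps — one per modality — plus modality-specific Gaussian
coordinate noise. Orthonormal maps preserve distances exactly, so at zero
noise the two systems are exactly second-order isomorphic and forced
choice is always correct; rising noise degrades accuracy monotonically.
Per-concept noise is scaled by `exp(-gamma * density)`
(`noise_density_link`, default 0.5), where density is the standardized
negative mean distance to the nearest tenth of latent neighbors: concepts
in dense neighborhoods occupy more stable positions across modalities.
This is the stability gradient that makes dense knowledge states genuinely
better aligners — with homoscedastic noise, density confers no advantage
and spread-out states win, which is not the regime the reference analyses
describe (short-range similarity relations are empirically the stable
ones).

`generate_acquisition_table()` selects an AoA subset of the vocabulary and
assigns acquisition onsets, both biased toward dense concepts with
strength `density_bias` (log-odds proportional to the density score; 0
gives density-independent acquisition), and builds cumulative monthly
probabilities with a logistic ramp (width 1.5 months) centered on each
onset — monotone by construction, no clipping needed.

Registered fixtures (`make_fixture()`), frozen once:

* `mirror10` — 10 concepts, zero noise: the perfect-alignment limit.
* `noisy30` — 30 concepts, 3 clusters, noise 1.2, mild density bias.
* `planted60` — 60 concepts, 4 clusters, noise 2.0, `noise_density_link`
  1.0, density bias 5: forced-choice accuracy sits off-ceiling
  (roughly 0.8–0.93 across months) so that differences between agent
  conditions are measurable, and the AoA-over-control ordering holds
  across the month range.

What the generator does *not* emulate: real lexical statistics (frequency,
phonology, semantic category structure), reporting noise in parental
inventories, growth or drift of the embedding spaces over development, and
the heavy-tailed degree distributions of real semantic networks. Passing
tests on these worlds show the machinery is correct and that the
density–stability mechanism behaves as designed; they do not certify
effect sizes on real embeddings.

## Problem sizes used in the test and acceptance runs

Desk-scale runs keep the full procedure but shrink the arithmetic: the
planted60 world with 30 agents and 20 probe pairs per month per condition;
generative training with 100 epochs x 5 restarts (Task-Optimized) or 60
epochs x 5 restarts (AoA-Matched), 300 normalizer samples per month, and
bootstrap sets of 30 tables x 30 sequences; schedule-arithmetic checks on
a 300-concept world with the 138-concept WordBank schedule. These sizes
are stated here as the package's reference configuration for its own
experiments; the full-scale defaults (100 agents, 150 epochs, 1000
bootstraps of 300 sequences, 5000 normalizer samples) remain the function
defaults.

## Known limitations

* The mean soft-alignment margin and forced-choice accuracy are related
  but not identical objectives: the margin rewards magnitude while
  accuracy rewards sign consistency. On the planted synthetic worlds the
  Task-Optimized agent reliably beats uniform control agents early in the
  schedule, but its margin-selected optimum over-concentrates on
  maximum-density states and its final-month accuracy lands at or slightly
  below the control level, with individual restarts on either side. The
  acceptance script reports both quantities; the comparison on real
  embedding data is outside what these worlds can settle.
* The probe-column scoring shortcut and the full-matrix alignment score
  disagree on a few percent of small-world decisions (rate measured and
  logged by the acceptance suite); both rules are exposed, and the
  shortcut is what the simulations use.
* Internal models are static over the schedule: a single `x_hat`/`w` pair
  serves all months, although the structural profile of the best next
  concept plausibly changes as the state grows.
* Bootstrapped acquisition tables treat the input table as the population;
  uncertainty from the underlying inventory sample is represented only
  through trajectory resampling.
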