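---
title: "Methods: partial-correlation networks of schizotypy and gesture processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partial-correlation networks of schizotypy and gesture processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gestnet)
```

## The scientific problem

Schizotypal personality traits are continuously distributed indicators of
schizophrenia liability, and patients on the schizophrenia spectrum show
marked difficulties matching co-speech gestures with their verbal content.
`gestnet` implements the analysis chain needed to study, in a large
nonclinical sample, how three facets of schizotypy (cognitive-perceptual,
interpersonal, disorganization; SPQ-B), four facets of self-reported
gesture processing (perception, production, social perception, social
production; BAG scale) and two behavioural speech-gesture matching indices
(iconic and metaphoric) hang together as a psychometric network. The
interesting questions are structural: which variables bridge the three
instruments, and which nodes would, under an interventionist reading of the
network, move the rest of the system most.

## The network model

The nine subscale variables are modelled as a Gaussian graphical model on
ranks. With `R` the Spearman correlation matrix and `P = R^-1`, the edge
weight between nodes *i* and *j* is the partial rank correlation

```
pcor(i, j) = -P[i, j] / sqrt(P[i, i] * P[j, j]),
```

the dependence between the two variables after conditioning on the other
seven. No regularization is used; with around a thousand observations for
nine nodes, shrinkage is unnecessary and would bias the edge weights.
Sparsity comes instead from an explicit decision rule:
`bootstrap_edge_selection()` resamples participants with replacement
(default 5000 resamples), recomputes the partial Spearman matrix on each
resample — ranks are recomputed inside every resample, because the
resample is of participants, not of ranks — and keeps an edge iff the
central 95% percentile interval of its bootstrap distribution excludes
zero. Retained edges carry the full-sample estimate; the bootstrap mean
would be biased toward zero under selection. The decision level `alpha`
and interval coverage `ci` are redundant parameters constrained to
`ci = 1 - alpha`; overriding the constraint requires an explicit flag so
the redundancy cannot drift apart silently.

Occasionally a resampled Spearman matrix is numerically indefinite (heavy
ties at small n). Such matrices are repaired by eigenvalue clipping at
1e-8 followed by rescaling to unit diagonal (`nearest_positive_definite()`)
rather than dropped — dropping resamples would bias the intervals — and
every repair is counted in the returned object. How indefinite resamples
should be handled is genuinely open; clipping is the least invasive
option and the count makes it auditable.

## Community detection

`fast_greedy()` is a from-scratch agglomerative Clauset–Newman–Moore
modularity maximizer: start from singletons, repeatedly apply the merge
with the largest modularity gain, and cut the merge tree at the earliest
level attaining the maximum Q. Two contracts are pinned deliberately:

* **Signs.** Newman–Girvan modularity is undefined for signed graphs, so
  detection runs on absolute selected weights; the signed matrix is kept
  for every other module.
* **Ties.** The single source of nondeterminism in CNM is tie-breaking
  among equal gains. Ties are resolved lexicographically by the pair of
  community labels (each community labelled by its alphabetically smallest
  node), making the partition a pure function of the input. Cutting at the
  *earliest* maximal level also means zero-gain merges (isolated nodes)
  are never applied.

The implementation is quadratic per merge, which is immaterial at 9 nodes;
the test suite checks it against exhaustive enumeration of all set
partitions (up to 8 nodes) and against igraph's independent implementation.
Detection defaults to the selected (sparsified) network; whether to use
the saturated matrix instead is a configuration choice.

## Bridge centralities

Given a partition, three node statistics quantify cross-community
importance: bridge expected influence (signed sum of a node's selected
edge weights to other communities), bridge closeness (inverse mean
shortest-path distance to out-community nodes) and bridge betweenness
(fractional count of cross-community geodesics through the node). Path
lengths use the standard psychometric convention `1/|weight|`, recorded in
the output metadata because it changes the closeness and betweenness
scales. Unreachable out-community nodes make the mean distance infinite
and closeness 0 by convention. Tied geodesics are split fractionally —
ties are nongeneric with continuous weights, but determinism must not
depend on genericity.

`bridge_difference_test()` bootstraps pairwise differences of a metric:
participants are resampled, partial correlations re-estimated, and the
*full-sample* inclusion mask and community partition are held fixed while
the metric is recomputed. Re-running selection inside the bootstrap would
mix model-selection variability into what is meant to be a test of
centrality differences given the network; holding the mask fixed is a
declared assumption, not an inference from any reference analysis.

## Controllability

The selected signed network is read as the adjacency of a discrete-time
linear system `x(t+1) = A x(t) + B u(t)`. `normalize_adjacency()` divides
by `c = 1 + |lambda_max|` so the dynamics are Schur stable. For input at
node *i* (`B = e_i`) the infinite-horizon controllability Gramian solves
the discrete Lyapunov equation `W = A W A' + B B'`; average
controllability is `trace(W)`, which for symmetric `A` has the closed
form `sum_j v_ij^2 / (1 - lambda_j^2)` over the eigendecomposition — the
exact Lyapunov solution, checked in the tests against the truncated power
series `sum_tau ||A^tau e_i||^2`. Modal controllability is
`phi_i = sum_j (1 - lambda_j^2) v_ij^2`. Both are convention-dependent
(the normalization constant is recorded in the output): absolute values
are only comparable across studies using the same normalization, which is
why the package treats the published per-node values of comparable
analyses as a plausibility band (roughly 1.0–1.2 for average
controllability of partial-correlation networks at this scale) rather
than reproduction targets. Control dynamics respect edge signs, so the
signed selected matrix — not its absolute value — is the input.

## Node predictability

`node_predictability()` regresses each node's ranks on the ranks of its
included neighbours and reports R². Using ranks keeps the measure
consistent with the Spearman network (the common mixed-graphical-model
definition works on raw scores; the rank choice is declared and the
neighbour sets configurable through the mask). Nodes without included
edges score 0 by convention; constant neighbour columns are dropped and
recorded.

## Scoring conventions

The SPQ-B contributes three summed subscales (8/8/6 items) plus their
total; the default item map uses contiguous blocks and is configuration
data, not code, because published item keys vary and burying the choice
would hide a researcher degree of freedom. The BAG's four 3-item subscales
are summed after reverse-keying; item 1 defaults to reverse-keyed because
the perception subscale's anchor item is worded negatively. The
speech-gesture matching indices are congruence contrasts:
`Icon = mean(concrete-related) - mean(concrete-unrelated)` and likewise
`Metaph` for abstract sentences. A relatedness-rating task admits several
summary measures; the related-minus-unrelated contrast is the natural
discrimination score, bounded in [-6, 6] and antisymmetric under swapping
condition labels, and the item maps make alternatives swappable.
Participants failing the attention check are excluded before analysis and
counted in the exclusion report. Missing items propagate NA to their
subscale (complete-case per variable).

## The synthetic-data generator

No participant-level data ship with the package, so every downstream stage
is exercised against a generator with known truth. `make_ground_truth()`
builds a 9-node partial-correlation matrix with three instrument blocks:
within-block weights drawn once from a declared interval (default
0.2–0.4, the typical within-instrument range of psychometric networks),
all cross-block entries zero except eight bridge edges (defaults of
magnitude 0.10–0.15, with the BAG social-production node carrying the
three strongest, mirroring the qualitative topology such studies report).
The construction is validated, not repaired: a weight request whose
precision matrix is not positive definite fails loudly with the offending
eigenvalue. `pcor_to_covariance()` inverts the parameterization exactly,
and `simulate_subscales()` draws standardized Gaussians with that
covariance.

`simulate_item_responses()` adds the measurement layer: each subscale
latent spawns equicorrelated item latents with loading 0.7 (typical
questionnaire reliability, consistent with the 0.49–0.74 internal
consistencies reported for the BAG subscales), discretized by quantile
thresholds on the latent scale — a latent-Gaussian/copula scheme that
preserves exactly the rank dependence the Spearman estimator assumes.
Related-condition video items load positively and unrelated ones
negatively on the corresponding task latent, shifted by ±1 so related
gestures are rated as more congruent. The attention check is an
independent Bernoulli flag (default 4% failure); the underlying free-text
judgment is out of scope because the pipeline only ever consumes the
boolean.

What the generator deliberately does *not* emulate: demographic
covariates, response times, careless-responding patterns beyond the
attention flag, and the unpublished marginal distributions of any real
sample (no subscale means/SDs are available to calibrate against, so
marginals are calibrated to instrument ranges only). Passing tests
therefore demonstrate estimator correctness and calibration under the
assumed latent-Gaussian measurement model, not robustness to real-data
pathologies such as skewed traits or systematic careless responding.

## Numerical choices and problem sizes

* Eigenvalue floor 1e-8 for positive-definite repair; repairs counted.
* Modularity tie tolerance 1e-12; geodesic tie tolerance 1e-10 (relative).
* Every stochastic function takes an explicit integer seed and is
  bit-reproducible; `run_pipeline()` derives per-stage seeds from the
  master seed by a fixed counter scheme (`master mod 1e6 + 1009 * stage`)
  so stages can be replayed in isolation.
* The packaged simulation studies use sizes chosen to make Monte-Carlo
  error small relative to the effects being checked while keeping a full
  run comfortably interactive: one dataset of n = 1000 with 1000
  bootstrap resamples for the community-recovery check; 200 datasets of
  n = 1000 with 500 resamples each for the type-I calibration of the
  edge-inclusion rule; 50 replicates at n = 1094 (the sample size such
  online studies reach after exclusions) with 500 resamples for
  sign-recovery and bridge-node identification.

## Known limitations

* Spearman partial correlations of discretized Likert data are attenuated
  relative to the generating latent correlations; the generator's
  item-level path therefore recovers structure, not exact weights.
* CNM community detection on absolute weights ignores edge signs; strongly
  negative within-block edges would be misread as cohesion. The package
  keeps the signed matrix for all other modules.
* The bridge difference test conditions on the estimated network; its
  intervals do not propagate edge-selection uncertainty.
* Controllability values depend on the stabilization convention and are
  not comparable across normalizations.
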