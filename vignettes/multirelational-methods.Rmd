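---
title: "Methods: multirelational network analysis of an online health community"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multirelational network analysis of an online health community}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multiohc)
```

## The problem

Online health communities (OHCs) let members interact through several
distinct channels at once — here blogs (BL), message boards (MB),
threaded group discussions (GD) and private messages (PM). Each channel
induces its own directed social network, and the four layers together
form a multirelational (multiplex) network. Questions that motivate
this package: do the layers have different topologies? do the same
pairs of users connect in several layers, and in what temporal order?
and is a member's position across layers related to a health outcome
(here, 30-day smoking abstinence measured in a trial subsample)?

## The tie rule

All analyses start from raw event logs: content-creation events
(author, content item, channel, time) and content-access events
(reader, content item, time), plus private messages with send and read
times. The tie rule is *information flow*: a directed edge
`A -> B` exists in a layer iff B **read** content contributed by A in
that channel. Posting alone creates nothing; an unread private message
creates nothing. Replies reciprocate edges only through reading: if A
reads B's reply, the reply (itself authored content) induces `B -> A`.
Self-reads are discarded. Each edge carries a first-contact timestamp,
the earliest event that establishes it, which makes construction
invariant to the row order of the input log.

One modeling choice deserves emphasis: the event-log schema carries no
thread structure. If a platform logs "user read thread X", the ingest
step must expand that into per-item access rows (one per post the
reader plausibly saw). `build_channel_network()` is deliberately
per-item, so that expansion policy lives at the data-preparation
boundary where platform semantics are known, not inside the network
constructor.

## Topology

Per layer and for the aggregated union (`build_multinet()`), the
package reports:

* **Density** `E / (N (N - 1))`, with N counting only nodes of degree
  > 0. This convention — rather than counting all registered users —
  is the one under which the published per-layer densities are exact
  consequences of published node and edge counts, which the acceptance
  tests verify.
* **Reciprocity** as a dyad fraction: mutual dyads / connected dyads.
  Since edges are unique ordered pairs, `edges = connected + mutual`
  holds identically, giving the worked-example identity
  `mutual = edges - connected dyads` used by
  `reciprocity_from_counts()`. The edge-based alternative (2·mutual /
  edges) does *not* reproduce the published percentages and is not
  offered.
* **Largest strongly connected component** (via igraph), with a
  deterministic lexicographic tie-break for the degenerate case of
  equal-size components.
* **Mean shortest path within the LSCC**, exact by BFS from every
  member by default. Exactness is the default because the published
  analysis does not state a sampling scheme; for very large components
  `mean_path_sample` switches to uniform source sampling and the
  result is flagged approximate.
* **Degree histograms** over the node set, so read-only users appear
  at out-degree 0 (empirically there are many more zero out-degrees
  than zero in-degrees).

## Cross-layer similarity

* **Multiplexity**: for each unordered pair, the number of layers
  (1–4) in which it is connected, direction-agnostic.
* **Degree-rank correlations**: Spearman with average ranks; p-values
  from the t approximation. The node scope defaults to the *union* of
  both layers' active nodes with zero-filled degrees — the only scope
  defined for all layer pairs; an intersection scope is available by
  flag. Published in-degree correlations involving the PM layer are
  negative; whether that survives a different scope is unknowable
  without the raw data, so the scope is explicit and configurable.
* **Edge overlap**: Jaccard coefficients on directed ordered-pair edge
  sets, because the ties themselves are directed.

## Tie coevolution

For each connected pair, the pair-level first-tie time in a layer is
the minimum timestamp over both directions; sorting the layers by that
time gives the pair's tie sequence (length 1–4, layers distinct).
Equal first-tie times across layers are broken by the fixed order
BL < MB < GD < PM, and the number of affected pairs is reported —
determinism was preferred over an unstated rule. The coevolution
report gives, per starting layer *s*: P(hosting the first tie),
P(2nd tie elsewhere | start in *s*), P(3rd tie | start in *s*), and
the top 2- and 3-tie sequences. The analysis is pair-level and
direction-agnostic, which is the convention under which first-tie
counts must sum to the multiplexity pair total — an identity asserted
on every synthetic run. Published top-sequence percentages use
denominators that are not derivable from their source text, so the
report exposes raw counts and offers the share denominator as an
explicit option (`"start"` by default) rather than guessing.

## User profiling and outcomes

Trial participants are represented by 8-vectors of in/out degrees in
the four layers (`extract_profiles()`), zero for members with no
community activity — wholly inactive enrollees are a real and large
stratum. Profiles are clustered with a Gaussian mixture model fitted
by expectation-maximization (`fit_mixture()`):

* **raw degrees**, not log-transformed, because published group
  centroids are reported on the raw scale (a `log1p` transform can be
  applied by the caller);
* **full covariances with a ridge** of 10⁻⁶ on the diagonal —
  zero-inflated integer features make near-singular components routine;
* **best of 10 restarts** by default, each initialized from a k-means
  partition (random partition when k-means is infeasible), with the
  complete per-iteration log-likelihood trace retained per restart;
* **K selected by a likelihood plateau** (`select_k()`): the smallest
  K whose relative gain to K+1 falls below 5%. The 5% threshold
  operationalizes a verbal plateau criterion (observed gains of
  0.4–4% past the plateau versus 16–61% before it); it is a
  configurable parameter and is echoed in every report. If no K
  satisfies the rule, the maximum K is returned with a warning flag
  rather than silently.

Groups are relabeled by decreasing total mean degree, and group mean
vectors are arithmetic means of member profiles (not component means),
so they can be recounted exactly. Abstinence is compared between
groups with intent-to-treat rates (nonresponders counted as smoking)
and responder-only rates; pairwise two-group ANOVAs on the 0/1
indicator mirror the published comparisons, with `F = t²` against the
pooled-variance t. No multiple-testing correction is applied, matching
the published analysis; reports carry the raw p-values so any
correction can be applied downstream. Degenerate inputs are defined,
not errors: two constant groups with equal means give F = 0; with
different means the infinite F is flagged.

## The synthetic community generator

Raw OHC logs are proprietary, so `generate_event_log()` produces event
logs with the statistical structure the analysis assumes:

* **heavy-tailed degrees** from preferential reading — a reader picks
  an author with probability ∝ `(1 + in-layer in-degree)^0.8`;
* **a read-only cohort** (35% by default) with zero out-degree in
  every layer;
* **low PM reciprocity** from one-way welcome messages: 90% of users
  receive a greeter's welcome, replied to only with the coupling
  probability (15%), reproducing the "many in-degree-1 PM nodes"
  pattern;
* **cross-layer coupling**: each established reader–author pair can
  interact again in each other channel with probability 0.15. All
  coupling randomness is pre-drawn and thresholded, so raising the
  coupling parameter under a common seed only adds events — the
  multi-layer pair fraction is provably monotone, a property the test
  suite checks;
* **outcomes** from a logistic model on log(1 + total aggregated
  degree), intercept `qlogis(0.09)` (the abstinence rate of wholly
  inactive users in the motivating trial) and slope 0.35, with 40%
  survey nonresponse (the trial observed 41.6%).

Timestamps are integer event counters: every downstream computation
uses only their order. Defaults describe a community of 800 users with
a 300-user trial cohort and mean activity of 3 posts and 3 reads per
user per public channel — a deliberate scale-down (the motivating
community has ~71k active users) chosen so a full pipeline run takes
about a second. What the generator does **not** emulate: bursty
longitudinal activity, thread topic structure, user churn, or
content-dependent reading. Passing tests therefore demonstrate the
correctness of the *computations*, and that the statistical machinery
(tail detection, mixture recovery, slope recovery) behaves as designed
under known ground truth — not that any particular real community has
these parameter values.

## Numerical choices and degenerate inputs

* Density requires ≥ 2 nodes, reciprocity ≥ 1 edge, mean path an LSCC
  of ≥ 2; `topology_report()` maps these to `NA` instead of erroring
  so that a report exists for every layer.
* EM convergence: relative log-likelihood change below 10⁻⁸, cap 200
  iterations; component weights floored at 10⁻¹⁰ in the M-step to
  avoid division by zero when a component empties.
* `select_k` requires a contiguous K range so the plateau rule is
  well-defined.
* Spearman p-values are `pt`-based; |rho| = 1 maps to p = 0.
* All randomness flows from explicit seeds; the pipeline splits one
  root seed per stage (synthesis: seed, outcomes: seed + 1,
  clustering: seed + 2), so a report bundle is reproducible from its
  configuration alone.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(synth = synth_config(seed = 1),
                       out_dir = "ohc_out", k_range = 2:6,
                       restarts = 5, seed = 1)
res <- run_pipeline(cfg)
res$topology$AGG
res$coevolution
res$profiling$itt
```

The test-suite problem sizes (communities of 120–500 users, oracle
graphs of ≤ 50 nodes with 25 seeds each, mixture recovery at n = 600
over 10 seeds, slope recovery at n = 2000) were chosen as the smallest
scales at which each statistical property is stable.

## Known limitations

* The generator's marginal activity distributions are conventions, not
  estimates of any real platform.
* Exact reproduction of the published seven-group clustering is not
  attempted: the published analysis does not state covariance
  structure, restarts, or feature scaling.
* Group-discussion thread semantics are delegated to log preparation
  (see above); a platform whose logs only record thread-level reads
  needs an expansion step before ingest.
* The abstinence analysis is associational; nothing here supports
  causal claims about network position and cessation.
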