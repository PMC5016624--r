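# multiohc

Multirelational (multiplex) social-network analysis of online health
communities, for researchers studying how members of peer-support
platforms interact through multiple communication channels — blogs
(BL), message boards (MB), group discussions (GD) and private messages
(PM) — and how network position relates to health outcomes such as
smoking abstinence.

From timestamped post/read event logs the package builds four directed
subnetworks under an **information-flow tie rule**: an edge A → B in a
layer means that B *read* content contributed by A in that channel (an
unread post or message creates no tie). On top of the four layers and
their aggregated union it computes:

* **Topology** per layer: density `E / (N(N−1))` over nodes with
  degree > 0; dyadic reciprocity (mutual dyads / connected dyads,
  with the identity `mutual = edges − connected dyads`); the largest
  strongly connected component (LSCC) and the exact mean shortest
  path within it; in/out/total degree histograms.
* **Cross-layer similarity**: multiplexity counts (pairs connected in
  exactly k ∈ 1..4 layers), Spearman degree-rank correlation matrices
  with zero-filled union node scope, and edge-overlap Jaccard
  coefficients `|E_A ∩ E_B| / |E_A ∪ E_B|` on directed edges.
* **Tie coevolution**: each connected pair's layers ordered by
  pair-level first-tie time, giving P(layer hosts the first tie) and
  the conditional probabilities of 2nd/3rd ties in other layers, plus
  top tie sequences (e.g. `BL->MB->GD`).
* **User profiling**: trial participants embedded as 8-vectors of
  in/out degrees over the four layers, clustered with a
  full-covariance Gaussian mixture fitted by best-of-restarts EM with
  a likelihood-plateau rule for K; per-group intent-to-treat and
  responder-only abstinence rates and pairwise two-group ANOVAs.

A seeded synthetic community generator (`generate_event_log()`,
`generate_outcomes()`) reproduces the structural features this kind of
platform exhibits — heavy-tailed degrees from preferential reading, a
large read-only cohort, one-way welcome messages that depress
private-message reciprocity, cross-layer tie coupling, and abstinence
probability rising with centrality under heavy survey nonresponse — so
the whole pipeline is testable end to end without proprietary data.

## Worked example

```r
library(multiohc)

cfg <- synth_config(seed = 1)         # 800 users, 300-user trial cohort
log <- generate_event_log(cfg)
mn  <- build_multinet(log)

topology_report(mn$layers$PM)
#> <topology_report PM> N=772 E=1476 density=0.00248 reciprocity=0.0438
#>   lscc=310 (40.2%) path=5.42
topology_report(mn$aggregated)
#> <topology_report AGG> N=800 E=8773 density=0.0137 reciprocity=0.102
#>   lscc=531 (66.4%) path=2.82

coevolution_report(pair_timelines(mn))
#> <coevolution_report> 7964 connected pairs
#>  layer n_start    p_first  p_second    p_third   top2       top3
#>     BL    2440 0.30637870 0.3618852 0.05491803 BL->MB BL->MB->GD
#>     MB    2432 0.30537418 0.3404605 0.03577303 MB->BL MB->BL->GD
#>     GD    2380 0.29884480 0.3092437 0.03823529 GD->BL GD->BL->MB
#>     PM     712 0.08940231 0.3483146 0.03651685 PM->MB PM->BL->MB

out  <- generate_outcomes(log, cfg)
prof <- extract_profiles(mn, out$user_id)
grp  <- select_k(prof, k_range = 2:6, restarts = 5, seed = 3)
grp
#> <grouping_result> K=2; group sizes: 202, 98
group_abstinence(grp, out, "ITT")
#>   group   n n_responders n_abstinent       rate
#> 1     1 202          120          16 0.07920792
#> 2     2  98           62          10 0.10204082
```

Reading the output: the PM layer is sparse, weakly reciprocated
(4.4% of connected dyads are mutual — welcome messages are rarely
answered) and poorly connected (40% of its nodes in the LSCC), while
the aggregated network is well connected (66% in the LSCC, mean path
2.8). Only 8.9% of pairs form their first tie via private message.
The plateau rule settles on two profile groups — contributors (group
1, nonzero out-degrees) and lurkers (group 2, zero out-degrees). At
this deliberately small scale the two groups' intent-to-treat
abstinence rates (7.9% vs 10.2%, i.e. 16/202 vs 10/98) differ by less
than their sampling noise; the generating model's positive
degree–abstinence slope is recovered reliably at larger cohort sizes
(see the statistical tests and the acceptance script's
`synthetic_abstinence_slope_estimate`).

`run_pipeline(pipeline_config(...))` executes all stages and writes
every report (JSON/CSV/TSV) to an output directory.

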