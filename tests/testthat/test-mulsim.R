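two_layer_multinet <- function(edges_by_layer) {
  layers <- lapply(OHC_CHANNELS, function(ch) {
    channel_network(ch, edges_by_layer[[ch]])
  })
  names(layers) <- OHC_CHANNELS
  agg <- do.call(rbind, lapply(layers, function(l) l$edges))
  structure(list(layers = layers, aggregated = channel_network("AGG", agg)),
            class = "multinet")
}

test_that("multiplexity is direction-agnostic and counted once per pair", {
  mn <- two_layer_multinet(list(
    BL = data.frame(src = "A", dst = "B", first_ts = 1),
    MB = data.frame(src = "B", dst = "A", first_ts = 2)
  ))
  counts <- multiplexity_counts(mn)
  expect_equal(as.integer(counts), c(0L, 1L, 0L, 0L))
  expect_equal(attr(counts, "total"), 1L)
  empty <- two_layer_multinet(list())
  expect_equal(attr(multiplexity_counts(empty), "total"), 0L)
})

test_that("multiplexity matches exhaustive per-pair enumeration", {
  mn <- build_multinet(generate_event_log(small_cfg(seed = 33)))
  counts <- multiplexity_counts(mn)
  # brute force: for every unordered node pair, count layers connecting it
  nodes <- mn$aggregated$nodes
  brute <- integer(4)
  for (i in seq_along(nodes)) {
    for (j in seq_len(i - 1L)) {
      k <- 0L
      for (ch in OHC_CHANNELS) {
        e <- mn$layers[[ch]]$edges
        if (any((e$src == nodes[i] & e$dst == nodes[j]) |
                  (e$src == nodes[j] & e$dst == nodes[i]))) k <- k + 1L
      }
      if (k > 0) brute[k] <- brute[k] + 1L
    }
  }
  expect_equal(as.integer(counts), brute)
  # conservation against the union of connected pairs
  union_pairs <- unique(unlist(lapply(mn$layers, function(l) {
    paste(pmin(l$edges$src, l$edges$dst), pmax(l$edges$src, l$edges$dst))
  })))
  expect_equal(attr(counts, "total"), length(union_pairs))
})

test_that("degree-rank correlation handles perfect agreement and reversal", {
  eA <- data.frame(src = c("a", "a", "b"), dst = c("b", "c", "c"),
                   first_ts = 1:3)
  netA <- channel_network("BL", eA)
  netA2 <- channel_network("MB", eA)
  expect_equal(degree_rank_correlation(netA, netA2, "in")$rho, 1)
  # in-degrees (0,1,2) vs (2,1,0): exact reversal
  eB <- data.frame(src = c("c", "c", "b"), dst = c("b", "a", "a"),
                   first_ts = 1:3)
  netB <- channel_network("MB", eB)
  r <- degree_rank_correlation(netA, netB, "in")
  expect_equal(r$rho, -1)
  expect_equal(r$p, 0)
  expect_error(
    degree_rank_correlation(
      channel_network("BL", data.frame(src = "a", dst = "b", first_ts = 1)),
      channel_network("MB", data.frame(src = "a", dst = "b", first_ts = 1)),
      "in"),
    "insufficient")
})

test_that("Spearman matches the rank-then-Pearson oracle on random layers", {
  for (s in 1:25) {
    netA <- random_net(15, 0.15, seed = 3000 + s, channel = "BL")
    netB <- random_net(12, 0.2, seed = 4000 + s, channel = "MB")
    if (length(union(netA$nodes, netB$nodes)) < 3) next
    for (side in c("in", "out")) {
      r <- degree_rank_correlation(netA, netB, side)
      # independent recount of zero-filled degree vectors from edge lists
      nodes <- sort(union(netA$nodes, netB$nodes))
      dcol <- if (side == "in") "dst" else "src"
      x <- vapply(nodes, function(nd) sum(netA$edges[[dcol]] == nd),
                  numeric(1))
      y <- vapply(nodes, function(nd) sum(netB$edges[[dcol]] == nd),
                  numeric(1))
      expect_equal(r$rho, spearman_oracle(x, y))
      ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                             exact = FALSE))
      expect_equal(r$p, ct$p.value, tolerance = 1e-12)
    }
  }
})

test_that("edge Jaccard counts directed overlap", {
  a <- channel_network("BL", data.frame(src = c("1", "2"),
                                        dst = c("2", "3"), first_ts = 1:2))
  b <- channel_network("MB", data.frame(src = c("2", "3"),
                                        dst = c("3", "1"), first_ts = 1:2))
  expect_equal(edge_jaccard(a, b), 1 / 3)
  expect_equal(edge_jaccard(a, a), 1)
  disjoint <- channel_network("GD", data.frame(src = "8", dst = "9",
                                               first_ts = 1))
  expect_equal(edge_jaccard(a, disjoint), 0)
  expect_error(edge_jaccard(channel_network("BL"), channel_network("MB")),
               "empty")
  # symmetry on random nets
  for (s in 1:10) {
    x <- random_net(10, 0.2, seed = 600 + s, channel = "BL")
    y <- random_net(10, 0.2, seed = 700 + s, channel = "MB")
    if (!nrow(x$edges) && !nrow(y$edges)) next
    expect_equal(edge_jaccard(x, y), edge_jaccard(y, x))
  }
})

test_that("the similarity report has symmetric, bounded matrices", {
  mn <- build_multinet(generate_event_log(small_cfg(seed = 41)))
  sim <- similarity_report(mn)
  expect_equal(sim$jaccard, t(sim$jaccard))
  off <- sim$jaccard[row(sim$jaccard) != col(sim$jaccard)]
  expect_true(all(off >= 0 & off <= 1))
  sp <- sim$spearman_in[row(sim$spearman_in) != col(sim$spearman_in)]
  expect_true(all(abs(sp) <= 1))
  expect_equal(sum(sim$multiplexity), attr(sim$multiplexity, "total"))
})
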