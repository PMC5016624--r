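# Shared fixtures and independent brute-force oracles.

# Random directed graph as a channel_network, edges timestamped 1..E.
random_net <- function(n, p, seed, channel = "BL") {
  set.seed(seed)
  nodes <- sprintf("u%02d", seq_len(n))
  pairs <- expand.grid(src = nodes, dst = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$src != pairs$dst, ]
  keep <- runif(nrow(pairs)) < p
  e <- pairs[keep, , drop = FALSE]
  if (!nrow(e)) return(channel_network(channel))
  e$first_ts <- seq_len(nrow(e))
  channel_network(channel, e)
}

# Reachability closure by the Warshall algorithm (O(n^3) oracle).
warshall_reach <- function(net) {
  nodes <- net$nodes
  n <- length(nodes)
  R <- diag(TRUE, n)
  R[cbind(match(net$edges$src, nodes), match(net$edges$dst, nodes))] <- TRUE
  for (k in seq_len(n)) {
    R <- R | (R[, k] %o% R[k, ])
  }
  dimnames(R) <- list(nodes, nodes)
  R
}

# LSCC membership via the closure: u,v strongly connected iff both reach
# each other; components from the equivalence classes, largest wins,
# size ties broken by smallest member.
scc_oracle <- function(net) {
  if (!length(net$nodes)) return(character())
  R <- warshall_reach(net)
  M <- R & t(R)
  classes <- unique(apply(M, 1, function(r) paste(which(r), collapse = ",")))
  comps <- lapply(classes, function(cl) {
    net$nodes[as.integer(strsplit(cl, ",")[[1]])]
  })
  sizes <- lengths(comps)
  best <- comps[sizes == max(sizes)]
  mins <- vapply(best, min, character(1))
  sort(best[[order(mins)[1]]])
}

# All-pairs shortest paths by Floyd-Warshall; mean over ordered pairs of
# `members` (u != v).
mean_path_oracle <- function(net, members) {
  nodes <- net$nodes
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  D[cbind(match(net$edges$src, nodes), match(net$edges$dst, nodes))] <- 1
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  d <- D[members, members]
  mean(d[row(d) != col(d)])
}

# Rank-then-Pearson Spearman oracle with average ranks.
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Tiny hand-rolled event log: A blogs, B reads and comments, A reads the
# comment; one read private message, one unread.
toy_log <- function() {
  event_log(
    creations = data.frame(
      author_id = c("A", "B"),
      content_id = c("blog1", "comment1"),
      channel = c("BL", "BL"),
      ts = c(1, 3),
      stringsAsFactors = FALSE
    ),
    accesses = data.frame(
      reader_id = c("B", "A"),
      content_id = c("blog1", "comment1"),
      ts = c(2, 4),
      stringsAsFactors = FALSE
    ),
    pm = data.frame(
      sender_id = c("A", "B"),
      recipient_id = c("C", "C"),
      message_id = c("m1", "m2"),
      send_ts = c(5, 7),
      read_ts = c(6, NA),
      stringsAsFactors = FALSE
    )
  )
}

# A small but multi-layer synthetic community used across tests.
small_cfg <- function(seed = 11, ...) {
  synth_config(n_users = 120, n_trial_users = 60, activity_rate = 2,
               coupling = 0.3, seed = seed, ...)
}

# Adjusted Rand index between two labelings (contingency-table formula).
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  exp_ <- si * sj / comb2(sum(tab))
  (sij - exp_) / ((si + sj) / 2 - exp_)
}
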