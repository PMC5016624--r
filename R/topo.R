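#' Directed network density
#'
#' Density of a directed network without self-loops: `E / (N * (N - 1))`
#' with `N` the number of nodes of degree > 0 (the network's node set)
#' and `E` the number of directed edges.
#'
#' @param net A [channel_network()] with at least 2 nodes.
#' @return Density in `[0, 1]`.
#' @seealso [density_from_counts()] for the summary-count form.
#' @export
net_density <- function(net) {
  stopifnot(inherits(net, "channel_network"))
  density_from_counts(length(net$nodes), nrow(net$edges))
}

#' Density from printed node and edge counts
#'
#' @param n_nodes Number of nodes with degree > 0 (must be >= 2).
#' @param n_edges Number of directed edges.
#' @return `n_edges / (n_nodes * (n_nodes - 1))`.
#' @export
#' @examples
#' density_from_counts(14827, 956506)  # 4.35e-3
density_from_counts <- function(n_nodes, n_edges) {
  if (n_nodes < 2) stop("density undefined for networks with fewer than 2 nodes")
  n_edges / (n_nodes * (n_nodes - 1))
}

#' Dyadic reciprocity
#'
#' Counts connected dyads (unordered node pairs with at least one edge)
#' and mutual dyads (pairs with edges in both directions), and returns
#' the fraction mutual / connected. Because edges are unique ordered
#' pairs, the identity `edges = connected + mutual` holds by
#' construction.
#'
#' @param net A [channel_network()] with at least one edge.
#' @return List with `mutual`, `connected` and `fraction`.
#' @seealso [reciprocity_from_counts()]
#' @export
#' @examples
#' net <- channel_network("BL", data.frame(src = c("a", "b"),
#'                                         dst = c("b", "a"),
#'                                         first_ts = 1:2))
#' reciprocity(net)  # 1 mutual of 1 connected dyad
reciprocity <- function(net) {
  stopifnot(inherits(net, "channel_network"))
  e <- net$edges
  if (!nrow(e)) stop("reciprocity undefined for a network with no edges")
  key <- paste(pmin(e$src, e$dst), pmax(e$src, e$dst), sep = "\x1f")
  mutual <- sum(duplicated(key))
  connected <- nrow(e) - mutual
  list(mutual = mutual, connected = connected,
       fraction = mutual / connected)
}

#' Reciprocity from printed edge and dyad counts
#'
#' Under the dyad convention, every mutual dyad contributes two directed
#' edges and every asymmetric dyad one, so
#' `mutual = edges - connected dyads`.
#'
#' @param n_edges Number of directed edges.
#' @param n_connected_dyads Number of unordered pairs with >= 1 edge.
#' @return List with `mutual`, `connected` and `fraction`.
#' @export
#' @examples
#' reciprocity_from_counts(60555, 55585)  # 4970 mutual, 8.94%
reciprocity_from_counts <- function(n_edges, n_connected_dyads) {
  if (n_connected_dyads <= 0) stop("no connected dyads")
  mutual <- n_edges - n_connected_dyads
  list(mutual = mutual, connected = n_connected_dyads,
       fraction = mutual / n_connected_dyads)
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("src", "dst")],
                                directed = TRUE, vertices = net$nodes)
}

#' Largest strongly connected component
#'
#' The maximal node set with a directed path between every ordered pair.
#' Size ties (possible on small or degenerate networks) are broken by
#' the component containing the lexicographically smallest node id, so
#' the result is deterministic.
#'
#' @param net A [channel_network()].
#' @return List with `members` (sorted character vector; empty for an
#'   empty network) and `fraction` of the network's nodes (NA when the
#'   network has no nodes).
#' @export
largest_scc <- function(net) {
  stopifnot(inherits(net, "channel_network"))
  if (!length(net$nodes)) {
    return(list(members = character(), fraction = NA_real_))
  }
  comp <- igraph::components(as_igraph(net), mode = "strong")
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    mins <- vapply(best, function(b) {
      min(net$nodes[comp$membership == b])
    }, character(1))
    best <- best[order(mins)][1L]
  }
  members <- sort(net$nodes[comp$membership == best])
  list(members = members, fraction = length(members) / length(net$nodes))
}

#' Mean shortest path length within the largest strongly connected component
#'
#' Unweighted directed shortest-path lengths averaged over all ordered
#' pairs `(u, v)`, `u != v`, of LSCC members, exact by breadth-first
#' search from every member. For very large components a uniform sample
#' of source nodes can be used instead; the result is then flagged via
#' the `"approximate"` attribute.
#'
#' @param net A [channel_network()] whose LSCC has >= 2 nodes.
#' @param sample_size Optional number of BFS source nodes to sample; NULL
#'   (default) computes the exact mean.
#' @param seed Optional seed for source sampling.
#' @return Mean path length (>= 1), with attribute `approximate`.
#' @export
mean_shortest_path_lscc <- function(net, sample_size = NULL, seed = NULL) {
  scc <- largest_scc(net)
  m <- length(scc$members)
  if (m < 2) stop("mean shortest path undefined: LSCC has fewer than 2 nodes")
  g <- igraph::induced_subgraph(as_igraph(net), scc$members)
  approx <- !is.null(sample_size) && sample_size < m
  sources <- igraph::V(g)
  if (approx) {
    if (!is.null(seed)) set.seed(seed)
    sources <- sources[sample.int(m, sample_size)]
  }
  d <- igraph::distances(g, v = sources, to = igraph::V(g), mode = "out")
  res <- sum(d) / (length(sources) * (m - 1))  # diagonal zeros drop out
  attr(res, "approximate") <- approx
  res
}

#' Exact in-, out- and total-degree frequency tables
#'
#' Frequencies are over the network's node set (degree > 0 overall), so
#' read-only users appear with out-degree 0 and write-only users with
#' in-degree 0. Total degree counts distinct neighbors irrespective of
#' direction.
#'
#' @param net A [channel_network()].
#' @return List of three data frames (`in`, `out`, `total`), each with
#'   columns `degree` and `count`; empty frames for an empty network.
#' @export
degree_histograms <- function(net) {
  deg <- net_degrees(net)
  hist1 <- function(x) {
    if (!length(x)) {
      return(data.frame(degree = integer(), count = integer()))
    }
    tb <- table(x)
    data.frame(degree = as.integer(names(tb)), count = as.integer(tb))
  }
  list(`in` = hist1(deg$in_deg), out = hist1(deg$out_deg),
       total = hist1(deg$total))
}

#' Full topological report for one network
#'
#' Assembles node/edge counts, density, the dyad census (connected and
#' mutual dyads, reciprocity), the largest strongly connected component,
#' the mean shortest path within it, and degree histograms. Quantities
#' undefined on degenerate networks (density with < 2 nodes, reciprocity
#' with no edges, paths with an LSCC < 2) are reported as `NA` rather
#' than raising.
#'
#' @param net A [channel_network()].
#' @param mean_path_sample Optional BFS source sample size passed to
#'   [mean_shortest_path_lscc()]; the default (NULL) is exact.
#' @param seed Seed for path sampling, if any.
#' @return A list of class `topology_report`.
#' @export
topology_report <- function(net, mean_path_sample = NULL, seed = NULL) {
  n <- length(net$nodes)
  e <- nrow(net$edges)
  rec <- if (e > 0) reciprocity(net) else
    list(mutual = 0L, connected = 0L, fraction = NA_real_)
  scc <- largest_scc(net)
  mp <- if (length(scc$members) >= 2) {
    mean_shortest_path_lscc(net, sample_size = mean_path_sample, seed = seed)
  } else NA_real_
  structure(list(
    channel = net$channel,
    n_nodes = n,
    n_edges = e,
    density = if (n >= 2) density_from_counts(n, e) else NA_real_,
    connected_dyads = rec$connected,
    mutual_dyads = rec$mutual,
    reciprocity = rec$fraction,
    lscc_size = length(scc$members),
    lscc_fraction = scc$fraction,
    mean_path_lscc = as.numeric(mp),
    mean_path_approximate = isTRUE(attr(mp, "approximate")),
    degree_histograms = degree_histograms(net)
  ), class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf(
    "<topology_report %s> N=%d E=%d density=%.3g reciprocity=%.3g lscc=%d (%.1f%%) path=%.3g\n",
    x$channel, x$n_nodes, x$n_edges, x$density, x$reciprocity,
    x$lscc_size, 100 * x$lscc_fraction, x$mean_path_lscc))
  invisible(x)
}
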