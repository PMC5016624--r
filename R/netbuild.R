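#' Construct a channel network object
#'
#' Low-level constructor for one directed layer. Edges are unique ordered
#' pairs carrying the first-contact timestamp; the node set is exactly
#' the users with degree > 0 (any endpoint of an edge). Node ids are
#' normalized to character.
#'
#' @param channel Channel label: `"BL"`, `"MB"`, `"GD"`, `"PM"` or
#'   `"AGG"` (aggregated union view).
#' @param edges Data frame with columns `src`, `dst`, `first_ts`; rows
#'   with `src == dst` are rejected, duplicate ordered pairs collapsed to
#'   the minimum timestamp.
#' @return An object of class `channel_network` with elements `channel`,
#'   `edges` and `nodes`.
#' @export
channel_network <- function(channel, edges = NULL) {
  if (!channel %in% c(OHC_CHANNELS, "AGG")) {
    stop("unknown channel token: ", channel)
  }
  if (is.null(edges) || !nrow(edges)) {
    edges <- data.frame(src = character(), dst = character(),
                        first_ts = numeric(), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(src = as.character(edges$src),
                        dst = as.character(edges$dst),
                        first_ts = as.numeric(edges$first_ts),
                        stringsAsFactors = FALSE)
    if (any(edges$src == edges$dst)) stop("self-loop edges are not allowed")
    edges <- edges[order(edges$first_ts, edges$src, edges$dst), ,
                   drop = FALSE]
    keep <- !duplicated(paste(edges$src, edges$dst, sep = "\x1f"))
    edges <- edges[keep, , drop = FALSE]
    edges <- edges[order(edges$src, edges$dst), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(channel = channel,
                 edges = edges,
                 nodes = sort(unique(c(edges$src, edges$dst)))),
            class = "channel_network")
}

#' @export
print.channel_network <- function(x, ...) {
  cat("<channel_network ", x$channel, "> ", length(x$nodes), " nodes, ",
      nrow(x$edges), " directed edges\n", sep = "")
  invisible(x)
}

#' Build one directed subnetwork from an event log
#'
#' Applies the information-flow tie rule. For the public channels (BL,
#' MB, GD) an edge `A -> B` exists iff `B` accessed (read) content
#' authored by `A` in that channel — so reading a reply creates the
#' reciprocating edge, because the reply is itself authored content. For
#' PM an edge `A -> B` exists iff `B` read a private message sent by `A`;
#' delivery alone creates no tie. Self-interactions are discarded. The
#' edge timestamp is the earliest qualifying access/read event, so the
#' result is invariant to the row order of the input log.
#'
#' @param log An [event_log()].
#' @param channel One of `"BL"`, `"MB"`, `"GD"`, `"PM"`.
#' @return A [channel_network()].
#' @export
#' @examples
#' log <- generate_event_log(synth_config(n_users = 60, n_trial_users = 10,
#'                                        seed = 3))
#' build_channel_network(log, "BL")
build_channel_network <- function(log, channel) {
  validate_event_log(log)
  if (length(channel) != 1L || !channel %in% OHC_CHANNELS) {
    stop("unknown channel token: ", paste(channel, collapse = ","))
  }
  if (channel == "PM") {
    p <- log$pm[!is.na(log$pm$read_ts), , drop = FALSE]
    edges <- data.frame(src = p$sender_id, dst = p$recipient_id,
                        first_ts = p$read_ts, stringsAsFactors = FALSE)
  } else {
    cre <- log$creations[log$creations$channel == channel, , drop = FALSE]
    idx <- match(log$accesses$content_id, cre$content_id)
    hit <- !is.na(idx)
    edges <- data.frame(src = cre$author_id[idx[hit]],
                        dst = log$accesses$reader_id[hit],
                        first_ts = log$accesses$ts[hit],
                        stringsAsFactors = FALSE)
  }
  edges <- edges[as.character(edges$src) != as.character(edges$dst), ,
                 drop = FALSE]
  channel_network(channel, edges)
}

#' Build the multirelational network (four layers + aggregated view)
#'
#' Builds all four channel layers and their aggregated union: the
#' aggregated node set is the union of layer node sets and the aggregated
#' edge set is the exact union of layer edge sets, each edge stamped with
#' the minimum first-contact time across layers. An empty log yields an
#' empty network.
#'
#' @param log An [event_log()].
#' @return An object of class `multinet`: a list with `layers` (named
#'   list of four [channel_network()]s) and `aggregated`.
#' @export
build_multinet <- function(log) {
  validate_event_log(log)
  layers <- lapply(OHC_CHANNELS, function(ch) build_channel_network(log, ch))
  names(layers) <- OHC_CHANNELS
  agg_edges <- do.call(rbind, lapply(layers, function(l) l$edges))
  mn <- structure(list(layers = layers,
                       aggregated = channel_network("AGG", agg_edges)),
                  class = "multinet")
  mn
}

#' @export
print.multinet <- function(x, ...) {
  cat("<multinet>\n")
  for (l in c(x$layers, list(x$aggregated))) {
    cat(sprintf("  %-3s %7d nodes %9d edges\n", l$channel,
                length(l$nodes), nrow(l$edges)))
  }
  invisible(x)
}

#' Write a channel network as a timestamped edge-list TSV
#'
#' Columns `src`, `dst`, `channel`, `first_ts`, tab-separated with a
#' header row. [read_edgelist()] restores the network losslessly.
#'
#' @param net A [channel_network()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(net, path) {
  stopifnot(inherits(net, "channel_network"))
  df <- data.frame(src = net$edges$src, dst = net$edges$dst,
                   channel = rep(net$channel, nrow(net$edges)),
                   first_ts = net$edges$first_ts,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a timestamped edge-list TSV written by [write_edgelist()]
#'
#' @param path File path.
#' @return A [channel_network()].
#' @export
read_edgelist <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c(src = "character", dst = "character",
                                  channel = "character",
                                  first_ts = "numeric"))
  ch <- unique(df$channel)
  if (length(ch) > 1L) stop("edge list mixes channels: ",
                            paste(ch, collapse = ", "))
  if (!length(ch)) ch <- "AGG"
  channel_network(ch, df[, c("src", "dst", "first_ts")])
}

#' Per-node degrees of a channel network
#'
#' In-degree = number of distinct in-neighbors, out-degree = distinct
#' out-neighbors, total degree = distinct neighbors irrespective of
#' direction (a mutual dyad counts once). Only nodes of the network
#' (degree > 0 overall) appear.
#'
#' @param net A [channel_network()].
#' @return Data frame with columns `node`, `in_deg`, `out_deg`, `total`.
#' @export
net_degrees <- function(net) {
  stopifnot(inherits(net, "channel_network"))
  nodes <- net$nodes
  e <- net$edges
  in_deg <- tabulate(match(e$dst, nodes), nbins = length(nodes))
  out_deg <- tabulate(match(e$src, nodes), nbins = length(nodes))
  a <- pmin(e$src, e$dst); b <- pmax(e$src, e$dst)
  keep <- !duplicated(paste(a, b, sep = "\x1f"))
  total <- tabulate(match(c(a[keep], b[keep]), nodes),
                    nbins = length(nodes))
  data.frame(node = nodes, in_deg = in_deg, out_deg = out_deg,
             total = total, stringsAsFactors = FALSE)
}
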