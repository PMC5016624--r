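pair_keys <- function(net) {
  e <- net$edges
  unique(paste(pmin(e$src, e$dst), pmax(e$src, e$dst), sep = "\x1f"))
}

edge_keys <- function(net) {
  paste(net$edges$src, net$edges$dst, sep = "\x1f")
}

#' Multiplexity counts: pairs connected in exactly k layers
#'
#' A pair is "connected in a layer" iff at least one directed edge in
#' either direction exists there; direction is ignored, so a pair with
#' `A -> B` in one layer and `B -> A` in another counts once under k = 2.
#'
#' @param multinet A [build_multinet()] result.
#' @return Named integer vector `c("1", "2", "3", "4")` with attribute
#'   `total` (total connected pairs = sum of counts).
#' @export
multiplexity_counts <- function(multinet) {
  stopifnot(inherits(multinet, "multinet"))
  keys <- unlist(lapply(multinet$layers, pair_keys), use.names = FALSE)
  counts <- integer(4)
  if (length(keys)) {
    k <- table(table(keys))
    counts[as.integer(names(k))] <- as.integer(k)
  }
  names(counts) <- as.character(1:4)
  attr(counts, "total") <- sum(counts)
  counts
}

#' Spearman rank correlation of node degrees between two layers
#'
#' Correlates each node's in- (or out-) degree in one layer with the same
#' node's degree in another, using average ranks for ties and the
#' t-distribution approximation for the p-value. The default node scope
#' is the union of both layers' nodes, with degree 0 filled in for the
#' layer a node is absent from (the only scope defined for every pair of
#' layers); `scope = "intersection"` restricts to nodes active in both.
#'
#' @param netA,netB Two [channel_network()]s.
#' @param side `"in"` or `"out"`.
#' @param scope `"union"` (default, zero-filled) or `"intersection"`.
#' @return List with `rho`, `p` and `n` (nodes in scope).
#' @export
degree_rank_correlation <- function(netA, netB, side = c("in", "out"),
                                    scope = c("union", "intersection")) {
  side <- match.arg(side)
  scope <- match.arg(scope)
  dA <- net_degrees(netA); dB <- net_degrees(netB)
  col <- if (side == "in") "in_deg" else "out_deg"
  nodes <- if (scope == "union") {
    sort(unique(c(dA$node, dB$node)))
  } else {
    sort(intersect(dA$node, dB$node))
  }
  if (length(nodes) < 3) {
    stop("insufficient data: fewer than 3 nodes in the ", scope, " scope")
  }
  x <- dA[[col]][match(nodes, dA$node)]; x[is.na(x)] <- 0
  y <- dB[[col]][match(nodes, dB$node)]; y[is.na(y)] <- 0
  n <- length(nodes)
  rho <- stats::cor(rank(x), rank(y))
  if (is.na(rho)) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  if (abs(rho) >= 1 - 1e-15) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Edge-overlap Jaccard coefficient between two layers
#'
#' `|E_A intersect E_B| / |E_A union E_B|` over directed (ordered-pair)
#' edge sets, because ties are directed.
#'
#' @param netA,netB Two [channel_network()]s, not both empty.
#' @return Jaccard coefficient in `[0, 1]`.
#' @export
#' @examples
#' a <- channel_network("BL", data.frame(src = c("1", "2"),
#'                                       dst = c("2", "3"), first_ts = 1:2))
#' b <- channel_network("MB", data.frame(src = c("2", "3"),
#'                                       dst = c("3", "1"), first_ts = 1:2))
#' edge_jaccard(a, b)  # 1/3
edge_jaccard <- function(netA, netB) {
  ea <- edge_keys(netA); eb <- edge_keys(netB)
  u <- length(union(ea, eb))
  if (u == 0) stop("Jaccard undefined: both edge sets are empty")
  length(intersect(ea, eb)) / u
}

#' Cross-layer structural similarity report
#'
#' Multiplexity counts plus 4x4 matrices of in-degree and out-degree
#' Spearman correlations (with p-values) and edge-overlap Jaccard
#' coefficients. Entries that are undefined (a layer pair with an empty
#' union, or fewer than 3 nodes in scope) are `NA`.
#'
#' @param multinet A [build_multinet()] result.
#' @param scope Node scope for correlations; see
#'   [degree_rank_correlation()].
#' @return A list of class `similarity_report` with elements
#'   `multiplexity`, `spearman_in`, `spearman_in_p`, `spearman_out`,
#'   `spearman_out_p`, `jaccard`.
#' @export
similarity_report <- function(multinet, scope = "union") {
  stopifnot(inherits(multinet, "multinet"))
  ch <- OHC_CHANNELS
  mk <- function() matrix(NA_real_, 4, 4, dimnames = list(ch, ch))
  sp_in <- sp_in_p <- sp_out <- sp_out_p <- jac <- mk()
  for (i in 1:4) {
    for (j in 1:4) {
      if (i == j) next
      a <- multinet$layers[[ch[i]]]; b <- multinet$layers[[ch[j]]]
      ri <- tryCatch(degree_rank_correlation(a, b, "in", scope),
                     error = function(e) NULL)
      ro <- tryCatch(degree_rank_correlation(a, b, "out", scope),
                     error = function(e) NULL)
      if (!is.null(ri)) { sp_in[i, j] <- ri$rho; sp_in_p[i, j] <- ri$p }
      if (!is.null(ro)) { sp_out[i, j] <- ro$rho; sp_out_p[i, j] <- ro$p }
      jac[i, j] <- tryCatch(edge_jaccard(a, b), error = function(e) NA_real_)
    }
  }
  structure(list(multiplexity = multiplexity_counts(multinet),
                 spearman_in = sp_in, spearman_in_p = sp_in_p,
                 spearman_out = sp_out, spearman_out_p = sp_out_p,
                 jaccard = jac, scope = scope),
            class = "similarity_report")
}
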