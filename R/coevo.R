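#' Per-pair tie-formation timelines across layers
#'
#' For every unordered user pair connected in at least one layer, takes
#' the pair-level first-tie time in each layer (the minimum timestamp
#' over both edge directions) and orders the layers by that time. Equal
#' first-tie times across layers are broken by the fixed channel order
#' BL < MB < GD < PM; the number of pairs affected by this tie-break is
#' recorded in the `ties_broken` attribute.
#'
#' @param multinet A [build_multinet()] result with timestamps on every
#'   edge.
#' @return Data frame of class `pair_timelines` with one row per
#'   connected pair: `a`, `b` (the pair, `a < b`), `n_layers`,
#'   `sequence` (channel tokens joined by `"->"`), `first_layer`,
#'   `seq2`/`seq3` (the first 2/3 layers, `NA` when shorter) and
#'   `first_ts`.
#' @export
pair_timelines <- function(multinet) {
  stopifnot(inherits(multinet, "multinet"))
  parts <- lapply(OHC_CHANNELS, function(ch) {
    e <- multinet$layers[[ch]]$edges
    if (!nrow(e)) return(NULL)
    if (any(is.na(e$first_ts))) {
      bad <- which(is.na(e$first_ts))[1L]
      stop("missing timestamp on edge ", e$src[bad], " -> ", e$dst[bad],
           " in layer ", ch)
    }
    a <- pmin(e$src, e$dst); b <- pmax(e$src, e$dst)
    key <- paste(a, b, sep = "\x1f")
    ord <- order(key, e$first_ts)
    keep <- !duplicated(key[ord])
    data.frame(a = a[ord][keep], b = b[ord][keep],
               layer = ch, t = e$first_ts[ord][keep],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, parts)
  if (is.null(df) || !nrow(df)) {
    res <- data.frame(a = character(), b = character(),
                      n_layers = integer(), sequence = character(),
                      first_layer = character(), seq2 = character(),
                      seq3 = character(), first_ts = numeric(),
                      stringsAsFactors = FALSE)
    class(res) <- c("pair_timelines", "data.frame")
    attr(res, "ties_broken") <- 0L
    return(res)
  }
  li <- match(df$layer, OHC_CHANNELS)
  key <- paste(df$a, df$b, sep = "\x1f")
  ord <- order(key, df$t, li)
  df <- df[ord, , drop = FALSE]
  key <- key[ord]
  grp <- cumsum(!duplicated(key))
  ties_broken <- sum(vapply(split(df$t, grp),
                            function(t) anyDuplicated(t) > 0, logical(1)))
  seqs <- split(df$layer, grp)
  first_row <- !duplicated(key)
  res <- data.frame(
    a = df$a[first_row], b = df$b[first_row],
    n_layers = lengths(seqs),
    sequence = vapply(seqs, paste, character(1), collapse = "->"),
    first_layer = df$layer[first_row],
    seq2 = vapply(seqs, function(s) {
      if (length(s) >= 2) paste(s[1:2], collapse = "->") else NA_character_
    }, character(1)),
    seq3 = vapply(seqs, function(s) {
      if (length(s) >= 3) paste(s[1:3], collapse = "->") else NA_character_
    }, character(1)),
    first_ts = df$t[first_row],
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  class(res) <- c("pair_timelines", "data.frame")
  attr(res, "ties_broken") <- as.integer(ties_broken)
  res
}

#' Coevolution report: first-tie attribution and subsequent-tie probabilities
#'
#' For each layer `s`: the probability of hosting a pair's first tie
#' (`P = pairs starting in s / all connected pairs`), the conditional
#' probabilities that a pair starting in `s` forms a 2nd (resp. 3rd) tie
#' in another layer, and the most common 2-tie and 3-tie sequences
#' starting in `s` (ranked by count, lexicographic tie-break). Raw
#' integer counts back every probability so alternative share
#' denominators can be recomputed.
#'
#' @param timelines A [pair_timelines()] result with >= 1 row.
#' @param top_denominator Denominator for the top-sequence shares:
#'   `"start"` (default; all pairs whose first tie is in `s`) or `"ge2"`
#'   (pairs starting in `s` with >= 2 ties; `"ge3"` for 3-tie
#'   sequences).
#' @return A list of class `coevolution_report` with `total_pairs`,
#'   `ties_broken` and a per-layer data frame `layers` (columns
#'   `layer`, `n_start`, `p_first`, `n_ge2`, `p_second`, `n_ge3`,
#'   `p_third`, `top2`, `top2_count`, `top2_share`, `top3`,
#'   `top3_count`, `top3_share`).
#' @export
coevolution_report <- function(timelines,
                               top_denominator = c("start", "ge2")) {
  top_denominator <- match.arg(top_denominator)
  if (!inherits(timelines, "pair_timelines")) {
    stop("timelines must come from pair_timelines()")
  }
  if (!nrow(timelines)) stop("no timelines: empty input")
  total <- nrow(timelines)
  rows <- lapply(OHC_CHANNELS, function(s) {
    tl <- timelines[timelines$first_layer == s, , drop = FALSE]
    n_start <- nrow(tl)
    n_ge2 <- sum(tl$n_layers >= 2)
    n_ge3 <- sum(tl$n_layers >= 3)
    top_of <- function(x) {
      x <- x[!is.na(x)]
      if (!length(x)) return(list(seq = NA_character_, count = 0L))
      tb <- table(x)
      tb <- tb[order(-tb, names(tb))]  # count desc, then lexicographic
      list(seq = names(tb)[1L], count = as.integer(tb[1L]))
    }
    t2 <- top_of(tl$seq2)
    t3 <- top_of(tl$seq3)
    den2 <- if (top_denominator == "start") n_start else n_ge2
    den3 <- if (top_denominator == "start") n_start else n_ge3
    data.frame(layer = s, n_start = n_start,
               p_first = n_start / total,
               n_ge2 = n_ge2,
               p_second = if (n_start) n_ge2 / n_start else NA_real_,
               n_ge3 = n_ge3,
               p_third = if (n_start) n_ge3 / n_start else NA_real_,
               top2 = t2$seq, top2_count = t2$count,
               top2_share = if (den2 > 0 && t2$count > 0)
                 t2$count / den2 else NA_real_,
               top3 = t3$seq, top3_count = t3$count,
               top3_share = if (den3 > 0 && t3$count > 0)
                 t3$count / den3 else NA_real_,
               stringsAsFactors = FALSE)
  })
  structure(list(total_pairs = total,
                 ties_broken = attr(timelines, "ties_broken"),
                 top_denominator = top_denominator,
                 layers = do.call(rbind, rows)),
            class = "coevolution_report")
}

#' @export
print.coevolution_report <- function(x, ...) {
  cat("<coevolution_report> ", x$total_pairs, " connected pairs\n", sep = "")
  print(x$layers[, c("layer", "n_start", "p_first", "p_second", "p_third",
                     "top2", "top3")], row.names = FALSE)
  invisible(x)
}
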