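multinet_from_edges <- function(edges_by_layer) {
  layers <- lapply(OHC_CHANNELS, function(ch) {
    channel_network(ch, edges_by_layer[[ch]])
  })
  names(layers) <- OHC_CHANNELS
  agg <- do.call(rbind, lapply(layers, function(l) l$edges))
  structure(list(layers = layers, aggregated = channel_network("AGG", agg)),
            class = "multinet")
}

test_that("timelines order distinct layers by pair-level first-tie time", {
  mn <- multinet_from_edges(list(
    BL = data.frame(src = "A", dst = "B", first_ts = 7),
    MB = data.frame(src = c("B", "A"), dst = c("A", "C"),
                    first_ts = c(2, 1)),
    GD = data.frame(src = "B", dst = "A", first_ts = 4)
  ))
  tl <- pair_timelines(mn)
  ab <- tl[tl$a == "A" & tl$b == "B", ]
  expect_equal(ab$sequence, "MB->GD->BL")
  expect_equal(ab$first_layer, "MB")
  expect_equal(ab$n_layers, 3L)
  expect_equal(ab$seq2, "MB->GD")
  ac <- tl[tl$a == "A" & tl$b == "C", ]
  expect_equal(ac$sequence, "MB")
  expect_true(is.na(ac$seq2))
})

test_that("the pair-level first-tie time is the minimum over both directions", {
  mn <- multinet_from_edges(list(
    BL = data.frame(src = c("A", "B"), dst = c("B", "A"),
                    first_ts = c(9, 3)),
    MB = data.frame(src = "A", dst = "B", first_ts = 5)
  ))
  tl <- pair_timelines(mn)
  expect_equal(tl$sequence, "BL->MB")
  expect_equal(tl$first_ts, 3)
})

test_that("equal first-tie times break by the fixed channel order", {
  mn <- multinet_from_edges(list(
    GD = data.frame(src = "A", dst = "B", first_ts = 5),
    MB = data.frame(src = "A", dst = "B", first_ts = 5)
  ))
  tl <- pair_timelines(mn)
  expect_equal(tl$sequence, "MB->GD")
  expect_equal(attr(tl, "ties_broken"), 1L)
})

test_that("timelines match an exhaustive re-derivation from the raw log", {
  log <- generate_event_log(small_cfg(seed = 55))
  mn <- build_multinet(log)
  tl <- pair_timelines(mn)
  # independent brute force straight from the event log
  acc_author <- log$creations$author_id[match(log$accesses$content_id,
                                              log$creations$content_id)]
  acc_chan <- log$creations$channel[match(log$accesses$content_id,
                                          log$creations$content_id)]
  contacts <- rbind(
    data.frame(u = as.character(acc_author),
               v = as.character(log$accesses$reader_id),
               layer = acc_chan, t = log$accesses$ts,
               stringsAsFactors = FALSE),
    data.frame(u = as.character(log$pm$sender_id[!is.na(log$pm$read_ts)]),
               v = as.character(log$pm$recipient_id[!is.na(log$pm$read_ts)]),
               layer = "PM", t = log$pm$read_ts[!is.na(log$pm$read_ts)],
               stringsAsFactors = FALSE)
  )
  contacts <- contacts[contacts$u != contacts$v, ]
  key <- paste(pmin(contacts$u, contacts$v), pmax(contacts$u, contacts$v),
               sep = "|")
  expected <- vapply(split(contacts, key), function(df) {
    first_t <- tapply(df$t, df$layer, min)
    ord <- order(first_t, match(names(first_t), OHC_CHANNELS))
    paste(names(first_t)[ord], collapse = "->")
  }, character(1))
  got <- setNames(tl$sequence, paste(tl$a, tl$b, sep = "|"))
  expect_equal(got[order(names(got))],
               expected[order(names(expected))])
})

test_that("the coevolution report is conserved and correctly conditioned", {
  mn <- build_multinet(generate_event_log(small_cfg(seed = 61)))
  tl <- pair_timelines(mn)
  rep <- coevolution_report(tl)
  expect_equal(sum(rep$layers$n_start), rep$total_pairs)
  expect_equal(rep$total_pairs,
               as.integer(attr(multiplexity_counts(mn), "total")))
  expect_equal(sum(rep$layers$p_first), 1)
  for (i in seq_len(nrow(rep$layers))) {
    row <- rep$layers[i, ]
    expect_lte(row$n_ge3, row$n_ge2)
    expect_lte(row$n_ge2, row$n_start)
    expect_lte(row$p_third, row$p_second)
    expect_lte(row$p_second, 1)
  }
})

test_that("single-layer timelines give zero conditional probabilities", {
  mn <- multinet_from_edges(list(
    BL = data.frame(src = c("A", "C"), dst = c("B", "D"), first_ts = 1:2)
  ))
  rep <- coevolution_report(pair_timelines(mn))
  expect_equal(rep$layers$p_second[rep$layers$layer == "BL"], 0)
  expect_equal(rep$layers$p_third[rep$layers$layer == "BL"], 0)
  expect_error(coevolution_report(pair_timelines(multinet_from_edges(list()))),
               "empty")
})

test_that("the report is identical from an order-shuffled log", {
  log <- generate_event_log(small_cfg(seed = 72))
  rep1 <- coevolution_report(pair_timelines(build_multinet(log)))
  set.seed(1)
  log$accesses <- log$accesses[sample(nrow(log$accesses)), ]
  rownames(log$accesses) <- NULL
  rep2 <- coevolution_report(pair_timelines(build_multinet(log)))
  expect_equal(rep1$layers, rep2$layers)
})
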