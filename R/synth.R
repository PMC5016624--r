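#' Configuration for the synthetic community generator
#'
#' Bundles and validates every parameter of [generate_event_log()] and
#' [generate_outcomes()]. Defaults describe a scaled-down online
#' smoking-cessation community: four communication channels with
#' heavy-tailed degree distributions, a sizeable cohort of users who only
#' read, pervasive one-way welcome messages that keep private-message
#' reciprocity low, and a modest probability that a connected pair
#' interacts again in another channel.
#'
#' @param n_users Number of community members (positive integer).
#' @param n_trial_users Number of members enrolled in the outcome trial;
#'   must not exceed `n_users`.
#' @param activity_rate Mean number of posts (and, separately, reads) per
#'   user per public channel; Poisson-distributed per user.
#' @param read_exponent Popularity-bias exponent: a reader picks an
#'   author with probability proportional to
#'   `(1 + author in-layer in-degree)^read_exponent`. Zero means uniform
#'   reading; larger values produce heavier-tailed degree distributions.
#' @param reader_only_frac Probability in `[0, 1]` that a user never
#'   contributes content (and never sends messages), i.e. is a lurker
#'   with zero out-degree in every layer.
#' @param welcome_prob Probability in `[0, 1]` that a new user receives a
#'   one-way private welcome message from a greeter.
#' @param coupling Probability in `[0, 1]` that a connected pair
#'   interacts again in another channel (and that a welcome message is
#'   replied to).
#' @param abstinence_intercept,abstinence_slope Coefficients of the
#'   logistic outcome model
#'   `logit P(abstinent) = intercept + slope * log(1 + total aggregated degree)`.
#' @param nonresponse_rate Probability in `[0, 1]` that a trial user does
#'   not complete the follow-up survey.
#' @param seed Integer seed; the same configuration always yields the
#'   same event log and outcome table.
#'
#' @return An object of class `synth_config` (a validated named list).
#' @seealso [generate_event_log()], [generate_outcomes()]
#' @export
#' @examples
#' cfg <- synth_config(n_users = 50, n_trial_users = 20, seed = 7)
#' log <- generate_event_log(cfg)
#' nrow(log$creations)
synth_config <- function(n_users = 800L,
                         n_trial_users = 300L,
                         activity_rate = 3,
                         read_exponent = 0.8,
                         reader_only_frac = 0.35,
                         welcome_prob = 0.9,
                         coupling = 0.15,
                         abstinence_intercept = qlogis(0.09),
                         abstinence_slope = 0.35,
                         nonresponse_rate = 0.4,
                         seed = 1L) {
  chk_count <- function(x, field, min = 1) {
    if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min ||
        x != floor(x)) {
      stop("invalid field '", field, "': must be an integer >= ", min,
           call. = FALSE)
    }
    as.integer(x)
  }
  chk_prob <- function(x, field) {
    if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
      stop("invalid field '", field, "': must be a probability in [0, 1]",
           call. = FALSE)
    }
    as.numeric(x)
  }
  chk_real <- function(x, field, min = -Inf) {
    if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min) {
      stop("invalid field '", field, "': must be a finite real",
           if (is.finite(min)) paste0(" >= ", min), call. = FALSE)
    }
    as.numeric(x)
  }
  cfg <- list(
    n_users = chk_count(n_users, "n_users"),
    n_trial_users = chk_count(n_trial_users, "n_trial_users", min = 0),
    activity_rate = chk_real(activity_rate, "activity_rate", min = 0),
    read_exponent = chk_real(read_exponent, "read_exponent", min = 0),
    reader_only_frac = chk_prob(reader_only_frac, "reader_only_frac"),
    welcome_prob = chk_prob(welcome_prob, "welcome_prob"),
    coupling = chk_prob(coupling, "coupling"),
    abstinence_intercept = chk_real(abstinence_intercept,
                                    "abstinence_intercept"),
    abstinence_slope = chk_real(abstinence_slope, "abstinence_slope"),
    nonresponse_rate = chk_prob(nonresponse_rate, "nonresponse_rate"),
    seed = chk_count(seed, "seed", min = 0)
  )
  if (cfg$n_trial_users > cfg$n_users) {
    stop("invalid field 'n_trial_users': must not exceed n_users",
         call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

#' Construct an event log from its component tables
#'
#' Assembles (and validates) the three tables the pipeline consumes:
#' content-creation events, content-access events and private messages.
#' Timestamps are integer event counters — only their order matters.
#'
#' @param creations Data frame with columns `author_id`, `content_id`,
#'   `channel` (one of `"BL"`, `"MB"`, `"GD"`) and `ts`.
#' @param accesses Data frame with columns `reader_id`, `content_id`,
#'   `ts`; every `content_id` must appear in `creations`.
#' @param pm Data frame with columns `sender_id`, `recipient_id`,
#'   `message_id`, `send_ts`, `read_ts` (`NA` read_ts = never read).
#' @param users Optional vector of all known user ids (defaults to every
#'   id appearing in the tables).
#'
#' @return An object of class `event_log`.
#' @export
event_log <- function(creations = NULL, accesses = NULL, pm = NULL,
                      users = NULL) {
  empty_cre <- data.frame(author_id = character(), content_id = character(),
                          channel = character(), ts = integer(),
                          stringsAsFactors = FALSE)
  empty_acc <- data.frame(reader_id = character(), content_id = character(),
                          ts = integer(), stringsAsFactors = FALSE)
  empty_pm <- data.frame(sender_id = character(), recipient_id = character(),
                         message_id = character(), send_ts = integer(),
                         read_ts = integer(), stringsAsFactors = FALSE)
  creations <- if (is.null(creations)) empty_cre else as.data.frame(creations)
  accesses <- if (is.null(accesses)) empty_acc else as.data.frame(accesses)
  pm <- if (is.null(pm)) empty_pm else as.data.frame(pm)
  if (is.null(users)) {
    users <- unique(c(creations$author_id, accesses$reader_id,
                      pm$sender_id, pm$recipient_id))
  }
  log <- structure(list(creations = creations, accesses = accesses,
                        pm = pm, users = users),
                   class = "event_log")
  validate_event_log(log)
  log
}

#' Validate the referential and temporal integrity of an event log
#'
#' Checks that every access refers to an existing content id, that read
#' times never precede send/post times, and that required columns are
#' present. Called by [build_multinet()] before any network is built.
#'
#' @param log An [event_log()].
#' @return `log`, invisibly; errors describe the first violation found.
#' @export
validate_event_log <- function(log) {
  if (!inherits(log, "event_log")) stop("not an event_log object")
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop("event log ", what, " table lacks column(s): ",
           paste(miss, collapse = ", "))
    }
  }
  need(log$creations, c("author_id", "content_id", "channel", "ts"),
       "creations")
  need(log$accesses, c("reader_id", "content_id", "ts"), "accesses")
  need(log$pm, c("sender_id", "recipient_id", "message_id",
                 "send_ts", "read_ts"), "pm")
  bad_chan <- setdiff(unique(log$creations$channel), c("BL", "MB", "GD"))
  if (length(bad_chan)) {
    stop("unknown channel token(s) in creations: ",
         paste(bad_chan, collapse = ", "))
  }
  dangling <- setdiff(log$accesses$content_id, log$creations$content_id)
  if (length(dangling)) {
    stop("access events reference unknown content id(s): ",
         paste(head(dangling, 5), collapse = ", "))
  }
  post_ts <- log$creations$ts[match(log$accesses$content_id,
                                    log$creations$content_id)]
  if (any(log$accesses$ts < post_ts)) {
    stop("access event precedes creation of its content")
  }
  if (nrow(log$pm)) {
    read <- !is.na(log$pm$read_ts)
    if (any(log$pm$read_ts[read] < log$pm$send_ts[read])) {
      stop("private message read before it was sent")
    }
  }
  invisible(log)
}

#' @export
print.event_log <- function(x, ...) {
  cat("<event_log> ", length(x$users), " users, ",
      nrow(x$creations), " creations, ", nrow(x$accesses), " accesses, ",
      nrow(x$pm), " private messages\n", sep = "")
  invisible(x)
}

#' Generate a synthetic community event log
#'
#' Simulates a community in four deterministic phases driven by a single
#' seed:
#'
#' 1. **Content**: each contributor (a user is a contributor with
#'    probability `1 - reader_only_frac`) posts a Poisson number of items
#'    in each public channel (BL, MB, GD).
#' 2. **Welcomes**: each non-greeter user receives, with probability
#'    `welcome_prob`, a private welcome message from a small greeter pool
#'    drawn from the earliest contributors; the message is read on
#'    arrival, and replied to with probability `coupling` when the
#'    recipient is a contributor.
#' 3. **Reads**: every user performs a Poisson number of reads per public
#'    channel, choosing authors with probability proportional to
#'    `(1 + current in-layer in-degree)^read_exponent` (preferential
#'    reading; produces heavy-tailed degree distributions), then a
#'    uniform item of that author. Self-reads are excluded.
#' 4. **Cross-layer coupling**: every reader–author pair established
#'    above generates one candidate interaction per channel where it is
#'    not yet connected (public channels require the author to have
#'    content there; the private channel requires the reader to be a
#'    contributor). Each candidate fires independently with probability
#'    `coupling`. All candidate randomness is pre-drawn, so increasing
#'    `coupling` with the same seed only *adds* events — the fraction of
#'    multi-layer pairs is monotone in `coupling`.
#'
#' Timestamps are strictly increasing integer counters; every access
#' postdates the creation of its content and every read postdates its
#' send.
#'
#' @param config A [synth_config()].
#' @return An [event_log()]; `log$users` lists all `n_users` ids
#'   (integers), including users who generated no events.
#' @export
#' @examples
#' log <- generate_event_log(synth_config(n_users = 60, n_trial_users = 30,
#'                                        seed = 42))
#' log
generate_event_log <- function(config) {
  if (!inherits(config, "synth_config")) {
    stop("config must be created by synth_config()")
  }
  n <- config$n_users
  set.seed(config$seed)
  users <- seq_len(n)
  is_poster <- runif(n) >= config$reader_only_frac
  greeters <- head(users[is_poster], 3L)
  pub <- c("BL", "MB", "GD")

  ## Phase 1: content creation
  posters <- users[is_poster]
  np <- length(posters)
  if (np) {
    counts <- rpois(np * 3L, config$activity_rate)
    cre_author <- rep(rep(posters, times = 3L), counts)
    cre_chan <- rep(rep(pub, each = np), counts)
  } else {
    cre_author <- integer()
    cre_chan <- character()
  }
  n_cre <- length(cre_author)
  creations <- data.frame(
    author_id = cre_author,
    content_id = if (n_cre) sprintf("c%07d", seq_len(n_cre)) else character(),
    channel = cre_chan,
    ts = seq_len(n_cre),
    stringsAsFactors = FALSE
  )
  t_next <- n_cre + 1L

  ## Phase 2: welcome messages (one-way unless replied)
  pm_sender <- integer(); pm_recipient <- integer()
  pm_send <- integer(); pm_read <- integer()
  welcome_pairs <- NULL
  cand <- setdiff(users, greeters)
  if (length(greeters) && length(cand)) {
    u_w <- runif(length(cand))
    recv <- cand[u_w < config$welcome_prob]
    k <- length(recv)
    if (k) {
      g_for <- greeters[sample.int(length(greeters), k, replace = TRUE)]
      r_w <- runif(k)  # reply uniforms pre-drawn for all welcomes
      send_ts <- t_next + 2L * seq_len(k) - 2L
      read_ts <- send_ts + 1L
      t_next <- t_next + 2L * k
      pm_sender <- g_for; pm_recipient <- recv
      pm_send <- send_ts; pm_read <- read_ts
      welcome_pairs <- cbind(reader = recv, author = g_for)
      rep_i <- which(r_w < config$coupling & is_poster[recv])
      if (length(rep_i)) {
        kr <- length(rep_i)
        send2 <- t_next + 2L * seq_len(kr) - 2L
        pm_sender <- c(pm_sender, recv[rep_i])
        pm_recipient <- c(pm_recipient, g_for[rep_i])
        pm_send <- c(pm_send, send2)
        pm_read <- c(pm_read, send2 + 1L)
        t_next <- t_next + 2L * kr
      }
    }
  }

  ## Phase 3: preferential base reads in public channels
  read_counts <- matrix(rpois(3L * n, config$activity_rate), nrow = n)
  max_reads <- sum(read_counts)
  acc_reader <- integer(max_reads)
  acc_content <- character(max_reads)
  acc_ts <- integer(max_reads)
  n_acc <- 0L
  base_pairs <- vector("list", 3L)  # established reader/author pairs/channel
  for (ci in seq_along(pub)) {
    ch <- pub[ci]
    sel <- creations$channel == ch
    auth <- sort(unique(creations$author_id[sel]))
    if (!length(auth)) next
    posts_by <- split(creations$content_id[sel],
                      factor(creations$author_id[sel], levels = auth))
    npost <- lengths(posts_by)
    indeg <- integer(length(auth))
    seen <- matrix(FALSE, n, length(auth))
    for (u in users) {
      k <- read_counts[u, ci]
      if (!k) next
      self_i <- match(u, auth)
      for (j in seq_len(k)) {
        w <- (1 + indeg)^config$read_exponent
        if (!is.na(self_i)) w[self_i] <- 0
        if (all(w == 0)) break
        ai <- sample.int(length(auth), 1L, prob = w)
        cid <- posts_by[[ai]][sample.int(npost[ai], 1L)]
        n_acc <- n_acc + 1L
        acc_reader[n_acc] <- u
        acc_content[n_acc] <- cid
        acc_ts[n_acc] <- t_next
        t_next <- t_next + 1L
        if (!seen[u, ai]) {
          seen[u, ai] <- TRUE
          indeg[ai] <- indeg[ai] + 1L
        }
      }
    }
    idx <- which(seen, arr.ind = TRUE)
    base_pairs[[ci]] <- if (nrow(idx)) {
      cbind(reader = idx[, 1L], author = auth[idx[, 2L]])
    } else NULL
  }

  ## Phase 4: coupled cross-layer interactions (pre-drawn, thresholded)
  est <- data.frame(reader = integer(), author = integer(),
                    layer = character(), stringsAsFactors = FALSE)
  for (ci in seq_along(pub)) {
    bp <- base_pairs[[ci]]
    if (!is.null(bp)) {
      est <- rbind(est, data.frame(reader = bp[, "reader"],
                                   author = bp[, "author"],
                                   layer = pub[ci],
                                   stringsAsFactors = FALSE))
    }
  }
  if (!is.null(welcome_pairs)) {
    est <- rbind(est, data.frame(reader = welcome_pairs[, "reader"],
                                 author = welcome_pairs[, "author"],
                                 layer = "PM", stringsAsFactors = FALSE))
  }
  if (nrow(est)) {
    est <- est[est$reader != est$author, , drop = FALSE]
  }
  if (nrow(est)) {
    est$ukey <- paste(pmin(est$reader, est$author),
                      pmax(est$reader, est$author))
    first <- !duplicated(est$ukey)
    pr <- est$reader[first]; pa <- est$author[first]; pk <- est$ukey[first]
    has_post_mat <- matrix(FALSE, n, 3L)
    for (ci in seq_along(pub)) {
      has_post_mat[unique(creations$author_id[creations$channel == pub[ci]]),
                   ci] <- TRUE
    }
    posts_ch <- lapply(pub, function(ch) {
      sel <- creations$channel == ch
      split(creations$content_id[sel], creations$author_id[sel])
    })
    names(posts_ch) <- pub
    all_l <- c(pub, "PM")
    K <- length(pr)
    cand_r <- rep(pr, each = 4L)
    cand_a <- rep(pa, each = 4L)
    cand_k <- rep(pk, each = 4L)
    cand_l <- rep(all_l, times = K)
    not_est <- !(paste(cand_k, cand_l) %in% paste(est$ukey, est$layer))
    li <- match(cand_l, pub)
    elig <- ifelse(is.na(li), is_poster[cand_r],
                   has_post_mat[cbind(cand_a, ifelse(is.na(li), 1L, li))])
    keep <- not_est & elig
    cand_r <- cand_r[keep]; cand_a <- cand_a[keep]; cand_l <- cand_l[keep]
    if (length(cand_r)) {
      ord <- order(cand_r, cand_a, match(cand_l, all_l))
      cand_r <- cand_r[ord]; cand_a <- cand_a[ord]; cand_l <- cand_l[ord]
      u_fire <- runif(length(cand_r))
      u_pick <- runif(length(cand_r))
      fire <- which(u_fire < config$coupling)
      for (i in fire) {
        ch <- cand_l[i]
        if (ch == "PM") {
          pm_sender <- c(pm_sender, cand_r[i])
          pm_recipient <- c(pm_recipient, cand_a[i])
          pm_send <- c(pm_send, t_next)
          pm_read <- c(pm_read, t_next + 1L)
          t_next <- t_next + 2L
        } else {
          items <- posts_ch[[ch]][[as.character(cand_a[i])]]
          cid <- items[pmin(length(items), floor(u_pick[i] * length(items)) + 1L)]
          n_acc <- n_acc + 1L
          if (n_acc > length(acc_reader)) {
            acc_reader <- c(acc_reader, integer(1024L))
            acc_content <- c(acc_content, character(1024L))
            acc_ts <- c(acc_ts, integer(1024L))
          }
          acc_reader[n_acc] <- cand_r[i]
          acc_content[n_acc] <- cid
          acc_ts[n_acc] <- t_next
          t_next <- t_next + 1L
        }
      }
    }
  }

  accesses <- data.frame(
    reader_id = acc_reader[seq_len(n_acc)],
    content_id = acc_content[seq_len(n_acc)],
    ts = acc_ts[seq_len(n_acc)],
    stringsAsFactors = FALSE
  )
  n_pm <- length(pm_sender)
  pm <- data.frame(
    sender_id = pm_sender,
    recipient_id = pm_recipient,
    message_id = if (n_pm) sprintf("m%06d", seq_len(n_pm)) else character(),
    send_ts = pm_send,
    read_ts = pm_read,
    stringsAsFactors = FALSE
  )
  log <- structure(list(creations = creations, accesses = accesses,
                        pm = pm, users = users),
                   class = "event_log")
  validate_event_log(log)
  log
}

#' Simulate trial abstinence outcomes linked to network centrality
#'
#' Samples `n_trial_users` community members as trial enrollees and draws
#' a latent 30-day abstinence indicator from the logistic model
#' `logit P = intercept + slope * log(1 + d)`, where `d` is the user's
#' total degree (distinct neighbors, either direction) in the aggregated
#' network. Each enrollee responds to the follow-up survey with
#' probability `1 - nonresponse_rate`; nonresponders carry no abstinence
#' report, so `abstinent = TRUE` implies `responded = TRUE` (the
#' intent-to-treat convention counts them as smoking).
#'
#' @param log An [event_log()] with at least one user.
#' @param config The [synth_config()] that produced (or parameterizes)
#'   the log; its `seed` plus one seeds this stage.
#' @return A data frame (`user_id`, `responded`, `abstinent`) with
#'   attributes `latent_abstinent` (outcome before nonresponse masking),
#'   `total_degree`, and `coefficients` (the generating intercept/slope),
#'   retained for parameter-recovery checks.
#' @export
generate_outcomes <- function(log, config) {
  validate_event_log(log)
  if (!inherits(config, "synth_config")) {
    stop("config must be created by synth_config()")
  }
  if (!length(log$users)) stop("event log contains no users")
  if (config$n_trial_users > length(log$users)) {
    stop("n_trial_users exceeds the number of users present in the log")
  }
  set.seed((config$seed + 1L) %% 2147483647L)
  m <- config$n_trial_users
  cohort <- sort(log$users[sample.int(length(log$users), m)])
  mn <- build_multinet(log)
  deg <- net_degrees(mn$aggregated)
  d <- deg$total[match(as.character(cohort), deg$node)]
  d[is.na(d)] <- 0
  p <- plogis(config$abstinence_intercept +
                config$abstinence_slope * log1p(d))
  latent <- runif(m) < p
  responded <- runif(m) >= config$nonresponse_rate
  out <- data.frame(user_id = cohort,
                    responded = responded,
                    abstinent = latent & responded,
                    stringsAsFactors = FALSE)
  attr(out, "latent_abstinent") <- latent
  attr(out, "total_degree") <- d
  attr(out, "coefficients") <- c(intercept = config$abstinence_intercept,
                                 slope = config$abstinence_slope)
  out
}
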