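#' Write an event log as three CSV files
#'
#' `creations.csv` (`author_id,content_id,channel,ts`), `accesses.csv`
#' (`reader_id,content_id,ts`) and `pm.csv`
#' (`sender_id,recipient_id,message_id,send_ts,read_ts`, empty read_ts
#' for unread messages). UTF-8 with a mandatory header row.
#'
#' @param log An [event_log()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_event_log <- function(log, dir) {
  validate_event_log(log)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(log$creations, file.path(dir, "creations.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(log$accesses, file.path(dir, "accesses.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(log$pm, file.path(dir, "pm.csv"), row.names = FALSE,
            quote = FALSE, na = "")
  invisible(dir)
}

#' Read an event log written by [write_event_log()]
#'
#' @param dir Directory holding `creations.csv`, `accesses.csv` and
#'   `pm.csv`.
#' @return An [event_log()].
#' @export
read_event_log <- function(dir) {
  paths <- file.path(dir, c("creations.csv", "accesses.csv", "pm.csv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing event-log file(s): ", paste(missing, collapse = ", "))
  }
  cre <- read.csv(paths[1], stringsAsFactors = FALSE,
                  colClasses = c(content_id = "character",
                                 channel = "character"))
  acc <- read.csv(paths[2], stringsAsFactors = FALSE,
                  colClasses = c(content_id = "character"))
  pm <- read.csv(paths[3], stringsAsFactors = FALSE,
                 colClasses = c(message_id = "character"))
  event_log(cre, acc, pm)
}

#' Write / read a trial outcome table
#'
#' `outcomes.csv` with columns `user_id,responded,abstinent`
#' (TRUE/FALSE).
#'
#' @param outcomes Outcome data frame.
#' @param path CSV file path.
#' @return `path` invisibly (writer); the data frame (reader).
#' @export
write_outcomes <- function(outcomes, path) {
  write.csv(outcomes[, c("user_id", "responded", "abstinent")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_outcomes
#' @export
read_outcomes <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  out$responded <- as.logical(out$responded)
  out$abstinent <- as.logical(out$abstinent)
  if (any(out$abstinent & !out$responded)) {
    stop("invalid outcome table: abstinent nonresponder")
  }
  out
}

pipeline_fields <- c("synth", "input_dir", "out_dir", "stages",
                     "corr_scope", "top_denominator", "k_range",
                     "restarts", "plateau_threshold", "mean_path_sample",
                     "seed")

pipeline_stages <- c("simulate", "build", "topology", "similarity",
                     "coevolution", "profile")

#' Pipeline configuration
#'
#' Everything [run_pipeline()] needs: either synthetic-generator
#' parameters or a directory of input CSVs, plus analysis settings and
#' an output directory. Round-trips losslessly through JSON via
#' [write_pipeline_config()] / [read_pipeline_config()]; unknown keys in
#' a config file are rejected.
#'
#' @param synth A [synth_config()], or NULL to read logs from
#'   `input_dir`.
#' @param input_dir Directory with `creations.csv`, `accesses.csv`,
#'   `pm.csv` (and `outcomes.csv` when profiling); ignored when `synth`
#'   is given.
#' @param out_dir Directory for all written reports.
#' @param stages Subset of
#'   `c("simulate", "build", "topology", "similarity", "coevolution",
#'   "profile")`.
#' @param corr_scope Node scope for degree-rank correlations (`"union"`
#'   or `"intersection"`).
#' @param top_denominator Top-sequence share denominator; see
#'   [coevolution_report()].
#' @param k_range,restarts,plateau_threshold Mixture-model settings; see
#'   [select_k()].
#' @param mean_path_sample Optional BFS source sample size for mean
#'   shortest paths on very large components.
#' @param seed Root seed; stage seeds are split from it (synthesis uses
#'   `seed`, outcomes `seed + 1`, clustering `seed + 2`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(), input_dir = NULL,
                            out_dir = tempfile("multiohc_out"),
                            stages = pipeline_stages,
                            corr_scope = "union",
                            top_denominator = "start",
                            k_range = 2:10, restarts = 10L,
                            plateau_threshold = 0.05,
                            mean_path_sample = NULL, seed = 1L) {
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(synth) && is.null(input_dir)) {
    stop("either synth parameters or input_dir must be given")
  }
  if (!is.null(synth) && !inherits(synth, "synth_config")) {
    stop("synth must be a synth_config() or NULL")
  }
  structure(list(synth = synth, input_dir = input_dir, out_dir = out_dir,
                 stages = stages, corr_scope = corr_scope,
                 top_denominator = top_denominator,
                 k_range = as.integer(k_range),
                 restarts = as.integer(restarts),
                 plateau_threshold = plateau_threshold,
                 mean_path_sample = mean_path_sample,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration as JSON
#'
#' @param config A [pipeline_config()].
#' @param path JSON file path.
#' @return `path` invisibly (writer); a [pipeline_config()] (reader).
#'   Reading rejects unknown keys.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  obj <- unclass(config)
  if (!is.null(obj$synth)) obj$synth <- unclass(obj$synth)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), pipeline_fields)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  synth <- if (is.null(raw$synth)) NULL else do.call(synth_config, raw$synth)
  pipeline_config(synth = synth, input_dir = raw$input_dir,
                  out_dir = raw$out_dir, stages = raw$stages,
                  corr_scope = raw$corr_scope,
                  top_denominator = raw$top_denominator,
                  k_range = raw$k_range, restarts = raw$restarts,
                  plateau_threshold = raw$plateau_threshold,
                  mean_path_sample = raw$mean_path_sample,
                  seed = raw$seed)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", force = TRUE)
  invisible(path)
}

#' Run the full multirelational analysis pipeline
#'
#' Executes the requested stages in order — simulate (or load inputs),
#' build networks, topology, cross-layer similarity, coevolution, user
#' profiling — and writes every report (JSON + CSV/TSV) under
#' `config$out_dir`. A failure in any stage aborts with an error naming
#' the stage. Per-stage counts are logged via [message()].
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results of each executed
#'   stage (`log`, `outcomes`, `multinet`, `topology`, `similarity`,
#'   `coevolution`, `profiling`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  res <- list()

  if ("simulate" %in% config$stages) {
    sim <- stage("simulate", {
      cfg <- config$synth
      cfg$seed <- config$seed  # root seed drives the synthetic stage
      log <- generate_event_log(cfg)
      write_event_log(log, out)
      outcomes <- generate_outcomes(log, cfg)
      write_outcomes(outcomes, file.path(out, "outcomes.csv"))
      message(sprintf("simulate: %d users, %d creations, %d accesses, %d PMs",
                      length(log$users), nrow(log$creations),
                      nrow(log$accesses), nrow(log$pm)))
      list(log = log, outcomes = outcomes)
    })
    res$log <- sim$log
    res$outcomes <- sim$outcomes
  } else if (!is.null(config$input_dir)) {
    loaded <- stage("load", {
      log <- read_event_log(config$input_dir)
      ocsv <- file.path(config$input_dir, "outcomes.csv")
      outcomes <- if (file.exists(ocsv)) read_outcomes(ocsv) else NULL
      list(log = log, outcomes = outcomes)
    })
    res$log <- loaded$log
    res$outcomes <- loaded$outcomes
  }

  if ("build" %in% config$stages) {
    res$multinet <- stage("build", {
      mn <- build_multinet(res$log)
      for (l in c(mn$layers, list(mn$aggregated))) {
        write_edgelist(l, file.path(out, paste0("edges_", l$channel, ".tsv")))
      }
      message(sprintf("build: aggregated %d nodes, %d edges",
                      length(mn$aggregated$nodes), nrow(mn$aggregated$edges)))
      mn
    })
  }

  if ("topology" %in% config$stages) {
    res$topology <- stage("topology", {
      nets <- c(list(AGG = res$multinet$aggregated), res$multinet$layers)
      reps <- lapply(nets, topology_report,
                     mean_path_sample = config$mean_path_sample,
                     seed = config$seed)
      for (r in reps) {
        write_json_report(r[setdiff(names(r), "degree_histograms")],
                          file.path(out, paste0("topology_", r$channel,
                                                ".json")))
        for (side in names(r$degree_histograms)) {
          write.csv(r$degree_histograms[[side]],
                    file.path(out, sprintf("degrees_%s_%s.csv",
                                           r$channel, side)),
                    row.names = FALSE)
        }
      }
      message("topology: reports for AGG + 4 layers")
      reps
    })
  }

  if ("similarity" %in% config$stages) {
    res$similarity <- stage("similarity", {
      sim <- similarity_report(res$multinet, scope = config$corr_scope)
      write_json_report(list(
        multiplexity = as.list(setNames(as.integer(sim$multiplexity),
                                        names(sim$multiplexity))),
        total_pairs = attr(sim$multiplexity, "total"),
        spearman_in = sim$spearman_in, spearman_out = sim$spearman_out,
        jaccard = sim$jaccard, scope = sim$scope),
        file.path(out, "similarity.json"))
      for (m in c("spearman_in", "spearman_out", "jaccard")) {
        write.csv(sim[[m]], file.path(out, paste0(m, ".csv")))
      }
      message(sprintf("similarity: %d connected pairs",
                      attr(sim$multiplexity, "total")))
      sim
    })
  }

  if ("coevolution" %in% config$stages) {
    res$coevolution <- stage("coevolution", {
      tl <- pair_timelines(res$multinet)
      rep <- coevolution_report(tl, top_denominator = config$top_denominator)
      write_json_report(list(total_pairs = rep$total_pairs,
                             ties_broken = rep$ties_broken,
                             top_denominator = rep$top_denominator,
                             layers = rep$layers),
                        file.path(out, "coevolution.json"))
      message(sprintf("coevolution: %d pair timelines (%d tie-broken)",
                      rep$total_pairs, rep$ties_broken))
      rep
    })
  }

  if ("profile" %in% config$stages) {
    res$profiling <- stage("profile", {
      if (is.null(res$outcomes)) {
        stop("no outcome table available (simulate stage or outcomes.csv)")
      }
      prof <- extract_profiles(res$multinet, res$outcomes$user_id)
      grp <- select_k(prof, k_range = config$k_range,
                      restarts = config$restarts,
                      seed = (config$seed + 2L) %% 2147483647L,
                      plateau_threshold = config$plateau_threshold)
      itt <- group_abstinence(grp, res$outcomes, "ITT")
      resp <- group_abstinence(grp, res$outcomes, "responders")
      write.csv(data.frame(user_id = names(grp$assignment),
                           group = as.integer(grp$assignment)),
                file.path(out, "groups.csv"), row.names = FALSE)
      pairs <- utils::combn(grp$K, 2)
      av <- apply(pairs, 2, function(pp) {
        sel1 <- grp$assignment == pp[1]; sel2 <- grp$assignment == pp[2]
        idx <- match(names(grp$assignment),
                     as.character(res$outcomes$user_id))
        y <- as.numeric(res$outcomes$abstinent[idx])
        if (sum(sel1) < 2 || sum(sel2) < 2) return(NULL)
        an <- pairwise_anova(y[sel1], y[sel2])
        data.frame(groupA = pp[1], groupB = pp[2], F = an$F,
                   df2 = an$df[2], p = an$p)
      })
      av <- do.call(rbind, av)
      if (!is.null(av)) {
        write.csv(av, file.path(out, "anova.csv"), row.names = FALSE)
      }
      write_json_report(list(K = grp$K, plateau = grp$plateau,
                             plateau_threshold = grp$plateau_threshold,
                             loglik = as.list(grp$loglik),
                             group_sizes = grp$group_sizes,
                             group_means = grp$group_means,
                             abstinence_itt = itt,
                             abstinence_responders = resp),
                        file.path(out, "profiling.json"))
      message(sprintf("profile: K=%d groups over %d users", grp$K,
                      length(grp$assignment)))
      list(profiles = prof, grouping = grp, itt = itt,
           responders = resp, anova = av)
    })
  }
  invisible(res)
}
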