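#' Cross-layer centrality profiles
#'
#' Represents each cohort member by the 8-vector of in- and out-degrees
#' in the four layers, ordered (MB_in, MB_out, BL_in, BL_out, GD_in,
#' GD_out, PM_in, PM_out). Members with no community activity get the
#' zero vector — inactive trial participants are a real (and large)
#' stratum, not an error.
#'
#' @param multinet A [build_multinet()] result.
#' @param cohort Nonempty vector of user ids.
#' @return Numeric matrix, one row per cohort member (rownames = user
#'   ids), 8 columns.
#' @export
extract_profiles <- function(multinet, cohort) {
  stopifnot(inherits(multinet, "multinet"))
  cohort <- as.character(cohort)
  if (!length(cohort)) stop("cohort is empty")
  layer_order <- c("MB", "BL", "GD", "PM")
  prof <- matrix(0, nrow = length(cohort), ncol = 8L,
                 dimnames = list(cohort,
                                 paste0(rep(layer_order, each = 2),
                                        c("_in", "_out"))))
  for (ch in layer_order) {
    deg <- net_degrees(multinet$layers[[ch]])
    idx <- match(cohort, deg$node)
    hit <- !is.na(idx)
    prof[hit, paste0(ch, "_in")] <- deg$in_deg[idx[hit]]
    prof[hit, paste0(ch, "_out")] <- deg$out_deg[idx[hit]]
  }
  prof
}

log_dmvnorm <- function(X, mu, Sigma) {
  L <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(L)) stop("singular covariance after regularization")
  z <- forwardsolve(t(L), t(X) - mu)
  -0.5 * colSums(z^2) - sum(log(diag(L))) -
    0.5 * ncol(X) * log(2 * pi)
}

em_once <- function(X, K, ridge, max_iter, tol) {
  n <- nrow(X); d <- ncol(X)
  ## hard initialization: k-means when feasible, random partition otherwise
  assign0 <- tryCatch(
    suppressWarnings(kmeans(X, centers = K, nstart = 2L,
                            iter.max = 50L)$cluster),
    error = function(e) sample(rep_len(seq_len(K), n))
  )
  resp <- matrix(1e-6, n, K)
  resp[cbind(seq_len(n), assign0)] <- 1
  resp <- resp / rowSums(resp)
  w <- rep(1 / K, K)
  mu <- matrix(0, K, d)
  covs <- array(0, c(d, d, K))
  trace <- numeric(0)
  ll <- -Inf
  for (iter in seq_len(max_iter)) {
    ## M-step
    Nk <- pmax(colSums(resp), 1e-10)
    w <- Nk / n
    mu <- t(resp) %*% X / Nk
    for (k in seq_len(K)) {
      Xc <- sweep(X, 2, mu[k, ])
      covs[, , k] <- crossprod(Xc * resp[, k], Xc) / Nk[k] +
        diag(ridge, d)
    }
    ## E-step
    ld <- vapply(seq_len(K), function(k) {
      log(w[k]) + log_dmvnorm(X, mu[k, ], covs[, , k])
    }, numeric(n))
    if (n == 1L) ld <- matrix(ld, nrow = 1L)
    mx <- apply(ld, 1, max)
    lse <- mx + log(rowSums(exp(ld - mx)))
    ll_new <- sum(lse)
    resp <- exp(ld - lse)
    trace <- c(trace, ll_new)
    if (is.finite(ll) && ll_new - ll < tol * (abs(ll_new) + 1)) {
      ll <- ll_new
      break
    }
    ll <- ll_new
  }
  list(loglik = ll, trace = trace, weights = w, means = mu, covs = covs,
       resp = resp)
}

#' Fit a Gaussian mixture model to centrality profiles by EM
#'
#' Best-of-restarts expectation-maximization on the raw (untransformed)
#' 8-dimensional degree vectors, with full covariance matrices
#' regularized by a small ridge on the diagonal — zero-inflated integer
#' features make singular components likely otherwise. Each restart is
#' initialized from a k-means partition (random partition when k-means
#' is infeasible, e.g. fewer distinct points than components) and the
#' restart with the highest log-likelihood wins.
#'
#' @param profiles Numeric matrix of profiles (rows = users).
#' @param K Number of mixture components (`1 <= K < nrow(profiles)`).
#' @param restarts Number of EM restarts (default 10).
#' @param seed Optional seed; given the seed the fit is deterministic.
#' @param ridge Diagonal regularization added to every covariance
#'   (default `1e-6`).
#' @param max_iter,tol EM iteration cap and relative convergence
#'   tolerance.
#' @return An object of class `gmm_fit`: `K`, `loglik`, `weights`,
#'   `means` (K x d), `covs` (d x d x K), `responsibilities`, `cluster`
#'   (hard assignment), `traces` (per-restart log-likelihood traces) and
#'   `best_restart`.
#' @export
fit_mixture <- function(profiles, K, restarts = 10L, seed = NULL,
                        ridge = 1e-6, max_iter = 200L, tol = 1e-8) {
  X <- as.matrix(profiles)
  storage.mode(X) <- "double"
  if (K < 1) stop("K must be at least 1")
  if (K >= nrow(X)) stop("K must be smaller than the number of profiles")
  if (!is.null(seed)) set.seed(seed)
  fits <- vector("list", restarts)
  for (r in seq_len(restarts)) {
    fits[[r]] <- em_once(X, K, ridge, max_iter, tol)
  }
  lls <- vapply(fits, `[[`, numeric(1), "loglik")
  best <- which.max(lls)
  f <- fits[[best]]
  structure(list(K = K, loglik = f$loglik, weights = f$weights,
                 means = f$means, covs = f$covs,
                 responsibilities = f$resp,
                 cluster = max.col(f$resp, ties.method = "first"),
                 traces = lapply(fits, `[[`, "trace"),
                 best_restart = best, ridge = ridge),
            class = "gmm_fit")
}

#' Select the number of user groups by the log-likelihood plateau rule
#'
#' Fits mixtures over a contiguous range of K and selects the smallest K
#' whose relative log-likelihood gain to K + 1,
#' `(ll[K+1] - ll[K]) / |ll[K]|`, falls below `plateau_threshold`. If no
#' K satisfies the rule the maximum K is returned with `plateau = FALSE`.
#' The full per-K trace is retained.
#'
#' Groups of the selected model are relabeled in decreasing order of
#' total mean degree, so group 1 is always the most connected.
#'
#' @param profiles Numeric profile matrix with user ids as rownames.
#' @param k_range Contiguous integer range of K values (e.g. `2:10`).
#' @param restarts,seed,ridge Passed to [fit_mixture()]; the seed is set
#'   once before the sweep.
#' @param plateau_threshold Relative-gain threshold (default 0.05).
#' @return An object of class `grouping_result`: `K`, `loglik` (named
#'   per-K vector), `assignment` (named integer vector of group labels),
#'   `group_sizes`, `group_means` (arithmetic means of member profiles),
#'   `model` (the selected [fit_mixture()] object), `plateau`,
#'   `plateau_threshold`.
#' @export
select_k <- function(profiles, k_range = 2:10, restarts = 10L,
                     seed = NULL, plateau_threshold = 0.05,
                     ridge = 1e-6) {
  k_range <- as.integer(k_range)
  if (length(k_range) < 2 || any(diff(k_range) != 1L)) {
    stop("k_range must be a contiguous range with at least two values")
  }
  X <- as.matrix(profiles)
  if (!is.null(seed)) set.seed(seed)
  fits <- lapply(k_range, function(k) {
    fit_mixture(X, k, restarts = restarts, seed = NULL, ridge = ridge)
  })
  ll <- vapply(fits, `[[`, numeric(1), "loglik")
  names(ll) <- k_range
  gains <- (ll[-1] - ll[-length(ll)]) / abs(ll[-length(ll)])
  below <- which(gains < plateau_threshold)
  if (length(below)) {
    sel_i <- below[1L]
    plateau <- TRUE
  } else {
    sel_i <- length(k_range)
    plateau <- FALSE
    warning("no log-likelihood plateau in k_range; returning the maximum K")
  }
  model <- fits[[sel_i]]
  K <- k_range[sel_i]
  ## relabel by decreasing total mean degree for a stable group order
  ord <- order(-rowSums(model$means))
  relabel <- match(seq_len(K), ord)
  cluster <- relabel[model$cluster]
  model$weights <- model$weights[ord]
  model$means <- model$means[ord, , drop = FALSE]
  model$covs <- model$covs[, , ord, drop = FALSE]
  model$responsibilities <- model$responsibilities[, ord, drop = FALSE]
  model$cluster <- cluster
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  assignment <- setNames(cluster, ids)
  sizes <- tabulate(cluster, nbins = K)
  gmeans <- matrix(NA_real_, K, ncol(X),
                   dimnames = list(seq_len(K), colnames(X)))
  for (g in seq_len(K)) {
    if (sizes[g]) {
      gmeans[g, ] <- colMeans(X[cluster == g, , drop = FALSE])
    }
  }
  structure(list(K = K, loglik = ll, gains = gains,
                 assignment = assignment,
                 group_sizes = sizes, group_means = gmeans,
                 model = model, plateau = plateau,
                 plateau_threshold = plateau_threshold),
            class = "grouping_result")
}

#' @export
print.grouping_result <- function(x, ...) {
  cat("<grouping_result> K=", x$K,
      if (!x$plateau) " (no plateau; maximum K)" else "",
      "; group sizes: ", paste(x$group_sizes, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Per-group abstinence rates
#'
#' Intent-to-treat (`"ITT"`) rates divide abstinent counts by the full
#' group size — survey nonresponders count as smoking; responder-only
#' rates divide by the number of responders (NA when a group has none).
#'
#' @param result A [select_k()] result.
#' @param outcomes Outcome table (`user_id`, `responded`, `abstinent`)
#'   covering every grouped user.
#' @param mode `"ITT"` or `"responders"`.
#' @return Data frame with `group`, `n`, `n_responders`, `n_abstinent`
#'   and `rate`.
#' @export
group_abstinence <- function(result, outcomes,
                             mode = c("ITT", "responders")) {
  mode <- match.arg(mode)
  stopifnot(inherits(result, "grouping_result"))
  ids <- names(result$assignment)
  idx <- match(ids, as.character(outcomes$user_id))
  if (anyNA(idx)) {
    stop("no outcome row for user ", ids[which(is.na(idx))[1L]])
  }
  responded <- outcomes$responded[idx]
  abstinent <- outcomes$abstinent[idx]
  res <- lapply(seq_len(result$K), function(g) {
    sel <- result$assignment == g
    n <- sum(sel)
    n_resp <- sum(responded[sel])
    n_abst <- sum(abstinent[sel])
    rate <- if (mode == "ITT") {
      if (n) n_abst / n else NA_real_
    } else {
      if (n_resp) n_abst / n_resp else NA_real_
    }
    data.frame(group = g, n = n, n_responders = n_resp,
               n_abstinent = n_abst, rate = rate)
  })
  do.call(rbind, res)
}

#' Two-group one-way ANOVA on a binary outcome
#'
#' F statistic for the difference in abstinence rates between two user
#' groups, computed on the 0/1 abstinence indicator; numerically
#' equivalent to the square of the pooled-variance two-sample t
#' statistic, with degrees of freedom `(1, nA + nB - 2)`. When both
#' groups are constant: equal means give F = 0 (p = 1); different means
#' give an infinite F, flagged.
#'
#' @param a,b Binary (0/1 or logical) outcome vectors, each of length
#'   >= 2.
#' @return List with `F`, `df` (length 2), `p` and `infinite`.
#' @seealso [anova_from_counts()] for printed group summaries.
#' @export
pairwise_anova <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  nA <- length(a); nB <- length(b)
  if (nA < 2 || nB < 2) stop("both groups need at least 2 observations")
  df <- c(1L, nA + nB - 2L)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(F = 0, df = df, p = 1, infinite = FALSE))
    }
    return(list(F = Inf, df = df, p = 0, infinite = TRUE))
  }
  y <- c(a, b)
  g <- factor(rep(c("A", "B"), c(nA, nB)))
  tab <- anova(lm(y ~ g))
  list(F = tab[["F value"]][1L], df = df, p = tab[["Pr(>F)"]][1L],
       infinite = FALSE)
}

#' Two-group ANOVA from printed counts
#'
#' Convenience wrapper around [pairwise_anova()] for summary data: group
#' sizes and abstinent counts, as printed in study tables.
#'
#' @param nA,xA Size and abstinent count of the first group.
#' @param nB,xB Size and abstinent count of the second group.
#' @return See [pairwise_anova()].
#' @export
#' @examples
#' anova_from_counts(18, 10, 88, 27)  # F ~ 4.15 on df (1, 104)
anova_from_counts <- function(nA, xA, nB, xB) {
  pairwise_anova(rep(c(1, 0), c(xA, nA - xA)),
                 rep(c(1, 0), c(xB, nB - xB)))
}
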