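test_that("centrality profiles are per-layer degree recounts", {
  mn <- build_multinet(generate_event_log(
    synth_config(n_users = 50, n_trial_users = 20, seed = 13)))
  cohort <- as.character(1:50)
  prof <- extract_profiles(mn, cohort)
  expect_equal(dim(prof), c(50L, 8L))
  # independent recount of incident edges per layer
  for (ch in OHC_CHANNELS) {
    e <- mn$layers[[ch]]$edges
    for (u in cohort) {
      expect_equal(prof[u, paste0(ch, "_in")], sum(e$dst == u))
      expect_equal(prof[u, paste0(ch, "_out")], sum(e$src == u))
    }
  }
  # a user absent from every layer gets the zero vector
  inactive <- cohort[!cohort %in% mn$aggregated$nodes]
  if (length(inactive)) {
    expect_true(all(prof[inactive, ] == 0))
  }
  expect_error(extract_profiles(mn, character()), "empty")
})

test_that("a single-component fit equals the closed-form Gaussian MLE", {
  set.seed(42)
  X <- matrix(rnorm(150 * 4), 150, 4)
  f <- fit_mixture(X, K = 1, restarts = 2, seed = 1)
  mu <- colMeans(X)
  S <- cov(X) * (nrow(X) - 1) / nrow(X) + diag(1e-6, 4)
  L <- chol(S)
  z <- forwardsolve(t(L), t(X) - mu)
  ll <- sum(-0.5 * colSums(z^2) - sum(log(diag(L))) - 2 * log(2 * pi))
  expect_equal(f$loglik, ll, tolerance = 1e-10)
})

test_that("two well-separated clouds are recovered exactly", {
  set.seed(7)
  lab <- rep(1:2, each = 100)
  X <- matrix(rnorm(200 * 8), 200, 8) + 12 * (lab - 1)
  f <- fit_mixture(X, K = 2, restarts = 5, seed = 3)
  expect_equal(ari_oracle(f$cluster, lab), 1)
})

test_that("component means of a 3-part mixture are recovered within 3 SE", {
  set.seed(10)
  true_means <- rbind(c(0, 0), c(10, 0), c(0, 10))
  lab <- rep(1:3, each = 500)
  X <- true_means[lab, ] + matrix(rnorm(1500 * 2), 1500, 2)
  f <- fit_mixture(X, K = 3, restarts = 5, seed = 5)
  # match fitted to true components by nearest mean
  perm <- apply(f$means, 1, function(m) {
    which.min(colSums((t(true_means) - m)^2))
  })
  expect_setequal(perm, 1:3)
  for (k in 1:3) {
    nk <- f$weights[k] * nrow(X)
    se <- 1 / sqrt(nk)  # unit component sd
    expect_true(all(abs(f$means[k, ] - true_means[perm[k], ]) < 3 * se))
  }
})

test_that("EM log-likelihood is non-decreasing within every restart", {
  set.seed(2)
  X <- matrix(rpois(120 * 8, 2), 120, 8)
  f <- fit_mixture(X, K = 3, restarts = 4, seed = 8)
  for (tr in f$traces) {
    expect_true(all(diff(tr) > -1e-6 * (abs(tr[-length(tr)]) + 1)))
  }
})

test_that("the fitted likelihood is comparable to an independent GMM fit", {
  withr::local_package("mclust")  # Mclust needs its namespace attached
  set.seed(31)
  lab <- rep(1:2, each = 150)
  X <- matrix(rnorm(300 * 3), 300, 3) + 6 * (lab - 1)
  f <- fit_mixture(X, K = 2, restarts = 5, seed = 2)
  mc <- mclust::Mclust(X, G = 2, modelNames = "VVV", verbose = FALSE)
  expect_equal(f$loglik, mc$loglik, tolerance = 0.01)
})

test_that("fit preconditions are enforced", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_mixture(X, K = 10), "smaller")
  expect_error(fit_mixture(X, K = 0), "at least 1")
})

test_that("select_k stops at the log-likelihood plateau", {
  set.seed(9)
  lab <- rep(1:3, each = 120)
  means <- rbind(c(0, 0, 0), c(15, 0, 0), c(0, 15, 0))
  X <- means[lab, ] + matrix(rnorm(360 * 3), 360, 3)
  g <- select_k(X, k_range = 2:5, restarts = 5, seed = 4)
  expect_equal(g$K, 3)
  expect_true(g$plateau)
  expect_length(g$loglik, 4)
  # an unsatisfiable plateau rule returns max K with a warning flag
  expect_warning(
    g2 <- select_k(X, k_range = 2:4, restarts = 3, seed = 4,
                   plateau_threshold = -1),
    "maximum K")
  expect_equal(g2$K, 4)
  expect_false(g2$plateau)
  expect_error(select_k(X, k_range = c(2, 4)), "contiguous")
})

test_that("group means and sizes are recounts of member profiles", {
  set.seed(12)
  lab <- rep(1:2, each = 80)
  X <- matrix(rpois(160 * 8, 1), 160, 8) + 10 * (lab - 1)
  rownames(X) <- sprintf("u%03d", seq_len(nrow(X)))
  g <- select_k(X, k_range = 2:3, restarts = 3, seed = 6)
  expect_equal(sum(g$group_sizes), nrow(X))
  for (k in seq_len(g$K)) {
    members <- names(g$assignment)[g$assignment == k]
    if (!length(members)) next
    expect_equal(g$group_means[k, ],
                 colMeans(X[members, , drop = FALSE]))
  }
})

test_that("group abstinence rates follow the ITT and responder conventions", {
  assignment <- setNames(rep(1:2, c(18, 20)), sprintf("u%02d", 1:38))
  fake <- structure(list(K = 2L, assignment = assignment),
                    class = "grouping_result")
  outcomes <- data.frame(
    user_id = sprintf("u%02d", 1:38),
    responded = c(rep(TRUE, 14), rep(FALSE, 4), rep(TRUE, 10),
                  rep(FALSE, 10)),
    abstinent = c(rep(TRUE, 10), rep(FALSE, 8), rep(FALSE, 20))
  )
  itt <- group_abstinence(fake, outcomes, "ITT")
  resp <- group_abstinence(fake, outcomes, "responders")
  expect_equal(round(100 * itt$rate[1], 1), 55.6)   # 10/18
  expect_equal(round(100 * resp$rate[1], 1), 71.4)  # 10/14
  expect_equal(itt$rate[2], 0)
  expect_equal(resp$rate[2], 0)
  expect_true(all(itt$rate <= resp$rate + 1e-12))
  missing <- outcomes[-1, ]
  expect_error(group_abstinence(fake, missing, "ITT"), "u01")
})

test_that("two-group ANOVA equals the squared pooled t on random data", {
  set.seed(77)
  for (i in 1:100) {
    nA <- sample(3:40, 1); nB <- sample(3:40, 1)
    a <- rbinom(nA, 1, runif(1, 0.2, 0.8))
    b <- rbinom(nB, 1, runif(1, 0.2, 0.8))
    if (stats::var(a) == 0 && stats::var(b) == 0) next
    an <- pairwise_anova(a, b)
    tt <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(an$F, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(an$p, tt$p.value, tolerance = 1e-9)
    expect_equal(an$df[2], nA + nB - 2)
  }
})

test_that("degenerate ANOVA inputs are handled as defined", {
  expect_equal(pairwise_anova(c(1, 0, 1, 0, 1), c(0, 1, 0, 1, 1))$F, 0)
  eq <- pairwise_anova(rep(0, 5), rep(0, 7))
  expect_equal(eq$F, 0); expect_false(eq$infinite)
  ne <- pairwise_anova(rep(0, 5), rep(1, 7))
  expect_true(is.infinite(ne$F)); expect_true(ne$infinite)
  expect_error(pairwise_anova(1, c(0, 1)), "at least 2")
})
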