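test_that("paired t maps follow the closed form and its symmetries", {
  dims <- c(2, 2, 2)
  a <- array(rnorm(3 * prod(dims)), c(3, dims))
  expect_true(all(paired_t_map(a, a)$stat == 0))
  a1 <- array(0, c(3, 1, 1, 1)); a1[, 1, 1, 1] <- c(1, 2, 3)
  b1 <- array(0, c(3, 1, 1, 1))
  tm <- paired_t_map(a1, b1)
  expect_equal(tm$stat[1, 1, 1], 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(tm$df, 2)
  # negating all differences flips every t
  withr::with_seed(2, b2 <- array(rnorm(3 * prod(dims)), c(3, dims)))
  expect_equal(paired_t_map(b2, a)$stat, -paired_t_map(a, b2)$stat)
  # zero-variance points are flagged NaN, not an error
  z <- array(1, c(3, 1, 1, 1))
  expect_true(is.nan(paired_t_map(z, array(0, c(3, 1, 1, 1)))$stat[1, 1, 1]))
})

test_that("correlation maps are Pearson r with the expected null spread", {
  n <- 36
  withr::with_seed(7, {
    diffs <- array(rnorm(n * 10 * 10 * 100), c(n, 10, 10, 100))
    cov_lin <- diffs[, 1, 1, 1] * 2 + 5
  })
  cm <- correlation_map(diffs, cov_lin)
  expect_equal(cm$stat[1, 1, 1], 1, tolerance = 1e-10)
  expect_equal(cm$stat[2, 3, 4],
               cor(diffs[, 2, 3, 4], cov_lin), tolerance = 1e-10)
  # consistent subject permutation leaves r unchanged
  perm <- sample(n)
  cm2 <- correlation_map(diffs[perm, , , , drop = FALSE], cov_lin[perm])
  expect_equal(cm2$stat, cm$stat, tolerance = 1e-10)
  # independent covariate: null r has mean ~0 and sd ~1/sqrt(n-1)
  withr::with_seed(8, cov_ind <- rnorm(n))
  r_null <- as.vector(correlation_map(diffs, cov_ind)$stat)
  expect_lt(abs(mean(r_null)), 0.005)
  expect_equal(sd(r_null), 1 / sqrt(n - 1), tolerance = 0.05)
  expect_error(correlation_map(diffs, rep(1, n)), class = "invalid_covariate")
})

test_that("forming thresholds match an independent CDF inversion", {
  thr <- forming_threshold(mode = "parametric", alpha = 0.025, df = 47)
  # oracle: invert the t CDF by bisection, no qt()
  oracle <- uniroot(function(q) pt(q, 47) - 0.975, c(0, 10), tol = 1e-12)$root
  expect_equal(thr$hi, oracle, tolerance = 1e-9)
  expect_equal(thr$lo, -oracle, tolerance = 1e-9)
  # r-scale threshold from the t critical value
  thr_r <- forming_threshold(mode = "parametric", alpha = 0.025, n = 36,
                             kind = "pearson_r")
  tc <- qt(0.975, 34)
  expect_equal(thr_r$hi, tc / sqrt(tc^2 + 34), tolerance = 1e-12)
})

test_that("nonparametric thresholds are per-point permutation quantiles", {
  withr::with_seed(9, null <- matrix(rnorm(2000 * 50), 2000, 50))
  thr <- forming_threshold(null, mode = "nonparametric_individual",
                           alpha = 0.025)
  expect_equal(thr$hi, apply(null, 2, quantile, 0.975, names = FALSE),
               tolerance = 1e-12)
  # symmetric null: thresholds approximately +/- the same magnitude
  expect_equal(mean(thr$hi), -mean(thr$lo), tolerance = 0.05)
  expect_false(any(thr$degenerate))
  degen <- forming_threshold(matrix(1, 200, 3), "nonparametric_individual")
  expect_true(all(degen$degenerate))
  expect_error(forming_threshold(matrix(rnorm(30), 10, 3),
                                 "nonparametric_individual", alpha = 0.025),
               class = "resolution_error")
})

test_that("cluster extraction obeys the combined adjacency rule", {
  adj <- toy_adjacency(4)
  # one isolated suprathreshold point
  m <- array(0L, c(4, 3, 3)); m[2, 2, 2] <- 1L
  fc <- find_clusters(m, adj)
  expect_equal(nrow(fc$clusters), 1)
  expect_equal(fc$clusters$size, 1)
  # two points at neighbouring channels, same freq and time -> one cluster
  m[3, 2, 2] <- 1L
  expect_equal(nrow(find_clusters(m, adj)$clusters), 1)
  # non-neighbouring channels stay separate
  m2 <- array(0L, c(4, 3, 3)); m2[1, 2, 2] <- 1L; m2[4, 2, 2] <- 1L
  expect_equal(nrow(find_clusters(m2, adj)$clusters), 2)
  # opposite signs never merge
  m3 <- array(0L, c(4, 3, 3)); m3[2, 2, 2] <- 1L; m3[2, 3, 2] <- -1L
  fc3 <- find_clusters(m3, adj)
  expect_equal(nrow(fc3$clusters), 2)
  expect_setequal(fc3$clusters$sign, c(1L, -1L))
})

test_that("cluster extraction matches the flood-fill oracle on random masks", {
  withr::with_seed(10, {
    m60 <- default_montage()
    labels <- sample(m60$labels, 8)
    adj <- m60$adjacency[labels, labels]
    for (i in 1:30) {
      state <- array(sample(c(-1L, 0L, 1L), 8 * 10 * 12, TRUE,
                            prob = c(0.15, 0.6, 0.25)), c(8, 10, 12))
      got <- find_clusters(state, adj, channels = labels)$labels
      want <- oracle_components(state, adj)
      expect_true(same_partition(got, want))
    }
  })
})

test_that("raising the forming threshold never grows a cluster", {
  withr::with_seed(12, stat <- array(rnorm(6 * 8 * 10), c(6, 8, 10)))
  adj <- toy_adjacency(6)
  lo_state <- array(0L, dim(stat)); lo_state[stat > 1] <- 1L
  hi_state <- array(0L, dim(stat)); hi_state[stat > 1.8] <- 1L
  lo_fc <- find_clusters(lo_state, adj, stat = stat)
  hi_fc <- find_clusters(hi_state, adj, stat = stat)
  expect_lte(sum(hi_fc$labels > 0), sum(lo_fc$labels > 0))
  # every high-threshold cluster lies inside one low-threshold cluster
  for (k in hi_fc$clusters$id) {
    parents <- unique(lo_fc$labels[hi_fc$labels == k])
    expect_length(parents, 1)
    expect_gt(parents, 0)
  }
})

test_that("the permutation test is deterministic and bounded below", {
  withr::with_seed(13, {
    x <- array(rnorm(10 * 4 * 5 * 6), c(10, 4, 5, 6))
    y <- array(rnorm(10 * 4 * 5 * 6), c(10, 4, 5, 6))
  })
  x[, 1:2, 2:3, 2:4] <- x[, 1:2, 2:3, 2:4] + 5   # overwhelming effect
  adj <- toy_adjacency(4)
  r1 <- cluster_permutation(x, y, adjacency = adj, n_perm = 200, seed = 5)
  r2 <- cluster_permutation(x, y, adjacency = adj, n_perm = 200, seed = 5)
  expect_identical(r1$clusters, r2$clusters)
  expect_identical(r1$labels, r2$labels)
  expect_equal(min(r1$clusters$p), 1 / 201)      # Monte Carlo lower bound
  expect_true(all(r1$clusters$p >= 1 / 201))
  expect_error(cluster_permutation(x, y, adjacency = adj, n_perm = 30,
                                   alpha = 0.025),
               class = "underpowered_permutation")
})

test_that("observed cluster masses are exchangeable over subject order", {
  withr::with_seed(14, {
    x <- array(rnorm(8 * 4 * 5 * 6), c(8, 4, 5, 6))
    y <- array(rnorm(8 * 4 * 5 * 6), c(8, 4, 5, 6))
  })
  x[, 1, , ] <- x[, 1, , ] + 1.5
  adj <- toy_adjacency(4)
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  r1 <- cluster_permutation(x, y, adjacency = adj, n_perm = 100,
                            forming = "parametric", seed = 5)
  r2 <- cluster_permutation(x[perm, , , ], y[perm, , , ], adjacency = adj,
                            n_perm = 100, forming = "parametric", seed = 5)
  expect_equal(sort(r1$clusters$mass), sort(r2$clusters$mass),
               tolerance = 1e-10)
})

test_that("the covariate design recovers a localized correlation cluster", {
  n <- 24
  withr::with_seed(15, {
    covar <- rnorm(n)
    diffs <- array(rnorm(n * 4 * 5 * 6), c(n, 4, 5, 6))
    for (ch in 1:2) for (f in 2:3) for (t in 2:4)
      diffs[, ch, f, t] <- diffs[, ch, f, t] + 1.5 * covar
  })
  adj <- toy_adjacency(4)
  res <- cluster_permutation(diffs, covariate = covar, adjacency = adj,
                             n_perm = 500, seed = 6)
  expect_identical(res$design, "covariate")
  top <- res$clusters[1, ]
  expect_true(top$significant)
  expect_gt(top$sign, 0)
  block <- array(FALSE, c(4, 5, 6)); block[1:2, 2:3, 2:4] <- TRUE
  overlap <- sum(res$labels == top$id & block) / sum(block)
  expect_gte(overlap, 0.5)
})
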