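test_that("feature construction flattens channel x frequency correctly", {
  # 60 channels x 2-60 Hz -> 3540 features per trial
  withr::with_seed(1, {
    power <- array(abs(rnorm(4 * 60 * 59 * 3)) + 1, dim = c(4, 60, 59, 3))
  })
  tf <- eeg_tfr(power, freqs = 2:60, times = c(-1000, -950, -900),
                channels = default_montage()$labels, unit = "raw",
                metadata = data.frame(rating = rep(c("negative", "positive"), 2)))
  fb <- build_features(tf, decode_config())
  expect_identical(ncol(fb$x), 3540L)
  expect_identical(nrow(fb$feature_info), 3540L)
  # channel-major ordering: first 59 features are all of channel 1
  expect_identical(unique(fb$feature_info$channel[1:59]), tf$channels[1])
  expect_identical(fb$feature_info$freq[1:59], as.numeric(2:60))
  # constant-power trials give identical feature rows
  tfc <- tf
  tfc$power[] <- 3
  fbc <- build_features(tfc, decode_config())
  expect_true(all(fbc$x == 3))
  # dB input and unbalanced labels are refused
  db <- tf
  db$unit <- "dB"
  db$baseline <- c(-1500, -500)
  expect_error(build_features(db, decode_config()), class = "wrong_unit")
  tfu <- tf
  tfu$metadata$rating <- c("negative", "negative", "negative", "positive")
  expect_error(build_features(tfu, decode_config()), class = "balance_error")
})

test_that("no post-onset sample ever enters a decoding feature", {
  cfg <- quick_config(n_subjects = 1, n_trials_exp1 = 12, n_trials_exp2 = 4,
                      montage = small_montage(4),
                      effect_channels = c("C3", "C1"),
                      bias_mean_exp1 = 0.5, seed = 3)
  ep <- simulate_subject(cfg, 1)$exp1
  # zero everything at t >= 0 ms and rebuild: features must be unchanged
  ep0 <- ep
  ep0$data[, , ep$times >= 0] <- 0
  toi <- seq(-1000, -200, 50)
  dc <- decode_config(fmax = 20)
  sel <- equalize_trials(ep$metadata$rating, seed = 1)
  idx <- sort(c(sel$negative$indices, sel$positive$indices))
  fb <- fb0 <- NULL
  for (e in list(ep, ep0)) {
    sub <- tfr_hanning(e, freqs = 2:20, toi = toi)
    sub$power <- sub$power[idx, , , , drop = FALSE]
    sub$metadata <- sub$metadata[idx, , drop = FALSE]
    f <- build_features(sub, dc)
    if (is.null(fb)) fb <- f else fb0 <- f
  }
  expect_identical(fb$x, fb0$x)
})

test_that("the SVM grid search separates, calibrates and is deterministic", {
  withr::with_seed(4, {
    n <- 40
    x <- rbind(matrix(rnorm(n / 2 * 6, mean = 3), ncol = 6),
               matrix(rnorm(n / 2 * 6, mean = -3), ncol = 6))
    y <- factor(rep(c("negative", "positive"), each = n / 2))
  })
  fit <- fit_svm_grid(x, y, decode_config(), seed = 9)
  expect_equal(mean(predict(fit$model, x) == y), 1)   # separable toy
  # shuffled labels: inner-CV accuracy near chance
  withr::with_seed(5, ys <- sample(y))
  fit_s <- fit_svm_grid(x, ys, decode_config(), seed = 9)
  expect_lt(abs(max(fit_s$grid) - 0.5), 0.2)
  # identical data and seed -> identical chosen C
  fit2 <- fit_svm_grid(x, y, decode_config(), seed = 9)
  expect_identical(fit$C, fit2$C)
  expect_error(fit_svm_grid(x, factor(rep("negative", n),
                                      levels = c("negative", "positive"))),
               class = "degenerate_labels")
})

test_that("binomial accuracy tests equal the closed-form tail sums", {
  bt <- binomial_accuracy_test(1, 38)
  expect_equal(bt$p, 0.5^38, tolerance = 1e-12)
  expect_gt(binomial_accuracy_test(0.5, 20)$p, 0.5)    # at-chance accuracy
  # k = 15 of n = 20: brute-force tail summation oracle
  oracle <- sum(choose(20, 15:20)) * 0.5^20
  expect_equal(binomial_accuracy_test(0.75, 20)$p, oracle, tolerance = 1e-12)
  expect_equal(oracle, 0.02069473, tolerance = 1e-6)
  expect_error(binomial_accuracy_test(0.517, 20), class = "inconsistent_count")
})

test_that("peak accuracy prefers the binomial mask with a global fallback", {
  expect_equal(peak_accuracy(list(accuracy = 0.8, mask = TRUE)), 0.8)
  expect_equal(peak_accuracy(list(accuracy = c(0.55, 0.71, 0.62),
                                  mask = c(FALSE, TRUE, FALSE))), 0.71)
  expect_equal(peak_accuracy(list(accuracy = c(0.52, 0.58),
                                  mask = c(FALSE, FALSE))), 0.58)
})

test_that("the group t-test against chance matches the closed form", {
  expect_equal(group_ttest_vs_chance(rep(0.5, 10))$t, 0)
  # printed-summary oracle: mean 0.739, sd 0.053, n 36
  withr::with_seed(6, {
    peaks <- rnorm(36)
    peaks <- (peaks - mean(peaks)) / sd(peaks) * 0.053 + 0.739
  })
  gt <- group_ttest_vs_chance(peaks)
  expect_equal(gt$t, (0.739 - 0.5) / (0.053 / 6), tolerance = 1e-10)
  expect_equal(gt$t, 27.0566, tolerance = 1e-4)
  expect_equal(gt$df, 35)
  expect_lt(gt$p, 1e-20)
  # location invariance: shifting peaks and chance together leaves t alone
  gt2 <- group_ttest_vs_chance(peaks + 0.1, chance = 0.6)
  expect_equal(gt2$t, gt$t, tolerance = 1e-10)
  expect_warning(out <- group_ttest_vs_chance(rep(0.7, 5)), "zero variance")
  expect_true(is.na(out$t))
})

test_that("cross-decoding transfers a shared pattern between toy sessions", {
  tf1 <- toy_decode_tfr(24, effect = 8, sd = 0.5, seed = 11)
  tf2 <- toy_decode_tfr(12, effect = 8, sd = 0.5, seed = 12)
  dc <- decode_config(window = c(-1000, -900), fmax = 6, C_grid = 1,
                      seed = 21)
  res <- cross_decode_subject(tf1, tf2, dc, min_trials = 5)
  expect_gt(res$accuracy, 0.9)
  expect_equal(res$n_test, 24)
  expect_lt(res$p, 0.001)
  expect_identical(res$peak, res$accuracy)
  # per-frequency mode: one accuracy per frequency, peak within the mask
  dcf <- decode_config(window = c(-1000, -900), fmax = 6, C_grid = 1,
                       mode = "per_frequency", seed = 21)
  resf <- cross_decode_subject(tf1, tf2, dcf, min_trials = 5)
  expect_length(resf$accuracy, 5)
  expect_true(resf$peak %in% resf$accuracy)
  expect_gt(resf$accuracy[2], 0.9)   # the informative frequency
})

test_that("group LOPOCV tests every subject exactly once on its own session", {
  cohort <- lapply(1:4, function(s) list(
    exp1 = toy_decode_tfr(16, effect = 3, sd = 1.2, seed = 100 + s),
    exp2 = toy_decode_tfr(8, effect = 3, sd = 1.2, seed = 200 + s)))
  dc <- decode_config(window = c(-1000, -900), fmax = 6, C_grid = 1,
                      seed = 31)
  res <- group_lopocv(cohort, dc, min_trials = 5)
  expect_length(res$accuracy, 4)
  expect_identical(res$n_test, rep(16, 4))
  expect_true(all(res$accuracy > 0.8))    # shared population-level effect
  expect_identical(res$peaks, res$accuracy)
  # a subject missing an experiment is dropped with a warning
  cohort[[2]]$exp2 <- NULL
  expect_warning(res3 <- group_lopocv(cohort, dc, min_trials = 5),
                 "excluded")
  expect_length(res3$accuracy, 3)
})

test_that("alternating labels make previous-label accuracy the complement", {
  # deterministic neg/pos alternation with a current-label effect:
  # previous = opposite of current, so training on previous labels learns
  # the inverted rule and acc_prev ~ 1 - acc_current
  labels <- rep(c("negative", "positive"), 20)
  tfs <- lapply(1:2, function(s)
    toy_decode_tfr(20, effect = 8, sd = 0.5, labels = labels,
                   seed = 300 + s))
  dc <- decode_config(window = c(-1000, -900), fmax = 6, C_grid = 1,
                      seed = 41)
  res <- previous_label_control(tfs, dc, folds = 5, repeats = 2,
                                min_trials = 5)
  expect_length(res$acc_prev, 2)
  expect_true(all(res$acc_current > 0.9))
  expect_true(all(res$acc_prev < 0.1))
  expect_equal(res$acc_prev, 1 - res$acc_current, tolerance = 0.1)
})
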