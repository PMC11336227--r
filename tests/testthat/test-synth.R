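# Independent oracle: least-squares slope of the log-log periodogram.
periodogram_slope <- function(x) {
  n <- length(x)
  p <- Mod(fft(x))^2 / n
  k <- 2:(n %/% 2)                      # skip DC, positive frequencies
  fit <- lm.fit(cbind(1, log(k - 1)), log(p[k]))
  fit$coefficients[2]
}

test_that("1/f^beta noise has the requested spectral slope and unit variance", {
  withr::with_seed(11, {
    for (x in replicate(5, pink_noise(4096, 1), simplify = FALSE)) {
      expect_equal(mean(x), 0, tolerance = 1e-12)
      expect_equal(var(x), 1, tolerance = 1e-9)
    }
    slope_white <- mean(replicate(50, periodogram_slope(pink_noise(4096, 0))))
    slope_pink <- mean(replicate(50, periodogram_slope(pink_noise(4096, 1))))
    expect_lt(abs(slope_white), 0.1)
    expect_lt(abs(slope_pink - (-1)), 0.1)
  })
  expect_error(pink_noise(4096, NaN), class = "invalid_parameter")
  expect_error(pink_noise(4096, 3), class = "invalid_parameter")
})

test_that("oscillatory bursts are confined to their window and band", {
  tt <- seq(-2000, 2000, by = 2)
  expect_identical(oscillatory_burst(10, 0, c(-500, 0), tt),
                   numeric(length(tt)))
  b <- oscillatory_burst(10, 2, c(-500, 0), tt)
  expect_true(all(b[tt < -500 | tt > 0] == 0))
  expect_true(any(b != 0))
  # periodogram of the windowed segment peaks at the 10 Hz bin (direct DFT)
  seg <- b[tt >= -500 & tt <= 0]
  fs <- 500
  freqs <- 2:40
  amp <- vapply(freqs, function(f) {
    k <- seq_along(seg) - 1
    Mod(sum(seg * exp(-2i * pi * f * k / fs)))
  }, 0)
  expect_equal(freqs[which.max(amp)], 10)
  expect_error(oscillatory_burst(10, 1, c(-3000, 0), tt),
               class = "invalid_parameter")
  expect_error(oscillatory_burst(400, 1, c(-500, 0), tt),
               class = "invalid_parameter")
})

test_that("rating simulation matches the requested label marginals", {
  expect_true(all(simulate_behavior(50, 1, 0, seed = 1) == "negative"))
  lab <- simulate_behavior(10000, 0.65, 0, seed = 2)
  expect_lt(abs(mean(lab == "negative") - 0.65), 0.01)
  lab <- simulate_behavior(10000, 0.5, 0, seed = 3)
  expect_lt(abs(mean(lab == "negative") - 0.5), 0.015)
  lab <- simulate_behavior(10000, 0.6, 0.1, seed = 4)
  expect_lt(abs(mean(lab == "negative") - 0.6), 0.015)
  expect_lt(abs(mean(lab == "neutral") - 0.1), 0.01)
  expect_error(simulate_behavior(10, 0.9, 0.2), class = "invalid_parameter")
})

test_that("cohort simulation is bit-identical under a fixed seed", {
  cfg <- quick_config(n_subjects = 1, n_trials_exp1 = 6, n_trials_exp2 = 4,
                      montage = small_montage(4),
                      effect_channels = c("C3", "C1"), seed = 99)
  a <- simulate_subject(cfg, 1)
  b <- simulate_subject(cfg, 1)
  expect_identical(a$exp1$data, b$exp1$data)
  expect_identical(a$exp2$data, b$exp2$data)
  expect_identical(a$behavior, b$behavior)
  # different subjects differ
  c2 <- simulate_subject(cfg, 2)
  expect_false(identical(a$exp1$data, c2$exp1$data))
})

test_that("config validation rejects invalid effect specifications", {
  expect_error(quick_config(effect_channels = c("CP3", "QQ7")),
               class = "unknown_channel")
  expect_error(quick_config(effect_band = c(1, 12)), class = "invalid_parameter")
  expect_error(quick_config(effect_window = c(-3000, 0)),
               class = "invalid_parameter")
  expect_error(quick_config(noise_exponent = 5), class = "invalid_parameter")
})

band_power_db_diff <- function(tf, channels = c("CP3", "CP5", "C3"),
                               band = 8:12, window = c(-500, 0)) {
  fi <- which(tf$freqs %in% band)
  ti <- which(tf$times >= window[1] & tf$times <= window[2])
  ci <- match(channels, tf$channels)
  neg <- which(tf$metadata$rating == "negative")
  pos <- which(tf$metadata$rating == "positive")
  10 * log10(mean(tf$power[neg, ci, fi, ti]) / mean(tf$power[pos, ci, fi, ti]))
}

test_that("a zero-dB effect yields no group power difference", {
  cfg <- quick_config(n_subjects = 1, n_trials_exp1 = 200, n_trials_exp2 = 4,
                      bias_mean_exp1 = 0.5, bias_mean_exp2 = 0.5,
                      bias_sd = 0.02, effect_size_db = 0, seed = 5)
  s <- simulate_subject(cfg, 1)
  tf <- tfr_hanning(s$exp1, freqs = 8:12, toi = seq(-500, 0, 50))
  fi <- seq_along(tf$freqs)
  ci <- match(c("CP3", "CP5", "C3"), tf$channels)
  neg <- which(tf$metadata$rating == "negative")
  pos <- which(tf$metadata$rating == "positive")
  x <- rowMeans(matrix(tf$power[neg, ci, fi, ], nrow = length(neg)))
  y <- rowMeans(matrix(tf$power[pos, ci, fi, ], nrow = length(pos)))
  se <- sqrt(var(x) / length(x) + var(y) / length(y))
  expect_lt(abs(mean(x) - mean(y)), 2 * se)
})

test_that("the realized dB contrast recovers the requested effect size", {
  dbs <- vapply(1:12, function(i) {
    cfg <- quick_config(n_subjects = 1, n_trials_exp1 = 40, n_trials_exp2 = 4,
                        bias_mean_exp1 = 0.5, bias_mean_exp2 = 0.5,
                        bias_sd = 0.02, effect_size_db = 3, seed = 700 + i)
    s <- simulate_subject(cfg, 1)
    band_power_db_diff(tfr_hanning(s$exp1, freqs = 8:12,
                                   toi = seq(-500, 0, 50)))
  }, 0)
  expect_lt(abs(mean(dbs) - 3), 0.2 * 3)
})

test_that("the injected effect is confined to its channels, band and window", {
  # per-subject dB condition-difference maps (the univariate pipeline's
  # quantity; the log scale symmetrizes single-trial power), paired t over
  # subjects, exceedance rate checked away from every effect coordinate
  n_sub <- 50
  cfg <- quick_config(n_subjects = n_sub, n_trials_exp1 = 32,
                      n_trials_exp2 = 4, bias_mean_exp1 = 0.5,
                      bias_mean_exp2 = 0.5, bias_sd = 0.02,
                      effect_size_db = 3, seed = 41)
  freqs <- 2:30
  toi <- seq(-1750, 500, 50)
  diffs <- array(NA_real_, c(n_sub, 16, length(freqs), length(toi)))
  for (i in seq_len(n_sub)) {
    s <- simulate_subject(cfg, i)
    db <- tfr_db_baseline(tfr_hanning(s$exp1, freqs = freqs, toi = toi),
                          c(-1500, -500))
    avg <- tfr_condition_average(db, equalize_trials(db$metadata$rating,
                                                     seed = i))
    diffs[i, , , ] <- avg$negative$power[1, , , ] - avg$positive$power[1, , , ]
  }
  tm <- paired_t_map(diffs, array(0, dim(diffs)))$stat
  # a point is effect-related if it shares the effect channels OR band OR
  # window; everything else must be null
  ch_eff <- cfg$montage$labels %in% c("CP3", "CP5", "C3")
  f_eff <- freqs >= 8 & freqs <= 12
  t_eff <- toi >= -500 & toi <= 0
  eff <- outer(outer(ch_eff, f_eff, `|`), t_eff, `|`)
  crit <- qt(0.9995, n_sub - 1)
  expect_lt(mean(abs(tm[!eff]) > crit), 0.002)
})
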