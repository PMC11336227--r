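#' Decoding configuration
#'
#' @param window Pre-stimulus feature window in ms (default -1000..-200).
#'   Feature construction additionally drops any window center whose
#'   analysis window would cross stimulus onset, so no sample recorded at or
#'   after onset ever enters a feature (see [build_features()]).
#' @param fmax Upper feature frequency in Hz (default 60).
#' @param C_grid Cost grid for the linear SVM (default `10^(-2:2)`).
#' @param inner_folds Stratified folds for the inner grid search (default 5).
#' @param chance Chance level (0.5 with balanced classes).
#' @param mode `"single"` (one accuracy from the full channel x frequency
#'   feature set) or `"per_frequency"` (one independent accuracy per
#'   frequency, making the binomial mask and peak extraction non-vacuous).
#' @param window_length TFR window length in ms used for the leakage check.
#' @param seed Seed governing grid-search fold assignment and equalization.
#' @return A list of class `decode_config`.
#' @export
decode_config <- function(window = c(-1000, -200), fmax = 60,
                          C_grid = 10^(-2:2), inner_folds = 5,
                          chance = 0.5, mode = c("single", "per_frequency"),
                          window_length = 500, seed = NULL) {
  mode <- match.arg(mode)
  if (!length(C_grid) || any(C_grid <= 0))
    stop_prestim("C_grid must be a nonempty set of positive values",
                 "invalid_parameter")
  if (window[2] >= 0 || window[1] >= window[2])
    stop_prestim("feature window must be strictly pre-stimulus",
                 "invalid_parameter")
  structure(list(window = window, fmax = fmax, C_grid = sort(C_grid),
                 inner_folds = inner_folds, chance = chance, mode = mode,
                 window_length = window_length, seed = seed),
            class = "decode_config")
}

#' Build decoding features from a raw-power TFR
#'
#' Time-averages raw (uncorrected) power over the pre-stimulus feature
#' window and flattens channels x frequencies (2..fmax Hz) to one feature
#' vector per trial, in channel-major order (all frequencies of channel 1,
#' then channel 2, ...).  Window centers whose analysis window would extend
#' to or past stimulus onset are excluded, guaranteeing that zeroing all
#' post-onset data changes no feature.
#'
#' @param tfr A trial-level raw-power [eeg_tfr()] whose metadata ratings are
#'   restricted to the two valences with equalized counts.
#' @param config A [decode_config()].
#' @param labels Optional label factor overriding the metadata ratings.
#' @return List: `x` (trials x features matrix), `y` (factor
#'   negative/positive), `feature_info` (channel/frequency per column).
#' @export
build_features <- function(tfr, config = decode_config(), labels = NULL) {
  stopifnot(inherits(tfr, "eeg_tfr"))
  if (tfr$unit != "raw")
    stop_prestim("decoding consumes raw (baseline-uncorrected) power",
                 "wrong_unit")
  # exclude centers whose analysis window reaches stimulus onset
  upper <- min(config$window[2], -tfr$window_length / 2)
  ta <- tfr_time_average(tfr, window = c(config$window[1], upper),
                         fmax = config$fmax)
  y <- labels %||% droplevels(factor(as.character(tfr$metadata$rating),
                                     levels = c("negative", "positive")))
  if (anyNA(y) || nlevels(y) != 2L)
    stop_prestim("labels must be negative/positive only", "invalid_parameter")
  if (length(unique(table(y))) != 1L)
    stop_prestim("class counts must be equalized before decoding",
                 "balance_error")
  n_tr <- dim(ta$power)[1]
  nch <- dim(ta$power)[2]
  nf <- dim(ta$power)[3]
  # channel-major flattening: feature = (channel - 1) * nf + freq index
  x <- matrix(aperm(ta$power, c(1, 3, 2)), nrow = n_tr)
  colnames(x) <- paste(rep(ta$channels, each = nf), rep(ta$freqs, nch),
                       sep = "_")
  list(x = x, y = y,
       feature_info = data.frame(channel = rep(ta$channels, each = nf),
                                 freq = rep(ta$freqs, nch)))
}

# Standardize train features; apply the train statistics to test features.
standardize_features <- function(train, test = NULL) {
  mu <- colMeans(train)
  sdv <- apply(train, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  out <- list(train = sweep(sweep(train, 2L, mu), 2L, sdv, `/`))
  if (!is.null(test)) out$test <- sweep(sweep(test, 2L, mu), 2L, sdv, `/`)
  out
}

# Deterministic stratified fold assignment.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Linear SVM with inner-fold grid search over C
#'
#' The cost parameter is chosen by stratified k-fold accuracy on the
#' training set only; ties go to the smallest C; the final rule is refit on
#' all training data at the chosen C.
#'
#' @param x Training feature matrix (already standardized by the caller).
#' @param y Training label factor (two classes, each with >= 2 trials).
#' @param config A [decode_config()].
#' @param seed Seed for the fold assignment (default `config$seed`).
#' @return List: `model` (an [e1071::svm()] fit), `C`, `grid` (accuracy per
#'   candidate C).
#' @export
fit_svm_grid <- function(x, y, config = decode_config(), seed = config$seed) {
  y <- droplevels(y)
  if (nlevels(y) < 2L || min(table(y)) < 2L)
    stop_prestim("training set must contain >= 2 trials of each class",
                 "degenerate_labels")
  grid <- config$C_grid
  acc <- rep(NA_real_, length(grid))
  if (length(grid) > 1L) {
    k <- min(config$inner_folds, min(table(y)))
    fold <- maybe_with_seed(seed, stratified_folds(y, k))
    acc <- vapply(grid, function(C) {
      hits <- vapply(seq_len(k), function(f) {
        tr <- fold != f
        m <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "linear",
                        cost = C, scale = FALSE)
        sum(predict(m, x[!tr, , drop = FALSE]) == y[!tr])
      }, 0)
      sum(hits) / length(y)
    }, 0)
    C <- grid[which.max(acc)]   # which.max takes the first, i.e. smallest, C
  } else {
    C <- grid
  }
  model <- e1071::svm(x, y, kernel = "linear", cost = C, scale = FALSE)
  list(model = model, C = C, grid = stats::setNames(acc, grid))
}

#' Exact binomial test of classification accuracies against chance
#'
#' One-sided exact binomial tail probability `P(K >= k | n_test, chance)`
#' with `k = round(accuracy * n_test)`, plus the significance mask at 0.05.
#'
#' @param accuracy Accuracy value(s) in `[0, 1]`.
#' @param n_test Number of test trials.
#' @param chance Chance level (default 0.5).
#' @param alpha Mask threshold (default 0.05).
#' @return List: `p` (per accuracy), `mask` (logical), `k` (correct counts).
#' @export
binomial_accuracy_test <- function(accuracy, n_test, chance = 0.5,
                                   alpha = 0.05) {
  stopifnot(n_test >= 1, all(accuracy >= 0 & accuracy <= 1))
  k <- round(accuracy * n_test)
  if (any(abs(accuracy * n_test - k) > 1e-6))
    stop_prestim("accuracy * n_test is not an integral correct count",
                 "inconsistent_count")
  p <- stats::pbinom(k - 1, n_test, chance, lower.tail = FALSE)
  list(p = p, mask = p <= alpha, k = k)
}

#' Peak accuracy within the binomial significance mask
#'
#' The maximum accuracy among binomially significant entries; if nothing is
#' significant, the maximum over all accuracies.
#'
#' @param result A `decode_result` (or any list with `accuracy` and `mask`).
#' @return Scalar peak accuracy.
#' @export
peak_accuracy <- function(result) {
  acc <- result$accuracy
  mask <- result$mask
  if (any(mask)) max(acc[mask]) else max(acc)
}

#' One-sample t-test of peak accuracies against chance
#'
#' @param peaks Per-subject (or per-iteration) peak accuracies, n >= 2.
#' @param chance Chance level (default 0.5).
#' @return List `t`, `df`, `p` (two-sided); `t` is `NA` (flagged) when the
#'   peaks have zero variance.
#' @export
group_ttest_vs_chance <- function(peaks, chance = 0.5) {
  n <- length(peaks)
  stopifnot(n >= 2)
  s <- stats::sd(peaks)
  if (s == 0) {
    if (all(peaks == chance)) return(list(t = 0, df = n - 1, p = 1))
    warning("zero variance of peak accuracies; t undefined")
    return(list(t = NA_real_, df = n - 1, p = NA_real_))
  }
  t_val <- (mean(peaks) - chance) / (s / sqrt(n))
  list(t = t_val, df = n - 1, p = 2 * stats::pt(-abs(t_val), n - 1))
}

# Equalize + build standardized features for one experiment of one subject.
prepare_subject_features <- function(tfr, config, seed) {
  sel <- equalize_trials(tfr$metadata$rating, seed = seed)
  idx <- sort(c(sel$negative$indices, sel$positive$indices))
  sub <- tfr
  sub$power <- tfr$power[idx, , , , drop = FALSE]
  sub$metadata <- tfr$metadata[idx, , drop = FALSE]
  build_features(sub, config)
}

#' Within-subject cross-experiment decoding
#'
#' Trains a linear SVM on all experiment-1 trials of one subject and tests
#' it exactly once on all of that subject's experiment-2 trials (experiment
#' 2 trials are few and unique, so no resampling).  Class counts are
#' equalized within each experiment first, so chance is exactly 0.5.
#' Features are standardized with training-set statistics only.
#'
#' @param tfr1,tfr2 Trial-level raw-power [eeg_tfr()]s for experiments 1
#'   and 2 of the same subject.
#' @param config A [decode_config()].
#' @param min_trials Per-class inclusion minimum after equalization
#'   (default 10).
#' @return A `decode_result`: `accuracy` (scalar in single mode, one per
#'   frequency otherwise), `n_test`, binomial `p` and `mask`, `peak`,
#'   chosen `C`, `mode`, and train/test experiment ids.
#' @export
cross_decode_subject <- function(tfr1, tfr2, config = decode_config(),
                                 min_trials = 10) {
  f1 <- prepare_subject_features(tfr1, config, seed = config$seed)
  f2 <- prepare_subject_features(tfr2, config,
                                 seed = derive_seed(config$seed, 2))
  if (!inclusion_check(table(f1$y) / 1, min_trials) ||
      !inclusion_check(table(f2$y) / 1, min_trials))
    stop_prestim("subject fails the minimum-trial inclusion rule",
                 "missing_data")

  decode_pair <- function(xtr, ytr, xte, yte, seed) {
    z <- standardize_features(xtr, xte)
    fit <- fit_svm_grid(z$train, ytr, config, seed = seed)
    list(acc = mean(predict(fit$model, z$test) == yte), C = fit$C)
  }

  if (config$mode == "single") {
    res <- decode_pair(f1$x, f1$y, f2$x, f2$y, config$seed)
    accuracy <- res$acc
    C <- res$C
  } else {
    freqs <- sort(unique(f1$feature_info$freq))
    per_f <- lapply(seq_along(freqs), function(i) {
      cols <- f1$feature_info$freq == freqs[i]
      decode_pair(f1$x[, cols, drop = FALSE], f1$y,
                  f2$x[, cols, drop = FALSE], f2$y,
                  derive_seed(config$seed, 100 + i))
    })
    accuracy <- stats::setNames(vapply(per_f, `[[`, 0, "acc"), freqs)
    C <- vapply(per_f, `[[`, 0, "C")
  }
  n_test <- length(f2$y)
  bt <- binomial_accuracy_test(accuracy, n_test, config$chance)
  out <- list(accuracy = accuracy, n_test = n_test, p = bt$p, mask = bt$mask,
              mode = config$mode, C = C, trained_on = 1L, tested_on = 2L,
              seed = config$seed)
  out$peak <- peak_accuracy(out)
  structure(out, class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("<decode_result> mode=%s, peak accuracy %.3f (n_test=%d, trained exp%d -> tested exp%d)\n",
              x$mode, x$peak, x$n_test, x$trained_on, x$tested_on))
  invisible(x)
}

#' Group-level leave-one-participant-out cross-decoding
#'
#' Per subject, trials are equalized and each feature is z-transformed
#' across that subject's trials, separately within each experiment (removing
#' subject-specific scale before pooling).  For each held-out subject the
#' SVM is trained on the pooled experiment-1 trials of the remaining
#' subjects and tested on the held-out subject's experiment-2 trials; every
#' subject is tested exactly once.
#'
#' @param cohort_tfrs List with one element per subject, each a list with
#'   raw-power `exp1` and `exp2` [eeg_tfr()]s; subjects missing an
#'   experiment are excluded with a warning.
#' @param config A [decode_config()].
#' @param min_trials Per-class inclusion minimum (default 10).
#' @return List: per-subject `accuracy`, `n_test`, binomial `p`/`mask`,
#'   `peaks` (per iteration), `group` ([group_ttest_vs_chance()] on the
#'   peaks), and the ids of included subjects.
#' @export
group_lopocv <- function(cohort_tfrs, config = decode_config(),
                         min_trials = 10) {
  usable <- vapply(cohort_tfrs, function(s)
    !is.null(s$exp1) && !is.null(s$exp2), TRUE)
  if (any(!usable))
    warning(sprintf("%d subject(s) missing an experiment; excluded",
                    sum(!usable)))
  subjects <- which(usable)
  if (length(subjects) < 3)
    stop_prestim("group cross-decoding needs >= 3 subjects with both experiments",
                 "missing_data")

  feats <- lapply(subjects, function(s) {
    f1 <- prepare_subject_features(cohort_tfrs[[s]]$exp1, config,
                                   seed = derive_seed(config$seed, 10 * s))
    f2 <- prepare_subject_features(cohort_tfrs[[s]]$exp2, config,
                                   seed = derive_seed(config$seed, 10 * s + 1))
    if (!inclusion_check(table(f1$y) / 1, min_trials) ||
        !inclusion_check(table(f2$y) / 1, min_trials))
      stop_prestim("subject fails the minimum-trial inclusion rule",
                   "missing_data")
    # z-transform per feature across this subject's trials, per experiment
    list(x1 = scale_safe(f1$x), y1 = f1$y,
         x2 = scale_safe(f2$x), y2 = f2$y)
  })

  acc <- n_test <- numeric(length(feats))
  for (i in seq_along(feats)) {
    xtr <- do.call(rbind, lapply(feats[-i], `[[`, "x1"))
    ytr <- factor(unlist(lapply(feats[-i], function(f) as.character(f$y1))),
                  levels = c("negative", "positive"))
    fit <- fit_svm_grid(xtr, ytr, config,
                        seed = derive_seed(config$seed, 1000 + i))
    acc[i] <- mean(predict(fit$model, feats[[i]]$x2) == feats[[i]]$y2)
    n_test[i] <- length(feats[[i]]$y2)
  }
  p <- mask <- numeric(length(acc))
  for (i in seq_along(acc)) {
    bt <- binomial_accuracy_test(acc[i], n_test[i], config$chance)
    p[i] <- bt$p
    mask[i] <- bt$mask
  }
  peaks <- acc   # single accuracy per iteration: the peak is that accuracy
  list(accuracy = acc, n_test = n_test, p = p, mask = as.logical(mask),
       peaks = peaks, group = group_ttest_vs_chance(peaks, config$chance),
       subjects = subjects)
}

scale_safe <- function(x) {
  z <- scale(x)
  z[, attr(z, "scaled:scale") == 0] <- 0
  z[, , drop = FALSE]
}

#' Previous-rating control analysis
#'
#' Tests whether pre-stimulus decodability merely reflects the previous
#' trial's rating.  Trials whose previous rating is neutral, missed or
#' undefined (first trial of a run) are removed; the remainder is balanced
#' over the four (previous, current) label combinations so both label sets
#' have equal class counts.  Control A trains on the PREVIOUS trial's rating
#' and tests those same trials against their CURRENT rating; control B is a
#' standard stratified k-fold (5 folds x 4 repetitions) decode of the
#' current rating.  Per-subject accuracies of A and B are compared with a
#' paired t-test.
#'
#' @param exp1_tfrs List of trial-level raw-power [eeg_tfr()]s (experiment 1),
#'   one per subject, with `rating` and `previous_rating` metadata.
#' @param config A [decode_config()].
#' @param folds,repeats Cross-validation layout for control B (defaults 5, 4).
#' @param min_trials Minimum usable trials per class after exclusion;
#'   subjects below it are skipped with a warning (default 10).
#' @return List: per-subject `acc_prev` and `acc_current`, the paired
#'   `t`/`df`/`p`, and the included subject indices.
#' @export
previous_label_control <- function(exp1_tfrs, config = decode_config(),
                                   folds = 5, repeats = 4, min_trials = 10) {
  acc_prev <- acc_cur <- numeric(0)
  included <- integer(0)
  for (s in seq_along(exp1_tfrs)) {
    tfr <- exp1_tfrs[[s]]
    md <- tfr$metadata
    ok <- as.character(md$rating) %in% c("negative", "positive") &
      as.character(md$previous_rating) %in% c("negative", "positive")
    combos <- factor(paste(md$previous_rating[ok], md$rating[ok], sep = "."),
                     levels = c("negative.negative", "positive.positive",
                                "negative.positive", "positive.negative"))
    counts <- table(combos)
    # both label margins are balanced iff the two diagonal cells are kept at
    # equal size and the two off-diagonal cells are kept at equal size; when
    # all four cells are populated they are kept at one common size, which
    # pins the previous/current agreement of the kept trials at exactly 1/2
    k_diag <- min(counts[1:2])
    k_off <- min(counts[3:4])
    if (k_diag > 0 && k_off > 0) k_diag <- k_off <- min(k_diag, k_off)
    per_class <- k_diag + k_off
    if (per_class < min_trials) {
      warning(sprintf("subject %d has too few usable trials; skipped", s))
      next
    }
    target <- c(k_diag, k_diag, k_off, k_off)
    keep <- maybe_with_seed(derive_seed(config$seed, 5000 + s), {
      unlist(lapply(seq_along(levels(combos)), function(ci) {
        idx <- which(ok)[combos == levels(combos)[ci]]
        if (length(idx) > target[ci]) sort(sample(idx, target[ci])) else idx
      }))
    })
    keep <- sort(keep)
    sub <- tfr
    sub$power <- tfr$power[keep, , , , drop = FALSE]
    sub$metadata <- md[keep, , drop = FALSE]

    f_cur <- build_features(sub, config)
    prev <- droplevels(factor(as.character(sub$metadata$previous_rating),
                              levels = c("negative", "positive")))

    # A: train on previous-trial labels, test the same trials on current
    # labels.  With high-dimensional features the fit typically reproduces
    # its training labels, so this accuracy reduces to the previous/current
    # label agreement of the kept trials (exactly 1/2 under the balanced
    # selection above); values above chance would indicate genuine
    # previous-label structure leaking into the patterns.
    z <- standardize_features(f_cur$x)
    fitA <- fit_svm_grid(z$train, prev, config,
                         seed = derive_seed(config$seed, 6000 + s))
    acc_prev <- c(acc_prev, mean(predict(fitA$model, z$train) == f_cur$y))

    # B: standard k-fold x repeats decode of the current labels
    accs <- maybe_with_seed(derive_seed(config$seed, 7000 + s), {
      vapply(seq_len(repeats), function(r) {
        fold <- stratified_folds(f_cur$y, folds)
        hits <- vapply(seq_len(folds), function(f) {
          tr <- fold != f
          zz <- standardize_features(f_cur$x[tr, , drop = FALSE],
                                     f_cur$x[!tr, , drop = FALSE])
          fit <- fit_svm_grid(zz$train, f_cur$y[tr], config, seed = NULL)
          sum(predict(fit$model, zz$test) == f_cur$y[!tr])
        }, 0)
        sum(hits) / length(f_cur$y)
      }, 0)
    })
    acc_cur <- c(acc_cur, mean(accs))
    included <- c(included, s)
  }
  if (length(included) < 2)
    stop_prestim("previous-rating control needs >= 2 usable subjects",
                 "missing_data")
  d <- acc_cur - acc_prev
  s_d <- stats::sd(d)
  t_val <- if (s_d == 0) NA_real_ else mean(d) / (s_d / sqrt(length(d)))
  list(acc_prev = acc_prev, acc_current = acc_cur, t = t_val,
       df = length(d) - 1,
       p = if (is.na(t_val)) NA_real_ else 2 * stats::pt(-abs(t_val), length(d) - 1),
       subjects = included)
}
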