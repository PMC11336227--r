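#' End-to-end run configuration
#'
#' Bundles the stage parameters for [run_pipeline()].  Every random stage
#' draws from a seed derived from the single `seed` here, so a rerun with an
#' identical configuration reproduces every number.
#'
#' @param sim A [sim_config()] describing the cohort.
#' @param freqs,toi,window_length Time-frequency decomposition grid
#'   (defaults 2..60 Hz, -1750..1750 ms at 50 ms steps, 500 ms window).
#' @param baseline dB baseline window in ms (default -1500..-500).
#' @param cluster_window Statistics window in ms (default -500..1500).
#' @param cluster_fmax Upper frequency for cluster statistics (default 60).
#' @param n_perm Cluster permutations (default 2000).
#' @param cluster_alpha Per-tail cluster alpha (default 0.025).
#' @param forming Cluster-forming threshold mode.
#' @param decode A [decode_config()].
#' @param min_trials Per-class inclusion minimum (default 10).
#' @param seed Master seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim,
                       freqs = 2:60,
                       toi = seq(-1750, 1750, by = 50),
                       window_length = 500,
                       baseline = c(-1500, -500),
                       cluster_window = c(-500, 1500),
                       cluster_fmax = 60,
                       n_perm = 2000,
                       cluster_alpha = 0.025,
                       forming = c("nonparametric_individual", "parametric"),
                       decode = decode_config(fmax = min(60, max(freqs))),
                       min_trials = 10,
                       seed = 1L) {
  forming <- match.arg(forming)
  stopifnot(inherits(sim, "sim_config"), inherits(decode, "decode_config"))
  structure(as.list(environment()), class = "run_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_prestim(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)), "stage_error")
  })
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Executes simulate -> preprocess (common average reference, valence
#' selection, trial equalization, inclusion rule) -> time-frequency
#' decomposition -> cluster permutation statistics (paired valence contrast
#' per experiment, plus the bias-correlation design on the combined
#' experiments) -> decoding (within-subject cross-experiment, group
#' leave-one-participant-out, previous-rating control) -> behavioral
#' statistics, and returns one results bundle whose report layer never
#' recomputes a number.
#'
#' @param config A [run_config()].
#' @return A list of class `prestim_results` with sections `config_echo`,
#'   `simulate`, `preprocess`, `tfr`, `cluster`, `decoding`, `behavior`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  sim <- config$sim
  dec_cfg <- config$decode
  dec_cfg$seed <- dec_cfg$seed %||% derive_seed(config$seed, 31)

  cohort <- run_stage("simulate", simulate_cohort(sim))
  n_sub <- sim$n_subjects

  # ---- preprocess + TFR per subject/experiment -------------------------
  tfrs <- vector("list", n_sub)
  subject_maps <- list(exp1 = list(), exp2 = list())
  counts_eq <- matrix(NA_integer_, n_sub, 2)
  run_stage("preprocess/tfr", {
    for (s in seq_len(n_sub)) {
      # inclusion rule first: the equalized per-class count is the smaller
      # class's count, so a subject short of trials (down to an empty
      # class) is excluded before any heavy computation, mirroring the
      # exclusion of under-sampled participants from the final sample
      for (e in c("exp1", "exp2")) {
        ratings <- as.character(cohort$subjects[[s]][[e]]$metadata$rating)
        counts_eq[s, 1 + (e == "exp2")] <-
          min(sum(ratings == "negative"), sum(ratings == "positive"))
      }
      if (any(counts_eq[s, ] < config$min_trials)) {
        warning(sprintf("subject %d fails the inclusion rule; excluded", s))
        next
      }
      tfrs[[s]] <- list()
      for (e in c("exp1", "exp2")) {
        ep <- common_average_reference(cohort$subjects[[s]][[e]])
        raw <- tfr_hanning(ep, freqs = config$freqs, toi = config$toi,
                           window_length = config$window_length)
        tfrs[[s]][[e]] <- raw
        sel <- equalize_trials(ep$metadata$rating,
                               seed = derive_seed(config$seed,
                                                  100 * s + (e == "exp2")))
        db <- tfr_db_baseline(raw, baseline = config$baseline)
        avg <- tfr_condition_average(db, sel)
        subject_maps[[e]][[s]] <- lapply(avg, function(a)
          restrict_map(a, config$cluster_window, config$cluster_fmax))
      }
    }
  })
  included <- which(counts_eq[, 1] >= config$min_trials &
                    counts_eq[, 2] >= config$min_trials)
  if (length(included) < 3)
    stop_prestim("fewer than 3 subjects pass the inclusion rule",
                 "stage_error")

  f_idx <- which(config$freqs >= 2 & config$freqs <= config$cluster_fmax)
  t_idx <- which(in_window(config$toi, config$cluster_window))
  map_dims <- c(length(sim$montage$labels), length(f_idx), length(t_idx))

  stack <- function(e, cond) {
    arr <- array(NA_real_, dim = c(length(included), map_dims))
    for (i in seq_along(included))
      arr[i, , , ] <- subject_maps[[e]][[included[i]]][[cond]]
    arr
  }

  # ---- cluster statistics ----------------------------------------------
  cluster_res <- run_stage("cluster", {
    res <- list()
    for (e in c("exp1", "exp2")) {
      res[[e]] <- cluster_permutation(
        stack(e, "negative"), stack(e, "positive"),
        adjacency = sim$montage, freqs = config$freqs[f_idx],
        times = config$toi[t_idx], n_perm = config$n_perm,
        alpha = config$cluster_alpha, forming = config$forming,
        seed = derive_seed(config$seed, 11 + (e == "exp2")))
    }
    # bias-correlation design on the combined experiments
    diffs <- (stack("exp1", "negative") - stack("exp1", "positive") +
              stack("exp2", "negative") - stack("exp2", "positive")) / 2
    bias <- vapply(included, function(s) {
      b <- cohort$behavior[cohort$behavior$subject == s, ]
      mean(vapply(seq_len(nrow(b)), function(i) negativity_bias(
        list(negative = b$n_negative[i], positive = b$n_positive[i],
             neutral = b$n_neutral[i])), 0))
    }, 0)
    res$bias <- cluster_permutation(
      diffs, covariate = bias, adjacency = sim$montage,
      freqs = config$freqs[f_idx], times = config$toi[t_idx],
      n_perm = config$n_perm, alpha = config$cluster_alpha,
      forming = config$forming, seed = derive_seed(config$seed, 13))
    res
  })

  # ---- decoding ---------------------------------------------------------
  decoding <- run_stage("decoding", {
    per_subject <- lapply(included, function(s)
      cross_decode_subject(tfrs[[s]]$exp1, tfrs[[s]]$exp2, dec_cfg,
                           min_trials = config$min_trials))
    peaks <- vapply(per_subject, `[[`, 0, "peak")
    group <- group_lopocv(tfrs[included], dec_cfg,
                          min_trials = config$min_trials)
    prev <- previous_label_control(lapply(tfrs[included], `[[`, "exp1"),
                                   dec_cfg, min_trials = config$min_trials)
    list(subject = list(peaks = peaks,
                        mean_peak = mean(peaks),
                        sd_peak = stats::sd(peaks),
                        t_vs_chance = group_ttest_vs_chance(peaks)),
         group = group, prev_control = prev)
  })

  # ---- behavioral statistics -------------------------------------------
  behavior <- run_stage("behavior", {
    bt <- cohort$behavior
    bt$bias_pct <- vapply(seq_len(nrow(bt)), function(i) negativity_bias(
      list(negative = bt$n_negative[i], positive = bt$n_positive[i],
           neutral = bt$n_neutral[i])), 0)
    b1 <- bt[bt$experiment == 1L, ]
    b2 <- bt[bt$experiment == 2L, ]
    shared <- intersect(b1$subject[b1$subject %in% included],
                        b2$subject[b2$subject %in% included])
    cmp <- compare_bias(b1$bias_pct[match(shared, b1$subject)],
                        b2$bias_pct[match(shared, b2$subject)])
    qc <- lapply(list(exp1 = b1, exp2 = b2), function(b)
      questionnaire_correlations(b$bias_pct,
                                 b[, c("bdi2", "stai_s", "stai_t")]))
    list(table = bt,
         bias_mean = c(exp1 = mean(b1$bias_pct), exp2 = mean(b2$bias_pct)),
         bias_sd = c(exp1 = stats::sd(b1$bias_pct),
                     exp2 = stats::sd(b2$bias_pct)),
         comparison = cmp, questionnaires = qc, shared_subjects = shared)
  })

  structure(
    list(
      config_echo = list(seed = config$seed, n_subjects = n_sub,
                         n_perm = config$n_perm,
                         cluster_alpha = config$cluster_alpha,
                         forming = config$forming,
                         freqs = range(config$freqs),
                         cluster_window = config$cluster_window,
                         decode_window = dec_cfg$window,
                         package_version = as.character(
                           utils::packageVersion("prestim"))),
      simulate = list(n_subjects = n_sub,
                      n_trials = c(exp1 = sim$n_trials_exp1,
                                   exp2 = sim$n_trials_exp2),
                      effect_size_db = sim$effect_size_db,
                      effect_channels = sim$effect_channels),
      preprocess = list(equalized_counts = counts_eq, included = included),
      tfr = list(freqs = range(config$freqs), step_ms = diff(config$toi[1:2]),
                 window_length = config$window_length,
                 baseline = config$baseline),
      cluster = cluster_res,
      decoding = decoding,
      behavior = behavior
    ),
    class = "prestim_results"
  )
}

restrict_map <- function(cond_tfr, window, fmax) {
  f_idx <- which(cond_tfr$freqs >= 2 & cond_tfr$freqs <= fmax)
  t_idx <- which(in_window(cond_tfr$times, window))
  cond_tfr$power[1, , f_idx, t_idx]
}

results_json_list <- function(res) {
  min_p <- function(cr) if (nrow(cr$clusters)) min(cr$clusters$p) else NA
  list(
    config = res$config_echo,
    behavior = list(
      bias_mean = as.list(res$behavior$bias_mean),
      bias_sd = as.list(res$behavior$bias_sd),
      comparison = res$behavior$comparison,
      questionnaires = res$behavior$questionnaires
    ),
    cluster = lapply(res$cluster, function(cr) list(
      n_clusters = nrow(cr$clusters),
      n_significant = sum(cr$clusters$significant),
      min_p = min_p(cr))),
    decoding = list(
      subject = res$decoding$subject[c("peaks", "mean_peak", "sd_peak",
                                       "t_vs_chance")],
      group = res$decoding$group[c("accuracy", "peaks", "group")],
      prev_control = res$decoding$prev_control[c("acc_prev", "acc_current",
                                                 "t", "df", "p")]
    )
  )
}

#' Write a pipeline results bundle to disk
#'
#' Emits `results.json` (every reported number), `behavior.tsv`,
#' `clusters.tsv`, `decoding.json` and a plain-text `report.txt` whose
#' numbers are exactly those in the JSON (the report layer formats, it never
#' recomputes).
#'
#' @param res A `prestim_results` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(res, dir) {
  stopifnot(inherits(res, "prestim_results"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  js <- results_json_list(res)
  jsonlite::write_json(js, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  utils::write.table(res$behavior$table, file.path(dir, "behavior.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  cl <- do.call(rbind, lapply(names(res$cluster), function(nm) {
    d <- res$cluster[[nm]]$clusters
    if (nrow(d)) cbind(analysis = nm, d) else NULL
  }))
  if (is.null(cl))
    cl <- data.frame(analysis = character(0), id = integer(0),
                     sign = integer(0), size = integer(0),
                     mass = numeric(0), p = numeric(0),
                     significant = logical(0))
  utils::write.table(cl, file.path(dir, "clusters.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(js$decoding, file.path(dir, "decoding.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  writeLines(format_report(js), file.path(dir, "report.txt"))
  invisible(dir)
}

format_report <- function(js) {
  fmt <- function(x, d = 3) formatC(x, digits = d, format = "g")
  c("prestim pipeline report",
    "=======================",
    "",
    sprintf("seed: %s   subjects: %s   permutations: %s",
            js$config$seed, js$config$n_subjects, js$config$n_perm),
    "",
    "[simulate]",
    sprintf("  cohort of %s subjects simulated", js$config$n_subjects),
    "",
    "[behavior]",
    sprintf("  negativity bias: exp1 %s%% (SD %s), exp2 %s%% (SD %s)",
            fmt(js$behavior$bias_mean$exp1), fmt(js$behavior$bias_sd$exp1),
            fmt(js$behavior$bias_mean$exp2), fmt(js$behavior$bias_sd$exp2)),
    sprintf("  paired t(%s) = %s, p = %s", js$behavior$comparison$df,
            fmt(js$behavior$comparison$t), fmt(js$behavior$comparison$p)),
    "",
    "[cluster]",
    vapply(names(js$cluster), function(nm) sprintf(
      "  %s: %s cluster(s), %s significant, min p = %s", nm,
      js$cluster[[nm]]$n_clusters, js$cluster[[nm]]$n_significant,
      fmt(js$cluster[[nm]]$min_p)), ""),
    "",
    "[decoding]",
    sprintf("  within-subject mean peak accuracy = %s (SD %s), t(%s) = %s, p = %s",
            fmt(js$decoding$subject$mean_peak), fmt(js$decoding$subject$sd_peak),
            js$decoding$subject$t_vs_chance$df,
            fmt(js$decoding$subject$t_vs_chance$t),
            fmt(js$decoding$subject$t_vs_chance$p)),
    sprintf("  group LOPOCV mean accuracy = %s, t(%s) = %s, p = %s",
            fmt(mean(unlist(js$decoding$group$accuracy))),
            js$decoding$group$group$df, fmt(js$decoding$group$group$t),
            fmt(js$decoding$group$group$p)),
    sprintf("  previous-rating control: prev %s vs current %s, t(%s) = %s, p = %s",
            fmt(mean(unlist(js$decoding$prev_control$acc_prev))),
            fmt(mean(unlist(js$decoding$prev_control$acc_current))),
            js$decoding$prev_control$df, fmt(js$decoding$prev_control$t),
            fmt(js$decoding$prev_control$p)))
}
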