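# Shared fixtures: reduced montages and simulation configurations sized for
# fast, deterministic test runs.  All data are generated in code.

central_channels <- c("C5", "C3", "C1", "Cz", "CP5", "CP3", "CP1", "CPz",
                      "P5", "P3", "P1", "Pz", "FC3", "FC1", "F3", "F1")

small_montage <- function(n = 16) {
  montage_subset(default_montage(), central_channels[seq_len(n)])
}

# Reduced-cohort configuration: the study's structure (two sessions, biased
# ratings, pre-stimulus alpha effect at left centro-parietal channels) at a
# trial/channel count that keeps a subject's simulation under a second.
quick_config <- function(..., n_subjects = 4, n_trials_exp1 = 48,
                         n_trials_exp2 = 28, montage = small_montage(),
                         neutral_prob = 0, seed = 1L) {
  sim_config(n_subjects = n_subjects, n_trials_exp1 = n_trials_exp1,
             n_trials_exp2 = n_trials_exp2, montage = montage,
             neutral_prob = neutral_prob, seed = seed, ...)
}

# TFR grid covering the pre-stimulus feature window only.
feature_tfr <- function(epochs, freqs = 2:30) {
  tfr_hanning(epochs, freqs = freqs, toi = seq(-1000, -250, 50))
}

# Hand-built trial-level TFR with injected class structure, for decoding
# unit tests that should not pay for a full simulation.  Class "negative"
# gets `effect` added to the given channel/frequency cells.
toy_decode_tfr <- function(n_per_class, nch = 4, nf = 5, nt = 3,
                           effect = 1, eff_ch = 1, eff_f = 2, sd = 1,
                           labels = NULL, seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    if (is.null(labels))
      labels <- rep(c("negative", "positive"), each = n_per_class)
    power <- array(abs(rnorm(n * nch * nf * nt, mean = 10, sd = sd)),
                   dim = c(n, nch, nf, nt))
    power[labels == "negative", eff_ch, eff_f, ] <-
      power[labels == "negative", eff_ch, eff_f, ] + effect
    prev <- c(NA, labels[-n])
    eeg_tfr(power, freqs = seq_len(nf) + 1,
            times = seq(-1000, by = 50, length.out = nt),
            channels = paste0("ch", seq_len(nch)), unit = "raw",
            window_length = 500, sampling_rate = 500,
            metadata = data.frame(rating = labels, previous_rating = prev))
  })
}

toy_adjacency <- function(nch, labels = paste0("ch", seq_len(nch))) {
  # chain adjacency ch1-ch2-...-chn
  adj <- matrix(FALSE, nch, nch, dimnames = list(labels, labels))
  for (i in seq_len(nch - 1)) adj[i, i + 1] <- adj[i + 1, i] <- TRUE
  adj
}
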