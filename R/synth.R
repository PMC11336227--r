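#' Simulation configuration for synthetic two-experiment EEG cohorts
#'
#' Describes a cohort in which every subject completes two sessions: a long
#' repeated-stimulus session ("experiment 1", default 210 trials) and a short
#' single-presentation session ("experiment 2", default 68 trials).  Each
#' trial carries a valence rating (negative / positive / neutral / missed)
#' drawn from a subject-specific negativity bias, and the EEG is 1/f
#' background noise plus ongoing alpha activity plus a band-limited
#' oscillatory burst at the effect channels whose amplitude is larger on
#' trials later rated negative.  The injected contrast is an amplitude
#' modulation of an always-present burst, so the manipulated quantity is
#' induced band power (in dB), not an additive evoked response.
#'
#' Per-subject negativity bias is drawn as `bias_mean_exp*` plus a shared
#' subject offset `~ N(0, bias_sd)`, truncated to `[0.05, 0.95]`: the
#' between-subject spread that bias-correlation analyses require, with the
#' experiment-2 mean 10 points above experiment 1 by default.
#'
#' @param n_subjects Number of subjects.
#' @param n_trials_exp1,n_trials_exp2 Trials per session (defaults 210, 68).
#' @param sampling_rate Sampling rate in Hz (default 500).
#' @param epoch_window Epoch limits in ms relative to face onset
#'   (default `c(-2000, 2000)`, closed interval).
#' @param bias_mean_exp1,bias_mean_exp2 Cohort mean probability that a rated
#'   trial is rated negative (defaults 0.55 and 0.65).
#' @param bias_sd Between-subject SD of the bias (default 0.12).
#' @param neutral_prob Probability of a neutral rating (default 0.05).
#' @param missed_prob Probability of a missed response (default 0).
#' @param effect_channels Channels carrying the valence-dependent burst
#'   (default left centro-parietal: CP3, CP5, C3).
#' @param effect_band Burst frequency band in Hz (default alpha, 8-12).
#' @param effect_window Burst support in ms (default pre-stimulus -500..0).
#' @param effect_size_db Expected pre-stimulus band-power difference,
#'   negative minus positive trials, in dB (default 3).
#' @param effect_amp Base burst amplitude in microvolts on positive-rated
#'   trials (default 25, a strong but physiological alpha burst; large
#'   enough that the burst dominates band power at the effect channels, so
#'   the realized dB contrast tracks `effect_size_db`).
#' @param effect_sign `"shared"` (same direction in every subject) or
#'   `"random"` (direction drawn per subject) - the latter builds cohorts
#'   with subject-specific but population-inconsistent effects.
#' @param effect_channels_exp2,effect_band_exp2,effect_window_exp2 Optional
#'   experiment-2 overrides; `NULL` (default) reuses the experiment-1 effect,
#'   giving the shared cross-experiment structure.  Setting disjoint
#'   channels/bands makes the two sessions' effects orthogonal.
#' @param bias_effect_slope_db Coupling between a subject's bias offset and
#'   their effect size, in dB per unit bias probability (default 0 =
#'   uncoupled).
#' @param post_effect Optional second effect specification, a list with
#'   elements `window`, `band`, `channels`, `size_db`, injected in addition
#'   to the pre-stimulus effect (default `NULL`: post-stimulus effects off).
#' @param noise_exponent Spectral slope beta of the 1/f^beta background
#'   (default 1).
#' @param noise_sd Background noise SD in microvolts (default 10).
#' @param alpha_amp Amplitude of ongoing (effect-independent) alpha activity
#'   in microvolts on every channel (default 3).
#' @param montage An `eeg_montage` (default [default_montage()]).
#' @param seed Integer master seed; per-subject streams are derived from it,
#'   so identical configurations regenerate bit-identical cohorts.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 10,
                       n_trials_exp1 = 210,
                       n_trials_exp2 = 68,
                       sampling_rate = 500,
                       epoch_window = c(-2000, 2000),
                       bias_mean_exp1 = 0.55,
                       bias_mean_exp2 = 0.65,
                       bias_sd = 0.12,
                       neutral_prob = 0.05,
                       missed_prob = 0,
                       effect_channels = c("CP3", "CP5", "C3"),
                       effect_band = c(8, 12),
                       effect_window = c(-500, 0),
                       effect_size_db = 3,
                       effect_amp = 25,
                       effect_sign = c("shared", "random"),
                       effect_channels_exp2 = NULL,
                       effect_band_exp2 = NULL,
                       effect_window_exp2 = NULL,
                       bias_effect_slope_db = 0,
                       post_effect = NULL,
                       noise_exponent = 1,
                       noise_sd = 10,
                       alpha_amp = 3,
                       montage = default_montage(),
                       seed = 1L) {
  effect_sign <- match.arg(effect_sign)
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_subjects >= 1, n_trials_exp1 >= 1, n_trials_exp2 >= 1,
              sampling_rate > 0, length(epoch_window) == 2,
              epoch_window[1] < epoch_window[2])
    if (bias_mean_exp1 < 0 || bias_mean_exp1 > 1 ||
        bias_mean_exp2 < 0 || bias_mean_exp2 > 1 ||
        neutral_prob < 0 || neutral_prob >= 1 ||
        missed_prob < 0 || missed_prob > 1)
      stop_prestim("rating probabilities must satisfy 0 <= bias <= 1, 0 <= neutral < 1",
                   "invalid_parameter")
    if (max(bias_mean_exp1, bias_mean_exp2) + neutral_prob > 1)
      stop_prestim("bias_prob + neutral_prob must be <= 1", "invalid_parameter")
    if (effect_window[1] < epoch_window[1] || effect_window[2] > epoch_window[2])
      stop_prestim("effect_window must lie within epoch_window", "invalid_parameter")
    if (effect_band[1] < 2 || effect_band[2] > 120 || effect_band[1] > effect_band[2])
      stop_prestim("effect_band must lie within 2-120 Hz", "invalid_parameter")
    if (!is.finite(noise_exponent) || noise_exponent < 0 || noise_exponent > 2)
      stop_prestim("noise_exponent must be finite and in [0, 2]", "invalid_parameter")
    missing_ch <- setdiff(effect_channels, montage$labels)
    if (length(missing_ch))
      stop_prestim(paste0("effect channels not in montage: ",
                          paste(missing_ch, collapse = ", ")), "unknown_channel")
    if (!is.null(effect_channels_exp2)) {
      missing2 <- setdiff(effect_channels_exp2, montage$labels)
      if (length(missing2))
        stop_prestim(paste0("effect channels not in montage: ",
                            paste(missing2, collapse = ", ")), "unknown_channel")
    }
  })
  invisible(cfg)
}

#' 1/f^beta background noise
#'
#' Spectral synthesis: complex Gaussian Fourier coefficients scaled by
#' `f^(-beta/2)` (so power follows `1/f^beta` in expectation), inverse
#' transformed, then exactly centred and scaled to unit sample variance.
#' Draws from the current RNG stream.
#'
#' @param n_samples Series length (>= 2).
#' @param exponent Spectral slope beta, in `[0, 2]` (0 = white noise).
#' @return Numeric vector with mean 0 and sample variance 1.
#' @export
pink_noise <- function(n_samples, exponent = 1) {
  if (!is.numeric(exponent) || length(exponent) != 1L || !is.finite(exponent) ||
      exponent < 0 || exponent > 2)
    stop_prestim("exponent must be a finite number in [0, 2]", "invalid_parameter")
  stopifnot(n_samples >= 2)
  n <- as.integer(n_samples)
  nf <- n %/% 2L
  amp <- seq_len(nf)^(-exponent / 2)
  z <- complex(real = rnorm(nf), imaginary = rnorm(nf)) * amp
  spec <- if (n %% 2L == 0L) {
    # Nyquist coefficient must be real for a real series
    c(0, z[seq_len(nf - 1L)], complex(real = Re(z[nf]) * sqrt(2)),
      Conj(rev(z[seq_len(nf - 1L)])))
  } else {
    c(0, z, Conj(rev(z)))
  }
  x <- Re(stats::fft(spec, inverse = TRUE))
  x <- x - mean(x)
  x / stats::sd(x)
}

#' Band-limited oscillatory burst
#'
#' A sinusoid under a smooth Hann envelope supported only inside `window`
#' (zero everywhere else), used as the carrier of injected band-power
#' effects.
#'
#' @param freq Carrier frequency in Hz (must be below Nyquist).
#' @param amplitude Peak amplitude in microvolts.
#' @param window ms pair giving the envelope support (closed interval).
#' @param times ms time axis the waveform is evaluated on.
#' @param phase Carrier phase in radians (default 0).
#' @return Numeric vector of `length(times)`.
#' @export
oscillatory_burst <- function(freq, amplitude, window, times, phase = 0) {
  stopifnot(length(window) == 2, window[1] < window[2])
  if (window[1] < min(times) || window[2] > max(times))
    stop_prestim("burst window lies outside the time axis", "invalid_parameter")
  sfreq <- 1000 / stats::median(diff(times))
  if (freq >= sfreq / 2)
    stop_prestim("burst frequency must be below Nyquist", "invalid_parameter")
  wave <- numeric(length(times))
  idx <- which(in_window(times, window))
  if (length(idx)) {
    env <- hann_window(length(idx))
    wave[idx] <- amplitude * env *
      sin(2 * pi * freq * (times[idx] - window[1]) / 1000 + phase)
  }
  wave
}

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

#' Simulate a sequence of valence ratings
#'
#' Draws i.i.d. trial labels such that, among logged ratings (negative,
#' positive or neutral), the expected negative fraction equals `bias_prob`
#' and the expected neutral fraction equals `neutral_prob`.
#'
#' @param n_trials Number of trials.
#' @param bias_prob Probability a rated trial is rated negative.
#' @param neutral_prob Probability a rated trial is rated neutral.
#' @param missed_prob Probability of a missed response (default 0).
#' @param seed Optional seed for a self-contained draw.
#' @return Factor with levels negative/positive/neutral/missed.
#' @export
simulate_behavior <- function(n_trials, bias_prob, neutral_prob = 0,
                              missed_prob = 0, seed = NULL) {
  if (bias_prob < 0 || bias_prob > 1 || neutral_prob < 0 || neutral_prob >= 1 ||
      bias_prob + neutral_prob > 1 || missed_prob < 0 || missed_prob > 1)
    stop_prestim("invalid rating probabilities", "invalid_parameter")
  p_rated <- 1 - missed_prob
  probs <- c(negative = bias_prob * p_rated,
             positive = (1 - bias_prob - neutral_prob) * p_rated,
             neutral = neutral_prob * p_rated,
             missed = missed_prob)
  maybe_with_seed(seed, {
    factor(sample(rating_levels(), n_trials, replace = TRUE, prob = probs),
           levels = rating_levels())
  })
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Subject-level latent parameters (bias offset, effect size/sign,
# questionnaire scores).  Called inside the subject's seeded stream.
draw_subject_traits <- function(cfg) {
  u <- stats::rnorm(1, 0, cfg$bias_sd)
  sgn <- if (cfg$effect_sign == "random") sample(c(-1, 1), 1L) else 1
  list(
    bias_offset = u,
    bias_exp1 = clamp(cfg$bias_mean_exp1 + u, 0.05, 0.95),
    bias_exp2 = clamp(cfg$bias_mean_exp2 + u, 0.05, 0.95),
    effect_db = sgn * (cfg$effect_size_db + cfg$bias_effect_slope_db * u),
    bdi2 = round(clamp(stats::rnorm(1, 4, 3.3), 0, 63)),
    stai_s = round(clamp(stats::rnorm(1, 31, 5.6), 20, 80)),
    stai_t = round(clamp(stats::rnorm(1, 31, 7.2), 20, 80))
  )
}

# One session's epochs: background + ongoing alpha + valence-modulated burst.
simulate_epochs <- function(cfg, labels, experiment, subject, effect_db,
                            effect_channels, effect_band, effect_window) {
  n_trials <- length(labels)
  times <- seq(cfg$epoch_window[1], cfg$epoch_window[2],
               by = 1000 / cfg$sampling_rate)
  nsamp <- length(times)
  chans <- cfg$montage$labels
  nch <- length(chans)
  eff_idx <- match(effect_channels, chans)

  # negative-rated trials carry the burst at amplitude * 10^(db/20), so the
  # expected burst power contrast is effect_db decibels
  amp_by_label <- ifelse(labels == "negative",
                         cfg$effect_amp * 10^(effect_db / 20), cfg$effect_amp)

  data <- array(0, dim = c(n_trials, nch, nsamp))
  for (tr in seq_len(n_trials)) {
    burst_freq <- stats::runif(1, effect_band[1], effect_band[2])
    burst_phase <- stats::runif(1, 0, 2 * pi)
    burst <- oscillatory_burst(burst_freq, amp_by_label[tr], effect_window,
                               times, burst_phase)
    post <- NULL
    if (!is.null(cfg$post_effect)) {
      pe <- cfg$post_effect
      pamp <- if (labels[tr] == "negative")
        cfg$effect_amp * 10^(pe$size_db / 20) else cfg$effect_amp
      post <- oscillatory_burst(stats::runif(1, pe$band[1], pe$band[2]), pamp,
                                pe$window, times, stats::runif(1, 0, 2 * pi))
      post_idx <- match(pe$channels %||% effect_channels, chans)
    }
    for (ch in seq_len(nch)) {
      x <- cfg$noise_sd * pink_noise(nsamp, cfg$noise_exponent) +
        cfg$alpha_amp * sin(2 * pi * 10 * times / 1000 + stats::runif(1, 0, 2 * pi))
      if (ch %in% eff_idx) x <- x + burst
      if (!is.null(post) && ch %in% post_idx) x <- x + post
      data[tr, ch, ] <- x
    }
  }

  eeg_epochs(
    data, times = times, sampling_rate = cfg$sampling_rate, channels = chans,
    metadata = data.frame(
      rating = labels,
      previous_rating = factor(c(NA, as.character(labels[-n_trials])),
                               levels = rating_levels()),
      subject = subject,
      experiment = experiment
    ),
    montage = cfg$montage
  )
}

#' Simulate one subject's two experimental sessions
#'
#' Both sessions share the montage and the subject's latent effect (size,
#' direction and, unless overridden, location), so cross-experiment analyses
#' see genuinely shared structure.  Fully deterministic given the
#' configuration seed and subject index.
#'
#' @param config A [sim_config()].
#' @param subject_index Positive integer identifying the subject.
#' @return List with `exp1` and `exp2` ([eeg_epochs()] objects) and
#'   `behavior` (one-row-per-experiment data frame of rating counts, true
#'   bias and questionnaire scores).
#' @export
simulate_subject <- function(config, subject_index) {
  stopifnot(inherits(config, "sim_config"), subject_index >= 1)
  maybe_with_seed(derive_seed(config$seed, subject_index), {
    traits <- draw_subject_traits(config)
    lab1 <- simulate_behavior(config$n_trials_exp1, traits$bias_exp1,
                              config$neutral_prob, config$missed_prob)
    lab2 <- simulate_behavior(config$n_trials_exp2, traits$bias_exp2,
                              config$neutral_prob, config$missed_prob)
    exp1 <- simulate_epochs(config, lab1, 1L, subject_index, traits$effect_db,
                            config$effect_channels, config$effect_band,
                            config$effect_window)
    exp2 <- simulate_epochs(
      config, lab2, 2L, subject_index, traits$effect_db,
      config$effect_channels_exp2 %||% config$effect_channels,
      config$effect_band_exp2 %||% config$effect_band,
      config$effect_window_exp2 %||% config$effect_window
    )
    behavior <- do.call(rbind, lapply(list(lab1, lab2), function(l) {
      tab <- table(l)
      data.frame(n_negative = tab[["negative"]], n_positive = tab[["positive"]],
                 n_neutral = tab[["neutral"]], n_missed = tab[["missed"]])
    }))
    behavior <- cbind(
      data.frame(subject = subject_index, experiment = c(1L, 2L)),
      behavior,
      data.frame(bias_true = c(traits$bias_exp1, traits$bias_exp2),
                 effect_db_true = traits$effect_db,
                 bdi2 = traits$bdi2, stai_s = traits$stai_s,
                 stai_t = traits$stai_t)
    )
    list(exp1 = exp1, exp2 = exp2, behavior = behavior)
  })
}

#' Simulate a full cohort
#'
#' @param config A [sim_config()].
#' @return List of class `sim_cohort`: `subjects` (list of
#'   [simulate_subject()] outputs), `behavior` (stacked behavior table) and
#'   `config`.
#' @export
simulate_cohort <- function(config) {
  subjects <- lapply(seq_len(config$n_subjects),
                     function(i) simulate_subject(config, i))
  structure(
    list(subjects = subjects,
         behavior = do.call(rbind, lapply(subjects, `[[`, "behavior")),
         config = config),
    class = "sim_cohort"
  )
}
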