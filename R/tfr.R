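#' Time-frequency representation container
#'
#' Power over (trials or subjects) x channels x frequencies x times.  Raw
#' power is in squared microvolts; after [tfr_db_baseline()] values are in
#' decibels relative to the recorded baseline window.  Grid points whose
#' analysis window would overrun the epoch are `NA` ("undefined"), never
#' zero-padded.
#'
#' @param power 4-d numeric array.
#' @param freqs Hz axis.
#' @param times ms axis of window centers.
#' @param channels Channel labels.
#' @param unit `"raw"` or `"dB"`.
#' @param window_length Analysis window length in ms.
#' @param sampling_rate Source sampling rate in Hz.
#' @param metadata Per-trial metadata (first array dimension), or `NULL`.
#' @param baseline Baseline ms window when `unit == "dB"`.
#' @return An object of class `eeg_tfr`.
#' @export
eeg_tfr <- function(power, freqs, times, channels, unit = c("raw", "dB"),
                    window_length = 500, sampling_rate = NULL,
                    metadata = NULL, baseline = NULL) {
  unit <- match.arg(unit)
  stopifnot(is.array(power), length(dim(power)) == 4L,
            dim(power)[2] == length(channels),
            dim(power)[3] == length(freqs),
            dim(power)[4] == length(times))
  if (unit == "raw" && any(power < 0, na.rm = TRUE))
    stop_prestim("raw power must be non-negative", "validation_error")
  if (unit == "dB" && is.null(baseline))
    stop_prestim("dB values require a recorded baseline window",
                 "validation_error")
  if (!is.null(metadata)) stopifnot(nrow(metadata) == dim(power)[1])
  structure(
    list(power = power, freqs = as.numeric(freqs), times = as.numeric(times),
         channels = as.character(channels), unit = unit,
         window_length = window_length, sampling_rate = sampling_rate,
         metadata = metadata, baseline = baseline),
    class = "eeg_tfr"
  )
}

#' @export
print.eeg_tfr <- function(x, ...) {
  cat(sprintf("<eeg_tfr> %d x %d ch x %d freqs (%g-%g Hz) x %d times (%g..%g ms), unit=%s\n",
              dim(x$power)[1], dim(x$power)[2], dim(x$power)[3],
              min(x$freqs), max(x$freqs), dim(x$power)[4],
              min(x$times), max(x$times), x$unit))
  invisible(x)
}

#' Sliding Hanning-taper spectrogram
#'
#' Single-trial power from a fixed-length Hann-tapered sliding-window
#' discrete Fourier transform: for every trial, channel, frequency `f` and
#' window center `t`, power is the squared magnitude of the Hann-tapered
#' Fourier coefficient of the `window_length` segment centered at `t`.  The
#' taper-energy normalization (`2 / sum(h)`) makes a unit-amplitude sinusoid
#' at an on-grid frequency yield power 1 independent of the window length.
#' Centers whose window extends past the epoch are `NA`.
#'
#' @param epochs An [eeg_epochs()].
#' @param freqs Hz frequencies of interest (default 2..120 in 1 Hz steps;
#'   all must lie below Nyquist).
#' @param toi ms window centers (default -2000..2000 in 50 ms steps).
#' @param window_length Window length in ms (default 500).
#' @return A raw-power [eeg_tfr()], trials x channels x freqs x times.
#' @export
tfr_hanning <- function(epochs, freqs = 2:120,
                        toi = seq(-2000, 2000, by = 50),
                        window_length = 500) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  sfreq <- epochs$sampling_rate
  if (max(freqs) >= sfreq / 2)
    stop_prestim("frequencies of interest must be below Nyquist",
                 "invalid_parameter")
  nsamp <- dim(epochs$data)[3]
  n_win <- round(window_length * sfreq / 1000)
  if (n_win > nsamp)
    stop_prestim("analysis window exceeds the epoch span", "invalid_parameter")
  if (n_win < 2)
    stop_prestim("analysis window too short", "invalid_parameter")

  # periodic Hann: its transform has exact nulls on the DFT grid, so an
  # on-grid unit sinusoid yields power exactly 1 regardless of window length
  taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, n_win - 1) / n_win)
  norm <- 2 / sum(taper)
  tk <- (seq_len(n_win) - 1) / sfreq
  # complex carrier matrix: window sample x frequency
  carrier <- exp(-2i * pi * outer(tk, freqs)) * taper * norm

  n_tr <- dim(epochs$data)[1]
  nch <- dim(epochs$data)[2]
  flat <- matrix(epochs$data, nrow = n_tr * nch, ncol = nsamp)

  half_lo <- n_win %/% 2L
  centers_idx <- round((toi - epochs$times[1]) * sfreq / 1000) + 1
  out <- array(NA_real_, dim = c(n_tr, nch, length(freqs), length(toi)))
  for (ti in seq_along(toi)) {
    start <- centers_idx[ti] - half_lo
    end <- start + n_win - 1L
    if (start < 1 || end > nsamp) next     # undefined at the epoch edge
    seg <- flat[, start:end, drop = FALSE]
    p <- Mod(seg %*% carrier)^2
    out[, , , ti] <- array(p, dim = c(n_tr, nch, length(freqs)))
  }
  eeg_tfr(out, freqs = freqs, times = toi, channels = epochs$channels,
          unit = "raw", window_length = window_length, sampling_rate = sfreq,
          metadata = epochs$metadata)
}

#' Decibel baseline correction
#'
#' Converts raw power to decibels relative to the mean power over the
#' baseline window, separately per trial (or per average), channel and
#' frequency: `10 * log10(power / baseline_mean)`.
#'
#' @param tfr A raw-power [eeg_tfr()].
#' @param baseline ms pair, fully defined in `tfr` (default -1500..-500).
#' @return A dB-unit `eeg_tfr` with the baseline window recorded.
#' @export
tfr_db_baseline <- function(tfr, baseline = c(-1500, -500)) {
  stopifnot(inherits(tfr, "eeg_tfr"))
  if (tfr$unit != "raw")
    stop_prestim("baseline correction expects raw power", "wrong_unit")
  bl_idx <- which(in_window(tfr$times, baseline))
  if (!length(bl_idx))
    stop_prestim("no window centers inside the baseline window",
                 "invalid_parameter")
  bl <- tfr$power[, , , bl_idx, drop = FALSE]
  if (anyNA(bl))
    stop_prestim("baseline window must be fully defined", "invalid_parameter")
  bl_mean <- apply(bl, c(1, 2, 3), mean)
  if (any(bl_mean == 0))
    stop_prestim("zero mean baseline power (degenerate baseline)",
                 "degenerate_baseline")
  db <- 10 * log10(sweep(tfr$power, c(1, 2, 3), bl_mean, `/`))
  eeg_tfr(db, freqs = tfr$freqs, times = tfr$times, channels = tfr$channels,
          unit = "dB", window_length = tfr$window_length,
          sampling_rate = tfr$sampling_rate, metadata = tfr$metadata,
          baseline = baseline)
}

#' Average a trial-level TFR within rating conditions
#'
#' @param tfr A trial-level [eeg_tfr()].
#' @param selections Named list of `trial_selection`s (or index vectors),
#'   typically from [equalize_trials()].
#' @return Named list of single-"trial" `eeg_tfr`s (the first dimension
#'   collapsed to the condition mean), each carrying `n_trials` used.
#' @export
tfr_condition_average <- function(tfr, selections) {
  stopifnot(inherits(tfr, "eeg_tfr"))
  lapply(selections, function(sel) {
    idx <- if (inherits(sel, "trial_selection")) sel$indices else as.integer(sel)
    if (!length(idx)) stop_prestim("empty trial selection", "empty_class")
    avg <- apply(tfr$power[idx, , , , drop = FALSE], c(2, 3, 4), mean)
    out <- eeg_tfr(array(avg, dim = c(1, dim(avg))), freqs = tfr$freqs,
                   times = tfr$times, channels = tfr$channels, unit = tfr$unit,
                   window_length = tfr$window_length,
                   sampling_rate = tfr$sampling_rate, baseline = tfr$baseline)
    out$n_trials <- length(idx)
    out
  })
}

#' Average a TFR over a time window (decoding feature construction)
#'
#' Means over window centers whose time lies in the closed `window`, with the
#' frequency axis restricted to `2..fmax` Hz.  Applied to raw power (no
#' baseline correction) when building decoding features.
#'
#' @param tfr An [eeg_tfr()].
#' @param window ms pair (default the pre-stimulus feature window
#'   -1000..-200).
#' @param fmax Upper frequency bound in Hz (default 60).
#' @return List: `power` (trials x channels x frequencies array), `freqs`,
#'   `channels`, `n_times` averaged, `metadata`.
#' @export
tfr_time_average <- function(tfr, window = c(-1000, -200), fmax = 60) {
  stopifnot(inherits(tfr, "eeg_tfr"))
  t_idx <- which(in_window(tfr$times, window))
  f_idx <- which(tfr$freqs >= 2 & tfr$freqs <= fmax)
  if (!length(t_idx))
    stop_prestim("no window centers inside the averaging window",
                 "invalid_window")
  block <- tfr$power[, , f_idx, t_idx, drop = FALSE]
  if (anyNA(block))
    stop_prestim("averaging window contains undefined bins", "invalid_window")
  list(power = apply(block, c(1, 2, 3), mean),
       freqs = tfr$freqs[f_idx], channels = tfr$channels,
       n_times = length(t_idx), metadata = tfr$metadata, unit = tfr$unit)
}
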