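#' Epoch-level EEG container
#'
#' Holds a trials x channels x samples voltage array (microvolts) cut around
#' face onset (time 0 ms; the stimulus is on screen 0-200 ms), together with
#' a regular ms time axis, channel labels and per-trial metadata (`rating`,
#' `previous_rating`, `subject`, `experiment`).
#'
#' @param data Numeric array, trials x channels x samples, finite values.
#' @param times Numeric ms axis, regular spacing `1000 / sampling_rate`.
#' @param sampling_rate Sampling rate in Hz.
#' @param channels Unique channel labels, one per data row.
#' @param metadata Data frame with one row per trial; a `rating` column is
#'   coerced to the standard four rating levels.
#' @param montage Optional [eeg_montage()] carried along for clustering.
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, times, sampling_rate, channels,
                       metadata = NULL, montage = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (!all(is.finite(data)))
    stop_prestim("epoch data must contain only finite values", "validation_error")
  if (anyDuplicated(channels))
    stop_prestim("channel labels must be unique", "validation_error")
  stopifnot(dim(data)[2] == length(channels), dim(data)[3] == length(times))
  dt <- diff(times)
  if (max(abs(dt - 1000 / sampling_rate)) > 1e-6)
    stop_prestim("times must be regular at 1/sampling_rate spacing",
                 "validation_error")
  if (is.null(metadata)) {
    metadata <- data.frame(rating = factor(rep(NA_character_, dim(data)[1]),
                                           levels = rating_levels()))
  }
  stopifnot(is.data.frame(metadata), nrow(metadata) == dim(data)[1])
  if (!is.null(metadata$rating))
    metadata$rating <- factor(as.character(metadata$rating),
                              levels = rating_levels())
  if (!is.null(metadata$previous_rating))
    metadata$previous_rating <- factor(as.character(metadata$previous_rating),
                                       levels = rating_levels())
  structure(
    list(data = data, times = as.numeric(times),
         sampling_rate = sampling_rate, channels = as.character(channels),
         metadata = metadata, montage = montage),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples (%g Hz, %g..%g ms)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$sampling_rate, min(x$times), max(x$times)))
  if (!is.null(x$metadata$rating)) {
    tab <- table(x$metadata$rating)
    cat("  ratings:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
dim.eeg_epochs <- function(x) dim(x$data)

#' Number of trials in an epoch set
#' @param epochs An `eeg_epochs`.
#' @return Integer trial count.
#' @export
n_trials <- function(epochs) dim(epochs$data)[1]

# ---- internal container I/O --------------------------------------------

SCHEMA_VERSION <- 1L

#' Write / read the internal epoch container
#'
#' The container is a raw little-endian float64 array (`<path>.dat`) plus a
#' JSON sidecar (`<path>.json`) carrying axes, labels, metadata and schema
#' version: a lossless, language-neutral round trip (bit-identical data).
#'
#' @param epochs An [eeg_epochs()].
#' @param path Path prefix (without extension).
#' @return `write_epochs` returns `path` invisibly; `read_epochs` returns the
#'   reconstructed `eeg_epochs`.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  sidecar <- list(
    schema = "prestim-epochs", schema_version = SCHEMA_VERSION,
    dim = dim(epochs$data), times = epochs$times,
    sampling_rate = epochs$sampling_rate, channels = epochs$channels,
    metadata = epochs$metadata
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(epochs$data), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(side$schema, "prestim-epochs") ||
      side$schema_version > SCHEMA_VERSION)
    stop_prestim("unknown epoch container schema", "format_error")
  n <- prod(side$dim)
  con <- file(paste0(path, ".dat"), "rb")
  on.exit(close(con))
  data <- array(readBin(con, "double", n = n, size = 8L, endian = "little"),
                dim = side$dim)
  md <- as.data.frame(side$metadata)
  eeg_epochs(data, side$times, side$sampling_rate, side$channels, md)
}

# ---- raw-recording import ----------------------------------------------

#' Read a BrainVision recording
#'
#' Minimal importer for the BrainVision triplet: INI-style `.vhdr` header,
#' binary multiplexed `.eeg` data (IEEE float32 or int16 with per-channel
#' resolution) and, if present, `.vmrk` markers.
#'
#' @param vhdr Path to the `.vhdr` header file.
#' @return List of class `eeg_raw`: `data` (channels x samples, microvolts),
#'   `sampling_rate`, `channels`, `events` (data frame of marker sample
#'   indices and descriptions, possibly empty).
#' @export
read_brainvision <- function(vhdr) {
  lines <- readLines(vhdr, warn = FALSE)
  get_field <- function(key) {
    hit <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (!length(hit)) stop_prestim(paste0("missing header field ", key),
                                   "format_error")
    sub(paste0("^", key, "="), "", hit[1])
  }
  if (toupper(get_field("DataFormat")) != "BINARY" ||
      toupper(get_field("DataOrientation")) != "MULTIPLEXED")
    stop_prestim("only binary multiplexed BrainVision data are supported",
                 "format_error")
  nch <- as.integer(get_field("NumberOfChannels"))
  sfreq <- 1e6 / as.numeric(get_field("SamplingInterval"))
  fmt <- toupper(get_field("BinaryFormat"))

  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  ch_info <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",")
  labels <- vapply(ch_info, `[[`, "", 1L)
  resolution <- vapply(ch_info, function(f) {
    r <- if (length(f) >= 3) suppressWarnings(as.numeric(f[[3]])) else NA_real_
    if (is.na(r)) 1 else r
  }, 0)
  if (length(labels) != nch)
    stop_prestim("channel info does not match NumberOfChannels",
                 "validation_error")

  dat_path <- file.path(dirname(vhdr), get_field("DataFile"))
  sz <- file.size(dat_path)
  con <- file(dat_path, "rb")
  on.exit(close(con))
  if (fmt == "IEEE_FLOAT_32") {
    raw_vals <- readBin(con, "double", n = sz / 4, size = 4L, endian = "little")
  } else if (fmt == "INT_16") {
    raw_vals <- readBin(con, "integer", n = sz / 2, size = 2L,
                        signed = TRUE, endian = "little")
  } else {
    stop_prestim(paste0("unsupported BinaryFormat ", fmt), "format_error")
  }
  nsamp <- length(raw_vals) %/% nch
  data <- matrix(raw_vals[seq_len(nsamp * nch)], nrow = nch) * resolution

  events <- data.frame(sample = integer(0), code = character(0))
  vmrk <- file.path(dirname(vhdr), sub("\\.vhdr$", ".vmrk", basename(vhdr)))
  mk_hit <- grep("^MarkerFile=", lines, value = TRUE)
  if (length(mk_hit)) vmrk <- file.path(dirname(vhdr), sub("^MarkerFile=", "", mk_hit[1]))
  if (file.exists(vmrk)) {
    mk <- grep("^Mk[0-9]+=", readLines(vmrk, warn = FALSE), value = TRUE)
    if (length(mk)) {
      parts <- strsplit(sub("^Mk[0-9]+=", "", mk), ",")
      events <- data.frame(
        sample = vapply(parts, function(p) as.integer(p[[3]]), 0L),
        code = vapply(parts, function(p) trimws(p[[2]]), "")
      )
    }
  }
  structure(list(data = data, sampling_rate = sfreq, channels = labels,
                 events = events), class = "eeg_raw")
}

#' Read an EDF/EDF+ recording
#'
#' Parses the fixed-width EDF header and 16-bit data records, rescaling
#' digital values to physical units per channel.  All channels must share
#' one sampling rate (the only layout the downstream pipeline consumes).
#'
#' @param path Path to the `.edf` file.
#' @return An `eeg_raw` list (see [read_brainvision()]); EDF carries no
#'   marker track here, so `events` is empty.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  version <- rd(8)
  if (!identical(version, "0"))
    stop_prestim("not an EDF file (bad version field)", "format_error")
  rd(80); rd(80); rd(8); rd(8); rd(8)          # patient, recording, date, time, header bytes
  rd(44)                                       # reserved
  n_records <- as.integer(rd(8))
  record_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)                # transducer
  for (i in seq_len(ns)) rd(8)                 # physical dimension
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)                # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)                # reserved
  if (length(unique(spr)) != 1L)
    stop_prestim("EDF signals with mixed sampling rates are not supported",
                 "format_error")
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- matrix(0, nrow = ns, ncol = n_records * spr[1])
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[s], size = 2L, signed = TRUE,
                   endian = "little")
      data[s, (r - 1) * spr[s] + seq_len(spr[s])] <-
        (d - dig_min[s]) * gain[s] + phys_min[s]
    }
  }
  structure(list(data = data, sampling_rate = spr[1] / record_dur,
                 channels = labels,
                 events = data.frame(sample = integer(0), code = character(0))),
            class = "eeg_raw")
}

#' Cut epochs around events in a continuous recording
#'
#' @param raw An `eeg_raw` (from [read_brainvision()] or [read_edf()]).
#' @param events Data frame with a `sample` column (1-based onset sample of
#'   each face stimulus); defaults to the recording's own marker track.
#'   Extra columns are carried into the metadata.
#' @param window ms pair cut around each onset (default `c(-2000, 2000)`,
#'   closed interval).
#' @param montage Optional montage attached to the result.
#' @return An [eeg_epochs()] with one trial per event.
#' @export
epoch_raw <- function(raw, events = raw$events, window = c(-2000, 2000),
                      montage = NULL) {
  stopifnot(inherits(raw, "eeg_raw"), nrow(events) >= 1)
  sfreq <- raw$sampling_rate
  pre <- round(window[1] * sfreq / 1000)
  post <- round(window[2] * sfreq / 1000)
  nsamp_total <- ncol(raw$data)
  nsel <- post - pre + 1
  data <- array(0, dim = c(nrow(events), nrow(raw$data), nsel))
  for (i in seq_len(nrow(events))) {
    s0 <- events$sample[i]
    lo <- s0 + pre
    hi <- s0 + post
    if (lo < 1 || hi > nsamp_total)
      stop_prestim(sprintf(
        "event %d (sample %d) extends past the recording edge", i, s0),
        "validation_error")
    data[i, , ] <- raw$data[, lo:hi]
  }
  md <- events
  md$sample <- NULL
  if (!ncol(md)) md <- NULL
  eeg_epochs(data, times = seq(pre, post) * 1000 / sfreq,
             sampling_rate = sfreq, channels = raw$channels,
             metadata = md, montage = montage)
}

# ---- preprocessing ------------------------------------------------------

#' Common average reference
#'
#' Re-expresses every channel relative to the instantaneous mean over all
#' channels, per trial and sample.  Idempotent; pairwise channel differences
#' are unchanged.
#'
#' @param epochs An [eeg_epochs()] with at least two channels.
#' @return The re-referenced `eeg_epochs`.
#' @export
common_average_reference <- function(epochs) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (dim(epochs$data)[2] < 2L)
    stop_prestim("common average reference needs at least 2 channels",
                 "invalid_input")
  mean_sig <- apply(epochs$data, c(1, 3), mean)   # trials x samples
  epochs$data <- epochs$data -
    aperm(array(mean_sig, dim = dim(epochs$data)[c(1, 3, 2)]), c(1, 3, 2))
  epochs
}

#' Select trials by rating
#'
#' @param epochs An [eeg_epochs()] with a `rating` metadata column.
#' @param keep Character set of ratings to keep (default the two valences).
#' @return A `trial_selection`: sorted unique trial indices plus provenance.
#' @export
select_rated <- function(epochs, keep = c("negative", "positive")) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  keep <- match.arg(keep, rating_levels(), several.ok = TRUE)
  idx <- which(as.character(epochs$metadata$rating) %in% keep)
  trial_selection(idx, note = paste0("rating in {", paste(keep, collapse = ","), "}"))
}

trial_selection <- function(indices, note = "", seed = NULL) {
  indices <- sort(unique(as.integer(indices)))
  structure(list(indices = indices, note = note, seed = seed),
            class = "trial_selection")
}

#' Equalize trial counts between two rating classes
#'
#' Both classes are brought to the size of the smaller one: the larger class
#' is subsampled uniformly without replacement under `seed`, the smaller is
#' kept whole.  This is the trial-count equalization applied before every
#' between-valence contrast and before decoding.
#'
#' @param labels Factor/character vector of per-trial ratings.
#' @param classes The two classes to equalize (default negative/positive).
#' @param seed Seed for the subsampling draw.
#' @return Named list of `trial_selection`s, one per class, equal sizes.
#' @export
equalize_trials <- function(labels, classes = c("negative", "positive"),
                            seed = NULL) {
  stopifnot(length(classes) == 2L)
  labels <- as.character(labels)
  idx <- lapply(classes, function(cl) which(labels == cl))
  names(idx) <- classes
  n <- vapply(idx, length, 0L)
  if (any(n == 0L))
    stop_prestim(paste0("class with zero trials: ",
                        paste(classes[n == 0L], collapse = ", ")),
                 "empty_class")
  n_keep <- min(n)
  out <- maybe_with_seed(seed, {
    lapply(idx, function(i) {
      if (length(i) > n_keep) sort(sample(i, n_keep)) else i
    })
  })
  lapply(out, trial_selection,
         note = sprintf("equalized to %d trials", n_keep), seed = seed)
}

#' Minimum-trial inclusion rule
#'
#' A subject enters the group analysis only if every rating class retains at
#' least `minimum` trials after equalization (default 10).
#'
#' @param counts Named or unnamed vector of per-class trial counts.
#' @param minimum Minimum per-class count (default 10).
#' @return `TRUE` if the subject is included.
#' @export
inclusion_check <- function(counts, minimum = 10) {
  all(counts >= minimum)
}
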