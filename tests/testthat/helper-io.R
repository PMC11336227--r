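# Writers for synthetic raw-EEG files (BrainVision, EDF) used by the import
# tests.  These are fixture generators, independent of the package readers.

write_synthetic_brainvision <- function(dir, data, sfreq, labels,
                                        event_samples,
                                        stem = "synthetic") {
  nch <- nrow(data)
  vhdr <- file.path(dir, paste0(stem, ".vhdr"))
  writeLines(c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", stem, ".eeg"),
    paste0("MarkerFile=", stem, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nch),
    paste0("SamplingInterval=", format(1e6 / sfreq)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    paste0("Ch", seq_len(nch), "=", labels, ",,1,µV")
  ), vhdr)
  con <- file(file.path(dir, paste0(stem, ".eeg")), "wb")
  writeBin(as.vector(data), con, size = 4L, endian = "little")
  close(con)
  writeLines(c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Marker Infos]",
    paste0("Mk", seq_along(event_samples), "=Stimulus,S  1,",
           event_samples, ",1,0")
  ), file.path(dir, paste0(stem, ".vmrk")))
  vhdr
}

write_synthetic_edf <- function(path, data, sfreq, labels,
                                phys_min = -200, phys_max = 200) {
  nch <- nrow(data)
  nsamp <- ncol(data)
  record_dur <- 1
  spr <- as.integer(sfreq * record_dur)
  n_records <- nsamp %/% spr
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeBin(charToRaw(pad(x, w)), con)
  wr("0", 8); wr("synthetic patient", 80); wr("synthetic recording", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(256 * (1 + nch), 8); wr("", 44)
  wr(n_records, 8); wr(record_dur, 8); wr(nch, 4)
  for (l in labels) wr(l, 16)
  for (i in seq_len(nch)) wr("synthetic", 80)
  for (i in seq_len(nch)) wr("uV", 8)
  for (i in seq_len(nch)) wr(phys_min, 8)
  for (i in seq_len(nch)) wr(phys_max, 8)
  for (i in seq_len(nch)) wr(-32768, 8)
  for (i in seq_len(nch)) wr(32767, 8)
  for (i in seq_len(nch)) wr("", 80)
  for (i in seq_len(nch)) wr(spr, 8)
  for (i in seq_len(nch)) wr("", 32)
  gain <- (phys_max - phys_min) / (32767 - -32768)
  for (r in seq_len(n_records)) {
    for (s in seq_len(nch)) {
      seg <- data[s, (r - 1) * spr + seq_len(spr)]
      dig <- as.integer(round((seg - phys_min) / gain + -32768))
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  path
}
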