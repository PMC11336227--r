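# Independent oracles used by unit and acceptance tests.  These deliberately
# share no code with the package implementation.

# Brute-force Hann-tapered windowed DFT (plain accumulation loop).
oracle_power <- function(x, times, sfreq, freq, center, window_length) {
  n_win <- round(window_length * sfreq / 1000)
  c_idx <- round((center - times[1]) * sfreq / 1000) + 1
  start <- c_idx - n_win %/% 2
  if (start < 1 || start + n_win - 1 > length(x)) return(NA_real_)
  seg <- x[start:(start + n_win - 1)]
  h <- 0.5 - 0.5 * cos(2 * pi * (0:(n_win - 1)) / n_win)   # periodic Hann
  re <- 0
  im <- 0
  for (k in seq_len(n_win)) {
    ang <- -2 * pi * freq * (k - 1) / sfreq
    re <- re + seg[k] * h[k] * cos(ang)
    im <- im + seg[k] * h[k] * sin(ang)
  }
  (re^2 + im^2) * (2 / sum(h))^2
}

# Flood-fill connected components over the channel x frequency x time grid,
# same-sign connectivity (recursive frontier growing).
oracle_components <- function(state, adj) {
  dims <- dim(state)
  labels <- array(0L, dims)
  k <- 0L
  for (p in which(state != 0)) {
    if (labels[p] != 0) next
    k <- k + 1L
    frontier <- p
    labels[p] <- k
    while (length(frontier)) {
      q <- frontier[1]
      frontier <- frontier[-1]
      idx <- arrayInd(q, dims)
      ch <- idx[1]; f <- idx[2]; t <- idx[3]
      cand <- list()
      for (nb in which(adj[ch, ])) cand <- c(cand, list(c(nb, f, t)))
      if (f > 1) cand <- c(cand, list(c(ch, f - 1, t)))
      if (f < dims[2]) cand <- c(cand, list(c(ch, f + 1, t)))
      if (t > 1) cand <- c(cand, list(c(ch, f, t - 1)))
      if (t < dims[3]) cand <- c(cand, list(c(ch, f, t + 1)))
      for (cc in cand) {
        lin <- cc[1] + dims[1] * (cc[2] - 1 + dims[2] * (cc[3] - 1))
        if (state[lin] == state[q] && labels[lin] == 0L) {
          labels[lin] <- k
          frontier <- c(frontier, lin)
        }
      }
    }
  }
  labels
}

# Identical component structure up to label renumbering.
same_partition <- function(a, b) {
  av <- as.vector(a)
  bv <- as.vector(b)
  if (!identical(av != 0, bv != 0)) return(FALSE)
  pairs <- unique(cbind(av, bv)[av != 0, , drop = FALSE])
  !anyDuplicated(pairs[, 1]) && !anyDuplicated(pairs[, 2])
}
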