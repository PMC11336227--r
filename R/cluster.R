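#' Pointwise paired t map over channel x frequency x time
#'
#' Per grid point, `t = mean(d) / (sd(d)/sqrt(n))` with `d = a - b` per
#' subject and `df = n - 1`.  Points with zero variance of `d` come back
#' `NaN` (flagged as undefined, never an error).
#'
#' @param a,b Numeric 4-d arrays, subjects x channels x freqs x times, same
#'   shape and subject order.
#' @return A `stat_map`: list with `stat` (channels x freqs x times array),
#'   `kind = "paired_t"`, `df` and `n`.
#' @export
paired_t_map <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)), length(dim(a)) == 4L)
  n <- dim(a)[1]
  if (n < 2) stop_prestim("paired t needs at least 2 subjects", "invalid_input")
  d <- matrix(a - b, nrow = n)
  m <- colMeans(d)
  v <- apply_col_var(d)
  t_vals <- m / sqrt(v / n)
  # identical conditions give t = 0; zero variance around a nonzero mean is
  # undefined (flagged NaN, excluded from clustering), never an error
  t_vals[v == 0 & m == 0] <- 0
  t_vals[v == 0 & m != 0] <- NaN
  structure(list(stat = array(t_vals, dim = dim(a)[-1]), kind = "paired_t",
                 df = n - 1, n = n), class = "stat_map")
}

apply_col_var <- function(m) {
  n <- nrow(m)
  (colSums(m^2) - n * colMeans(m)^2) / (n - 1)
}

#' Pointwise Pearson correlation map with a per-subject covariate
#'
#' Correlates the per-subject power difference at every channel x frequency
#' x time point with a per-subject scalar (e.g. negativity bias in percent).
#'
#' @param diffs Numeric 4-d array, subjects x channels x freqs x times, of
#'   per-subject condition differences.
#' @param covariate Numeric vector, one value per subject, nonconstant.
#' @return A `stat_map` with `kind = "pearson_r"`.
#' @export
correlation_map <- function(diffs, covariate) {
  stopifnot(length(dim(diffs)) == 4L, dim(diffs)[1] == length(covariate))
  n <- length(covariate)
  if (n < 3) stop_prestim("correlation needs at least 3 subjects", "invalid_input")
  if (stats::sd(covariate) == 0)
    stop_prestim("covariate has zero variance", "invalid_covariate")
  d <- matrix(diffs, nrow = n)
  zc <- as.vector(scale(covariate))
  zd <- scale(d)                      # columns with sd 0 become NaN
  r <- as.vector(crossprod(zc, zd) / (n - 1))
  structure(list(stat = array(r, dim = dim(diffs)[-1]), kind = "pearson_r",
                 df = n - 2, n = n), class = "stat_map")
}

#' Cluster-forming threshold
#'
#' Two-sided per-point thresholds at `alpha` per tail.  `"parametric"` uses
#' the Student-t critical value (transformed to the r scale for correlation
#' maps); `"nonparametric_individual"` uses each point's own empirical
#' `alpha` / `1 - alpha` permutation quantiles.
#'
#' @param point_null For the nonparametric mode: matrix of permutation
#'   statistics, permutations x points.
#' @param mode `"parametric"` or `"nonparametric_individual"`.
#' @param alpha Per-tail forming alpha (default 0.025).
#' @param df Degrees of freedom (parametric t mode).
#' @param n Number of subjects (parametric r mode).
#' @param kind `"paired_t"` or `"pearson_r"`.
#' @return List with per-point `lo` and `hi` thresholds and a `degenerate`
#'   logical flag (points whose permutation distribution collapses).
#' @export
forming_threshold <- function(point_null = NULL,
                              mode = c("nonparametric_individual", "parametric"),
                              alpha = 0.025, df = NULL, n = NULL,
                              kind = c("paired_t", "pearson_r")) {
  mode <- match.arg(mode)
  kind <- match.arg(kind)
  if (mode == "parametric") {
    if (kind == "paired_t") {
      stopifnot(!is.null(df))
      hi <- stats::qt(1 - alpha, df)
    } else {
      stopifnot(!is.null(n))
      tc <- stats::qt(1 - alpha, n - 2)
      hi <- tc / sqrt(tc^2 + n - 2)
    }
    return(list(lo = -hi, hi = hi, degenerate = FALSE, mode = mode,
                alpha = alpha))
  }
  stopifnot(is.matrix(point_null))
  n_perm <- nrow(point_null)
  if (n_perm * alpha < 1)
    stop_prestim("too few permutation samples to resolve the forming quantile",
                 "resolution_error")
  qs <- apply(point_null, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE, type = 7, na.rm = TRUE)
  lo <- qs[1L, ]
  hi <- qs[2L, ]
  degen <- !is.finite(lo) | !is.finite(hi) | lo == hi
  list(lo = lo, hi = hi, degenerate = degen, mode = mode, alpha = alpha)
}

# 0-based channel neighbour list from a montage or adjacency matrix,
# matched to the data's channel order.
adjacency_list <- function(adjacency, channels) {
  adj <- if (inherits(adjacency, "eeg_montage")) adjacency$adjacency else adjacency
  stopifnot(is.matrix(adj))
  missing <- setdiff(channels, rownames(adj))
  if (length(missing))
    stop_prestim(paste0("channels missing from adjacency: ",
                        paste(missing, collapse = ", ")), "unknown_channel")
  adj <- adj[channels, channels, drop = FALSE]
  if (!isSymmetric(unname(adj)) || any(diag(adj)))
    stop_prestim("adjacency must be symmetric and irreflexive",
                 "validation_error")
  lapply(seq_along(channels), function(i) which(adj[i, ]) - 1L)
}

#' Connected suprathreshold clusters over channel x frequency x time
#'
#' Components of the signed suprathreshold mask under the combined
#' neighbourhood: neighbouring channels at the same frequency/time bin,
#' adjacent frequency bins at the same channel/time, and adjacent time bins
#' at the same channel/frequency - with the constraint that member points
#' share the same sign.
#'
#' @param mask Integer/numeric 3-d array (channels x freqs x times) of
#'   -1 / 0 / +1 states.
#' @param adjacency An [eeg_montage()] or a named logical adjacency matrix
#'   covering the channel dimension.
#' @param channels Channel labels for the first array dimension (defaults to
#'   the adjacency's own labels in order).
#' @param stat Optional array of point statistics (same shape) used for the
#'   cluster masses; defaults to the mask itself (mass = signed extent).
#' @return List: `labels` (3-d integer array, 0 = unclustered) and
#'   `clusters` (data frame of id, sign, size, mass).
#' @export
find_clusters <- function(mask, adjacency, channels = NULL, stat = NULL) {
  stopifnot(length(dim(mask)) == 3L)
  if (is.null(channels)) {
    channels <- if (inherits(adjacency, "eeg_montage")) adjacency$labels
                else rownames(adjacency)
  }
  stopifnot(length(channels) == dim(mask)[1])
  if (is.null(stat)) stat <- mask
  adj_list <- adjacency_list(adjacency, channels)
  state <- as.integer(sign(mask))
  state[is.na(state)] <- 0L
  labels <- label_clusters_cpp(state, adj_list,
                               dim(mask)[1], dim(mask)[2], dim(mask)[3])
  k <- attr(labels, "n_clusters")
  clusters <- if (k > 0) {
    mass <- vapply(seq_len(k), function(c) sum(stat[labels == c]), 0)
    size <- tabulate(labels, nbins = k)
    sgn <- vapply(seq_len(k), function(c) state[which(labels == c)[1]], 0L)
    data.frame(id = seq_len(k), sign = sgn, size = size, mass = mass)
  } else {
    data.frame(id = integer(0), sign = integer(0), size = integer(0),
               mass = numeric(0))
  }
  list(labels = array(as.integer(labels), dim = dim(mask)), clusters = clusters)
}

#' Cluster-based permutation test (Monte Carlo)
#'
#' Nonparametric multiple-comparison correction over channel x frequency x
#' time.  For the paired design the null is generated by random within-
#' subject condition swaps (sign flips of the per-subject differences); for
#' the covariate design by random re-pairing of the covariate with the
#' subjects.  Per permutation the maximal positive cluster mass and maximal
#' absolute negative cluster mass are recorded; each observed cluster's
#' Monte Carlo p is `(1 + #(null >= observed)) / (n_perm + 1)`, assessed per
#' tail at `alpha`.
#'
#' Undefined points (epoch-edge `NA`s, zero-variance points, degenerate
#' permutation distributions) are excluded from clustering entirely.
#'
#' @param x Subjects x channels x freqs x times array: condition A maps
#'   (paired design) or per-subject difference maps (covariate design).
#' @param y Condition B maps for the paired design; `NULL` for covariate.
#' @param covariate Per-subject scalar for the covariate design.
#' @param adjacency An [eeg_montage()] or adjacency matrix.
#' @param channels,freqs,times Axis labels (channels defaults to the
#'   adjacency labels).
#' @param n_perm Number of random permutations (default 2000).
#' @param alpha Per-tail cluster alpha (default 0.025); `n_perm` must be at
#'   least `1/alpha`.
#' @param forming Cluster-forming threshold mode (default
#'   `"nonparametric_individual"`); the forming alpha equals `alpha`.
#' @param seed Seed for the permutation draws.
#' @return An object of class `cluster_result`: `clusters` data frame (id,
#'   sign, size, mass, p, significant), `labels` array, the observed
#'   `stat_map`, thresholds, per-permutation null max masses, and the
#'   configuration (n_perm, alpha, forming, seed).
#' @export
cluster_permutation <- function(x, y = NULL, covariate = NULL, adjacency,
                                channels = NULL, freqs = NULL, times = NULL,
                                n_perm = 2000, alpha = 0.025,
                                forming = c("nonparametric_individual",
                                            "parametric"),
                                seed = NULL) {
  forming <- match.arg(forming)
  stopifnot(length(dim(x)) == 4L)
  if (n_perm < 1 / alpha)
    stop_prestim("n_perm is too small for the requested alpha",
                 "underpowered_permutation")
  design <- if (!is.null(covariate)) "covariate" else "paired"
  n <- dim(x)[1]
  dims <- dim(x)[-1]
  P <- prod(dims)
  if (is.null(channels)) {
    channels <- if (inherits(adjacency, "eeg_montage")) adjacency$labels
                else rownames(adjacency)
  }
  adj_list <- adjacency_list(adjacency, channels)

  if (design == "paired") {
    stopifnot(identical(dim(x), dim(y)))
    obs_map <- paired_t_map(x, y)
    d <- matrix(x - y, nrow = n)
  } else {
    obs_map <- correlation_map(x, covariate)
    d <- matrix(x, nrow = n)
  }
  obs <- as.vector(obs_map$stat)
  usable <- apply(is.finite(d), 2L, all) & is.finite(obs)

  perm_stats <- maybe_with_seed(seed, {
    if (design == "paired") {
      signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                      nrow = n_perm)
      perm_t_stats(signs, d)
    } else {
      zc <- as.vector(scale(covariate))
      zperm <- t(vapply(seq_len(n_perm), function(i) zc[sample.int(n)],
                        numeric(n)))
      zd <- scale(d)
      zperm %*% zd / (n - 1)
    }
  })

  thr <- if (forming == "parametric") {
    ft <- forming_threshold(mode = "parametric", alpha = alpha,
                            df = obs_map$df, n = n, kind = obs_map$kind)
    list(lo = rep(ft$lo, P), hi = rep(ft$hi, P),
         degenerate = rep(FALSE, P), mode = ft$mode, alpha = alpha)
  } else {
    forming_threshold(perm_stats, mode = "nonparametric_individual",
                      alpha = alpha, kind = obs_map$kind)
  }
  usable <- usable & !thr$degenerate

  state <- integer(P)
  state[usable & obs > thr$hi] <- 1L
  state[usable & obs < thr$lo] <- -1L
  labels <- label_clusters_cpp(state, adj_list, dims[1], dims[2], dims[3])
  k <- attr(labels, "n_clusters")

  null_max <- perm_max_mass_cpp(perm_stats, thr$lo, thr$hi,
                                as.integer(usable), adj_list,
                                dims[1], dims[2], dims[3])

  clusters <- if (k > 0) {
    mass <- vapply(seq_len(k), function(c) sum(obs[labels == c]), 0)
    size <- tabulate(labels, nbins = k)
    sgn <- vapply(seq_len(k), function(c) state[which(labels == c)[1]], 0L)
    p <- vapply(seq_len(k), function(c) {
      if (sgn[c] > 0) (1 + sum(null_max[, 1] >= mass[c])) / (n_perm + 1)
      else (1 + sum(null_max[, 2] >= -mass[c])) / (n_perm + 1)
    }, 0)
    df <- data.frame(id = seq_len(k), sign = sgn, size = size, mass = mass,
                     p = p)
    df$significant <- df$p <= alpha
    df[order(df$p, -abs(df$mass)), ]
  } else {
    data.frame(id = integer(0), sign = integer(0), size = integer(0),
               mass = numeric(0), p = numeric(0), significant = logical(0))
  }

  structure(
    list(clusters = clusters,
         labels = array(as.integer(labels), dim = dims),
         stat_map = obs_map, thresholds = thr, null_max = null_max,
         design = design, n_perm = n_perm, alpha = alpha, forming = forming,
         seed = seed, channels = channels, freqs = freqs, times = times),
    class = "cluster_result"
  )
}

# t statistics for sign-flip permutations: signs is n_perm x n, d is n x P.
# Sign flips leave each d_i^2 unchanged, so only the mean varies.
perm_t_stats <- function(signs, d) {
  n <- ncol(signs)
  m <- signs %*% d / n
  ss <- colSums(d^2)
  v <- sweep(-n * m^2, 2L, ss, `+`) / (n - 1)
  v[v < 0] <- 0
  m / sqrt(v / n)
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %s design, %d permutations, alpha=%g (%s forming)\n",
              x$design, x$n_perm, x$alpha, x$forming))
  if (nrow(x$clusters)) {
    sig <- x$clusters[x$clusters$significant, , drop = FALSE]
    cat(sprintf("  %d cluster(s), %d significant; smallest p = %g\n",
                nrow(x$clusters), nrow(sig), min(x$clusters$p)))
  } else {
    cat("  no suprathreshold clusters\n")
  }
  invisible(x)
}

#' Minimum attainable Monte Carlo p-value
#' @param n_perm Number of permutations.
#' @return `1 / (n_perm + 1)`.
#' @export
min_cluster_p <- function(n_perm) 1 / (n_perm + 1)
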