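#' Scalp montage with neighbourhood structure
#'
#' A montage couples 10-20/10-10 channel labels with schematic 2-D scalp
#' positions and a symmetric, irreflexive channel adjacency graph.  The
#' adjacency is what defines "neighbouring channels" for cluster formation
#' over channel x frequency x time grids.
#'
#' Positions are a template layout (top view, nose up, unit head radius),
#' not digitized electrode coordinates: rows of the extended 10-20 grid map
#' to anterior-posterior coordinates and lateral indices to left-right
#' coordinates, shrunk towards the midline near the front and back of the
#' head.  This is sufficient for a realistic neighbour graph; it is not a
#' co-registration product.
#'
#' @param labels Character vector of channel labels.
#' @param positions Two-column numeric matrix (x = left-right, y =
#'   posterior-anterior) with one row per channel.
#' @param neighbour_dist Distance threshold under which two channels are
#'   neighbours.  `NULL` (default) calibrates the threshold so the median
#'   neighbour count is approximately 6 while every channel keeps at least
#'   one neighbour.
#' @return An object of class `eeg_montage`: list with `labels`, `positions`,
#'   `adjacency` (logical matrix) and `neighbours` (list of label vectors).
#' @export
eeg_montage <- function(labels, positions, neighbour_dist = NULL) {
  stopifnot(is.character(labels), !anyDuplicated(labels))
  positions <- as.matrix(positions)
  stopifnot(nrow(positions) == length(labels), ncol(positions) == 2)
  if (length(labels) < 2L)
    stop_prestim("a montage needs at least 2 channels", "invalid_parameter")

  d <- as.matrix(stats::dist(positions))
  if (is.null(neighbour_dist)) neighbour_dist <- calibrate_neighbour_dist(d)
  adj <- d <= neighbour_dist
  diag(adj) <- FALSE
  dimnames(adj) <- list(labels, labels)

  if (any(rowSums(adj) == 0))
    stop_prestim("montage has isolated channels at this neighbour distance",
                 "invalid_parameter")

  structure(
    list(
      labels = labels,
      positions = structure(positions, dimnames = list(labels, c("x", "y"))),
      adjacency = adj,
      neighbours = apply(adj, 1L, function(r) labels[r], simplify = FALSE),
      neighbour_dist = neighbour_dist
    ),
    class = "eeg_montage"
  )
}

# Smallest pairwise-distance cut-off giving median degree >= 6 (target of
# roughly 6 neighbours per channel) and no isolated channel.
calibrate_neighbour_dist <- function(d) {
  cand <- sort(unique(d[upper.tri(d)]))
  for (th in cand) {
    adj <- d <= th
    diag(adj) <- FALSE
    deg <- rowSums(adj)
    if (min(deg) >= 1 && stats::median(deg) >= 6) return(th)
  }
  cand[length(cand)]
}

#' Default 60-channel scalp montage
#'
#' The default layout mirrors a 64-electrode 10-20 cap after removal of the
#' online reference, the ground and mastoid-adjacent electrodes, leaving 60
#' scalp channels (the channel count entering all group analyses).
#'
#' @inheritParams eeg_montage
#' @return An `eeg_montage` with 60 channels.
#' @export
default_montage <- function(neighbour_dist = NULL) {
  rows <- list(
    Fp = list(y = 0.90, ch = c(Fp1 = -0.30, Fp2 = 0.30)),
    AF = list(y = 0.70, ch = c(AF7 = -0.80, AF3 = -0.35, AF4 = 0.35, AF8 = 0.80)),
    F  = list(y = 0.48, ch = c(F7 = -0.90, F5 = -0.70, F3 = -0.48, F1 = -0.24,
                               Fz = 0, F2 = 0.24, F4 = 0.48, F6 = 0.70, F8 = 0.90)),
    FC = list(y = 0.24, ch = c(FT7 = -0.92, FC5 = -0.70, FC3 = -0.47, FC1 = -0.23,
                               FC2 = 0.23, FC4 = 0.47, FC6 = 0.70, FT8 = 0.92)),
    C  = list(y = 0.00, ch = c(T7 = -0.95, C5 = -0.71, C3 = -0.48, C1 = -0.24,
                               Cz = 0, C2 = 0.24, C4 = 0.48, C6 = 0.71, T8 = 0.95)),
    CP = list(y = -0.24, ch = c(TP7 = -0.92, CP5 = -0.70, CP3 = -0.47, CP1 = -0.23,
                                CPz = 0, CP2 = 0.23, CP4 = 0.47, CP6 = 0.70, TP8 = 0.92)),
    P  = list(y = -0.48, ch = c(P7 = -0.90, P5 = -0.70, P3 = -0.48, P1 = -0.24,
                                Pz = 0, P2 = 0.24, P4 = 0.48, P6 = 0.70, P8 = 0.90)),
    PO = list(y = -0.70, ch = c(PO9 = -0.95, PO7 = -0.75, PO3 = -0.35, POz = 0,
                                PO4 = 0.35, PO8 = 0.75, PO10 = 0.95)),
    O  = list(y = -0.90, ch = c(O1 = -0.30, Oz = 0, O2 = 0.30))
  )
  labels <- unlist(lapply(rows, function(r) names(r$ch)), use.names = FALSE)
  y <- unlist(lapply(rows, function(r) rep(r$y, length(r$ch))), use.names = FALSE)
  lat <- unlist(lapply(rows, function(r) unname(r$ch)), use.names = FALSE)
  # shrink rows towards the midline near the poles to keep the head round
  x <- lat * sqrt(pmax(1 - 0.55 * y^2, 0.2))
  eeg_montage(labels, cbind(x, y), neighbour_dist = neighbour_dist)
}

#' Restrict a montage to a channel subset
#'
#' The adjacency graph is recomputed on the subset (recalibrating the
#' neighbour distance for the sparser layout), so reduced montages used in
#' simulations keep a sensible neighbourhood structure.
#'
#' @param montage An `eeg_montage`.
#' @param channels Labels to keep (order preserved as given).
#' @param neighbour_dist Optional fixed threshold; default recalibrates.
#' @return An `eeg_montage` over `channels`.
#' @export
montage_subset <- function(montage, channels, neighbour_dist = NULL) {
  stopifnot(inherits(montage, "eeg_montage"))
  missing <- setdiff(channels, montage$labels)
  if (length(missing))
    stop_prestim(paste0("unknown channels: ", paste(missing, collapse = ", ")),
                 "unknown_channel")
  idx <- match(channels, montage$labels)
  eeg_montage(channels, montage$positions[idx, , drop = FALSE],
              neighbour_dist = neighbour_dist)
}

#' @export
print.eeg_montage <- function(x, ...) {
  deg <- rowSums(x$adjacency)
  cat(sprintf("<eeg_montage> %d channels, median %d neighbours (range %d-%d)\n",
              length(x$labels), as.integer(stats::median(deg)),
              min(deg), max(deg)))
  invisible(x)
}
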