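#' Negativity bias in percent
#'
#' Percentage of negative ratings among all logged ratings.  A neutral
#' response is a logged rating and counts in the denominator; missed trials
#' are excluded (no response was logged).
#'
#' @param counts Named numeric vector or list with `negative`, `positive`,
#'   `neutral` entries (a `missed` entry is ignored).
#' @return Bias in percent, `100 * negative / (negative + positive + neutral)`.
#' @export
negativity_bias <- function(counts) {
  counts <- as.list(counts)
  neg <- counts$negative %||% 0
  total <- neg + (counts$positive %||% 0) + (counts$neutral %||% 0)
  if (total < 1)
    stop_prestim("no logged ratings; negativity bias undefined",
                 "undefined_bias")
  100 * neg / total
}

#' Paired comparison of negativity bias between experiments
#'
#' @param bias1,bias2 Per-subject bias percentages over the same subjects in
#'   the same order (subjects with both experiments usable).
#' @return List `t`, `df`, `p` (two-sided paired t); `t` is `NA` (flagged)
#'   when the differences have zero variance.
#' @export
compare_bias <- function(bias1, bias2) {
  stopifnot(length(bias1) == length(bias2))
  n <- length(bias1)
  if (n < 2) stop_prestim("paired comparison needs >= 2 shared subjects",
                          "pairing_error")
  d <- bias1 - bias2
  s <- stats::sd(d)
  if (s == 0) {
    if (all(d == 0)) return(list(t = 0, df = n - 1, p = 1))
    warning("zero variance of bias differences; t undefined")
    return(list(t = NA_real_, df = n - 1, p = NA_real_))
  }
  t_val <- mean(d) / (s / sqrt(n))
  list(t = t_val, df = n - 1, p = 2 * stats::pt(-abs(t_val), n - 1))
}

#' Correlation of negativity bias with questionnaire scores
#'
#' Pearson correlation of the per-subject bias with each questionnaire
#' instrument (e.g. BDI-2, STAI-S, STAI-T), with two-sided p-values.
#'
#' @param bias Per-subject bias percentages (n >= 3).
#' @param scores Data frame of per-subject scores, one column per
#'   instrument; every column must have nonzero variance.
#' @return Data frame with `instrument`, `r`, `p`.
#' @export
questionnaire_correlations <- function(bias, scores) {
  scores <- as.data.frame(scores)
  stopifnot(length(bias) == nrow(scores))
  if (length(bias) < 3)
    stop_prestim("correlation needs >= 3 subjects", "invalid_input")
  out <- lapply(names(scores), function(nm) {
    s <- scores[[nm]]
    if (stats::sd(s) == 0)
      stop_prestim(paste0("constant scores for ", nm), "invalid_covariate")
    ct <- stats::cor.test(bias, s, method = "pearson")
    data.frame(instrument = nm, r = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, out)
}
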