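#' Area under the ROC curve (rank statistic)
#'
#' Exact AUROC via the Mann-Whitney U statistic with midrank tie handling:
#' the probability that a random positive scores above a random negative,
#' counting ties as 1/2.
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param labels logical (or 0/1) true labels.
#' @return AUROC in [0, 1]; `NA` if either class is absent.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-interpolated average precision: thresholds swept over distinct
#' scores in decreasing order, each recall increment weighted by the
#' precision at that threshold (the scikit-learn `average_precision`
#' convention, which does not linearly interpolate the PR curve).
#'
#' @inheritParams auroc
#' @return PR-AUC in [0, 1]; `NA` if no positives.
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n_pos <- sum(labels)
  if (n_pos == 0L) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  tp <- cumsum(lab)
  fp <- cumsum(!lab)
  # evaluate only at the last index of each distinct score (tie group ends)
  last <- c(sc[-1] != sc[-length(sc)], TRUE)
  tp <- tp[last]; fp <- fp[last]
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Calibration curve over equal-width probability bins
#'
#' Bins predicted probabilities into equal-width bins on [0, 1] and reports
#' per bin the count, mean predicted probability and observed event rate.
#'
#' @param probs predicted probabilities in [0, 1].
#' @param truth logical outcomes.
#' @param bins number of equal-width bins (default 10).
#' @return data.frame with `bin`, `n`, `mean_predicted`, `observed_rate`
#'   (NA for empty bins).
#' @export
calibration_curve <- function(probs, truth, bins = 10L) {
  if (any(probs < 0 | probs > 1, na.rm = TRUE)) {
    stop("calibration_curve: probs must be in [0, 1]")
  }
  edges <- seq(0, 1, length.out = bins + 1L)
  idx <- pmin(pmax(findInterval(probs, edges, rightmost.closed = TRUE), 1L),
              bins)
  out <- data.frame(bin = seq_len(bins),
                    lower = edges[-length(edges)], upper = edges[-1])
  out$n <- as.integer(tabulate(idx, nbins = bins))
  out$mean_predicted <- vapply(seq_len(bins), function(b) {
    if (out$n[b] == 0L) NA_real_ else mean(probs[idx == b])
  }, numeric(1))
  out$observed_rate <- vapply(seq_len(bins), function(b) {
    if (out$n[b] == 0L) NA_real_ else mean(truth[idx == b])
  }, numeric(1))
  out
}

#' Per-group AUROC with bootstrap confidence intervals
#'
#' AUROC within each group with a percentile bootstrap over encounters.
#' A group observing only one outcome class has undefined AUROC and is
#' reported with `NA` values (never silently dropped).
#'
#' @inheritParams auroc
#' @param group group membership vector (factor/character).
#' @param n_boot bootstrap replicates (default 200).
#' @param conf confidence level (default 0.95).
#' @param seed RNG seed for the bootstrap.
#' @return data.frame with `group`, `n`, `auroc`, `ci_low`, `ci_high`.
#' @export
group_auroc <- function(scores, labels, group, n_boot = 200L, conf = 0.95,
                        seed = 1L) {
  set.seed(seed)
  groups <- sort(unique(as.character(group)))
  alpha <- (1 - conf) / 2
  rows <- lapply(groups, function(g) {
    idx <- which(group == g)
    a <- auroc(scores[idx], labels[idx])
    if (is.na(a)) {
      return(data.frame(group = g, n = length(idx), auroc = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_))
    }
    boot <- vapply(seq_len(n_boot), function(i) {
      bi <- sample(idx, length(idx), replace = TRUE)
      auroc(scores[bi], labels[bi])
    }, numeric(1))
    q <- quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
    data.frame(group = g, n = length(idx), auroc = a,
               ci_low = q[1], ci_high = q[2])
  })
  do.call(rbind, rows)
}
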